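test_that("arc and chord lengths match closed-form cases", {
  p345 <- polyline(c(0, 3), c(0, 4))
  expect_equal(arc_length(p345), 5)
  expect_equal(chord_length(p345), 5)

  tri <- polyline(c(0, 1, 2), c(0, 1, 0))
  expect_equal(arc_length(tri), 2 * sqrt(2), tolerance = 1e-12)
  expect_equal(chord_length(tri), 2)

  # dense semicircle: polygonal arc within 0.1% of pi * r
  th <- seq(0, pi, length.out = 2000)
  semi <- polyline(100 * cos(th), 100 * sin(th))
  expect_equal(arc_length(semi), pi * 100, tolerance = 1e-3)
  expect_equal(chord_length(semi), 200, tolerance = 1e-9)

  # physical units scale both lengths
  pu <- polyline(c(0, 3), c(0, 4), pixel_size_um = 0.5)
  expect_equal(arc_length(pu), 2.5)
})

test_that("arc >= chord with equality only for monotone collinear points", {
  set.seed(101)
  for (i in 1:1000) {
    n <- sample(2:12, 1)
    p <- polyline(rnorm(n, sd = 50), rnorm(n, sd = 50))
    expect_gte(arc_length(p) - chord_length(p), -1e-12)
  }
  straight <- polyline(c(0, 2, 7, 10), c(0, 0, 0, 0))
  expect_equal(arc_length(straight), chord_length(straight))
})

test_that("lengths are rigid-motion invariant and scale equivariant", {
  set.seed(7)
  p <- polyline(cumsum(runif(8, 0.5, 3)), rnorm(8))
  q <- transform_polyline(p, angle_deg = 123.4, dx = -17, dy = 42)
  expect_equal(arc_length(q), arc_length(p), tolerance = 1e-12)
  expect_equal(chord_length(q), chord_length(p), tolerance = 1e-12)
  s <- polyline(3 * p$points[, 1], 3 * p$points[, 2])
  expect_equal(arc_length(s), 3 * arc_length(p), tolerance = 1e-12)
})

test_that("resampling preserves endpoints and lengths", {
  seg <- polyline(c(0, 10), c(5, 5))
  r <- resample_polyline(seg, 1)
  expect_equal(nrow(r$points), 11)
  expect_identical(r$points[1, ], seg$points[1, ])
  expect_identical(r$points[11, ], seg$points[2, ])
  expect_equal(arc_length(r), 10)
  expect_equal(chord_length(r), 10)

  # generator sinusoid: arc changes < 0.5% at spacing <= 1 px
  sin1 <- make_centerline(1.3, 400, 0, phase = 1.1)
  rs <- resample_polyline(sin1, 1)
  expect_lt(abs(arc_length(rs) - arc_length(sin1)) / arc_length(sin1), 0.005)
})

test_that("waviness follows arc/chord and rejects degenerate chords", {
  expect_equal(fiber_waviness(polyline(c(0, 10), c(0, 0))), 1)
  expect_equal(fiber_waviness(polyline(c(0, 1, 2), c(0, 1, 0))),
               sqrt(2), tolerance = 1e-9)
  loop <- polyline(c(0, 5, 0.01), c(0, 5, 0.01))
  expect_error(fiber_waviness(loop), "degenerate")
})

test_that("polyline validates its inputs", {
  expect_error(polyline(1, 1), "at least 2")
  expect_error(polyline(c(0, NA), c(0, 1)), "finite")
  expect_error(polyline(c(0, 1), c(0, 1), pixel_size_um = -1), "positive")
  # consecutive duplicates are dropped, not fatal
  p <- polyline(c(0, 0, 1), c(0, 0, 1))
  expect_equal(nrow(p$points), 2)
})
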