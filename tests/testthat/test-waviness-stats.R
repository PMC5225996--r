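test_that("hierarchical averaging follows the fibers-then-images protocol", {
  expect_equal(image_mean_waviness(rep(1.2, 10)), 1.2)
  expect_warning(m <- image_mean_waviness(c(1.1, 1.3)), "protocol")
  expect_equal(m, 1.2)
  df <- data.frame(image_id = c("a", "b"), fiber_id = 1:2,
                   arc = c(1, 1), chord = c(1, 1), waviness = c(1.1, 1.2))
  expect_error(image_mean_waviness(df), "more than one image")
  expect_error(image_mean_waviness(numeric(0)), "no fiber")

  cw <- condition_waviness(c(1.1, 1.3), "ctrl")
  expect_equal(cw$condition_mean, 1.2)
  expect_equal(cw$condition_sd, sd(c(1.1, 1.3)))
  expect_equal(cw$condition_sd, 0.1414214, tolerance = 1e-6)
  cw10 <- condition_waviness(rep(1.2, 10), "x")
  expect_equal(cw10$condition_sd, 0)
  expect_error(condition_waviness(1.2, "x"), ">= 2")
})

test_that("hierarchical mean equals the flat mean only for balanced images", {
  w_a <- c(1.10, 1.20, 1.30)          # image a, 3 fibers
  w_b <- c(1.40, 1.50)                # image b, 2 fibers
  hier <- mean(c(mean(w_a), mean(w_b)))
  flat <- mean(c(w_a, w_b))
  expect_false(isTRUE(all.equal(hier, flat)))
  # balanced case: identical
  w_b2 <- c(1.40, 1.50, 1.60)
  expect_equal(mean(c(mean(w_a), mean(w_b2))), mean(c(w_a, w_b2)))
})

test_that("the Waviness-% formula and its edge cases", {
  tr <- condition_waviness(rep(1.165, 10), "treated")
  ct <- condition_waviness(rep(1.300, 10), "control")
  expect_error(r <- waviness_percent(tr, ct), NA)
  expect_equal(r$waviness_percent, 55.0, tolerance = 1e-9)

  tr40 <- condition_waviness(rep(1.189, 10), "treated")
  expect_equal(waviness_percent(tr40, ct)$waviness_percent, 63.0,
               tolerance = 1e-9)

  same <- waviness_percent(condition_waviness(c(1.24, 1.26), "t"),
                           condition_waviness(c(1.26, 1.24), "c"))
  expect_equal(same$waviness_percent, 100)

  straight <- condition_waviness(rep(1, 5), "c")
  expect_error(waviness_percent(tr, straight), "undefined")
})

test_that("the paired t-test matches the closed-form t statistic", {
  # differences 1, 2, 3: t = mean/sd * sqrt(n) = 2/1 * sqrt(3)
  treated <- c(2, 4, 6)
  control <- c(1, 2, 3)
  r <- compare_waviness(treated, control, paired = TRUE)
  expect_equal(r$statistic, 2 * sqrt(3), tolerance = 1e-6)
  expect_equal(r$df, 2)
  expect_equal(r$p_value, 2 * pt(-2 * sqrt(3), df = 2), tolerance = 1e-9)
  expect_equal(r$p_value, 0.0742, tolerance = 1e-3)
})

test_that("identical arms give p = 1 (Welch) and error when degenerate", {
  a <- c(1.1, 1.2, 1.3)
  r <- compare_waviness(a, a, paired = FALSE)
  expect_equal(r$p_value, 1)
  expect_equal(r$statistic, 0)
  expect_error(compare_waviness(a, a, paired = TRUE), "degenerate")
  expect_error(compare_waviness(a, c(1, 2), paired = TRUE), "equal numbers")
})

test_that("measure_fibers summarizes traces correctly", {
  tr <- list(polyline(c(0, 3), c(0, 4)), polyline(c(0, 1, 2), c(0, 1, 0)))
  m <- measure_fibers(tr, "img1")
  expect_equal(m$arc, c(5, 2 * sqrt(2)))
  expect_equal(m$chord, c(5, 2))
  expect_equal(m$waviness, c(1, sqrt(2)))
  expect_equal(m$image_id, c("img1", "img1"))
})
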