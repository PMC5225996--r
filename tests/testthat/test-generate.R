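# generator-level invariants use a reduced field (128 px, proportionally
# scaled fibers) so the property suite stays fast; the brightness contract
# is scale-free by construction
small <- function(name, seed, ...) {
  preset_config(name, seed = seed, image_size = c(128L, 128L),
                fiber_length = 25, n_fibers_per_image = 9L, ...)
}

test_that("generation is bit-identical under a fixed (config, seed)", {
  s1 <- generate_condition_set(small("cfg-int-40", seed = 5, n_rabbits = 2))
  s2 <- generate_condition_set(small("cfg-int-40", seed = 5, n_rabbits = 2))
  expect_identical(s1$rabbits[[1]]$treated$pixels,
                   s2$rabbits[[1]]$treated$pixels)
  expect_identical(s1$rabbits[[2]]$control$pixels,
                   s2$rabbits[[2]]$control$pixels)
  s3 <- generate_condition_set(small("cfg-int-40", seed = 6, n_rabbits = 2))
  expect_false(identical(s1$rabbits[[1]]$treated$pixels,
                         s3$rabbits[[1]]$treated$pixels))
})

test_that("stored true_waviness matches the centerline arc/chord ratio", {
  set <- generate_condition_set(small("cfg-wav-40", seed = 3, n_rabbits = 2,
                                      fiber_length = 40,
                                      n_fibers_per_image = 4L,
                                      fiber_separation = 12))
  for (rb in set$rabbits) {
    for (arm in c("treated", "control")) {
      for (f in rb$fibers[[arm]]) {
        expect_equal(f$true_waviness, fiber_waviness(f$centerline),
                     tolerance = 1e-6)
      }
    }
  }
})

test_that("treated-minus-control mean recovers the configured difference", {
  diffs <- c()
  for (s in 1:20) {
    set <- generate_condition_set(small("cfg-int-40", seed = 400 + s,
                                        n_rabbits = 3))
    r <- condition_set_intensity(set)
    diffs <- c(diffs, r$per_rabbit_differences)
  }
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs) - 66.3), 3 * se)
  # the spread reflects the configured per-animal treatment variability
  expect_gt(sd(diffs), 10)
  expect_lt(sd(diffs), 50)
})

test_that("zero-offset configuration has zero expected difference", {
  cfg <- small("cfg-null", seed = 17, n_rabbits = 4)
  expect_equal(cfg$expected_mean_difference, 0)
  set <- generate_condition_set(cfg)
  r <- condition_set_intensity(set)
  # per-pair differences are pure treatment-effect noise (SD ~ 28)
  expect_lt(abs(r$mean_difference), 3 * 28 / sqrt(4) * 2)
})

test_that("clean image mean equals background + offset exactly (no noise)", {
  cfg <- small("cfg-int-40", seed = 23, n_rabbits = 2,
               noise = noise_model("none"), rabbit_intercept_sd = 0,
               difference_sd = 0)
  set <- generate_condition_set(cfg)
  for (rb in set$rabbits) {
    # pixel rounding moves the realized mean by well under a count
    expect_equal(mean_pixel_density(rb$control), 500 + 100, tolerance = 0.05)
    expect_equal(mean_pixel_density(rb$treated), 500 + 166.3,
                 tolerance = 0.05)
  }
})

test_that("config validation catches bad parameters", {
  expect_error(generator_config("x", waviness_control = 0.8), ">= 1")
  expect_error(generator_config("x", n_rabbits = 1), "n_rabbits")
  expect_error(generator_config("x", fiber_intensity_offset_control = -5),
               ">= 0")
  expect_error(preset_config("no-such-preset"), "unknown preset")
  expect_error(generator_config("x", expected_mean_difference = 10),
               "must equal")
  ok <- generator_config("x", fiber_intensity_offset_treated = 150,
                         fiber_intensity_offset_control = 100,
                         expected_mean_difference = 50)
  expect_equal(ok$expected_mean_difference, 50)
})

test_that("overfull fields fail with a capacity error", {
  expect_error(
    generate_condition_set(small("cfg-int-40", seed = 1, n_rabbits = 2,
                                 n_fibers_per_image = 500L)),
    "cannot place")
})

test_that("Tm tables: reproducibility, shifts, and validation", {
  cfg <- tm_preset("cfg-tm-400-insitu", seed = 12)
  t1 <- generate_tm_table(cfg)
  t2 <- generate_tm_table(cfg)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 3 * 16)

  # zero noise: sector 2 shifted by exactly 13, all others 0
  t0 <- generate_tm_table(tm_preset("cfg-tm-400-insitu", seed = 1,
                                    noise_sd = 0))
  d <- t0$treated_tm - t0$control_tm
  expect_true(all(d[t0$sector == 2] == 13))
  expect_true(all(d[t0$sector != 2] == 0))

  expect_error(tm_table_config(n_rabbits = 1), ">= 2")
  expect_warning(tm_table_config(n_rabbits = 2), "minimum of 3")
  expect_error(tm_table_config(sector_shifts = c(`17` = 1)), "1..16")
  expect_error(tm_table_config(noise_sd = -1), ">= 0")
})
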