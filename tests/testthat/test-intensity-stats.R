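test_that("histogram mean equals the direct pixel mean exactly", {
  img <- image16(matrix(c(0L, 100L, 200L, 300L), 2, 2))
  h <- image_histogram(img)
  expect_equal(h$mean, 150)
  expect_equal(mean_pixel_density(img), 150)
  expect_equal(sum(h$counts), h$n_pixels)

  const <- image16(matrix(500L, 8, 8))
  hc <- image_histogram(const)
  expect_equal(hc$mean, 500)
  expect_equal(sum(hc$counts > 0), 1)

  set.seed(12)
  rnd <- image16(matrix(sample.int(4096, 900, TRUE) - 1L, 30, 30))
  expect_identical(image_histogram(rnd)$mean, mean_pixel_density(rnd))
})

test_that("paired analysis reports differences, SD and t-test", {
  treated <- c(510, 530, 550, 570)
  control <- c(500, 505, 520, 515)
  r <- paired_intensity_analysis(treated, control)
  d <- treated - control
  expect_equal(r$per_rabbit_differences, d)
  expect_equal(r$mean_difference, mean(d))
  expect_equal(r$sd_difference, sd(d))
  expect_equal(r$p_value, t.test(d)$p.value)
  expect_false(r$degenerate)

  same <- paired_intensity_analysis(treated, treated)
  expect_true(same$degenerate)
  expect_equal(same$mean_difference, 0)
  expect_true(is.na(same$p_value))
  expect_error(paired_intensity_analysis(1, 1), ">= 2")
  expect_error(paired_intensity_analysis(1:3, 1:2), "paired")
})

test_that("balanced mixed-model contrast equals the mean paired difference", {
  set.seed(42)
  for (i in 1:5) {
    n <- sample(4:8, 1)
    ic <- rnorm(n, 0, 10)
    ctrl <- 500 + ic + rnorm(n, 0, 5)
    trt <- 566 + ic + rnorm(n, 0, 5)
    obs <- data.frame(rabbit = rep(seq_len(n), 2),
                      condition = rep(c("ctrl", "trt"), each = n),
                      value = c(ctrl, trt))
    fit <- fit_random_intercept(obs, reference = "ctrl")
    expect_equal(unname(fit$condition_effects["trt"]), mean(trt - ctrl),
                 tolerance = 1e-8)
    expect_gte(fit$rabbit_intercept_variance, 0)
    expect_gte(fit$residual_variance, 0)
  }
})

test_that("noiseless observations are recovered exactly, contrasts antisymmetric", {
  ic <- c(-8, 3, 12, 0, -5)
  obs <- data.frame(rabbit = rep(1:5, 3),
                    condition = rep(c("c0", "c40", "c400"), each = 5),
                    value = c(ic + 500, ic + 566.3, ic + 861.4))
  fit <- suppressWarnings(fit_random_intercept(obs, reference = "c0"))
  expect_equal(unname(fit$condition_effects["c40"]), 66.3, tolerance = 1e-6)
  expect_equal(unname(fit$condition_effects["c400"]), 361.4, tolerance = 1e-6)
  pc <- fit$pairwise_contrasts
  # each pair appears once; a-vs-b estimate equals effect difference
  expect_equal(nrow(pc), 3)
  i <- which(pc$a == "c400" & pc$b == "c40" | pc$a == "c40" & pc$b == "c400")
  expect_equal(abs(pc$estimate[i]), 361.4 - 66.3, tolerance = 1e-6)
})

test_that("mixed model rejects unidentifiable designs", {
  obs1 <- data.frame(rabbit = 1, condition = c("a", "b"), value = c(1, 2))
  expect_error(fit_random_intercept(obs1), "single rabbit")
  obs2 <- data.frame(rabbit = 1:4, condition = "a", value = 1:4)
  expect_error(fit_random_intercept(obs2), ">= 2 conditions")
})

test_that("type-I error of the condition contrast is near alpha", {
  set.seed(202)
  hits <- 0
  n_sim <- 100
  for (i in 1:n_sim) {
    n <- 10
    ic <- rnorm(n, 0, 10)
    obs <- data.frame(rabbit = rep(seq_len(n), 2),
                      condition = rep(c("ctrl", "trt"), each = n),
                      value = c(500 + ic + rnorm(n, 0, 20),
                                500 + ic + rnorm(n, 0, 20)))
    fit <- suppressWarnings(fit_random_intercept(obs, reference = "ctrl"))
    p <- fit$pairwise_contrasts$p_value[1]
    if (p < 0.05) hits <- hits + 1
  }
  # Wald/normal inference is slightly liberal at n = 10; binomial band
  # around alpha = 0.05 plus that liberality
  expect_gte(hits, 1)
  expect_lte(hits, 15)
})
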