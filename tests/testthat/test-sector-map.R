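make_table <- function(diffs_by_sector, n_rabbits = 3, baseline = 65) {
  do.call(rbind, lapply(seq_len(n_rabbits), function(r) {
    data.frame(rabbit_id = r, sector = 1:16,
               treated_tm = baseline + diffs_by_sector[, r],
               control_tm = baseline)
  }))
}

test_that("per-sector deltas: means and sample SDs", {
  d <- matrix(0, 16, 3)
  d[7, ] <- c(3, 4, 5)
  tab <- make_table(d)
  res <- sector_delta(tab)
  expect_equal(nrow(res), 16)
  expect_equal(res$delta_mean[res$sector == 7], 4)
  expect_equal(res$delta_sd[res$sector == 7], 1)
  expect_equal(res$delta_mean[res$sector == 1], 0)
  expect_equal(res$n, rep(3, 16))
})

test_that("identical arms give all-zero deltas and degenerate tests", {
  tab <- make_table(matrix(0, 16, 3))
  res <- sector_tests(tab)
  expect_true(all(res$delta_mean == 0))
  expect_true(all(res$delta_sd == 0))
  expect_true(all(res$degenerate))
  expect_true(all(res$p_value == 1))
  expect_false(any(res$significant))
})

test_that("noise-free preset tables recover shifts exactly", {
  cfg <- tm_preset("cfg-tm-40-map", seed = 4, noise_sd = 0)
  tab <- generate_tm_table(cfg)
  res <- sector_tests(tab)
  for (s in 1:3) {
    expect_equal(res$delta_mean[res$sector == s], 3.4, tolerance = 1e-12)
  }
  for (s in 14:16) {
    expect_equal(res$delta_mean[res$sector == s], 0, tolerance = 1e-12)
  }
  # nonzero shift with zero variance: limit-significant, flagged degenerate
  expect_true(all(res$degenerate))
  expect_true(all(res$significant[res$sector %in% 1:3]))
  expect_false(any(res$significant[res$sector %in% 14:16]))
})

test_that("delta antisymmetry under arm swap; p-values unchanged", {
  cfg <- tm_preset("cfg-tm-400-map", seed = 9)
  tab <- generate_tm_table(cfg)
  swapped <- transform(tab, treated_tm = control_tm, control_tm = treated_tm)
  a <- sector_tests(tab)
  b <- sector_tests(swapped)
  expect_equal(b$delta_mean, -a$delta_mean)
  expect_equal(b$p_value, a$p_value, tolerance = 1e-12)
})

test_that("validation: duplicates fail, missing sectors warn", {
  tab <- make_table(matrix(0, 16, 2), n_rabbits = 2)
  expect_error(sector_delta(rbind(tab, tab[1, ])), "duplicate")
  part <- tab[tab$sector != 9, ]
  expect_warning(res <- sector_delta(part), "sector")
  expect_false(9 %in% res$sector)
})

test_that("null tables reject each sector at about the alpha rate", {
  set.seed(303)
  n_sim <- 200
  rejections <- 0
  total <- 0
  for (i in 1:n_sim) {
    cfg <- suppressWarnings(
      tm_table_config(n_rabbits = 3, sector_shifts = numeric(16),
                      noise_sd = 0.5, seed = 30000 + i))
    res <- sector_tests(generate_tm_table(cfg))
    rejections <- rejections + sum(res$significant)
    total <- total + nrow(res)
  }
  rate <- rejections / total
  bounds <- qbinom(c(0.0025, 0.9975), total, 0.05) / total
  expect_gte(rate, bounds[1])
  expect_lte(rate, bounds[2])
})

test_that("zone of effect lists significant sectors and renders the map", {
  d <- matrix(0, 16, 3)
  d[2, ] <- c(3.3, 3.4, 3.5)
  res <- sector_tests(make_table(d))
  z <- zone_of_effect(res)
  expect_equal(z$sectors, 2)
  expect_length(z$text, 4)
  expect_true(any(grepl("\\*", z$text)))
  empty <- zone_of_effect(sector_tests(make_table(matrix(0, 16, 3))))
  expect_equal(empty$sectors, integer(0))
})

test_that("Bonferroni option shrinks the significant set", {
  set.seed(8)
  d <- matrix(rnorm(48, 0, 0.4), 16, 3)
  d[2, ] <- d[2, ] + 1.2
  tab <- make_table(d)
  raw <- sector_tests(tab)
  adj <- sector_tests(tab, p_adjust = "bonferroni")
  expect_lte(sum(adj$significant), sum(raw$significant))
})
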