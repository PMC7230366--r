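# Cohort statistics: regression, correlations, mixed models,
# sample size, group comparisons.

test_that("regression recovers a noiseless slope per 10 kg exactly", {
  d <- tibble::tibble(weight = c(60, 75, 90, 110, 130, 150),
                      sex = c("F", "M", "F", "M", "F", "M"),
                      auc = 50 - 0.169 * c(60, 75, 90, 110, 130, 150))
  fit <- auc_weight_regression(d, "auc", "weight")
  expect_equal(fit$slope_per_10, -1.69, tolerance = 1e-12)
  expect_equal(fit$ci95, c(-1.69, -1.69), tolerance = 1e-9)
  # single-sex data drop the sex covariate rather than failing
  d$sex <- "F"
  expect_equal(auc_weight_regression(d, "auc", "weight")$slope_per_10,
               -1.69, tolerance = 1e-12)
})

test_that("degenerate regression designs error", {
  d <- tibble::tibble(weight = rep(80, 6), sex = rep(c("F", "M"), 3),
                      auc = rnorm(6))
  expect_error(auc_weight_regression(d, "auc", "weight"),
               class = "tpk_invalid_input")
  expect_error(auc_weight_regression(d[1:3, ], "auc", "weight"),
               class = "tpk_invalid_input")
})

test_that("Fisher-Z interval matches its closed form and round-trips", {
  ci <- fisher_ci(-0.61, 30)
  z <- atanh(-0.61) + c(-1, 1) * qnorm(0.975) / sqrt(27)
  expect_equal(ci, tanh(z), tolerance = 1e-12)
  # round trip: the z-scale midpoint of the CI is r
  expect_equal(tanh(mean(atanh(ci))), -0.61, tolerance = 1e-12)
})

test_that("correlation_fisher reports r, CI and p consistently", {
  set.seed(10)
  x <- rnorm(30)
  y <- -0.7 * x + rnorm(30, 0, 0.6)
  res <- correlation_fisher(x, y)
  expect_equal(res$r, cor(x, y))
  expect_equal(res$ci95, fisher_ci(res$r, 30))
  expect_equal(res$p, cor.test(x, y)$p.value, tolerance = 1e-12)
  td <- tidy(res)
  expect_named(td, c("estimate", "conf.low", "conf.high", "p.value", "n",
                     "method"))
})

test_that("perfect correlation yields degenerate bounds, not an error", {
  x <- 1:10
  res <- correlation_fisher(x, 2 * x + 3)
  expect_equal(res$r, 1)
  expect_equal(res$ci95, c(1, 1))
  expect_equal(res$p, 0)
  expect_error(correlation_fisher(x, rep(1, 10)), class = "tpk_invalid_input")
  expect_error(correlation_fisher(x[1:3], x[1:3]), class = "tpk_invalid_input")
})

test_that("robust correlation resists a single extreme subject", {
  set.seed(12)
  w <- rnorm(29, 90, 20)
  auc <- 40 - 0.12 * w + rnorm(29, 0, 3)
  w <- c(w, 230) # one extreme body weight
  auc <- c(auc, 35) # exposure not following the trend
  pearson_all <- correlation_fisher(w, auc)$r
  pearson_drop <- correlation_fisher(w[-30], auc[-30])$r
  robust_all <- correlation_fisher(w, auc, robust = TRUE)$r
  # the recompute without the outlier changes Pearson's r; the robust
  # estimate with the outlier stays closer to that recomputed value
  expect_gt(abs(pearson_all - pearson_drop), 0.02)
  expect_lt(abs(robust_all - pearson_drop),
            abs(pearson_all - pearson_drop))
})

test_that("zero-noise longitudinal data are recovered exactly", {
  d <- simulate_longitudinal(n_per_group = 4, sd_intercept = 0,
                             sd_slope = 0, sd_resid = 0,
                             catheter_ratio = 0.95, seed = 1)
  fit <- suppressWarnings(longitudinal_mixed_model(d))
  expect_equal(fit$group_ratio, 0.52, tolerance = 1e-6)
  expect_equal(fit$decline_rate_ratio, 1.06, tolerance = 1e-6)
  expect_equal(fit$catheter_ratio, 0.95, tolerance = 1e-6)
})

test_that("a symmetric-catheter simulation keeps the catheter CI around 1", {
  d <- simulate_longitudinal(n_per_group = 10, catheter_ratio = 1, seed = 21)
  fit <- longitudinal_mixed_model(d)
  expect_lt(fit$catheter_ratio_ci[1], 1)
  expect_gt(fit$catheter_ratio_ci[2], 1)
  td <- tidy(fit)
  expect_equal(td$term,
               c("group_ratio", "decline_rate_ratio", "catheter_ratio"))
  gl <- glance(fit)
  expect_true(all(c("sigma", "re_sd_intercept", "singular_fallback") %in%
                    names(gl)))
})

test_that("mixed-model ratios ignore a common concentration rescaling", {
  d <- simulate_longitudinal(n_per_group = 5, seed = 31)
  f1 <- longitudinal_mixed_model(d)
  f2 <- longitudinal_mixed_model(dplyr::mutate(d, conc = conc * 100))
  expect_equal(f1$group_ratio, f2$group_ratio, tolerance = 1e-6)
  expect_equal(f1$decline_rate_ratio, f2$decline_rate_ratio,
               tolerance = 1e-6)
})

test_that("sample-size formula gives the study's planning value", {
  expect_equal(sample_size_correlation(0.52, 0.80, 0.05), 27L)
  expect_equal(sample_size_correlation(0.999), 4L) # r -> 1 limit
  expect_equal(sample_size_correlation(0.5, power = 1e-6), 4L)
  expect_error(sample_size_correlation(0), class = "tpk_invalid_input")
  expect_error(sample_size_correlation(1.2), class = "tpk_invalid_input")
})

test_that("allometric cohorts show a significant negative exposure-weight slope", {
  hits <- 0L
  for (s in 1:10) {
    cfg <- cohort_config(n_per_group = 15, seed = 400 + s,
                         allometric = TRUE)
    coh <- draw_cohort(cfg)
    pl <- simulate_plasma(coh, cfg) |>
      dplyr::filter(.data$matrix == "plasma_unbound")
    res <- nca(pl |> dplyr::mutate(matrix = "plasma_unbound")) |>
      dplyr::left_join(coh[c("subject_id", "weight", "sex")],
                       by = "subject_id")
    fit <- auc_weight_regression(res, "auc_0_8", "weight")
    if (fit$slope_per_10 < 0 && fit$p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 8L) # negative, significant in at least 80% of seeds
})

test_that("group comparison handles shifted, identical and ratio scales", {
  d <- tibble::tibble(group = rep(c("obese", "non_obese"), each = 4),
                      v = c(41, 42, 40, 43, 31, 32, 30, 33))
  res <- group_compare(d, "v")
  expect_equal(res$estimate, 10)
  expect_lt(res$p, 0.01)
  expect_true(res$ci_lo < 10 && res$ci_hi > 10)
  same <- tibble::tibble(group = rep(c("obese", "non_obese"), each = 3),
                         v = rep(5, 6))
  res0 <- group_compare(same, "v")
  expect_equal(res0$estimate, 0)
  expect_equal(res0$p, 1)
  ratio <- group_compare(d, "v", log_scale = TRUE)
  expect_equal(ratio$estimate, exp(mean(log(d$v[1:4])) - mean(log(d$v[5:8]))))
  expect_equal(ratio$scale, "ratio")
  rank_res <- group_compare(d, "v", method = "wilcoxon")
  expect_lt(rank_res$p, 0.05)
  expect_error(group_compare(d[1:5, ][-1, ], "v"))
})
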