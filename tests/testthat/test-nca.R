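# Non-compartmental analysis operations.

test_that("terminal regression recovers an exact exponential", {
  prof <- mono_profile(10, 0.2, c(4, 5, 6, 8))
  fit <- fit_lambda_z(prof)
  expect_true(fit$estimable)
  expect_equal(fit$lambda_z, 0.2, tolerance = 1e-10)
  expect_equal(fit$t_half, log(2) / 0.2, tolerance = 1e-10)
  expect_equal(fit$n_points, 3L) # Tmax at 4 h is excluded
  expect_equal(predict(fit, 8), 10 * exp(-1.6), tolerance = 1e-10)
})

test_that("terminal regression reports not-estimable cases", {
  flat <- tibble::tibble(t = 1:6, conc = rep(5, 6), blq = FALSE)
  expect_false(fit_lambda_z(flat)$estimable)
  few <- mono_profile(10, 0.2, c(1, 2, 3))
  expect_false(fit_lambda_z(few)$estimable)
  rising <- tibble::tibble(t = 1:5, conc = 1:5, blq = FALSE)
  expect_false(fit_lambda_z(rising)$estimable)
})

test_that("window selection matches a brute-force search on noisy profiles", {
  sched <- plasma_schedule()
  for (s in 1:20) {
    set.seed(s)
    m <- example_model(CL = runif(1, 5, 11), V1 = runif(1, 10, 25),
                       V2 = runif(1, 10, 25), Q = runif(1, 8, 25))
    conc <- m$conc_plasma(sched) * (1 + rnorm(length(sched), 0, 0.1))
    prof <- tibble::tibble(t = sched, conc = pmax(conc, 0.01), blq = FALSE)
    fit <- fit_lambda_z(prof)
    oracle <- brute_lambda_z(prof$t, prof$conc)
    expect_equal(fit$window[1], oracle$window[1])
    expect_equal(fit$lambda_z, oracle$lambda, tolerance = 1e-9)
  }
})

test_that("linear-up/log-down segments match their closed forms", {
  up <- tibble::tibble(t = c(0, 0.5), conc = c(0, 10), blq = FALSE)
  expect_equal(auc_lin_up_log_down(up), 2.5)
  down <- tibble::tibble(t = c(0, 1), conc = c(10, 5), blq = FALSE)
  expect_equal(auc_lin_up_log_down(down), 5 / log(2), tolerance = 1e-12)
  one <- tibble::tibble(t = 1, conc = 5, blq = FALSE)
  expect_error(auc_lin_up_log_down(one), class = "tpk_not_estimable")
})

test_that("log-down integration is exact on exponential decline", {
  lam <- 0.31
  prof <- mono_profile(12, lam, c(0, 0.5, 1, 2, 3, 5, 8))
  expect_equal(auc_lin_up_log_down(prof),
               12 / lam * (1 - exp(-lam * 8)), tolerance = 1e-12)
  # dense sampling of a hump-shaped curve against quadrature
  m <- example_model()
  tt <- seq(0, 8, by = 0.02)
  prof2 <- tibble::tibble(t = tt, conc = m$conc_plasma(tt), blq = FALSE)
  expect_equal(auc_lin_up_log_down(prof2),
               quad_oracle(m$conc_plasma, 0, 8, n = 100001),
               tolerance = 1e-4)
})

test_that("partial AUC interpolates the bracketing segment with the same rule", {
  lam <- 0.25
  prof <- mono_profile(10, lam, c(0.5, 1, 2, 3))
  expect_equal(auc_lin_up_log_down(prof, t_end = 2.5),
               10 / lam * (exp(-lam * 0.5) - exp(-lam * 2.5)),
               tolerance = 1e-12)
  expect_error(auc_lin_up_log_down(prof, t_end = 4),
               class = "tpk_invalid_input")
})

test_that("AUC is additive over interior sample points", {
  set.seed(8)
  for (i in 1:10) {
    tt <- sort(runif(9, 0, 8))
    prof <- tibble::tibble(t = c(0, tt), conc = c(0, runif(9, 0.5, 20)),
                           blq = FALSE)
    a <- prof$t[5]
    full <- auc_lin_up_log_down(prof)
    left <- auc_lin_up_log_down(prof, t_end = a)
    right <- auc_lin_up_log_down(prof[prof$t >= a, ])
    expect_equal(left + right, full, tolerance = 1e-12)
  }
})

test_that("log trapezoid never exceeds the linear trapezoid when declining", {
  set.seed(9)
  for (i in 1:50) {
    c1 <- runif(1, 1, 20)
    c2 <- runif(1, 0.01, c1 * 0.999)
    dt <- runif(1, 0.1, 3)
    prof <- tibble::tibble(t = c(0, dt), conc = c(c1, c2), blq = FALSE)
    expect_lte(auc_lin_up_log_down(prof), (c1 + c2) / 2 * dt)
  }
})

test_that("extrapolation uses the predicted last concentration", {
  prof <- mono_profile(10, 0.2, c(0, 1, 2, 4, 6, 8))
  fit <- fit_lambda_z(prof)
  ext <- extrapolate_auc(prof, fit)
  expect_equal(ext$tail, predict(fit, 8) / 0.2, tolerance = 1e-10)
  expect_equal(ext$auc_inf, 10 / 0.2, tolerance = 1e-10) # C0 / lambda
  expect_equal(ext$pct_extrap, 100 * exp(-1.6), tolerance = 1e-8)
  # direct arithmetic: C_hat = 2, lambda = 0.2 -> tail = 10
  expect_equal(2 / fit$lambda_z, 10, tolerance = 1e-10)
})

test_that("moments and MRT match closed forms", {
  lam <- 0.2
  # moment trapezoids on t*C are not exact on an exponential: use a
  # dense grid so discretisation error is negligible
  prof <- mono_profile(10, lam, seq(0, 30, by = 0.1))
  fit <- fit_lambda_z(prof)
  mom <- nca_moments(prof, fit, t_inf = 0)
  expect_equal(mom$aumc_inf, 10 / lam^2, tolerance = 1e-4)
  expect_equal(mom$mrt, 1 / lam, tolerance = 1e-4) # bolus: MRT = 1/lambda
  # infusion correction: minus half the infusion time
  mom2 <- nca_moments(prof, fit, t_inf = 0.5)
  expect_equal(mom$mrt - mom2$mrt, 0.25)
})

test_that("two-compartment MRT estimate matches the analytic moment identity", {
  m <- example_model()
  tt <- c(seq(0, 12, by = 0.1), seq(12.5, 48, by = 0.5))
  prof <- tibble::tibble(t = tt, conc = m$conc_plasma(tt), blq = FALSE)
  fit <- fit_lambda_z(prof)
  ext <- extrapolate_auc(prof, fit)
  mom <- nca_moments(prof, fit, t_inf = 0.5)
  expect_equal(mom$mrt, m$vss / m$params$CL, tolerance = 0.02)
  expect_equal(ext$auc_inf, m$auc_plasma_inf, tolerance = 0.005)
})

test_that("clearance and Vss follow their defining ratios, plasma only", {
  prof <- tibble::tibble(t = 0:3, conc = c(1, 2, 1, 0.5), blq = FALSE,
                         matrix = "plasma_total")
  clv <- clearance_vss(prof, auc_inf = 60, mrt = 4.75, dose = 600)
  expect_equal(clv$cl, 10)
  expect_equal(clv$vss, 47.5)
  isf_prof <- dplyr::mutate(prof, matrix = "isf")
  expect_error(clearance_vss(isf_prof, 60, 4.75),
               class = "tpk_contract_violation")
})

test_that("daily AUC doubles the single-dose extrapolated AUC", {
  expect_equal(auc24(60), 120)
  expect_error(auc24(0), class = "tpk_invalid_input")
  expect_error(auc24(-2), class = "tpk_invalid_input")
})

test_that("Cmax/Tmax with tie-break and BLQ handling", {
  prof <- tibble::tibble(t = c(0, 1, 2, 3), conc = c(0, 7, 7, 2),
                         blq = c(TRUE, FALSE, FALSE, FALSE))
  ct <- cmax_tmax(prof)
  expect_equal(ct$cmax, 7)
  expect_equal(ct$tmax, 1) # earliest of the tie
  allblq <- tibble::tibble(t = 1:3, conc = rep(NA_real_, 3), blq = TRUE)
  expect_error(cmax_tmax(allblq), class = "tpk_not_estimable")
})

test_that("every NCA output matches closed form on a noiseless exponential", {
  lam <- log(2) / 3.4
  c0 <- 18
  v_true <- 600 / c0
  prof <- tibble::tibble(subject_id = "S01", matrix = "plasma_total",
                         t = plasma_schedule(),
                         conc = c0 * exp(-lam * plasma_schedule()),
                         blq = FALSE)
  prof$conc[prof$t == 0] <- c0 # bolus-like: defined at t = 0
  res <- nca(prof, dose = 600, t_inf = 0)
  expect_equal(res$lambda_z, lam, tolerance = 1e-3)
  expect_equal(res$t_half, 3.4, tolerance = 1e-3)
  expect_equal(res$auc_inf, c0 / lam, tolerance = 1e-3)
  # MRT carries the moment-trapezoid discretisation of the 8 h schedule
  expect_equal(res$mrt, 1 / lam, tolerance = 5e-3)
  expect_equal(res$cl, 600 / (c0 / lam), tolerance = 1e-3)
  expect_equal(res$vss, v_true, tolerance = 5e-3)
  expect_equal(res$auc_24, 2 * res$auc_inf)
  expect_equal(res$cmax, c0)
})

test_that("NCA is scale-equivariant", {
  cfg <- noiseless_config()
  coh <- draw_cohort(cfg)
  pl <- simulate_plasma(coh, cfg) |>
    dplyr::filter(.data$subject_id == "S01", .data$matrix == "plasma_total")
  base <- nca(pl)
  k <- 3.7
  scaled <- nca(dplyr::mutate(pl, conc = .data$conc * k))
  expect_equal(scaled$auc_0_8, k * base$auc_0_8, tolerance = 1e-10)
  expect_equal(scaled$auc_inf, k * base$auc_inf, tolerance = 1e-10)
  expect_equal(scaled$aumc_inf, k * base$aumc_inf, tolerance = 1e-10)
  expect_equal(scaled$cmax, k * base$cmax, tolerance = 1e-10)
  expect_equal(scaled$lambda_z, base$lambda_z, tolerance = 1e-10)
  expect_equal(scaled$mrt, base$mrt, tolerance = 1e-10)
  expect_equal(scaled$cl, base$cl / k, tolerance = 1e-10)
  expect_equal(scaled$vss, base$vss / k, tolerance = 1e-10)
})

test_that("noiseless dense-sampled cohort recovers CL and Vss", {
  cfg <- noiseless_config()
  coh <- draw_cohort(cfg)
  dense <- simulate_plasma(coh, cfg, times = c(seq(0, 12, 0.25), seq(13, 36, 1)))
  res <- nca(dense |> dplyr::filter(.data$matrix == "plasma_total"),
             dose = 600, t_inf = 0.5, t_end = 8)
  expect_equal(res$cl, coh$true_cl, tolerance = 0.05)
  expect_equal(res$vss, coh$true_vss, tolerance = 0.10)
})

test_that("duplicate sample times are rejected", {
  prof <- tibble::tibble(t = c(0, 1, 1, 2), conc = c(0, 3, 3, 1), blq = FALSE)
  expect_error(fit_lambda_z(prof), class = "tpk_invalid_input")
})
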