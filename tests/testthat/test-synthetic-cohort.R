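# Cohort generator: covariates, determinism, noise and BLQ handling.

test_that("cohort draws match the study design", {
  cfg <- cohort_config(n_per_group = 15, seed = 1)
  coh <- draw_cohort(cfg)
  expect_equal(nrow(coh), 30)
  expect_equal(unname(table(coh$group))[order(names(table(coh$group)))],
               c(15, 15), ignore_attr = TRUE)
  expect_true(all(coh$weight > 0))
  expect_true(all(coh$bmi[coh$group == "obese"] >= 35))
  expect_true(all(dplyr::between(coh$bmi[coh$group == "non_obese"],
                                 18.5, 30)))
  # 87% female per group (13 of 15)
  expect_equal(sum(coh$sex == "F"), 26)
  # BMI is consistent with weight / height^2
  expect_equal(coh$bmi, coh$weight / coh$height^2, tolerance = 1e-10)
  # weights centred near the reported group means (wide tolerance:
  # n = 15 draws of sd 34.3 / 8.8)
  expect_equal(mean(coh$weight[coh$group == "obese"]), 134.3,
               tolerance = 0.25)
  expect_equal(mean(coh$weight[coh$group == "non_obese"]), 67.9,
               tolerance = 0.1)
})

test_that("zero variability collapses draws to group means", {
  coh <- draw_cohort(noiseless_config(n_per_group = 2))
  expect_equal(coh$weight, c(134.3, 134.3, 67.9, 67.9))
  expect_equal(coh$CL, c(8.2, 8.2, 7.0, 7.0))
  expect_equal(coh$recovery_left, rep(0.48, 4))
  expect_equal(coh$true_vss, c(41, 41, 30.8, 30.8))
})

test_that("a fixed seed gives bit-identical cohorts and data", {
  cfg <- cohort_config(n_per_group = 3, seed = 99)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$subjects, s2$subjects)
  expect_identical(s1$data, s2$data)
  expect_identical(s1$calibration, s2$calibration)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_per_group = 0), class = "tpk_invalid_config")
  expect_error(cohort_config(dose = -600), class = "tpk_invalid_config")
  expect_error(cohort_config(fu = 1.2), class = "tpk_invalid_config")
  expect_error(cohort_config(group_params = list(obese = list(CL = -1))),
               class = "tpk_invalid_config")
  expect_error(cohort_config(group_params = list(lean = list(CL = 5))),
               class = "tpk_invalid_config")
})

test_that("noiseless plasma AUC matches dose/CL and baseline is zero", {
  cfg <- noiseless_config(lloq = 0) # keep the full tail quantifiable
  coh <- draw_cohort(cfg)
  dense <- simulate_plasma(coh, cfg, times = seq(0, 96, by = 0.02))
  one <- dense[dense$subject_id == "S01" & dense$matrix == "plasma_total", ]
  auc <- sum((one$conc[-1] + one$conc[-nrow(one)]) / 2 * diff(one$t))
  expect_equal(auc, 600 / 8.2, tolerance = 0.005)
  pl <- simulate_plasma(coh, noiseless_config())
  expect_true(all(pl$blq[pl$t == 0])) # 0 mg/L is below the LLOQ
})

test_that("obese unbound Cmax is lower than non-obese at group medians", {
  cfg <- noiseless_config()
  coh <- draw_cohort(cfg)
  pl <- simulate_plasma(coh, cfg)
  cmax <- pl |>
    dplyr::filter(.data$matrix == "plasma_unbound", !.data$blq) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(cmax = max(.data$conc), .groups = "drop")
  expect_lt(cmax$cmax[cmax$group == "obese"],
            cmax$cmax[cmax$group == "non_obese"])
})

test_that("dialysate intervals scale the true ISF average by the recovery", {
  cfg <- noiseless_config()
  coh <- draw_cohort(cfg)
  dial <- simulate_microdialysate(coh, cfg)
  sub <- coh[1, ]
  m <- pk_model(CL = sub$CL, V1 = sub$V1, V2 = sub$V2, Q = sub$Q,
                dose = cfg$dose, t_inf = cfg$t_inf, fu = cfg$fu,
                k_isf = sub$k_isf, penetration = sub$penetration)
  d1 <- dial[dial$subject_id == "S01" & dial$catheter == "left", ]
  truth <- m$isf_interval_avg(d1$t_start, d1$t_end) * 0.48
  got <- ifelse(d1$blq, 0, d1$conc)
  expect_equal(got[!d1$blq], truth[!d1$blq], tolerance = 1e-12)
  expect_true(all(d1$blq == (truth < cfg$lloq)))
})

test_that("calibration pairs encode the catheter recovery exactly at zero noise", {
  cfg <- noiseless_config(n_per_group = 2)
  coh <- draw_cohort(cfg)
  cal <- simulate_calibration(coh, cfg)
  expect_equal(1 - cal$c_rd / cal$c_rp, cal$recovery, tolerance = 1e-12)
})

test_that("all emitted concentrations are non-negative and BLQ iff < LLOQ", {
  cfg <- cohort_config(n_per_group = 5, seed = 7)
  sim <- simulate_cohort(cfg)
  vals <- sim$data$conc_mg_L
  expect_true(all(vals[!is.na(vals)] >= 0))
  expect_true(all(vals[!is.na(vals)] >= cfg$lloq)) # quantifiable values
  expect_true(all(is.na(sim$data$conc_mg_L[sim$data$blq])))
})

test_that("median unbound AUC ratio across groups tracks the inverse CL ratio", {
  coh <- draw_cohort(cohort_config(n_per_group = 200, seed = 11))
  med <- coh |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(auc = median(.data$true_fauc_plasma), .groups = "drop")
  ratio <- med$auc[med$group == "obese"] / med$auc[med$group == "non_obese"]
  expect_equal(ratio, 7.0 / 8.2, tolerance = 0.1) # Monte-Carlo slack
})

test_that("allometric mode induces a negative exposure-weight trend", {
  cfg <- cohort_config(n_per_group = 60, seed = 5, allometric = TRUE)
  coh <- draw_cohort(cfg)
  expect_lt(cor(coh$weight, coh$true_fauc_plasma), -0.3)
})

test_that("longitudinal generator reproduces its own truth at zero noise", {
  d <- simulate_longitudinal(n_per_group = 3, sd_intercept = 0, sd_slope = 0,
                             sd_resid = 0, catheter_ratio = 0.95, seed = 2)
  ob <- d[d$group == "obese" & d$catheter == "left", ]
  no <- d[d$group == "non_obese" & d$catheter == "left", ]
  t1 <- d$t[1]
  # level ratio at t = 0 and slope ratio match the construction
  fit_ob <- lm(log(conc) ~ t, data = ob)
  fit_no <- lm(log(conc) ~ t, data = no)
  expect_equal(exp(coef(fit_ob)[1] - coef(fit_no)[1]), c("(Intercept)" = 0.52))
  expect_equal(unname(coef(fit_ob)[2] / coef(fit_no)[2]), 1.06)
  right <- d[d$group == "obese" & d$catheter == "right", ]
  expect_equal(right$conc / ob$conc, rep(0.95, nrow(ob)))
})
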