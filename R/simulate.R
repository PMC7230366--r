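# Synthetic obese / non-obese cohort generator. Emulates the trial
# design: 600 mg / 0.5 h infusion, rich plasma sampling to 8 h, two
# subcutaneous microdialysis catheters with retrodialysis calibration.

seed_offset <- function(config, k) {
  if (is.null(config$seed)) return(invisible(NULL))
  set.seed((as.integer(config$seed) + k) %% .Machine$integer.max)
}

# Beta distribution moment-matched (by quartiles) to the observed
# recovery median / IQR; fitted once per call, deterministically.
fit_recovery_beta <- function(med, iqr) {
  target <- c(iqr[1], med, iqr[2])
  obj <- function(par) {
    q <- stats::qbeta(c(0.25, 0.5, 0.75), exp(par[1]), exp(par[2]))
    sum((q - target)^2)
  }
  fit <- stats::optim(c(log(3), log(3)), obj)
  list(shape1 = exp(fit$par[1]), shape2 = exp(fit$par[2]))
}

#' Draw the synthetic cohort: covariates, individual PK parameters,
#' catheter recoveries and ground-truth exposures
#'
#' Subjects are drawn per group with weights about 134.3 +/- 34.3 kg
#' (obese) and 67.9 +/- 8.8 kg (non-obese), heights consistent with the
#' group BMI definition (obese: BMI >= 35; non-obese: 18.5 <= BMI <= 30,
#' enforced by rejection), 87% females, and lognormal inter-individual
#' variability on CL, V1, V2 and k_isf. Per-catheter relative recoveries
#' are drawn from a Beta distribution quartile-matched to median 0.48,
#' IQR (0.34, 0.58). With `iiv_cv = 0` every draw collapses to its
#' central value, giving a fully deterministic cohort.
#'
#' @param config A [cohort_config()].
#' @return A tibble with one row per subject: covariates (`group`,
#'   `sex`, `age`, `weight`, `height`, `bmi`), individual parameters
#'   (`CL`, `V1`, `V2`, `Q`, `k_isf`, `penetration`, `recovery_left`,
#'   `recovery_right`) and analytic ground truths (`true_cl`, `true_vss`,
#'   `true_auc_plasma`, `true_fauc_plasma`, `true_auc_isf`).
#' @examples
#' draw_cohort(cohort_config(n_per_group = 2, seed = 1))
#' @export
draw_cohort <- function(config) {
  validate_config(config)
  seed_offset(config, 0L)
  n <- config$n_per_group
  iiv <- config$iiv_cv
  sdlog <- sqrt(log(1 + iiv^2))
  beta_par <- fit_recovery_beta(config$recovery_median, config$recovery_iqr)
  draw_rec <- function(m) {
    if (iiv == 0) rep(config$recovery_median, m)
    else stats::rbeta(m, beta_par$shape1, beta_par$shape2)
  }

  groups <- names(config$group_params)
  rows <- purrr::map(groups, function(g) {
    p <- config$group_params[[g]]
    bmi_ok <- if (g == "obese") function(b) b >= 35 else function(b) b >= 18.5 & b <= 30
    wt <- ht <- numeric(n)
    for (i in seq_len(n)) {
      if (iiv == 0) {
        wt[i] <- p$weight_mean
        ht[i] <- p$height_mean
        if (!bmi_ok(wt[i] / ht[i]^2)) {
          abort("group means violate the group BMI definition",
                class = "tpk_invalid_config")
        }
      } else {
        repeat {
          w <- stats::rnorm(1, p$weight_mean, p$weight_sd)
          h <- stats::rnorm(1, p$height_mean, p$height_sd)
          if (w > 0 && h > 0 && bmi_ok(w / h^2)) break
        }
        wt[i] <- w
        ht[i] <- h
      }
    }
    n_f <- round(n * config$prop_female)
    sex <- if (iiv == 0) {
      rep(c("F", "M"), c(n_f, n - n_f))
    } else {
      sample(rep(c("F", "M"), c(n_f, n - n_f)))
    }
    age <- if (iiv == 0) rep(p$age_mean, n) else {
      pmax(stats::rnorm(n, p$age_mean, p$age_sd), 18)
    }
    eta <- function() if (iiv == 0) rep(0, n) else stats::rnorm(n, 0, sdlog)
    size_cl <- if (config$allometric) (wt / p$weight_mean)^0.75 else 1
    size_v <- if (config$allometric) wt / p$weight_mean else 1
    cl_i <- p$CL * size_cl * exp(eta())
    v1_i <- p$V1 * size_v * exp(eta())
    v2_i <- p$V2 * size_v * exp(eta())
    k_i <- p$k_isf * exp(eta())
    tibble(
      group = g, sex = sex, age = age, weight = wt, height = ht,
      bmi = wt / ht^2,
      CL = cl_i, V1 = v1_i, V2 = v2_i,
      Q = (p$Q / p$CL) * cl_i, # Q tracks individual CL: proportional split
      k_isf = k_i, penetration = p$penetration,
      recovery_left = draw_rec(n), recovery_right = draw_rec(n)
    )
  })
  dplyr::bind_rows(rows) |>
    dplyr::mutate(
      subject_id = sprintf("S%02d", dplyr::row_number()),
      true_cl = .data$CL,
      true_vss = .data$V1 + .data$V2,
      true_auc_plasma = config$dose / .data$CL,
      true_fauc_plasma = config$fu * config$dose / .data$CL,
      true_auc_isf = .data$penetration * config$fu * config$dose / .data$CL
    ) |>
    dplyr::relocate("subject_id")
}

#' Ground-truth exposures of a drawn cohort
#'
#' @param cohort A tibble from [draw_cohort()].
#' @return A tibble with `subject_id`, `true_auc_plasma`,
#'   `true_fauc_plasma`, `true_auc_isf`, `true_cl`, `true_vss`.
#' @export
true_exposures <- function(cohort) {
  cohort |>
    dplyr::select("subject_id", "group", "true_auc_plasma",
                  "true_fauc_plasma", "true_auc_isf", "true_cl", "true_vss")
}

subject_model <- function(subject, config) {
  pk_model(CL = subject$CL, V1 = subject$V1, V2 = subject$V2,
           Q = subject$Q, dose = config$dose, t_inf = config$t_inf,
           fu = config$fu, k_isf = subject$k_isf,
           penetration = subject$penetration)
}

#' Continuous ISF concentration function for one subject
#'
#' @param subject A one-row tibble (one row of [draw_cohort()] output).
#' @param config The matching [cohort_config()].
#' @return A function of time `t` (h) returning the noiseless ISF
#'   concentration (mg/L).
#' @export
isf_profile_fun <- function(subject, config) {
  stopifnot(nrow(subject) == 1)
  subject_model(subject, config)$conc_isf
}

apply_lloq <- function(conc, lloq) {
  blq <- conc < lloq
  tibble(conc = ifelse(blq, NA_real_, conc), blq = blq, lloq = lloq)
}

#' Simulate plasma concentration-time data for a cohort
#'
#' Evaluates the closed-form bi-exponential infusion solution at the
#' blood-sampling times, applies proportional residual error to the
#' total concentration, derives unbound concentrations as `fu` times the
#' (noisy) total, and flags values below the LLOQ as BLQ.
#'
#' @param cohort A tibble from [draw_cohort()].
#' @param config The matching [cohort_config()].
#' @param times Sampling times in h (default [plasma_schedule()]).
#' @return A long tibble: `subject_id`, `group`, `matrix`
#'   (`plasma_total` / `plasma_unbound`), `t`, `conc` (mg/L, `NA` when
#'   BLQ), `blq`, `lloq`.
#' @export
simulate_plasma <- function(cohort, config, times = plasma_schedule()) {
  validate_config(config)
  seed_offset(config, 1L)
  cv <- config$residual_cv[["plasma"]]
  purrr::map(seq_len(nrow(cohort)), function(i) {
    sub <- cohort[i, ]
    m <- subject_model(sub, config)
    true_tot <- m$conc_plasma(times)
    eps <- if (cv == 0) rep(0, length(times)) else stats::rnorm(length(times), 0, cv)
    tot <- pmax(true_tot * (1 + eps), 0)
    unb <- config$fu * tot
    dplyr::bind_rows(
      tibble(matrix = "plasma_total", t = times, apply_lloq(tot, config$lloq)),
      tibble(matrix = "plasma_unbound", t = times, apply_lloq(unb, config$lloq))
    ) |>
      dplyr::mutate(subject_id = sub$subject_id, group = sub$group)
  }) |>
    dplyr::bind_rows() |>
    dplyr::relocate("subject_id", "group")
}

#' Simulate (noiseless) ISF concentrations on a time grid
#'
#' Evaluates each subject's first-order tissue-link solution. This is
#' the latent target-site curve; observed dialysate data come from
#' [simulate_microdialysate()].
#'
#' @inheritParams simulate_plasma
#' @param times Evaluation times in h.
#' @return A tibble: `subject_id`, `group`, `t`, `conc`.
#' @export
simulate_isf <- function(cohort, config, times = seq(0, 8, by = 0.1)) {
  validate_config(config)
  purrr::map(seq_len(nrow(cohort)), function(i) {
    sub <- cohort[i, ]
    tibble(subject_id = sub$subject_id, group = sub$group, t = times,
           conc = subject_model(sub, config)$conc_isf(times))
  }) |>
    dplyr::bind_rows()
}

#' Simulate microdialysate collections on two catheters
#'
#' Each collection interval yields the analytic time-average of the ISF
#' concentration over the interval, scaled by the catheter's relative
#' recovery, with proportional residual error; values below the LLOQ are
#' flagged BLQ.
#'
#' @inheritParams simulate_plasma
#' @param intervals Collection intervals (default [dialysate_schedule()]).
#' @return A tibble: `subject_id`, `group`, `catheter` (`left`/`right`),
#'   `t_start`, `t_end`, `conc` (dialysate mg/L, `NA` when BLQ), `blq`,
#'   `lloq`, and the generating `recovery` (fraction).
#' @export
simulate_microdialysate <- function(cohort, config,
                                    intervals = dialysate_schedule()) {
  validate_config(config)
  seed_offset(config, 2L)
  cv <- config$residual_cv[["dialysate"]]
  purrr::map(seq_len(nrow(cohort)), function(i) {
    sub <- cohort[i, ]
    m <- subject_model(sub, config)
    avg <- m$isf_interval_avg(intervals$t_start, intervals$t_end)
    purrr::map(c("left", "right"), function(side) {
      rec <- sub[[paste0("recovery_", side)]]
      eps <- if (cv == 0) rep(0, nrow(intervals)) else {
        stats::rnorm(nrow(intervals), 0, cv)
      }
      dial <- pmax(avg * rec * (1 + eps), 0)
      tibble(subject_id = sub$subject_id, group = sub$group,
             catheter = side, t_start = intervals$t_start,
             t_end = intervals$t_end, apply_lloq(dial, config$lloq),
             recovery = rec)
    }) |>
      dplyr::bind_rows()
  }) |>
    dplyr::bind_rows()
}

#' Simulate retrodialysis calibration pairs
#'
#' Emits one retroperfusate / retrodialysate concentration pair per
#' catheter, consistent with the catheter's generating recovery:
#' `c_rd = c_rp * (1 - recovery)` before assay noise, so that
#' `1 - c_rd / c_rp` recovers the recovery exactly at zero noise.
#'
#' @inheritParams simulate_plasma
#' @param c_rp Spiked retroperfusate concentration (mg/L, default 10).
#' @return A tibble: `subject_id`, `catheter`, `c_rp`, `c_rd`,
#'   `recovery` (generating fraction).
#' @export
simulate_calibration <- function(cohort, config, c_rp = 10) {
  validate_config(config)
  seed_offset(config, 3L)
  cv <- config$residual_cv[["dialysate"]]
  purrr::map(c("left", "right"), function(side) {
    rec <- cohort[[paste0("recovery_", side)]]
    eps <- if (cv == 0) rep(0, nrow(cohort)) else stats::rnorm(nrow(cohort), 0, cv)
    tibble(subject_id = cohort$subject_id, catheter = side,
           c_rp = c_rp, c_rd = pmax(c_rp * (1 - rec) * (1 + eps), 0),
           recovery = rec)
  }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$subject_id, .data$catheter)
}

#' Simulate the complete synthetic study data set
#'
#' Runs [draw_cohort()], [simulate_plasma()], [simulate_microdialysate()]
#' and [simulate_calibration()] under one seed and bundles the results,
#' including the canonical long-format concentration table used by the
#' CSV interface.
#'
#' @param config A [cohort_config()].
#' @return An object of class `tpk_cohort`: a list with `subjects`,
#'   `plasma`, `dialysate`, `calibration`, `truth`, `data` (canonical
#'   combined table) and `config`.
#' @examples
#' sim <- simulate_cohort(cohort_config(n_per_group = 2, seed = 1))
#' sim$subjects
#' @export
simulate_cohort <- function(config = cohort_config()) {
  validate_config(config)
  subjects <- draw_cohort(config)
  plasma <- simulate_plasma(subjects, config)
  dialysate <- simulate_microdialysate(subjects, config)
  calibration <- simulate_calibration(subjects, config)
  data <- dplyr::bind_rows(
    plasma |>
      dplyr::transmute(.data$subject_id, .data$group, .data$matrix,
                       catheter = NA_character_, time_or_tstart = .data$t,
                       tend = NA_real_, conc_mg_L = .data$conc, .data$blq,
                       .data$lloq),
    dialysate |>
      dplyr::transmute(.data$subject_id, .data$group,
                       matrix = "microdialysate", .data$catheter,
                       time_or_tstart = .data$t_start, tend = .data$t_end,
                       conc_mg_L = .data$conc, .data$blq, .data$lloq)
  )
  structure(list(subjects = subjects, plasma = plasma,
                 dialysate = dialysate, calibration = calibration,
                 truth = true_exposures(subjects), data = data,
                 config = config),
            class = "tpk_cohort")
}

#' @export
print.tpk_cohort <- function(x, ...) {
  cat(sprintf("<tpk_cohort> %d subjects (%s)\n", nrow(x$subjects),
              paste(table(x$subjects$group), names(table(x$subjects$group)),
                    collapse = ", ")))
  cat(sprintf("  %d plasma rows, %d dialysate rows, %d calibration pairs\n",
              nrow(x$plasma), nrow(x$dialysate), nrow(x$calibration)))
  invisible(x)
}

#' Simulate log-linear longitudinal concentration data
#'
#' Direct generator for the longitudinal mixed-model layer: log
#' concentrations decline linearly in time, with a multiplicative group
#' level effect, a group-specific decline-rate ratio, a catheter effect,
#' per-subject random intercepts and slopes, and lognormal residual
#' error. Used to verify mixed-model recovery against known truth.
#'
#' @param n_per_group Subjects per group.
#' @param times Observation times (h), default the dialysate interval
#'   midpoints.
#' @param group_ratio True obese / non-obese concentration ratio
#'   (default 0.52).
#' @param decline_ratio True obese / non-obese decline-rate ratio
#'   (default 1.06): obese log-slope = `decline_ratio` times the
#'   non-obese log-slope.
#' @param catheter_ratio True right / left concentration ratio
#'   (default 1).
#' @param c0 Non-obese left-catheter concentration at t = 0 (mg/L).
#' @param half_life Non-obese decline half-life (h), default 3.8.
#' @param sd_intercept,sd_slope Random-effect SDs on the log scale
#'   (defaults 0.30 and 0.05).
#' @param sd_resid Residual SD on the log scale (default 0.15).
#' @param seed Optional seed.
#' @return A tibble: `subject_id`, `group`, `catheter`, `t`, `conc`.
#' @export
simulate_longitudinal <- function(n_per_group = 15,
                                  times = rowMeans(dialysate_schedule()),
                                  group_ratio = 0.52,
                                  decline_ratio = 1.06,
                                  catheter_ratio = 1,
                                  c0 = 6, half_life = 3.8,
                                  sd_intercept = 0.30, sd_slope = 0.05,
                                  sd_resid = 0.15, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  slope0 <- -log(2) / half_life
  grid <- tidyr::expand_grid(
    subject_id = sprintf("S%02d", seq_len(2 * n_per_group)),
    catheter = c("left", "right"), t = times
  )
  subj <- tibble(
    subject_id = sprintf("S%02d", seq_len(2 * n_per_group)),
    group = rep(c("non_obese", "obese"), each = n_per_group),
    b0 = stats::rnorm(2 * n_per_group, 0, sd_intercept),
    b1 = stats::rnorm(2 * n_per_group, 0, sd_slope)
  )
  grid |>
    dplyr::left_join(subj, by = "subject_id") |>
    dplyr::mutate(
      logc = log(c0) + .data$b0 +
        ifelse(.data$group == "obese", log(group_ratio), 0) +
        (slope0 * ifelse(.data$group == "obese", decline_ratio, 1) + .data$b1) * .data$t +
        ifelse(.data$catheter == "right", log(catheter_ratio), 0) +
        stats::rnorm(dplyr::n(), 0, sd_resid),
      conc = exp(.data$logc)
    ) |>
    dplyr::select("subject_id", "group", "catheter", "t", "conc")
}
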