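# Non-compartmental analysis: terminal log-linear regression,
# linear-up/log-down trapezoidal areas, moments, clearance and Vss.
#
# A "profile" is a tibble with columns `t` (h), `conc` (mg/L, NA when
# BLQ) and optionally `blq`; records must be at strictly increasing
# times. BLQ handling follows the documented rules: a BLQ baseline at
# t = 0 counts as concentration 0, any other BLQ record is excluded
# from both the trapezoids and the terminal fit.

clean_profile <- function(profile) {
  stopifnot(all(c("t", "conc") %in% names(profile)))
  p <- profile[order(profile$t), ]
  if (any(duplicated(p$t))) {
    abort("duplicated sample times in profile", class = "tpk_invalid_input")
  }
  if (!"blq" %in% names(p)) p$blq <- is.na(p$conc)
  p$conc[p$blq & p$t == 0] <- 0 # pre-dose baseline counts as zero
  p <- p[!(p$blq & p$t != 0), ]
  if (any(p$conc < 0, na.rm = TRUE)) {
    abort("negative concentrations in profile", class = "tpk_invalid_input")
  }
  p
}

quantifiable <- function(p) p[!is.na(p$conc) & p$conc > 0, ]

#' Terminal log-linear regression (lambda-z)
#'
#' Fits ordinary least squares of log concentration on time over the
#' best terminal window: among all suffixes of at least three
#' quantifiable points strictly after Tmax (Tmax itself excluded), the
#' window maximising adjusted R-squared is selected; ties within 1e-4
#' go to the window with more points. The slope must be negative.
#'
#' @param profile A profile tibble (`t`, `conc`, optional `blq`).
#' @return An object of class `tpk_terminal_fit` with elements
#'   `lambda_z` (1/h), `intercept` (log mg/L at t = 0), `n_points`,
#'   `adj_r2`, `t_half` (h), `window` (first and last time used) and
#'   `estimable`. When fewer than three usable points exist, or no
#'   window yields a negative slope, the fit is returned with
#'   `estimable = FALSE` and missing parameters (the subject is
#'   retained; the parameter is simply not reported).
#' @examples
#' prof <- tibble::tibble(t = c(4, 5, 6, 8), conc = 10 * exp(-0.2 * c(4, 5, 6, 8)))
#' fit_lambda_z(prof)$t_half # log(2) / 0.2
#' @export
fit_lambda_z <- function(profile) {
  not_estimable <- structure(
    list(lambda_z = NA_real_, intercept = NA_real_, n_points = NA_integer_,
         adj_r2 = NA_real_, t_half = NA_real_,
         window = c(NA_real_, NA_real_), estimable = FALSE),
    class = "tpk_terminal_fit"
  )
  p <- quantifiable(clean_profile(profile))
  if (nrow(p) < 4) return(not_estimable) # Tmax + 3 terminal points
  tmax <- p$t[which.max(p$conc)]
  term <- p[p$t > tmax, ]
  m <- nrow(term)
  if (m < 3) return(not_estimable)
  best <- NULL
  for (i in seq_len(m - 2)) {
    tt <- term$t[i:m]
    yy <- log(term$conc[i:m])
    npts <- m - i + 1
    # closed-form OLS (equivalent to lm(yy ~ tt))
    mx <- mean(tt)
    my <- mean(yy)
    sxx <- sum((tt - mx)^2)
    sxy <- sum((tt - mx) * (yy - my))
    syy <- sum((yy - my)^2)
    slope <- sxy / sxx
    # a numerically-zero slope (flat profile) is not an elimination phase
    if (!is.finite(slope) || slope >= -1e-10) next
    r2raw <- if (syy <= 0) 1 else sxy^2 / (sxx * syy)
    r2 <- 1 - (1 - r2raw) * (npts - 1) / (npts - 2)
    if (is.null(best) || r2 > best$adj_r2 + 1e-4 ||
        (abs(r2 - best$adj_r2) <= 1e-4 && npts > best$n_points)) {
      best <- list(lambda_z = -slope, intercept = my - slope * mx,
                   n_points = npts, adj_r2 = r2,
                   window = c(tt[1], tt[npts]))
    }
  }
  if (is.null(best)) return(not_estimable)
  structure(
    c(best[c("lambda_z", "intercept", "n_points", "adj_r2")],
      list(t_half = log(2) / best$lambda_z, window = best$window,
           estimable = TRUE)),
    class = "tpk_terminal_fit"
  )
}

#' @export
print.tpk_terminal_fit <- function(x, ...) {
  if (!x$estimable) {
    cat("<tpk_terminal_fit> not estimable\n")
  } else {
    cat(sprintf(
      "<tpk_terminal_fit> lambda_z=%.4f /h (t1/2 %.2f h), %d points on [%g, %g] h, adj R2=%.4f\n",
      x$lambda_z, x$t_half, x$n_points, x$window[1], x$window[2], x$adj_r2))
  }
  invisible(x)
}

#' @param object A `tpk_terminal_fit`.
#' @param t Times (h) at which to predict.
#' @param ... Unused.
#' @return Predicted concentrations (mg/L) from the terminal regression.
#' @rdname fit_lambda_z
#' @export
predict.tpk_terminal_fit <- function(object, t, ...) {
  if (!object$estimable) return(rep(NA_real_, length(t)))
  exp(object$intercept - object$lambda_z * t)
}

# one segment of the linear-up/log-down rule
segment_auc <- function(t1, c1, t2, c2) {
  dt <- t2 - t1
  if (c2 >= c1 || c1 <= 0 || c2 <= 0) (c1 + c2) / 2 * dt
  else (c1 - c2) * dt / log(c1 / c2)
}

# concentration at an interior time, interpolated with the same rule
interp_conc <- function(t1, c1, t2, c2, t) {
  if (c2 >= c1 || c1 <= 0 || c2 <= 0) {
    c1 + (c2 - c1) * (t - t1) / (t2 - t1)
  } else {
    c1 * (c2 / c1)^((t - t1) / (t2 - t1))
  }
}

#' Linear-up/log-down trapezoidal AUC
#'
#' Rising (or zero-bounded) segments contribute linear trapezoids,
#' declining segments with both concentrations positive contribute
#' logarithmic trapezoids \eqn{(C_1 - C_2)\Delta t / \ln(C_1/C_2)}. The
#' sum runs from the first record to `t_end`; if `t_end` falls between
#' samples the bracketing segment is split by interpolating with the
#' same rule.
#'
#' @param profile A profile tibble (`t`, `conc`, optional `blq`).
#' @param t_end Upper limit (h); defaults to the last sample time, and
#'   must not exceed it.
#' @param value_fun Optional transform applied to concentrations before
#'   integration (used internally with `t * C` for moment areas).
#' @return AUC in mg h/L.
#' @examples
#' prof <- tibble::tibble(t = c(0, 1), conc = c(10, 5))
#' auc_lin_up_log_down(prof) # 5 / log(2)
#' @export
auc_lin_up_log_down <- function(profile, t_end = NULL, value_fun = NULL) {
  p <- quantifiable_with_zeros(clean_profile(profile))
  if (nrow(p) < 2) {
    abort("need at least two records for an AUC", class = "tpk_not_estimable")
  }
  t_end <- t_end %||% max(p$t)
  if (t_end > max(p$t) + 1e-9) {
    abort("t_end exceeds the last sample time", class = "tpk_invalid_input")
  }
  tt <- p$t
  cc <- p$conc
  vv <- if (is.null(value_fun)) cc else value_fun(tt, cc)
  total <- 0
  for (j in seq_len(length(tt) - 1)) {
    t1 <- tt[j]; t2 <- tt[j + 1]
    if (t1 >= t_end) break
    if (t2 <= t_end) {
      total <- total + segment_auc(t1, vv[j], t2, vv[j + 1])
    } else {
      # partial segment: interpolate concentration, transform, integrate
      c_end <- interp_conc(t1, cc[j], t2, cc[j + 1], t_end)
      v_end <- if (is.null(value_fun)) c_end else value_fun(t_end, c_end)
      total <- total + segment_auc(t1, vv[j], t_end, v_end)
    }
  }
  total
}

# zero-concentration anchors (t = 0 baseline) are kept for trapezoids
quantifiable_with_zeros <- function(p) p[!is.na(p$conc), ]

#' Extrapolate AUC to infinity
#'
#' The tail beyond the last quantifiable sample is the regression-
#' predicted concentration at that time divided by lambda-z (predicted,
#' not observed, last concentration).
#'
#' @param profile A profile tibble.
#' @param fit A [fit_lambda_z()] result.
#' @return A list with `auc_tlast`, `tail`, `auc_inf` (mg h/L) and
#'   `pct_extrap` (percent of `auc_inf` extrapolated). All `NA` when the
#'   terminal fit is not estimable.
#' @export
extrapolate_auc <- function(profile, fit) {
  stopifnot(inherits(fit, "tpk_terminal_fit"))
  if (!fit$estimable) {
    return(list(auc_tlast = NA_real_, tail = NA_real_, auc_inf = NA_real_,
                pct_extrap = NA_real_))
  }
  p <- quantifiable(clean_profile(profile))
  t_last <- max(p$t)
  auc_tlast <- auc_lin_up_log_down(profile, t_end = t_last)
  c_hat <- predict(fit, t_last)
  tail <- c_hat / fit$lambda_z
  auc_inf <- auc_tlast + tail
  list(auc_tlast = auc_tlast, tail = tail, auc_inf = auc_inf,
       pct_extrap = 100 * tail / auc_inf)
}

#' First-moment area and mean residence time
#'
#' AUMC applies the same linear-up/log-down segment rules to
#' \eqn{t \cdot C(t)}, with tail
#' \eqn{\hat{C}_{last} t_{last} / \lambda_z + \hat{C}_{last} / \lambda_z^2}.
#' MRT for a constant-rate infusion is AUMC/AUC (both to infinity) minus
#' half the infusion duration.
#'
#' @param profile A profile tibble.
#' @param fit A [fit_lambda_z()] result.
#' @param t_inf Infusion duration (h).
#' @return A list with `aumc_inf` (mg h^2/L) and `mrt` (h); `NA` when
#'   not estimable.
#' @export
nca_moments <- function(profile, fit, t_inf = 0.5) {
  stopifnot(inherits(fit, "tpk_terminal_fit"))
  if (!fit$estimable) return(list(aumc_inf = NA_real_, mrt = NA_real_))
  p <- quantifiable(clean_profile(profile))
  t_last <- max(p$t)
  aumc_tlast <- auc_lin_up_log_down(profile, t_end = t_last,
                                    value_fun = function(t, c) t * c)
  c_hat <- predict(fit, t_last)
  aumc_inf <- aumc_tlast + c_hat * t_last / fit$lambda_z +
    c_hat / fit$lambda_z^2
  ext <- extrapolate_auc(profile, fit)
  list(aumc_inf = aumc_inf, mrt = aumc_inf / ext$auc_inf - t_inf / 2)
}

#' Clearance and steady-state volume of distribution
#'
#' CL = dose / AUC-infinity and Vss = CL x MRT. Both are defined from
#' plasma data only; passing an ISF profile is a contract violation.
#'
#' @param profile The plasma profile the AUC was computed from; if it
#'   carries a `matrix` column it must be a plasma matrix.
#' @param auc_inf AUC extrapolated to infinity (mg h/L).
#' @param mrt Mean residence time (h).
#' @param dose Dose (mg).
#' @return A list with `cl` (L/h) and `vss` (L).
#' @export
clearance_vss <- function(profile, auc_inf, mrt, dose = 600) {
  if ("matrix" %in% names(profile) &&
      !all(startsWith(unique(profile$matrix), "plasma"))) {
    abort("CL and Vss are defined from plasma data only",
          class = "tpk_contract_violation")
  }
  if (!is.na(auc_inf) && auc_inf <= 0) {
    abort("auc_inf must be > 0", class = "tpk_invalid_input")
  }
  cl <- dose / auc_inf
  list(cl = cl, vss = cl * mrt)
}

#' Daily-dose AUC from a single-dose AUC-infinity
#'
#' For twice-daily dosing of the single administered dose,
#' AUC24 = 2 x AUC-infinity.
#'
#' @param auc_inf Single-dose AUC to infinity (mg h/L), > 0.
#' @return AUC24 (mg h/L); `NA` propagates.
#' @examples
#' auc24(60) # 120
#' @export
auc24 <- function(auc_inf) {
  if (any(!is.na(auc_inf) & auc_inf <= 0)) {
    abort("auc_inf must be > 0", class = "tpk_invalid_input")
  }
  2 * auc_inf
}

#' Maximum concentration and its time
#'
#' @param profile A profile tibble.
#' @return A list with `cmax` (mg/L) and `tmax` (h); ties are broken by
#'   the earliest time.
#' @export
cmax_tmax <- function(profile) {
  p <- quantifiable(clean_profile(profile))
  if (nrow(p) == 0) {
    abort("no quantifiable records", class = "tpk_not_estimable")
  }
  i <- which.max(p$conc) # first index on ties; p is time-ordered
  list(cmax = p$conc[i], tmax = p$t[i])
}

nca_one <- function(profile, dose, t_inf, t_end, is_plasma) {
  # ensure a zero anchor at t = 0 (ISF profiles start at the first
  # interval midpoint; plasma baselines are BLQ and become zero)
  if (!any(profile$t <= 0)) {
    profile <- dplyr::bind_rows(tibble(t = 0, conc = 0, blq = FALSE),
                                profile[c("t", "conc", "blq")])
  }
  na_row <- tibble(
    cmax = NA_real_, tmax = NA_real_, auc_0_8 = NA_real_,
    auc_inf = NA_real_, pct_extrap = NA_real_, aumc_inf = NA_real_,
    mrt = NA_real_, cl = NA_real_, vss = NA_real_, auc_24 = NA_real_,
    lambda_z = NA_real_, t_half = NA_real_, lz_n_points = NA_integer_,
    lz_adj_r2 = NA_real_, lz_t_first = NA_real_, lz_t_last = NA_real_
  )
  ct <- rlang::try_fetch(cmax_tmax(profile),
                         tpk_not_estimable = function(e) NULL)
  if (is.null(ct)) return(na_row)
  p <- quantifiable(clean_profile(profile))
  t_end_eff <- min(t_end, max(p$t))
  auc8 <- rlang::try_fetch(auc_lin_up_log_down(profile, t_end = t_end_eff),
                           tpk_not_estimable = function(e) NA_real_)
  fit <- fit_lambda_z(profile)
  ext <- extrapolate_auc(profile, fit)
  mom <- nca_moments(profile, fit, t_inf = t_inf)
  clv <- if (is_plasma && !is.na(ext$auc_inf)) {
    clearance_vss(profile, ext$auc_inf, mom$mrt, dose = dose)
  } else list(cl = NA_real_, vss = NA_real_)
  tibble(
    cmax = ct$cmax, tmax = ct$tmax, auc_0_8 = auc8,
    auc_inf = ext$auc_inf, pct_extrap = ext$pct_extrap,
    aumc_inf = mom$aumc_inf, mrt = mom$mrt, cl = clv$cl, vss = clv$vss,
    auc_24 = if (is.na(ext$auc_inf)) NA_real_ else auc24(ext$auc_inf),
    lambda_z = fit$lambda_z, t_half = fit$t_half,
    lz_n_points = fit$n_points, lz_adj_r2 = fit$adj_r2,
    lz_t_first = fit$window[1], lz_t_last = fit$window[2]
  )
}

#' Non-compartmental analysis of a concentration data set
#'
#' Runs the full NCA per subject and matrix: Cmax/Tmax, AUC(0-t_end) by
#' the linear-up/log-down rule, terminal lambda-z by best-adjusted-R2
#' suffix regression, AUC and AUMC extrapolated to infinity from the
#' predicted last concentration, MRT (minus half the infusion time),
#' CL = dose/AUC-infinity and Vss = CL x MRT (plasma matrices only), and
#' AUC24 = 2 x AUC-infinity.
#'
#' @param data A long tibble with columns `subject_id`, `matrix`, `t`,
#'   `conc`, optional `blq` and `group`. Point records only (convert
#'   dialysate intervals with [dialysate_to_isf()] first).
#' @param dose Dose in mg (default 600).
#' @param t_inf Infusion duration in h (default 0.5).
#' @param t_end Upper limit of the primary AUC (default 8 h); profiles
#'   ending earlier (ISF midpoints end at 7.5 h) use their last sample.
#' @return A tibble of class `tpk_nca`, one row per subject x matrix,
#'   with all NCA parameters; parameters that are not estimable for a
#'   subject are `NA`, the subject is retained.
#' @examples
#' sched <- plasma_schedule()
#' dat <- tibble::tibble(subject_id = "S01", matrix = "plasma_total",
#'                       t = sched, conc = 20 * exp(-0.2 * sched), blq = FALSE)
#' nca(dat)
#' @export
nca <- function(data, dose = 600, t_inf = 0.5, t_end = 8) {
  stopifnot(all(c("subject_id", "matrix", "t", "conc") %in% names(data)))
  if (!"blq" %in% names(data)) data$blq <- is.na(data$conc)
  grouped <- data |>
    dplyr::group_by(dplyr::across(dplyr::any_of(c("subject_id", "group",
                                                  "matrix"))))
  keys <- dplyr::group_keys(grouped)
  out <- purrr::map2(
    dplyr::group_split(grouped, .keep = FALSE), seq_len(nrow(keys)),
    function(prof, i) {
      k <- keys[i, ]
      dplyr::bind_cols(
        k, nca_one(prof[c("t", "conc", "blq")], dose = dose, t_inf = t_inf,
                   t_end = t_end, is_plasma = startsWith(k$matrix, "plasma"))
      )
    }
  ) |>
    dplyr::bind_rows()
  class(out) <- c("tpk_nca", class(out))
  out
}
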