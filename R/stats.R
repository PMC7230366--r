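# Cohort-level statistical layer: exposure-size regression, Fisher-Z
# correlation intervals (with a robust fallback), the longitudinal
# mixed model on log concentrations, group comparisons, and the
# correlation-based sample-size computation.

#' Linear regression of exposure on body size and sex
#'
#' Ordinary least squares of an exposure measure (AUC) on one body-size
#' descriptor (`weight` or `bmi`) plus sex. Weight and BMI are never
#' entered together (collinearity); the slope is reported per 10 kg
#' (or per 10 BMI units) with a 95% CI and two-sided p-value.
#'
#' @param data A tibble with the outcome, the size column and `sex`.
#' @param outcome Name of the outcome column (string), e.g. an AUC.
#' @param size `"weight"` or `"bmi"`.
#' @return An object of class `tpk_reg`: the underlying `lm` plus
#'   `slope_per_10`, `ci95`, `p` and metadata. Has [tidy()] and
#'   [glance()] methods.
#' @examples
#' d <- tibble::tibble(weight = c(60, 80, 100, 120), sex = c("F", "F", "M", "M"),
#'                     auc = 50 - 0.169 * weight)
#' auc_weight_regression(d, "auc", "weight")$slope_per_10 # -1.69
#' @export
auc_weight_regression <- function(data, outcome, size = c("weight", "bmi")) {
  size <- match.arg(size)
  stopifnot(all(c(outcome, size, "sex") %in% names(data)))
  d <- data[stats::complete.cases(data[c(outcome, size, "sex")]), ]
  if (nrow(d) < 4) abort("need at least 4 complete rows", class = "tpk_invalid_input")
  if (sd(d[[size]]) == 0) {
    abort(paste0("degenerate design: ", size, " is constant"),
          class = "tpk_invalid_input")
  }
  has_sex <- length(unique(d$sex)) > 1
  fml <- stats::reformulate(c(size, if (has_sex) "sex"), response = outcome)
  fit <- lm(fml, data = d)
  if (any(is.na(coef(fit)))) {
    abort("collinear covariates in regression", class = "tpk_invalid_input")
  }
  slope <- coef(fit)[[size]]
  ci <- suppressWarnings(confint(fit)[size, ])
  p <- suppressWarnings(summary(fit))$coefficients[size, "Pr(>|t|)"]
  structure(
    list(fit = fit, outcome = outcome, size = size,
         slope_per_unit = slope, slope_per_10 = 10 * slope,
         ci95 = 10 * unname(ci), p = p, n = nrow(d), sex_included = has_sex),
    class = "tpk_reg"
  )
}

#' @export
print.tpk_reg <- function(x, ...) {
  cat(sprintf(
    "<tpk_reg> %s ~ %s%s (n=%d): slope %.3f per 10 units (95%% CI %.3f to %.3f), p=%.3g\n",
    x$outcome, x$size, if (x$sex_included) " + sex" else "", x$n,
    x$slope_per_10, x$ci95[1], x$ci95[2], x$p))
  invisible(x)
}

#' Fisher-Z confidence interval for a correlation coefficient
#'
#' @param r Correlation in (-1, 1); boundary values return degenerate
#'   intervals at +/-1.
#' @param n Sample size (> 3).
#' @param conf_level Confidence level (default 0.95).
#' @return Length-2 vector: `tanh(atanh(r) +/- z / sqrt(n - 3))`.
#' @examples
#' fisher_ci(-0.61, 30) # c(-0.80, -0.32) to printed precision
#' @export
fisher_ci <- function(r, n, conf_level = 0.95) {
  stopifnot(n > 3, abs(r) <= 1)
  z <- qnorm(1 - (1 - conf_level) / 2)
  tanh(atanh(r) + c(-1, 1) * z / sqrt(n - 3))
}

# percentage-bend correlation (Wilcox), the documented outlier-resistant
# fallback; beta is the bend fraction
pbend_cor <- function(x, y, beta = 0.2) {
  psi <- function(u) pmax(-1, pmin(1, u))
  phi <- function(v) {
    m <- floor((1 - beta) * length(v) + 0.5)
    what <- sort(abs(v - median(v)))[m]
    if (what == 0) abort("zero spread in robust correlation",
                         class = "tpk_invalid_input")
    u <- (v - median(v)) / what
    i1 <- sum(u < -1)
    i2 <- sum(u > 1)
    sx <- sum(v[abs(u) <= 1])
    loc <- (what * (i2 - i1) + sx) / (length(v) - i1 - i2)
    list(omega = what, loc = loc)
  }
  px <- phi(x)
  py <- phi(y)
  a <- psi((x - px$loc) / px$omega)
  b <- psi((y - py$loc) / py$omega)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

#' Correlation with a Fisher-Z confidence interval
#'
#' Pearson's correlation (or, with `robust = TRUE`, the percentage-bend
#' correlation as an outlier-resistant sensitivity analysis) with the
#' confidence interval from Fisher's Z transform and a two-sided
#' p-value from the t statistic on n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length, n >= 4.
#' @param robust Use the percentage-bend estimator (bend fraction 0.2).
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `tpk_cor` with `r`, `ci95`, `p`, `n` and
#'   `method`. Has [tidy()] and [glance()] methods.
#' @examples
#' set.seed(1)
#' x <- rnorm(30); y <- 0.6 * x + rnorm(30, 0, 0.8)
#' correlation_fisher(x, y)
#' @export
correlation_fisher <- function(x, y, robust = FALSE, conf_level = 0.95) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 4) abort("need n >= 4", class = "tpk_invalid_input")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("zero variance in x or y", class = "tpk_invalid_input")
  }
  r <- if (robust) pbend_cor(x, y) else cor(x, y)
  ci <- fisher_ci(r, n, conf_level)
  p <- if (abs(r) >= 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tt), df = n - 2)
  }
  structure(list(r = r, ci95 = ci, p = p, n = n,
                 method = if (robust) "percentage-bend" else "pearson",
                 conf_level = conf_level),
            class = "tpk_cor")
}

#' @export
print.tpk_cor <- function(x, ...) {
  cat(sprintf("<tpk_cor> %s r = %.3f (95%% CI %.3f to %.3f), n = %d, p = %.3g\n",
              x$method, x$r, x$ci95[1], x$ci95[2], x$n, x$p))
  invisible(x)
}

#' Longitudinal linear mixed model on log concentrations
#'
#' Maximum-likelihood fit of log concentration on group, time, their
#' interaction and catheter, with a per-subject random intercept and
#' slope. Exponentiated fixed effects are returned as ratios with Wald
#' 95% CIs: the group level effect (obese / non-obese concentration
#' ratio at time zero), the right / left catheter ratio, and the
#' decline-rate ratio (obese slope / non-obese slope, delta-method CI).
#' A singular random-effects fit falls back to a random intercept only,
#' with a warning.
#'
#' @param data A tibble with columns `subject_id`, `group`
#'   (`obese` / `non_obese`), `catheter` (optional), `t` and `conc`
#'   (> 0; non-positive and missing values are dropped).
#' @param ref_group Reference group level (default `"non_obese"`).
#' @return An object of class `tpk_lmm` with the `lme4` fit and the
#'   three ratio estimates with CIs. Has [tidy()] and [glance()] methods.
#' @export
longitudinal_mixed_model <- function(data, ref_group = "non_obese") {
  stopifnot(all(c("subject_id", "group", "t", "conc") %in% names(data)))
  d <- data |>
    dplyr::filter(!is.na(.data$conc), .data$conc > 0) |>
    dplyr::mutate(group = stats::relevel(factor(.data$group), ref = ref_group),
                  logc = log(.data$conc))
  if (dplyr::n_distinct(d$group) < 2) {
    abort("need both groups", class = "tpk_invalid_input")
  }
  has_cath <- "catheter" %in% names(d) && dplyr::n_distinct(d$catheter) > 1
  fixed <- paste("logc ~ group * t", if (has_cath) "+ catheter" else "")
  fml <- stats::as.formula(paste(fixed, "+ (1 + t | subject_id)"))
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  fit <- suppressMessages(lme4::lmer(fml, data = d, REML = FALSE,
                                     control = ctrl))
  fallback <- FALSE
  if (lme4::isSingular(fit, tol = 1e-4)) {
    warn("singular random intercept+slope fit; falling back to random intercept only")
    fallback <- TRUE
    fml2 <- stats::as.formula(paste(fixed, "+ (1 | subject_id)"))
    fit <- suppressMessages(lme4::lmer(fml2, data = d, REML = FALSE,
                                       control = ctrl))
  }
  fe <- lme4::fixef(fit)
  vc <- as.matrix(stats::vcov(fit))
  z <- qnorm(0.975)
  grp_term <- grep("^group", names(fe), value = TRUE)[1]
  int_term <- grep("^group.*:t$", names(fe), value = TRUE)[1]
  ratio_ci <- function(term) {
    est <- fe[[term]]
    se <- sqrt(vc[term, term])
    list(ratio = exp(est), ci = exp(est + c(-1, 1) * z * se),
         p = 2 * pnorm(-abs(est / se)))
  }
  grp <- ratio_ci(grp_term)
  cath <- if (has_cath) {
    ct <- grep("^catheter", names(fe), value = TRUE)[1]
    ratio_ci(ct)
  } else NULL
  # decline-rate ratio (b_t + b_int) / b_t, delta-method SE on the log
  # of the ratio is not defined when signs differ; use the ratio scale
  bt <- fe[["t"]]
  bi <- fe[[int_term]]
  ratio <- (bt + bi) / bt
  grad <- c(-bi / bt^2, 1 / bt) # d ratio / d (bt, bi)
  vsub <- vc[c("t", int_term), c("t", int_term)]
  se_r <- sqrt(drop(t(grad) %*% vsub %*% grad))
  decline <- list(ratio = ratio, ci = ratio + c(-1, 1) * z * se_r,
                  p = 2 * pnorm(-abs(bi / sqrt(vc[int_term, int_term]))))
  vcre <- as.data.frame(lme4::VarCorr(fit))
  structure(
    list(fit = fit, n_obs = nrow(d),
         n_subjects = dplyr::n_distinct(d$subject_id),
         group_ratio = grp$ratio, group_ratio_ci = grp$ci, group_p = grp$p,
         decline_rate_ratio = decline$ratio, decline_rate_ci = decline$ci,
         decline_p = decline$p,
         catheter_ratio = if (has_cath) cath$ratio else NA_real_,
         catheter_ratio_ci = if (has_cath) cath$ci else c(NA_real_, NA_real_),
         catheter_p = if (has_cath) cath$p else NA_real_,
         re_sd = stats::setNames(vcre$sdcor[vcre$grp == "subject_id"],
                                 vcre$var1[vcre$grp == "subject_id"]),
         sigma = stats::sigma(fit), singular_fallback = fallback),
    class = "tpk_lmm"
  )
}

#' @export
print.tpk_lmm <- function(x, ...) {
  cat("<tpk_lmm> log-concentration mixed model",
      if (x$singular_fallback) "(random intercept fallback)" else "", "\n")
  cat(sprintf("  group ratio (obese/non-obese): %.3f (95%% CI %.3f to %.3f)\n",
              x$group_ratio, x$group_ratio_ci[1], x$group_ratio_ci[2]))
  cat(sprintf("  decline-rate ratio:            %.3f (95%% CI %.3f to %.3f)\n",
              x$decline_rate_ratio, x$decline_rate_ci[1], x$decline_rate_ci[2]))
  if (!is.na(x$catheter_ratio)) {
    cat(sprintf("  catheter ratio (right/left):   %.3f (95%% CI %.3f to %.3f)\n",
                x$catheter_ratio, x$catheter_ratio_ci[1], x$catheter_ratio_ci[2]))
  }
  invisible(x)
}

#' Sample size to detect a correlation
#'
#' Smallest n reaching the target power for a two-sided test of zero
#' correlation under the Fisher-Z approximation:
#' `n = ceiling(((z_{1-alpha/2} + z_{power}) / atanh(r))^2 + 3)`,
#' floored at 4.
#'
#' @param r_target Correlation to detect, in (0, 1).
#' @param power Target power (default 0.80).
#' @param alpha Two-sided significance level (default 0.05).
#' @return Integer sample size.
#' @examples
#' sample_size_correlation(0.52) # 27
#' @export
sample_size_correlation <- function(r_target, power = 0.80, alpha = 0.05) {
  if (is.na(r_target) || r_target <= 0 || r_target >= 1) {
    abort("r_target must be in (0, 1)", class = "tpk_invalid_input")
  }
  if (power <= 0 || power >= 1 || alpha <= 0 || alpha >= 1) {
    abort("power and alpha must be in (0, 1)", class = "tpk_invalid_input")
  }
  zsum <- qnorm(1 - alpha / 2) + qnorm(power)
  if (zsum <= 0) return(4L) # vanishing power: the formula floor applies
  n <- ceiling((zsum / atanh(r_target))^2 + 3)
  max(as.integer(n), 4L)
}

#' Two-group comparison of a PK parameter
#'
#' Welch's t-test (default) or a rank-based alternative comparing a
#' parameter between groups, reporting the difference (or, on the log
#' scale, the ratio) with a 95% CI and two-sided p-value. Degenerate
#' inputs (both groups constant) are handled explicitly: identical
#' groups give difference 0 with p = 1.
#'
#' @param data A tibble with the value column and a `group` column.
#' @param value Name of the value column (string).
#' @param ref_group Reference group; the estimate is (other - reference)
#'   or other / reference on the log scale.
#' @param method `"welch"` or `"wilcoxon"`.
#' @param log_scale Compare on the log scale and report a ratio.
#' @return A one-row tibble: `estimate`, `ci_lo`, `ci_hi`, `p`,
#'   `scale` (`"difference"` / `"ratio"`), `method`, `n1`, `n2`.
#' @export
group_compare <- function(data, value, ref_group = "non_obese",
                          method = c("welch", "wilcoxon"),
                          log_scale = FALSE) {
  method <- match.arg(method)
  stopifnot(all(c(value, "group") %in% names(data)))
  d <- data[!is.na(data[[value]]), ]
  grps <- unique(d$group)
  if (length(grps) != 2 || !ref_group %in% grps) {
    abort("need exactly two groups including the reference",
          class = "tpk_invalid_input")
  }
  other <- setdiff(grps, ref_group)
  x <- d[[value]][d$group == other]
  y <- d[[value]][d$group == ref_group]
  if (length(x) < 2 || length(y) < 2) {
    abort("need at least 2 observations per group", class = "tpk_invalid_input")
  }
  if (log_scale) {
    if (any(c(x, y) <= 0)) abort("log scale requires positive values",
                                 class = "tpk_invalid_input")
    x <- log(x)
    y <- log(y)
  }
  back <- if (log_scale) exp else identity
  res <- if (method == "welch") {
    if (sd(x) == 0 && sd(y) == 0) {
      dd <- mean(x) - mean(y)
      list(estimate = dd, ci = c(dd, dd), p = if (dd == 0) 1 else 0)
    } else {
      tt <- t.test(x, y)
      list(estimate = unname(diff(rev(tt$estimate))), ci = tt$conf.int,
           p = tt$p.value)
    }
  } else {
    wt <- wilcox.test(x, y, conf.int = TRUE, exact = FALSE)
    list(estimate = unname(wt$estimate), ci = wt$conf.int, p = wt$p.value)
  }
  tibble(
    estimate = back(res$estimate), ci_lo = back(res$ci[1]),
    ci_hi = back(res$ci[2]), p = res$p,
    scale = if (log_scale) "ratio" else "difference",
    method = method, n1 = length(x), n2 = length(y)
  )
}
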