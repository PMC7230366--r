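# broom-style tidiers for the fitted-object classes.

#' Tidy a correlation result
#'
#' @param x A `tpk_cor` from [correlation_fisher()].
#' @param ... Unused.
#' @return A one-row tibble: `estimate`, `conf.low`, `conf.high`,
#'   `p.value`, `n`, `method`.
#' @method tidy tpk_cor
#' @export
tidy.tpk_cor <- function(x, ...) {
  tibble(estimate = x$r, conf.low = x$ci95[1], conf.high = x$ci95[2],
         p.value = x$p, n = x$n, method = x$method)
}

#' @rdname tidy.tpk_cor
#' @method glance tpk_cor
#' @export
glance.tpk_cor <- function(x, ...) tidy.tpk_cor(x)

#' Tidy an exposure-size regression
#'
#' @param x A `tpk_reg` from [auc_weight_regression()].
#' @param ... Unused.
#' @return `tidy()`: one row per coefficient with Wald 95% CIs, plus a
#'   `slope_per_10` row for the size covariate rescaled to a 10-unit
#'   increment. `glance()`: model-level statistics.
#' @method tidy tpk_reg
#' @export
tidy.tpk_reg <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))$coefficients
  ci <- suppressWarnings(confint(x$fit))
  base <- tibble(
    term = rownames(s), estimate = s[, "Estimate"],
    std.error = s[, "Std. Error"], p.value = s[, "Pr(>|t|)"],
    conf.low = ci[, 1], conf.high = ci[, 2]
  )
  dplyr::bind_rows(
    base,
    tibble(term = paste0(x$size, "_per_10"), estimate = x$slope_per_10,
           std.error = 10 * s[x$size, "Std. Error"], p.value = x$p,
           conf.low = x$ci95[1], conf.high = x$ci95[2])
  )
}

#' @rdname tidy.tpk_reg
#' @method glance tpk_reg
#' @export
glance.tpk_reg <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))
  tibble(r.squared = s$r.squared, adj.r.squared = s$adj.r.squared,
         sigma = s$sigma, nobs = x$n, outcome = x$outcome, size = x$size)
}

#' Tidy a longitudinal mixed-model fit
#'
#' @param x A `tpk_lmm` from [longitudinal_mixed_model()].
#' @param ... Unused.
#' @return `tidy()`: one row per reported ratio (`group_ratio`,
#'   `decline_rate_ratio`, `catheter_ratio`) with 95% CIs and p-values.
#'   `glance()`: fit-level statistics including random-effect SDs.
#' @method tidy tpk_lmm
#' @export
tidy.tpk_lmm <- function(x, ...) {
  tibble(
    term = c("group_ratio", "decline_rate_ratio", "catheter_ratio"),
    estimate = c(x$group_ratio, x$decline_rate_ratio, x$catheter_ratio),
    conf.low = c(x$group_ratio_ci[1], x$decline_rate_ci[1],
                 x$catheter_ratio_ci[1]),
    conf.high = c(x$group_ratio_ci[2], x$decline_rate_ci[2],
                  x$catheter_ratio_ci[2]),
    p.value = c(x$group_p, x$decline_p, x$catheter_p)
  )
}

#' @rdname tidy.tpk_lmm
#' @method glance tpk_lmm
#' @export
glance.tpk_lmm <- function(x, ...) {
  tibble(nobs = x$n_obs, n_subjects = x$n_subjects,
         sigma = x$sigma,
         re_sd_intercept = unname(x$re_sd["(Intercept)"]),
         re_sd_slope = if ("t" %in% names(x$re_sd)) {
           unname(x$re_sd["t"])
         } else NA_real_,
         logLik = as.numeric(stats::logLik(x$fit)),
         AIC = stats::AIC(x$fit),
         singular_fallback = x$singular_fallback)
}
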