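# ggplot2 figures: concentration-time curves and exposure-weight
# scatter plots.

#' Concentration-time plot of a simulated or measured cohort
#'
#' Geometric-mean concentration over time per matrix and group, with
#' the per-subject trajectories in the background.
#'
#' @param object A `tpk_cohort` from [simulate_cohort()].
#' @param matrices Which matrices to show (default plasma total/unbound).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tpk_cohort
#' @export
autoplot.tpk_cohort <- function(object,
                                matrices = c("plasma_total",
                                             "plasma_unbound"), ...) {
  d <- object$plasma |>
    dplyr::filter(.data$matrix %in% matrices, !.data$blq)
  mean_d <- d |>
    dplyr::group_by(.data$group, .data$matrix, .data$t) |>
    dplyr::summarise(conc = exp(mean(log(.data$conc))), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data$conc,
                                  colour = .data$group)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$subject_id),
                       alpha = 0.25, linewidth = 0.3) +
    ggplot2::geom_line(data = mean_d, linewidth = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$matrix)) +
    ggplot2::labs(x = "Time (h)", y = "Concentration (mg/L)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the ISF profiles of a pipeline report
#'
#' Recovery-corrected ISF concentrations at interval midpoints, per
#' subject, coloured by group.
#'
#' @param report A `tpk_report` from [run_pipeline()].
#' @return A ggplot object.
#' @export
plot_isf_profiles <- function(report) {
  stopifnot(inherits(report, "tpk_report"))
  d <- report$isf_merged |> dplyr::filter(!.data$blq)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data$conc,
                                  colour = .data$group,
                                  group = .data$subject_id)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Time (h)", y = "ISF concentration (mg/L)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Exposure versus body weight
#'
#' Scatter of a per-subject exposure (AUC) against weight with the
#' fitted regression line, the visual counterpart of
#' [auc_weight_regression()].
#'
#' @param report A `tpk_report` from [run_pipeline()].
#' @param matrix Exposure matrix: `"isf"` (default) or a plasma matrix.
#' @return A ggplot object.
#' @export
plot_auc_weight <- function(report, matrix = "isf") {
  stopifnot(inherits(report, "tpk_report"))
  d <- report$nca |>
    dplyr::filter(.data$matrix == !!matrix) |>
    dplyr::left_join(report$subjects[c("subject_id", "weight")],
                     by = "subject_id")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$weight, y = .data$auc_0_8)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$group)) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         colour = "grey30", linewidth = 0.6) +
    ggplot2::labs(x = "Weight (kg)",
                  y = sprintf("AUC0-8 %s (mg·h/L)", matrix),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
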