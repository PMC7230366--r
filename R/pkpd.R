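# fAUC24/MIC exposure indices over an MIC grid and attainment of the
# therapeutic target fAUC24/MIC > 80.

#' fAUC24/MIC over an MIC grid
#'
#' Divides a daily unbound exposure by each MIC on the grid and flags
#' attainment of the target. The comparison is strict (`ratio >
#' threshold`): a ratio exactly at the threshold is not attained.
#'
#' @param fauc24 Daily AUC of unbound drug (mg h/L), > 0.
#' @param mic MIC grid in mg/L (default `c(0.5, 1, 2, 4)`), all > 0.
#' @param threshold Attainment threshold (default 80).
#' @return A tibble with columns `mic`, `ratio` and `attained`. Ratios
#'   halve exactly across doubling MICs.
#' @examples
#' fauc_over_mic(176.8 * 0.5) # the all-patients ISF exposure
#' @export
fauc_over_mic <- function(fauc24, mic = c(0.5, 1, 2, 4), threshold = 80) {
  if (length(fauc24) != 1 || is.na(fauc24) || fauc24 <= 0) {
    abort("fauc24 must be a single positive value", class = "tpk_invalid_input")
  }
  if (any(is.na(mic)) || any(mic <= 0)) {
    abort("all MICs must be > 0", class = "tpk_invalid_input")
  }
  tibble(mic = mic, ratio = fauc24 / mic, attained = fauc24 / mic > threshold)
}

#' Group-level fAUC24/MIC attainment summary
#'
#' Builds the target-attainment table: per group, matrix and MIC, the
#' median [IQR] of individual fAUC24/MIC ratios, the fraction of
#' subjects attaining the target, and whether the group median attains
#' it (strict inequality).
#'
#' @param exposures A tibble with one row per subject and matrix,
#'   columns `subject_id`, `matrix`, `fauc24` and optionally `group`
#'   (a single pseudo-group is used when absent).
#' @param mic MIC grid (mg/L).
#' @param threshold Attainment threshold (default 80).
#' @return A tibble: `group`, `matrix`, `mic`, `n`, `median`, `q25`,
#'   `q75`, `frac_attained`, `median_attained`.
#' @export
attainment_summary <- function(exposures, mic = c(0.5, 1, 2, 4),
                               threshold = 80) {
  stopifnot(all(c("subject_id", "matrix", "fauc24") %in% names(exposures)))
  if (nrow(exposures) == 0) {
    abort("no exposures supplied", class = "tpk_invalid_input")
  }
  if (!"group" %in% names(exposures)) exposures$group <- "all"
  ratios <- exposures |>
    dplyr::filter(!is.na(.data$fauc24)) |>
    tidyr::expand_grid(mic = mic) |>
    dplyr::mutate(ratio = .data$fauc24 / .data$mic)
  ratios |>
    dplyr::group_by(.data$group, .data$matrix, .data$mic) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = median(.data$ratio),
      q25 = unname(quantile(.data$ratio, 0.25)),
      q75 = unname(quantile(.data$ratio, 0.75)),
      frac_attained = mean(.data$ratio > threshold),
      median_attained = median(.data$ratio) > threshold,
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$matrix, .data$group, .data$mic)
}
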