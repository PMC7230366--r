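# Retrodialysis recovery calibration and conversion of raw dialysate
# data into interstitial-fluid concentration-time profiles.

#' Relative recovery from a retrodialysis calibration pair
#'
#' During retrodialysis the perfusate is spiked with drug and the loss
#' across the membrane measures how completely the catheter samples the
#' surrounding fluid: recovery (%) = (1 - C_RD / C_RP) x 100, with C_RP
#' the retroperfusate and C_RD the retrodialysate concentration.
#'
#' @param c_rd Retrodialysate concentration (mg/L).
#' @param c_rp Retroperfusate concentration (mg/L), must be > 0.
#' @return Relative recovery in percent, in (0, 100].
#' @section Errors: `c_rp <= 0` or `c_rd < 0` raises
#'   `tpk_invalid_calibration`; a non-positive recovery (no measurable
#'   loss, i.e. an unusable catheter) raises `tpk_calibration_failure`
#'   so the caller can exclude the catheter, as was done in the study
#'   when a catheter failed.
#' @examples
#' relative_recovery(c_rd = 5.2, c_rp = 10) # 48%
#' @export
relative_recovery <- function(c_rd, c_rp) {
  if (any(c_rp <= 0) || any(c_rd < 0)) {
    abort("calibration requires c_rp > 0 and c_rd >= 0",
          class = "tpk_invalid_calibration")
  }
  rec <- (1 - c_rd / c_rp) * 100
  if (any(rec <= 0)) {
    abort("relative recovery <= 0%: catheter calibration failed",
          class = "tpk_calibration_failure")
  }
  rec
}

#' ISF concentration from a dialysate concentration
#'
#' Inverts the recovery loss: C_ISF = C_uD x 100 / recovery.
#'
#' @param c_ud Microdialysate concentration (mg/L), >= 0.
#' @param recovery Relative recovery in percent, in (0, 100].
#' @return ISF concentration (mg/L).
#' @examples
#' isf_concentration(1.92, 48) # 4 mg/L
#' @export
isf_concentration <- function(c_ud, recovery) {
  if (any(recovery <= 0) || any(recovery > 100)) {
    abort("recovery must be in (0, 100]", class = "tpk_calibration_failure")
  }
  if (any(c_ud < 0, na.rm = TRUE)) {
    abort("dialysate concentration must be >= 0", class = "tpk_invalid_input")
  }
  c_ud * 100 / recovery
}

check_intervals <- function(series) {
  stopifnot(all(c("t_start", "t_end") %in% names(series)))
  if (any(series$t_end <= series$t_start)) {
    abort("intervals must have t_end > t_start", class = "tpk_invalid_input")
  }
  s <- series[order(series$t_start), ]
  if (nrow(s) > 1 && any(s$t_start[-1] < s$t_end[-nrow(s)] - 1e-9)) {
    abort("intervals must not overlap", class = "tpk_invalid_input")
  }
  s
}

#' Map interval dialysate collections to a point ISF profile
#'
#' Each collection interval is recovery-corrected and assigned to its
#' midpoint time: an interval (t1, t2) with dialysate concentration C
#' becomes a record at (t1 + t2) / 2 with concentration
#' `isf_concentration(C, recovery)`. BLQ intervals are retained as
#' flagged records with missing concentration.
#'
#' @param series A tibble of one catheter's collections with columns
#'   `t_start`, `t_end`, `conc` (dialysate mg/L, `NA` allowed when BLQ)
#'   and optionally `blq`; additional identifier columns
#'   (`subject_id`, `catheter`, ...) are carried through.
#' @param recovery The catheter's relative recovery in percent.
#' @return A tibble with `t` (midpoint, h), `conc` (ISF mg/L) and `blq`,
#'   ordered by time; identifier columns preserved.
#' @examples
#' series <- dialysate_schedule()
#' series$conc <- 2 * exp(-0.2 * rowMeans(series))
#' dialysate_to_isf(series, recovery = 48)
#' @export
dialysate_to_isf <- function(series, recovery) {
  if (nrow(series) == 0) {
    warn("empty dialysate series: returning empty profile")
    return(tibble(t = numeric(), conc = numeric(), blq = logical()))
  }
  s <- check_intervals(series)
  if (!"blq" %in% names(s)) s$blq <- is.na(s$conc)
  keep <- setdiff(names(s), c("t_start", "t_end", "conc", "blq"))
  out <- tibble(
    t = (s$t_start + s$t_end) / 2,
    conc = ifelse(s$blq, NA_real_, isf_concentration(ifelse(s$blq, 0, s$conc),
                                                     recovery)),
    blq = s$blq
  )
  dplyr::bind_cols(s[keep], out)
}

#' Average the ISF profiles of the two catheters
#'
#' Quantifiable values at a common time are averaged on the arithmetic
#' concentration scale; times where only one catheter is quantifiable
#' pass through; times where both are BLQ (or missing) are dropped from
#' the quantifiable profile but retained as BLQ records.
#'
#' @param left,right Tibbles with columns `t`, `conc`, `blq` (as from
#'   [dialysate_to_isf()]). Either may be `NULL` or empty (e.g. a
#'   catheter that slipped out), in which case the other passes through.
#' @return A tibble `t`, `conc`, `blq`, plus `n_catheters` recording how
#'   many catheters contributed at each time.
#' @export
merge_catheters <- function(left, right) {
  norm <- function(x) {
    if (is.null(x) || nrow(x) == 0) {
      return(tibble(t = numeric(), conc = numeric(), blq = logical()))
    }
    if (!"blq" %in% names(x)) x$blq <- is.na(x$conc)
    x[c("t", "conc", "blq")]
  }
  dplyr::bind_rows(norm(left), norm(right)) |>
    dplyr::group_by(.data$t) |>
    dplyr::summarise(
      n_catheters = sum(!.data$blq & !is.na(.data$conc)),
      conc = if (any(!.data$blq & !is.na(.data$conc))) {
        mean(.data$conc[!.data$blq & !is.na(.data$conc)])
      } else NA_real_,
      blq = all(.data$blq | is.na(.data$conc)),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$t) |>
    dplyr::select("t", "conc", "blq", "n_catheters")
}

#' Per-catheter recovery calibration with exclusion decisions
#'
#' Applies [relative_recovery()] to every calibration pair, flagging
#' catheters whose calibration fails (recovery <= 0 or invalid inputs)
#' instead of raising, so a whole-cohort run can proceed with the
#' surviving catheters.
#'
#' @param calibration A tibble with columns `subject_id`, `catheter`,
#'   `c_rp`, `c_rd`.
#' @return The input with `recovery_pct` (NA when excluded), `usable`
#'   and `reason` columns.
#' @export
calibrate_recoveries <- function(calibration) {
  stopifnot(all(c("subject_id", "catheter", "c_rp", "c_rd") %in%
                  names(calibration)))
  calibration |>
    dplyr::mutate(purrr::map2_dfr(.data$c_rd, .data$c_rp, function(rd, rp) {
      res <- rlang::try_fetch(
        tibble(recovery_pct = relative_recovery(rd, rp), usable = TRUE,
               reason = NA_character_),
        tpk_calibration_failure = function(e) {
          tibble(recovery_pct = NA_real_, usable = FALSE,
                 reason = "recovery <= 0")
        },
        tpk_invalid_calibration = function(e) {
          tibble(recovery_pct = NA_real_, usable = FALSE,
                 reason = "invalid calibration pair")
        }
      )
      res
    }))
}
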