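# CSV interchange for concentration-time data. One fixed column
# contract covers point samples (plasma) and interval collections
# (microdialysate):
#   subject_id, group, matrix, catheter, time_or_tstart, tend,
#   conc_mg_L, blq, lloq
# Point records leave `tend` (and `catheter`) empty; BLQ cells may hold
# the literal "BLQ" in `conc_mg_L`.

tpk_csv_cols <- c("subject_id", "group", "matrix", "catheter",
                  "time_or_tstart", "tend", "conc_mg_L", "blq", "lloq")

tpk_matrices <- c("plasma_total", "plasma_unbound", "microdialysate", "isf")

#' Read / write concentration data CSV
#'
#' `read_concentration_csv()` validates the header, the matrix labels,
#' strictly increasing times within each subject x matrix x catheter
#' series, and BLQ consistency (a numeric value below its LLOQ, or the
#' literal `"BLQ"`, is flagged); errors name the offending row.
#' `write_concentration_csv()` writes the same layout at full
#' precision, storing BLQ concentrations as `"BLQ"`, so that
#' write-then-read round-trips exactly.
#'
#' @param path File path.
#' @param data A tibble in the canonical layout (as `simulate_cohort()$data`).
#' @return A tibble in the canonical layout (`read`), or `path`
#'   invisibly (`write`).
#' @export
read_concentration_csv <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(), group = readr::col_character(),
    matrix = readr::col_character(), catheter = readr::col_character(),
    time_or_tstart = readr::col_double(), tend = readr::col_double(),
    conc_mg_L = readr::col_character(), blq = readr::col_logical(),
    lloq = readr::col_double()
  ), na = c("", "NA"))
  missing_cols <- setdiff(tpk_csv_cols, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste("missing columns:", paste(missing_cols, collapse = ", ")),
          class = "tpk_parse_error")
  }
  bad_matrix <- which(!raw$matrix %in% tpk_matrices)
  if (length(bad_matrix) > 0) {
    abort(sprintf("unknown matrix label '%s' in row %d",
                  raw$matrix[bad_matrix[1]], bad_matrix[1]),
          class = "tpk_parse_error")
  }
  is_blq_cell <- toupper(trimws(raw$conc_mg_L)) %in% "BLQ"
  conc <- suppressWarnings(as.numeric(raw$conc_mg_L))
  bad_num <- which(!is_blq_cell & !is.na(raw$conc_mg_L) & is.na(conc))
  if (length(bad_num) > 0) {
    abort(sprintf("unparseable concentration '%s' in row %d",
                  raw$conc_mg_L[bad_num[1]], bad_num[1]),
          class = "tpk_parse_error")
  }
  out <- raw |>
    dplyr::mutate(
      conc_mg_L = ifelse(is_blq_cell, NA_real_, conc),
      blq = dplyr::coalesce(.data$blq, FALSE) | is_blq_cell |
        (!is.na(conc) & conc < .data$lloq)
    )
  # strictly increasing times within each series; errors name the row
  out |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(.data$subject_id, .data$matrix, .data$catheter) |>
    dplyr::arrange(.data$time_or_tstart, .by_group = TRUE) |>
    dplyr::mutate(.dup = duplicated(.data$time_or_tstart)) |>
    dplyr::ungroup() |>
    (function(d) {
      if (any(d$.dup)) {
        r <- d$.row[d$.dup][1]
        abort(sprintf("non-increasing time in row %d (subject %s, matrix %s)",
                      r, d$subject_id[d$.dup][1], d$matrix[d$.dup][1]),
              class = "tpk_parse_error")
      }
      d
    })()
  out[tpk_csv_cols]
}

#' @rdname read_concentration_csv
#' @export
write_concentration_csv <- function(data, path) {
  missing_cols <- setdiff(tpk_csv_cols, names(data))
  if (length(missing_cols) > 0) {
    abort(paste("missing columns:", paste(missing_cols, collapse = ", ")),
          class = "tpk_parse_error")
  }
  out <- data[tpk_csv_cols] |>
    dplyr::mutate(conc_mg_L = dplyr::case_when(
      .data$blq & is.na(.data$conc_mg_L) ~ "BLQ",
      is.na(.data$conc_mg_L) ~ NA_character_,
      TRUE ~ sprintf("%.17g", .data$conc_mg_L) # full-precision round trip
    ))
  readr::write_csv(out, path)
  invisible(path)
}

# split the canonical table back into plasma point data and dialysate
# interval data
split_canonical <- function(data) {
  plasma <- data |>
    dplyr::filter(startsWith(.data$matrix, "plasma")) |>
    dplyr::transmute(.data$subject_id, .data$group, .data$matrix,
                     t = .data$time_or_tstart, conc = .data$conc_mg_L,
                     .data$blq, .data$lloq)
  dialysate <- data |>
    dplyr::filter(.data$matrix == "microdialysate") |>
    dplyr::transmute(.data$subject_id, .data$group, .data$catheter,
                     t_start = .data$time_or_tstart, t_end = .data$tend,
                     conc = .data$conc_mg_L, .data$blq, .data$lloq)
  list(plasma = plasma, dialysate = dialysate)
}
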