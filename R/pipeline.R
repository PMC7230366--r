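# End-to-end orchestration: simulate (or ingest) -> recovery
# calibration -> ISF profiles -> NCA -> fAUC24/MIC targets -> cohort
# statistics, producing a study-report object with Table 1/2/3-shaped
# summaries.

#' Run the full target-site PK pipeline
#'
#' With only a `config`, simulates a synthetic cohort and analyses it;
#' alternatively takes measured data in the canonical CSV layout plus
#' its calibration pairs and subject covariates. Every exclusion
#' (failed catheter calibration, non-estimable terminal phase) is
#' recorded in the report's exclusion log. For a fixed config and seed
#' the report is a pure function of its inputs.
#'
#' @param config A [cohort_config()]; used to simulate when `data` is
#'   `NULL`, and always the source of dose, infusion time, unbound
#'   fraction and LLOQ.
#' @param data Optional canonical concentration table (see
#'   [read_concentration_csv()]).
#' @param calibration Optional retrodialysis calibration pairs
#'   (`subject_id`, `catheter`, `c_rp`, `c_rd`); required with `data`.
#' @param subjects Optional subject covariates (`subject_id`, `group`,
#'   `sex`, `weight`, `bmi`); required with `data`.
#' @param mic MIC grid (mg/L).
#' @param threshold fAUC24/MIC attainment threshold (default 80).
#' @param out_dir Optional directory; when given, all intermediate and
#'   final tables are written there as CSV via [write_report()].
#' @return An object of class `tpk_report`; see Details.
#' @details The report bundles `subjects`, `recoveries`, `isf_profiles`
#'   (per catheter and merged), `nca` (per subject x matrix),
#'   `exposures` (fAUC24), `table1` (cohort summary), `table2` (PK
#'   parameter medians with group comparisons), `table3` (target
#'   attainment), `stats` (regressions, correlations, mixed models,
#'   sample size), `exclusions` and `config`.
#' @examples
#' rep <- run_pipeline(cohort_config(n_per_group = 3, seed = 42))
#' rep$table3
#' @export
run_pipeline <- function(config = cohort_config(), data = NULL,
                         calibration = NULL, subjects = NULL,
                         mic = c(0.5, 1, 2, 4), threshold = 80,
                         out_dir = NULL) {
  validate_config(config)
  truth <- NULL
  if (is.null(data)) {
    sim <- simulate_cohort(config)
    data <- sim$data
    calibration <- sim$calibration
    subjects <- sim$subjects
    truth <- sim$truth
  } else if (is.null(calibration) || is.null(subjects)) {
    abort("measured data require `calibration` and `subjects`",
          class = "tpk_stage_error")
  }
  exclusions <- tibble(subject_id = character(), stage = character(),
                       item = character(), reason = character())
  note_exclusion <- function(subject_id, stage, item, reason) {
    dplyr::bind_rows(exclusions,
                     tibble(subject_id = subject_id, stage = stage,
                            item = item, reason = reason))
  }

  # --- stage: recovery calibration -------------------------------------
  recoveries <- with_stage("recovery", calibrate_recoveries(calibration))
  for (i in which(!recoveries$usable)) {
    exclusions <- note_exclusion(recoveries$subject_id[i], "recovery",
                                 recoveries$catheter[i], recoveries$reason[i])
  }

  # --- stage: dialysate -> ISF profiles --------------------------------
  parts <- with_stage("isf", {
    split <- split_canonical(data)
    per_cath <- split$dialysate |>
      dplyr::inner_join(recoveries[c("subject_id", "catheter",
                                     "recovery_pct", "usable")],
                        by = c("subject_id", "catheter")) |>
      dplyr::filter(.data$usable)
    isf_cath <- per_cath |>
      dplyr::group_by(.data$subject_id, .data$group, .data$catheter) |>
      dplyr::group_modify(function(d, k) {
        dialysate_to_isf(d[c("t_start", "t_end", "conc", "blq")],
                         recovery = d$recovery_pct[1])
      }) |>
      dplyr::ungroup()
    merged <- isf_cath |>
      dplyr::group_by(.data$subject_id, .data$group) |>
      dplyr::group_modify(function(d, k) {
        merge_catheters(d[d$catheter == "left", c("t", "conc", "blq")],
                        d[d$catheter == "right", c("t", "conc", "blq")])
      }) |>
      dplyr::ungroup()
    list(plasma = split$plasma, isf_cath = isf_cath, merged = merged)
  })

  # --- stage: NCA ------------------------------------------------------
  nca_tbl <- with_stage("nca", {
    nca_input <- dplyr::bind_rows(
      parts$plasma,
      parts$merged |> dplyr::mutate(matrix = "isf")
    )
    nca(nca_input, dose = config$dose, t_inf = config$t_inf, t_end = 8)
  })
  for (i in which(is.na(nca_tbl$lambda_z))) {
    exclusions <- note_exclusion(nca_tbl$subject_id[i], "nca",
                                 nca_tbl$matrix[i],
                                 "terminal phase not estimable")
  }

  # --- stage: fAUC24 exposures and targets -----------------------------
  table3 <- NULL
  exposures <- with_stage("targets", {
    unbound <- nca_tbl |>
      dplyr::filter(.data$matrix == "plasma_unbound") |>
      dplyr::transmute(.data$subject_id, .data$group, matrix = "plasma",
                       fauc24 = .data$auc_24)
    if (nrow(unbound) == 0) {
      # fall back to total x fu when unbound was not measured
      unbound <- nca_tbl |>
        dplyr::filter(.data$matrix == "plasma_total") |>
        dplyr::transmute(.data$subject_id, .data$group, matrix = "plasma",
                         fauc24 = config$fu * .data$auc_24)
    }
    isf_exp <- nca_tbl |>
      dplyr::filter(.data$matrix == "isf") |>
      dplyr::transmute(.data$subject_id, .data$group, matrix = "isf",
                       fauc24 = .data$auc_24) # ISF is entirely unbound
    dplyr::bind_rows(isf_exp, unbound)
  })
  table3 <- with_stage("targets", dplyr::bind_rows(
    attainment_summary(exposures, mic = mic, threshold = threshold),
    attainment_summary(dplyr::mutate(exposures, group = "all"),
                       mic = mic, threshold = threshold)
  ))

  # --- stage: statistics ----------------------------------------------
  # each analysis is computed independently; ones that are not
  # estimable on the given cohort (e.g. too few subjects) are NULL and
  # logged rather than failing the run
  stat_notes <- character()
  safe_stat <- function(name, expr) {
    rlang::try_fetch(expr, error = function(e) {
      stat_notes <<- c(stat_notes,
                       paste0(name, ": ", conditionMessage(e)))
      NULL
    })
  }
  stats_out <- with_stage("stats", {
    covs <- subjects[c("subject_id", "group", "sex", "weight", "bmi")]
    wide <- nca_tbl |>
      dplyr::select("subject_id", "matrix", "auc_0_8") |>
      tidyr::pivot_wider(names_from = "matrix", values_from = "auc_0_8",
                         names_prefix = "auc8_") |>
      dplyr::left_join(covs, by = "subject_id")
    if ("auc8_plasma_unbound" %in% names(wide)) {
      wide$fauc8_plasma <- wide$auc8_plasma_unbound
    } else {
      wide$fauc8_plasma <- config$fu * wide$auc8_plasma_total
    }
    cath_long <- parts$isf_cath |>
      dplyr::select("subject_id", "group", "catheter", "t", "conc")
    plasma_long <- parts$plasma |>
      dplyr::filter(.data$matrix == "plasma_unbound", .data$t > 0) |>
      dplyr::select("subject_id", "group", "t", "conc")
    list(
      reg_isf = safe_stat("reg_isf",
                          auc_weight_regression(wide, "auc8_isf", "weight")),
      reg_plasma = safe_stat("reg_plasma",
                             auc_weight_regression(wide, "fauc8_plasma",
                                                   "weight")),
      cor_weight_isf = safe_stat("cor_weight_isf",
                                 correlation_fisher(wide$weight,
                                                    wide$auc8_isf)),
      cor_weight_plasma = safe_stat("cor_weight_plasma",
                                    correlation_fisher(wide$weight,
                                                       wide$fauc8_plasma)),
      cor_bmi_isf = safe_stat("cor_bmi_isf",
                              correlation_fisher(wide$bmi, wide$auc8_isf)),
      cor_bmi_plasma = safe_stat("cor_bmi_plasma",
                                 correlation_fisher(wide$bmi,
                                                    wide$fauc8_plasma)),
      lmm_isf = safe_stat("lmm_isf", longitudinal_mixed_model(cath_long)),
      lmm_plasma = safe_stat("lmm_plasma",
                             longitudinal_mixed_model(plasma_long)),
      sample_size = sample_size_correlation(0.52, 0.80, 0.05),
      notes = stat_notes
    )
  })

  table1 <- with_stage("report", cohort_summary(subjects))
  table2 <- with_stage("report", pk_parameter_table(nca_tbl, subjects))

  report <- structure(
    list(subjects = subjects, recoveries = recoveries,
         isf_profiles = parts$isf_cath, isf_merged = parts$merged,
         nca = nca_tbl, exposures = exposures, truth = truth,
         table1 = table1, table2 = table2, table3 = table3,
         stats = stats_out, exclusions = exclusions, config = config,
         mic = mic, threshold = threshold),
    class = "tpk_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

with_stage <- function(stage, expr) {
  rlang::try_fetch(expr, error = function(e) {
    abort(paste0("pipeline stage '", stage, "' failed: ",
                 conditionMessage(e)),
          class = "tpk_stage_error", parent = e)
  })
}

cohort_summary <- function(subjects) {
  subjects |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_female = sum(.data$sex == "F"),
      age_mean = mean(.data$age), age_sd = sd(.data$age),
      weight_mean = mean(.data$weight), weight_sd = sd(.data$weight),
      bmi_mean = mean(.data$bmi), bmi_sd = sd(.data$bmi),
      .groups = "drop"
    )
}

pk_parameter_table <- function(nca_tbl, subjects) {
  params <- tibble::tribble(
    ~parameter, ~matrix, ~log_scale,
    "cmax", "isf", TRUE,
    "cmax", "plasma_total", TRUE,
    "cmax", "plasma_unbound", TRUE,
    "t_half", "isf", FALSE,
    "t_half", "plasma_total", FALSE,
    "vss", "plasma_total", FALSE,
    "cl", "plasma_total", FALSE,
    "mrt", "plasma_total", FALSE,
    "auc_0_8", "isf", TRUE,
    "auc_0_8", "plasma_total", TRUE,
    "auc_0_8", "plasma_unbound", TRUE
  )
  long <- nca_tbl |>
    dplyr::select("subject_id", "group", "matrix", "cmax", "t_half",
                  "vss", "cl", "mrt", "auc_0_8") |>
    tidyr::pivot_longer(cols = c("cmax", "t_half", "vss", "cl", "mrt",
                                 "auc_0_8"),
                        names_to = "parameter", values_to = "value")
  purrr::pmap(params, function(parameter, matrix, log_scale) {
    d <- long[long$parameter == parameter & long$matrix == matrix &
                !is.na(long$value), ]
    if (nrow(d) == 0) return(NULL)
    med_iqr <- function(v) {
      c(median = median(v), q25 = unname(quantile(v, 0.25)),
        q75 = unname(quantile(v, 0.75)))
    }
    all_s <- med_iqr(d$value)
    by_grp <- lapply(split(d$value, d$group), med_iqr)
    p <- tryCatch(
      group_compare(d, "value", log_scale = log_scale)$p,
      error = function(e) NA_real_
    )
    tibble(
      parameter = parameter, matrix = matrix, n = nrow(d),
      all_median = all_s["median"], all_q25 = all_s["q25"],
      all_q75 = all_s["q75"],
      obese_median = by_grp$obese["median"] %||% NA_real_,
      obese_q25 = by_grp$obese["q25"] %||% NA_real_,
      obese_q75 = by_grp$obese["q75"] %||% NA_real_,
      non_obese_median = by_grp$non_obese["median"] %||% NA_real_,
      non_obese_q25 = by_grp$non_obese["q25"] %||% NA_real_,
      non_obese_q75 = by_grp$non_obese["q75"] %||% NA_real_,
      p = p
    )
  }) |>
    dplyr::bind_rows()
}

#' @export
print.tpk_report <- function(x, ...) {
  cat("<tpk_report>\n")
  cat(sprintf("  %d subjects, %d usable catheters, %d exclusions logged\n",
              nrow(x$subjects), sum(x$recoveries$usable), nrow(x$exclusions)))
  cat("  PK parameters (median [IQR] by group):\n")
  t2 <- x$table2
  for (i in seq_len(nrow(t2))) {
    cat(sprintf("    %-8s %-14s ob %6.2f [%6.2f,%6.2f]  non %6.2f [%6.2f,%6.2f]  p=%s\n",
                t2$parameter[i], t2$matrix[i], t2$obese_median[i],
                t2$obese_q25[i], t2$obese_q75[i], t2$non_obese_median[i],
                t2$non_obese_q25[i], t2$non_obese_q75[i],
                format.pval(t2$p[i], digits = 2)))
  }
  cat("  fAUC24/MIC medians (ISF):\n")
  t3 <- x$table3[x$table3$matrix == "isf" & x$table3$group != "all", ]
  for (i in seq_len(nrow(t3))) {
    cat(sprintf("    MIC %-4g %-9s %7.1f  attained: %s\n", t3$mic[i],
                t3$group[i], t3$median[i], t3$median_attained[i]))
  }
  invisible(x)
}

#' Write all report tables to a directory
#'
#' Writes the intermediate artifacts (recoveries, ISF profiles, NCA
#' results, exposures, exclusion log) and the three summary tables as
#' CSV files, plus the configuration as JSON.
#'
#' @param report A `tpk_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "tpk_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) readr::write_csv(df, file.path(dir, name))
  wr(report$subjects, "subjects.csv")
  wr(report$recoveries, "recoveries.csv")
  wr(report$isf_profiles, "isf_profiles_per_catheter.csv")
  wr(report$isf_merged, "isf_profiles_merged.csv")
  wr(report$nca, "nca_results.csv")
  wr(report$exposures, "fauc24_exposures.csv")
  wr(report$table1, "table1_cohort.csv")
  wr(report$table2, "table2_pk_parameters.csv")
  wr(report$table3, "table3_target_attainment.csv")
  wr(report$exclusions, "exclusions.csv")
  st <- report$stats
  fitted <- st[c("reg_isf", "reg_plasma", "cor_weight_isf",
                 "cor_weight_plasma", "cor_bmi_isf", "cor_bmi_plasma",
                 "lmm_isf", "lmm_plasma")]
  stats_tbl <- purrr::imap(fitted, function(f, nm) {
    if (is.null(f)) NULL else dplyr::mutate(tidy(f), analysis = nm)
  }) |>
    dplyr::bind_rows()
  if (nrow(stats_tbl) > 0) wr(stats_tbl, "stats.csv")
  write_config_json(report$config, file.path(dir, "config.json"))
  write_concentration_csv(
    dplyr::bind_rows(
      report$isf_merged |>
        dplyr::transmute(.data$subject_id, .data$group, matrix = "isf",
                         catheter = NA_character_,
                         time_or_tstart = .data$t, tend = NA_real_,
                         conc_mg_L = .data$conc, .data$blq,
                         lloq = report$config$lloq)
    ),
    file.path(dir, "isf_concentrations.csv")
  )
  invisible(dir)
}
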