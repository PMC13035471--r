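#' Published calibration targets for the synthetic cohort generator
#'
#' Summary characteristics of a large UK double-reading screening programme
#' (five retrospective services, ~125,000 women, 39-month follow-up; two
#' prospective services, ~10,000 women, within-episode follow-up) and its
#' workflow read counts, shipped as plain-text tables. The generator defaults
#' and the package's self-checks are calibrated against these.
#'
#' @return A list of data frames: `retrospective` (per-service cohort
#'   composition and rates), `prospective` (per-service prospective counts
#'   split by operating-point period), `workflow_reads` (screening and
#'   arbitration read counts per workflow arm) and `prevalent_performance`
#'   (recall rate and CDR on first screens by reader).
#' @export
calibration_targets <- function() {
  path <- function(f) system.file("extdata", f, package = "screeneval", mustWork = TRUE)
  list(
    retrospective = utils::read.csv(path("retrospective_service_summary.csv"),
                                    stringsAsFactors = FALSE),
    prospective = utils::read.csv(path("prospective_summary.csv"),
                                  stringsAsFactors = FALSE),
    workflow_reads = utils::read.csv(path("workflow_read_counts.csv"),
                                     stringsAsFactors = FALSE),
    prevalent_performance = utils::read.csv(path("prevalent_screen_performance.csv"),
                                            stringsAsFactors = FALSE)
  )
}

#' Cohort composition quantities from the calibration tables
#'
#' Recomputes the headline composition figures from the raw counts in
#' [calibration_targets()]: inclusion percentage, cancer fraction among
#' included women, the prospective screen-detected fraction, the number of
#' cases read under the adjusted operating point, and the relative CDR gain
#' of the AI over the first reader on prevalent screens.
#'
#' @param targets Output of [calibration_targets()].
#' @return Named list of numbers (percentages on the 0-100 scale).
#' @export
cohort_composition <- function(targets = calibration_targets()) {
  retro <- targets$retrospective
  all_row <- retro[retro$service == "all", ]
  pro <- targets$prospective
  both <- pro[pro$service == "both", ]
  prev <- targets$prevalent_performance
  ai_cdr <- prev$cdr_per_1000[prev$reader == "ai"]
  r1_cdr <- prev$cdr_per_1000[prev$reader == "reader1"]
  list(
    inclusion_pct = 100 * all_row$included / all_row$total_women,
    cancer_fraction_pct = 100 * all_row$all_cancers / all_row$included,
    outcome_sum_check = all_row$screen_detected + all_row$interval_cancers +
      all_row$next_screen_detected,
    prospective_screen_detected_pct = 100 * both$screen_detected / both$included_cases,
    adjusted_op_cases = sum(pro$period2_adjusted_op[pro$service != "both"]),
    prevalent_cdr_gain_pct = 100 * (ai_cdr - r1_cdr) / r1_cdr
  )
}
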