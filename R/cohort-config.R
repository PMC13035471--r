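#' Configuration for the synthetic screening cohort generator
#'
#' Builds and validates the full parameter set for [generate_cohort()]. The
#' defaults emulate the published summary characteristics of a large UK
#' double-reading screening programme (see
#' `system.file("extdata", "retrospective_service_summary.csv", package = "screeneval")`):
#' roughly 1.7% of screened women have a cancer outcome within a 39-month
#' follow-up window, split into screen-detected, interval and next-round
#' components, with first-reader recall rates near 5.5% and an AI reader whose
#' score distribution yields sensitivity ~0.54 and specificity ~0.94 at the
#' default operating point.
#'
#' @param n_women Number of screening episodes to generate.
#' @param prevalence_screen_detected,prevalence_interval,prevalence_next_round
#'   Marginal probabilities of the three cancer outcome classes. Their sum is
#'   the overall cancer prevalence and must be at most 1.
#' @param prevalent_screen_fraction Fraction of episodes that are a woman's
#'   first screening attendance (no prior imaging).
#' @param reader_pool_size Number of distinct human readers; each episode is
#'   assigned two distinct readers, which form the inference clusters.
#' @param reader_sensitivity_mean,reader_sensitivity_sd Mean and
#'   between-reader standard deviation of human reader sensitivity against the
#'   39-month ground truth (all cancer classes pooled).
#' @param reader_specificity_mean,reader_specificity_sd Same for specificity.
#' @param inter_reader_correlation Tetrachoric correlation between the two
#'   readers' latent opinions on the same case, induced by a shared per-case
#'   difficulty effect. In `[0, 1]`.
#' @param reader_class_profile Relative detectability of the three cancer
#'   classes for human readers. Screen-detected cancers are, by construction
#'   of the outcome classes, far easier for readers than cancers that later
#'   present as interval or next-round disease. Rescaled internally so the
#'   prevalence-weighted mean equals `reader_sensitivity_mean`.
#' @param ai_sensitivity Marginal AI sensitivity (all cancer classes pooled)
#'   at the default operating point.
#' @param ai_class_profile Relative per-class AI detectability, analogous to
#'   `reader_class_profile`.
#' @param ai_specificity AI specificity at the default operating point.
#' @param operating_point Score threshold on the `[0, 1]` AI score scale; a
#'   case is AI-recalled when its score strictly exceeds this value. The score
#'   scale is constructed so that the configured sensitivity/specificity
#'   targets hold exactly at `operating_point = 0.5`.
#' @param device_mix Named proportions of mammography device strata.
#' @param device_score_shift Named additive shifts (latent probit scale)
#'   applied to AI scores per device stratum; defaults to no shift. Used to
#'   build in a device-dependent distribution shift at generation time (see
#'   also [inject_distribution_shift()] for post-hoc shifts).
#' @param subgroup_mix Named list of named proportion vectors for
#'   `age_band`, `imd_decile`, `ethnicity` and `density_quartile`. Each must
#'   sum to 1; an explicit `"missing"` level is allowed.
#' @param arbitration_style `"discordant_only"` or `"arbitrate_all"`.
#' @param direct_to_clinic_rate Probability that a reader-concordant recall
#'   bypasses arbitration and goes straight to assessment.
#' @param panel_sensitivity,panel_specificity Accuracy of the arbitration
#'   panel, modelled as a third reader. The source programmes report only
#'   arbitration counts, not panel accuracy, so these are stated defaults.
#' @param unilateral_rate Fraction of episodes with only one imaged breast.
#' @param multifocal_rate Probability that a cancer breast carries two lesion
#'   foci rather than one.
#' @param exclusion_rates Named per-episode probabilities of the eligibility
#'   flags `technical_recall`, `implants`, `missing_views`, `extra_views` and
#'   `size`. An episode carrying any flag is study-ineligible and also
#'   AI-ineligible; the defaults give ~7.2% exclusions (92.8% inclusion).
#' @param roi_hit_rate Named per-class probabilities that, for an AI-detected
#'   cancer, the candidate ROI overlaps the true lesion with controllable IoU
#'   (a lesion-level "hit").
#' @param sensitivity_deficit Optional `list(attribute=, level=, amount=)`
#'   injecting a subgroup-specific absolute AI sensitivity deficit, used for
#'   fairness-audit power studies.
#' @param n_weeks Length of the simulated screening period; episodes receive
#'   screening dates uniform over this window (for weekly monitoring series).
#' @param start_date First screening date.
#' @param service_id Service identifier stamped on every episode.
#' @param seed Integer RNG seed; the generator is fully reproducible given
#'   the configuration and seed.
#'
#' @return An object of class `cohort_config` (a validated named list).
#' @seealso [generate_cohort()], [apply_exclusions()]
#' @export
cohort_config <- function(n_women = 25000,
                          prevalence_screen_detected = 0.0076,
                          prevalence_interval = 0.0029,
                          prevalence_next_round = 0.0068,
                          prevalent_screen_fraction = 0.139,
                          reader_pool_size = 20,
                          reader_sensitivity_mean = 0.437,
                          reader_sensitivity_sd = 0.05,
                          reader_specificity_mean = 0.952,
                          reader_specificity_sd = 0.010,
                          inter_reader_correlation = 0.4,
                          reader_class_profile = c(screen_detected = 2.08,
                                                   interval = 0.185,
                                                   next_round = 0.150),
                          ai_sensitivity = 0.541,
                          ai_class_profile = c(screen_detected = 1.688,
                                               interval = 0.462,
                                               next_round = 0.464),
                          ai_specificity = 0.943,
                          operating_point = 0.5,
                          device_mix = c(hologic_lorad = 0.67,
                                         hologic_dimensions = 0.04,
                                         siemens = 0.22, ge = 0.07),
                          device_score_shift = NULL,
                          subgroup_mix = default_subgroup_mix(),
                          arbitration_style = c("discordant_only", "arbitrate_all"),
                          direct_to_clinic_rate = 0,
                          panel_sensitivity = 0.60,
                          panel_specificity = 0.75,
                          unilateral_rate = 0.006,
                          multifocal_rate = 0.15,
                          exclusion_rates = c(technical_recall = 0.002,
                                              implants = 0.005,
                                              missing_views = 0.010,
                                              extra_views = 0.030,
                                              size = 0.025),
                          roi_hit_rate = c(screen_detected = 0.80,
                                           interval = 0.58,
                                           next_round = 0.53),
                          sensitivity_deficit = NULL,
                          n_weeks = 8,
                          start_date = as.Date("2023-11-27"),
                          service_id = 1L,
                          seed = 1L) {
  arbitration_style <- match.arg(arbitration_style)

  n_women <- check_positive_int(n_women, "n_women")
  reader_pool_size <- check_positive_int(reader_pool_size, "reader_pool_size")
  if (reader_pool_size < 2) config_error("reader_pool_size", "needs at least 2 readers")

  check_proportion(prevalence_screen_detected, "prevalence_screen_detected")
  check_proportion(prevalence_interval, "prevalence_interval")
  check_proportion(prevalence_next_round, "prevalence_next_round")
  prev_sum <- prevalence_screen_detected + prevalence_interval + prevalence_next_round
  if (prev_sum > 1) config_error("prevalence_*", "the three prevalence components must sum to at most 1")

  check_proportion(prevalent_screen_fraction, "prevalent_screen_fraction")
  check_proportion(reader_sensitivity_mean, "reader_sensitivity_mean")
  check_proportion(reader_specificity_mean, "reader_specificity_mean")
  check_proportion(inter_reader_correlation, "inter_reader_correlation")
  check_proportion(ai_sensitivity, "ai_sensitivity")
  check_proportion(ai_specificity, "ai_specificity")
  check_proportion(operating_point, "operating_point")
  check_proportion(direct_to_clinic_rate, "direct_to_clinic_rate")
  check_proportion(panel_sensitivity, "panel_sensitivity")
  check_proportion(panel_specificity, "panel_specificity")
  check_proportion(unilateral_rate, "unilateral_rate")
  check_proportion(multifocal_rate, "multifocal_rate")
  check_proportion(exclusion_rates, "exclusion_rates")
  check_proportion(roi_hit_rate, "roi_hit_rate")

  check_mix(device_mix, "device_mix")
  if (!is.list(subgroup_mix) ||
      !all(c("age_band", "imd_decile", "ethnicity", "density_quartile") %in%
             names(subgroup_mix))) {
    config_error("subgroup_mix",
                 "must be a list with age_band, imd_decile, ethnicity, density_quartile")
  }
  for (nm in names(subgroup_mix)) {
    check_mix(subgroup_mix[[nm]], paste0("subgroup_mix$", nm))
  }

  class_names <- c("screen_detected", "interval", "next_round")
  for (fld in c("reader_class_profile", "ai_class_profile", "roi_hit_rate")) {
    v <- get(fld)
    if (!all(class_names %in% names(v))) {
      config_error(fld, "must name screen_detected, interval and next_round")
    }
  }
  if (is.null(device_score_shift)) {
    device_score_shift <- stats::setNames(numeric(length(device_mix)), names(device_mix))
  }
  if (!all(names(device_score_shift) %in% names(device_mix))) {
    config_error("device_score_shift", "names must be device strata from device_mix")
  }

  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    config_error("seed", "must be a single integer")
  }

  structure(list(
    n_women = n_women,
    prevalence_screen_detected = prevalence_screen_detected,
    prevalence_interval = prevalence_interval,
    prevalence_next_round = prevalence_next_round,
    prevalent_screen_fraction = prevalent_screen_fraction,
    reader_pool_size = reader_pool_size,
    reader_sensitivity_mean = reader_sensitivity_mean,
    reader_sensitivity_sd = reader_sensitivity_sd,
    reader_specificity_mean = reader_specificity_mean,
    reader_specificity_sd = reader_specificity_sd,
    inter_reader_correlation = inter_reader_correlation,
    reader_class_profile = reader_class_profile[class_names],
    ai_sensitivity = ai_sensitivity,
    ai_class_profile = ai_class_profile[class_names],
    ai_specificity = ai_specificity,
    operating_point = operating_point,
    device_mix = device_mix,
    device_score_shift = device_score_shift,
    subgroup_mix = subgroup_mix,
    arbitration_style = arbitration_style,
    direct_to_clinic_rate = direct_to_clinic_rate,
    panel_sensitivity = panel_sensitivity,
    panel_specificity = panel_specificity,
    unilateral_rate = unilateral_rate,
    multifocal_rate = multifocal_rate,
    exclusion_rates = exclusion_rates,
    roi_hit_rate = roi_hit_rate[class_names],
    sensitivity_deficit = sensitivity_deficit,
    n_weeks = n_weeks,
    start_date = as.Date(start_date),
    service_id = service_id,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Default subgroup attribute mix
#'
#' Named proportion vectors for the demographic and technical attributes
#' carried by synthetic episodes. Missingness levels reflect the incomplete
#' routine data collection typical of NHS screening services.
#'
#' @return A named list of named proportion vectors.
#' @export
default_subgroup_mix <- function() {
  list(
    age_band = c("50-54" = 0.30, "55-59" = 0.25, "60-64" = 0.25, "65-70" = 0.20),
    imd_decile = c(stats::setNames(rep(0.097, 10), as.character(1:10)), missing = 0.03),
    ethnicity = c(white = 0.75, asian = 0.08, black = 0.05, mixed = 0.02,
                  other = 0.03, missing = 0.07),
    density_quartile = c(q1 = 0.22, q2 = 0.22, q3 = 0.22, q4 = 0.22, missing = 0.12)
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  prev <- x$prevalence_screen_detected + x$prevalence_interval + x$prevalence_next_round
  cat("Synthetic screening cohort configuration\n")
  cat(sprintf("  women: %d  cancer prevalence: %.2f%% (SD %.2f%% / IC %.2f%% / NR %.2f%%)\n",
              x$n_women, 100 * prev, 100 * x$prevalence_screen_detected,
              100 * x$prevalence_interval, 100 * x$prevalence_next_round))
  cat(sprintf("  readers: %d (sens %.3f±%.3f, spec %.3f±%.3f, latent corr %.2f)\n",
              x$reader_pool_size, x$reader_sensitivity_mean, x$reader_sensitivity_sd,
              x$reader_specificity_mean, x$reader_specificity_sd,
              x$inter_reader_correlation))
  cat(sprintf("  AI: sens %.3f / spec %.3f at OP %.2f;  arbitration: %s\n",
              x$ai_sensitivity, x$ai_specificity, x$operating_point,
              x$arbitration_style))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# Rescale a relative class profile so the prevalence-weighted mean recall
# probability equals the overall target. Probabilities are clamped to
# [0.001, 0.999]; clamping slightly biases the marginal toward the interior,
# so targets very near 0 or 1 are refused upstream.
class_probabilities <- function(target, profile, prevalences) {
  w <- prevalences / sum(prevalences)
  k <- 1 / sum(w * profile)
  p <- target * profile * k
  pmin(pmax(p, 0.001), 0.999)
}
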