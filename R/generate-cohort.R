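#' Generate a synthetic screening cohort
#'
#' Simulates one service's screening episodes with the statistical structure
#' the downstream evaluation assumes: correlated human reader recall
#' decisions clustered by reader identity, a continuous AI cancer score from a
#' class- and device-conditional binormal model, outcome classes
#' (screen-detected / interval / next-round / normal) with confirmatory
#' follow-up for normals, subgroup attributes, eligibility flags, lesion
#' bounding boxes and candidate AI regions of interest.
#'
#' The reader model is a latent-threshold probit: reader `j` recalls a case
#' when `sqrt(rho) * w + sqrt(1 - rho) * e < qnorm(p_j)`, where `w` is a
#' per-case difficulty effect shared by both readers (and the arbitration
#' panel), `e` is reader-case noise and `p_j` the reader- and class-specific
#' recall probability. This yields the configured marginal
#' sensitivity/specificity exactly and a tetrachoric inter-reader correlation
#' of `rho`.
#'
#' The AI score is a monotone logistic transform of a latent Gaussian: each
#' breast draws `N(0, 1)` (normal tissue) or `N(mu_class, 1)` (cancer side),
#' plus any device stratum shift; the case latent is the maximum over breasts
#' and the case score is `plogis(latent - t + qlogis(op))`, with `t` chosen so
#' the configured specificity and per-class sensitivities hold exactly at the
#' configured operating point `op` (case score therefore equals the maximum of
#' the breast scores).
#'
#' @param config A [cohort_config()] object.
#' @return A list of class `screen_cohort` with elements `episodes`,
#'   `lesions`, `rois` (data frames), `readers` (the simulated reader pool
#'   with its per-reader accuracies) and `config`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_women = 2000, seed = 7))
#' table(cohort$episodes$outcome)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    config_error("config", "must be created by cohort_config()")
  }
  with_rng_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  n <- config$n_women
  prev <- c(screen_detected = config$prevalence_screen_detected,
            interval = config$prevalence_interval,
            next_round = config$prevalence_next_round)

  outcome <- sample(c(names(prev), "normal"), n, replace = TRUE,
                    prob = c(prev, 1 - sum(prev)))
  is_cancer <- outcome != "normal"
  n_cancer <- sum(is_cancer)

  # -- attributes ------------------------------------------------------------
  sg <- config$subgroup_mix
  age_band <- draw_levels(n, sg$age_band)
  age_lo <- c("50-54" = 50, "55-59" = 55, "60-64" = 60, "65-70" = 65)[age_band]
  age_hi <- c("50-54" = 54, "55-59" = 59, "60-64" = 64, "65-70" = 70)[age_band]
  age <- as.integer(age_lo + floor(stats::runif(n) * (age_hi - age_lo + 1)))
  imd_decile <- draw_levels(n, sg$imd_decile)
  ethnicity <- draw_levels(n, sg$ethnicity)
  density_quartile <- draw_levels(n, sg$density_quartile)
  manufacturer_model <- draw_levels(n, config$device_mix)
  screen_type <- ifelse(stats::runif(n) < config$prevalent_screen_fraction,
                        "prevalent", "incident")
  screen_date <- config$start_date +
    sample.int(7L * config$n_weeks, n, replace = TRUE) - 1L

  # -- eligibility flags -----------------------------------------------------
  er <- config$exclusion_rates
  flags <- vapply(names(er), function(r) stats::runif(n) < er[[r]], logical(n))
  colnames(flags) <- paste0("flag_", names(er))
  ai_eligible <- rowSums(flags) == 0

  # -- outcome record --------------------------------------------------------
  outcome_interval_months <- numeric(n)
  outcome_interval_months[outcome == "normal"] <- stats::runif(sum(outcome == "normal"), 24, 39)
  outcome_interval_months[outcome == "screen_detected"] <- 0
  outcome_interval_months[outcome == "interval"] <- stats::runif(sum(outcome == "interval"), 4, 30)
  outcome_interval_months[outcome == "next_round"] <- stats::runif(sum(outcome == "next_round"), 30, 39)

  pathology <- rep("none", n)
  pathology[is_cancer] <- sample(c("invasive", "dcis_high", "dcis_low_intermediate"),
                                 n_cancer, replace = TRUE, prob = c(0.78, 0.13, 0.09))
  lesion_side <- rep("none", n)
  lesion_side[is_cancer] <- sample(c("right", "left"), n_cancer, replace = TRUE)
  max_lesion_size_mm <- rep(NA_real_, n)
  max_lesion_size_mm[is_cancer] <- pmin(pmax(stats::rlnorm(n_cancer, log(18), 0.5), 4), 80)

  unilateral <- stats::runif(n) < config$unilateral_rate
  # a unilateral cancer case's imaged breast is the affected one;
  # unilateral normals keep a random side
  imaged_right <- rep(TRUE, n)
  imaged_left <- rep(TRUE, n)
  uc <- unilateral & is_cancer
  imaged_right[uc] <- lesion_side[uc] == "right"
  imaged_left[uc] <- lesion_side[uc] == "left"
  un <- unilateral & !is_cancer
  keep_right <- stats::runif(n) < 0.5
  imaged_right[un] <- keep_right[un]
  imaged_left[un] <- !keep_right[un]

  # -- readers ---------------------------------------------------------------
  pool <- config$reader_pool_size
  readers <- data.frame(
    reader_id = sprintf("R%02d", seq_len(pool)),
    sensitivity = pmin(pmax(stats::rnorm(pool, config$reader_sensitivity_mean,
                                         config$reader_sensitivity_sd), 0.02), 0.98),
    specificity = pmin(pmax(stats::rnorm(pool, config$reader_specificity_mean,
                                         config$reader_specificity_sd), 0.02), 0.98)
  )
  r1 <- sample.int(pool, n, replace = TRUE)
  r2 <- sample.int(pool - 1L, n, replace = TRUE)
  r2 <- r2 + (r2 >= r1)

  w_case <- stats::rnorm(n)                      # shared difficulty effect
  gamma <- sqrt(config$inter_reader_correlation)

  reader_recall <- function(idx, sens, spec) {
    # per-episode recall threshold on the latent N(0,1) opinion scale
    p <- numeric(n)
    for (cls in c("screen_detected", "interval", "next_round")) {
      sel <- outcome == cls
      if (!any(sel)) next
      pc <- vapply(sens, function(s)
        class_probabilities(s, config$reader_class_profile, prev)[[cls]], 0)
      p[sel] <- pc[idx[sel]]
    }
    sel <- outcome == "normal"
    p[sel] <- (1 - spec[idx])[sel]
    latent <- gamma * w_case + sqrt(1 - gamma^2) * stats::rnorm(n)
    latent < stats::qnorm(p)
  }

  reader1_recall <- reader_recall(r1, readers$sensitivity, readers$specificity)
  reader2_recall <- reader_recall(r2, readers$sensitivity, readers$specificity)
  panel_recall <- reader_recall(rep(1L, n), config$panel_sensitivity,
                                rep(config$panel_specificity, n))

  both <- reader1_recall & reader2_recall
  any_rec <- reader1_recall | reader2_recall
  dtc <- stats::runif(n) < config$direct_to_clinic_rate
  consensus_recall <- if (config$arbitration_style == "discordant_only") {
    ifelse(both, ifelse(dtc, TRUE, panel_recall),
           ifelse(any_rec, panel_recall, FALSE))
  } else {
    ifelse(any_rec, panel_recall, FALSE)
  }

  # -- AI scores -------------------------------------------------------------
  # threshold on the latent scale such that the marginal specificity over the
  # unilateral/bilateral mixture is exact: a case clears when every imaged
  # breast clears, so Phi(t) * (u + (1 - u) * Phi(t)) = specificity
  u <- config$unilateral_rate
  spec <- config$ai_specificity
  x <- if (u < 1) (-u + sqrt(u^2 + 4 * (1 - u) * spec)) / (2 * (1 - u)) else spec
  t_lat <- stats::qnorm(x)
  clear_other <- u + (1 - u) * stats::pnorm(t_lat)  # P(non-affected side clears)
  op <- config$operating_point
  ai_p_class <- class_probabilities(config$ai_sensitivity, config$ai_class_profile, prev)
  p_episode <- rep(NA_real_, n)
  for (cls in names(ai_p_class)) p_episode[outcome == cls] <- ai_p_class[[cls]]
  dfc <- config$sensitivity_deficit
  if (!is.null(dfc)) {
    att <- get(dfc$attribute)
    hit <- is_cancer & att == dfc$level
    p_episode[hit] <- pmax(0.001, p_episode[hit] - dfc$amount)
  }
  mu <- t_lat - stats::qnorm(pmin(0.999, (1 - p_episode) / clear_other))

  shift <- config$device_score_shift[manufacturer_model]
  shift[is.na(shift)] <- 0
  lat_right <- stats::rnorm(n) + shift
  lat_left <- stats::rnorm(n) + shift
  aff_right <- is_cancer & lesion_side == "right"
  aff_left <- is_cancer & lesion_side == "left"
  lat_right[aff_right] <- stats::rnorm(sum(aff_right), mu[aff_right]) + shift[aff_right]
  lat_left[aff_left] <- stats::rnorm(sum(aff_left), mu[aff_left]) + shift[aff_left]

  to_score <- function(z) stats::plogis(z - t_lat + stats::qlogis(op))
  ai_breast_score_right <- ifelse(imaged_right, to_score(lat_right), NA_real_)
  ai_breast_score_left <- ifelse(imaged_left, to_score(lat_left), NA_real_)
  ai_score <- pmax(ai_breast_score_right, ai_breast_score_left, na.rm = TRUE)
  ai_recall <- ai_score > op

  episode_id <- sprintf("S%s-E%06d", config$service_id, seq_len(n))
  episodes <- data.frame(
    episode_id = episode_id,
    service_id = config$service_id,
    screen_date = screen_date,
    reader1_id = readers$reader_id[r1],
    reader2_id = readers$reader_id[r2],
    age = age,
    age_band = age_band,
    imd_decile = imd_decile,
    ethnicity = ethnicity,
    density_quartile = density_quartile,
    manufacturer_model = manufacturer_model,
    screen_type = screen_type,
    reader1_recall = reader1_recall,
    reader2_recall = reader2_recall,
    reader2_blinded = TRUE,
    consensus_recall = consensus_recall,
    ai_score = ai_score,
    ai_breast_score_right = ai_breast_score_right,
    ai_breast_score_left = ai_breast_score_left,
    ai_recall = ai_recall,
    ai_eligible = ai_eligible,
    outcome = outcome,
    outcome_interval_months = outcome_interval_months,
    pathology = pathology,
    lesion_side = lesion_side,
    max_lesion_size_mm = max_lesion_size_mm,
    stringsAsFactors = FALSE
  )
  episodes <- cbind(episodes, as.data.frame(flags))
  attr(episodes, "operating_point") <- op

  lesions <- make_lesions(episodes, config)
  rois <- make_rois(episodes, lesions, config)

  structure(list(episodes = episodes, lesions = lesions, rois = rois,
                 readers = readers, config = config),
            class = "screen_cohort")
}

# Image frame used for all boxes: width x height pixels, origin top-left,
# half-open boxes [x_min, x_max) x [y_min, y_max), ~7 px per mm.
IMAGE_W <- 2800
IMAGE_H <- 3500
PX_PER_MM <- 7

make_lesions <- function(episodes, config) {
  ce <- episodes[episodes$outcome != "normal", ]
  if (nrow(ce) == 0) {
    return(data.frame(episode_id = character(), lesion_id = character(),
                      side = character(), view = character(),
                      x_min = numeric(), y_min = numeric(),
                      x_max = numeric(), y_max = numeric(),
                      focality = character(), stringsAsFactors = FALSE))
  }
  n_foci <- 1L + stats::rbinom(nrow(ce), 1L, config$multifocal_rate)
  idx <- rep(seq_len(nrow(ce)), n_foci)
  focus <- unlist(lapply(n_foci, seq_len))
  m <- length(idx)
  size_px <- ce$max_lesion_size_mm[idx] * PX_PER_MM * stats::runif(m, 0.6, 1.0)
  # one annotated box per view for every focus
  out <- do.call(rbind, lapply(c("CC", "MLO"), function(v) {
    x0 <- stats::runif(m, 0, IMAGE_W - size_px)
    y0 <- stats::runif(m, 0, IMAGE_H - size_px)
    data.frame(
      episode_id = ce$episode_id[idx],
      lesion_id = sprintf("%s-L%d", ce$episode_id[idx], focus),
      side = ce$lesion_side[idx],
      view = v,
      x_min = x0, y_min = y0, x_max = x0 + size_px, y_max = y0 + size_px,
      focality = ifelse(n_foci[idx] > 1, "multifocal", "unifocal"),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

# Place a box of the same size as `box` shifted along x to a target IoU.
shifted_box <- function(box, iou_target) {
  w <- box$x_max - box$x_min
  dx <- w * (1 - iou_target) / (1 + iou_target)
  data.frame(x_min = box$x_min + dx, y_min = box$y_min,
             x_max = box$x_max + dx, y_max = box$y_max)
}

make_rois <- function(episodes, lesions, config) {
  n <- nrow(episodes)
  # candidate ROI side: affected side for cancers, higher-scoring side otherwise
  side <- ifelse(episodes$outcome != "normal", episodes$lesion_side,
                 ifelse(is.na(episodes$ai_breast_score_left) |
                          (!is.na(episodes$ai_breast_score_right) &
                             episodes$ai_breast_score_right >= episodes$ai_breast_score_left),
                        "right", "left"))
  score <- ifelse(side == "right", episodes$ai_breast_score_right,
                  episodes$ai_breast_score_left)
  hit_p <- config$roi_hit_rate[episodes$outcome]
  hit_p[is.na(hit_p)] <- 0
  hit <- stats::runif(n) < hit_p
  mlo_hit <- hit & stats::runif(n) < 0.7   # CC always hit when the lesion is hit

  rows <- vector("list", n)
  first_focus <- lesions[!duplicated(paste(lesions$episode_id, lesions$view)), ]
  cc_boxes <- first_focus[first_focus$view == "CC", ]
  mlo_boxes <- first_focus[first_focus$view == "MLO", ]
  cc_ix <- match(episodes$episode_id, cc_boxes$episode_id)
  mlo_ix <- match(episodes$episode_id, mlo_boxes$episode_id)

  random_box <- function(k) {
    s <- stats::runif(k, 60, 250)
    x0 <- stats::runif(k, 0, IMAGE_W - s)
    y0 <- stats::runif(k, 0, IMAGE_H - s)
    data.frame(x_min = x0, y_min = y0, x_max = x0 + s, y_max = y0 + s)
  }

  build_view <- function(view, view_hit, box_ix, boxes) {
    b <- random_box(n)
    has_truth <- view_hit & !is.na(box_ix)
    if (any(has_truth)) {
      tb <- boxes[box_ix[has_truth], c("x_min", "y_min", "x_max", "y_max")]
      iou_t <- stats::runif(sum(has_truth), 0.15, 0.85)
      sb <- shifted_box(tb, iou_t)
      b[has_truth, ] <- sb
    }
    data.frame(episode_id = episodes$episode_id, side = side, view = view,
               b, score = score, stringsAsFactors = FALSE)
  }

  out <- rbind(build_view("CC", hit, cc_ix, cc_boxes),
               build_view("MLO", mlo_hit, mlo_ix, mlo_boxes))
  out <- out[!is.na(out$score), ]
  rownames(out) <- NULL
  out
}

#' @export
print.screen_cohort <- function(x, ...) {
  e <- x$episodes
  cat(sprintf("Synthetic screening cohort: %d episodes (service %s)\n",
              nrow(e), x$config$service_id))
  tab <- table(e$outcome)
  cat("  outcomes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("  AI recall %.2f%%  R1 recall %.2f%%  consensus recall %.2f%%\n",
              100 * mean(e$ai_recall), 100 * mean(e$reader1_recall),
              100 * mean(e$consensus_recall)))
  cat(sprintf("  lesions: %d rows, candidate ROIs: %d rows\n",
              nrow(x$lesions), nrow(x$rois)))
  invisible(x)
}

#' Filter candidate ROIs to those an AI system would emit at an operating point
#'
#' Deployed systems surface a region of interest only when its score exceeds
#' the active operating point; the generator keeps all candidates so that
#' FROC analysis can sweep the full threshold range.
#'
#' @param rois Candidate ROI table from [generate_cohort()].
#' @param op Operating point (score threshold); ROIs with score strictly above
#'   it are emitted.
#' @return The emitted subset of `rois`.
#' @export
emitted_rois <- function(rois, op) {
  rois[rois$score > op, , drop = FALSE]
}
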