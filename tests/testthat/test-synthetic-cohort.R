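test_that("invalid configurations raise errors naming the offending field", {
  expect_error(cohort_config(prevalence_screen_detected = 1.5),
               "prevalence_screen_detected")
  expect_error(cohort_config(prevalence_screen_detected = 0.5,
                             prevalence_interval = 0.4,
                             prevalence_next_round = 0.3),
               "prevalence_")
  expect_error(cohort_config(device_mix = c(a = 0.5, b = 0.4)), "device_mix")
  expect_error(cohort_config(inter_reader_correlation = -0.1),
               "inter_reader_correlation")
  expect_error(cohort_config(n_women = 0), "n_women")
})

test_that("identical config and seed give byte-identical cohorts", {
  a <- small_cohort(n = 2000, seed = 9)
  b <- small_cohort(n = 2000, seed = 9)
  expect_identical(a$episodes, b$episodes)
  expect_identical(a$lesions, b$lesions)
  expect_identical(a$rois, b$rois)
  d <- small_cohort(n = 2000, seed = 10)
  expect_false(identical(a$episodes$ai_score, d$episodes$ai_score))
})

test_that("large-cohort marginals recover the configured rates within 3 SE", {
  ch <- generate_cohort(cohort_config(n_women = 50000, seed = 3))
  e <- ch$episodes
  cfg <- ch$config
  prev_target <- cfg$prevalence_screen_detected + cfg$prevalence_interval +
    cfg$prevalence_next_round
  n <- nrow(e)

  prev_hat <- mean(e$outcome != "normal")
  expect_lt(abs(prev_hat - prev_target), 3 * sqrt(prev_target * (1 - prev_target) / n))

  y <- as.integer(e$outcome != "normal")
  n_pos <- sum(y); n_neg <- n - n_pos
  ai_sens <- mean(e$ai_recall[y == 1])
  expect_lt(abs(ai_sens - cfg$ai_sensitivity),
            3 * sqrt(cfg$ai_sensitivity * (1 - cfg$ai_sensitivity) / n_pos))
  ai_spec <- 1 - mean(e$ai_recall[y == 0])
  expect_lt(abs(ai_spec - cfg$ai_specificity),
            3 * sqrt(cfg$ai_specificity * (1 - cfg$ai_specificity) / n_neg))

  # reader recall on normals tracks 1 - specificity; allow for the
  # between-reader spread on top of binomial error
  r1_fpr <- mean(e$reader1_recall[y == 0])
  expect_lt(abs(r1_fpr - (1 - cfg$reader_specificity_mean)),
            3 * (cfg$reader_specificity_sd / sqrt(cfg$reader_pool_size) +
                   sqrt(0.05 * 0.95 / n_neg)))

  # device and subgroup mixes
  for (dev in names(cfg$device_mix)) {
    p <- cfg$device_mix[[dev]]
    expect_lt(abs(mean(e$manufacturer_model == dev) - p),
              3 * sqrt(p * (1 - p) / n))
  }
})

test_that("zero inter-reader correlation with identical readers gives independent agreement", {
  # identical readers, no shared case effect, and a flat class profile so
  # every cancer carries the same recall probability: agreement must then
  # match the independence product
  ch <- generate_cohort(cohort_config(
    n_women = 60000, seed = 5, inter_reader_correlation = 0,
    reader_sensitivity_sd = 0, reader_specificity_sd = 0,
    reader_class_profile = c(screen_detected = 1, interval = 1, next_round = 1)))
  e <- ch$episodes
  cancers <- e[e$outcome != "normal", ]
  p1 <- mean(cancers$reader1_recall)
  p2 <- mean(cancers$reader2_recall)
  both <- mean(cancers$reader1_recall & cancers$reader2_recall)
  se <- sqrt(p1 * p2 * (1 - p1 * p2) / nrow(cancers))
  expect_lt(abs(both - p1 * p2), 3 * se)
})

test_that("an uninformative score distribution gives AUC near 0.5", {
  ch <- generate_cohort(cohort_config(
    n_women = 30000, seed = 6,
    ai_sensitivity = 1 - 0.943,   # cancer class distribution == normal class
    ai_class_profile = c(screen_detected = 1, interval = 1, next_round = 1)))
  e <- ch$episodes
  y <- as.integer(e$outcome != "normal")
  auc <- roc_curve(e$ai_score, y)$auc
  n_pos <- sum(y)
  expect_lt(abs(auc - 0.5), 3 * sqrt(1 / (12 * n_pos)))
})

test_that("ground-truth structure is internally consistent", {
  ch <- small_cohort(n = 8000, seed = 12)
  e <- ch$episodes
  normals <- e[e$outcome == "normal", ]
  expect_true(all(normals$outcome_interval_months >= 24 &
                    normals$outcome_interval_months <= 39))
  cancers <- e[e$outcome != "normal", ]
  expect_true(all(cancers$pathology != "none"))
  expect_true(all(cancers$lesion_side %in% c("right", "left")))
  # case score equals the max of the available breast scores
  expect_equal(e$ai_score,
               pmax(e$ai_breast_score_right, e$ai_breast_score_left, na.rm = TRUE))
  # every cancer has lesion rows on the affected side only
  les <- ch$lesions
  expect_setequal(unique(les$episode_id), cancers$episode_id)
  side_of <- cancers$lesion_side[match(les$episode_id, cancers$episode_id)]
  expect_true(all(les$side == side_of))
  expect_true(all(les$x_min < les$x_max & les$y_min < les$y_max))
})

test_that("exclusions conserve counts and apply a fixed precedence", {
  ch <- small_cohort(n = 5000, seed = 21)
  res <- apply_exclusions(ch$episodes)
  expect_equal(nrow(res$included) + nrow(res$excluded), nrow(ch$episodes))
  expect_equal(sum(unlist(res$log$by_reason)), res$log$n_excluded)
  expect_true(all(res$included$ai_eligible))

  # no flags -> identity
  clean <- ch$episodes
  for (cl in grep("^flag_", names(clean), value = TRUE)) clean[[cl]] <- FALSE
  res0 <- apply_exclusions(clean)
  expect_equal(nrow(res0$included), nrow(clean))
  expect_equal(res0$log$n_excluded, 0L)

  # an episode with several flags is counted once, under the highest-precedence
  # reason; enumerate all flag combinations
  reasons <- c("technical_recall", "implants", "missing_views", "extra_views", "size")
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), 5))
  names(combos) <- paste0("flag_", reasons)
  combos$episode_id <- sprintf("C%02d", seq_len(nrow(combos)))
  res2 <- apply_exclusions(combos)
  expect_equal(res2$log$n_excluded, sum(rowSums(combos[, 1:5]) > 0))
  expect_equal(sum(unlist(res2$log$by_reason)), res2$log$n_excluded)
  first_flag <- apply(as.matrix(combos[, paste0("flag_", reasons)]), 1,
                      function(r) reasons[match(TRUE, r)])
  expect_equal(res2$excluded$exclusion_reason,
               first_flag[rowSums(combos[, 1:5]) > 0])
})

test_that("distribution shift touches only the targeted stratum and round-trips", {
  ch <- small_cohort(n = 20000, seed = 31)
  e <- ch$episodes
  spec <- list(stratum = "hologic_dimensions", logit_shift = 1.2)

  expect_error(inject_distribution_shift(e, list(stratum = "nope", logit_shift = 1)),
               "unknown device stratum")
  expect_identical(inject_distribution_shift(e, list(stratum = "siemens",
                                                     logit_shift = 0)), e)

  shifted <- inject_distribution_shift(e, spec)
  sel <- e$manufacturer_model == spec$stratum
  expect_identical(shifted$ai_score[!sel], e$ai_score[!sel])
  expect_identical(shifted$reader1_recall, e$reader1_recall)
  # recall rises at the fixed operating point in that stratum only
  expect_gt(mean(shifted$ai_recall[sel]), mean(e$ai_recall[sel]))
  expect_identical(shifted$ai_recall[!sel], e$ai_recall[!sel])

  back <- inject_distribution_shift(shifted, list(stratum = spec$stratum,
                                                  logit_shift = -spec$logit_shift))
  expect_lt(abs(mean(back$ai_recall) - mean(e$ai_recall)), 0.002)
})
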