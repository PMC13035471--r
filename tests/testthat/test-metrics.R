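test_that("confusion counts enumerate units exactly", {
  # 10 units, 3 cancers, 2 found, 1 false alarm
  labels <- c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0)
  dec <- c(TRUE, TRUE, FALSE, TRUE, rep(FALSE, 6))
  cc <- confusion_counts(dec, labels, "case")
  expect_equal(unlist(cc[c("tp", "fn", "fp", "tn")]),
               c(tp = 2L, fn = 1L, fp = 1L, tn = 6L))

  perfect <- confusion_counts(labels == 1, labels, "case")
  expect_equal(perfect$fp + perfect$fn, 0L)
  inverted <- confusion_counts(labels == 0, labels, "case")
  expect_equal(inverted$tp + inverted$tn, 0L)

  expect_error(confusion_counts(dec, labels[-1], "case"), "length")
  expect_error(confusion_counts(dec, labels, "case",
                                ids = list(decisions = 1:10, labels = 10:1)),
               "not aligned")
})

test_that("point metrics compute rates on the documented scales", {
  cc <- confusion_counts(c(rep(TRUE, 2), rep(FALSE, 998)),
                         c(rep(1, 2), rep(0, 998)), "case")
  pm <- point_metrics(cc)
  expect_equal(pm$value[pm$name == "cdr"], 2.0)  # per 1,000 women

  # tp=76, fp=400 in 10,000 -> recall rate 4.76%
  dec <- c(rep(TRUE, 76), rep(FALSE, 24), rep(TRUE, 400), rep(FALSE, 9500))
  lab <- c(rep(1, 100), rep(0, 9900))
  pm2 <- point_metrics(confusion_counts(dec, lab, "case"))
  expect_equal(pm2$value[pm2$name == "recall_rate"], 0.0476)

  # all-negative decisions
  pm3 <- point_metrics(confusion_counts(rep(FALSE, 100), c(rep(1, 10), rep(0, 90)), "case"))
  expect_equal(pm3$value[pm3$name == "sensitivity"], 0)
  expect_equal(pm3$value[pm3$name == "specificity"], 1)
  expect_equal(pm3$value[pm3$name == "recall_rate"], 0)
  # zero recalls -> PPV undefined, not 0
  expect_true(is.na(pm3$value[pm3$name == "ppv"]))
  expect_equal(pm3$ci_method[pm3$name == "ppv"], "undefined")
})

test_that("the CI policy routes Wald at n >= 50 and bootstrap otherwise", {
  expect_equal(ci_policy("sensitivity", 50), "wald")
  expect_equal(ci_policy("sensitivity", 49), "bootstrap")
  expect_equal(ci_policy("ppv", 10000), "bootstrap")
  expect_equal(ci_policy("npv", 10000), "bootstrap")
  expect_equal(ci_policy("recall_rate", 200), "wald")

  # and point_metrics honours it
  dec <- c(rep(TRUE, 30), rep(FALSE, 30), rep(TRUE, 5), rep(FALSE, 100))
  lab <- c(rep(1, 60), rep(0, 105))
  pm <- point_metrics(confusion_counts(dec, lab, "case"))
  expect_equal(pm$ci_method[pm$name == "sensitivity"], "wald")
  expect_equal(pm$ci_method[pm$name == "ppv"], "bootstrap")
  expect_true(all(pm$ci_low <= pm$value & pm$value <= pm$ci_high, na.rm = TRUE))
})

test_that("ROC AUC equals the pairwise rank statistic", {
  r <- roc_curve(c(0.9, 0.8, 0.8, 0.1), c(1, 1, 0, 0))
  expect_equal(r$auc, 0.875)

  # perfectly separated and uninformative scores
  expect_equal(roc_curve(c(3, 4, 1, 2), c(1, 1, 0, 0))$auc, 1.0)
  expect_equal(roc_curve(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_error(roc_curve(1:5, rep(1, 5)), "positive and one negative")

  set.seed(99)
  for (i in 1:20) {
    n <- sample(20:80, 1)
    scores <- round(stats::runif(n), 2)      # force ties
    labels <- stats::rbinom(n, 1, 0.4)
    if (sum(labels) == 0 || sum(labels) == n) next
    r <- roc_curve(scores, labels)
    expect_equal(r$auc, rank_auc(scores, labels), tolerance = 1e-12)
    expect_true(all(diff(r$points$sensitivity) >= 0))
    expect_true(all(diff(r$points$fpr) >= 0))
  }
})

test_that("ROC agrees with an independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(7)
  scores <- stats::rnorm(300)
  labels <- stats::rbinom(300, 1, 0.3)
  ours <- roc_curve(scores, labels)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("IoU follows half-open box arithmetic", {
  b <- box(0, 0, 10, 10)
  expect_equal(box_iou(b, b), 1.0)
  expect_equal(box_iou(b, box(20, 20, 30, 30)), 0.0)
  expect_equal(box_iou(b, box(5, 5, 15, 15)), 25 / 175)
  expect_equal(box_iou(b, box(10, 0, 20, 10)), 0.0)      # touching, half-open
  expect_equal(box_iou(box(0, 0, 0, 0), b), 0.0)          # degenerate
  expect_error(box_iou(box(5, 0, 1, 10), b), "malformed")
  expect_error(box_iou(c(x_min = 0), b), "malformed")
})

test_that("lesion matching uses either-view hits and the any-focus rule", {
  lesions <- rbind(
    box_df("E1", "left", "CC", 100, 100, 200, 200, lesion_id = "E1-L1", focality = "unifocal"),
    box_df("E1", "left", "MLO", 300, 300, 400, 400, lesion_id = "E1-L1", focality = "unifocal"),
    box_df("E2", "right", "CC", 100, 100, 200, 200, lesion_id = "E2-L1", focality = "multifocal"),
    box_df("E2", "right", "CC", 500, 500, 600, 600, lesion_id = "E2-L2", focality = "multifocal"))

  # ROI exactly on the lesion in CC only -> hit
  rois <- box_df("E1", "left", "CC", 100, 100, 200, 200, score = 0.9)
  m <- lesion_match(rois, lesions)
  expect_true(m$lesion_hits$hit[m$lesion_hits$lesion_id == "E1-L1"])

  # same box on the wrong side -> miss
  m2 <- lesion_match(box_df("E1", "right", "CC", 100, 100, 200, 200, score = 0.9),
                     lesions)
  expect_false(any(m2$lesion_hits$hit))

  # two foci, one overlapped -> breast hit under the any-focus rule
  m3 <- lesion_match(box_df("E2", "right", "CC", 120, 120, 220, 220, score = 0.8),
                     lesions)
  hits <- m3$lesion_hits[m3$lesion_hits$episode_id == "E2", ]
  expect_equal(sum(hits$hit), 1L)
  expect_true(m3$breast_hits$hit[m3$breast_hits$episode_id == "E2"])

  # borderline overlaps are exported for review
  m4 <- lesion_match(box_df("E1", "left", "CC", 180, 180, 280, 280, score = 0.5),
                     lesions)  # IoU = 400/19600 ~ 0.02
  expect_false(any(m4$lesion_hits$hit))
  expect_equal(nrow(m4$borderline), 1L)
  expect_lt(m4$borderline$iou, 0.30)
})

test_that("FROC equals an exhaustive threshold-sweep oracle and is monotone", {
  set.seed(17)
  n_cases <- 30
  eps <- sprintf("E%02d", 1:n_cases)
  cancer_eps <- eps[1:8]
  lesions <- do.call(rbind, lapply(cancer_eps, function(id) {
    box_df(id, "left", "CC", 100, 100, 200, 200,
           lesion_id = paste0(id, "-L1"), focality = "unifocal")
  }))
  rois <- do.call(rbind, lapply(eps, function(id) {
    hit <- id %in% cancer_eps && stats::runif(1) < 0.6
    if (hit) box_df(id, "left", "CC", 120, 100, 220, 200,
                    score = round(stats::runif(1), 2))
    else box_df(id, "left", "CC", 1000, 1000, 1100, 1100,
                score = round(stats::runif(1), 2))
  }))

  fr <- froc_curve(rois, lesions, n_cases = n_cases)
  expect_equal(fr$lesion_sensitivity[fr$threshold == Inf], 0)
  expect_equal(fr$fp_per_case[fr$threshold == Inf], 0)

  # brute-force oracle at every threshold
  for (k in seq_len(nrow(fr))) {
    t <- fr$threshold[k]
    active <- rois[rois$score > t, , drop = FALSE]
    hits <- vapply(seq_len(nrow(lesions)), function(i) {
      same <- active[active$episode_id == lesions$episode_id[i] &
                       active$side == lesions$side[i] &
                       active$view == lesions$view[i], , drop = FALSE]
      any(vapply(seq_len(nrow(same)), function(j)
        box_iou(lesions[i, c("x_min", "y_min", "x_max", "y_max")],
                same[j, c("x_min", "y_min", "x_max", "y_max")]) > 0.1, NA))
    }, NA)
    fp <- vapply(seq_len(nrow(active)), function(j) {
      cand <- lesions[lesions$episode_id == active$episode_id[j] &
                        lesions$side == active$side[j] &
                        lesions$view == active$view[j], , drop = FALSE]
      !any(vapply(seq_len(nrow(cand)), function(i)
        box_iou(cand[i, c("x_min", "y_min", "x_max", "y_max")],
                active[j, c("x_min", "y_min", "x_max", "y_max")]) > 0.1, NA))
    }, NA)
    expect_equal(fr$lesion_sensitivity[k], mean(hits))
    expect_equal(fr$fp_per_case[k], sum(fp) / n_cases)
  }
  # lowest threshold recovers every lesion that is ever matched
  expect_equal(fr$lesion_sensitivity[nrow(fr)],
               max(fr$lesion_sensitivity))
  expect_true(all(diff(fr$lesion_sensitivity) >= 0))
  expect_true(all(diff(fr$fp_per_case) >= 0))
})
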