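test_that("operating-point selection matches a brute-force scan", {
  set.seed(61)
  scores <- round(stats::runif(400), 2)
  labels <- stats::rbinom(400, 1, stats::plogis(4 * scores - 3))
  if (sum(labels) == 0) labels[1] <- 1

  op <- select_op(scores, labels, constraints = list(max_recall_rate = 0.2))

  # oracle: loop over every unique threshold
  cand <- sort(unique(scores))
  stats_at <- t(vapply(cand, function(t) {
    d <- scores > t
    c(sens = mean(d[labels == 1]), spec = mean(!d[labels == 0]),
      recall = mean(d))
  }, c(sens = 0, spec = 0, recall = 0)))
  feas <- stats_at[, "recall"] <= 0.2
  best_sens <- max(stats_at[feas, "sens"])
  ties <- feas & stats_at[, "sens"] == best_sens
  best_spec <- max(stats_at[ties, "spec"])
  pick <- max(cand[ties & stats_at[, "spec"] == best_spec])
  expect_equal(op$threshold, pick)
  expect_equal(op$sensitivity, best_sens)

  # no constraint: the maximal-sensitivity point
  op_free <- select_op(scores, labels)
  expect_equal(op_free$sensitivity, max(stats_at[, "sens"]))

  # infeasible constraint names the binding constraint
  expect_error(select_op(scores, labels, constraints = list(max_recall_rate = 0)),
               "max_recall_rate")
})

test_that("tuning/evaluation identifier overlap is a hard error", {
  expect_error(select_op(c(0.1, 0.9), c(0, 1),
                         tuning_ids = c("a", "b"), eval_ids = c("b", "c")),
               "overlap")
  expect_silent(op <- select_op(c(0.1, 0.9, 0.5), c(0, 1, 0),
                                tuning_ids = c("a", "b", "c"),
                                eval_ids = c("d", "e")))
})

test_that("recall rate is non-increasing in the threshold", {
  set.seed(62)
  scores <- stats::runif(500)
  for (i in 1:5) {
    t1 <- stats::runif(1); t2 <- t1 + stats::runif(1, 0, 1 - t1)
    expect_gte(mean(scores > t1), mean(scores > t2))
  }
})

test_that("monitoring triggers on a large recall gap but not at exactly 2 pp", {
  op <- list(threshold = 0.5)
  # 11.3% AI vs 3.8% reader 1: the over-recall pattern that forced an OP change
  w1 <- window_fixture(1000, n_ai = 113, n_r1 = 38, n_r1_ai_overlap = 30)
  snap1 <- monitor_window(w1, op)
  expect_equal(snap1$ai_recall_rate, 0.113)
  expect_equal(snap1$reader1_recall_rate, 0.038)
  expect_true(snap1$triggered)
  expect_match(paste(snap1$trigger_reasons, collapse = ";"), "recall gap")

  # 6.7% vs 4.7%: a 2.0-pp gap sits on the (exclusive) boundary
  w2 <- window_fixture(1000, n_ai = 67, n_r1 = 47, n_r1_ai_overlap = 40,
                       n_r2 = 47, n_r12_overlap = 24)
  snap2 <- monitor_window(w2, op)
  expect_equal(round(snap2$ai_recall_rate - snap2$reader1_recall_rate, 3), 0.02)
  expect_false(snap2$triggered)

  # equal rates never trigger
  w3 <- window_fixture(1000, n_ai = 50, n_r1 = 50, n_r1_ai_overlap = 50,
                       n_r2 = 50, n_r12_overlap = 50)
  expect_false(monitor_window(w3, op)$triggered)

  expect_error(monitor_window(w3[0, ], op), "empty")
})

test_that("arbitration-load projection can trigger on its own", {
  op <- list(threshold = 0.5)
  # small recall gap but AI recalls disjoint from reader 1's: predicted
  # discordant arbitration far exceeds the human-only rate
  w <- window_fixture(1000, n_ai = 40, n_r1 = 40, n_r1_ai_overlap = 0,
                      n_r2 = 40, n_r12_overlap = 38)
  snap <- monitor_window(w, op)
  expect_lte(snap$ai_recall_rate - snap$reader1_recall_rate, 0.02)
  expect_true(snap$triggered)
  expect_match(paste(snap$trigger_reasons, collapse = ";"), "arbitration")
})

test_that("recalibration restores the recall band and is idempotent", {
  ch <- generate_cohort(cohort_config(n_women = 12000, seed = 63))
  e <- inject_distribution_shift(ch$episodes,
                                 list(stratum = "hologic_lorad", logit_shift = 1.0))
  op0 <- list(threshold = 0.5, service_id = 1, history = list())
  class(op0) <- "operating_point"
  snap <- monitor_window(e, op0)
  expect_true(snap$triggered)

  half <- seq_len(nrow(e)) %% 2 == 0
  op1 <- recalibrate_op(op0, e[half, ])
  expect_gt(op1$threshold, op0$threshold)

  # recount on the held-out half: recall back inside the target band
  held <- e[!half, ]
  ai_recall <- mean(held$ai_score > op1$threshold)
  r1_recall <- mean(held$reader1_recall)
  n <- nrow(held)
  expect_lt(ai_recall - r1_recall, 0.02 + 3 * sqrt(ai_recall * (1 - ai_recall) / n))

  # idempotence on an unchanged window
  op2 <- recalibrate_op(op1, e[half, ])
  expect_equal(op2$threshold, op1$threshold)
  # prior OP archived with provenance
  expect_gte(length(op1$history), 1L)

  expect_warning(small <- recalibrate_op(op0, e[1:100, ]), "deferred")
  expect_true(attr(small, "deferred"))
  expect_equal(small$threshold, op0$threshold)
})

test_that("weekly series aggregates exactly and keeps single-week windows", {
  ep <- data.frame(
    episode_id = sprintf("E%02d", 1:10),
    screen_date = as.Date("2024-01-01") + c(rep(0, 6), rep(7, 4)),  # two Mondays
    ai_score = c(0.9, 0.9, 0.1, 0.1, 0.1, 0.1, 0.9, 0.1, 0.1, 0.1),
    outcome = c("screen_detected", rep("normal", 5), "screen_detected",
                rep("normal", 3)),
    stringsAsFactors = FALSE)
  ws <- weekly_series(ep, list(threshold = 0.5))
  expect_equal(nrow(ws), 2L)
  expect_equal(ws$n, c(6L, 4L))
  expect_equal(ws$recall_rate, c(2 / 6, 1 / 4))
  expect_equal(ws$cdr_per_1000, c(1000 / 6, 250))

  one <- weekly_series(ep[1:6, ], list(threshold = 0.5))
  expect_equal(nrow(one), 1L)
})
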