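# Shared fixtures built in code.

small_cohort <- function(n = 4000, seed = 42, ...) {
  generate_cohort(cohort_config(n_women = n, seed = seed, ...))
}

# Hand-built episode rows for labelling edge cases.
episode_row <- function(episode_id = "E1", outcome = "normal",
                        months = 30, pathology = NULL, side = NULL) {
  if (is.null(pathology)) {
    pathology <- if (outcome == "normal") "none" else "invasive"
  }
  if (is.null(side)) side <- if (outcome == "normal") "none" else "left"
  data.frame(episode_id = episode_id, outcome = outcome,
             outcome_interval_months = months, pathology = pathology,
             lesion_side = side, stringsAsFactors = FALSE)
}

box <- function(x1, y1, x2, y2) c(x_min = x1, y_min = y1, x_max = x2, y_max = y2)

box_df <- function(episode_id, side, view, x1, y1, x2, y2, ...) {
  data.frame(episode_id = episode_id, side = side, view = view,
             x_min = x1, y_min = y1, x_max = x2, y_max = y2, ...,
             stringsAsFactors = FALSE)
}

# Deterministic monitoring windows with exact recall patterns.
window_fixture <- function(n, n_ai, n_r1, n_r1_ai_overlap, n_r2 = n_r1,
                           n_r12_overlap = n_r1) {
  ai_score <- rep(0.1, n); ai_score[seq_len(n_ai)] <- 0.9
  r1 <- rep(FALSE, n)
  r1[seq_len(n_r1_ai_overlap)] <- TRUE                      # overlap with AI
  if (n_r1 > n_r1_ai_overlap) {
    r1[(n_ai + 1):(n_ai + n_r1 - n_r1_ai_overlap)] <- TRUE  # outside AI recalls
  }
  r2 <- rep(FALSE, n)
  r2[which(r1)[seq_len(n_r12_overlap)]] <- TRUE
  if (n_r2 > n_r12_overlap) {
    free <- setdiff(seq_len(n), which(r1 | r2 | ai_score > 0.5))
    r2[free[seq_len(n_r2 - n_r12_overlap)]] <- TRUE
  }
  data.frame(episode_id = sprintf("W%04d", seq_len(n)), service_id = 1,
             screen_date = as.Date("2024-01-01") + (seq_len(n) %% 14),
             ai_score = ai_score, reader1_recall = r1, reader2_recall = r2)
}

# Rank-statistic AUC oracle: mean over all positive-negative pairs,
# ties counting one half.
rank_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
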