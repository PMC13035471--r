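#' Select an operating point from a tuning set
#'
#' Scans every unique score threshold (strict-exceed decision rule) and,
#' among thresholds meeting all constraints, returns the one maximising
#' sensitivity, breaking ties toward higher specificity (and then the higher
#' threshold). The tuning set must be disjoint from any evaluation set; pass
#' `eval_ids` to enforce the identifier audit.
#'
#' @param tuning_scores Numeric AI scores on the tuning set.
#' @param tuning_labels 0/1 labels.
#' @param constraints Named list; supported: `max_recall_rate`,
#'   `min_specificity`, `max_recall_gap` (AI recall minus
#'   `reader_recall_rate`), `reader_recall_rate`.
#' @param service_id Service the OP is selected for.
#' @param tuning_ids,eval_ids Optional identifier vectors; overlap is an
#'   error.
#' @param selected_on Label for the tuning set recorded in provenance.
#' @return Object of class `operating_point`: `service_id`, `threshold`,
#'   `selected_on`, `constraints_satisfied`, `active_period` (unset),
#'   and the tuning-set `sensitivity`, `specificity`, `recall_rate` at the
#'   threshold.
#' @export
select_op <- function(tuning_scores, tuning_labels, constraints = list(),
                      service_id = 1L, tuning_ids = NULL, eval_ids = NULL,
                      selected_on = "tuning") {
  if (!is.null(tuning_ids) && !is.null(eval_ids)) {
    overlap <- intersect(tuning_ids, eval_ids)
    if (length(overlap)) {
      stop("tuning and evaluation sets overlap on ", length(overlap),
           " identifiers; OP selection requires disjoint sets")
    }
  }
  y <- as.integer(tuning_labels)
  if (sum(y == 1) == 0 || sum(y == 0) == 0) {
    stop("tuning set needs both positive and negative cases")
  }
  grid <- op_scan(tuning_scores, y)
  feasible <- rep(TRUE, nrow(grid))
  binding <- character()
  if (!is.null(constraints$max_recall_rate)) {
    ok <- grid$recall_rate <= constraints$max_recall_rate
    if (!any(ok)) binding <- c(binding, sprintf("max_recall_rate <= %g",
                                                constraints$max_recall_rate))
    feasible <- feasible & ok
  }
  if (!is.null(constraints$min_specificity)) {
    ok <- grid$specificity >= constraints$min_specificity
    if (!any(ok)) binding <- c(binding, sprintf("min_specificity >= %g",
                                                constraints$min_specificity))
    feasible <- feasible & ok
  }
  if (!is.null(constraints$max_recall_gap)) {
    rr <- constraints$reader_recall_rate
    if (is.null(rr)) stop("max_recall_gap constraint needs reader_recall_rate")
    ok <- grid$recall_rate - rr <= constraints$max_recall_gap
    if (!any(ok)) binding <- c(binding, sprintf("max_recall_gap <= %g",
                                                constraints$max_recall_gap))
    feasible <- feasible & ok
  }
  if (!any(feasible)) {
    if (!length(binding)) binding <- "joint constraint set"
    stop("no feasible operating point; binding constraint(s): ",
         paste(binding, collapse = "; "))
  }
  g <- grid[feasible, , drop = FALSE]
  g <- g[order(-g$sensitivity, -g$specificity, -g$threshold), , drop = FALSE]
  best <- g[1, ]
  structure(list(
    service_id = service_id,
    threshold = best$threshold,
    selected_on = selected_on,
    constraints_satisfied = names(constraints),
    active_period = NULL,
    sensitivity = best$sensitivity,
    specificity = best$specificity,
    recall_rate = best$recall_rate,
    history = list()
  ), class = "operating_point")
}

# Sensitivity/specificity/recall at every unique threshold (strict exceed).
op_scan <- function(scores, y) {
  n <- length(scores)
  n_pos <- sum(y == 1); n_neg <- n - n_pos
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  runs <- rle(ss)
  ends <- cumsum(runs$lengths)
  cnt <- c(0, utils::head(ends, -1))           # units above each unique threshold
  ctp <- c(0, utils::head(cumsum(ys)[ends], -1))
  out <- data.frame(
    threshold = runs$values,
    sensitivity = ctp / n_pos,
    specificity = 1 - (cnt - ctp) / n_neg,
    recall_rate = cnt / n
  )
  # an operating point that recalls nobody is clinically meaningless;
  # candidate thresholds sit strictly below the maximum observed score
  out[out$recall_rate > 0, , drop = FALSE]
}

#' @export
print.operating_point <- function(x, ...) {
  cat(sprintf("Operating point for service %s: threshold %.6f (selected on %s)\n",
              x$service_id, x$threshold, x$selected_on))
  cat(sprintf("  tuning-set sensitivity %.3f, specificity %.3f, recall %.2f%%\n",
              x$sensitivity, x$specificity, 100 * x$recall_rate))
  if (!is.null(x$active_period)) {
    cat(sprintf("  active: %s .. %s\n", x$active_period[1], x$active_period[2]))
  }
  if (length(x$history)) cat(sprintf("  archived prior OPs: %d\n", length(x$history)))
  invisible(x)
}

#' Monitoring snapshot with proxy-metric triggers
#'
#' Follow-up outcomes lag by months, so deployed performance is monitored by
#' recall-rate proxies: a recalibration trigger fires when the AI recall rate
#' exceeds the first reader's by strictly more than `max_recall_gap`
#' (2 absolute percentage points) or when the predicted arbitration rate
#' reaches `max_arbitration_ratio` (2.5) times the human-only arbitration
#' rate. The predicted arbitration rate is obtained by routing the window's
#' decisions through the workflow rules at the active operating point.
#'
#' @param window_episodes Episode table for the monitoring window.
#' @param op [select_op()] object (or a list with `threshold`).
#' @param arbitration_style Workflow style used for the arbitration rates.
#' @param max_recall_gap Trigger gap (default 0.02, strictly exceeded).
#' @param max_arbitration_ratio Trigger ratio (default 2.5, reached).
#' @return Object of class `monitoring_snapshot` with the observed rates,
#'   `triggered` flag and `trigger_reasons`.
#' @export
monitor_window <- function(window_episodes, op,
                           arbitration_style = c("discordant_only", "arbitrate_all"),
                           max_recall_gap = 0.02, max_arbitration_ratio = 2.5) {
  arbitration_style <- match.arg(arbitration_style)
  n <- nrow(window_episodes)
  if (n == 0) stop("empty monitoring window")
  ai <- window_episodes$ai_score > op$threshold
  r1 <- as.logical(window_episodes$reader1_recall)
  r2 <- as.logical(window_episodes$reader2_recall)
  arb_of <- function(first, second) {
    if (arbitration_style == "discordant_only") mean(first != second)
    else mean(first | second)
  }
  snap <- list(
    service_id = window_episodes$service_id[1],
    window = range(window_episodes$screen_date),
    n_cases = n,
    ai_recall_rate = mean(ai),
    reader1_recall_rate = mean(r1),
    predicted_arbitration_rate = arb_of(r1, ai),
    human_only_arbitration_rate = arb_of(r1, r2)
  )
  reasons <- character()
  # tolerance keeps the exclusive 2-pp boundary exact under floating point
  eps <- 1e-9
  if (snap$ai_recall_rate - snap$reader1_recall_rate > max_recall_gap + eps) {
    reasons <- c(reasons, sprintf("recall gap %.1fpp > %.1fpp",
                                  100 * (snap$ai_recall_rate - snap$reader1_recall_rate),
                                  100 * max_recall_gap))
  }
  if (snap$human_only_arbitration_rate > 0 &&
      snap$predicted_arbitration_rate >=
        max_arbitration_ratio * snap$human_only_arbitration_rate - eps) {
    reasons <- c(reasons, sprintf("arbitration ratio %.2f >= %.1f",
                                  snap$predicted_arbitration_rate /
                                    snap$human_only_arbitration_rate,
                                  max_arbitration_ratio))
  }
  snap$triggered <- length(reasons) > 0
  snap$trigger_reasons <- reasons
  class(snap) <- "monitoring_snapshot"
  snap
}

#' @export
print.monitoring_snapshot <- function(x, ...) {
  cat(sprintf("Monitoring snapshot, service %s (%s .. %s), n = %d\n",
              x$service_id, x$window[1], x$window[2], x$n_cases))
  cat(sprintf("  AI recall %.1f%% vs reader 1 %.1f%%; arbitration predicted %.1f%% vs human-only %.1f%%\n",
              100 * x$ai_recall_rate, 100 * x$reader1_recall_rate,
              100 * x$predicted_arbitration_rate, 100 * x$human_only_arbitration_rate))
  cat(if (x$triggered) paste("  TRIGGERED:", paste(x$trigger_reasons, collapse = "; "), "\n")
      else "  within tolerance\n")
  invisible(x)
}

#' Recalibrate an operating point from a monitoring window
#'
#' After a trigger fires, picks the lowest threshold (maximising sensitivity)
#' whose projected recall rate on the recent window satisfies the monitoring
#' constraints, archives the prior OP with its active period, and records
#' provenance. Deterministic: re-running on the same window returns the same
#' threshold.
#'
#' @param current_op Active [select_op()] object.
#' @param window_episodes Recent episode table (with `ai_score`,
#'   `reader1_recall`, `reader2_recall`).
#' @param arbitration_style Workflow style for the arbitration projection.
#' @param max_recall_gap,max_arbitration_ratio Monitoring constraints.
#' @param min_window Minimum window size; smaller windows defer with a
#'   warning and return the current OP unchanged.
#' @return A new `operating_point` (or the current one when deferred, with
#'   attribute `deferred = TRUE`).
#' @export
recalibrate_op <- function(current_op, window_episodes,
                           arbitration_style = c("discordant_only", "arbitrate_all"),
                           max_recall_gap = 0.02, max_arbitration_ratio = 2.5,
                           min_window = 1000) {
  arbitration_style <- match.arg(arbitration_style)
  n <- nrow(window_episodes)
  if (n < min_window) {
    warning(sprintf("window has %d cases (< %d); recalibration deferred", n, min_window))
    attr(current_op, "deferred") <- TRUE
    return(current_op)
  }
  s <- window_episodes$ai_score
  r1 <- as.logical(window_episodes$reader1_recall)
  r2 <- as.logical(window_episodes$reader2_recall)
  r1_rate <- mean(r1)
  human_arb <- if (arbitration_style == "discordant_only") mean(r1 != r2) else mean(r1 | r2)

  cand <- sort(unique(s))
  ok <- vapply(cand, function(t) {
    ai <- s > t
    pred_arb <- if (arbitration_style == "discordant_only") mean(r1 != ai) else mean(r1 | ai)
    (mean(ai) - r1_rate <= max_recall_gap) &&
      (human_arb == 0 || pred_arb < max_arbitration_ratio * human_arb)
  }, NA)
  if (!any(ok)) stop("no threshold satisfies the monitoring constraints on this window")
  new_thr <- min(cand[ok])   # lowest feasible threshold = maximal sensitivity proxy

  ai_new <- s > new_thr
  prior <- current_op
  prior$history <- NULL
  out <- structure(list(
    service_id = current_op$service_id,
    threshold = new_thr,
    selected_on = sprintf("recalibration window %s..%s (n=%d)",
                          min(window_episodes$screen_date),
                          max(window_episodes$screen_date), n),
    constraints_satisfied = c("max_recall_gap", "max_arbitration_ratio"),
    active_period = NULL,
    sensitivity = NA_real_,
    specificity = NA_real_,
    recall_rate = mean(ai_new),
    history = c(current_op$history, list(prior))
  ), class = "operating_point")
  out
}

#' Weekly recall rate and cancer detection rate
#'
#' Aggregates episodes by calendar week (weeks starting Monday) at a given
#' operating point, with Wald binomial CIs. Weeks inside the observed range
#' with zero cases are omitted and listed in the `"omitted_weeks"` attribute.
#'
#' @param episodes Episode table with `screen_date` and `ai_score`.
#' @param op `operating_point` (or list with `threshold`).
#' @param labels Optional [label_cases()] output; without it CDR uses the
#'   episode `outcome` field against the generator's truth.
#' @param conf_level CI level.
#' @return Data frame: `week` (start date), `n`, `recall_rate`, `recall_lo`,
#'   `recall_hi`, `cdr_per_1000`, `cdr_lo`, `cdr_hi`.
#' @export
weekly_series <- function(episodes, op, labels = NULL, conf_level = 0.95) {
  if (!"screen_date" %in% names(episodes)) stop("episodes must carry screen_date")
  ai <- episodes$ai_score > op$threshold
  lab <- if (!is.null(labels)) {
    labels$case_label[match(episodes$episode_id, labels$episode_id)]
  } else {
    as.integer(episodes$outcome != "normal")
  }
  week <- as.Date(cut(as.Date(episodes$screen_date), "week"))
  out <- do.call(rbind, lapply(split(seq_along(week), week), function(ix) {
    n <- length(ix)
    rr <- mean(ai[ix])
    tp <- sum(ai[ix] & lab[ix] == 1, na.rm = TRUE)
    cdr <- tp / n
    ci_r <- wald_ci_prop(rr, n, conf_level)
    ci_c <- wald_ci_prop(cdr, n, conf_level)
    data.frame(week = week[ix[1]], n = n,
               recall_rate = rr, recall_lo = ci_r[1], recall_hi = ci_r[2],
               cdr_per_1000 = 1000 * cdr, cdr_lo = 1000 * ci_c[1],
               cdr_hi = 1000 * ci_c[2])
  }))
  rownames(out) <- NULL
  all_weeks <- seq(min(out$week), max(out$week), by = 7)
  attr(out, "omitted_weeks") <- as.character(setdiff(as.character(all_weeks),
                                                     as.character(out$week)))
  out
}
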