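#' Workflow simulation configuration
#'
#' @param arbitration_style How cases reach the arbitration panel:
#'   `"discordant_only"` sends only cases where the two readers disagree;
#'   `"arbitrate_all"` sends any case flagged by either reader.
#' @param direct_to_clinic_enabled When `TRUE`, reader-concordant recalls
#'   bypass arbitration with probability `direct_to_clinic_rate`.
#' @param direct_to_clinic_rate Per-case probability of the bypass.
#' @param arbitration_cost_in_reads Workload of one arbitration in units of
#'   single screening reads (default 5, from an average 132 s arbitration
#'   read versus a 25 s single read).
#' @param single_read_seconds,arbitration_read_seconds Read durations; when
#'   their ratio disagrees with `arbitration_cost_in_reads` a warning (not an
#'   error) is raised.
#' @param panel_model Arbitration outcome model: `"fixed"` (a panel with its
#'   own sensitivity/specificity), `"oracle"` (recalls exactly the cancers)
#'   or `"always_uphold"` (upholds every recall sent to it). The programmes
#'   this emulates report only arbitration counts, so detection outcomes
#'   under simulated arbitration are model-dependent.
#' @param panel_sensitivity,panel_specificity Accuracy of the `"fixed"` panel.
#' @param seed RNG seed for panel and bypass draws.
#' @return List of class `workflow_config`.
#' @export
workflow_config <- function(arbitration_style = c("discordant_only", "arbitrate_all"),
                            direct_to_clinic_enabled = FALSE,
                            direct_to_clinic_rate = 0.03,
                            arbitration_cost_in_reads = 5,
                            single_read_seconds = 25,
                            arbitration_read_seconds = 132,
                            panel_model = c("fixed", "oracle", "always_uphold"),
                            panel_sensitivity = 0.60,
                            panel_specificity = 0.75,
                            seed = 1L) {
  arbitration_style <- match.arg(arbitration_style)
  panel_model <- match.arg(panel_model)
  if (arbitration_cost_in_reads <= 0 || single_read_seconds <= 0 ||
      arbitration_read_seconds <= 0) {
    config_error("arbitration_cost_in_reads", "costs must be positive")
  }
  ratio <- arbitration_read_seconds / single_read_seconds
  if (abs(ratio - arbitration_cost_in_reads) > 0.5) {
    warning(sprintf(
      "arbitration_cost_in_reads (%.2f) inconsistent with seconds ratio (%.2f)",
      arbitration_cost_in_reads, ratio))
  }
  structure(list(
    arbitration_style = arbitration_style,
    direct_to_clinic_enabled = direct_to_clinic_enabled,
    direct_to_clinic_rate = direct_to_clinic_rate,
    arbitration_cost_in_reads = arbitration_cost_in_reads,
    single_read_seconds = single_read_seconds,
    arbitration_read_seconds = arbitration_read_seconds,
    panel_model = panel_model,
    panel_sensitivity = panel_sensitivity,
    panel_specificity = panel_specificity,
    seed = as.integer(seed)
  ), class = "workflow_config")
}

# Vectorised routing of first/second opinions through the double-read rules.
# Returns per-episode: arbitrated (logical), recall (logical), direct (logical).
route_decisions <- function(first, second, is_cancer, config) {
  n <- length(first)
  if (length(second) != n) stop("missing second opinion for some episodes")
  both <- first & second
  any_rec <- first | second
  panel_says <- switch(config$panel_model,
    oracle = is_cancer,
    always_uphold = rep(TRUE, n),
    fixed = {
      p <- ifelse(is_cancer, config$panel_sensitivity, 1 - config$panel_specificity)
      stats::runif(n) < p
    })
  if (config$arbitration_style == "discordant_only") {
    direct <- both & config$direct_to_clinic_enabled &
      stats::runif(n) < config$direct_to_clinic_rate
    arbitrated <- any_rec & !direct
    recall <- ifelse(direct, TRUE, ifelse(arbitrated, panel_says, FALSE))
  } else {
    direct <- rep(FALSE, n)
    arbitrated <- any_rec
    recall <- ifelse(arbitrated, panel_says, FALSE)
  }
  list(arbitrated = arbitrated, recall = recall, direct = direct)
}

#' Route a single episode through the double-read workflow
#'
#' The per-episode view of the routing rules used by [run_arm()]: concordant
#' negatives are cleared without arbitration; under `discordant_only`,
#' concordant recalls go direct to clinic (when enabled, with the configured
#' probability) or to arbitration, and disagreements go to arbitration; under
#' `arbitrate_all` any flagged case goes to arbitration.
#'
#' @param episode One-row episode data frame.
#' @param arm `"human_double"` (reader 1 + reader 2) or `"human_plus_ai"`
#'   (reader 1 + AI when eligible, human second reader otherwise).
#' @param config [workflow_config()].
#' @param label Optional 0/1 ground-truth label (for the oracle panel).
#' @return List: `screening_reads` (human reads consumed before arbitration),
#'   `arbitrated`, `recall`, `second_opinion_source`.
#' @export
route_episode <- function(episode, arm = c("human_double", "human_plus_ai"),
                          config = workflow_config(), label = NULL) {
  arm <- match.arg(arm)
  first <- as.logical(episode$reader1_recall)
  if (arm == "human_double") {
    second <- as.logical(episode$reader2_recall)
    src <- "reader2"
    reads <- 2L
  } else if (isTRUE(as.logical(episode$ai_eligible))) {
    second <- episode$ai_score > (attr(episode, "operating_point") %||% 0.5)
    src <- "ai"
    reads <- 1L
  } else {
    second <- as.logical(episode$reader2_recall)
    src <- "reader2_fallback"
    reads <- 2L
  }
  if (is.na(second)) stop("missing second opinion")
  is_cancer <- if (!is.null(label)) label == 1 else episode$outcome != "normal"
  r <- with_rng_seed(config$seed, route_decisions(first, second, is_cancer, config))
  list(screening_reads = reads, arbitrated = r$arbitrated, recall = r$recall,
       second_opinion_source = src)
}

#' Simulate one workflow arm over a cohort
#'
#' Routes every episode through the configured double-read rules and
#' aggregates read counts, arbitration load, recalls and detected cancers.
#' In the `human_plus_ai` arm the AI replaces the second reader for
#' AI-eligible episodes (consuming zero human reads); AI-ineligible episodes
#' retain their traditional double-read workflow. Equivalent reads weight
#' each arbitration as `arbitration_cost_in_reads` single reads.
#'
#' @param episodes Episode table.
#' @param labels [label_cases()] output aligned by `episode_id`.
#' @param arm `"human_double"` or `"human_plus_ai"`.
#' @param config [workflow_config()].
#' @param op Operating point for the AI decision (default the generator's).
#' @return Object of class `workflow_outcome` with the per-arm counts.
#' @export
run_arm <- function(episodes, labels, arm = c("human_double", "human_plus_ai"),
                    config = workflow_config(), op = NULL) {
  arm <- match.arg(arm)
  op <- op %||% attr(episodes, "operating_point") %||% 0.5
  ix <- match(episodes$episode_id, labels$episode_id)
  keep <- !is.na(ix)
  e <- episodes[keep, , drop = FALSE]
  lab <- labels$case_label[ix[keep]]
  n <- nrow(e)

  first <- as.logical(e$reader1_recall)
  if (arm == "human_double") {
    second <- as.logical(e$reader2_recall)
    screening_reads <- 2L * n
  } else {
    eligible <- as.logical(e$ai_eligible)
    second <- ifelse(eligible, e$ai_score > op, as.logical(e$reader2_recall))
    # 1 human read per AI-eligible episode, 2 per ineligible fallback
    screening_reads <- n + sum(!eligible)
  }
  r <- with_rng_seed(config$seed + match(arm, c("human_double", "human_plus_ai")),
                     route_decisions(first, second, lab == 1, config))

  outcome <- workflow_outcome(
    arm = arm,
    screening_reads = as.integer(screening_reads),
    arbitration_reads = sum(r$arbitrated),
    recalls = sum(r$recall),
    detected_cancers = sum(r$recall & lab == 1),
    n_episodes = n,
    arbitration_cost_in_reads = config$arbitration_cost_in_reads
  )
  attr(outcome, "decisions") <- data.frame(episode_id = e$episode_id,
                                           recall = r$recall,
                                           arbitrated = r$arbitrated,
                                           case_label = lab)
  outcome
}

#' Assemble a workflow outcome record
#'
#' Computes the derived quantities (equivalent reads, CDR per 1,000 women,
#' recall rate) from raw per-arm counts; used both by [run_arm()] and to
#' analyse externally reported read counts.
#'
#' @param arm Arm label.
#' @param screening_reads Human screening reads before arbitration.
#' @param arbitration_reads Arbitration events.
#' @param recalls Recalled women.
#' @param detected_cancers True-positive recalls.
#' @param n_episodes Episodes routed.
#' @param arbitration_cost_in_reads Equivalent-read weight of one arbitration.
#' @return Object of class `workflow_outcome`.
#' @export
workflow_outcome <- function(arm, screening_reads, arbitration_reads,
                             recalls = NA_integer_, detected_cancers = NA_integer_,
                             n_episodes = NA_integer_,
                             arbitration_cost_in_reads = 5) {
  structure(list(
    arm = arm,
    screening_reads = screening_reads,
    arbitration_reads = arbitration_reads,
    equivalent_reads = screening_reads + arbitration_cost_in_reads * arbitration_reads,
    recalls = recalls,
    detected_cancers = detected_cancers,
    n_episodes = n_episodes,
    cdr_per_1000 = if (!is.na(n_episodes) && n_episodes > 0)
      1000 * detected_cancers / n_episodes else NA_real_,
    recall_rate = if (!is.na(n_episodes) && n_episodes > 0)
      recalls / n_episodes else NA_real_,
    arbitration_cost_in_reads = arbitration_cost_in_reads
  ), class = "workflow_outcome")
}

#' @export
print.workflow_outcome <- function(x, ...) {
  cat(sprintf("Workflow arm `%s`\n", x$arm))
  cat(sprintf("  screening reads: %s, arbitration reads: %s, equivalent reads: %s\n",
              format(x$screening_reads, big.mark = ","),
              format(x$arbitration_reads, big.mark = ","),
              format(x$equivalent_reads, big.mark = ",")))
  if (!is.na(x$n_episodes)) {
    cat(sprintf("  recalls: %s (%.2f%%), detected cancers: %s (CDR %.2f/1,000)\n",
                format(x$recalls, big.mark = ","), 100 * x$recall_rate,
                format(x$detected_cancers, big.mark = ","), x$cdr_per_1000))
  }
  invisible(x)
}

#' Compare two workflow arms
#'
#' Percent changes computed as `100 * (a - b) / b` (arm `a` relative to
#' baseline `b`), in exact double arithmetic before any rounding.
#'
#' @param outcome_a,outcome_b [workflow_outcome()] objects on the same cohort.
#' @return Data frame: `quantity`, `value_a`, `value_b`, `pct_change`
#'   (`NA` and flagged when the baseline is zero).
#' @export
compare_arms <- function(outcome_a, outcome_b) {
  qs <- c("equivalent_reads", "screening_reads", "arbitration_reads",
          "recalls", "detected_cancers", "cdr_per_1000", "recall_rate")
  rows <- lapply(qs, function(q) {
    a <- outcome_a[[q]]; b <- outcome_b[[q]]
    pct <- if (is.na(a) || is.na(b)) NA_real_
    else if (b == 0) NA_real_ else 100 * (a - b) / b
    data.frame(quantity = q, value_a = a, value_b = b, pct_change = pct,
               baseline_zero = !is.na(b) && b == 0)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Detection overlap between two workflow arms
#'
#' Partitions ground-truth cancers into detected-by-both / only-A / only-B /
#' neither, with the higher-risk fraction of each cell.
#'
#' @param decisions_a,decisions_b Final per-episode recall decisions
#'   (data frames with `episode_id` and `recall`, e.g. the `"decisions"`
#'   attribute of [run_arm()]).
#' @param labels [label_cases()] output (positives define the cancer set).
#' @return Data frame with one row per cell: `cell`, `n`, `n_higher_risk`,
#'   `pct_higher_risk`.
#' @export
detection_overlap <- function(decisions_a, decisions_b, labels) {
  pos <- labels[labels$case_label == 1, , drop = FALSE]
  a <- decisions_a$recall[match(pos$episode_id, decisions_a$episode_id)]
  b <- decisions_b$recall[match(pos$episode_id, decisions_b$episode_id)]
  a[is.na(a)] <- FALSE; b[is.na(b)] <- FALSE
  higher <- pos$risk_class == "higher"
  cells <- list(both = a & b, only_a = a & !b, only_b = !a & b,
                neither = !a & !b)
  out <- do.call(rbind, lapply(names(cells), function(nm) {
    sel <- cells[[nm]]
    n <- sum(sel); nh <- sum(sel & higher)
    data.frame(cell = nm, n = n, n_higher_risk = nh,
               pct_higher_risk = if (n > 0) 100 * nh / n else NA_real_)
  }))
  rownames(out) <- NULL
  out
}
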