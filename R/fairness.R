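#' Subgroup performance report with per-subgroup noninferiority screening
#'
#' For each level of each requested attribute, computes AI and first-reader
#' sensitivity/specificity with CIs (policy-routed), the clustered paired
#' differences, and noninferiority p-values at the prespecified margin. No
#' multiplicity adjustment is applied: subgroup analyses are exploratory.
#' Missing attribute values form an explicit `"missing"` level and are never
#' silently dropped. Subgroups with fewer positives than
#' `min_positives_warning` are flagged as limiting the strength of
#' statistical conclusions; subgroups with zero positives report sensitivity
#' as undefined (`NA`), never 0.
#'
#' @param episodes Episode table (AI decisions from `ai_score` and `op`;
#'   reader decisions from `reader1_recall`; clusters from `reader1_id`).
#' @param labels [label_cases()] output.
#' @param attributes Character vector of episode columns to stratify by.
#' @param op Operating point (list with `threshold`); default generator OP.
#' @param margin,alpha Noninferiority margin and one-sided level.
#' @param min_positives_warning Flag threshold (default 50 positives).
#' @return Data frame with one row per (attribute, level, metric).
#' @export
subgroup_report <- function(episodes, labels,
                            attributes = c("age_band", "imd_decile", "ethnicity",
                                           "density_quartile", "manufacturer_model",
                                           "screen_type"),
                            op = NULL, margin = 0.05, alpha = 0.025,
                            min_positives_warning = 50) {
  thr <- if (is.null(op)) attr(episodes, "operating_point") %||% 0.5 else op$threshold
  ix <- match(episodes$episode_id, labels$episode_id)
  keep <- !is.na(ix)
  e <- episodes[keep, , drop = FALSE]
  y <- labels$case_label[ix[keep]]
  ai <- e$ai_score > thr
  r1 <- as.logical(e$reader1_recall)
  cl <- as.character(e$reader1_id)

  one_level <- function(attribute, level, sel) {
    rows <- lapply(c("sensitivity", "specificity"), function(metric) {
      sub_y <- y[sel]
      n_pos <- sum(sub_y == 1)
      n_neg <- sum(sub_y == 0)
      n_sub <- if (metric == "sensitivity") n_pos else n_neg
      base <- data.frame(attribute = attribute, level = level,
                         metric = metric, n = sum(sel), n_positives = n_pos,
                         stringsAsFactors = FALSE)
      if (n_sub == 0) {
        return(cbind(base, data.frame(
          ai_value = NA_real_, reader_value = NA_real_, difference = NA_real_,
          ci_low = NA_real_, ci_high = NA_real_, p_noninferiority = NA_real_,
          verdict = "undefined", low_positives_flag = TRUE)))
      }
      n_cl <- length(unique(cl[sel][if (metric == "sensitivity") sub_y == 1 else sub_y == 0]))
      if (n_cl < 2) {
        pd <- paired_difference(ai[sel], r1[sel], sub_y,
                                if (metric == "sensitivity") "positives" else "negatives")
        return(cbind(base, data.frame(
          ai_value = pd$ai_value, reader_value = pd$reader_value,
          difference = pd$difference, ci_low = NA_real_, ci_high = NA_real_,
          p_noninferiority = NA_real_, verdict = "inconclusive",
          low_positives_flag = TRUE)))
      }
      cmp <- compare_readers(ai[sel], r1[sel], sub_y, cl[sel],
                             metric = metric, margin = margin, alpha = alpha)
      cbind(base, data.frame(
        ai_value = cmp$ai_value, reader_value = cmp$reader_value,
        difference = cmp$difference, ci_low = cmp$ci_low, ci_high = cmp$ci_high,
        p_noninferiority = cmp$p_noninferiority, verdict = cmp$verdict,
        low_positives_flag = n_pos < min_positives_warning))
    })
    do.call(rbind, rows)
  }

  out <- list(one_level("all", "all", rep(TRUE, nrow(e))))
  for (attribute in attributes) {
    vals <- e[[attribute]]
    vals[is.na(vals)] <- "missing"
    for (level in sort(unique(vals))) {
      out <- c(out, list(one_level(attribute, level, vals == level)))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Quantile-binned calibration curves per subgroup
#'
#' Bins AI scores into `n_bins` quantile bins within each subgroup and
#' compares the observed per-bin cancer fraction against the mean score
#' (treating the score as a nominal disease probability). When a subgroup has
#' fewer distinct scores than bins, the bin count is reduced with a warning.
#'
#' @param scores AI scores.
#' @param labels 0/1 labels.
#' @param groups Subgroup assignment (single grouping vector; use
#'   `rep("all", length(scores))` for the cohort curve).
#' @param n_bins Number of quantile bins (default 10).
#' @return Data frame of class `calibration_curves`: `subgroup`, `bin`,
#'   `bin_low`, `bin_high`, `expected_rate` (mean score), `observed_rate`,
#'   `n`. The `"divergence"` attribute summarises the per-subgroup mean
#'   absolute expected-observed gap weighted by bin size (expected
#'   calibration error).
#' @export
calibration_curves <- function(scores, labels, groups = NULL, n_bins = 10) {
  y <- as.integer(labels)
  groups <- groups %||% rep("all", length(scores))
  out <- list(); div <- list()
  for (g in sort(unique(groups))) {
    sel <- groups == g
    s <- scores[sel]; yy <- y[sel]
    k <- min(n_bins, length(unique(s)))
    if (k < n_bins) {
      warning(sprintf("subgroup %s: only %d distinct scores; using %d bins", g,
                      length(unique(s)), k))
    }
    if (sum(yy == 1) == 0) {
      warning(sprintf("subgroup %s has no positives; curve flagged", g))
    }
    edges <- unique(stats::quantile(s, probs = seq(0, 1, length.out = k + 1),
                                    names = FALSE))
    if (length(edges) < 2) edges <- c(edges[1], edges[1])
    bin <- if (length(unique(edges)) < 2) rep(1L, length(s)) else
      cut(s, breaks = edges, include.lowest = TRUE, labels = FALSE)
    rows <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
      ix <- bin == b
      data.frame(subgroup = g, bin = b,
                 bin_low = edges[b], bin_high = edges[b + 1],
                 expected_rate = mean(s[ix]), observed_rate = mean(yy[ix]),
                 n = sum(ix), stringsAsFactors = FALSE)
    }))
    out <- c(out, list(rows))
    div[[g]] <- sum(abs(rows$expected_rate - rows$observed_rate) * rows$n) / sum(rows$n)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "divergence") <- unlist(div)
  class(res) <- c("calibration_curves", "data.frame")
  res
}

#' Positives required for a target CI half-width (or noninferiority power)
#'
#' Inverts the Wald half-width of a paired sensitivity difference:
#' `n = z^2 * v / h^2` with per-pair variance `v = discordance - d^2`, where
#' `discordance` is the expected fraction of reader-AI disagreements among
#' positives and `d` the expected difference. With `power` supplied, returns
#' instead the positives needed for a one-sided noninferiority test at level
#' `alpha` with the stated margin: `n = (z_alpha + z_power)^2 * v /
#' (margin + d)^2`.
#'
#' @param margin Target CI half-width (or noninferiority margin when `power`
#'   is given), in absolute proportion points.
#' @param expected_difference Anticipated true difference.
#' @param alpha Two-sided CI level complement (default 0.05) or one-sided
#'   test level when `power` is given.
#' @param power Optional target power.
#' @param discordance Expected disagreement fraction among positives
#'   (default 0.12, typical reader-AI concordance).
#' @param prevalence Optional positives-per-examination rate; when given the
#'   result includes the implied number of examinations.
#' @return List: `positives`, and `examinations` when `prevalence` is given.
#' @export
required_sample_size <- function(margin, expected_difference = 0, alpha = 0.05,
                                 power = NULL, discordance = 0.12,
                                 prevalence = NULL) {
  if (margin <= 0) stop("margin must be positive")
  v <- max(discordance - expected_difference^2, 0)
  if (is.null(power)) {
    z <- stats::qnorm(1 - alpha / 2)
    n <- ceiling(z^2 * v / margin^2)
  } else {
    if (power >= 1) stop("power must be below 1")
    z <- stats::qnorm(1 - alpha) + stats::qnorm(power)
    eff <- margin + expected_difference
    if (eff <= 0) stop("margin + expected_difference must be positive")
    n <- ceiling(z^2 * v / eff^2)
  }
  n <- max(n, 1L)
  out <- list(positives = n)
  if (!is.null(prevalence)) {
    check_proportion(prevalence, "prevalence")
    out$examinations <- ceiling(n / prevalence)
  }
  out
}
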