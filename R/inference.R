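#' Paired difference in sensitivity or specificity
#'
#' Difference (AI minus comparator) in the proportion of correct decisions
#' over the positive subset (sensitivity) or negative subset (specificity).
#'
#' @param ai_decisions,reader_decisions Logical recall decisions, aligned.
#' @param labels 0/1 ground-truth labels.
#' @param subset `"positives"` (sensitivity) or `"negatives"` (specificity).
#' @return List: `difference`, `ai_value`, `reader_value`, `n`, and the
#'   per-unit paired indicator difference `d` (AI success minus reader
#'   success) restricted to the subset, with the subset row indices in `idx`.
#' @export
paired_difference <- function(ai_decisions, reader_decisions, labels,
                              subset = c("positives", "negatives")) {
  subset <- match.arg(subset)
  y <- as.integer(labels)
  sel <- if (subset == "positives") y == 1 else y == 0
  if (!any(sel)) stop("empty ", subset, " subset")
  ai <- as.logical(ai_decisions)[sel]
  rd <- as.logical(reader_decisions)[sel]
  # a "success" is recalling a positive, or clearing a negative
  ok_ai <- if (subset == "positives") ai else !ai
  ok_rd <- if (subset == "positives") rd else !rd
  d <- as.integer(ok_ai) - as.integer(ok_rd)
  list(difference = mean(ok_ai) - mean(ok_rd),
       ai_value = mean(ok_ai), reader_value = mean(ok_rd),
       n = sum(sel), d = d, idx = which(sel))
}

#' Split oversized clusters deterministically
#'
#' Reader clusters are capped to avoid single high-volume readers dominating
#' the variance estimate; members of an oversized cluster are dealt
#' round-robin into the smallest number of subclusters respecting the cap.
#'
#' @param clusters Cluster identifiers, one per unit.
#' @param max_cluster_size Cap (default 1000).
#' @return Character cluster identifiers after splitting.
#' @export
split_clusters <- function(clusters, max_cluster_size = 1000) {
  cl <- as.character(clusters)
  sizes <- table(cl)
  big <- names(sizes)[sizes > max_cluster_size]
  for (b in big) {
    ix <- which(cl == b)
    k <- ceiling(length(ix) / max_cluster_size)
    cl[ix] <- paste0(b, ".", ((seq_along(ix) - 1L) %% k) + 1L)
  }
  cl
}

#' Cluster-robust (Obuchowski-type) variance of a paired mean difference
#'
#' For per-unit paired indicator differences `d` grouped into clusters
#' (screens read by the same reader), estimates the variance of the mean
#' difference as `I/(I-1) * sum_i (S_i - m_i * D)^2 / N^2` with `I` clusters,
#' cluster sums `S_i`, cluster sizes `m_i`, grand mean `D` and total `N`.
#' With all-singleton clusters this equals the classical unbiased paired
#' variance `var(d)/n` exactly.
#'
#' @param d Per-unit paired differences (typically in `{-1, 0, 1}`).
#' @param clusters Cluster identifiers, one per unit (use [split_clusters()]
#'   first to apply the cluster-size ceiling).
#' @return Variance of the mean difference (a scalar, `>= 0`).
#' @export
obuchowski_variance <- function(d, clusters) {
  if (length(d) != length(clusters)) stop("d and clusters differ in length")
  S <- rowsum(d, clusters)
  m <- rowsum(rep(1, length(d)), clusters)
  I <- nrow(S)
  if (I < 2) stop("need at least 2 clusters for a cluster-robust variance")
  N <- length(d)
  D <- mean(d)
  as.numeric(I / (I - 1) * sum((S - m * D)^2) / N^2)
}

#' One-sided Wald noninferiority test for a clustered paired difference
#'
#' Tests `H0: difference <= -margin` against `H1: difference > -margin` with
#' `z = (difference + margin) / sqrt(variance)` and `p = pnorm(-z)`. The AI is
#' declared noninferior when `p < alpha`.
#'
#' @param difference Observed difference (AI minus comparator).
#' @param variance Cluster-robust variance of the difference
#'   ([obuchowski_variance()]).
#' @param margin Absolute noninferiority margin (default 0.05).
#' @param alpha One-sided level (default 0.025).
#' @param d,clusters Optional per-unit differences and clusters, used for a
#'   cluster-bootstrap fallback when the plug-in variance is degenerate
#'   (zero) while the difference is away from the margin.
#' @param df Reference-distribution degrees of freedom. With few reader
#'   clusters the cluster-robust variance is noisy and a plain normal
#'   reference is anticonservative, so the test uses the standard
#'   small-sample correction of referring `z` to a t distribution with
#'   `n_clusters - 1` degrees of freedom; `Inf` (the default when no cluster
#'   count is supplied) gives the normal reference.
#' @return List of class `ni_test`: `z`, `p_value`, `noninferior`, `margin`,
#'   `alpha`, `method` (`"wald"` or `"bootstrap_fallback"`).
#' @export
noninferiority_test <- function(difference, variance, margin = 0.05,
                                alpha = 0.025, d = NULL, clusters = NULL,
                                df = if (is.null(clusters)) Inf else
                                  length(unique(clusters)) - 1) {
  if (margin <= 0) stop("margin must be positive")
  method <- "wald"
  if (variance <= 0) {
    if (difference == 0 || is.null(d)) {
      # no observed disagreement at all: the difference is identically 0,
      # which exceeds any -margin
      z <- Inf
      p <- if (difference > -margin) 0 else 1
      return(structure(list(z = z, p_value = p, noninferior = p < alpha,
                            margin = margin, alpha = alpha,
                            method = "degenerate"), class = "ni_test"))
    }
    method <- "bootstrap_fallback"
    boot <- cluster_bootstrap_means(d, clusters, n_iter = 2000, seed = 1L)
    p <- mean(boot <= -margin)
    return(structure(list(z = NA_real_, p_value = p, noninferior = p < alpha,
                          margin = margin, alpha = alpha, method = method),
                     class = "ni_test"))
  }
  z <- (difference + margin) / sqrt(variance)
  p <- stats::pt(-z, df = max(df, 1))
  structure(list(z = z, p_value = p, noninferior = p < alpha,
                 margin = margin, alpha = alpha, df = df, method = method),
            class = "ni_test")
}

#' @export
print.ni_test <- function(x, ...) {
  cat(sprintf("Noninferiority (margin %.3f, one-sided alpha %.3f): z = %.3f, p = %.3g -> %s\n",
              x$margin, x$alpha, x$z, x$p_value,
              if (x$noninferior) "noninferior" else "not shown"))
  invisible(x)
}

#' Clustered McNemar superiority test
#'
#' Obuchowski-style extension of McNemar's test to clustered paired binary
#' data, using per-cluster discordant differences `g_i` (cluster sum of the
#' paired indicator differences): `T = (sum g_i)^2 / sum g_i^2`, referred to a
#' chi-squared distribution with 1 degree of freedom. With singleton clusters
#' this reduces exactly to classical McNemar `(b - c)^2 / (b + c)`. The
#' one-tailed p-value follows the observed direction and is intended to be
#' used only after noninferiority has been established (the cascade is
#' enforced by [compare_readers()]).
#'
#' @param d Per-unit paired differences in `{-1, 0, 1}`.
#' @param clusters Cluster identifiers.
#' @return List of class `clustered_mcnemar`: `statistic`, `p_two_sided`,
#'   `p_one_sided`, `direction` (+1 favours AI), `degenerate` (no discordant
#'   pairs: p reported as 1 and flagged).
#' @export
superiority_test <- function(d, clusters) {
  g <- as.numeric(rowsum(d, clusters))
  ss <- sum(g^2)
  if (ss == 0) {
    return(structure(list(statistic = 0, p_two_sided = 1, p_one_sided = 1,
                          direction = 0, degenerate = TRUE),
                     class = "clustered_mcnemar"))
  }
  stat <- sum(g)^2 / ss
  p2 <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  dir <- sign(sum(g))
  # balanced discordance carries no directional evidence at all
  p1 <- if (dir > 0) p2 / 2 else if (dir < 0) 1 - p2 / 2 else 1
  structure(list(statistic = stat, p_two_sided = p2, p_one_sided = p1,
                 direction = dir, degenerate = FALSE),
            class = "clustered_mcnemar")
}

#' Holm-Bonferroni step-down multiplicity correction
#'
#' Wraps `stats::p.adjust(method = "holm")`, returning both adjusted p-values
#' and rejection decisions at the family level `alpha`. Holm's rejections are
#' always a superset of plain Bonferroni's.
#'
#' @param p_values Numeric vector of raw p-values.
#' @param alpha Family-wise error level.
#' @return Data frame: `p_raw`, `p_adjusted`, `reject`.
#' @export
holm_bonferroni <- function(p_values, alpha = 0.025) {
  if (anyNA(p_values)) stop("p_values must be finite")
  adj <- stats::p.adjust(p_values, method = "holm")
  data.frame(p_raw = p_values, p_adjusted = adj, reject = adj <= alpha)
}

# Cluster bootstrap distribution of the mean of d (resampling whole clusters).
cluster_bootstrap_means <- function(d, clusters, n_iter = 10000, seed = 1L) {
  spl <- split(d, clusters)
  I <- length(spl)
  sums <- vapply(spl, sum, 0)
  sizes <- lengths(spl)
  with_rng_seed(seed, {
    ix <- matrix(sample.int(I, I * n_iter, replace = TRUE), nrow = I)
    colSums(matrix(sums[ix], nrow = I)) / colSums(matrix(sizes[ix], nrow = I))
  })
}

#' Case-level percentile bootstrap confidence interval
#'
#' Resamples case identifiers with replacement and recomputes the statistic
#' on each resample; breast- and lesion-level rows move with their case.
#'
#' @param statistic_fn Function `data -> numeric(1)`.
#' @param data Data frame with a case identifier column.
#' @param case_ids Name of the identifier column (default `"episode_id"`).
#' @param n_iter Bootstrap iterations (default 10000).
#' @param conf_level Confidence level.
#' @param seed RNG seed; fixed seed gives identical endpoints.
#' @param max_undefined Error when the statistic is undefined (NA) on more
#'   than this fraction of resamples (default 0.01).
#' @return List of class `boot_ci`: `estimate`, `ci_low`, `ci_high`,
#'   `n_iter`, `n_undefined`.
#' @export
bootstrap_ci <- function(statistic_fn, data, case_ids = "episode_id",
                         n_iter = 10000, conf_level = 0.95, seed = 1L,
                         max_undefined = 0.01) {
  ids <- unique(data[[case_ids]])
  rows_by_id <- split(seq_len(nrow(data)), data[[case_ids]])
  est <- statistic_fn(data)
  stats_v <- with_rng_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      take <- sample(ids, length(ids), replace = TRUE)
      statistic_fn(data[unlist(rows_by_id[take], use.names = FALSE), , drop = FALSE])
    }, 0)
  })
  n_undef <- sum(is.na(stats_v))
  if (n_undef > max_undefined * n_iter) {
    stop(sprintf("statistic undefined on %d/%d bootstrap resamples", n_undef, n_iter))
  }
  q <- stats::quantile(stats_v, c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2),
                       na.rm = TRUE, names = FALSE)
  structure(list(estimate = est, ci_low = q[1], ci_high = q[2],
                 n_iter = n_iter, n_undefined = n_undef),
            class = "boot_ci")
}

#' Confidence-interval method policy
#'
#' Wald intervals for sensitivity, specificity, CDR and recall rate when the
#' relevant denominator has at least 50 units; bootstrap otherwise and always
#' for PPV and NPV.
#'
#' @param metric Metric name.
#' @param n Denominator size.
#' @return `"wald"` or `"bootstrap"`.
#' @export
ci_policy <- function(metric, n) {
  if (metric %in% c("sensitivity", "specificity", "cdr", "recall_rate") && n >= 50) {
    "wald"
  } else {
    "bootstrap"
  }
}

#' Full paired comparison of AI against a human reader
#'
#' Runs the complete clustered inference cascade for one endpoint: paired
#' difference, cluster-robust variance (with cluster-size ceiling), Wald
#' noninferiority at the stated margin, and — only if noninferiority is shown
#' — the one-tailed clustered McNemar superiority test.
#'
#' @param ai_decisions,reader_decisions Logical decisions, aligned.
#' @param labels 0/1 labels.
#' @param clusters Reader cluster identifiers, one per unit.
#' @param metric `"sensitivity"` or `"specificity"`.
#' @param level Analysis level label carried in the result.
#' @param margin Noninferiority margin (default 0.05).
#' @param alpha One-sided working level (default 0.025).
#' @param conf_level Level of the Wald CI on the difference.
#' @param max_cluster_size Cluster-size ceiling (default 1000).
#' @return Object of class `paired_comparison`: difference, variance, CI,
#'   p-values, verdict in `{noninferior_and_superior, noninferior,
#'   inconclusive}`, `n`, `n_clusters`.
#' @export
compare_readers <- function(ai_decisions, reader_decisions, labels, clusters,
                            metric = c("sensitivity", "specificity"),
                            level = "case", margin = 0.05, alpha = 0.025,
                            conf_level = 0.95, max_cluster_size = 1000) {
  metric <- match.arg(metric)
  subset <- if (metric == "sensitivity") "positives" else "negatives"
  pd <- paired_difference(ai_decisions, reader_decisions, labels, subset)
  cl <- split_clusters(as.character(clusters)[pd$idx], max_cluster_size)
  v <- obuchowski_variance(pd$d, cl)
  ni <- noninferiority_test(pd$difference, v, margin, alpha, d = pd$d, clusters = cl)
  sup <- NULL
  verdict <- "inconclusive"
  if (ni$noninferior) {
    verdict <- "noninferior"
    sup <- superiority_test(pd$d, cl)
    if (!sup$degenerate && sup$direction > 0 && sup$p_one_sided < alpha) {
      verdict <- "noninferior_and_superior"
    }
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(v)
  structure(list(
    metric = metric, level = level,
    ai_value = pd$ai_value, reader_value = pd$reader_value,
    difference = pd$difference, variance = v,
    ci_low = pd$difference - z * se, ci_high = pd$difference + z * se,
    margin = margin, alpha = alpha,
    p_noninferiority = ni$p_value,
    p_superiority = if (!is.null(sup)) sup$p_one_sided else NA_real_,
    verdict = verdict,
    n = pd$n, n_clusters = length(unique(cl))
  ), class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("%s-level %s: AI %.4f vs reader %.4f (diff %+.4f, 95%% CI %.4f..%.4f)\n",
              x$level, x$metric, x$ai_value, x$reader_value, x$difference,
              x$ci_low, x$ci_high))
  cat(sprintf("  noninferiority p = %.3g (margin %.2f); superiority p = %s; verdict: %s\n",
              x$p_noninferiority, x$margin,
              if (is.na(x$p_superiority)) "-" else sprintf("%.3g", x$p_superiority),
              x$verdict))
  cat(sprintf("  n = %d units in %d clusters\n", x$n, x$n_clusters))
  invisible(x)
}

#' Empirical size of the noninferiority test at the margin boundary
#'
#' Simulates cohorts of paired reader-clustered binary reads whose true
#' sensitivity difference sits exactly at `-margin` and reports the fraction
#' of cohorts in which the clustered Wald test (wrongly) declares
#' noninferiority. Each cohort draws a shared per-cluster accuracy
#' perturbation (inducing reader-cluster correlation) and a shared per-case
#' component (inducing within-pair concordance); both leave the marginal
#' sensitivities exact.
#'
#' @param n_sim Number of simulated cohorts.
#' @param n_cases Positive cases per cohort.
#' @param reader_sensitivity True comparator sensitivity.
#' @param margin Noninferiority margin; AI truth is
#'   `reader_sensitivity - margin`.
#' @param n_readers Reader clusters per cohort.
#' @param cluster_sd Half-width of the uniform per-cluster perturbation.
#' @param pair_concordance Probability that the two reads of a case share the
#'   same latent uniform draw.
#' @param alpha One-sided level.
#' @param seed RNG seed.
#' @return List: `rejection_rate`, `n_sim`, `mc_se`, `bound`
#'   (`alpha + 3 * mc_se`).
#' @export
boundary_type1_error <- function(n_sim = 2000, n_cases = 5000,
                                 reader_sensitivity = 0.54, margin = 0.05,
                                 n_readers = 20, cluster_sd = 0.06,
                                 pair_concordance = 0.4, alpha = 0.025,
                                 seed = 1L) {
  p_r <- reader_sensitivity
  p_a <- reader_sensitivity - margin
  with_rng_seed(seed, {
    rejections <- vapply(seq_len(n_sim), function(s) {
      cl <- sample.int(n_readers, n_cases, replace = TRUE)
      delta <- stats::runif(n_readers, -cluster_sd, cluster_sd)
      pa_i <- p_a + delta[cl]
      pr_i <- p_r + delta[cl]
      shared <- stats::runif(n_cases)
      mix <- stats::runif(n_cases) < pair_concordance
      ua <- ifelse(mix, shared, stats::runif(n_cases))
      ur <- ifelse(mix, shared, stats::runif(n_cases))
      d <- as.integer(ua < pa_i) - as.integer(ur < pr_i)
      v <- obuchowski_variance(d, cl)
      nt <- noninferiority_test(mean(d), v, margin = margin, alpha = alpha,
                                df = n_readers - 1)
      nt$noninferior
    }, NA)
    rate <- mean(rejections)
    mc_se <- sqrt(alpha * (1 - alpha) / n_sim)
    list(rejection_rate = rate, n_sim = n_sim, mc_se = mc_se,
         bound = alpha + 3 * mc_se)
  })
}
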