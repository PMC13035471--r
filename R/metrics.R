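#' Confusion counts at a given analysis level
#'
#' @param decisions Logical/0-1 vector of recall decisions.
#' @param labels 0/1 ground-truth labels aligned with `decisions`.
#' @param level Analysis level the units represent: `"case"`, `"breast"` or
#'   `"lesion"`.
#' @param ids Optional unit identifiers for both vectors; when given as a
#'   2-column list `list(decisions=, labels=)` they must match exactly.
#' @return A list of class `confusion_counts`: `tp`, `fp`, `tn`, `fn`, `n`,
#'   `level`.
#' @export
confusion_counts <- function(decisions, labels, level = c("case", "breast", "lesion"),
                             ids = NULL) {
  level <- match.arg(level)
  if (!is.null(ids)) {
    if (!identical(ids$decisions, ids$labels)) {
      stop("decision and label identifiers are not aligned")
    }
  }
  if (length(decisions) != length(labels)) {
    stop("decisions and labels differ in length")
  }
  d <- as.logical(decisions)
  y <- as.integer(labels)
  if (anyNA(d) || anyNA(y)) stop("decisions/labels contain missing values")
  structure(list(
    tp = sum(d & y == 1), fp = sum(d & y == 0),
    tn = sum(!d & y == 0), fn = sum(!d & y == 1),
    n = length(d), level = level
  ), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("%s-level confusion: TP=%d FP=%d TN=%d FN=%d (n=%d)\n",
              x$level, x$tp, x$fp, x$tn, x$fn, x$n))
  invisible(x)
}

#' Point accuracy metrics with confidence intervals
#'
#' Computes sensitivity, specificity, recall rate, cancer detection rate
#' (per 1,000 women), PPV and NPV from confusion counts. The CI method
#' follows the programme's policy (see [ci_policy()]): Wald intervals for
#' sensitivity/specificity/CDR/recall rate when the relevant denominator has
#' at least 50 units, percentile bootstrap otherwise and always for PPV/NPV.
#' Metrics with a zero denominator are reported as `NA` (undefined), never 0.
#'
#' @param counts A [confusion_counts()] object.
#' @param conf_level Confidence level (default 0.95).
#' @param cluster_variance Optional named list of cluster-robust variances
#'   (e.g. `list(sensitivity = v)`) replacing the binomial variance in the
#'   Wald interval, for reader-clustered decisions.
#' @param n_boot Bootstrap iterations for bootstrap CIs.
#' @param seed Seed for the bootstrap draws.
#' @return Data frame with `name`, `value`, `ci_low`, `ci_high`, `ci_method`,
#'   `n` (the denominator).
#' @export
point_metrics <- function(counts, conf_level = 0.95, cluster_variance = NULL,
                          n_boot = 10000, seed = 1L) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  total <- counts$n
  defs <- list(
    sensitivity = c(tp, tp + fn),
    specificity = c(tn, tn + fp),
    recall_rate = c(tp + fp, total),
    cdr         = c(tp, total),
    ppv         = c(tp, tp + fp),
    npv         = c(tn, tn + fn)
  )
  rows <- lapply(names(defs), function(nm) {
    num <- defs[[nm]][1]; den <- defs[[nm]][2]
    if (den == 0) {
      return(data.frame(name = nm, value = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, ci_method = "undefined", n = 0L))
    }
    p <- num / den
    method <- ci_policy(nm, den)
    if (method == "wald") {
      v <- cluster_variance[[nm]] %||% (p * (1 - p) / den)
      ci <- wald_ci_prop(p, den, conf_level, variance = v)
    } else {
      ci <- with_rng_seed(seed, {
        draws <- stats::rbinom(n_boot, den, p) / den
        stats::quantile(draws, c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2),
                        names = FALSE)
      })
    }
    scale <- if (nm == "cdr") 1000 else 1
    data.frame(name = nm, value = scale * p, ci_low = scale * ci[1],
               ci_high = scale * ci[2], ci_method = method, n = den)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' ROC curve and AUC
#'
#' Sweeps all observed score thresholds using the strict-exceed decision rule
#' (`score > threshold` means recall). The trapezoidal AUC equals the
#' Mann-Whitney rank statistic (probability that a random positive outranks a
#' random negative, ties counting one half).
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels; both classes must be present.
#' @return List of class `roc_curve`: `points` (threshold, sensitivity,
#'   specificity, fpr) ordered from the highest threshold down, and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  y <- as.integer(labels)
  if (length(scores) != length(y)) stop("scores and labels differ in length")
  if (anyNA(scores) || anyNA(y)) stop("scores/labels contain missing values")
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("ROC requires at least one positive and one negative unit")
  }
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  runs <- rle(ss)
  ends <- cumsum(runs$lengths)
  # units recalled at threshold uniq[k] (strict exceed) = ends[k - 1]
  cnt <- c(0, ends)
  cum_tp <- c(0, cumsum(ys)[ends])
  tpr <- cum_tp / n_pos
  fpr <- (cnt - cum_tp) / n_neg
  points <- data.frame(threshold = c(runs$values, -Inf), sensitivity = tpr,
                       specificity = 1 - fpr, fpr = fpr)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(points = points, auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d thresholds, AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' Intersection over union of two axis-aligned boxes
#'
#' Boxes are half-open rectangles `[x_min, x_max) x [y_min, y_max)` in pixel
#' coordinates. Disjoint boxes give 0; degenerate zero-area boxes give 0.
#'
#' @param box_a,box_b Named vectors/lists/one-row data frames with `x_min`,
#'   `y_min`, `x_max`, `y_max`.
#' @return IoU in `[0, 1]`.
#' @examples
#' box_iou(c(x_min = 0, y_min = 0, x_max = 10, y_max = 10),
#'         c(x_min = 5, y_min = 5, x_max = 15, y_max = 15))  # 25/175
#' @export
box_iou <- function(box_a, box_b) {
  a <- as.list(box_a); b <- as.list(box_b)
  for (bx in list(a, b)) {
    if (is.null(bx$x_min) || is.null(bx$x_max) || is.null(bx$y_min) || is.null(bx$y_max)) {
      stop("malformed box: needs x_min, y_min, x_max, y_max")
    }
    if (bx$x_min > bx$x_max || bx$y_min > bx$y_max) {
      stop("malformed box: min coordinate exceeds max")
    }
  }
  area <- function(bx) (bx$x_max - bx$x_min) * (bx$y_max - bx$y_min)
  iw <- max(0, min(a$x_max, b$x_max) - max(a$x_min, b$x_min))
  ih <- max(0, min(a$y_max, b$y_max) - max(a$y_min, b$y_min))
  inter <- iw * ih
  union <- area(a) + area(b) - inter
  if (union <= 0) return(0)
  inter / union
}

# Vectorised IoU between matched rows of two box tables.
iou_rows <- function(a, b) {
  iw <- pmax(0, pmin(a$x_max, b$x_max) - pmax(a$x_min, b$x_min))
  ih <- pmax(0, pmin(a$y_max, b$y_max) - pmax(a$y_min, b$y_min))
  inter <- iw * ih
  union <- (a$x_max - a$x_min) * (a$y_max - a$y_min) +
    (b$x_max - b$x_min) * (b$y_max - b$y_min) - inter
  ifelse(union <= 0, 0, inter / union)
}

#' Match AI regions of interest to annotated lesions
#'
#' A lesion is hit when some same-side ROI in at least one view overlaps it
#' with IoU strictly above `threshold`. For multifocal breasts the automated
#' rule counts the breast as hit when any focus is hit; overlaps with
#' `0 < IoU <= borderline` are additionally exported for external review,
#' replacing the clinical review of borderline matches with a pure-threshold
#' rule plus an audit trail.
#'
#' @param ai_rois ROI table (`episode_id`, `side`, `view`, box columns,
#'   `score`).
#' @param lesions Lesion table (`episode_id`, `lesion_id`, `side`, `view`,
#'   box columns, `focality`).
#' @param threshold IoU threshold (default 0.1, strict exceed).
#' @param borderline Upper IoU bound for the borderline export (default 0.30).
#' @param min_score Optional score threshold: only ROIs with score strictly
#'   above it participate (use the active operating point for deployment-time
#'   matching; default `-Inf` uses all candidate ROIs).
#' @return List with `lesion_hits` (one row per unique lesion: `lesion_id`,
#'   `episode_id`, `side`, `focality`, `hit`, `best_iou`), `breast_hits`
#'   (per episode-side: `hit` under the any-focus rule) and `borderline`
#'   (ROI-lesion pairs with IoU in `(0, borderline]`).
#' @export
lesion_match <- function(ai_rois, lesions, threshold = 0.1, borderline = 0.30,
                         min_score = -Inf) {
  rois <- ai_rois[ai_rois$score > min_score, , drop = FALSE]
  # candidate pairs: same episode, side and view
  key_l <- paste(lesions$episode_id, lesions$side, lesions$view)
  key_r <- paste(rois$episode_id, rois$side, rois$view)
  pair_ix <- lapply(seq_len(nrow(lesions)), function(i) which(key_r == key_l[i]))
  n_pairs <- lengths(pair_ix)
  li <- rep(seq_len(nrow(lesions)), n_pairs)
  ri <- unlist(pair_ix)

  iou <- if (length(li)) iou_rows(lesions[li, ], rois[ri, ]) else numeric(0)

  lesion_view <- data.frame(
    lesion_id = lesions$lesion_id, episode_id = lesions$episode_id,
    side = lesions$side, focality = lesions$focality,
    best_iou = 0, stringsAsFactors = FALSE
  )
  if (length(li)) {
    agg <- tapply(iou, li, max)
    lesion_view$best_iou[as.integer(names(agg))] <- as.numeric(agg)
  }
  # collapse views: a lesion is hit if matched in at least one view
  split_key <- lesion_view$lesion_id
  lesion_hits <- do.call(rbind, lapply(split(lesion_view, split_key), function(d) {
    data.frame(lesion_id = d$lesion_id[1], episode_id = d$episode_id[1],
               side = d$side[1], focality = d$focality[1],
               best_iou = max(d$best_iou),
               hit = any(d$best_iou > threshold),
               stringsAsFactors = FALSE)
  }))
  rownames(lesion_hits) <- NULL

  breast_key <- paste(lesion_hits$episode_id, lesion_hits$side)
  breast_hits <- do.call(rbind, lapply(split(lesion_hits, breast_key), function(d) {
    data.frame(episode_id = d$episode_id[1], side = d$side[1],
               n_foci = nrow(d), hit = any(d$hit), stringsAsFactors = FALSE)
  }))
  rownames(breast_hits) <- NULL

  border_sel <- which(iou > 0 & iou <= borderline)
  borderline_tab <- if (length(border_sel)) {
    data.frame(lesion_id = lesions$lesion_id[li[border_sel]],
               episode_id = lesions$episode_id[li[border_sel]],
               view = lesions$view[li[border_sel]],
               iou = iou[border_sel],
               roi_score = rois$score[ri[border_sel]],
               stringsAsFactors = FALSE)
  } else {
    data.frame(lesion_id = character(), episode_id = character(),
               view = character(), iou = numeric(), roi_score = numeric())
  }
  list(lesion_hits = lesion_hits, breast_hits = breast_hits,
       borderline = borderline_tab)
}

#' FROC curve: lesion sensitivity against false-positive marks per case
#'
#' Sweeps the ROI score threshold; at each threshold a unique lesion counts as
#' detected when matched ([lesion_match()] rule) by an ROI scoring strictly
#' above the threshold, and every above-threshold ROI not overlapping any
#' same-side/view lesion (IoU above the matching threshold) counts as a
#' false-positive mark. Lesion sensitivity is non-decreasing as the threshold
#' falls.
#'
#' @param ai_rois ROI table with scores.
#' @param lesions Lesion table.
#' @param n_cases Number of cases in the cohort (denominator for
#'   false-positive marks per case; includes non-cancer cases).
#' @param iou_threshold IoU matching threshold (default 0.1).
#' @return Data frame of class `froc_curve`: `threshold`,
#'   `lesion_sensitivity`, `fp_per_case`.
#' @export
froc_curve <- function(ai_rois, lesions, n_cases, iou_threshold = 0.1) {
  lesion_ids <- unique(lesions$lesion_id)
  n_lesions <- length(lesion_ids)
  if (n_lesions == 0) stop("no lesions to match")

  # per-ROI: does it match any lesion (same episode/side/view, IoU > thr)?
  key_l <- paste(lesions$episode_id, lesions$side, lesions$view)
  key_r <- paste(ai_rois$episode_id, ai_rois$side, ai_rois$view)
  pair_ix <- lapply(seq_len(nrow(lesions)), function(i) which(key_r == key_l[i]))
  li <- rep(seq_len(nrow(lesions)), lengths(pair_ix))
  ri <- unlist(pair_ix)
  iou <- if (length(li)) iou_rows(lesions[li, ], ai_rois[ri, ]) else numeric(0)
  match_pairs <- iou > iou_threshold

  roi_matches_any <- rep(FALSE, nrow(ai_rois))
  roi_matches_any[unique(ri[match_pairs])] <- TRUE

  # best (highest) ROI score that detects each unique lesion
  lesion_best_score <- rep(-Inf, n_lesions)
  if (any(match_pairs)) {
    det <- data.frame(lesion = lesions$lesion_id[li[match_pairs]],
                      score = ai_rois$score[ri[match_pairs]])
    agg <- tapply(det$score, det$lesion, max)
    lesion_best_score[match(names(agg), lesion_ids)] <- as.numeric(agg)
  }

  thresholds <- c(Inf, sort(unique(ai_rois$score), decreasing = TRUE), -Inf)
  points <- do.call(rbind, lapply(thresholds, function(t) {
    data.frame(
      threshold = t,
      lesion_sensitivity = sum(lesion_best_score > t) / n_lesions,
      fp_per_case = sum(!roi_matches_any & ai_rois$score > t) / n_cases
    )
  }))
  rownames(points) <- NULL
  class(points) <- c("froc_curve", "data.frame")
  points
}
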