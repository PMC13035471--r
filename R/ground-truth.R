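#' Derive case-level ground-truth labels under a follow-up window
#'
#' A case is labelled positive when a documented cancer falls within
#' `window_months` of the index screen (boundary inclusive: a diagnosis at
#' exactly the window edge counts). The retrospective definition uses 39
#' months, so screen-detected, interval and next-round cancers are all
#' positives; the within-episode definition uses 3 months, so only
#' screen-detected cancers count. Episodes with neither a cancer record nor a
#' confirmatory follow-up attendance are excluded with reason
#' `"no ground truth"`.
#'
#' @param episodes Episode table with `outcome` and `outcome_interval_months`.
#' @param window_months Follow-up window in months (default 39; use 3 for the
#'   within-episode definition).
#' @return A data frame of class `ground_truth` with one row per labelled
#'   episode: `episode_id`, `window_months`, `case_label` (0/1),
#'   `breast_label_right`, `breast_label_left`, `outcome_class` (the outcome
#'   as seen through the window: out-of-window cancers become `"normal"`),
#'   `risk_class` and `pathology`. Excluded episodes are recorded in the
#'   `"excluded"` attribute.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_women = 1000, seed = 1))
#' labels39 <- label_cases(cohort$episodes, window_months = 39)
#' table(labels39$outcome_class)
#' @export
label_cases <- function(episodes, window_months = 39) {
  req <- c("episode_id", "outcome", "outcome_interval_months")
  if (!all(req %in% names(episodes))) {
    stop("episodes must carry columns: ", paste(req, collapse = ", "))
  }
  is_cancer <- episodes$outcome != "normal"
  has_followup <- !is.na(episodes$outcome_interval_months) &
    episodes$outcome == "normal" &
    episodes$outcome_interval_months >= 24 & episodes$outcome_interval_months <= 39
  labellable <- is_cancer | has_followup
  excluded <- episodes$episode_id[!labellable]

  e <- episodes[labellable, , drop = FALSE]
  in_window <- e$outcome != "normal" & e$outcome_interval_months <= window_months
  case_label <- as.integer(in_window)
  outcome_class <- ifelse(in_window, e$outcome, "normal")

  side <- ifelse(in_window, e$lesion_side %||% "none", "none")
  pathology <- ifelse(in_window, e$pathology, "none")
  risk_class <- classify_risk(pathology)

  out <- data.frame(
    episode_id = e$episode_id,
    window_months = window_months,
    case_label = case_label,
    breast_label_right = as.integer(in_window & side == "right"),
    breast_label_left = as.integer(in_window & side == "left"),
    outcome_class = outcome_class,
    risk_class = risk_class,
    pathology = pathology,
    stringsAsFactors = FALSE
  )
  attr(out, "excluded") <- data.frame(
    episode_id = excluded,
    reason = rep("no ground truth", length(excluded)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("ground_truth", "data.frame")
  out
}

#' Classify cancer risk from pathology
#'
#' Higher-risk disease comprises all invasive cancers and high-grade in situ
#' cancers; lower-risk disease is low/intermediate-grade in situ cancer;
#' non-cancers map to `"none"`.
#'
#' @param pathology Character vector of pathology codes: `"invasive"`,
#'   `"dcis_high"`, `"dcis_low_intermediate"` or `"none"`.
#' @return Character vector over `{"higher", "lower", "none"}`.
#' @export
classify_risk <- function(pathology) {
  map <- c(invasive = "higher", dcis_high = "higher",
           dcis_low_intermediate = "lower", none = "none")
  bad <- setdiff(unique(pathology), names(map))
  if (length(bad)) {
    stop("unknown pathology code(s): ", paste(bad, collapse = ", "),
         "; accepted codes: ", paste(names(map), collapse = ", "))
  }
  unname(map[pathology])
}

#' Per-breast labels from lesion records
#'
#' A breast is positive when at least one in-window cancer lesion lies on that
#' side. Unilateral episodes contribute a single breast record, so the breast
#' count equals twice the case count minus the unilateral deficit.
#'
#' @param lesions Lesion table (`episode_id`, `side`).
#' @param episodes Episode table; columns `ai_breast_score_right/left` (when
#'   present) define which breasts were imaged.
#' @param labels Optional [label_cases()] output restricting lesions to
#'   in-window cancer episodes.
#' @return Data frame with one row per imaged breast: `episode_id`, `side`,
#'   `breast_label`.
#' @export
breast_labels_from_lesions <- function(lesions, episodes, labels = NULL) {
  has_right <- if ("ai_breast_score_right" %in% names(episodes)) {
    !is.na(episodes$ai_breast_score_right)
  } else rep(TRUE, nrow(episodes))
  has_left <- if ("ai_breast_score_left" %in% names(episodes)) {
    !is.na(episodes$ai_breast_score_left)
  } else rep(TRUE, nrow(episodes))

  if (!is.null(labels)) {
    pos_ids <- labels$episode_id[labels$case_label == 1]
    lesions <- lesions[lesions$episode_id %in% pos_ids, , drop = FALSE]
  }
  bad_side <- !lesions$side %in% c("right", "left")
  if (any(bad_side)) {
    stop("lesion rows with invalid side: ",
         paste(unique(lesions$side[bad_side]), collapse = ", "))
  }
  key <- paste(lesions$episode_id, lesions$side)
  # a lesion on a side that was not imaged is a data integrity error
  imaged_key <- c(paste(episodes$episode_id, "right")[has_right],
                  paste(episodes$episode_id, "left")[has_left])
  orphan <- setdiff(unique(key), imaged_key)
  if (length(orphan)) {
    stop("lesion references a breast absent from the episode table: ",
         paste(utils::head(orphan, 5), collapse = "; "))
  }

  out <- rbind(
    data.frame(episode_id = episodes$episode_id[has_right], side = "right",
               stringsAsFactors = FALSE),
    data.frame(episode_id = episodes$episode_id[has_left], side = "left",
               stringsAsFactors = FALSE)
  )
  out$breast_label <- as.integer(paste(out$episode_id, out$side) %in% key)
  out <- out[order(out$episode_id, out$side), , drop = FALSE]
  rownames(out) <- NULL
  out
}
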