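#' Apply study eligibility exclusions
#'
#' Filters episodes carrying any eligibility flag, attributing each excluded
#' episode to exactly one reason under a fixed precedence order:
#' technical recall > implants > missing views > extra views > mammogram size.
#'
#' @param episodes Episode table from [generate_cohort()] (or any table with
#'   logical `flag_*` columns).
#' @return A list with `included` (eligible episodes), `excluded` (the rest,
#'   with an `exclusion_reason` column) and `log`, a named count of exclusions
#'   per reason plus totals. `log` serialises cleanly to JSON.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_women = 1000, seed = 1))
#' excl <- apply_exclusions(cohort$episodes)
#' excl$log
#' @export
apply_exclusions <- function(episodes) {
  precedence <- c("technical_recall", "implants", "missing_views",
                  "extra_views", "size")
  cols <- paste0("flag_", precedence)
  missing_cols <- setdiff(cols, names(episodes))
  if (length(missing_cols)) {
    stop("episodes table lacks eligibility flag columns: ",
         paste(missing_cols, collapse = ", "))
  }
  flag_mat <- as.matrix(episodes[, cols, drop = FALSE])
  any_flag <- rowSums(flag_mat) > 0
  reason <- rep(NA_character_, nrow(episodes))
  # first TRUE column in precedence order
  first_ix <- apply(flag_mat, 1L, function(r) match(TRUE, r))
  reason[any_flag] <- precedence[first_ix[any_flag]]

  excluded <- episodes[any_flag, , drop = FALSE]
  if (nrow(excluded)) excluded$exclusion_reason <- reason[any_flag]

  counts <- stats::setNames(
    vapply(precedence, function(r) sum(reason == r, na.rm = TRUE), 0L),
    precedence
  )
  log <- list(
    n_total = nrow(episodes),
    n_included = sum(!any_flag),
    n_excluded = sum(any_flag),
    inclusion_fraction = if (nrow(episodes)) sum(!any_flag) / nrow(episodes) else NA_real_,
    by_reason = as.list(counts)
  )
  list(included = episodes[!any_flag, , drop = FALSE],
       excluded = excluded,
       log = log)
}

#' Inject a device-conditional AI score distribution shift
#'
#' Perturbs the AI scores of one device stratum on the logit scale, leaving
#' every other stratum untouched. Emulates the distribution shift seen when a
#' newer device model enters service, which raises the recall rate at a fixed
#' operating point in that stratum only.
#'
#' @param episodes Episode table.
#' @param shift_spec A list with `stratum` (a level of `manufacturer_model`)
#'   and `logit_shift` (additive shift applied to `qlogis(score)`).
#' @return The episode table with shifted `ai_score`, `ai_breast_score_*` and
#'   recomputed `ai_recall` for the targeted stratum. A zero shift returns the
#'   input unchanged.
#' @export
inject_distribution_shift <- function(episodes, shift_spec) {
  if (!is.list(shift_spec) || is.null(shift_spec$stratum) ||
      is.null(shift_spec$logit_shift)) {
    stop("shift_spec must be list(stratum=, logit_shift=)")
  }
  if (!shift_spec$stratum %in% episodes$manufacturer_model) {
    stop("unknown device stratum: ", shift_spec$stratum)
  }
  delta <- shift_spec$logit_shift
  if (delta == 0) return(episodes)

  sel <- episodes$manufacturer_model == shift_spec$stratum
  bump <- function(s) ifelse(is.na(s), s, stats::plogis(stats::qlogis(s) + delta))
  for (col in c("ai_score", "ai_breast_score_right", "ai_breast_score_left")) {
    episodes[[col]][sel] <- bump(episodes[[col]][sel])
  }
  if ("ai_recall" %in% names(episodes) && "ai_score" %in% names(episodes)) {
    # recall decisions at the generator's operating point must track the score
    op <- attr(episodes, "operating_point") %||% 0.5
    episodes$ai_recall[sel] <- episodes$ai_score[sel] > op
  }
  episodes
}
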