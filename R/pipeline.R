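#' Run the full evaluation pipeline
#'
#' Orchestrates generation (optional), eligibility exclusions, ground-truth
#' labelling under one or more follow-up windows, case-level accuracy
#' metrics, clustered paired inference against the first reader with
#' Holm-Bonferroni control over the primary family, subgroup fairness and
#' calibration auditing, workflow-arm simulation, and operating-point
#' monitoring. Every artifact is written to `out_dir` as CSV/JSON with a
#' provenance block (config digest and seed), and numeric outputs are
#' reproducible byte-for-byte under a fixed seed.
#'
#' @param config A named list (or path to a YAML file) with elements:
#'   `cohort` (arguments to [cohort_config()]), `windows` (follow-up windows
#'   in months, default `c(39, 3)`), `workflow` (arguments to
#'   [workflow_config()]), `fairness_attributes`, `out_dir`, `seed`.
#' @return Invisibly, a list with the in-memory results of every stage:
#'   `cohort`, `exclusions`, `labels` (one per window), `metrics`,
#'   `comparisons`, `multiplicity`, `fairness`, `calibration`, `workflow`,
#'   `monitoring`, `paths`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out_dir %||% tempfile("screeneval_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  windows <- config$windows %||% c(39, 3)

  failed <- function(stage, err) {
    manifest <- list(stage = stage, message = conditionMessage(err),
                     time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
    write_json_report(manifest, file.path(out_dir, "failure_manifest.json"))
    stop(sprintf("pipeline stage `%s` failed: %s", stage, conditionMessage(err)),
         call. = FALSE)
  }
  stage <- function(name, expr) {
    message(sprintf("[%s] stage: %s", format(Sys.time(), "%H:%M:%S"), name))
    tryCatch(expr, error = function(e) failed(name, e))
  }

  # provenance: config written first, digested, stamped into every report
  cohort_args <- config$cohort %||% list()
  cohort_args$seed <- cohort_args$seed %||% seed
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(list(cohort = cohort_args, windows = windows,
                        seed = seed), cfg_path)
  config_digest <- unname(tools::md5sum(cfg_path))
  provenance <- list(config_digest = config_digest, seed = seed)

  results <- list()
  results$cohort <- stage("generate", {
    cc <- do.call(cohort_config, cohort_args)
    generate_cohort(cc)
  })
  op <- list(threshold = results$cohort$config$operating_point)

  results$exclusions <- stage("exclusions", apply_exclusions(results$cohort$episodes))
  included <- results$exclusions$included

  results$labels <- stage("labels", {
    labs <- lapply(windows, function(w) label_cases(included, w))
    names(labs) <- paste0("window_", windows)
    labs
  })
  primary_labels <- results$labels[[1]]

  results$metrics <- stage("metrics", {
    lapply(results$labels, function(lab) {
      e <- included[match(lab$episode_id, included$episode_id), ]
      y <- lab$case_label
      lapply(list(ai = e$ai_score > op$threshold,
                  reader1 = as.logical(e$reader1_recall),
                  consensus = as.logical(e$consensus_recall)),
             function(dec) point_metrics(confusion_counts(dec, y, "case"), seed = seed))
    })
  })

  results$comparisons <- stage("inference", {
    ids <- primary_labels$episode_id
    e <- included[match(ids, included$episode_id), ]
    y <- primary_labels$case_label
    ai <- e$ai_score > op$threshold
    list(
      sensitivity = compare_readers(ai, e$reader1_recall, y, e$reader1_id,
                                    metric = "sensitivity"),
      specificity = compare_readers(ai, e$reader1_recall, y, e$reader1_id,
                                    metric = "specificity")
    )
  })
  results$multiplicity <- stage("multiplicity", {
    p <- vapply(results$comparisons, function(x) x$p_noninferiority, 0)
    cbind(endpoint = names(results$comparisons), holm_bonferroni(p, alpha = 0.025))
  })

  results$fairness <- stage("fairness", {
    subgroup_report(included, primary_labels,
                    attributes = config$fairness_attributes %||%
                      c("age_band", "imd_decile", "ethnicity", "density_quartile",
                        "manufacturer_model", "screen_type"),
                    op = op)
  })
  results$calibration <- stage("calibration", {
    ids <- primary_labels$episode_id
    e <- included[match(ids, included$episode_id), ]
    calibration_curves(e$ai_score, primary_labels$case_label,
                       groups = e$ethnicity)
  })

  results$workflow <- stage("workflow", {
    wf_args <- config$workflow %||% list()
    wf_args$seed <- wf_args$seed %||% seed
    wf <- do.call(workflow_config, wf_args)
    human <- run_arm(included, primary_labels, "human_double", wf, op = op$threshold)
    with_ai <- run_arm(included, primary_labels, "human_plus_ai", wf, op = op$threshold)
    list(human_double = human, human_plus_ai = with_ai,
         comparison = compare_arms(with_ai, human),
         overlap = detection_overlap(attr(with_ai, "decisions"),
                                     attr(human, "decisions"), primary_labels))
  })

  results$monitoring <- stage("monitoring", {
    snap <- monitor_window(included, op)
    list(snapshot = snap, weekly = weekly_series(included, op, primary_labels))
  })

  stage("write", {
    w <- function(df, f) utils::write.csv(df, file.path(out_dir, f), row.names = FALSE)
    w(results$cohort$episodes, "episodes.csv")
    w(results$cohort$lesions, "lesions.csv")
    w(results$cohort$rois, "rois.csv")
    write_json_report(c(results$exclusions$log, provenance),
                      file.path(out_dir, "exclusion_log.json"))
    for (nm in names(results$labels)) w(results$labels[[nm]], paste0("labels_", nm, ".csv"))
    metrics_tab <- do.call(rbind, lapply(names(results$metrics), function(win) {
      do.call(rbind, lapply(names(results$metrics[[win]]), function(nm) {
        cbind(window = win, reader = nm, results$metrics[[win]][[nm]])
      }))
    }))
    w(metrics_tab, "metrics.csv")
    comp_tab <- do.call(rbind, lapply(results$comparisons, function(x) {
      data.frame(metric = x$metric, level = x$level, difference = x$difference,
                 ci_low = x$ci_low, ci_high = x$ci_high,
                 p_noninferiority = x$p_noninferiority,
                 p_superiority = x$p_superiority, verdict = x$verdict,
                 n = x$n, n_clusters = x$n_clusters)
    }))
    w(comp_tab, "comparisons.csv")
    w(results$multiplicity, "multiplicity.csv")
    w(results$fairness, "fairness.csv")
    w(results$calibration, "calibration.csv")
    w(results$monitoring$weekly, "weekly_series.csv")
    wf_json <- list(
      human_double = unclass(results$workflow$human_double),
      human_plus_ai = unclass(results$workflow$human_plus_ai),
      provenance = provenance
    )
    wf_json$human_double <- wf_json$human_double[!vapply(wf_json$human_double, is.data.frame, NA)]
    wf_json$human_plus_ai <- wf_json$human_plus_ai[!vapply(wf_json$human_plus_ai, is.data.frame, NA)]
    write_json_report(wf_json, file.path(out_dir, "workflow.json"))
    w(results$workflow$comparison, "workflow_comparison.csv")
    w(results$workflow$overlap, "detection_overlap.csv")
    write_json_report(list(snapshot = unclass(results$monitoring$snapshot),
                           provenance = provenance),
                      file.path(out_dir, "monitoring.json"))
  })

  results$paths <- list(out_dir = out_dir, config = cfg_path)
  results$provenance <- provenance
  invisible(results)
}

#' Validate episode, lesion and ROI tables
#'
#' Schema, range and join-integrity checks distinguishing hard errors (which
#' make downstream analyses unsound: missing required columns, ages outside
#' the screening range, malformed boxes, scores outside `[0, 1]`, lesion or
#' ROI rows referencing unknown episodes) from warnings (unknown demographic
#' codes, which are mapped to the explicit `"missing"` level).
#'
#' @param episodes Episode table (required).
#' @param lesions,rois Optional lesion and ROI tables.
#' @return List with `report` (data frame: `severity`, `check`, `detail`,
#'   `n`), `ok` (no hard errors) and `episodes` (with unknown demographic
#'   codes remapped).
#' @export
validate_tables <- function(episodes, lesions = NULL, rois = NULL) {
  report <- list()
  note <- function(severity, check, detail, n = 1L) {
    report[[length(report) + 1L]] <<- data.frame(
      severity = severity, check = check, detail = detail, n = n,
      stringsAsFactors = FALSE)
  }

  required <- c("episode_id", "reader1_recall", "reader2_recall", "ai_score",
                "outcome", "outcome_interval_months")
  miss <- setdiff(required, names(episodes))
  if (length(miss)) {
    note("error", "schema", paste("missing episode columns:",
                                  paste(miss, collapse = ", ")))
  }
  if ("age" %in% names(episodes)) {
    bad <- which(!is.na(episodes$age) & (episodes$age < 0))
    if (length(bad)) note("error", "range",
                          sprintf("negative age (rows %s)",
                                  paste(utils::head(bad, 5), collapse = ",")),
                          length(bad))
    off <- which(!is.na(episodes$age) & episodes$age >= 0 &
                   (episodes$age < 50 | episodes$age > 70))
    if (length(off)) note("warning", "range",
                          "age outside routine screening range 50-70", length(off))
  }
  if ("ai_score" %in% names(episodes)) {
    bad <- which(!is.na(episodes$ai_score) &
                   (episodes$ai_score < 0 | episodes$ai_score > 1))
    if (length(bad)) note("error", "range", "ai_score outside [0, 1]", length(bad))
  }
  if ("ethnicity" %in% names(episodes)) {
    known <- c("white", "asian", "black", "mixed", "other", "missing")
    bad <- which(!is.na(episodes$ethnicity) & !episodes$ethnicity %in% known)
    if (length(bad)) {
      note("warning", "codes",
           sprintf("unknown ethnicity code(s) %s mapped to 'missing'",
                   paste(unique(episodes$ethnicity[bad]), collapse = ", ")),
           length(bad))
      episodes$ethnicity[bad] <- "missing"
    }
  }
  if ("episode_id" %in% names(episodes) && anyDuplicated(episodes$episode_id)) {
    note("error", "keys", "duplicate episode identifiers")
  }

  check_boxes <- function(tab, what) {
    box_cols <- c("x_min", "y_min", "x_max", "y_max")
    if (!all(box_cols %in% names(tab))) {
      note("error", "schema", sprintf("%s table lacks box columns", what))
      return()
    }
    bad <- which(tab$x_min > tab$x_max | tab$y_min > tab$y_max |
                   tab$x_min < 0 | tab$y_min < 0)
    if (length(bad)) note("error", "range",
                          sprintf("malformed %s boxes", what), length(bad))
    if ("episode_id" %in% names(episodes)) {
      orphan <- which(!tab$episode_id %in% episodes$episode_id)
      if (length(orphan)) note("error", "join",
                               sprintf("%s rows reference unknown episodes", what),
                               length(orphan))
    }
  }
  if (!is.null(lesions)) check_boxes(lesions, "lesion")
  if (!is.null(rois)) {
    check_boxes(rois, "roi")
    if ("score" %in% names(rois)) {
      bad <- which(rois$score < 0 | rois$score > 1)
      if (length(bad)) note("error", "range", "roi score outside [0, 1]", length(bad))
    }
  }

  rep_df <- if (length(report)) do.call(rbind, report) else
    data.frame(severity = character(), check = character(),
               detail = character(), n = integer())
  list(report = rep_df, ok = !any(rep_df$severity == "error"),
       episodes = episodes)
}
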