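# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_rng_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

config_error <- function(field, msg) {
  stop(structure(
    class = c("screeneval_config_error", "error", "condition"),
    list(message = sprintf("invalid configuration field `%s`: %s", field, msg),
         call = sys.call(-1))
  ))
}

check_proportion <- function(x, field, allow_na = FALSE) {
  if (allow_na && all(is.na(x))) return(invisible(x))
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    config_error(field, "must be a proportion in [0, 1]")
  }
  invisible(x)
}

check_mix <- function(x, field, tol = 1e-9) {
  check_proportion(x, field)
  if (abs(sum(x) - 1) > tol) {
    config_error(field, sprintf("must sum to 1 (got %.12f)", sum(x)))
  }
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    config_error(field, "must be a named vector of level proportions")
  }
  invisible(x)
}

check_positive_int <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 1 || x != floor(x)) {
    config_error(field, "must be a positive integer")
  }
  invisible(as.integer(x))
}

# Draw categorical levels for n units from a named proportion vector.
draw_levels <- function(n, mix) {
  sample(names(mix), n, replace = TRUE, prob = mix)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Wald interval for a proportion, optionally cluster-robust.
wald_ci_prop <- function(p, n, conf_level = 0.95, variance = NULL) {
  if (n == 0 || is.na(p)) return(c(NA_real_, NA_real_))
  v <- if (is.null(variance)) p * (1 - p) / n else variance
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  half <- z * sqrt(v)
  c(max(0, p - half), min(1, p + half))
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  invisible(path)
}
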