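test_that("paired differences count successes on the right subset", {
  lab <- c(rep(1, 10), rep(0, 10))
  ai <- c(rep(TRUE, 6), rep(FALSE, 4), rep(TRUE, 10))
  rd <- c(rep(TRUE, 4), rep(FALSE, 6), rep(FALSE, 10))
  expect_equal(paired_difference(ai, ai, lab, "positives")$difference, 0)
  expect_equal(paired_difference(ai, rd, lab, "positives")$difference, 0.2)
  # AI recalls every negative while the reader clears them all
  expect_equal(paired_difference(ai, rd, lab, "negatives")$difference, -1)
  expect_error(paired_difference(ai, rd, rep(1, 20), "negatives"), "empty")
})

test_that("Obuchowski variance reduces to the classical paired variance for singleton clusters", {
  set.seed(4)
  for (i in 1:10) {
    n <- sample(30:200, 1)
    d <- sample(c(-1L, 0L, 1L), n, replace = TRUE, prob = c(0.2, 0.6, 0.2))
    v <- obuchowski_variance(d, seq_len(n))
    expect_equal(v, stats::var(d) / n, tolerance = 1e-12)
    # closed form: (b + c - n D^2) / (n (n-1))
    b <- sum(d == 1); cc <- sum(d == -1); D <- mean(d)
    expect_equal(v, (b + cc - n * D^2) / (n * (n - 1)), tolerance = 1e-12)
  }
  expect_equal(obuchowski_variance(rep(0, 50), rep(1:5, 10)), 0)
  expect_error(obuchowski_variance(c(1, 0), c("a", "a")), "2 clusters")
})

test_that("the cluster-robust variance agrees with a cluster-resampling oracle", {
  set.seed(8)
  n_cl <- 60
  sizes <- sample(5:20, n_cl, replace = TRUE)
  cl_eff <- stats::rnorm(n_cl, 0, 0.15)
  cl <- rep(seq_len(n_cl), sizes)
  p <- pmin(pmax(0.3 + cl_eff[cl], 0.05), 0.95)
  d <- as.integer(stats::runif(length(cl)) < p) -
    as.integer(stats::runif(length(cl)) < p)
  v_est <- obuchowski_variance(d, cl)

  # brute-force cluster bootstrap of the mean difference
  spl <- split(d, cl)
  sums <- vapply(spl, sum, 0); ns <- lengths(spl)
  boot <- replicate(10000, {
    take <- sample.int(n_cl, n_cl, replace = TRUE)
    sum(sums[take]) / sum(ns[take])
  })
  v_boot <- stats::var(boot)
  expect_gt(v_est / v_boot, 0.7)
  expect_lt(v_est / v_boot, 1.4)
})

test_that("noninferiority Wald test behaves at and around the margin", {
  # difference exactly at -margin: z = 0, p = 0.5
  nt <- noninferiority_test(-0.05, 1e-4, margin = 0.05)
  expect_equal(nt$z, 0)
  expect_equal(nt$p_value, 0.5)
  expect_false(nt$noninferior)

  # zero difference with tiny variance: noninferior at any positive margin
  expect_true(noninferiority_test(0, 1e-8, margin = 0.001)$noninferior)

  # the small specificity deficit pattern at large n is noninferior
  v <- 0.001^2
  expect_true(noninferiority_test(-0.009, v, margin = 0.05)$noninferior)

  # monotonicity: p falls as the margin grows
  ps <- vapply(c(0.01, 0.03, 0.05, 0.08),
               function(m) noninferiority_test(-0.02, 1e-3, margin = m)$p_value, 0)
  expect_true(all(diff(ps) < 0))

  expect_error(noninferiority_test(0, 1e-4, margin = 0), "positive")
})

test_that("clustered McNemar reduces to the classical statistic for singleton clusters", {
  d <- c(rep(1L, 10), rep(-1L, 2), rep(0L, 30))
  st <- superiority_test(d, seq_along(d))
  expect_equal(st$statistic, 16 / 3, tolerance = 1e-12)
  expect_equal(st$p_two_sided, stats::pchisq(16 / 3, 1, lower.tail = FALSE))
  expect_equal(st$direction, 1)

  # b = c: direction-free, p = 1
  d2 <- c(rep(1L, 5), rep(-1L, 5), rep(0L, 10))
  st2 <- superiority_test(d2, seq_along(d2))
  expect_equal(st2$p_two_sided, 1)
  expect_equal(st2$p_one_sided, 1)

  # no discordant pairs: flagged, p = 1
  st3 <- superiority_test(rep(0L, 20), seq_len(20))
  expect_true(st3$degenerate)
  expect_equal(st3$p_one_sided, 1)

  set.seed(12)
  for (i in 1:10) {
    n <- sample(40:120, 1)
    d <- sample(c(-1L, 0L, 1L), n, replace = TRUE)
    if (sum(d != 0) == 0) next
    b <- sum(d == 1); cc <- sum(d == -1)
    expect_equal(superiority_test(d, seq_len(n))$statistic,
                 (b - cc)^2 / (b + cc), tolerance = 1e-12)
  }
})

test_that("Holm-Bonferroni step-down matches hand-worked cases", {
  one <- holm_bonferroni(0.04, alpha = 0.05)
  expect_equal(one$p_adjusted, 0.04)
  expect_true(one$reject)

  both <- holm_bonferroni(c(0.01, 0.04), alpha = 0.05)
  expect_true(all(both$reject))

  neither <- holm_bonferroni(c(0.03, 0.04), alpha = 0.05)
  expect_false(any(neither$reject))

  # rejections are a superset of plain Bonferroni's
  set.seed(3)
  p <- stats::runif(8, 0, 0.2)
  holm_rej <- holm_bonferroni(p, alpha = 0.05)$reject
  bonf_rej <- p.adjust(p, "bonferroni") <= 0.05
  expect_true(all(!bonf_rej | holm_rej))
})

test_that("case-level bootstrap CIs are reproducible and degenerate correctly", {
  dat <- data.frame(episode_id = rep(1:50, each = 2), x = rep(3, 100))
  b <- bootstrap_ci(function(d) mean(d$x), dat, n_iter = 200, seed = 5)
  expect_equal(b$ci_low, 3)
  expect_equal(b$ci_high, 3)

  set.seed(1)
  dat2 <- data.frame(episode_id = 1:80, x = stats::rnorm(80))
  b1 <- bootstrap_ci(function(d) mean(d$x), dat2, n_iter = 500, seed = 7)
  b2 <- bootstrap_ci(function(d) mean(d$x), dat2, n_iter = 500, seed = 7)
  expect_identical(b1[c("ci_low", "ci_high")], b2[c("ci_low", "ci_high")])
  expect_lt(b1$ci_low, mean(dat2$x))
  expect_gt(b1$ci_high, mean(dat2$x))

  # statistics undefined on too many resamples error out with a diagnostic
  expect_error(
    bootstrap_ci(function(d) if (any(d$episode_id == 1)) NA_real_ else 1,
                 dat2, n_iter = 100, seed = 2),
    "undefined")
})

test_that("cluster-size ceiling splits deterministically and caps sizes", {
  cl <- c(rep("A", 25), rep("B", 5))
  out <- split_clusters(cl, max_cluster_size = 10)
  expect_true(all(table(out) <= 10))
  expect_equal(length(unique(out[1:25])), 3L)
  expect_identical(out, split_clusters(cl, max_cluster_size = 10))
  expect_identical(unique(out[26:30]), "B")
})

test_that("the comparison cascade gates superiority on noninferiority", {
  set.seed(21)
  n <- 4000
  lab <- c(rep(1, 800), rep(0, n - 800))
  cl <- sample(sprintf("R%02d", 1:15), n, replace = TRUE)
  reader <- ifelse(lab == 1, stats::runif(n) < 0.44, stats::runif(n) < 0.05)
  ai <- ifelse(lab == 1, stats::runif(n) < 0.58, stats::runif(n) < 0.05)

  cmp <- compare_readers(ai, reader, lab, cl, metric = "sensitivity")
  expect_equal(cmp$verdict, "noninferior_and_superior")
  expect_false(is.na(cmp$p_superiority))
  expect_true(cmp$ci_low <= cmp$difference && cmp$difference <= cmp$ci_high)

  # a clearly inferior AI is inconclusive and superiority is never attempted
  ai_bad <- ifelse(lab == 1, stats::runif(n) < 0.20, stats::runif(n) < 0.05)
  cmp2 <- compare_readers(ai_bad, reader, lab, cl, metric = "sensitivity")
  expect_equal(cmp2$verdict, "inconclusive")
  expect_true(is.na(cmp2$p_superiority))
})
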