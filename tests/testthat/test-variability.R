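# exhaustive-scan reference for the sequential correlation filter
bf_corr_filter <- function(m, thr) {
  keep <- integer(0)
  for (j in seq_len(ncol(m))) {
    drop <- FALSE
    for (k in keep) if (cor(m[, j], m[, k])^2 >= thr) { drop <- TRUE; break }
    if (!drop) keep <- c(keep, j)
  }
  keep
}

test_that("correlation filter removes later duplicates, matches exhaustive scan", {
  set.seed(1)
  m <- matrix(rnorm(50 * 6), 50, 6)
  m[, 4] <- m[, 2]  # exact duplicate, later position
  colnames(m) <- paste0("LV_firstorder_F", 1:6)
  out <- correlation_filter(m, 0.9)
  expect_false("LV_firstorder_F4" %in% colnames(out))
  expect_true("LV_firstorder_F2" %in% colnames(out))

  # independent columns at large n: nothing removed
  big <- matrix(rnorm(2000 * 8), 2000, 8)
  colnames(big) <- paste0("LV_firstorder_G", 1:8)
  expect_identical(ncol(correlation_filter(big, 0.9)), 8L)

  # randomized instances vs the exhaustive oracle
  for (rep in 1:30) {
    p <- sample(3:10, 1)
    base <- matrix(rnorm(40 * p), 40, p)
    for (j in seq_len(p)) if (runif(1) < 0.4 && j > 1)
      base[, j] <- base[, sample(j - 1, 1)] + rnorm(40, 0, runif(1, 0, 0.5))
    colnames(base) <- paste0("LV_firstorder_H", seq_len(p))
    thr <- runif(1, 0.5, 0.99)
    expect_identical(colnames(correlation_filter(base, thr)),
                     colnames(base)[bf_corr_filter(base, thr)])
  }

  # zero-variance column removed with warning
  m[, 5] <- 3
  expect_warning(out <- correlation_filter(m, 0.9),
                 class = "radharm_degenerate")
  expect_false("LV_firstorder_F5" %in% colnames(out))
})

test_that("JSD analytic cases: identity, disjoint support, hand-computed half", {
  x <- rnorm(300)
  expect_equal(jsd(x, x), 0, tolerance = 1e-9)
  expect_equal(jsd(runif(500, 0, 1), runif(500, 10, 11)), 1, tolerance = 1e-6)
  # p = (1/2, 1/2, 0), q = (0, 1/2, 1/2): both KL terms are 1/2
  expect_equal(jsd_hist(c(.5, .5, 0), c(0, .5, .5)), 0.5, tolerance = 1e-12)
  expect_warning(z <- jsd(rep(1, 5), rep(1, 7)), class = "radharm_degenerate")
  expect_equal(z, 0)
  expect_error(jsd(numeric(0), x), class = "radharm_bad_input")
})

test_that("JSD is symmetric and bounded on random histogram pairs", {
  set.seed(2)
  for (rep in 1:200) {
    k <- sample(2:30, 1)
    p <- rgamma(k, 0.5); q <- rgamma(k, 0.5)
    if (sum(p) == 0) p[1] <- 1
    if (sum(q) == 0) q[1] <- 1
    v1 <- jsd_hist(p, q); v2 <- jsd_hist(q, p)
    expect_equal(v1, v2, tolerance = 1e-12)
    expect_gte(v1, 0); expect_lte(v1, 1 + 1e-12)
  }
  # sample-level symmetry
  a <- rnorm(100); b <- rnorm(120, 1)
  expect_equal(jsd(a, b), jsd(b, a))
})

test_that("centre-pair records cover all pairs and detect shifts monotonically", {
  set.seed(3)
  n_c <- 5; n_per <- 12
  centres <- rep(paste0("C", 1:n_c), each = n_per)
  m <- matrix(rnorm(length(centres) * 2), length(centres), 2)
  colnames(m) <- c("LV_firstorder_A", "MYO_glcm_B")
  ft <- feature_table(m, data.frame(
    subject_id = seq_along(centres), centre = centres,
    pathology = "healthy", phase = "ED"))
  recs <- centre_pair_jsd(ft)
  expect_identical(nrow(recs), as.integer(choose(n_c, 2) * 2))

  # duplicated centre: JSD exactly 0 for that pair
  m2 <- m; m2[centres == "C2", ] <- m[centres == "C1", ]
  recs2 <- centre_pair_jsd(feature_table(m2, ft$row_meta))
  pair12 <- recs2$centre_a == "C1" & recs2$centre_b == "C2"
  expect_true(all(recs2$jsd[pair12] < 1e-9))

  # increasing location shift raises the pairwise JSD monotonically
  jsds <- vapply(c(0.5, 1.5, 3, 6), function(s) {
    m3 <- m; m3[centres == "C1", ] <- m[centres == "C1", ] + s
    r <- centre_pair_jsd(feature_table(m3, ft$row_meta), bins = 20)
    mean(r$jsd[r$centre_a == "C1" | r$centre_b == "C1"])
  }, 0)
  expect_true(all(diff(jsds) > 0))
})

test_that("summary thresholds behave at the boundary and flag dissimilarity", {
  recs <- data.frame(
    feature = rep(c("LV_firstorder_A", "LV_firstorder_B"), each = 2),
    roi = "LV", family = "firstorder", order = "first", phase = "ED",
    centre_a = c("C1", "C1"), centre_b = c("C2", "C3"),
    jsd = c(0.009, 0.012, 0.0, 0.0), stringsAsFactors = FALSE
  )
  rep1 <- summarise_variability(recs, tau = 0.01)
  # per (pair, roi) cell: C1-C2 has {0.009, 0} -> 100%, C1-C3 {0.012, 0} -> 50%
  expect_equal(sort(unname(
    tapply(rep1$below_tau$pct_below_mean, rep1$below_tau$order, mean))), 75)
  expect_equal(summarise_variability(recs, tau = 0)$below_tau$pct_below_mean, 0)
  all0 <- recs; all0$jsd <- 0
  expect_equal(summarise_variability(all0, tau = 0.01)$below_tau$pct_below_mean,
               100)
})

test_that("variability summaries are invariant to subject row order", {
  set.seed(4)
  centres <- rep(c("C1", "C2", "C3"), each = 10)
  m <- matrix(rnorm(30 * 4), 30, 4)
  colnames(m) <- c("LV_firstorder_A", "LV_glcm_B", "MYO_firstorder_C",
                   "MYO_glszm_D")
  rm_ <- data.frame(subject_id = 1:30, centre = centres,
                    pathology = "healthy", phase = "ED")
  r1 <- variability_analysis(feature_table(m, rm_), tau = 0.02)
  perm <- sample(30)
  r2 <- variability_analysis(feature_table(m[perm, ], rm_[perm, ]),
                             tau = 0.02)
  expect_equal(r1$below_tau, r2$below_tau)
  expect_equal(r1$family_table, r2$family_table)
})

test_that("group comparisons use the right test and Bonferroni level", {
  res <- compare_methods(c(1, 2, 3), c(1, 2, 3))
  expect_identical(res$test, "mann-whitney")
  expect_gt(res$p_value, 0.9)

  res <- compare_methods(c(1, 2), c(3, 4))
  expect_identical(unname(res$statistic), 0)  # complete separation, U = 0

  res <- compare_methods(rnorm(10), rnorm(10), rnorm(10))
  expect_identical(res$test, "kruskal-wallis")

  res <- compare_methods(c(1, 2), c(3, 4), alpha = 0.01, m_comparisons = 5)
  expect_equal(res$alpha_adjusted, 0.002)
  expect_error(compare_methods(numeric(0), 1:3), class = "radharm_bad_input")
})
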