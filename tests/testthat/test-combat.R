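# small Gaussian multi-batch feature tables with injected location/scale
# batch effects, used throughout
sim_batch_table <- function(n_per_batch = 40, n_feat = 20, shift = 0,
                            scale = 1, n_batch = 3, seed = 1) {
  set.seed(seed)
  batches <- rep(paste0("B", seq_len(n_batch)), each = n_per_batch)
  m <- matrix(rnorm(length(batches) * n_feat), length(batches), n_feat)
  shifts <- c(0, rep_len(shift, n_batch - 1))
  scales <- c(1, rep_len(scale, n_batch - 1))
  for (b in seq_len(n_batch)) {
    rows <- batches == paste0("B", b)
    m[rows, ] <- m[rows, ] * scales[b] + shifts[b]
  }
  colnames(m) <- paste0("LV_firstorder_F", seq_len(n_feat))
  feature_table(m, data.frame(
    subject_id = sprintf("S%03d", seq_along(batches)), centre = batches,
    pathology = "healthy", phase = "ED", stringsAsFactors = FALSE
  ), data.frame(name = colnames(m), roi = "LV", family = "firstorder",
                feature = paste0("F", seq_len(n_feat)), order = "first",
                stringsAsFactors = FALSE))
}

test_that("quantile Gaussianisation is rank-preserving and batch-wise", {
  ft <- sim_batch_table(shift = 3, scale = 2, seed = 2)
  qg <- quantile_gaussianise(ft)
  for (b in unique(ft$row_meta$centre)) {
    rows <- ft$row_meta$centre == b
    for (j in c(1, 5)) {
      expect_equal(cor(ft$matrix[rows, j], qg$matrix[rows, j],
                       method = "spearman"), 1)
    }
  }
  # two batches with identical values map identically
  m <- ft$matrix
  m[ft$row_meta$centre == "B2", ] <- m[ft$row_meta$centre == "B1", ]
  ft2 <- feature_table(m, ft$row_meta, ft$col_meta)
  qg2 <- quantile_gaussianise(ft2)
  expect_equal(qg2$matrix[ft$row_meta$centre == "B2", ],
               qg2$matrix[ft$row_meta$centre == "B1", ],
               ignore_attr = TRUE)
})

test_that("gaussianised output approximates the source normal at large n", {
  set.seed(3)
  n <- 500
  m <- matrix(rnorm(2 * n), 2 * n, 1)
  colnames(m) <- "LV_firstorder_F1"
  ft <- feature_table(m, data.frame(
    subject_id = sprintf("S%03d", 1:(2 * n)),
    centre = rep(c("A", "B"), each = n),
    pathology = "healthy", phase = "ED"))
  qg <- quantile_gaussianise(ft, K = 20)
  ks <- suppressWarnings(ks.test(qg$matrix[, 1], m[, 1]))$statistic
  expect_lt(unname(ks), 0.08)
  expect_error(quantile_gaussianise(
    feature_table(m[c(1, 2), , drop = FALSE], ft$row_meta[c(1, 2), ]),
    by = "subject_id"), class = "radharm_small_batch")
})

test_that("ComBat needs >= 2 batches and recovers injected shifts", {
  ft <- sim_batch_table()
  one <- feature_table(ft$matrix[ft$row_meta$centre == "B1", ],
                       ft$row_meta[ft$row_meta$centre == "B1", ])
  expect_error(fit_combat(one), class = "radharm_small_batch")

  # identically distributed batches: gamma* ~ 0, delta* ~ 1
  ft0 <- sim_batch_table(n_per_batch = 150, n_feat = 30, seed = 4)
  m0 <- fit_combat(ft0)
  expect_lt(max(abs(m0$gamma_star)), 0.35)
  expect_lt(max(abs(m0$delta2_star - 1)), 0.4)
  adj0 <- apply_combat(ft0, m0)
  expect_equal(adj0$matrix, ft0$matrix, tolerance = 0.5)

  # known shift is recovered by the naive estimates
  delta <- 1.5
  fts <- sim_batch_table(n_per_batch = 200, n_feat = 30, shift = delta,
                         n_batch = 2, seed = 5)
  ms <- fit_combat(fts)
  sd_all <- apply(fts$matrix, 2, sd)
  est <- (ms$gamma_hat["B2", ] - ms$gamma_hat["B1", ]) * sd_all
  expect_equal(mean(est), delta, tolerance = 0.1)
})

test_that("adjustment equalises batch means and is idempotent in gamma", {
  fts <- sim_batch_table(n_per_batch = 120, n_feat = 30, shift = 2,
                         scale = 1.6, seed = 6)
  model <- fit_combat(fts)
  adj <- apply_combat(fts, model)
  for (j in 1:5) {
    means <- tapply(adj$matrix[, j], adj$row_meta$centre, mean)
    expect_lt(diff(range(means)), 0.2)
  }
  refit <- fit_combat(adj)
  expect_lt(max(abs(refit$gamma_star)), 0.05)

  unseen <- fts
  unseen$row_meta$centre[1] <- "NEW"
  expect_error(apply_combat(feature_table(unseen$matrix, unseen$row_meta,
                                          unseen$col_meta), model),
               class = "radharm_unseen_batch")
})

test_that("EB shrinkage pulls batch effects toward the prior mean", {
  fts <- sim_batch_table(n_per_batch = 25, n_feat = 40, shift = 0.8, seed = 7)
  model <- fit_combat(fts)
  for (b in model$batches) {
    centred_hat <- abs(model$gamma_hat[b, ] - model$gamma_bar[b])
    centred_star <- abs(model$gamma_star[b, ] - model$gamma_bar[b])
    expect_true(all(centred_star <= centred_hat + 1e-8))
  }
})

test_that("zero-variance features pass through with a warning", {
  ft <- sim_batch_table(seed = 8)
  m <- ft$matrix
  m[, 3] <- 7
  ft2 <- feature_table(m, ft$row_meta, ft$col_meta)
  expect_warning(model <- fit_combat(ft2), class = "radharm_degenerate")
  adj <- apply_combat(ft2, model)
  expect_equal(unname(adj$matrix[, 3]), rep(7, nrow(m)))
})

test_that("harmonisation agrees with the reference ComBat on effect removal", {
  skip_if_not_installed("sva")
  fts <- sim_batch_table(n_per_batch = 200, n_feat = 25, shift = 1.5,
                         scale = 1.5, seed = 9)
  ours <- apply_combat(fts, fit_combat(fts))
  theirs <- t(sva::ComBat(dat = t(fts$matrix), batch = fts$row_meta$centre,
                          par.prior = TRUE, prior.plots = FALSE))
  # mean over features of the spread of per-batch means
  gap <- function(m) mean(vapply(seq_len(ncol(m)), function(j)
    diff(range(tapply(m[, j], fts$row_meta$centre, mean))), 0))
  raw_gap <- gap(fts$matrix)
  expect_lt(gap(ours$matrix), raw_gap * 0.15)
  expect_lt(gap(theirs), raw_gap * 0.15)
  # the two variants standardise differently but agree closely overall
  expect_gt(cor(as.vector(ours$matrix), as.vector(theirs)), 0.98)
})
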