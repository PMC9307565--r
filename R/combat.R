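#' Per-batch quantile Gaussianisation of a feature table
#'
#' Within every batch (centre) and feature independently, values are mapped
#' through the batch's empirical quantile function onto the standard normal
#' quantile function evaluated on a K-point probability grid, with linear
#' interpolation between grid quantiles and rank-midpoint handling of ties.
#' The map is monotone, so within-batch ranks are preserved. This enforces
#' the per-batch normality that the downstream location/scale harmonisation
#' model assumes.
#'
#' @param table a [feature_table].
#' @param K number of quantiles (default 20).
#' @param by row-metadata column defining batches (default `"centre"`).
#' @return A [feature_table] of transformed values.
#' @export
quantile_gaussianise <- function(table, K = 20L, by = "centre") {
  batches <- table$row_meta[[by]]
  sizes <- table(batches)
  if (any(sizes < 2))
    rh_abort(paste("batch of size 1:",
                   paste(names(sizes)[sizes < 2], collapse = ", ")),
             "radharm_small_batch")
  probs <- seq(0, 1, length.out = K)
  zgrid <- stats::qnorm(pmin(pmax(probs, 1e-7), 1 - 1e-7))
  m <- table$matrix
  out <- m
  for (b in unique(batches)) {
    rows <- which(batches == b)
    for (jcol in seq_len(ncol(m))) {
      x <- m[rows, jcol]
      q <- stats::quantile(x, probs, names = FALSE, type = 7)
      keep <- !duplicated(q)
      qx <- q[keep]
      zy <- vapply(split(zgrid, match(q, qx)), mean, 0)
      out[rows, jcol] <- if (length(qx) == 1L)
        rep(0, length(x)) else stats::approx(qx, zy, xout = x, rule = 2)$y
    }
  }
  feature_table(out, table$row_meta, table$col_meta)
}

#' Fit a ComBat harmonisation model
#'
#' Parametric empirical-Bayes location/scale batch-effect model with no
#' covariates, aligned to a virtual reference: each feature is standardised
#' by its grand mean and pooled standard deviation over all subjects (no
#' batch is privileged), per-batch location (`gamma`) and scale (`delta^2`)
#' effects are estimated on the standardised scale, and shrunk towards
#' normal / inverse-gamma priors whose hyperparameters are estimated across
#' features by the method of moments, using the standard iterative
#' conditional update.
#'
#' @param table a [feature_table]; quantile-Gaussianised input recommended
#'   (see [quantile_gaussianise()]).
#' @param by row-metadata column defining batches (default `"centre"`).
#' @param tol convergence tolerance on the maximum parameter change
#'   (default `1e-4`).
#' @param max_iter iteration cap (default 500).
#' @return A `combat_model`.
#' @export
fit_combat <- function(table, by = "centre", tol = 1e-4, max_iter = 500L) {
  batches <- as.character(table$row_meta[[by]])
  blevels <- unique(batches)
  if (length(blevels) < 2L)
    rh_abort("ComBat requires at least 2 batches", "radharm_small_batch")
  m <- table$matrix
  p <- ncol(m)
  alpha <- colMeans(m)
  sigma <- apply(m, 2, stats::sd)
  degenerate <- sigma == 0 | !is.finite(sigma)
  if (any(degenerate)) {
    rh_warn(sprintf("%d zero-variance feature(s) passed through unharmonised",
                    sum(degenerate)), "radharm_degenerate")
    sigma[degenerate] <- 1
  }
  z <- sweep(sweep(m, 2, alpha, "-"), 2, sigma, "/")

  gamma_hat <- matrix(NA_real_, length(blevels), p,
                      dimnames = list(blevels, colnames(m)))
  delta2_hat <- gamma_hat
  n_i <- stats::setNames(integer(length(blevels)), blevels)
  for (b in blevels) {
    rows <- batches == b
    n_i[b] <- sum(rows)
    if (n_i[b] < 2L)
      rh_abort(paste("batch of size 1:", b), "radharm_small_batch")
    gamma_hat[b, ] <- colMeans(z[rows, , drop = FALSE])
    delta2_hat[b, ] <- apply(z[rows, , drop = FALSE], 2, stats::var)
  }

  # method-of-moments EB hyperparameters, per batch across features
  gamma_bar <- rowMeans(gamma_hat)
  tau2 <- apply(gamma_hat, 1, stats::var)
  aprior <- function(d) { mb <- mean(d); s2 <- stats::var(d); (2 * s2 + mb^2) / s2 }
  bprior <- function(d) { mb <- mean(d); s2 <- stats::var(d); (mb * s2 + mb^3) / s2 }
  lambda <- apply(delta2_hat, 1, aprior)
  theta <- apply(delta2_hat, 1, bprior)

  gamma_star <- gamma_hat
  delta2_star <- delta2_hat
  for (b in blevels) {
    rows <- batches == b
    zb <- z[rows, , drop = FALSE]
    g <- gamma_hat[b, ]
    d2 <- delta2_hat[b, ]
    n <- n_i[b]
    for (it in seq_len(max_iter)) {
      g_new <- (n * tau2[b] * gamma_hat[b, ] + d2 * gamma_bar[b]) /
        (n * tau2[b] + d2)
      ss <- colSums(sweep(zb, 2, g_new, "-")^2)
      d2_new <- (theta[b] + 0.5 * ss) / (n / 2 + lambda[b] - 1)
      change <- max(abs(g_new - g), abs(d2_new - d2))
      g <- g_new; d2 <- d2_new
      if (change < tol) break
    }
    gamma_star[b, ] <- g
    delta2_star[b, ] <- d2
  }
  gamma_star[, degenerate] <- 0
  delta2_star[, degenerate] <- 1

  structure(
    list(alpha = alpha, sigma = sigma,
         gamma_hat = gamma_hat, delta2_hat = delta2_hat,
         gamma_star = gamma_star, delta2_star = delta2_star,
         gamma_bar = gamma_bar, tau2 = tau2, lambda = lambda, theta = theta,
         batches = blevels, n_per_batch = n_i, by = by,
         degenerate = degenerate),
    class = "combat_model"
  )
}

#' @export
print.combat_model <- function(x, ...) {
  cat(sprintf("<combat_model> %d features, %d batches (%s)\n",
              length(x$alpha), length(x$batches),
              paste(x$batches, collapse = ", ")))
  cat(sprintf("  |gamma*| mean %.3f, delta*^2 range [%.3f, %.3f]\n",
              mean(abs(x$gamma_star)), min(x$delta2_star), max(x$delta2_star)))
  invisible(x)
}

#' Apply a fitted ComBat model
#'
#' `y* = sigma * (z - gamma*) / delta* + alpha`, with `z` the virtual-
#' reference standardised value and the batch's shrunk effects.
#'
#' @param table a [feature_table] whose batches all appear in the model.
#' @param model a `combat_model` from [fit_combat()].
#' @return Harmonised [feature_table], same dimensions.
#' @export
apply_combat <- function(table, model) {
  batches <- as.character(table$row_meta[[model$by]])
  unseen <- setdiff(unique(batches), model$batches)
  if (length(unseen))
    rh_abort(paste("batch not in model:", paste(unseen, collapse = ", ")),
             "radharm_unseen_batch")
  z <- sweep(sweep(table$matrix, 2, model$alpha, "-"), 2, model$sigma, "/")
  out <- z
  for (b in unique(batches)) {
    rows <- batches == b
    adj <- sweep(z[rows, , drop = FALSE], 2, model$gamma_star[b, ], "-")
    adj <- sweep(adj, 2, sqrt(model$delta2_star[b, ]), "/")
    out[rows, ] <- adj
  }
  out <- sweep(sweep(out, 2, model$sigma, "*"), 2, model$alpha, "+")
  if (any(model$degenerate))
    out[, model$degenerate] <- table$matrix[, model$degenerate]
  feature_table(out, table$row_meta, table$col_meta)
}

#' Quantile-Gaussianise and ComBat-harmonise in one step
#'
#' @param table a [feature_table].
#' @param K number of quantiles for the Gaussianisation.
#' @param by batch column.
#' @return List with elements `table` (harmonised [feature_table]) and
#'   `model` (the fitted `combat_model`).
#' @export
harmonise_features <- function(table, K = 20L, by = "centre") {
  qg <- quantile_gaussianise(table, K = K, by = by)
  model <- fit_combat(qg, by = by)
  list(table = apply_combat(qg, model), model = model)
}
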