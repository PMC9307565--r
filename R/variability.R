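#' Sequential correlation-based feature filter
#'
#' Greedy scan in the table's (canonical) column order: feature `j` is
#' removed iff its squared Pearson correlation with some retained earlier
#' feature reaches the threshold. Zero-variance columns have undefined
#' correlation and are removed with a warning.
#'
#' @param table a [feature_table] (or plain numeric matrix).
#' @param r2_threshold removal threshold on the squared correlation,
#'   in (0, 1]; default 0.9.
#' @param rows optional row subset (e.g. healthy subjects only) on which
#'   correlations are computed; the returned table keeps all rows.
#' @return The filtered [feature_table] (or matrix) with attribute
#'   `"removed"` listing dropped column names.
#' @export
correlation_filter <- function(table, r2_threshold = 0.9, rows = NULL) {
  stopifnot(r2_threshold > 0, r2_threshold <= 1)
  m <- if (inherits(table, "feature_table")) table$matrix else as.matrix(table)
  fitm <- if (is.null(rows)) m else m[rows, , drop = FALSE]
  p <- ncol(m)
  keep <- logical(p)
  sds <- apply(fitm, 2, stats::sd)
  for (j in seq_len(p)) {
    if (!is.finite(sds[j]) || sds[j] == 0) {
      rh_warn(paste("zero-variance feature removed:", colnames(m)[j]),
              "radharm_degenerate")
      next
    }
    ks <- which(keep)
    if (length(ks)) {
      r2 <- stats::cor(fitm[, j], fitm[, ks, drop = FALSE])^2
      if (any(r2 >= r2_threshold, na.rm = TRUE)) next
    }
    keep[j] <- TRUE
  }
  removed <- colnames(m)[!keep]
  out <- if (inherits(table, "feature_table")) {
    feature_table(m[, keep, drop = FALSE], table$row_meta,
                  table$col_meta[keep, , drop = FALSE])
  } else m[, keep, drop = FALSE]
  attr(out, "removed") <- removed
  out
}

#' Jensen-Shannon divergence between two intensity samples
#'
#' Histograms are built on shared equal-width bins spanning the pooled range
#' (bin count: the larger of 10 and the Freedman-Diaconis rule on the pooled
#' sample), normalised, smoothed additively by `eps`, and compared with
#' `JSD = KL(p, m)/2 + KL(q, m)/2`, `m = (p + q)/2`, logarithms base 2, so
#' the result lies in `[0, 1]`: 0 for identical histograms, 1 for disjoint
#' supports.
#'
#' @param p_samples,q_samples numeric sample vectors (non-empty).
#' @param bins number of shared bins; `NULL` for the automatic rule.
#' @param eps additive smoothing mass per bin (default `1e-10`).
#' @return JSD in `[0, 1]` (base 2).
#' @export
jsd <- function(p_samples, q_samples, bins = NULL, eps = 1e-10) {
  if (!length(p_samples) || !length(q_samples))
    rh_abort("both samples must be non-empty", "radharm_bad_input")
  pooled <- c(p_samples, q_samples)
  rng <- range(pooled)
  if (rng[1] == rng[2]) {
    rh_warn("degenerate shared support: JSD set to 0", "radharm_degenerate")
    return(0)
  }
  if (is.null(bins)) bins <- max(10L, grDevices::nclass.FD(pooled))
  edges <- seq(rng[1], rng[2], length.out = bins + 1L)
  h <- function(x) {
    cnt <- tabulate(pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE),
                              1L), bins), nbins = bins)
    w <- cnt / sum(cnt) + eps
    w / sum(w)
  }
  jsd_hist(h(p_samples), h(q_samples))
}

#' Jensen-Shannon divergence between two histograms
#'
#' @param p,q non-negative vectors of equal length; normalised internally.
#' @return Base-2 JSD in `[0, 1]`.
#' @export
jsd_hist <- function(p, q) {
  stopifnot(length(p) == length(q), all(p >= 0), all(q >= 0))
  p <- p / sum(p)
  q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / b[nz]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

#' Per-feature, per-centre-pair JSD records
#'
#' For every feature column and unordered centre pair, the JSD between the
#' two centres' per-subject feature distributions. Only healthy subjects are
#' used by default (the pathological group could carry uncontrolled
#' sub-structure). Centres contributing fewer than `min_n` subjects to a
#' pair are skipped with a warning.
#'
#' @param table a [feature_table], already correlation-filtered.
#' @param healthy_only logical, default `TRUE`.
#' @param bins,eps passed to [jsd()].
#' @param min_n minimum subjects per centre (default 2).
#' @return data.frame with columns `feature`, `roi`, `family`, `order`,
#'   `phase`, `centre_a`, `centre_b`, `jsd`.
#' @export
centre_pair_jsd <- function(table, healthy_only = TRUE, bins = NULL,
                            eps = 1e-10, min_n = 2L) {
  rm_ <- table$row_meta
  rows <- if (healthy_only) rm_$pathology == "healthy" else rep(TRUE, nrow(rm_))
  centres <- sort(unique(rm_$centre[rows]))
  if (length(centres) < 2L)
    rh_abort("need at least 2 centres", "radharm_bad_input")
  pairs <- utils::combn(centres, 2)
  recs <- list()
  for (ph in unique(rm_$phase)) {
    for (k in seq_len(ncol(pairs))) {
      a <- pairs[1, k]; b <- pairs[2, k]
      ra <- rows & rm_$centre == a & rm_$phase == ph
      rb <- rows & rm_$centre == b & rm_$phase == ph
      if (sum(ra) < min_n || sum(rb) < min_n) {
        rh_warn(sprintf("pair %s-%s (%s) skipped: too few subjects", a, b, ph),
                "radharm_small_batch")
        next
      }
      vals <- vapply(seq_len(ncol(table$matrix)), function(jcol)
        suppressWarnings(jsd(table$matrix[ra, jcol], table$matrix[rb, jcol],
                             bins = bins, eps = eps)),
        0)
      recs[[length(recs) + 1L]] <- data.frame(
        feature = table$col_meta$name, roi = table$col_meta$roi,
        family = table$col_meta$family, order = table$col_meta$order,
        phase = ph, centre_a = a, centre_b = b, jsd = vals,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, recs)
}

#' Summarise JSD records into a variability report
#'
#' For each (order, phase): the percentage of features with `JSD < tau`,
#' computed per (centre pair, ROI) cell and then averaged (mean and SD over
#' cells). Per (family, phase): mean and SD of the JSD values. Features
#' whose JSD standard deviation across centre pairs exceeds `sd_flag` in
#' every phase are flagged as most-dissimilar.
#'
#' @param records data.frame from [centre_pair_jsd()].
#' @param tau similarity threshold (default 0.01; strict inequality).
#' @param sd_flag flagging threshold on the per-feature JSD SD (default 0.01).
#' @return A `variability_report`: list with `below_tau` (per order x phase),
#'   `family_table` (per family x phase), `dissimilar` (flagged features),
#'   `records`, `tau`.
#' @export
summarise_variability <- function(records, tau = 0.01, sd_flag = 0.01) {
  if (!nrow(records)) rh_abort("no JSD records", "radharm_bad_input")
  below <- do.call(rbind, lapply(split(records,
                                       records[c("order", "phase")], drop = TRUE),
    function(df) {
      cells <- split(df, interaction(df$centre_a, df$centre_b, df$roi,
                                     drop = TRUE))
      pct <- vapply(cells, function(cc) 100 * mean(cc$jsd < tau), 0)
      data.frame(order = df$order[1], phase = df$phase[1],
                 pct_below_mean = mean(pct), pct_below_sd = stats::sd(pct),
                 n_cells = length(pct), stringsAsFactors = FALSE)
    }))
  rownames(below) <- NULL
  fam <- do.call(rbind, lapply(split(records,
                                     records[c("family", "phase")], drop = TRUE),
    function(df) data.frame(
      family = df$family[1], phase = df$phase[1],
      jsd_mean = mean(df$jsd), jsd_sd = stats::sd(df$jsd),
      stringsAsFactors = FALSE
    )))
  rownames(fam) <- NULL
  per_feat <- split(records, list(records$feature, records$phase), drop = TRUE)
  sds <- vapply(per_feat, function(df) stats::sd(df$jsd), 0)
  feat_names <- vapply(per_feat, function(df) df$feature[1], "")
  flagged <- tapply(sds > sd_flag, feat_names, all)
  dissimilar <- sort(names(flagged)[flagged])
  structure(
    list(below_tau = below, family_table = fam, dissimilar = dissimilar,
         records = records, tau = tau),
    class = "variability_report"
  )
}

#' @export
print.variability_report <- function(x, ...) {
  cat(sprintf("<variability_report> tau = %g, %d JSD records\n",
              x$tau, nrow(x$records)))
  cat("% features below tau (mean over centre pairs x ROI):\n")
  print(x$below_tau, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Full variability analysis of a feature table
#'
#' Applies the sequential correlation filter independently within each
#' (ROI, phase, order) feature block — fitted on healthy subjects — then
#' computes per-centre-pair JSD records for the retained features and
#' summarises them.
#'
#' @param table a [feature_table].
#' @param tau JSD similarity threshold (default 0.01).
#' @param r2_threshold correlation-filter threshold (default 0.9).
#' @param healthy_only use healthy subjects only (default `TRUE`).
#' @param bins,eps passed to [jsd()].
#' @return A `variability_report` with an extra `n_retained` table.
#' @export
variability_analysis <- function(table, tau = 0.01, r2_threshold = 0.9,
                                 healthy_only = TRUE, bins = NULL,
                                 eps = 1e-10) {
  rm_ <- table$row_meta
  healthy <- if (healthy_only) rm_$pathology == "healthy" else
    rep(TRUE, nrow(rm_))
  recs <- list()
  retained <- list()
  for (ph in unique(rm_$phase)) {
    rows_fit <- healthy & rm_$phase == ph
    for (r in unique(table$col_meta$roi)) {
      for (ord in unique(table$col_meta$order)) {
        block <- ft_subset(table, roi = r, order = ord)
        filt <- suppressWarnings(
          correlation_filter(block, r2_threshold, rows = rows_fit))
        sub <- ft_subset(filt, rows = rm_$phase == ph)
        retained[[length(retained) + 1L]] <- data.frame(
          roi = r, order = ord, phase = ph,
          n_retained = ncol(filt$matrix), stringsAsFactors = FALSE)
        if (!ncol(filt$matrix)) next
        recs[[length(recs) + 1L]] <-
          centre_pair_jsd(sub, healthy_only = healthy_only,
                          bins = bins, eps = eps)
      }
    }
  }
  rep <- summarise_variability(do.call(rbind, recs), tau = tau)
  rep$n_retained <- do.call(rbind, retained)
  rep
}

#' Nonparametric group comparison with Bonferroni-corrected level
#'
#' Two groups: two-sided Mann-Whitney U (Wilcoxon rank-sum); three or more:
#' Kruskal-Wallis. The significance level `alpha` is Bonferroni-divided by
#' `m_comparisons`.
#'
#' @param ... two or more numeric vectors, or a single list of them.
#' @param alpha nominal level (default 0.01).
#' @param m_comparisons number of comparisons in the family (default 1).
#' @return List with `test`, `statistic`, `p_value`, `alpha_adjusted`,
#'   `significant`.
#' @export
compare_methods <- function(..., alpha = 0.01, m_comparisons = 1L) {
  groups <- list(...)
  if (length(groups) == 1L && is.list(groups[[1]])) groups <- groups[[1]]
  if (length(groups) < 2L) rh_abort("need >= 2 groups", "radharm_bad_input")
  if (any(!lengths(groups))) rh_abort("empty group", "radharm_bad_input")
  if (length(groups) == 2L) {
    ht <- suppressWarnings(stats::wilcox.test(groups[[1]], groups[[2]],
                                              alternative = "two.sided"))
    test <- "mann-whitney"
  } else {
    ht <- stats::kruskal.test(groups)
    test <- "kruskal-wallis"
  }
  alpha_adj <- alpha / m_comparisons
  list(test = test, statistic = unname(ht$statistic),
       p_value = ht$p.value, alpha_adjusted = alpha_adj,
       significant = ht$p.value < alpha_adj)
}
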