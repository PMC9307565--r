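# Feature panels follow the reference radiomics taxonomy: 18 first-order
# features plus 24 GLCM, 16 GLRLM, 16 GLSZM and 14 GLDM features per ROI
# (88 texture features; shape features are deliberately excluded).

.eps <- 2.2e-16

#' First-order (histogram) features
#'
#' Moments, order statistics and energies are computed on the raw in-ROI
#' intensities; entropy and uniformity on the fixed-bin-width discretised
#' histogram. Skewness and kurtosis use population moments (kurtosis is not
#' excess-corrected); both are 0 for constant input.
#'
#' @param d a `discretised_roi` from [discretise_roi()] (carries both raw
#'   values and levels).
#' @return Named numeric vector of 18 features.
#' @export
first_order_features <- function(d) {
  x <- d$raw
  n <- length(x)
  p <- tabulate(d$levels[d$levels > 0L], nbins = d$Ng) / n
  m <- mean(x)
  m2 <- mean((x - m)^2)
  q <- stats::quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE, type = 7)
  mid <- x[x >= q[1] & x <= q[5]]
  vol <- prod(d$spacing)
  c(
    `10Percentile` = q[1],
    `90Percentile` = q[5],
    Energy = sum(x^2),
    Entropy = -sum(p * log2(p + .eps)),
    InterquartileRange = q[4] - q[2],
    Kurtosis = if (m2 > 0) mean((x - m)^4) / m2^2 else 0,
    Maximum = max(x),
    Mean = m,
    MeanAbsoluteDeviation = mean(abs(x - m)),
    Median = q[3],
    Minimum = min(x),
    Range = max(x) - min(x),
    RobustMeanAbsoluteDeviation =
      if (length(mid)) mean(abs(mid - mean(mid))) else 0,
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = if (m2 > 0) mean((x - m)^3) / m2^1.5 else 0,
    TotalEnergy = vol * sum(x^2),
    Uniformity = sum(p^2),
    Variance = m2
  )
}

glcm_features <- function(tm) {
  stopifnot(tm$kind == "GLCM")
  P <- tm$matrix
  tot <- sum(P)
  if (tot == 0) rh_abort("empty GLCM", "radharm_empty_matrix")
  p <- P / tot
  ng <- nrow(p)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(p); py <- colSums(p)
  ux <- sum(seq_len(ng) * px); uy <- sum(seq_len(ng) * py)
  sx <- sqrt(sum((seq_len(ng) - ux)^2 * px))
  sy <- sqrt(sum((seq_len(ng) - uy)^2 * py))
  # diagonal and cross-diagonal marginals
  kd <- seq_len(2 * ng)                      # i + j in 2..2Ng
  pxy_sum <- vapply(kd, function(k) sum(p[i + j == k]), 0)
  ks <- 0:(ng - 1)                           # |i - j|
  pxy_diff <- vapply(ks, function(k) sum(p[abs(i - j) == k]), 0)
  da <- sum(ks * pxy_diff)
  hx <- -sum(px * log2(px + .eps))
  hy <- -sum(py * log2(py + .eps))
  hxy <- -sum(p * log2(p + .eps))
  pp <- outer(px, py)
  hxy1 <- -sum(p * log2(pp + .eps))
  hxy2 <- -sum(pp * log2(pp + .eps))
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy))))
  mcc <- if (ng == 1L) 1 else {
    # Q_ij = sum_k p_ik p_jk / (px_i py_k); MCC is the square root of Q's
    # second largest eigenvalue
    Q <- (p %*% diag(1 / pmax(py, .eps), ng)) %*% t(p) /
      pmax(matrix(px, ng, ng), .eps)
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(pmax(0, ev[2]))
  }
  corr <- if (sx * sy > 0) (sum(p * i * j) - ux * uy) / (sx * sy) else 1
  c(
    Autocorrelation = sum(p * i * j),
    ClusterProminence = sum(p * (i + j - ux - uy)^4),
    ClusterShade = sum(p * (i + j - ux - uy)^3),
    ClusterTendency = sum(p * (i + j - ux - uy)^2),
    Contrast = sum(p * (i - j)^2),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(pxy_diff * log2(pxy_diff + .eps)),
    DifferenceVariance = sum((ks - da)^2 * pxy_diff),
    Id = sum(p / (1 + abs(i - j))),
    Idm = sum(p / (1 + (i - j)^2)),
    Idmn = sum(p / (1 + (i - j)^2 / ng^2)),
    Idn = sum(p / (1 + abs(i - j) / ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = sum(p[i != j] / (i - j)[i != j]^2),
    JointAverage = ux,
    JointEnergy = sum(p^2),
    JointEntropy = hxy,
    MCC = mcc,
    MaximumProbability = max(p),
    SumAverage = sum(kd * pxy_sum),
    SumEntropy = -sum(pxy_sum * log2(pxy_sum + .eps)),
    SumSquares = sum(p * (i - ux)^2)
  )
}

glrlm_features <- function(tm) {
  stopifnot(tm$kind == "GLRLM")
  P <- tm$matrix
  nr <- sum(P)
  if (nr == 0) rh_abort("empty GLRLM", "radharm_empty_matrix")
  ng <- nrow(P); nl <- ncol(P)
  i <- matrix(seq_len(ng), ng, nl)
  j <- matrix(seq_len(nl), ng, nl, byrow = TRUE)
  p <- P / nr
  mu_i <- sum(p * i); mu_j <- sum(p * j)
  nd <- if (!is.null(tm$n_directions)) tm$n_directions else 1L
  c(
    GrayLevelNonUniformity = sum(rowSums(P)^2) / nr,
    GrayLevelNonUniformityNormalized = sum(rowSums(P)^2) / nr^2,
    GrayLevelVariance = sum(p * (i - mu_i)^2),
    HighGrayLevelRunEmphasis = sum(P * i^2) / nr,
    LongRunEmphasis = sum(P * j^2) / nr,
    LongRunHighGrayLevelEmphasis = sum(P * i^2 * j^2) / nr,
    LongRunLowGrayLevelEmphasis = sum(P * j^2 / i^2) / nr,
    LowGrayLevelRunEmphasis = sum(P / i^2) / nr,
    RunEntropy = -sum(p * log2(p + .eps)),
    RunLengthNonUniformity = sum(colSums(P)^2) / nr,
    RunLengthNonUniformityNormalized = sum(colSums(P)^2) / nr^2,
    RunPercentage = nr / (tm$n_voxels * nd),
    RunVariance = sum(p * (j - mu_j)^2),
    ShortRunEmphasis = sum(P / j^2) / nr,
    ShortRunHighGrayLevelEmphasis = sum(P * i^2 / j^2) / nr,
    ShortRunLowGrayLevelEmphasis = sum(P / (i^2 * j^2)) / nr
  )
}

glszm_features <- function(tm) {
  stopifnot(tm$kind == "GLSZM")
  P <- tm$matrix
  nz <- sum(P)
  if (nz == 0) rh_abort("empty GLSZM", "radharm_empty_matrix")
  ng <- nrow(P); ns <- ncol(P)
  i <- matrix(seq_len(ng), ng, ns)
  j <- matrix(seq_len(ns), ng, ns, byrow = TRUE)
  p <- P / nz
  mu_i <- sum(p * i); mu_j <- sum(p * j)
  c(
    GrayLevelNonUniformity = sum(rowSums(P)^2) / nz,
    GrayLevelNonUniformityNormalized = sum(rowSums(P)^2) / nz^2,
    GrayLevelVariance = sum(p * (i - mu_i)^2),
    HighGrayLevelZoneEmphasis = sum(P * i^2) / nz,
    LargeAreaEmphasis = sum(P * j^2) / nz,
    LargeAreaHighGrayLevelEmphasis = sum(P * i^2 * j^2) / nz,
    LargeAreaLowGrayLevelEmphasis = sum(P * j^2 / i^2) / nz,
    LowGrayLevelZoneEmphasis = sum(P / i^2) / nz,
    SizeZoneNonUniformity = sum(colSums(P)^2) / nz,
    SizeZoneNonUniformityNormalized = sum(colSums(P)^2) / nz^2,
    SmallAreaEmphasis = sum(P / j^2) / nz,
    SmallAreaHighGrayLevelEmphasis = sum(P * i^2 / j^2) / nz,
    SmallAreaLowGrayLevelEmphasis = sum(P / (i^2 * j^2)) / nz,
    ZoneEntropy = -sum(p * log2(p + .eps)),
    ZonePercentage = nz / tm$n_voxels,
    ZoneVariance = sum(p * (j - mu_j)^2)
  )
}

gldm_features <- function(tm) {
  stopifnot(tm$kind == "GLDM")
  P <- tm$matrix
  nz <- sum(P)
  if (nz == 0) rh_abort("empty GLDM", "radharm_empty_matrix")
  ng <- nrow(P); ndp <- ncol(P)
  i <- matrix(seq_len(ng), ng, ndp)
  j <- matrix(seq_len(ndp), ng, ndp, byrow = TRUE)
  p <- P / nz
  mu_i <- sum(p * i); mu_j <- sum(p * j)
  c(
    DependenceEntropy = -sum(p * log2(p + .eps)),
    DependenceNonUniformity = sum(colSums(P)^2) / nz,
    DependenceNonUniformityNormalized = sum(colSums(P)^2) / nz^2,
    DependenceVariance = sum(p * (j - mu_j)^2),
    GrayLevelNonUniformity = sum(rowSums(P)^2) / nz,
    GrayLevelVariance = sum(p * (i - mu_i)^2),
    HighGrayLevelEmphasis = sum(P * i^2) / nz,
    LargeDependenceEmphasis = sum(P * j^2) / nz,
    LargeDependenceHighGrayLevelEmphasis = sum(P * i^2 * j^2) / nz,
    LargeDependenceLowGrayLevelEmphasis = sum(P * j^2 / i^2) / nz,
    LowGrayLevelEmphasis = sum(P / i^2) / nz,
    SmallDependenceEmphasis = sum(P / j^2) / nz,
    SmallDependenceHighGrayLevelEmphasis = sum(P * i^2 / j^2) / nz,
    SmallDependenceLowGrayLevelEmphasis = sum(P / (i^2 * j^2)) / nz
  )
}

#' Second-order (texture-matrix) features
#'
#' @param matrices a single `texture_matrix` or a list of them.
#' @return Named numeric vector; names are `family_Feature`.
#' @export
second_order_features <- function(matrices) {
  if (inherits(matrices, "texture_matrix")) matrices <- list(matrices)
  out <- numeric(0)
  for (tm in matrices) {
    f <- switch(tm$kind,
                GLCM = glcm_features(tm),
                GLRLM = glrlm_features(tm),
                GLSZM = glszm_features(tm),
                GLDM = gldm_features(tm),
                rh_abort("unknown texture matrix kind", "radharm_bad_input"))
    names(f) <- paste(tolower(tm$kind), names(f), sep = "_")
    out <- c(out, f)
  }
  out
}

#' Extract the full per-ROI feature panel for one study
#'
#' For each ROI (LV, MYO, RV): the 18 first-order features and the four
#' texture-matrix families (GLCM 24, GLDM 14, GLRLM 16, GLSZM 16), after
#' fixed-bin-width discretisation. Shape features are excluded by design.
#' An empty ROI yields `NA` for its features with a warning.
#'
#' @param study an [image_study], already resampled to the target spacing.
#' @param W bin width (25 for raw images, 0.05 after normalisation).
#' @param mode `"3D"` (13 directions, 26-connectivity) or `"2D"` (in-plane).
#' @return Named numeric vector of `3 x 88` features, names `ROI_family_Feature`,
#'   in canonical column order.
#' @export
extract_study <- function(study, W, mode = c("3D", "2D")) {
  mode <- match.arg(mode)
  out <- numeric(0)
  for (r in names(roi_labels)) {
    if (!any(study$mask == roi_labels[[r]])) {
      rh_warn(sprintf("study %s: ROI %s empty, features set to NA",
                      study$subject_id, r), "radharm_empty_roi")
      f <- rep(NA_real_, length(feature_panel_names()) / 3)
      names(f) <- grep(paste0("^", r, "_"), feature_panel_names(), value = TRUE)
      names(f) <- sub(paste0("^", r, "_"), "", names(f))
    } else {
      d <- discretise_roi(study, r, W)
      fo <- first_order_features(d)
      f <- c(
        stats::setNames(fo, paste0("firstorder_", names(fo))),
        second_order_features(list(glcm(d, mode = mode),
                                   gldm(d, mode = mode),
                                   glrlm(d, mode = mode),
                                   glszm(d, mode = mode)))
      )
    }
    names(f) <- paste(r, names(f), sep = "_")
    out <- c(out, f)
  }
  out[feature_panel_names()]
}

#' Canonical feature column names
#'
#' ROI blocks (LV, MYO, RV); within each, families in the order firstorder,
#' glcm, gldm, glrlm, glszm; features alphabetical within family. Fixed
#' because the sequential correlation filter depends on column order.
#'
#' @return Character vector of 264 names.
#' @export
feature_panel_names <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    dummy <- list(raw = c(0, 1, 2, 1), levels = array(c(1L, 2L, 3L, 2L, 0L, 0L, 0L, 0L),
                                                      c(2, 2, 2)),
                  Ng = 3L, bin_width = 1, roi = "LV", n_voxels = 4L,
                  spacing = c(1, 1, 1))
    class(dummy) <- "discretised_roi"
    fo <- sort(names(first_order_features(dummy)))
    fams <- list(
      firstorder = fo,
      glcm = sort(names(glcm_features(glcm(dummy)))),
      gldm = sort(names(gldm_features(gldm(dummy)))),
      glrlm = sort(names(glrlm_features(glrlm(dummy)))),
      glszm = sort(names(glszm_features(glszm(dummy))))
    )
    nm <- unlist(lapply(names(roi_labels), function(r)
      unlist(lapply(names(fams), function(fam)
        paste(r, fam, fams[[fam]], sep = "_")))), use.names = FALSE)
    cache <<- nm
    nm
  }
})

#' Extract features for a whole cohort
#'
#' @param studies list of [image_study] objects.
#' @param W bin width.
#' @param mode `"3D"` or `"2D"`.
#' @param resample_to in-plane target spacing (mm) applied before extraction;
#'   `NULL` to skip resampling.
#' @return A [feature_table] with one row per study.
#' @export
extract_cohort <- function(studies, W, mode = c("3D", "2D"),
                           resample_to = c(1, 1)) {
  mode <- match.arg(mode)
  rows <- lapply(studies, function(s) {
    if (!is.null(resample_to)) s <- resample_inplane(s, resample_to)
    extract_study(s, W, mode)
  })
  m <- do.call(rbind, rows)
  feature_table(m, cohort_metadata(studies))
}
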