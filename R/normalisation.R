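#' Intensity rescaling to [0, 1]
#'
#' `(x - min) / (max - min)`. A constant input is mapped to all zeros with a
#' warning (degenerate-range policy; keeps pipelines running on flat ROIs).
#'
#' @param values numeric vector with at least one finite value.
#' @return Rescaled vector in `[0, 1]`.
#' @export
rescale <- function(values) {
  if (!length(values) || any(!is.finite(values)))
    rh_abort("rescale needs finite values", "radharm_bad_input")
  rng <- range(values)
  if (rng[1] == rng[2]) {
    rh_warn("constant input: rescale returns zeros", "radharm_degenerate")
    return(rep(0, length(values)))
  }
  (values - rng[1]) / (rng[2] - rng[1])
}

#' Intensity z-normalisation
#'
#' Mean subtraction and division by the population (1/n) standard deviation.
#' Zero-variance input returns zeros with a warning.
#'
#' @param values numeric vector, length >= 2.
#' @return Vector with mean 0 and population SD 1.
#' @export
znorm <- function(values) {
  if (length(values) < 2L || any(!is.finite(values)))
    rh_abort("znorm needs >= 2 finite values", "radharm_bad_input")
  s <- sd_pop(values)
  if (s == 0) {
    rh_warn("zero variance: znorm returns zeros", "radharm_degenerate")
    return(rep(0, length(values)))
  }
  (values - mean(values)) / s
}

#' Histogram matching by empirical quantile mapping
#'
#' Each value is sent to the template quantile at its own mid-rank plotting
#' position, with linear interpolation between template order statistics: a
#' monotone, rank-preserving remapping whose output distribution approximates
#' the template's. Matching a sample against itself is the identity.
#'
#' @param values numeric vector to transform.
#' @param template numeric vector of template intensities (or a
#'   `histogram_template`).
#' @return Transformed vector.
#' @export
histogram_match <- function(values, template) {
  if (inherits(template, "histogram_template")) template <- template$values
  if (!length(values)) rh_abort("empty input", "radharm_bad_input")
  if (!length(template)) rh_abort("empty template", "radharm_bad_input")
  n <- length(values)
  p <- (rank(values, ties.method = "average") - 0.5) / n
  ts <- sort(template)
  m <- length(ts)
  tp <- (seq_len(m) - 0.5) / m
  if (m == 1L) return(rep(ts, n))
  stats::approx(tp, ts, xout = p, rule = 2)$y
}

#' Histogram template from a reference subject
#'
#' @param study an [image_study] from the reference centre.
#' @param scope `"whole"` (all voxels, one template) or `"roi"` (one template
#'   per ROI label from the same subject).
#' @return A `histogram_template` (scope `"whole"`) or named list of them.
#' @export
fit_histogram_template <- function(study, scope = c("whole", "roi")) {
  scope <- match.arg(scope)
  mk <- function(v, sc) structure(
    list(values = sort(as.numeric(v)), scope = sc, source = study$subject_id),
    class = "histogram_template"
  )
  if (scope == "whole") return(mk(study$voxels, "whole"))
  stats::setNames(
    lapply(names(roi_labels), function(r) mk(roi_sample(study, r), "roi")),
    names(roi_labels)
  )
}

#' Fit piecewise-linear histogram-matching landmarks (Nyul-Udupa)
#'
#' For each training intensity sample the percentiles on `grid` are computed
#' and mapped by the linear transform sending the two anchor percentiles
#' (first and last grid entries) onto `standard_range`; the mapped landmark
#' vectors are averaged across training samples to give the standard-scale
#' landmarks.
#'
#' @param training list of numeric vectors (one per training image or ROI).
#' @param grid ordered percentile grid in (0, 100); default the deciles
#'   flanked by the 1st and 99th percentile anchors.
#' @param standard_range numeric length 2, the standard scale; default `[0, 1]`.
#' @param training_centre optional centre id recorded on the result.
#' @return A `landmark_set`.
#' @export
fit_plhm <- function(training, grid = c(1, seq(10, 90, by = 10), 99),
                     standard_range = c(0, 1), training_centre = NA_character_) {
  if (!length(training)) rh_abort("no training arrays", "radharm_bad_input")
  if (is.numeric(training)) training <- list(training)
  if (is.unsorted(grid, strictly = TRUE) || any(grid <= 0) || any(grid >= 100))
    rh_abort("grid must be strictly increasing within (0, 100)",
             "radharm_bad_input")
  s_min <- standard_range[1]; s_max <- standard_range[2]
  mapped <- vapply(training, function(x) {
    if (any(!is.finite(x))) rh_abort("non-finite training values",
                                     "radharm_bad_input")
    q <- stats::quantile(x, probs = grid / 100, names = FALSE, type = 7)
    lo <- q[1]; hi <- q[length(q)]
    if (hi == lo) return(rep((s_min + s_max) / 2, length(q)))
    (q - lo) / (hi - lo) * (s_max - s_min) + s_min
  }, numeric(length(grid)))
  lm <- rowMeans(as.matrix(mapped))
  structure(
    list(percentile_grid = grid, standard_landmarks = lm,
         standard_range = c(s_min, s_max), training_centre = training_centre,
         n_training = length(training)),
    class = "landmark_set"
  )
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> %d landmarks on [%g, %g], trained on %d image(s)%s\n",
              length(x$standard_landmarks), x$standard_range[1],
              x$standard_range[2], x$n_training,
              if (is.na(x$training_centre)) "" else
                paste0(" from ", x$training_centre)))
  print(stats::setNames(signif(x$standard_landmarks, 4),
                        paste0("p", x$percentile_grid)))
  invisible(x)
}

#' Apply piecewise-linear histogram matching
#'
#' The input's own percentiles at the landmark grid are computed and the
#' piecewise-linear map sending them onto the standard landmarks is applied;
#' values beyond the anchor percentiles are extrapolated linearly with the
#' end-segment slopes. Monotone non-decreasing.
#'
#' @param values numeric vector.
#' @param landmarks a `landmark_set` from [fit_plhm()].
#' @return Transformed vector on the standard scale.
#' @export
apply_plhm <- function(values, landmarks) {
  if (!inherits(landmarks, "landmark_set"))
    rh_abort("`landmarks` must be a landmark_set", "radharm_bad_input")
  q <- stats::quantile(values, probs = landmarks$percentile_grid / 100,
                       names = FALSE, type = 7)
  lm <- landmarks$standard_landmarks
  if (q[length(q)] == q[1]) {
    rh_warn("constant input: mapped to standard-range midpoint",
            "radharm_degenerate")
    return(rep(mean(landmarks$standard_range), length(values)))
  }
  # collapse tied input percentiles (discrete data) keeping landmark means
  keep <- !duplicated(q)
  qx <- q[keep]
  ly <- vapply(split(lm, match(q, qx)), mean, 0)
  piecewise_linear(values, qx, ly)
}

# Monotone piecewise-linear map through (qx, ly) with linear extrapolation
# from the end segments.
piecewise_linear <- function(x, qx, ly) {
  if (length(qx) == 1L) return(rep(ly, length(x)))
  out <- stats::approx(qx, ly, xout = x, rule = 2)$y
  k <- length(qx)
  slope_lo <- (ly[2] - ly[1]) / (qx[2] - qx[1])
  slope_hi <- (ly[k] - ly[k - 1]) / (qx[k] - qx[k - 1])
  below <- x < qx[1]; above <- x > qx[k]
  out[below] <- ly[1] + (x[below] - qx[1]) * slope_lo
  out[above] <- ly[k] + (x[above] - qx[k]) * slope_hi
  out
}

#' Fit a normalisation reference on a cohort
#'
#' `HM` fits a histogram template from one reference subject (the
#' alphabetically first healthy ED study of the reference centre); `PLHM`
#' fits standard-scale landmarks on all studies of the reference centre.
#' `O`, `R` and `N` need no fitting and return `NULL`.
#'
#' @param studies list of [image_study] objects.
#' @param method one of `"O"`, `"R"`, `"N"`, `"HM"`, `"PLHM"`.
#' @param scope `"whole"` or `"roi"`.
#' @param reference_centre centre id; default the centre with most studies.
#' @return Fitted reference (template, landmark set, per-ROI list of either)
#'   or `NULL`.
#' @export
fit_normalisation <- function(studies, method, scope = c("whole", "roi"),
                              reference_centre = NULL) {
  scope <- match.arg(scope)
  method <- match.arg(method, c("O", "R", "N", "HM", "PLHM"))
  if (method %in% c("O", "R", "N")) return(NULL)
  centres <- vapply(studies, `[[`, "", "centre_id")
  if (is.null(reference_centre))
    reference_centre <- names(which.max(table(centres)))
  ref <- studies[centres == reference_centre]
  if (!length(ref))
    rh_abort(paste("no studies from reference centre", reference_centre),
             "radharm_bad_input")
  if (method == "HM") {
    healthy <- vapply(ref, function(s)
      s$class_label == "healthy" && s$phase == "ED", TRUE)
    pool <- if (any(healthy)) ref[healthy] else ref
    ids <- vapply(pool, `[[`, "", "subject_id")
    return(fit_histogram_template(pool[[order(ids)[1]]], scope))
  }
  # PLHM
  if (scope == "whole") {
    fit_plhm(lapply(ref, function(s) as.numeric(s$voxels)),
             training_centre = reference_centre)
  } else {
    stats::setNames(lapply(names(roi_labels), function(r)
      fit_plhm(lapply(ref, function(s) as.numeric(roi_sample(s, r))),
               training_centre = reference_centre)), names(roi_labels))
  }
}

#' Apply an intensity normalisation to a study
#'
#' With `scope = "whole"` the transform is fitted on and applied to all
#' voxels; with `scope = "roi"` it is fitted and applied independently per
#' ROI label, leaving background voxels untouched. Method `"O"` is the
#' identity (no normalisation).
#'
#' @param study an [image_study].
#' @param method one of `"O"`, `"R"` (rescale), `"N"` (z-normalisation),
#'   `"HM"` (histogram matching), `"PLHM"` (piecewise linear histogram
#'   matching).
#' @param scope `"whole"` or `"roi"`; ignored for `"O"`.
#' @param fitted fitted reference from [fit_normalisation()] (required for
#'   `HM`/`PLHM`; for ROI scope a named per-ROI list).
#' @return A normalised [image_study] (z-normalised volumes contain negative
#'   intensities; downstream discretisation anchors at the ROI minimum).
#' @export
apply_normalisation <- function(study, method, scope = c("whole", "roi"),
                                fitted = NULL) {
  method <- match.arg(method, c("O", "R", "N", "HM", "PLHM"))
  if (method == "O") return(study)
  scope <- match.arg(scope)
  if (method %in% c("HM", "PLHM") && is.null(fitted))
    rh_abort(paste(method, "requires a fitted reference"), "radharm_missing_fit")
  tf <- function(v, fit) switch(method,
    R = rescale(v),
    N = znorm(v),
    HM = histogram_match(v, fit),
    PLHM = apply_plhm(v, fit)
  )
  vox <- study$voxels
  if (scope == "whole") {
    new <- array(tf(as.numeric(vox), fitted), dim(vox))
  } else {
    new <- vox
    for (r in names(roi_labels)) {
      idx <- study$mask == roi_labels[[r]]
      if (!any(idx)) next
      fit <- if (is.null(fitted)) NULL else fitted[[r]]
      new[idx] <- tf(vox[idx], fit)
    }
  }
  image_study(new, study$mask, study$spacing, study$centre_id,
              study$class_label, study$phase, study$subject_id)
}

#' Serialise / restore a landmark set as JSON
#'
#' @param landmarks a `landmark_set` (or per-ROI named list of them).
#' @param path JSON file path.
#' @return `write_landmarks` invisibly returns `path`; `read_landmarks`
#'   returns the `landmark_set` (or named list).
#' @export
write_landmarks <- function(landmarks, path) {
  unclassed <- if (inherits(landmarks, "landmark_set"))
    unclass(landmarks) else lapply(landmarks, unclass)
  jsonlite::write_json(unclassed, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_lm <- function(l) structure(l, class = "landmark_set")
  if ("standard_landmarks" %in% names(x)) as_lm(x) else lapply(x, as_lm)
}
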