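#' Construct an image study
#'
#' An `image_study` bundles one subject's grayscale short-axis volume with its
#' integer-label segmentation mask and acquisition metadata. Voxel arrays are
#' indexed `[row, col, slice]`; `spacing` gives the physical size of one voxel
#' step along each of those axes, in millimetres. Mask labels are 0 background,
#' 1 left-ventricular cavity (LV), 2 myocardium (MYO), 3 right-ventricular
#' cavity (RV).
#'
#' @param voxels 3D numeric array of non-negative intensities.
#' @param mask 3D integer array, same dimensions, labels in `{0, 1, 2, 3}`.
#' @param spacing numeric length-3, strictly positive, millimetres per voxel
#'   along (row, col, slice).
#' @param centre_id character scalar, acquisition centre.
#' @param class_label `"healthy"` or `"HCM"`.
#' @param phase cardiac phase, `"ED"` or `"ES"`.
#' @param subject_id character scalar.
#' @return An object of class `image_study`. If one of the three ROI labels is
#'   absent the study is still constructed but carries
#'   `attr(, "missing_rois")` listing the absent labels.
#' @export
image_study <- function(voxels, mask, spacing,
                        centre_id = "unknown", class_label = c("healthy", "HCM"),
                        phase = c("ED", "ES"), subject_id = "S0") {
  class_label <- match.arg(class_label)
  phase <- match.arg(phase)
  if (length(dim(voxels)) != 3L)
    rh_abort("`voxels` must be a 3D array", "radharm_bad_geometry")
  if (!identical(dim(voxels), dim(mask)))
    rh_abort(sprintf(
      "image/mask shape mismatch: image %s vs mask %s",
      paste(dim(voxels), collapse = "x"), paste(dim(mask), collapse = "x")
    ), "radharm_shape_mismatch")
  labs <- sort(unique(as.integer(mask)))
  bad <- setdiff(labs, 0:3)
  if (length(bad))
    rh_abort(paste0("unknown label(s) in mask: ", paste(bad, collapse = ", ")),
             "radharm_unknown_label")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    rh_abort("`spacing` must be 3 strictly positive numbers (mm)",
             "radharm_bad_geometry")
  if (any(!is.finite(voxels)))
    rh_abort("voxel intensities must be finite", "radharm_bad_geometry")
  out <- structure(
    list(
      voxels = voxels,
      mask = array(as.integer(mask), dim(mask)),
      spacing = as.numeric(spacing),
      centre_id = as.character(centre_id),
      class_label = class_label,
      phase = phase,
      subject_id = as.character(subject_id)
    ),
    class = "image_study"
  )
  missing_rois <- setdiff(1:3, labs)
  if (length(missing_rois)) attr(out, "missing_rois") <- missing_rois
  out
}

roi_labels <- c(LV = 1L, MYO = 2L, RV = 3L)

#' @export
print.image_study <- function(x, ...) {
  cat(sprintf(
    "<image_study> %s  centre=%s class=%s phase=%s\n  dims %s  spacing %s mm\n",
    x$subject_id, x$centre_id, x$class_label, x$phase,
    paste(dim(x$voxels), collapse = "x"),
    paste(signif(x$spacing, 4), collapse = " x ")
  ))
  for (r in names(roi_labels))
    cat(sprintf("  %-3s %d voxels\n", r, sum(x$mask == roi_labels[[r]])))
  invisible(x)
}

#' Intensities inside one region of interest
#'
#' @param study an [image_study].
#' @param roi ROI name (`"LV"`, `"MYO"`, `"RV"`) or integer label 1..3.
#' @return Numeric vector of in-ROI voxel intensities with attributes `roi`
#'   and `source` (subject id).
#' @export
roi_sample <- function(study, roi) {
  lab <- if (is.character(roi)) roi_labels[[roi]] else as.integer(roi)
  v <- study$voxels[study$mask == lab]
  if (!length(v))
    rh_abort(sprintf("ROI %s is empty in study %s", roi, study$subject_id),
             "radharm_empty_roi")
  structure(v, roi = names(roi_labels)[match(lab, roi_labels)],
            source = study$subject_id)
}

#' Read one study from NIfTI files plus a metadata record
#'
#' Intensities are read bit-exactly as stored; voxel spacing is taken from the
#' image header. The metadata record must provide `subject_id`, `centre`,
#' `pathology` and `phase`.
#'
#' @param image_path path to the grayscale NIfTI volume.
#' @param mask_path path to the integer-label NIfTI mask on the same grid.
#' @param meta one-row data.frame or named list of metadata.
#' @return An [image_study].
#' @export
read_study <- function(image_path, mask_path, meta) {
  img <- RNifti::readNifti(image_path)
  msk <- RNifti::readNifti(mask_path)
  sp <- RNifti::pixdim(img)[1:3]
  image_study(
    voxels = array(as.numeric(img), dim(img)),
    mask = array(as.integer(round(as.numeric(msk))), dim(msk)),
    spacing = sp,
    centre_id = as.character(meta$centre),
    class_label = as.character(meta$pathology),
    phase = as.character(meta$phase),
    subject_id = as.character(meta$subject_id)
  )
}

#' Write one study as a NIfTI image/mask pair
#'
#' @param study an [image_study].
#' @param image_path,mask_path output paths (`.nii` or `.nii.gz`).
#' @return Invisibly, the study.
#' @export
write_study <- function(study, image_path, mask_path) {
  img <- RNifti::asNifti(study$voxels)
  RNifti::pixdim(img) <- study$spacing
  RNifti::writeNifti(img, image_path)
  msk <- RNifti::asNifti(array(as.numeric(study$mask), dim(study$mask)))
  RNifti::pixdim(msk) <- study$spacing
  RNifti::writeNifti(msk, mask_path)
  invisible(study)
}

# Interpolation weight matrix mapping an n_in grid at spacing d_in onto the
# grid at spacing d_out covering the same physical extent, corner-aligned:
# sample i sits at (i - 1) * d. Each output row has at most two non-zeros.
interp_matrix <- function(n_in, d_in, d_out, method = c("linear", "nearest")) {
  method <- match.arg(method)
  extent <- (n_in - 1) * d_in
  n_out <- floor(extent / d_out + 1e-9) + 1L
  pos <- (seq_len(n_out) - 1) * d_out / d_in + 1  # fractional input index
  pos <- pmin(pmax(pos, 1), n_in)
  W <- matrix(0, n_out, n_in)
  if (method == "nearest") {
    W[cbind(seq_len(n_out), round(pos))] <- 1
  } else {
    i0 <- pmin(floor(pos), n_in - 1L)
    if (n_in == 1L) i0 <- rep(1L, n_out)
    f <- pos - i0
    W[cbind(seq_len(n_out), i0)] <- W[cbind(seq_len(n_out), i0)] + (1 - f)
    i1 <- pmin(i0 + 1L, n_in)
    W[cbind(seq_len(n_out), i1)] <- W[cbind(seq_len(n_out), i1)] + f
  }
  W
}

#' Resample a study in-plane to a target pixel size
#'
#' Each slice is interpolated onto a grid at the target in-plane spacing
#' covering the same physical extent (corner-aligned sample positions).
#' The image is interpolated bilinearly; the mask by nearest neighbour, so no
#' new labels can appear. Slice count and slice thickness are unchanged.
#'
#' @param study an [image_study].
#' @param target length-2 target (row, col) spacing in mm; default `c(1, 1)`.
#' @return A resampled [image_study].
#' @export
resample_inplane <- function(study, target = c(1, 1)) {
  if (length(target) == 1L) target <- rep(target, 2)
  if (any(!is.finite(target)) || any(target <= 0))
    rh_abort("target spacing must be strictly positive", "radharm_bad_geometry")
  d <- dim(study$voxels)
  Wr <- interp_matrix(d[1], study$spacing[1], target[1], "linear")
  Wc <- interp_matrix(d[2], study$spacing[2], target[2], "linear")
  Nr <- interp_matrix(d[1], study$spacing[1], target[1], "nearest")
  Nc <- interp_matrix(d[2], study$spacing[2], target[2], "nearest")
  nv <- array(0, c(nrow(Wr), nrow(Wc), d[3]))
  nm <- array(0L, dim(nv))
  for (k in seq_len(d[3])) {
    nv[, , k] <- Wr %*% study$voxels[, , k] %*% t(Wc)
    nm[, , k] <- as.integer(Nr %*% study$mask[, , k] %*% t(Nc))
  }
  out <- image_study(
    voxels = pmax(nv, 0), mask = nm,
    spacing = c(target, study$spacing[3]),
    centre_id = study$centre_id, class_label = study$class_label,
    phase = study$phase, subject_id = study$subject_id
  )
  out
}
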