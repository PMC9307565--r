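#' Centre acquisition profile
#'
#' Describes how one centre's scanner maps the canonical tissue-intensity
#' scale `[0, 1]` onto raw stored values: a monotone gain/offset/gamma
#' transform scaled to the centre's dynamic range, plus additive Gaussian
#' noise. The default five profiles emulate the very different raw intensity
#' ranges observed across 1.5T scanners from five vendors (maxima from a few
#' hundred to above ten thousand), together with centre-specific in-plane
#' resolution.
#'
#' @param centre_id character scalar.
#' @param gain multiplicative gain, > 0.
#' @param offset additive offset on the canonical scale, >= 0.
#' @param gamma contrast exponent applied to canonical intensities, > 0.
#' @param noise_sd additive Gaussian noise SD in raw output units, >= 0.
#' @param max_intensity target raw dynamic range (canonical 1 maps near this).
#' @param inplane_mm acquisition pixel size (mm), square pixels.
#' @return A `centre_profile` object.
#' @export
centre_profile <- function(centre_id, gain = 1, offset = 0, gamma = 1,
                           noise_sd = 0, max_intensity = 1, inplane_mm = 1) {
  stopifnot(gain > 0, offset >= 0, gamma > 0, noise_sd >= 0,
            max_intensity > 0, inplane_mm > 0)
  structure(list(centre_id = centre_id, gain = gain, offset = offset,
                 gamma = gamma, noise_sd = noise_sd,
                 max_intensity = max_intensity, inplane_mm = inplane_mm),
            class = "centre_profile")
}

#' Default five-centre acquisition profiles
#'
#' Dynamic ranges, noise floors and pixel sizes chosen to mirror the spread
#' reported for the five clinical centres (raw maxima ~357 to ~14,442;
#' in-plane resolution 0.85-1.45 mm). `null_effect = TRUE` gives all centres
#' an identical mid-range profile, so any downstream centre signal must be
#' spurious.
#'
#' @param null_effect logical; if `TRUE` all five centres share one profile.
#' @return Named list of [centre_profile] objects.
#' @export
default_centre_profiles <- function(null_effect = FALSE) {
  if (null_effect) {
    p <- lapply(default_centre_names, function(cn)
      centre_profile(cn, gain = 1, offset = 0.01, gamma = 1,
                     noise_sd = 10, max_intensity = 1000, inplane_mm = 1.25))
    return(stats::setNames(p, default_centre_names))
  }
  list(
    CreuBlanca = centre_profile("CreuBlanca", gain = 0.9, offset = 0.002,
                                gamma = 0.9, noise_sd = 140,
                                max_intensity = 14442, inplane_mm = 0.85),
    Dexeus = centre_profile("Dexeus", gain = 1.0, offset = 0.04, gamma = 1.15,
                            noise_sd = 30, max_intensity = 3030,
                            inplane_mm = 1.36),
    SagradaFamilia = centre_profile("SagradaFamilia", gain = 0.95, offset = 0,
                                    gamma = 1.0, noise_sd = 4,
                                    max_intensity = 357, inplane_mm = 1.20),
    Hamburg = centre_profile("Hamburg", gain = 1.05, offset = 0.01,
                             gamma = 0.85, noise_sd = 37,
                             max_intensity = 3725, inplane_mm = 1.45),
    VallHebron = centre_profile("VallHebron", gain = 0.9, offset = 0.02,
                                gamma = 1.1, noise_sd = 12,
                                max_intensity = 1193, inplane_mm = 1.32)
  )
}

default_centre_names <- c("CreuBlanca", "Dexeus", "SagradaFamilia",
                          "Hamburg", "VallHebron")

#' Cohort specification
#'
#' Per-centre subject counts and phantom geometry. The default counts
#' reproduce the clinical study's distribution: 112 healthy and 106 HCM
#' subjects over five centres (14/11/33/32/22 healthy and 15/5/37/24/25 HCM
#' for Creu Blanca / Dexeus / Sagrada Familia / Hamburg / Vall d'Hebron).
#'
#' @param counts data.frame with columns `centre`, `healthy`, `HCM`.
#' @param seed integer master seed for cohort generation.
#' @param fov_mm in-plane field of view (square), mm.
#' @param n_slices number of short-axis slices.
#' @param slice_mm slice thickness, mm.
#' @param geometry list of phantom geometry parameters, see
#'   [default_phantom_geometry()].
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(counts = default_cohort_counts(), seed = 1L,
                        fov_mm = 64, n_slices = 3, slice_mm = 10,
                        geometry = default_phantom_geometry(fov_mm)) {
  stopifnot(all(c("centre", "healthy", "HCM") %in% names(counts)),
            all(counts$healthy >= 0), all(counts$HCM >= 0))
  structure(list(counts = counts, seed = as.integer(seed), fov_mm = fov_mm,
                 n_slices = n_slices, slice_mm = slice_mm, geometry = geometry),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_cohort_counts <- function() {
  data.frame(
    centre = default_centre_names,
    healthy = c(14L, 11L, 33L, 32L, 22L),
    HCM = c(15L, 5L, 37L, 24L, 25L),
    stringsAsFactors = FALSE
  )
}

#' Phantom geometry defaults
#'
#' All lengths in mm. The HCM class has a mean myocardial wall thickness twice
#' the healthy mean and a rougher, longer-range myocardial texture (higher
#' variance and spatial autocorrelation of the stationary random field), the
#' two class effects the generator injects.
#'
#' @param fov_mm field of view; centres and radii scale with it (defaults
#'   below are quoted for the standard 64 mm FOV).
#' @return Named list of geometry parameters.
#' @export
default_phantom_geometry <- function(fov_mm = 64) {
  s <- fov_mm / 64
  list(
    lv_centre = fov_mm * c(0.50, 0.40),  # (row, col) mm within the FOV
    rv_centre = fov_mm * c(0.50, 0.71),
    cavity_radius_mean = 8 * s, cavity_radius_sd = 1 * s,
    wall_mean = list(healthy = 5 * s, HCM = 10 * s),
    wall_sd = list(healthy = 0.6 * s, HCM = 1.2 * s),
    rv_radius_mean = 9 * s, rv_radius_sd = 1 * s,
    rv_gap = 1.5 * s,               # clearance between RV crescent and LV wall
    es_cavity_scale = 0.75, es_wall_scale = 1.25, es_rv_scale = 0.8,
    base_intensity = c(background = 0.05, LV = 0.85, MYO = 0.35, RV = 0.8),
    texture_sd = list(healthy_myo = 0.06, HCM_myo = 0.12, blood = 0.04,
                      background = 0.02),
    texture_len_mm = list(healthy_myo = 1.5, HCM_myo = 3.0, blood = 1.0)
  )
}

#' Generate one centre-free phantom study
#'
#' Builds a concentric-ring short-axis phantom on the canonical intensity
#' scale `[0, 1]`: LV cavity disc, myocardial ring, and an RV crescent, per
#' slice, plus stationary Gaussian-random-field texture whose variance and
#' correlation length are class-specific in the myocardium. Uses the current
#' RNG state; seed externally for reproducibility.
#'
#' @param class_label `"healthy"` or `"HCM"`.
#' @param geometry geometry list, see [default_phantom_geometry()].
#' @param phase `"ED"` or `"ES"` (systole shrinks cavities and thickens wall).
#' @param fov_mm,n_slices,slice_mm grid parameters.
#' @param inplane_mm acquisition pixel size in mm.
#' @param subject_id,centre_id metadata passed through.
#' @param textured logical; `FALSE` gives a piecewise-constant phantom.
#' @return An [image_study] on the canonical `[0, 1]` scale.
#' @export
make_phantom <- function(class_label = c("healthy", "HCM"),
                         geometry = default_phantom_geometry(),
                         phase = c("ED", "ES"),
                         fov_mm = 64, n_slices = 3, slice_mm = 10,
                         inplane_mm = 1, subject_id = "S0",
                         centre_id = "none", textured = TRUE) {
  class_label <- match.arg(class_label)
  phase <- match.arg(phase)
  g <- geometry
  cav <- max(2, stats::rnorm(1, g$cavity_radius_mean, g$cavity_radius_sd))
  wall <- max(1.5, stats::rnorm(1, g$wall_mean[[class_label]],
                                g$wall_sd[[class_label]]))
  rvr <- max(2, stats::rnorm(1, g$rv_radius_mean, g$rv_radius_sd))
  if (phase == "ES") {
    cav <- cav * g$es_cavity_scale
    wall <- wall * g$es_wall_scale
    rvr <- rvr * g$es_rv_scale
  }
  if (cav <= 0 || wall <= 0 || rvr <= 0)
    rh_abort("phantom geometry yields an empty ROI", "radharm_bad_geometry")

  n <- max(8L, round(fov_mm / inplane_mm))
  ctr <- function(p) p / inplane_mm  # mm -> pixel coordinates (1-based grid)
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  dist2 <- function(centre_mm) {
    (rows - ctr(centre_mm[1]))^2 + (cols - ctr(centre_mm[2]))^2
  }
  px <- function(mm) mm / inplane_mm
  d_lv <- sqrt(dist2(g$lv_centre)) * inplane_mm
  d_rv <- sqrt(dist2(g$rv_centre)) * inplane_mm

  mask2d <- matrix(0L, n, n)
  mask2d[d_rv <= rvr & d_lv > cav + wall + g$rv_gap] <- 3L
  mask2d[d_lv <= cav + wall] <- 2L
  mask2d[d_lv <= cav] <- 1L
  if (!all(1:3 %in% mask2d))
    rh_abort("phantom geometry yields an empty ROI", "radharm_bad_geometry")

  base <- g$base_intensity
  vox <- array(0, c(n, n, n_slices))
  msk <- array(0L, c(n, n, n_slices))
  ts <- g$texture_sd
  tl <- g$texture_len_mm
  myo_key <- if (class_label == "HCM") "HCM_myo" else "healthy_myo"
  for (k in seq_len(n_slices)) {
    sl <- matrix(base[["background"]], n, n)
    sl[mask2d == 1L] <- base[["LV"]]
    sl[mask2d == 2L] <- base[["MYO"]]
    sl[mask2d == 3L] <- base[["RV"]]
    if (textured) {
      fld <- function(len_mm, sd) {
        f <- gauss_smooth2d(matrix(stats::rnorm(n * n), n, n), px(len_mm))
        s <- stats::sd(f)
        if (s > 0) f * (sd / s) else f
      }
      blood <- fld(tl$blood, ts$blood)
      myo <- fld(tl[[myo_key]], ts[[myo_key]])
      bg <- matrix(stats::rnorm(n * n, 0, ts$background), n, n)
      sl <- sl + bg * (mask2d == 0L) + blood * (mask2d %in% c(1L, 3L)) +
        myo * (mask2d == 2L)
    }
    vox[, , k] <- pmin(pmax(sl, 0), 1)
    msk[, , k] <- mask2d
  }
  image_study(vox, msk, spacing = c(inplane_mm, inplane_mm, slice_mm),
              centre_id = centre_id, class_label = class_label, phase = phase,
              subject_id = subject_id)
}

#' Apply one centre's acquisition transform to a canonical-scale study
#'
#' `raw = max_intensity * (gain * canonical^gamma + offset) + noise`,
#' clipped at zero. The transform is monotone in the canonical intensity, so
#' rank order within the study is preserved up to noise.
#'
#' @param study an [image_study] on the canonical `[0, 1]` scale.
#' @param profile a [centre_profile].
#' @return An [image_study] on the centre's raw scale, with `centre_id` set.
#' @export
apply_centre_effect <- function(study, profile) {
  v <- study$voxels
  if (max(v) > 1 + 1e-9)
    rh_abort("apply_centre_effect expects canonical-scale input in [0, 1]",
             "radharm_bad_geometry")
  out <- profile$max_intensity * (profile$gain * v^profile$gamma + profile$offset)
  if (profile$noise_sd > 0)
    out <- out + array(stats::rnorm(length(v), 0, profile$noise_sd), dim(v))
  image_study(pmax(out, 0), study$mask, study$spacing,
              centre_id = profile$centre_id, class_label = study$class_label,
              phase = study$phase, subject_id = study$subject_id)
}

#' Generate a full multi-centre cohort
#'
#' Deterministic under `spec$seed`. For every subject each requested cardiac
#' phase is generated (geometry drawn per phase, systolic scaling applied for
#' ES), then the centre's acquisition transform is applied.
#'
#' @param spec a [cohort_spec].
#' @param profiles named list of [centre_profile]s covering every centre in
#'   `spec$counts`.
#' @param phases which phases to generate, default both.
#' @return List of [image_study] objects (one per subject and phase).
#' @export
generate_cohort <- function(spec = cohort_spec(),
                            profiles = default_centre_profiles(),
                            phases = c("ED", "ES")) {
  missing_profiles <- setdiff(spec$counts$centre, names(profiles))
  if (length(missing_profiles))
    rh_abort(paste("no centre_profile for:",
                   paste(missing_profiles, collapse = ", ")),
             "radharm_missing_profile")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  studies <- list()
  sid <- 0L
  for (i in seq_len(nrow(spec$counts))) {
    cn <- spec$counts$centre[i]
    prof <- profiles[[cn]]
    for (cls in c("healthy", "HCM")) {
      for (j in seq_len(spec$counts[[cls]][i])) {
        sid <- sid + 1L
        subject <- sprintf("SUB%03d", sid)
        for (ph in phases) {
          st <- make_phantom(
            class_label = cls, geometry = spec$geometry, phase = ph,
            fov_mm = spec$fov_mm, n_slices = spec$n_slices,
            slice_mm = spec$slice_mm, inplane_mm = prof$inplane_mm,
            subject_id = subject
          )
          studies[[length(studies) + 1L]] <- apply_centre_effect(st, prof)
        }
      }
    }
  }
  studies
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Cohort metadata as a data.frame
#'
#' @param studies list of [image_study] objects.
#' @return data.frame with one row per study.
#' @export
cohort_metadata <- function(studies) {
  do.call(rbind, lapply(studies, function(s) data.frame(
    subject_id = s$subject_id, centre = s$centre_id,
    pathology = s$class_label, phase = s$phase,
    stringsAsFactors = FALSE
  )))
}

#' Write a cohort to a directory as NIfTI + metadata CSV
#'
#' @param studies list of [image_study] objects.
#' @param dir output directory (created if needed).
#' @return Invisibly, the metadata data.frame (also written as
#'   `metadata.csv` with image/mask file columns).
#' @export
write_cohort <- function(studies, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- cohort_metadata(studies)
  meta$image <- sprintf("%s_%s.nii.gz", meta$subject_id, meta$phase)
  meta$mask <- sprintf("%s_%s_mask.nii.gz", meta$subject_id, meta$phase)
  for (i in seq_along(studies))
    write_study(studies[[i]], file.path(dir, meta$image[i]),
                file.path(dir, meta$mask[i]))
  utils::write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  invisible(meta)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `metadata.csv` and the NIfTI files.
#' @return List of [image_study] objects.
#' @export
read_cohort <- function(dir) {
  meta <- utils::read.csv(file.path(dir, "metadata.csv"),
                          stringsAsFactors = FALSE)
  lapply(seq_len(nrow(meta)), function(i)
    read_study(file.path(dir, meta$image[i]), file.path(dir, meta$mask[i]),
               meta[i, ]))
}
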