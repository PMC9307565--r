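#' Pipeline run configuration
#'
#' Bundles every knob of the end-to-end study with defaults matching the
#' reference protocol: the nine normalisation variants (O plus R/N/HM/PLHM at
#' whole-image and ROI scope), with and without ComBat, bin widths 25 (raw)
#' and 0.05 (normalised), JSD threshold 0.01, correlation threshold R^2 0.9,
#' 20 ComBat quantiles, 5 folds, 5 seeds, 1x1 mm in-plane resampling.
#'
#' @param cohort a [cohort_spec].
#' @param profiles named list of [centre_profile]s.
#' @param methods data.frame with columns `method`, `scope` (the variant
#'   grid); default all nine variants.
#' @param combat logical vector of ComBat states to run (default both).
#' @param bin_width_raw,bin_width_norm discretisation bin widths.
#' @param tau,r2_threshold variability thresholds.
#' @param n_quantiles ComBat quantile count.
#' @param folds,n_seeds evaluation protocol sizes.
#' @param seed master seed.
#' @param reference_centre HM/PLHM reference centre; `NULL` = largest.
#' @param train_centres centres to train generalisation models on.
#' @param centre_id_orders,centre_id_rois centre-ID protocol grid.
#' @param phase phase used by the classification protocols.
#' @param resample_to in-plane target spacing (mm).
#' @param mode texture extraction mode, `"3D"` or `"2D"`.
#' @param tasks character subset of `c("variability", "centre_id",
#'   "generalisation")` to run.
#' @param out_dir optional output directory for [render_report()].
#' @return A validated `run_config`.
#' @export
run_config <- function(cohort = cohort_spec(),
                       profiles = default_centre_profiles(),
                       methods = default_method_grid(),
                       combat = c(FALSE, TRUE),
                       bin_width_raw = 25, bin_width_norm = 0.05,
                       tau = 0.01, r2_threshold = 0.9, n_quantiles = 20L,
                       folds = 5L, n_seeds = 5L, seed = 1L,
                       reference_centre = NULL,
                       train_centres = c("SagradaFamilia", "VallHebron"),
                       centre_id_orders = c("first", "second"),
                       centre_id_rois = c("LV", "MYO", "RV"),
                       phase = "ED", resample_to = c(1, 1), mode = "3D",
                       tasks = c("variability", "centre_id", "generalisation"),
                       out_dir = NULL) {
  cfg <- structure(as.list(environment()), class = "run_config")
  validate_run_config(cfg)
}

#' @rdname run_config
#' @export
default_method_grid <- function() {
  data.frame(
    method = c("O", "R", "N", "HM", "PLHM", "R", "N", "HM", "PLHM"),
    scope = c("none", rep("whole", 4), rep("roi", 4)),
    stringsAsFactors = FALSE
  )
}

validate_run_config <- function(cfg) {
  ok_m <- c("O", "R", "N", "HM", "PLHM")
  bad <- setdiff(cfg$methods$method, ok_m)
  if (length(bad))
    rh_abort(paste("unknown normalisation method:", paste(bad, collapse = ", ")),
             "radharm_bad_config")
  if (any(cfg$methods$scope[cfg$methods$method != "O"] %in% "none") ||
      !all(cfg$methods$scope %in% c("none", "whole", "roi")))
    rh_abort("scope must be 'whole' or 'roi' ('none' only for O)",
             "radharm_bad_config")
  if (!is_scalar_number(cfg$seed))
    rh_abort("seed is mandatory", "radharm_bad_config")
  for (fld in c("bin_width_raw", "bin_width_norm", "tau", "r2_threshold"))
    if (!is_scalar_number(cfg[[fld]]) || cfg[[fld]] <= 0)
      rh_abort(paste(fld, "must be a positive number"), "radharm_bad_config")
  stopifnot(all(cfg$tasks %in% c("variability", "centre_id", "generalisation")))
  cfg
}

method_key <- function(method, scope) {
  if (method == "O") "O" else if (scope == "roi")
    paste0("R.", method) else method
}

#' Run the full pipeline on a synthetic cohort
#'
#' Generates the cohort, resamples in-plane, fits normalisation references on
#' the reference centre, and for every (method, scope) x ComBat cell extracts
#' features and runs the requested analyses. Deterministic under the config
#' seed: rerunning an identical config reproduces the bundle.
#'
#' @param config a [run_config()].
#' @param studies optional pre-generated cohort (skips generation; must match
#'   the config's cohort spec).
#' @return A `report_bundle`: list with `config`, `manifest`, `cells` (one
#'   entry per grid cell with `variability`, `centre_id`, `generalisation`),
#'   and `features` (per method-key [feature_table]s).
#' @export
run_pipeline <- function(config = run_config(), studies = NULL) {
  config <- validate_run_config(config)
  if (is.null(studies))
    studies <- generate_cohort(config$cohort, config$profiles)
  studies <- lapply(studies, resample_inplane, target = config$resample_to)

  centres <- vapply(studies, `[[`, "", "centre_id")
  ref_centre <- config$reference_centre
  if (is.null(ref_centre)) ref_centre <- names(which.max(table(centres)))

  cells <- list()
  features <- list()
  for (i in seq_len(nrow(config$methods))) {
    method <- config$methods$method[i]
    scope <- config$methods$scope[i]
    key <- method_key(method, scope)
    fitted <- if (method %in% c("HM", "PLHM"))
      fit_normalisation(studies, method, scope, ref_centre) else NULL
    norm_studies <- if (method == "O") studies else
      lapply(studies, function(s)
        suppressWarnings(apply_normalisation(s, method, scope, fitted)))
    W <- if (method == "O") config$bin_width_raw else config$bin_width_norm
    ft <- extract_cohort(norm_studies, W, mode = config$mode,
                         resample_to = NULL)
    features[[key]] <- ft
    for (cb in config$combat) {
      tbl <- if (cb) {
        h <- harmonise_features(ft, K = config$n_quantiles)
        features[[paste0(key, "+combat")]] <- h$table
        h$table
      } else ft
      cell <- list(method = method, scope = scope, combat = cb, key = key)
      if ("variability" %in% config$tasks)
        cell$variability <- suppressWarnings(variability_analysis(
          tbl, tau = config$tau, r2_threshold = config$r2_threshold))
      if ("centre_id" %in% config$tasks) {
        grid <- expand.grid(order = config$centre_id_orders,
                            roi = config$centre_id_rois,
                            stringsAsFactors = FALSE)
        cell$centre_id <- lapply(seq_len(nrow(grid)), function(g)
          centre_id_protocol(tbl, cohort = "healthy",
                             order = grid$order[g], roi = grid$roi[g],
                             phase = config$phase, folds = config$folds,
                             seed = config$seed))
        names(cell$centre_id) <- paste(grid$order, grid$roi, sep = ".")
      }
      if ("generalisation" %in% config$tasks)
        cell$generalisation <- stats::setNames(lapply(
          config$train_centres, function(tc)
            generalisation_protocol(tbl, tc, n_seeds = config$n_seeds,
                                    folds = config$folds,
                                    phase = config$phase,
                                    seed = config$seed)),
          config$train_centres)
      cells[[paste0(key, if (cb) "+combat" else "")]] <- cell
    }
  }
  structure(
    list(config = config, manifest = bundle_manifest(config),
         cells = cells, features = features),
    class = "report_bundle"
  )
}

bundle_manifest <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  fields <- sort(setdiff(names(unclass(config)), "out_dir"))
  writeLines(deparse(unclass(config)[fields]), tmp)
  list(config_hash = unname(tools::md5sum(tmp)),
       seed = config$seed,
       package_version = as.character(utils::packageVersion("radharm")),
       n_cells = nrow(config$methods) * length(config$combat))
}

#' Render a report bundle as comparison tables
#'
#' @param bundle a `report_bundle` from [run_pipeline()].
#' @param out_dir directory for CSV output; `NULL` (default) returns the
#'   tables without writing.
#' @return List of data.frames: `summary` (one row per grid cell with the %
#'   of features below tau per order/phase, centre-ID and generalisation
#'   balanced accuracies) and `families` (per-family JSD mean/SD table).
#' @export
render_report <- function(bundle, out_dir = bundle$config$out_dir) {
  rows <- list()
  fams <- list()
  for (nm in names(bundle$cells)) {
    cell <- bundle$cells[[nm]]
    row <- data.frame(cell = nm, method = cell$method, scope = cell$scope,
                      combat = cell$combat, stringsAsFactors = FALSE)
    if (!is.null(cell$variability)) {
      bt <- cell$variability$below_tau
      for (k in seq_len(nrow(bt))) {
        tag <- paste0("pct_below_tau_", bt$order[k], "_", bt$phase[k])
        row[[tag]] <- bt$pct_below_mean[k]
        row[[paste0(tag, "_sd")]] <- bt$pct_below_sd[k]
      }
      f <- cell$variability$family_table
      f$cell <- nm
      fams[[nm]] <- f
    }
    if (!is.null(cell$centre_id)) {
      accs <- vapply(cell$centre_id, `[[`, 0, "mean_accuracy")
      row$centre_id_mean <- mean(accs)
      for (k in names(cell$centre_id))
        row[[paste0("centre_id_", k)]] <- cell$centre_id[[k]]$mean_accuracy
    }
    if (!is.null(cell$generalisation)) {
      for (tc in names(cell$generalisation)) {
        r <- cell$generalisation[[tc]]
        row[[paste0("gen_val_", tc)]] <- r$validation_mean
        row[[paste0("gen_test_", tc)]] <- r$mean_accuracy
        row[[paste0("gen_test_sd_", tc)]] <- r$sd_accuracy
      }
    }
    rows[[nm]] <- row
  }
  all_cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    r[setdiff(all_cols, names(r))] <- NA
    r[all_cols]
  })
  out <- list(summary = do.call(rbind, c(rows, list(make.row.names = FALSE))),
              families = if (length(fams))
                do.call(rbind, c(fams, list(make.row.names = FALSE))) else NULL,
              manifest = bundle$manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out$summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    if (!is.null(out$families))
      utils::write.csv(out$families, file.path(out_dir, "families.csv"),
                       row.names = FALSE)
    jsonlite::write_json(bundle$manifest,
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("<report_bundle> %d cells, seed %d, config %s\n",
              length(x$cells), x$manifest$seed, x$manifest$config_hash))
  invisible(x)
}
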