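#' Balanced accuracy
#'
#' Mean of per-class recalls over the classes present in `y_true`; robust to
#' class imbalance. Classes that are only predicted (never true) are ignored.
#'
#' @param y_true,y_pred label vectors of equal length.
#' @return Balanced accuracy in `[0, 1]`.
#' @export
balanced_accuracy <- function(y_true, y_pred) {
  if (!length(y_true) || length(y_true) != length(y_pred))
    rh_abort("labels must be non-empty and of equal length",
             "radharm_bad_input")
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  mean(vapply(unique(y_true), function(cl)
    mean(y_pred[y_true == cl] == cl), 0))
}

# Stratified k-fold assignment; deterministic under the current RNG state.
stratified_folds <- function(strata, k) {
  fold <- integer(length(strata))
  for (s in unique(strata)) {
    idx <- which(strata == s)
    if (length(idx) < k)
      rh_abort(sprintf(
        "stratum '%s' has %d subjects, fewer than %d folds; reduce folds",
        s, length(idx), k), "radharm_small_stratum")
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

rf_fit <- function(x, y, ntree = 500L) {
  randomForest::randomForest(
    x = as.data.frame(x), y = factor(y), ntree = ntree,
    mtry = max(1L, floor(sqrt(ncol(x)))), importance = FALSE
  )
}

rf_importance <- function(model) {
  imp <- model$importance[, "MeanDecreaseGini"]
  s <- sum(imp)
  if (s > 0) imp / s else imp
}

#' Centre-identification protocol
#'
#' How much centre-of-origin signal a feature set carries: a random forest
#' (500 trees, sqrt(p) variables per split) predicts the acquisition centre
#' under stratified 5-fold cross-validation, restricted to one feature order
#' and one ROI, on one patient cohort (healthy by default). Balanced
#' accuracy per fold; lower is better (less centre information).
#'
#' @param table a [feature_table].
#' @param cohort `"healthy"`, `"HCM"` or `"all"`.
#' @param order `"first"` or `"second"`.
#' @param roi `"LV"`, `"MYO"` or `"RV"`.
#' @param phase cardiac phase used (default `"ED"`).
#' @param folds number of CV folds (default 5).
#' @param seed RNG seed fixed before fold assignment and training.
#' @return An `eval_report` (task `"centre_id"`).
#' @export
centre_id_protocol <- function(table, cohort = c("healthy", "HCM", "all"),
                               order = c("first", "second"),
                               roi = c("LV", "MYO", "RV"),
                               phase = "ED", folds = 5L, seed = 1L) {
  cohort <- match.arg(cohort)
  order <- match.arg(order)
  roi <- match.arg(roi)
  rows <- table$row_meta$phase == phase
  if (cohort != "all") rows <- rows & table$row_meta$pathology == cohort
  sub <- ft_subset(table, rows = rows, roi = roi, order = order)
  centres <- sub$row_meta$centre
  if (length(unique(centres)) < 2L)
    rh_abort("need >= 2 centres", "radharm_bad_input")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold <- stratified_folds(centres, folds)
  ba <- numeric(folds)
  imps <- matrix(0, folds, ncol(sub$matrix),
                 dimnames = list(NULL, colnames(sub$matrix)))
  for (f in seq_len(folds)) {
    tr <- fold != f
    model <- rf_fit(sub$matrix[tr, , drop = FALSE], centres[tr])
    pred <- stats::predict(model,
                           as.data.frame(sub$matrix[!tr, , drop = FALSE]))
    ba[f] <- balanced_accuracy(centres[!tr], as.character(pred))
    imps[f, ] <- rf_importance(model)
  }
  new_eval_report(
    task = "centre_id", folds = folds, seeds = seed,
    per_fold = data.frame(fold = seq_len(folds), balanced_accuracy = ba),
    mean_accuracy = mean(ba), sd_accuracy = stats::sd(ba),
    chance = 1 / length(unique(centres)),
    importances = colMeans(imps), col_meta = sub$col_meta,
    grouping = list(cohort = cohort, order = order, roi = roi, phase = phase)
  )
}

#' Cross-centre generalisation protocol
#'
#' Disease classification (healthy vs HCM) trained on a single centre and
#' tested on all others: for each of `n_seeds` seeds, class-stratified
#' 5-fold CV inside the training centre gives a validation balanced accuracy
#' per fold, and each fold's model is evaluated on the pooled held-out-centre
#' subjects (test balanced accuracy). Inputs are first plus second order
#' features from all three ROIs, with no prior feature selection.
#'
#' @param table a [feature_table].
#' @param train_centre centre id to train on.
#' @param n_seeds number of repeated runs (default 5).
#' @param folds CV folds (default 5).
#' @param phase cardiac phase used (default `"ED"`).
#' @param seed base seed; run `s` uses `seed + s - 1`.
#' @return An `eval_report` (task `"generalisation"`) with per-(seed, fold)
#'   validation and test accuracies and a per-centre test breakdown.
#' @export
generalisation_protocol <- function(table, train_centre, n_seeds = 5L,
                                    folds = 5L, phase = "ED", seed = 1L) {
  rows <- table$row_meta$phase == phase
  sub <- ft_subset(table, rows = rows)
  meta <- sub$row_meta
  tr_rows <- meta$centre == train_centre
  if (!any(tr_rows))
    rh_abort(paste("unknown training centre:", train_centre),
             "radharm_bad_input")
  if (length(unique(meta$pathology[tr_rows])) < 2L)
    rh_abort("training centre has a single class", "radharm_bad_input")
  if (all(tr_rows))
    rh_abort("no held-out centres", "radharm_bad_input")
  xtr <- sub$matrix[tr_rows, , drop = FALSE]
  ytr <- meta$pathology[tr_rows]
  xte <- sub$matrix[!tr_rows, , drop = FALSE]
  yte <- meta$pathology[!tr_rows]
  te_centre <- meta$centre[!tr_rows]
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  res <- list()
  imp_acc <- numeric(ncol(xtr))
  per_centre <- list()
  n_models <- 0L
  for (s in seq_len(n_seeds)) {
    set.seed(seed + s - 1L)
    fold <- stratified_folds(ytr, folds)
    for (f in seq_len(folds)) {
      tr <- fold != f
      model <- rf_fit(xtr[tr, , drop = FALSE], ytr[tr])
      pv <- stats::predict(model, as.data.frame(xtr[!tr, , drop = FALSE]))
      pt <- stats::predict(model, as.data.frame(xte))
      res[[length(res) + 1L]] <- data.frame(
        seed = seed + s - 1L, fold = f,
        validation = balanced_accuracy(ytr[!tr], as.character(pv)),
        test = balanced_accuracy(yte, as.character(pt))
      )
      per_centre[[length(per_centre) + 1L]] <- vapply(
        unique(te_centre), function(cn)
          balanced_accuracy(yte[te_centre == cn],
                            as.character(pt)[te_centre == cn]), 0)
      imp_acc <- imp_acc + rf_importance(model)
      n_models <- n_models + 1L
    }
  }
  res <- do.call(rbind, res)
  pc <- colMeans(do.call(rbind, per_centre))
  new_eval_report(
    task = "generalisation", folds = folds, seeds = n_seeds,
    per_fold = res,
    mean_accuracy = mean(res$test), sd_accuracy = stats::sd(res$test),
    validation_mean = mean(res$validation),
    validation_sd = stats::sd(res$validation),
    chance = 0.5,
    per_centre_test = pc,
    importances = imp_acc / n_models, col_meta = sub$col_meta,
    grouping = list(train_centre = train_centre, phase = phase)
  )
}

new_eval_report <- function(...) {
  structure(list(...), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> task = %s (%d folds", x$task, x$folds))
  if (x$task == "generalisation")
    cat(sprintf(" x %d seeds, trained on %s", x$seeds,
                x$grouping$train_centre))
  cat(")\n")
  if (!is.null(x$validation_mean))
    cat(sprintf("  validation balanced accuracy %.3f +/- %.3f\n",
                x$validation_mean, x$validation_sd))
  cat(sprintf("  %s balanced accuracy %.3f +/- %.3f (chance %.2f)\n",
              if (x$task == "generalisation") "test" else "CV",
              x$mean_accuracy, x$sd_accuracy, x$chance))
  invisible(x)
}

#' Top-k feature importances of a protocol run
#'
#' Gini (mean impurity decrease) importances, normalised to sum 1 per model
#' and averaged over folds/seeds, annotated with ROI and family.
#'
#' @param report an `eval_report`.
#' @param k number of features (default 20; truncated with a warning if it
#'   exceeds the feature count).
#' @return data.frame sorted by decreasing importance.
#' @export
feature_importances <- function(report, k = 20L) {
  imp <- report$importances
  if (k > length(imp)) {
    rh_warn(sprintf("k = %d exceeds %d features; truncated", k, length(imp)),
            "radharm_truncated")
    k <- length(imp)
  }
  ord <- order(imp, decreasing = TRUE)[seq_len(k)]
  cm <- report$col_meta[ord, , drop = FALSE]
  data.frame(feature = names(imp)[ord], roi = cm$roi, family = cm$family,
             importance = unname(imp[ord]), stringsAsFactors = FALSE)
}
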