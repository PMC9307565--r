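#' Construct a feature table
#'
#' A `feature_table` is a subjects-by-features numeric matrix plus row
#' metadata (subject, centre, pathology, phase) and column metadata (ROI,
#' feature family, feature name, order). Columns follow the canonical
#' ordering: ROI (LV, MYO, RV), then family (firstorder, glcm, gldm, glrlm,
#' glszm), then alphabetical feature name — fixed because the sequential
#' correlation filter is order-dependent.
#'
#' @param matrix numeric matrix, one row per (subject, phase).
#' @param row_meta data.frame with columns `subject_id`, `centre`,
#'   `pathology`, `phase`; one row per matrix row.
#' @param col_meta data.frame with columns `name`, `roi`, `family`,
#'   `feature`, `order`; one row per matrix column. If `NULL`, reconstructed
#'   from `colnames(matrix)` of the form `ROI_family_Feature`.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(matrix, row_meta, col_meta = NULL) {
  matrix <- as.matrix(matrix)
  if (nrow(row_meta) != nrow(matrix))
    rh_abort("row_meta rows must match matrix rows", "radharm_bad_table")
  need <- c("subject_id", "centre", "pathology", "phase")
  if (!all(need %in% names(row_meta)))
    rh_abort(paste("row_meta must contain:", paste(need, collapse = ", ")),
             "radharm_bad_table")
  if (is.null(col_meta)) col_meta <- parse_feature_names(colnames(matrix))
  if (nrow(col_meta) != ncol(matrix))
    rh_abort("col_meta rows must match matrix columns", "radharm_bad_table")
  if (anyDuplicated(col_meta$name))
    rh_abort("duplicate feature names", "radharm_bad_table")
  colnames(matrix) <- col_meta$name
  structure(
    list(matrix = matrix,
         row_meta = as.data.frame(row_meta, stringsAsFactors = FALSE),
         col_meta = as.data.frame(col_meta, stringsAsFactors = FALSE)),
    class = "feature_table"
  )
}

feature_families <- c("firstorder", "glcm", "gldm", "glrlm", "glszm")

parse_feature_names <- function(nm) {
  parts <- strsplit(nm, "_", fixed = TRUE)
  if (any(lengths(parts) != 3L))
    rh_abort("feature names must have the form ROI_family_Feature",
             "radharm_bad_table")
  roi <- vapply(parts, `[[`, "", 1L)
  fam <- vapply(parts, `[[`, "", 2L)
  feat <- vapply(parts, `[[`, "", 3L)
  if (!all(fam %in% feature_families))
    rh_abort("unknown feature family in column names", "radharm_bad_table")
  data.frame(
    name = nm, roi = roi, family = fam, feature = feat,
    order = ifelse(fam == "firstorder", "first", "second"),
    stringsAsFactors = FALSE
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf(
    "<feature_table> %d rows x %d features (%d ROI x %d families)\n",
    nrow(x$matrix), ncol(x$matrix),
    length(unique(x$col_meta$roi)), length(unique(x$col_meta$family))
  ))
  cat("  centres:", paste(sort(unique(x$row_meta$centre)), collapse = ", "), "\n")
  cat("  classes:", paste(sort(unique(x$row_meta$pathology)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.feature_table <- function(object, ...) {
  with(object, list(
    n_rows = nrow(matrix), n_features = ncol(matrix),
    centres = table(row_meta$centre, row_meta$pathology),
    families = table(col_meta$roi, col_meta$family),
    n_missing = sum(is.na(matrix))
  ))
}

#' Subset a feature table
#'
#' @param table a [feature_table].
#' @param rows logical/integer row index (optional).
#' @param roi,order,family restrict columns to the given ROI(s), feature
#'   order(s) (`"first"`/`"second"`) or family(ies); `NULL` keeps all.
#' @return A [feature_table].
#' @export
ft_subset <- function(table, rows = NULL, roi = NULL, order = NULL, family = NULL) {
  keep <- rep(TRUE, ncol(table$matrix))
  if (!is.null(roi)) keep <- keep & table$col_meta$roi %in% roi
  if (!is.null(order)) keep <- keep & table$col_meta$order %in% order
  if (!is.null(family)) keep <- keep & table$col_meta$family %in% family
  m <- table$matrix[, keep, drop = FALSE]
  rm <- table$row_meta
  if (!is.null(rows)) {
    m <- m[rows, , drop = FALSE]
    rm <- rm[rows, , drop = FALSE]
  }
  feature_table(m, rm, table$col_meta[keep, , drop = FALSE])
}

#' Write / read a feature table as CSV
#'
#' Metadata columns are written first with a `meta_` prefix so they cannot
#' collide with feature names; the round trip reproduces the table to
#' near machine precision.
#'
#' @param table a [feature_table] with no missing values.
#' @param path CSV path.
#' @return `write_feature_table` invisibly returns `path`;
#'   `read_feature_table` returns the [feature_table].
#' @export
write_feature_table <- function(table, path) {
  if (anyNA(table$matrix)) {
    idx <- which(is.na(table$matrix), arr.ind = TRUE)[1, ]
    rh_abort(sprintf("missing value at row %d (%s), column %s",
                     idx[1], table$row_meta$subject_id[idx[1]],
                     colnames(table$matrix)[idx[2]]),
             "radharm_missing_values")
  }
  df <- cbind(
    stats::setNames(table$row_meta[, c("subject_id", "centre", "pathology", "phase")],
                    c("meta_subject_id", "meta_centre", "meta_pathology", "meta_phase")),
    as.data.frame(format(table$matrix, digits = 17, trim = TRUE, scientific = NA),
                  stringsAsFactors = FALSE)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  meta_cols <- c("meta_subject_id", "meta_centre", "meta_pathology", "meta_phase")
  feat_cols <- setdiff(names(df), meta_cols)
  m <- as.matrix(as.data.frame(lapply(df[feat_cols], as.numeric)))
  colnames(m) <- feat_cols
  rm <- stats::setNames(df[meta_cols],
                        c("subject_id", "centre", "pathology", "phase"))
  feature_table(m, rm)
}
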