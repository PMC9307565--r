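#' Fixed-bin-width gray-level discretisation
#'
#' `level(x) = floor((x - min(x)) / W) + 1`, anchoring the first bin at the
#' ROI minimum, so the level image is invariant to intensity shifts of the
#' ROI. Bin widths of 25 (raw images) and 0.05 (after normalisation) are the
#' conventional defaults.
#'
#' @param values numeric vector of in-ROI intensities.
#' @param W bin width, > 0.
#' @return Integer vector of levels (1..Ng) with attributes `Ng`, `bin_width`
#'   and `min` (the anchor).
#' @export
discretise <- function(values, W) {
  if (!is_scalar_number(W) || W <= 0)
    rh_abort("bin width must be a positive number", "radharm_bad_input")
  if (!length(values) || any(!is.finite(values)))
    rh_abort("discretise needs finite values", "radharm_bad_input")
  lv <- as.integer(floor((values - min(values)) / W)) + 1L
  ng <- max(lv)
  if (ng > 1000L)
    rh_warn(sprintf("%d gray levels after discretisation; check bin width", ng),
            "radharm_many_levels")
  structure(lv, Ng = ng, bin_width = W, min = min(values))
}

#' Discretise one ROI of a study for texture analysis
#'
#' @param study an [image_study].
#' @param roi ROI name or integer label.
#' @param W bin width.
#' @return A `discretised_roi`: the 3D level array (0 outside the ROI), the
#'   raw in-ROI intensities, `Ng` and bookkeeping fields.
#' @export
discretise_roi <- function(study, roi, W) {
  lab <- if (is.character(roi)) roi_labels[[roi]] else as.integer(roi)
  raw <- roi_sample(study, roi)
  lv <- discretise(as.numeric(raw), W)
  arr <- array(0L, dim(study$voxels))
  arr[study$mask == lab] <- lv
  structure(
    list(levels = arr, raw = as.numeric(raw), Ng = attr(lv, "Ng"),
         bin_width = W, roi = names(roi_labels)[match(lab, roi_labels)],
         n_voxels = length(raw), spacing = study$spacing),
    class = "discretised_roi"
  )
}

# --- direction sets -------------------------------------------------------

# Unique 3D directions up to sign (13) or in-plane 2D directions (4).
# Offsets are (row, col, slice) steps.
texture_directions <- function(mode = c("3D", "2D")) {
  mode <- match.arg(mode)
  if (mode == "2D") {
    return(list(c(0L, 1L, 0L), c(1L, 0L, 0L), c(1L, 1L, 0L), c(1L, -1L, 0L)))
  }
  dirs <- list()
  for (ds in -1:1) for (dr in -1:1) for (dc in -1:1) {
    d <- c(dr, dc, ds)
    if (all(d == 0L)) next
    # keep one representative per +/- pair: first non-zero component positive
    nz <- d[d != 0L][1]
    if (nz > 0) dirs[[length(dirs) + 1L]] <- as.integer(d)
  }
  dirs
}

# S[v] = L[v + d], 0 where v + d is out of bounds.
shift_arr <- function(L, d) {
  dm <- dim(L)
  S <- array(0L, dm)
  idx <- vector("list", 3)
  src <- vector("list", 3)
  for (ax in 1:3) {
    n <- dm[ax]
    if (abs(d[ax]) >= n) return(S)
    if (d[ax] >= 0) {
      idx[[ax]] <- seq_len(n - d[ax])
      src[[ax]] <- seq_len(n - d[ax]) + d[ax]
    } else {
      idx[[ax]] <- seq.int(1 - d[ax], n)
      src[[ax]] <- seq_len(n + d[ax])
    }
  }
  S[idx[[1]], idx[[2]], idx[[3]]] <- L[src[[1]], src[[2]], src[[3]]]
  S
}

new_texture_matrix <- function(kind, m, d, extra = list()) {
  structure(c(list(kind = kind, matrix = m, Ng = d$Ng,
                   n_voxels = d$n_voxels, roi = d$roi), extra),
            class = "texture_matrix")
}

#' @export
print.texture_matrix <- function(x, ...) {
  cat(sprintf("<texture_matrix> %s  %d x %d (Ng = %d, %d ROI voxels)\n",
              x$kind, nrow(x$matrix), ncol(x$matrix), x$Ng, x$n_voxels))
  invisible(x)
}

#' Gray-level co-occurrence matrix
#'
#' Counts co-occurring level pairs at each offset, restricted to voxel pairs
#' both inside the ROI, symmetrised (by adding the transpose) and summed over
#' the direction set.
#'
#' @param d a `discretised_roi`.
#' @param directions list of integer offsets; default all 13 unique 3D
#'   directions (or 4 in-plane for `mode = "2D"`).
#' @param symmetric logical, symmetrise per offset (default `TRUE`).
#' @param mode `"3D"` or `"2D"` (used when `directions` is `NULL`).
#' @return A `texture_matrix` of kind `"GLCM"` (Ng x Ng counts).
#' @export
glcm <- function(d, directions = NULL, symmetric = TRUE,
                 mode = c("3D", "2D")) {
  if (is.null(directions)) directions <- texture_directions(match.arg(mode))
  L <- d$levels
  ng <- d$Ng
  if (ng > 2000L)
    rh_abort(sprintf(
      "%d gray levels would need a %dx%d co-occurrence matrix; check bin width",
      ng, ng, ng), "radharm_many_levels")
  M <- matrix(0, ng, ng)
  for (dir in directions) {
    S <- shift_arr(L, dir)
    ok <- L > 0L & S > 0L
    if (!any(ok)) next
    a <- L[ok]; b <- S[ok]
    tab <- tabulate((b - 1L) * ng + a, nbins = ng * ng)
    M <- M + matrix(tab, ng, ng)
  }
  if (sum(M) == 0)
    rh_abort("no valid co-occurring voxel pairs in ROI", "radharm_empty_roi")
  if (symmetric) M <- M + t(M)
  new_texture_matrix("GLCM", M, d,
                     list(n_directions = length(directions)))
}

#' Gray-level run-length matrix
#'
#' Counts maximal runs of identical gray level along each direction, summed
#' over the direction set. Runs are confined to the ROI.
#'
#' @inheritParams glcm
#' @return A `texture_matrix` of kind `"GLRLM"` (Ng x max-run-length counts).
#' @export
glrlm <- function(d, directions = NULL, mode = c("3D", "2D")) {
  if (is.null(directions)) directions <- texture_directions(match.arg(mode))
  L <- d$levels
  dm <- dim(L)
  ng <- d$Ng
  counts <- list()  # accumulate (level, length) pairs
  maxlen <- 1L
  acc <- matrix(0, ng, max(dm))
  for (dir in directions) {
    prev <- shift_arr(L, -dir)
    startv <- which(L > 0L & prev != L)
    if (!length(startv)) next
    # coordinates of run heads
    co <- arrayInd(startv, dm)
    lev <- L[startv]
    len <- rep(1L, length(startv))
    active <- seq_along(startv)
    pos <- co
    while (length(active)) {
      nxt <- pos[active, , drop = FALSE] +
        matrix(dir, length(active), 3, byrow = TRUE)
      inb <- nxt[, 1] >= 1 & nxt[, 1] <= dm[1] &
        nxt[, 2] >= 1 & nxt[, 2] <= dm[2] &
        nxt[, 3] >= 1 & nxt[, 3] <= dm[3]
      cont <- logical(length(active))
      if (any(inb)) {
        lin <- nxt[inb, 1] + (nxt[inb, 2] - 1L) * dm[1] +
          (nxt[inb, 3] - 1L) * dm[1] * dm[2]
        cont[inb] <- L[lin] == lev[active][inb]
      }
      keep <- active[cont]
      if (length(keep)) {
        len[keep] <- len[keep] + 1L
        pos[keep, ] <- pos[keep, , drop = FALSE] +
          matrix(dir, length(keep), 3, byrow = TRUE)
      }
      active <- keep
    }
    acc <- acc + matrix(
      tabulate((len - 1L) * ng + lev, nbins = ng * ncol(acc)),
      ng, ncol(acc))
  }
  maxlen <- max(1L, which(colSums(acc) > 0))
  new_texture_matrix("GLRLM", acc[, seq_len(maxlen), drop = FALSE], d,
                     list(n_directions = length(directions)))
}

#' Gray-level size-zone matrix
#'
#' Counts connected zones of identical gray level by level and zone size;
#' connectivity is 26-neighbour in 3D (8-neighbour in-plane for 2D mode).
#'
#' @inheritParams glcm
#' @return A `texture_matrix` of kind `"GLSZM"` (Ng x max-zone-size counts).
#' @export
glszm <- function(d, mode = c("3D", "2D")) {
  mode <- match.arg(mode)
  dirs <- texture_directions(mode)
  L <- d$levels
  dm <- dim(L)
  ng <- d$Ng
  zone_sizes <- vector("list", ng)
  for (g in seq_len(ng)) {
    idx <- which(L == g)
    if (!length(idx)) next
    co <- arrayInd(idx, dm)
    from <- integer(0); to <- integer(0)
    for (dir in dirs) {
      nbr <- co + matrix(dir, nrow(co), 3, byrow = TRUE)
      inb <- nbr[, 1] >= 1 & nbr[, 1] <= dm[1] &
        nbr[, 2] >= 1 & nbr[, 2] <= dm[2] &
        nbr[, 3] >= 1 & nbr[, 3] <= dm[3]
      if (!any(inb)) next
      lin <- nbr[inb, 1] + (nbr[inb, 2] - 1L) * dm[1] +
        (nbr[inb, 3] - 1L) * dm[1] * dm[2]
      hit <- match(lin, idx)
      ok <- !is.na(hit)
      from <- c(from, which(inb)[ok])
      to <- c(to, hit[ok])
    }
    if (length(from)) {
      gr <- igraph::make_graph(as.vector(rbind(from, to)), n = length(idx),
                               directed = FALSE)
      zone_sizes[[g]] <- igraph::components(gr)$csize
    } else {
      zone_sizes[[g]] <- rep(1L, length(idx))
    }
  }
  maxs <- max(1L, unlist(zone_sizes))
  M <- matrix(0, ng, maxs)
  for (g in seq_len(ng)) {
    zs <- zone_sizes[[g]]
    if (length(zs)) M[g, ] <- M[g, ] + tabulate(zs, nbins = maxs)
  }
  new_texture_matrix("GLSZM", M, d)
}

#' Gray-level dependence matrix
#'
#' For every ROI voxel, counts neighbours (26-connectivity in 3D, 8 in 2D)
#' whose level differs by at most `alpha`; voxels are tallied by gray level
#' and dependence count (dependent neighbours + 1, so the smallest dependence
#' is 1, the voxel itself).
#'
#' @inheritParams glcm
#' @param alpha dependence tolerance on the level difference; default 0.
#' @return A `texture_matrix` of kind `"GLDM"` (Ng x max-dependence counts).
#' @export
gldm <- function(d, alpha = 0, mode = c("3D", "2D")) {
  mode <- match.arg(mode)
  half <- texture_directions(mode)
  dirs <- c(half, lapply(half, function(x) -x))
  L <- d$levels
  ng <- d$Ng
  dep <- array(0L, dim(L))
  for (dir in dirs) {
    S <- shift_arr(L, dir)
    dep <- dep + (L > 0L & S > 0L & abs(S - L) <= alpha)
  }
  inroi <- L > 0L
  j <- dep[inroi] + 1L  # dependence count includes the voxel itself
  lev <- L[inroi]
  maxj <- max(j)
  M <- matrix(tabulate((j - 1L) * ng + lev, nbins = ng * maxj), ng, maxj)
  new_texture_matrix("GLDM", M, d, list(alpha = alpha))
}
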