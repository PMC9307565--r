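# Independent brute-force oracles, written against the definitions only
# (plain loops; no code shared with the package implementation).

# all 26 unit offsets / their 13 representatives, as the package defines them
oracle_dirs_half <- function(mode = "3D") {
  dirs <- list()
  rng <- if (mode == "2D") 0L else -1:1
  for (ds in rng) for (dr in -1:1) for (dc in -1:1) {
    d <- c(dr, dc, ds)
    if (all(d == 0)) next
    nz <- d[d != 0][1]
    if (nz > 0) dirs[[length(dirs) + 1]] <- d
  }
  dirs
}

inside <- function(co, dm) all(co >= 1) && all(co <= dm)

# co-occurrence counts by exhaustive voxel-pair enumeration
bf_glcm <- function(L, dirs, symmetric = TRUE) {
  dm <- dim(L)
  ng <- max(L)
  M <- matrix(0, ng, ng)
  for (r in 1:dm[1]) for (c in 1:dm[2]) for (s in 1:dm[3]) {
    a <- L[r, c, s]
    if (a == 0) next
    for (d in dirs) {
      co <- c(r, c, s) + d
      if (!inside(co, dm)) next
      b <- L[co[1], co[2], co[3]]
      if (b == 0) next
      M[a, b] <- M[a, b] + 1
    }
  }
  if (symmetric) M <- M + t(M)
  M
}

# maximal runs by walking each line voxel by voxel
bf_glrlm <- function(L, dirs) {
  dm <- dim(L)
  ng <- max(L)
  M <- matrix(0, ng, max(dm))
  for (d in dirs) {
    for (r in 1:dm[1]) for (c in 1:dm[2]) for (s in 1:dm[3]) {
      a <- L[r, c, s]
      if (a == 0) next
      prev <- c(r, c, s) - d
      if (inside(prev, dm) && L[prev[1], prev[2], prev[3]] == a) next
      len <- 1
      nxt <- c(r, c, s) + d
      while (inside(nxt, dm) && L[nxt[1], nxt[2], nxt[3]] == a) {
        len <- len + 1
        nxt <- nxt + d
      }
      M[a, len] <- M[a, len] + 1
    }
  }
  M[, seq_len(max(1, which(colSums(M) > 0))), drop = FALSE]
}

# connected zones by breadth-first flood fill (26- or 8-connectivity)
bf_glszm <- function(L, mode = "3D") {
  dm <- dim(L)
  ng <- max(L)
  half <- oracle_dirs_half(mode)
  dirs <- c(half, lapply(half, function(x) -x))
  seen <- array(FALSE, dm)
  sizes <- list()
  for (r in 1:dm[1]) for (c in 1:dm[2]) for (s in 1:dm[3]) {
    a <- L[r, c, s]
    if (a == 0 || seen[r, c, s]) next
    queue <- list(c(r, c, s))
    seen[r, c, s] <- TRUE
    size <- 0
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      size <- size + 1
      for (d in dirs) {
        w <- v + d
        if (inside(w, dm) && !seen[w[1], w[2], w[3]] &&
            L[w[1], w[2], w[3]] == a) {
          seen[w[1], w[2], w[3]] <- TRUE
          queue[[length(queue) + 1]] <- w
        }
      }
    }
    sizes[[length(sizes) + 1]] <- c(a, size)
  }
  maxs <- max(vapply(sizes, `[`, 0, 2))
  M <- matrix(0, ng, maxs)
  for (z in sizes) M[z[1], z[2]] <- M[z[1], z[2]] + 1
  M
}

# dependence counts by per-voxel neighbour scan
bf_gldm <- function(L, alpha = 0, mode = "3D") {
  dm <- dim(L)
  ng <- max(L)
  half <- oracle_dirs_half(mode)
  dirs <- c(half, lapply(half, function(x) -x))
  recs <- list()
  for (r in 1:dm[1]) for (c in 1:dm[2]) for (s in 1:dm[3]) {
    a <- L[r, c, s]
    if (a == 0) next
    dep <- 0
    for (d in dirs) {
      w <- c(r, c, s) + d
      if (inside(w, dm) && L[w[1], w[2], w[3]] != 0 &&
          abs(L[w[1], w[2], w[3]] - a) <= alpha) dep <- dep + 1
    }
    recs[[length(recs) + 1]] <- c(a, dep + 1)
  }
  maxj <- max(vapply(recs, `[`, 0, 2))
  M <- matrix(0, ng, maxj)
  for (z in recs) M[z[1], z[2]] <- M[z[1], z[2]] + 1
  M
}

# direct bilinear interpolation on the corner-aligned grid convention
bf_bilinear_slice <- function(slice, d_in, d_out) {
  n_in <- dim(slice)
  n_out <- sapply(1:2, function(ax) floor((n_in[ax] - 1) * d_in[ax] / d_out[ax] + 1e-9) + 1)
  out <- matrix(0, n_out[1], n_out[2])
  for (i in 1:n_out[1]) for (j in 1:n_out[2]) {
    y <- min(max((i - 1) * d_out[1] / d_in[1] + 1, 1), n_in[1])
    x <- min(max((j - 1) * d_out[2] / d_in[2] + 1, 1), n_in[2])
    y0 <- min(floor(y), n_in[1] - 1); x0 <- min(floor(x), n_in[2] - 1)
    if (n_in[1] == 1) y0 <- 1
    if (n_in[2] == 1) x0 <- 1
    fy <- y - y0; fx <- x - x0
    y1 <- min(y0 + 1, n_in[1]); x1 <- min(x0 + 1, n_in[2])
    out[i, j] <- (1 - fy) * (1 - fx) * slice[y0, x0] +
      (1 - fy) * fx * slice[y0, x1] +
      fy * (1 - fx) * slice[y1, x0] +
      fy * fx * slice[y1, x1]
  }
  out
}

# random small discretised ROI for oracle-equivalence fuzzing
random_level_array <- function(dims = c(8, 8, 2), n_levels = 5,
                               p_background = 0.3) {
  arr <- array(sample(0:n_levels, prod(dims), replace = TRUE,
                      prob = c(p_background,
                               rep((1 - p_background) / n_levels, n_levels))),
               dims)
  if (all(arr == 0)) arr[1] <- 1L
  arr
}

# wrap a level array as the package's discretised_roi
as_droi <- function(L, raw = NULL) {
  structure(list(levels = L, raw = if (is.null(raw)) as.numeric(L[L > 0]) else raw,
                 Ng = max(L), bin_width = 1, roi = "LV",
                 n_voxels = sum(L > 0), spacing = c(1, 1, 1)),
            class = "discretised_roi")
}

# small deterministic toy study used across tests
toy_study <- function(seed = 42, n = 24, slices = 2) {
  set.seed(seed)
  vox <- array(runif(n * n * slices, 0, 100), c(n, n, slices))
  msk <- array(0L, c(n, n, slices))
  msk[5:10, 5:10, ] <- 1L
  msk[12:18, 5:12, ] <- 2L
  msk[5:10, 14:20, ] <- 3L
  image_study(vox, msk, spacing = c(1, 1, 10), subject_id = "TOY")
}
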