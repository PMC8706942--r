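# Independent brute-force oracles for the texture-matrix builders and the
# concordance statistic. These deliberately use naive per-voxel loops and a
# different code path from the package implementations.

oracle_offsets13 <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g[g[, 3] > 0 | (g[, 3] == 0 & g[, 2] > 0) |
      (g[, 3] == 0 & g[, 2] == 0 & g[, 1] > 0), , drop = FALSE]
}

.inb <- function(p, d) all(p >= 1) && all(p <= d)

# Symmetric co-occurrence counts per direction; NULL for directions with no
# valid pair.
oracle_glcm <- function(L, ng = max(L, na.rm = TRUE)) {
  d <- dim(L)
  offs <- oracle_offsets13()
  out <- vector("list", nrow(offs))
  for (r in seq_len(nrow(offs))) {
    M <- matrix(0, ng, ng)
    for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
      a <- L[i, j, k]
      if (is.na(a)) next
      q <- c(i, j, k) + offs[r, ]
      if (!.inb(q, d)) next
      b <- L[q[1], q[2], q[3]]
      if (is.na(b)) next
      M[a, b] <- M[a, b] + 1
      M[b, a] <- M[b, a] + 1
    }
    if (sum(M) > 0) out[[r]] <- M
  }
  out
}

# Run-length counts (levels x lengths) per direction by explicit run walks.
oracle_glrlm <- function(L, ng = max(L, na.rm = TRUE)) {
  d <- dim(L)
  offs <- oracle_offsets13()
  out <- vector("list", nrow(offs))
  for (r in seq_len(nrow(offs))) {
    off <- offs[r, ]
    lens <- integer(0)
    levs <- integer(0)
    for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
      a <- L[i, j, k]
      if (is.na(a)) next
      prev <- c(i, j, k) - off
      if (.inb(prev, d) && !is.na(L[prev[1], prev[2], prev[3]]) &&
          L[prev[1], prev[2], prev[3]] == a) next  # continuation, not a start
      len <- 1L
      cur <- c(i, j, k) + off
      while (.inb(cur, d) && !is.na(L[cur[1], cur[2], cur[3]]) &&
             L[cur[1], cur[2], cur[3]] == a) {
        len <- len + 1L
        cur <- cur + off
      }
      lens <- c(lens, len)
      levs <- c(levs, a)
    }
    if (length(lens) > 0) {
      M <- matrix(0, ng, max(lens))
      for (t in seq_along(lens)) M[levs[t], lens[t]] <- M[levs[t], lens[t]] + 1
      out[[r]] <- M
    }
  }
  out
}

# Zone counts (levels x sizes) by BFS flood fill over the 26-neighbourhood.
oracle_glszm <- function(L, ng = max(L, na.rm = TRUE)) {
  d <- dim(L)
  offs <- rbind(oracle_offsets13(), -oracle_offsets13())
  seen <- array(FALSE, dim = d)
  sizes <- integer(0)
  levs <- integer(0)
  coords <- which(!is.na(L), arr.ind = TRUE)
  for (s in seq_len(nrow(coords))) {
    p0 <- coords[s, ]
    if (seen[p0[1], p0[2], p0[3]]) next
    lv <- L[p0[1], p0[2], p0[3]]
    queue <- list(p0)
    seen[p0[1], p0[2], p0[3]] <- TRUE
    size <- 0L
    while (length(queue) > 0) {
      p <- queue[[1]]
      queue <- queue[-1]
      size <- size + 1L
      for (r in seq_len(nrow(offs))) {
        q <- p + offs[r, ]
        if (!.inb(q, d)) next
        if (seen[q[1], q[2], q[3]]) next
        b <- L[q[1], q[2], q[3]]
        if (is.na(b) || b != lv) next
        seen[q[1], q[2], q[3]] <- TRUE
        queue[[length(queue) + 1]] <- q
      }
    }
    sizes <- c(sizes, size)
    levs <- c(levs, lv)
  }
  M <- matrix(0, ng, max(sizes))
  for (t in seq_along(sizes)) M[levs[t], sizes[t]] <- M[levs[t], sizes[t]] + 1
  M
}

# Dependence counts (levels x dependence size, centre included) by a naive
# per-voxel neighbourhood scan.
oracle_gldm <- function(L, ng = max(L, na.rm = TRUE), alpha = 0) {
  d <- dim(L)
  offs <- rbind(oracle_offsets13(), -oracle_offsets13())
  levs <- integer(0)
  deps <- integer(0)
  coords <- which(!is.na(L), arr.ind = TRUE)
  for (s in seq_len(nrow(coords))) {
    p <- coords[s, ]
    a <- L[p[1], p[2], p[3]]
    dep <- 0L
    for (r in seq_len(nrow(offs))) {
      q <- p + offs[r, ]
      if (!.inb(q, d)) next
      b <- L[q[1], q[2], q[3]]
      if (!is.na(b) && abs(a - b) <= alpha) dep <- dep + 1L
    }
    levs <- c(levs, a)
    deps <- c(deps, dep + 1L)
  }
  M <- matrix(0, ng, max(deps))
  for (t in seq_along(levs)) M[levs[t], deps[t]] <- M[levs[t], deps[t]] + 1
  M
}

# NGTDM per-level counts n_i and difference sums s_i by per-voxel loops.
oracle_ngtdm <- function(L, ng = max(L, na.rm = TRUE)) {
  d <- dim(L)
  offs <- rbind(oracle_offsets13(), -oracle_offsets13())
  n_i <- integer(ng)
  s_i <- numeric(ng)
  coords <- which(!is.na(L), arr.ind = TRUE)
  for (s in seq_len(nrow(coords))) {
    p <- coords[s, ]
    a <- L[p[1], p[2], p[3]]
    nb <- numeric(0)
    for (r in seq_len(nrow(offs))) {
      q <- p + offs[r, ]
      if (!.inb(q, d)) next
      b <- L[q[1], q[2], q[3]]
      if (!is.na(b)) nb <- c(nb, b)
    }
    if (length(nb) == 0) next
    n_i[a] <- n_i[a] + 1L
    s_i[a] <- s_i[a] + abs(a - mean(nb))
  }
  list(n_i = n_i, s_i = s_i)
}

# Lin's CCC for two matched samples via the Pearson-correlation formula —
# a different algebraic route from the package's moment-form OCCC.
oracle_lin_ccc <- function(x, y) {
  n <- length(x)
  r <- stats::cor(x, y)
  sx <- stats::sd(x) * sqrt((n - 1) / n)
  sy <- stats::sd(y) * sqrt((n - 1) / n)
  2 * r * sx * sy / (sx^2 + sy^2 + (mean(x) - mean(y))^2)
}

# Wrap a level array as a discretized ROI for the matrix builders.
make_droi <- function(arr) {
  stopifnot(length(dim(arr)) == 3)
  structure(list(levels_vec = arr[!is.na(arr)], levels = arr,
                 ng = max(arr, na.rm = TRUE), bin_width = 1,
                 bin_edges = NULL, n_voxels = sum(!is.na(arr))),
            class = "discretized_roi")
}

# Random masked integer level array with at least `min_vox` in-mask voxels.
random_level_array <- function(max_dim = c(5, 5, 3), ng = 4, p_mask = 0.8,
                               min_vox = 3) {
  repeat {
    d <- c(sample(2:max_dim[1], 1), sample(2:max_dim[2], 1),
           sample(1:max_dim[3], 1))
    arr <- array(sample.int(ng, prod(d), replace = TRUE), dim = d)
    arr[stats::runif(prod(d)) > p_mask] <- NA_integer_
    if (sum(!is.na(arr)) >= min_vox) return(arr)
  }
}

# Pad count matrices to a common number of columns before comparison.
pad_cols <- function(M, nc) {
  if (ncol(M) < nc) cbind(M, matrix(0, nrow(M), nc - ncol(M))) else M
}

expect_matrix_lists_equal <- function(got, want, tol = 1e-10) {
  # got/want: lists per direction, NULL where a direction is empty
  stopifnot(length(want) > 0)
  keep_g <- !vapply(got, is.null, logical(1))
  keep_w <- !vapply(want, is.null, logical(1))
  expect_identical(keep_g, keep_w)
  for (i in which(keep_w)) {
    nc <- max(ncol(got[[i]]), ncol(want[[i]]))
    expect_equal(pad_cols(got[[i]], nc), pad_cols(want[[i]], nc),
                 tolerance = tol, ignore_attr = TRUE)
  }
}
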