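# Internal helpers shared by the geometry and texture modules.

# The 13 unique 3D offsets of the 26-neighbourhood (one of each +/- pair),
# as rows (dx, dy, dz). Used for GLCM/GLRLM directions and, together with
# their negations, for the 26-connected neighbourhood scans.
.offsets13 <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  keep <- g[, 3L] > 0L |
    (g[, 3L] == 0L & g[, 2L] > 0L) |
    (g[, 3L] == 0L & g[, 2L] == 0L & g[, 1L] > 0L)
  g[keep, , drop = FALSE]
}

.offsets26 <- function() {
  h <- .offsets13()
  rbind(h, -h)
}

# Value of `a` at each voxel's neighbour v + off; NA where the neighbour
# falls outside the array.
.neighbour_array <- function(a, off) {
  d <- dim(a)
  out <- array(a[c(NA_integer_)], dim = d)  # NA of a's storage mode
  idx <- vector("list", 3L)
  src <- vector("list", 3L)
  for (ax in 1:3) {
    o <- off[ax]
    lo <- max(1L, 1L - o)
    hi <- min(d[ax], d[ax] - o)
    if (lo > hi) return(out)  # offset exceeds this axis extent
    dst <- seq.int(lo, hi)
    idx[[ax]] <- dst
    src[[ax]] <- dst + o
  }
  out[idx[[1L]], idx[[2L]], idx[[3L]]] <- a[src[[1L]], src[[2L]], src[[3L]]]
  out
}

# Deterministic 31-bit seed derived from a master seed and string labels.
# Plain polynomial rolling hash mod (2^31 - 1); doubles keep exact integer
# arithmetic well below 2^53.
.derive_seed <- function(master, ...) {
  s <- paste(c(...), collapse = "\r")
  h <- as.double(master) %% 2147483647
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

.is_count <- function(x) is.numeric(x) && length(x) == 1L && x >= 0 && x == round(x)
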