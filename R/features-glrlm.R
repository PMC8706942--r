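# Gray level run length matrix: maximal runs of equal level along each of
# the 13 unique 3D directions. The run decomposition is vectorized: voxels
# are grouped into lattice lines by the direction's pairwise invariants,
# ordered along the line, and split with a run-length encoding; out-of-mask
# voxels break runs.

#' Build gray level run length matrices
#'
#' @param d A [discretize_fixed_bin_width()] result carrying a 3D level
#'   array.
#' @return An object of class `texture_matrix`, family `"GLRLM"`: one count
#'   matrix (levels x run lengths) per direction, plus the in-mask voxel
#'   count `n_voxels` (mass conservation: `sum(count * length) = n_voxels`
#'   per direction).
#' @export
build_glrlm <- function(d) {
  L <- .require_level_array(d)
  ng <- d$ng
  dm <- dim(L)
  np <- sum(!is.na(L))
  idx0 <- arrayInd(seq_along(L), dm) - 1L  # 0-based voxel coordinates
  I <- idx0[, 1L]; J <- idx0[, 2L]; K <- idx0[, 3L]
  v <- as.vector(L)
  offs <- .offsets13()
  M <- max(dm) + 1L
  B <- 2L * M + 1L
  mats <- list()
  dirs <- list()
  for (r in seq_len(nrow(offs))) {
    dx <- offs[r, 1L]; dy <- offs[r, 2L]; dz <- offs[r, 3L]
    t_along <- I * dx + J * dy + K * dz
    u1 <- I * dy - J * dx
    u2 <- I * dz - K * dx
    u3 <- J * dz - K * dy
    key <- ((u1 + M) * B + (u2 + M)) * B + (u3 + M)
    ord <- order(key, t_along)
    vv <- v[ord]
    kk <- key[ord]
    nain <- is.na(vv)
    newrun <- c(TRUE,
                kk[-1L] != kk[-length(kk)] |
                  nain[-1L] != nain[-length(nain)] |
                  (!nain[-1L] & !nain[-length(nain)] &
                     vv[-1L] != vv[-length(vv)]))
    grp <- cumsum(newrun)
    len <- tabulate(grp)
    lev <- vv[newrun]
    keep <- !is.na(lev)
    len <- len[keep]; lev <- lev[keep]
    if (length(len) == 0L) next
    nr <- max(len)
    mats[[length(mats) + 1L]] <-
      matrix(tabulate((len - 1L) * ng + lev, ng * nr), ng, nr)
    dirs[[length(dirs) + 1L]] <- offs[r, ]
  }
  if (length(mats) == 0L) .stopf("GLRLM: empty ROI")
  structure(list(family = "GLRLM", matrices = mats, directions = dirs,
                 ng = ng, n_voxels = np),
            class = "texture_matrix")
}

# 16 run-length features for one count matrix P (levels x lengths).
.glrlm_features_one <- function(P, np) {
  ng <- nrow(P); nr <- ncol(P)
  iv <- seq_len(ng); jv <- seq_len(nr)
  ns <- sum(P)
  g <- rowSums(P); rl <- colSums(P)
  pr <- P / ns
  mu_i <- sum(iv * g) / ns
  mu_j <- sum(jv * rl) / ns
  pv <- pr[pr > 0]
  c(glrlm_gray_level_non_uniformity = sum(g^2) / ns,
    glrlm_gray_level_non_uniformity_normalized = sum(g^2) / ns^2,
    glrlm_gray_level_variance = sum((iv - mu_i)^2 * g) / ns,
    glrlm_high_gray_level_run_emphasis = sum(iv^2 * g) / ns,
    glrlm_long_run_emphasis = sum(jv^2 * rl) / ns,
    glrlm_long_run_high_gray_level_emphasis =
      sum(outer(iv^2, jv^2) * P) / ns,
    glrlm_long_run_low_gray_level_emphasis =
      sum(outer(1 / iv^2, jv^2) * P) / ns,
    glrlm_low_gray_level_run_emphasis = sum(g / iv^2) / ns,
    glrlm_run_entropy = -sum(pv * log2(pv)),
    glrlm_run_length_non_uniformity = sum(rl^2) / ns,
    glrlm_run_length_non_uniformity_normalized = sum(rl^2) / ns^2,
    glrlm_run_percentage = ns / np,
    glrlm_run_variance = sum((jv - mu_j)^2 * rl) / ns,
    glrlm_short_run_emphasis = sum(rl / jv^2) / ns,
    glrlm_short_run_high_gray_level_emphasis =
      sum(outer(iv^2, 1 / jv^2) * P) / ns,
    glrlm_short_run_low_gray_level_emphasis =
      sum(outer(1 / iv^2, 1 / jv^2) * P) / ns)
}

#' GLRLM features
#'
#' The 16 run-length features, computed per direction and averaged over
#' directions.
#'
#' @param m A `texture_matrix` from [build_glrlm()].
#' @return Named numeric vector of 16 features.
#' @export
glrlm_features <- function(m) {
  stopifnot(inherits(m, "texture_matrix"), m$family == "GLRLM")
  per_dir <- lapply(m$matrices, .glrlm_features_one, np = m$n_voxels)
  Reduce(`+`, per_dir) / length(per_dir)
}
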