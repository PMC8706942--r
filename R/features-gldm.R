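# Gray level dependence matrix: for every in-mask voxel, the dependence
# size j counts the voxel itself plus its in-mask 26-neighbours whose level
# differs by at most alpha (default 0, i.e. equal level). Counting the
# centre makes the smallest dependence 1, so the 1/j^2 emphases are always
# defined.

#' Build the gray level dependence matrix
#'
#' @param d A [discretize_fixed_bin_width()] result carrying a 3D level
#'   array.
#' @param alpha Dependence tolerance on the level difference (default 0).
#' @return An object of class `texture_matrix`, family `"GLDM"`: a single
#'   count matrix (levels x dependence sizes); every in-mask voxel
#'   contributes exactly one count.
#' @export
build_gldm <- function(d, alpha = 0) {
  L <- .require_level_array(d)
  ng <- d$ng
  inmask <- !is.na(L)
  n <- sum(inmask)
  if (n == 0L) .stopf("GLDM: empty ROI")
  dep <- array(0L, dim = dim(L))
  offs <- .offsets26()
  for (r in seq_len(nrow(offs))) {
    nb <- .neighbour_array(L, offs[r, ])
    dep <- dep + (inmask & !is.na(nb) & abs(L - nb) <= alpha)
  }
  j <- dep[inmask] + 1L  # dependence size includes the centre voxel
  lev <- L[inmask]
  nd <- max(j)
  P <- matrix(tabulate((j - 1L) * ng + lev, ng * nd), ng, nd)
  structure(list(family = "GLDM", matrix = P, ng = ng, n_voxels = n,
                 alpha = alpha),
            class = "texture_matrix")
}

#' GLDM features
#'
#' The 14 dependence features (small/large dependence emphasis, gray-level
#' and dependence non-uniformity, variance and entropy terms, and the
#' low/high gray-level crosses).
#'
#' @param m A `texture_matrix` from [build_gldm()].
#' @return Named numeric vector of 14 features.
#' @export
gldm_features <- function(m) {
  stopifnot(inherits(m, "texture_matrix"), m$family == "GLDM")
  P <- m$matrix
  ng <- nrow(P); nd <- ncol(P)
  iv <- seq_len(ng); jv <- seq_len(nd)
  nz <- sum(P)  # equals the voxel count
  g <- rowSums(P); dd <- colSums(P)
  pr <- P / nz
  mu_i <- sum(iv * g) / nz
  mu_j <- sum(jv * dd) / nz
  pv <- pr[pr > 0]
  c(gldm_dependence_entropy = -sum(pv * log2(pv)),
    gldm_dependence_non_uniformity = sum(dd^2) / nz,
    gldm_dependence_non_uniformity_normalized = sum(dd^2) / nz^2,
    gldm_dependence_variance = sum((jv - mu_j)^2 * dd) / nz,
    gldm_gray_level_non_uniformity = sum(g^2) / nz,
    gldm_gray_level_variance = sum((iv - mu_i)^2 * g) / nz,
    gldm_high_gray_level_emphasis = sum(iv^2 * g) / nz,
    gldm_large_dependence_emphasis = sum(jv^2 * dd) / nz,
    gldm_large_dependence_high_gray_level_emphasis =
      sum(outer(iv^2, jv^2) * P) / nz,
    gldm_large_dependence_low_gray_level_emphasis =
      sum(outer(1 / iv^2, jv^2) * P) / nz,
    gldm_low_gray_level_emphasis = sum(g / iv^2) / nz,
    gldm_small_dependence_emphasis = sum(dd / jv^2) / nz,
    gldm_small_dependence_high_gray_level_emphasis =
      sum(outer(iv^2, 1 / jv^2) * P) / nz,
    gldm_small_dependence_low_gray_level_emphasis =
      sum(outer(1 / iv^2, 1 / jv^2) * P) / nz)
}
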