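# Gray level co-occurrence matrix: symmetric co-occurrence counts of
# discretized levels at distance delta = 1 (index space, Chebyshev) along
# each of the 13 unique 3D directions. Features are computed per direction
# and averaged over directions that contain at least one voxel pair
# (directions with no pairs — e.g. through-plane offsets in a single-slice
# ROI — are skipped).

#' Build gray level co-occurrence matrices
#'
#' @param d A [discretize_fixed_bin_width()] result carrying a 3D level
#'   array.
#' @return An object of class `texture_matrix`, family `"GLCM"`, holding one
#'   symmetric count matrix per direction with at least one pair.
#' @export
build_glcm <- function(d) {
  L <- .require_level_array(d)
  ng <- d$ng
  offs <- .offsets13()
  mats <- list()
  dirs <- list()
  for (r in seq_len(nrow(offs))) {
    off <- offs[r, ]
    nb <- .neighbour_array(L, off)
    ok <- !is.na(L) & !is.na(nb)
    if (!any(ok)) next
    idx <- (nb[ok] - 1L) * ng + L[ok]
    m <- matrix(tabulate(idx, ng * ng), ng, ng)
    m <- m + t(m)  # symmetric: count each pair in both orders
    mats[[length(mats) + 1L]] <- m
    dirs[[length(dirs) + 1L]] <- off
  }
  if (length(mats) == 0L)
    .stopf("GLCM: no valid neighbour pairs in the ROI")
  structure(list(family = "GLCM", matrices = mats, directions = dirs,
                 ng = ng, delta = 1L),
            class = "texture_matrix")
}

# 24 GLCM features for one normalized symmetric matrix P (sums to 1).
.glcm_features_one <- function(P) {
  ng <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(seq_len(ng) * px); muy <- sum(seq_len(ng) * py)
  sigx <- sqrt(sum((seq_len(ng) - mux)^2 * px))
  sigy <- sqrt(sum((seq_len(ng) - muy)^2 * py))
  pvec <- as.vector(P)
  # diagonal (i - j) and cross (i + j) marginal distributions
  kdiff <- as.vector(abs(i - j))
  ksum <- as.vector(i + j)
  pxmy <- as.vector(rowsum(pvec, kdiff))          # k = 0 .. ng-1
  kd <- sort(unique(kdiff))
  pxpy_s <- as.vector(rowsum(pvec, ksum))         # k = 2 .. 2 ng
  ks <- sort(unique(ksum))
  da <- sum(kd * pxmy)
  ent2 <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  hxy <- ent2(pvec)
  hx <- ent2(px); hy <- ent2(py)
  pp <- as.vector(outer(px, py))
  pos <- pvec > 0 & pp > 0
  hxy1 <- -sum(pvec[pos] * log2(pp[pos]))
  ppos <- pp > 0
  hxy2 <- -sum(pp[ppos] * log2(pp[ppos]))

  corr <- if (ng == 1L) 1
          else if (sigx * sigy > 1e-12) (sum(i * j * P) - mux * muy) / (sigx * sigy)
          else 1  # all mass on one level pair: perfect (degenerate) agreement
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  mcc <- .glcm_mcc(P, px, py)

  c(glcm_autocorrelation = sum(i * j * P),
    glcm_cluster_prominence = sum((i + j - mux - muy)^4 * P),
    glcm_cluster_shade = sum((i + j - mux - muy)^3 * P),
    glcm_cluster_tendency = sum((i + j - mux - muy)^2 * P),
    glcm_contrast = sum((i - j)^2 * P),
    glcm_correlation = corr,
    glcm_difference_average = da,
    glcm_difference_entropy = ent2(pxmy),
    glcm_difference_variance = sum((kd - da)^2 * pxmy),
    glcm_id = sum(P / (1 + abs(i - j))),
    glcm_idm = sum(P / (1 + (i - j)^2)),
    glcm_idmn = sum(P / (1 + ((i - j) / ng)^2)),
    glcm_idn = sum(P / (1 + abs(i - j) / ng)),
    glcm_imc1 = imc1,
    glcm_imc2 = imc2,
    glcm_inverse_variance = sum(P[i != j] / (i[i != j] - j[i != j])^2),
    glcm_joint_average = mux,
    glcm_joint_energy = sum(P^2),
    glcm_joint_entropy = hxy,
    glcm_max_probability = max(P),
    glcm_mcc = mcc,
    glcm_sum_average = sum(ks * pxpy_s),
    glcm_sum_entropy = ent2(pxpy_s),
    glcm_sum_squares = sum((i - mux)^2 * P))
}

# Maximal correlation coefficient: sqrt of the second-largest eigenvalue of
# Q[a,b] = sum_k P[a,k] P[b,k] / (px[a] py[k]), restricted to levels with
# mass. Defined as 1 when only one level carries mass.
.glcm_mcc <- function(P, px, py) {
  nz <- px > 0
  if (sum(nz) <= 1L) return(1)
  Ps <- P[nz, nz, drop = FALSE]
  pxs <- px[nz]; pys <- py[nz]
  Q <- (Ps %*% (t(Ps) / pys)) / pxs
  ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
  sqrt(min(1, max(0, ev[2L])))
}

#' GLCM features
#'
#' The 24 co-occurrence features (autocorrelation, cluster
#' prominence/shade/tendency, contrast, correlation, difference
#' average/entropy/variance, inverse differences id/idm/idmn/idn, the
#' informational measures of correlation imc1/imc2, inverse variance, joint
#' average/energy/entropy, maximum probability, maximal correlation
#' coefficient, sum average/entropy, and sum of squares), averaged over
#' directions. Degenerate single-level matrices give correlation = 1,
#' mcc = 1 and imc2 = 0 by convention.
#'
#' @param m A `texture_matrix` from [build_glcm()].
#' @return Named numeric vector of 24 features.
#' @export
glcm_features <- function(m) {
  stopifnot(inherits(m, "texture_matrix"), m$family == "GLCM")
  per_dir <- lapply(m$matrices, function(cnt) .glcm_features_one(cnt / sum(cnt)))
  Reduce(`+`, per_dir) / length(per_dir)
}

.require_level_array <- function(d) {
  stopifnot(inherits(d, "discretized_roi"))
  if (is.null(d$levels))
    .stopf("texture matrices need the 3D level array; pass coords to discretize_fixed_bin_width()")
  d$levels
}
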