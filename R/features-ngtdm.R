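# Neighbouring gray tone difference matrix: for each level i, s_i sums the
# absolute difference between the level of each voxel of level i and the
# mean level of its in-mask 26-neighbours. Voxels with no in-mask neighbour
# are excluded from the counts.

#' Build the neighbouring gray tone difference matrix
#'
#' @param d A [discretize_fixed_bin_width()] result carrying a 3D level
#'   array.
#' @return An object of class `texture_matrix`, family `"NGTDM"`: a table
#'   with, per level, the voxel count `n_i`, probability `p_i` and
#'   difference sum `s_i`.
#' @export
build_ngtdm <- function(d) {
  L <- .require_level_array(d)
  ng <- d$ng
  inmask <- !is.na(L)
  nb_sum <- array(0, dim = dim(L))
  nb_cnt <- array(0L, dim = dim(L))
  offs <- .offsets26()
  for (r in seq_len(nrow(offs))) {
    nb <- .neighbour_array(L, offs[r, ])
    has <- !is.na(nb)
    nb_sum[has] <- nb_sum[has] + nb[has]
    nb_cnt <- nb_cnt + has
  }
  use <- inmask & nb_cnt > 0L
  nvp <- sum(use)
  if (nvp == 0L) .stopf("NGTDM: no voxel has an in-mask neighbour")
  lev <- L[use]
  diffs <- abs(lev - nb_sum[use] / nb_cnt[use])
  n_i <- tabulate(lev, ng)
  s_i <- numeric(ng)
  agg <- rowsum(diffs, lev)  # rows only for levels that occur
  s_i[as.integer(rownames(agg))] <- agg[, 1L]
  structure(list(family = "NGTDM", n_i = n_i, s_i = s_i,
                 p_i = n_i / nvp, ng = ng, n_voxels = nvp),
            class = "texture_matrix")
}

#' NGTDM features
#'
#' The five neighbourhood-gray-tone-difference features: coarseness,
#' contrast, busyness, complexity and strength. Degenerate conventions
#' (documented): coarseness is capped at 1e6 when the spatial rate of
#' change is zero; contrast is 0 when only one level is present; busyness
#' and strength are 0 when their denominators vanish.
#'
#' @param m A `texture_matrix` from [build_ngtdm()].
#' @return Named numeric vector of 5 features.
#' @export
ngtdm_features <- function(m) {
  stopifnot(inherits(m, "texture_matrix"), m$family == "NGTDM")
  p <- m$p_i; s <- m$s_i
  nvp <- m$n_voxels
  act <- p > 0
  iv <- seq_len(m$ng)
  ngp <- sum(act)
  i_a <- iv[act]; p_a <- p[act]; s_a <- s[act]
  ps <- sum(p_a * s_a)
  coarseness <- if (ps > 0) min(1 / ps, 1e6) else 1e6
  contrast <- if (ngp > 1L) {
    sum(outer(p_a, p_a) * outer(i_a, i_a, `-`)^2) /
      (ngp * (ngp - 1)) * sum(s_a) / nvp
  } else 0
  ipd <- abs(outer(i_a * p_a, i_a * p_a, `-`))
  busyness <- if (sum(ipd) > 0) ps / sum(ipd) else 0
  pij <- outer(p_a, p_a, `+`)
  dij <- abs(outer(i_a, i_a, `-`))
  complexity <- sum(dij * (outer(p_a * s_a, p_a * s_a, `+`)) / pij) / nvp
  strength <- if (sum(s_a) > 0) sum(pij * dij^2) / sum(s_a) else 0
  c(ngtdm_busyness = busyness,
    ngtdm_coarseness = coarseness,
    ngtdm_complexity = complexity,
    ngtdm_contrast = contrast,
    ngtdm_strength = strength)
}
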