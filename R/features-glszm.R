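# Gray level size zone matrix: 26-connected zones of equal level. Zone
# labelling is delegated to igraph's connected components on the
# equal-level neighbour graph.

#' Build the gray level size zone matrix
#'
#' @param d A [discretize_fixed_bin_width()] result carrying a 3D level
#'   array.
#' @return An object of class `texture_matrix`, family `"GLSZM"`: a single
#'   count matrix (levels x zone sizes); mass conservation
#'   `sum(count * size) = n_voxels`.
#' @export
build_glszm <- function(d) {
  L <- .require_level_array(d)
  ng <- d$ng
  inmask <- !is.na(L)
  n <- sum(inmask)
  if (n == 0L) .stopf("GLSZM: empty ROI")
  id <- array(NA_integer_, dim = dim(L))
  id[inmask] <- seq_len(n)
  lev <- L[inmask]
  edges <- list()
  for (r in seq_len(nrow(.offsets13()))) {
    off <- .offsets13()[r, ]
    nb_id <- .neighbour_array(id, off)
    nb_lv <- .neighbour_array(L, off)
    ok <- inmask & !is.na(nb_id) & L == nb_lv
    if (any(ok))
      edges[[length(edges) + 1L]] <- rbind(id[ok], nb_id[ok])
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges) > 0L)
    g <- igraph::add_edges(g, as.vector(do.call(cbind, edges)))
  comp <- igraph::components(g)
  zone_size <- comp$csize
  zone_level <- lev[match(seq_len(comp$no), comp$membership)]
  nsmax <- max(zone_size)
  P <- matrix(tabulate((zone_size - 1L) * ng + zone_level, ng * nsmax),
              ng, nsmax)
  structure(list(family = "GLSZM", matrix = P, ng = ng, n_voxels = n),
            class = "texture_matrix")
}

#' GLSZM features
#'
#' The 16 size-zone features (the run-length analogues with zones in place
#' of runs, e.g. small/large area emphasis, zone entropy, zone percentage).
#'
#' @param m A `texture_matrix` from [build_glszm()].
#' @return Named numeric vector of 16 features.
#' @export
glszm_features <- function(m) {
  stopifnot(inherits(m, "texture_matrix"), m$family == "GLSZM")
  P <- m$matrix
  np <- m$n_voxels
  ng <- nrow(P); ns <- ncol(P)
  iv <- seq_len(ng); jv <- seq_len(ns)
  nz <- sum(P)
  g <- rowSums(P); z <- colSums(P)
  pr <- P / nz
  mu_i <- sum(iv * g) / nz
  mu_j <- sum(jv * z) / nz
  pv <- pr[pr > 0]
  c(glszm_gray_level_non_uniformity = sum(g^2) / nz,
    glszm_gray_level_non_uniformity_normalized = sum(g^2) / nz^2,
    glszm_gray_level_variance = sum((iv - mu_i)^2 * g) / nz,
    glszm_high_gray_level_zone_emphasis = sum(iv^2 * g) / nz,
    glszm_large_area_emphasis = sum(jv^2 * z) / nz,
    glszm_large_area_high_gray_level_emphasis =
      sum(outer(iv^2, jv^2) * P) / nz,
    glszm_large_area_low_gray_level_emphasis =
      sum(outer(1 / iv^2, jv^2) * P) / nz,
    glszm_low_gray_level_zone_emphasis = sum(g / iv^2) / nz,
    glszm_size_zone_non_uniformity = sum(z^2) / nz,
    glszm_size_zone_non_uniformity_normalized = sum(z^2) / nz^2,
    glszm_small_area_emphasis = sum(z / jv^2) / nz,
    glszm_small_area_high_gray_level_emphasis =
      sum(outer(iv^2, 1 / jv^2) * P) / nz,
    glszm_small_area_low_gray_level_emphasis =
      sum(outer(1 / iv^2, 1 / jv^2) * P) / nz,
    glszm_zone_entropy = -sum(pv * log2(pv)),
    glszm_zone_percentage = nz / np,
    glszm_zone_variance = sum((jv - mu_j)^2 * z) / nz)
}
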