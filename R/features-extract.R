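#' Canonical feature names
#'
#' The 93 canonical feature names in fixed order: 18 `firstorder_`, 24
#' `glcm_`, 14 `gldm_`, 16 `glrlm_`, 16 `glszm_`, 5 `ngtdm_`.
#'
#' @param family Optional family filter, one of `"firstorder"`, `"glcm"`,
#'   `"gldm"`, `"glrlm"`, `"glszm"`, `"ngtdm"`.
#' @return Character vector of feature names.
#' @examples
#' length(feature_names())        # 93
#' table(sub("_.*", "", feature_names()))
#' @export
feature_names <- function(family = NULL) {
  nm <- c(
    names(first_order_features(c(0, 1))),
    names(.glcm_features_one(matrix(1))),
    names(gldm_features(structure(list(family = "GLDM", matrix = matrix(1L),
                                       ng = 1L, n_voxels = 1L),
                                  class = "texture_matrix"))),
    names(.glrlm_features_one(matrix(1L), 1L)),
    names(glszm_features(structure(list(family = "GLSZM", matrix = matrix(1L),
                                        ng = 1L, n_voxels = 1L),
                                   class = "texture_matrix"))),
    c("ngtdm_busyness", "ngtdm_coarseness", "ngtdm_complexity",
      "ngtdm_contrast", "ngtdm_strength"))
  if (!is.null(family)) nm <- nm[startsWith(nm, paste0(family, "_"))]
  nm
}

#' Extract all 93 radiomic features from one ROI
#'
#' Runs the full feature set on the intensity sample under `mask`:
#' first-order statistics on the raw values, and the five texture families
#' (GLCM, GLDM, GLRLM, GLSZM, NGTDM) on the fixed-bin-width discretized
#' levels at distance 1 in the 26-neighbourhood. Deterministic for fixed
#' inputs.
#'
#' @param volume A [subject_volume()].
#' @param mask A congruent [sphere_mask()] result with at least 2 voxels.
#' @param bin_width Discretization bin width in signal units.
#' @return Named numeric vector of 93 features in [feature_names()] order,
#'   with a `provenance` attribute recording `bin_width`, `ng`,
#'   `voxel_count` and the ROI `diameter`.
#' @export
extract_all <- function(volume, mask, bin_width = 25) {
  rv <- extract_roi_values(volume, mask)
  if (length(rv$values) < 2L)
    .stopf("texture families need at least 2 in-mask voxels (got %d)",
           length(rv$values))
  d <- discretize_fixed_bin_width(rv$values, rv$coords, bin_width)
  fam <- function(name, expr) {
    tryCatch(expr, error = function(e)
      .stopf("%s: %s", name, conditionMessage(e)))
  }
  out <- c(
    fam("firstorder", first_order_features(rv$values,
                                           voxel_volume = prod(volume$spacing),
                                           bin_width = bin_width)),
    fam("GLCM",  glcm_features(build_glcm(d))),
    fam("GLDM",  gldm_features(build_gldm(d))),
    fam("GLRLM", glrlm_features(build_glrlm(d))),
    fam("GLSZM", glszm_features(build_glszm(d))),
    fam("NGTDM", ngtdm_features(build_ngtdm(d))))
  stopifnot(identical(names(out), feature_names()))
  attr(out, "provenance") <- list(bin_width = bin_width, ng = d$ng,
                                  voxel_count = mask$voxel_count,
                                  diameter = mask$source$diameter)
  out
}
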