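# NIfTI and CSV interchange. Volumes and masks go out as NIfTI-1 with the
# physical spacing in pixdim; tabular results as CSV with doubles printed
# at full precision (17 significant digits) so that reloading reproduces
# the numbers bit-for-bit.

#' Write a subject volume as NIfTI-1
#'
#' @param volume A [subject_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_volume_nifti <- function(volume, path) {
  stopifnot(inherits(volume, "subject_volume"))
  img <- RNifti::asNifti(volume$voxels)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a subject volume from NIfTI-1
#'
#' @param path NIfTI file path.
#' @param subject_id,scanner,sequence Labels to attach.
#' @return A [subject_volume()].
#' @export
read_volume_nifti <- function(path, subject_id = NA_character_,
                              scanner = NA_character_,
                              sequence = NA_character_) {
  img <- RNifti::readNifti(path)
  subject_volume(array(as.numeric(img), dim = dim(img)),
                 RNifti::pixdim(img)[1:3], subject_id, scanner, sequence)
}

#' Write an ROI mask as NIfTI-1
#'
#' The mask is written as a 0/1 volume with the source spacing.
#'
#' @param mask An [sphere_mask()] result.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_mask_nifti <- function(mask, path) {
  stopifnot(inherits(mask, "roi_mask"))
  img <- RNifti::asNifti(array(as.integer(mask$mask), dim = dim(mask$mask)))
  RNifti::pixdim(img) <- mask$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a cohort to disk with a manifest
#'
#' Writes every volume as NIfTI and a `manifest.csv` with one row per
#' volume (`subject_id`, `scanner`, `sequence`, `path`).
#'
#' @param volumes List of [subject_volume()] objects.
#' @param dir Output directory (created if needed).
#' @return Path to the manifest, invisibly.
#' @export
write_cohort_nifti <- function(volumes, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(volumes, function(v) {
    fn <- sprintf("%s_%s.nii.gz", v$subject_id, v$sequence)
    write_volume_nifti(v, file.path(dir, fn))
    data.frame(subject_id = v$subject_id, scanner = v$scanner,
               sequence = v$sequence, path = fn)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Write a results table at full double precision
#'
#' Numeric columns are formatted with 17 significant digits, so
#' `read_features_csv()` reproduces the doubles exactly.
#'
#' @param df Data frame.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_features_csv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a results table written by [write_features_csv()]
#'
#' @param path CSV path.
#' @return Data frame with numeric columns restored.
#' @export
read_features_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  for (j in seq_along(df)) {
    if (is.character(df[[j]])) {
      if (all(df[[j]] %in% c("TRUE", "FALSE"))) {
        df[[j]] <- as.logical(df[[j]])
      } else {
        num <- suppressWarnings(as.numeric(df[[j]]))
        if (!anyNA(num)) df[[j]] <- num
      }
    }
  }
  df
}
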