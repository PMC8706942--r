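#' Scanner/sequence acquisition profile
#'
#' A `scanner_profile` bundles the voxel geometry of one scanner/sequence
#' combination with the intensity model used by [simulate_volume()]:
#' a per-subject mean drawn from `Normal(mean_intensity, subject_sd)` plus a
#' stationary correlated noise field of marginal standard deviation
#' `noise_sd` and isotropic correlation scale `correlation_length` (mm).
#'
#' @param name Scanner label, e.g. `"3T_I"`.
#' @param sequence Pulse-sequence contrast label, `"T1w"` or `"T2w"`.
#' @param in_plane_spacing In-plane pixel spacing in mm (single value; pixels
#'   are square in-plane).
#' @param z_spacing Spacing between slice centres in mm. Must be at least the
#'   in-plane spacing (clinical abdominal MRI is anisotropic, with thick
#'   slices).
#' @param mean_intensity Population mean signal, arbitrary units.
#' @param subject_sd Between-subject standard deviation of the volume-level
#'   mean signal.
#' @param noise_sd Marginal standard deviation of the voxel-level texture
#'   field (after smoothing; the field is re-normalized).
#' @param correlation_length Isotropic Gaussian smoothing scale of the
#'   texture field, in mm. `0` gives white noise.
#' @return An object of class `scanner_profile`.
#' @seealso [default_profiles()], [simulate_volume()]
#' @export
scanner_profile <- function(name, sequence, in_plane_spacing, z_spacing,
                            mean_intensity, subject_sd, noise_sd,
                            correlation_length) {
  stopifnot(is.character(name), length(name) == 1L,
            sequence %in% c("T1w", "T2w"))
  if (!(in_plane_spacing > 0) || !(z_spacing > 0))
    .stopf("voxel spacings must be strictly positive")
  if (z_spacing < in_plane_spacing)
    .stopf("z_spacing (%g) must be >= in-plane spacing (%g)",
           z_spacing, in_plane_spacing)
  if (!(noise_sd > 0)) .stopf("noise_sd must be > 0")
  if (subject_sd < 0) .stopf("subject_sd must be >= 0")
  if (correlation_length < 0) .stopf("correlation_length must be >= 0")
  structure(
    list(name = name, sequence = sequence,
         in_plane_spacing = in_plane_spacing, z_spacing = z_spacing,
         mean_intensity = mean_intensity, subject_sd = subject_sd,
         noise_sd = noise_sd, correlation_length = correlation_length),
    class = "scanner_profile")
}

#' @export
print.scanner_profile <- function(x, ...) {
  cat(sprintf("<scanner_profile> %s / %s: %.7g x %.7g x %.2f mm, mean %g, subject_sd %g, noise_sd %g, corr %g mm\n",
              x$name, x$sequence, x$in_plane_spacing, x$in_plane_spacing,
              x$z_spacing, x$mean_intensity, x$subject_sd, x$noise_sd,
              x$correlation_length))
  invisible(x)
}

#' Default scanner profiles for the three-scanner liver study design
#'
#' Six profiles (3 scanners x 2 sequences) carrying the acquisition geometry
#' of the emulated study: both 3 T scanners acquire at 1.125 x 1.125 mm
#' in-plane with 5.5 mm spacing between slices; the 1.5 T scanner at
#' 1.09375 mm (T1w) or 1.3671875 mm (T2w) in-plane with 6.6 mm slice
#' spacing. Intensity parameters are model defaults, not measured values:
#' T1w mean 350 and T2w mean 180 arbitrary units, between-subject SD 10% of
#' the mean, voxel noise SD 8% of the mean, correlation length 2 mm. Only
#' the ratios of these parameters matter to the rank-based tests and the
#' scale-free concordance analysis downstream.
#'
#' @return A list of six [scanner_profile()] objects.
#' @examples
#' pr <- default_profiles()
#' sapply(pr, function(p) p$name)
#' @export
default_profiles <- function() {
  mk <- function(name, seq, ip, z) {
    m <- if (seq == "T1w") 350 else 180
    scanner_profile(name, seq, ip, z,
                    mean_intensity = m, subject_sd = 0.10 * m,
                    noise_sd = 0.08 * m, correlation_length = 2)
  }
  list(
    mk("3T_I",  "T1w", 1.125,     5.5),
    mk("3T_I",  "T2w", 1.125,     5.5),
    mk("3T_II", "T1w", 1.125,     5.5),
    mk("3T_II", "T2w", 1.125,     5.5),
    mk("1p5T",  "T1w", 1.09375,   6.6),
    mk("1p5T",  "T2w", 1.3671875, 6.6)
  )
}

#' Cohort specification
#'
#' Describes a synthetic cohort: how many subjects to simulate per scanner,
#' the master seed, the voxel grid shape, and the scanner profiles. The
#' defaults reproduce the emulated study's group sizes: 25 + 19 + 22 = 66
#' subjects over three scanners, each imaged with both sequences.
#'
#' @param subjects_per_scanner Named integer vector, scanner name -> subject
#'   count. Scanner names must match the `name` fields of `profiles`.
#' @param seed Master seed; per-volume seeds are derived deterministically
#'   from it and the (subject, scanner, sequence) labels.
#' @param volume_shape Voxel grid dimensions; must accommodate a 30 mm
#'   sphere with at least one voxel of margin at every profile's spacing.
#' @param profiles List of [scanner_profile()] objects.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(subjects_per_scanner = c("3T_I" = 25, "3T_II" = 19, "1p5T" = 22),
                        seed = 1L,
                        volume_shape = c(48L, 48L, 12L),
                        profiles = default_profiles()) {
  if (is.null(names(subjects_per_scanner)) || any(names(subjects_per_scanner) == ""))
    .stopf("subjects_per_scanner must be a named vector")
  if (!all(vapply(subjects_per_scanner, .is_count, logical(1))))
    .stopf("subject counts must be nonnegative integers")
  prof_names <- unique(vapply(profiles, `[[`, character(1), "name"))
  unknown <- setdiff(names(subjects_per_scanner), prof_names)
  if (length(unknown) > 0L)
    .stopf("no profile for scanner(s): %s", paste(unknown, collapse = ", "))
  stopifnot(length(volume_shape) == 3L, all(volume_shape >= 1))
  structure(
    list(subjects_per_scanner = subjects_per_scanner,
         seed = as.integer(seed),
         volume_shape = as.integer(volume_shape),
         profiles = profiles),
    class = "cohort_spec")
}
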