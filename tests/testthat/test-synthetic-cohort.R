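test_that("default profiles carry the study acquisition geometry", {
  pr <- default_profiles()
  expect_length(pr, 6L)
  key <- vapply(pr, function(p) paste(p$name, p$sequence), character(1))
  expect_setequal(key, c("3T_I T1w", "3T_I T2w", "3T_II T1w", "3T_II T2w",
                         "1p5T T1w", "1p5T T2w"))
  get <- function(nm, sq) pr[[which(key == paste(nm, sq))]]
  expect_equal(get("3T_I", "T1w")$z_spacing, 5.5)
  expect_equal(get("3T_I", "T1w")$in_plane_spacing, 1.125)
  expect_equal(get("3T_II", "T2w")$in_plane_spacing, 1.125)
  expect_equal(get("3T_II", "T2w")$z_spacing, 5.5)
  expect_equal(get("1p5T", "T1w")$in_plane_spacing, 1.09375)
  expect_equal(get("1p5T", "T2w")$in_plane_spacing, 1.3671875)
  expect_equal(get("1p5T", "T2w")$z_spacing, 6.6)
  for (p in pr) expect_gte(p$z_spacing, p$in_plane_spacing)
})

test_that("profile invariants are enforced", {
  expect_error(scanner_profile("A", "T1w", 1, 0.5, 100, 10, 8, 2), "z_spacing")
  expect_error(scanner_profile("A", "T1w", -1, 5, 100, 10, 8, 2), "positive")
  expect_error(scanner_profile("A", "T1w", 1, 5, 100, 10, 0, 2), "noise_sd")
  expect_error(scanner_profile("A", "T1w", 1, 5, 100, -1, 8, 2), "subject_sd")
})

test_that("degenerate noise gives a constant volume at the subject mean", {
  p <- scanner_profile("A", "T1w", 1.125, 5.5, mean_intensity = 42,
                       subject_sd = 0, noise_sd = 1e-12,
                       correlation_length = 0)
  v <- simulate_volume(p, "S01", c(40, 40, 10), seed = 3)
  expect_equal(max(abs(v$voxels - 42)), 0, tolerance = 1e-9)
})

test_that("simulation is deterministic in the seed", {
  p <- default_profiles()[[1]]
  v1 <- simulate_volume(p, "S01", seed = 11)
  v2 <- simulate_volume(p, "S01", seed = 11)
  v3 <- simulate_volume(p, "S01", seed = 12)
  expect_identical(v1$voxels, v2$voxels)
  expect_false(identical(v1$voxels, v3$voxels))
})

test_that("marginal voxel sd matches noise_sd after renormalized smoothing", {
  # white noise: direct Monte-Carlo check of the stated marginal sd
  p0 <- scanner_profile("A", "T1w", 1.125, 5.5, 100, 0, 8, 0)
  v0 <- simulate_volume(p0, "S01", c(48, 48, 12), seed = 5)
  expect_equal(sd(v0$voxels), 8, tolerance = 0.05)
  # smoothed field: renormalization must restore the same marginal sd
  p2 <- scanner_profile("A", "T1w", 1.125, 5.5, 100, 0, 8, 2)
  sds <- vapply(1:8, function(s)
    sd(simulate_volume(p2, "S01", c(48, 48, 12), seed = s)$voxels),
    numeric(1))
  expect_equal(mean(sds), 8, tolerance = 0.05 * 8)
})

test_that("volumes too small for a 30 mm sphere are rejected, naming the axis", {
  p <- default_profiles()[[1]]
  expect_error(simulate_volume(p, "S01", c(48, 48, 4), seed = 1), "axis 3")
  expect_error(simulate_volume(p, "S01", c(10, 48, 12), seed = 1), "axis 1")
})

test_that("default cohort has 132 volumes split 25/19/22 by scanner", {
  spec <- cohort_spec()
  vols <- simulate_cohort(spec)
  expect_length(vols, 132L)
  scanners <- vapply(vols, `[[`, character(1), "scanner")
  seqs <- vapply(vols, `[[`, character(1), "sequence")
  subj <- vapply(vols, `[[`, character(1), "subject_id")
  expect_equal(length(unique(subj[scanners == "3T_I"])), 25L)
  expect_equal(length(unique(subj[scanners == "3T_II"])), 19L)
  expect_equal(length(unique(subj[scanners == "1p5T"])), 22L)
  expect_equal(sum(seqs == "T1w"), 66L)
})

test_that("small custom cohorts and bad scanner names behave as specified", {
  p <- scanner_profile("A", "T1w", 1.125, 5.5, 100, 10, 8, 0)
  spec <- cohort_spec(subjects_per_scanner = c(A = 1), seed = 1,
                      volume_shape = c(40, 40, 10), profiles = list(p))
  expect_length(simulate_cohort(spec), 1L)
  expect_error(cohort_spec(subjects_per_scanner = c(B = 1), profiles = list(p)),
               "no profile")
})

test_that("cohort generation is reproducible from the spec seed", {
  spec <- cohort_spec(subjects_per_scanner = c("3T_I" = 2), seed = 9)
  v1 <- simulate_cohort(spec)
  v2 <- simulate_cohort(spec)
  expect_identical(lapply(v1, `[[`, "voxels"), lapply(v2, `[[`, "voxels"))
})

test_that("the texture field is stationary: disjoint sphere means agree", {
  # white-noise profile on a wide grid holding two disjoint 30 mm spheres;
  # the difference of sphere means stays within 3 standard errors
  p <- scanner_profile("A", "T1w", 1.125, 5.5, 100, 0, 8, 0)
  shape <- c(64, 40, 12)
  exceed <- 0L
  for (s in 1:20) {
    v <- simulate_volume(p, "S01", shape, seed = 100 + s)
    m1 <- sphere_mask(v$spacing, shape, sphere_roi(c(16, 21, 30), 30))
    m2 <- sphere_mask(v$spacing, shape, sphere_roi(c(53, 21, 30), 30))
    expect_equal(sum(m1$mask & m2$mask), 0L)  # disjoint
    x1 <- extract_roi_values(v, m1)$values
    x2 <- extract_roi_values(v, m2)$values
    se <- 8 * sqrt(1 / length(x1) + 1 / length(x2))
    if (abs(mean(x1) - mean(x2)) >= 3 * se) exceed <- exceed + 1L
  }
  expect_lte(exceed, 1L)
})
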