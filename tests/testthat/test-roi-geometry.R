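spacing_3t <- c(1.125, 1.125, 5.5)

test_that("a 1 mm sphere on a voxel centre resolves exactly one voxel", {
  center <- c(10, 10, 1) * spacing_3t  # the centre of voxel (11, 11, 2)
  m <- sphere_mask(spacing_3t, c(21, 21, 4), sphere_roi(center, 1))
  expect_equal(m$voxel_count, 1L)
  expect_true(m$mask[11, 11, 2])
})

test_that("masks of increasing diameter at a fixed centre are strictly nested", {
  shape <- c(48, 48, 12)
  center <- c(23, 23, 5) * spacing_3t
  prev <- NULL
  for (dia in c(10, 20, 30)) {
    m <- sphere_mask(spacing_3t, shape, sphere_roi(center, dia))
    if (!is.null(prev)) {
      expect_true(all(m$mask[prev]))           # containment
      expect_gt(sum(m$mask), sum(prev))        # strict growth
    }
    prev <- m$mask
  }
})

test_that("30 mm mask voxel count is near the continuum volume ratio", {
  shape <- c(48, 48, 12)
  center <- c(23, 23, 5) * spacing_3t
  m <- sphere_mask(spacing_3t, shape, sphere_roi(center, 30))
  continuum <- (4 / 3) * pi * 15^3 / prod(spacing_3t)
  expect_lt(abs(m$voxel_count - continuum) / continuum, 0.15)
})

test_that("masks are 6-connected for well-resolved spheres", {
  shape <- c(48, 48, 12)
  center <- c(23, 23, 5) * spacing_3t
  m <- sphere_mask(spacing_3t, shape, sphere_roi(center, 30))
  # flood fill with face-adjacency from one voxel must reach the whole mask
  idx <- which(m$mask, arr.ind = TRUE)
  key <- paste(idx[, 1], idx[, 2], idx[, 3])
  seen <- setNames(logical(nrow(idx)), key)
  queue <- list(idx[1, ])
  seen[1] <- TRUE
  faces <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))
  while (length(queue) > 0) {
    p <- queue[[1]]; queue <- queue[-1]
    for (r in 1:6) {
      q <- p + faces[r, ]
      k <- paste(q[1], q[2], q[3])
      if (!is.na(seen[k]) && !seen[k]) {
        seen[k] <- TRUE
        queue[[length(queue) + 1]] <- q
      }
    }
  }
  expect_true(all(seen))
})

test_that("spheres beyond the grid raise a geometry error naming the axis", {
  expect_error(sphere_mask(spacing_3t, c(48, 48, 12),
                           sphere_roi(c(2, 26, 27.5), 30)), "axis 1")
  expect_error(sphere_mask(spacing_3t, c(48, 48, 12),
                           sphere_roi(c(26, 26, 2), 30)), "axis 3")
})

test_that("mask is symmetric under axis reflection about a central voxel", {
  m <- sphere_mask(c(1, 1, 2), c(21, 21, 11), sphere_roi(c(10, 10, 10), 12))
  expect_identical(m$mask, m$mask[21:1, , ])
  expect_identical(m$mask, m$mask[, 21:1, ])
  expect_identical(m$mask, m$mask[, , 11:1])
})

test_that("place_center snaps to the central voxel and is diameter-free", {
  p <- default_profiles()[[1]]
  v <- simulate_volume(p, "S01", c(41, 41, 11), seed = 2)
  center <- place_center(v)
  expect_equal(center, c(20, 20, 5) * v$spacing)
  rois <- lapply(c(10, 20, 30), function(d) place_center(v, d))
  centers <- unique(lapply(rois, `[[`, "center"))
  expect_length(centers, 1L)
})

test_that("extract_roi_values returns the masked sample with coordinates", {
  p <- scanner_profile("A", "T1w", 1.125, 5.5, 7, 0, 1e-9, 0)
  v <- simulate_volume(p, "S01", c(40, 40, 10), seed = 1)
  m <- sphere_mask(v$spacing, dim(v$voxels), place_center(v, 20))
  rv <- extract_roi_values(v, m)
  expect_length(rv$values, m$voxel_count)
  expect_equal(nrow(rv$coords), m$voxel_count)
  expect_equal(rv$values, rep(7, m$voxel_count), tolerance = 1e-6)
  # coordinates index the volume consistently
  expect_equal(v$voxels[rv$coords], rv$values)
  # shape mismatch is a contract error
  v2 <- simulate_volume(p, "S02", c(41, 41, 10), seed = 2)
  expect_error(extract_roi_values(v2, m), "shape")
})

test_that("ROI mean tracks the field mean on a stationary volume", {
  p <- scanner_profile("A", "T1w", 1.125, 5.5, 100, 0, 8, 0)
  devs <- vapply(1:10, function(s) {
    v <- simulate_volume(p, "S01", c(48, 48, 12), seed = 400 + s)
    m <- sphere_mask(v$spacing, dim(v$voxels), place_center(v, 30))
    mean(extract_roi_values(v, m)$values) - 100
  }, numeric(1))
  expect_lt(max(abs(devs)), 3 * 8 / sqrt(2000))
})

test_that("physical-space geometry: axis permutation with matching spacing
           permutation leaves masks and downstream features unchanged", {
  p <- default_profiles()[[1]]
  v <- simulate_volume(p, "S01", c(44, 40, 12), seed = 21)
  perm <- c(3, 1, 2)
  v2 <- subject_volume(aperm(v$voxels, perm), v$spacing[perm],
                       v$subject_id, v$scanner, v$sequence)
  for (dia in c(10, 30)) {
    m1 <- sphere_mask(v$spacing, dim(v$voxels), place_center(v, dia))
    m2 <- sphere_mask(v2$spacing, dim(v2$voxels), place_center(v2, dia))
    expect_identical(aperm(m1$mask, perm), m2$mask)
    f1 <- extract_all(v, m1)
    f2 <- extract_all(v2, m2)
    expect_equal(f1, f2, tolerance = 1e-10, ignore_attr = TRUE)
  }
})
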