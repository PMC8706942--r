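test_that("checkerboard strip puts all GLCM mass off-diagonal", {
  arr <- array(rep(c(1L, 2L), 5), dim = c(10, 1, 1))
  m <- build_glcm(make_droi(arr))
  expect_length(m$matrices, 1L)  # only the in-strip direction has pairs
  M <- m$matrices[[1]]
  expect_equal(sum(diag(M)), 0)
  expect_equal(sum(M), 2 * 9)  # 9 pairs, symmetric
})

test_that("constant ROI degenerates cleanly across all families", {
  arr <- array(1L, dim = c(3, 3, 2))
  d <- make_droi(arr)
  g <- glcm_features(build_glcm(d))
  expect_equal(unname(g["glcm_joint_entropy"]), 0)
  expect_equal(unname(g["glcm_correlation"]), 1)
  expect_equal(unname(g["glcm_mcc"]), 1)
  expect_equal(unname(g["glcm_imc2"]), 0)
  expect_equal(unname(g["glcm_contrast"]), 0)
  # one zone of size N
  z <- build_glszm(d)
  expect_equal(sum(z$matrix), 1)
  expect_equal(z$matrix[1, 18], 1)
  n <- ngtdm_features(build_ngtdm(d))
  expect_equal(unname(n["ngtdm_contrast"]), 0)
})

test_that("alternating two-level line gives all runs length 1 with the
           closed-form run-length non-uniformity", {
  n <- 12L
  arr <- array(rep(c(1L, 2L), n / 2), dim = c(n, 1, 1))
  m <- build_glrlm(make_droi(arr))
  along <- which(vapply(m$directions, function(o) all(o == c(1, 0, 0)),
                        logical(1)))
  P <- m$matrices[[along]]
  expect_equal(ncol(P), 1L)          # every run has length 1
  expect_equal(sum(P), n)            # n runs
  f <- roistab:::.glrlm_features_one(P, n)
  # all runs length 1: RLN = n^2 / n = n; run percentage 1
  expect_equal(unname(f["glrlm_run_length_non_uniformity"]), n)
  expect_equal(unname(f["glrlm_run_percentage"]), 1)
})

test_that("texture matrices match brute-force oracles on random masked arrays", {
  set.seed(42)
  for (case in 1:60) {
    arr <- random_level_array()
    d <- make_droi(arr)
    np <- sum(!is.na(arr))
    # GLCM (skip cases with no neighbour pairs at all)
    want <- oracle_glcm(arr, d$ng)
    if (any(!vapply(want, is.null, logical(1)))) {
      got <- expand_dirs(build_glcm(d))
      expect_matrix_lists_equal(got, want)
    }
    # GLRLM + per-direction mass conservation
    rl <- build_glrlm(d)
    expect_matrix_lists_equal(expand_dirs(rl), oracle_glrlm(arr, d$ng))
    for (P in rl$matrices) {
      expect_equal(sum(P %*% seq_len(ncol(P))), np)
    }
    # GLSZM + mass conservation
    sz <- build_glszm(d)
    want_sz <- oracle_glszm(arr, d$ng)
    nc <- max(ncol(sz$matrix), ncol(want_sz))
    expect_equal(pad_cols(sz$matrix, nc), pad_cols(want_sz, nc),
                 ignore_attr = TRUE)
    expect_equal(sum(sz$matrix %*% seq_len(ncol(sz$matrix))), np)
    # GLDM: every voxel contributes one count
    dl <- build_gldm(d)
    want_dl <- oracle_gldm(arr, d$ng)
    nc <- max(ncol(dl$matrix), ncol(want_dl))
    expect_equal(pad_cols(dl$matrix, nc), pad_cols(want_dl, nc),
                 ignore_attr = TRUE)
    expect_equal(sum(dl$matrix), np)
    # NGTDM
    nt <- build_ngtdm(d)
    want_nt <- oracle_ngtdm(arr, d$ng)
    expect_equal(nt$n_i, want_nt$n_i, ignore_attr = TRUE)
    expect_equal(nt$s_i, want_nt$s_i, tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("normalized GLCM sums to one per direction", {
  set.seed(7)
  arr <- random_level_array(min_vox = 8)
  m <- build_glcm(make_droi(arr))
  for (M in m$matrices) expect_equal(sum(M / sum(M)), 1, tolerance = 1e-12)
})

test_that("axis permutation leaves direction-averaged features unchanged", {
  set.seed(8)
  arr <- array(sample.int(4, 60, replace = TRUE), dim = c(5, 4, 3))
  d1 <- make_droi(arr)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    d2 <- make_droi(aperm(arr, perm))
    expect_equal(glcm_features(build_glcm(d1)),
                 glcm_features(build_glcm(d2)), tolerance = 1e-10)
    expect_equal(glrlm_features(build_glrlm(d1)),
                 glrlm_features(build_glrlm(d2)), tolerance = 1e-10)
    expect_equal(glszm_features(build_glszm(d1)),
                 glszm_features(build_glszm(d2)), tolerance = 1e-10)
    expect_equal(gldm_features(build_gldm(d1)),
                 gldm_features(build_gldm(d2)), tolerance = 1e-10)
    expect_equal(ngtdm_features(build_ngtdm(d1)),
                 ngtdm_features(build_ngtdm(d2)), tolerance = 1e-10)
  }
})

test_that("GLCM/GLDM features on a 3x3x1 hand phantom equal the oracle route", {
  arr <- array(c(1L, 2L, 1L,
                 2L, 3L, 2L,
                 1L, 2L, 1L), dim = c(3, 3, 1))
  d <- make_droi(arr)
  got <- expand_dirs(build_glcm(d))
  expect_matrix_lists_equal(got, oracle_glcm(arr, 3L))
  dl <- build_gldm(d)
  want <- oracle_gldm(arr, 3L)
  nc <- max(ncol(dl$matrix), ncol(want))
  expect_equal(pad_cols(dl$matrix, nc), pad_cols(want, nc), ignore_attr = TRUE)
})
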