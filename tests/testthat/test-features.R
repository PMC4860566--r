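test_that("the 13 directions cover the 26-neighbourhood half-axes once", {
  offs <- direction_offsets()
  expect_equal(nrow(offs), 13L)
  expect_true(all(offs %in% c(-1L, 0L, 1L)))
  expect_false(any(rowSums(abs(offs)) == 0))
  # pairwise neither equal nor antiparallel
  for (i in 1:12) for (j in (i + 1):13) {
    expect_false(all(offs[i, ] == offs[j, ]))
    expect_false(all(offs[i, ] == -offs[j, ]))
  }
  # the stated angle parameterization maps as expected
  expect_equal(unname(offs[1, ]), c(1L, 0L, 0L))   # (alpha1, alpha2) = (0, 90)
  expect_equal(unname(offs[9, ]), c(0L, 0L, 1L))   # (0, 0) is the Z axis
  expect_equal(unname(offs[13, ]), c(1L, -1L, 1L)) # completion (-45, 45)
})

test_that("intensity normalization is a scale-invariant min-max map", {
  expect_equal(normalize_intensity(c(10, 20, 30)), c(0, 0.5, 1))
  expect_equal(normalize_intensity(rep(4, 5)), rep(0, 5))
  x <- c(3, 9, 1, 7)
  expect_equal(normalize_intensity(x), normalize_intensity(100 + 17 * x))
})

test_that("block statistics match a brute-force loop, edges cropped", {
  a <- array(0.5, c(6, 6, 6))
  expect_equal(unname(block_stats(a, c(3, 3, 3))), c(0.5, 0))
  b <- array(rep(c(0, 1), length.out = 5 * 5 * 4), c(5, 5, 4))
  expect_equal(unname(block_stats(b, c(3, 3, 2)))[2], 0.5)
  set.seed(21)
  r <- array(runif(7^3), c(7, 7, 7))
  for (cv in list(c(4, 4, 4), c(1, 1, 1), c(7, 2, 5))) {
    expect_equal(unname(block_stats(r, cv)), oracle_block_stats(r, cv),
                 tolerance = 1e-12)
  }
})

test_that("directional absolute differences follow the clamped 13-direction mean", {
  a <- array(1, c(5, 5, 5))
  expect_equal(abs_diff_feature(a, c(3, 3, 3), 1), 0)
  expect_equal(abs_diff_feature(a, c(3, 3, 3), 2), 0)
  b <- array(0, c(5, 5, 5)); b[3, 3, 3] <- 1
  expect_equal(abs_diff_feature(b, c(3, 3, 3), 1), 1)
  set.seed(22)
  r <- array(runif(4 * 5 * 6), c(4, 5, 6))
  offs <- direction_offsets()
  for (cv in list(c(2, 3, 3), c(1, 1, 6), c(4, 5, 1))) {
    for (st in 1:2)
      expect_equal(abs_diff_feature(r, cv, st),
                   oracle_abs_diff(r, cv, st, offs), tolerance = 1e-12)
  }
})

test_that("GLCM construction and properties match hand-derived values", {
  p <- glcm(array(c(0L, 1L, 1L), c(3, 1, 1)), c(1, 0, 0), 2)
  expect_equal(p, matrix(c(0, 0.25, 0.25, 0.5), 2, 2))
  pr <- glcm_props(p)
  expect_equal(unname(pr), c(0.5, -1/3, 0.375, 0.75), tolerance = 1e-12)

  # constant block: all mass on the diagonal, degenerate correlation 0
  pc <- glcm(array(3L, c(4, 4, 4)), c(0, 0, 1), 8)
  expect_equal(pc[4, 4], 1)
  expect_equal(unname(glcm_props(pc)), c(0, 0, 1, 1))

  # uniform GLCM: energy is 1/n^2
  pu <- matrix(1 / 16, 4, 4)
  expect_equal(unname(glcm_props(pu)[["energy"]]), 1 / 16)

  expect_error(glcm_props(matrix(0.3, 2, 2)), "normalized")
  # degenerate direction (no pairs) is flagged
  pd <- glcm(array(0L, c(1, 1, 1)), c(1, 0, 0), 2)
  expect_true(attr(pd, "degenerate"))
  expect_equal(unname(glcm_props(pd)), c(0, 0, 0, 0))
})

test_that("GLCMs are symmetric probability matrices for random blocks", {
  set.seed(23)
  offs <- direction_offsets()
  for (rep in 1:5) {
    blk <- array(sample(0:7, 125, replace = TRUE), c(5, 5, 5))
    d <- offs[sample(13, 1), ]
    p <- glcm(blk, d, 8)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_equal(p, t(p))
    pr <- glcm_props(p)
    expect_gte(pr[["contrast"]], 0)
    expect_true(pr[["energy"]] > 0 && pr[["energy"]] <= 1)
    expect_true(pr[["homogeneity"]] > 0 && pr[["homogeneity"]] <= 1)
    expect_lte(abs(pr[["correlation"]]), 1 + 1e-12)
  }
})

test_that("extract_features builds 57 columns in table order with stable voxel order", {
  set.seed(24)
  vol <- oct_volume(array(runif(8 * 6 * 10), c(8, 6, 10)), c(1, 1, 1))
  voi <- array(FALSE, c(8, 6, 10)); voi[2:7, 2:5, 4:6] <- TRUE
  fm <- extract_features(vol, voxel_mask(voi, "voi"))
  expect_equal(ncol(fm$X), 57L)
  expect_equal(colnames(fm$X), feature_names())
  expect_equal(nrow(fm$X), sum(voi))
  # x-major, then y, then z ordering
  expect_equal(fm$voxels, arrayInd(which(voi), dim(voi)))
  expect_true(all(is.finite(fm$X)))
  expect_true(all(fm$X[, 1] >= 0 & fm$X[, 1] <= 1))
  expect_error(extract_features(vol, voxel_mask(array(FALSE, c(8, 6, 10)), "voi")),
               "empty")
})

test_that("a constant VOI yields the degenerate descriptor", {
  vol <- oct_volume(array(0.7, c(6, 6, 8)), c(1, 1, 1))
  voi <- array(FALSE, c(6, 6, 8)); voi[2:5, 2:5, 3:5] <- TRUE
  fm <- extract_features(vol, voxel_mask(voi, "voi"))
  expect_true(all(fm$X[, 1] == 0))                 # normalized intensity
  expect_true(all(fm$X[, 6:18] == 0))              # contrast
  expect_true(all(fm$X[, 32:44] == 1))             # energy
  expect_true(all(fm$X[, 45:57] == 1))             # homogeneity
})

test_that("the full descriptor equals per-feature brute force on random volumes", {
  set.seed(25)
  vol <- oct_volume(array(runif(9^3), c(9, 9, 9)), c(1, 1, 1))
  voi <- array(FALSE, c(9, 9, 9))
  voi[cbind(sample(9, 8, TRUE), sample(9, 8, TRUE), sample(9, 8, TRUE))] <- TRUE
  fm <- extract_features(vol, voxel_mask(voi, "voi"))
  for (r in seq_len(nrow(fm$X))) {
    want <- oracle_feature_row(vol$intensities, voi, fm$voxels[r, ])
    expect_equal(unname(fm$X[r, ]), want, tolerance = 1e-10)
  }
})

test_that("PCA standardizes, returns 10 orthonormal components, and warns", {
  set.seed(26)
  X <- matrix(rnorm(300 * 57), 300)
  X[, 10] <- 0                               # zero-variance column passes as zeros
  expect_warning(m <- fit_pca(X), "variance")  # noise: 10 comps explain < 90%
  expect_equal(ncol(m$rotation), 10L)
  S <- apply_pca(m, X)
  expect_equal(ncol(S), 10L)
  expect_lt(max(abs(crossprod(m$rotation) - diag(10))), 1e-8)
  # projected training columns are uncorrelated
  cv <- cov(S)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-8)
  expect_error(fit_pca(X[1:10, ]), "at least")

  # rank-2 data: everything beyond 2 components is numerically empty
  B <- matrix(rnorm(200 * 2), 200) %*% matrix(rnorm(2 * 57), 2)
  m2 <- suppressWarnings(fit_pca(B))
  expect_lt(sum(m2$explained_variance_ratio[3:10]), 1e-8)
  expect_gt(sum(m2$explained_variance_ratio[1:2]), 0.999)
})
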