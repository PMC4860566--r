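test_that("bilateral filtering preserves constants and never widens the range", {
  p <- bilateral_params()
  const <- matrix(0.4, 16, 20)
  expect_equal(ezdetect:::bilateral_slice(const, p), const)

  ph <- generate_phantom(small_phantom_config(seed = 2))
  den <- bilateral_filter_volume(ph$volume)
  expect_equal(dim(den), dim(ph$volume))
  for (j in seq_len(ph$volume$ny)) {
    sl <- ph$volume$intensities[, j, ]
    fl <- den$intensities[, j, ]
    expect_gte(min(fl), min(sl) - 1e-12)
    expect_lte(max(fl), max(sl) + 1e-12)
  }
  bad <- ph$volume
  bad$intensities[1] <- NA
  expect_error(bilateral_filter_volume(bad), "finite")
})

test_that("bilateral filter matches the direct double-loop oracle", {
  set.seed(5)
  p <- bilateral_params(sigma_spatial = 1.5, sigma_range = 0.3,
                        downsample_spatial = 1, downsample_range = 1)
  imgs <- list(matrix(c(rep(0, 12), 1, rep(0, 12)), 5, 5),
               matrix(runif(25), 5, 5),
               matrix(runif(25, 2, 7), 5, 5))
  for (img in imgs) {
    got <- ezdetect:::bilateral_slice(img, p)
    want <- oracle_bilateral(img, 1.5, 0.3)
    expect_lt(abs(got[3, 3] - want[3, 3]) / abs(want[3, 3]), 0.02)
  }
})

test_that("huge sigma_range degrades to pure spatial Gaussian smoothing", {
  set.seed(6)
  img <- matrix(runif(49), 7, 7)
  p <- bilateral_params(sigma_spatial = 1.2, sigma_range = 1e6,
                        downsample_spatial = 1, downsample_range = 1)
  got <- ezdetect:::bilateral_slice(img, p)
  # direct spatial-only convolution with the same truncated kernel support
  want <- img
  for (i in 1:7) for (j in 1:7) {
    w <- 0; v <- 0
    for (a in 1:7) for (b in 1:7) {
      wt <- exp(-((i - a)^2 + (j - b)^2) / (2 * 1.2^2))
      w <- w + wt; v <- v + wt * img[a, b]
    }
    want[i, j] <- v / w
  }
  expect_lt(max(abs(got - want)), 0.02 * diff(range(img)))
})

test_that("scanline DP attains the exhaustive-search optimum", {
  set.seed(7)
  for (rep in 1:5) {
    cost <- matrix(rnorm(5 * 7), 5, 7)
    lo <- sample(1:2, 5, replace = TRUE)
    hi <- sample(5:7, 5, replace = TRUE)
    for (delta in 1:2) {
      got <- ezdetect:::dp_scanline(cost, lo, hi, delta)
      want <- oracle_best_path(cost, lo, hi, delta)
      expect_equal(got$total, want, tolerance = 1e-12)
      # returned path is feasible
      expect_true(all(diff(got$z) <= delta & diff(got$z) >= -delta))
      expect_true(all(got$z >= lo & got$z <= hi))
    }
  }
})

test_that("segmentation returns 11 ordered surfaces and recovers noise-free truth", {
  cfg <- small_phantom_config(speckle_sd = 0, n_disruptions = 0, n_vessels = 0,
                              seed = 11)
  ph <- generate_phantom(cfg)
  for (lv in 1:2) {
    s <- segment_surfaces(ph$volume, graph_search_params(levels = lv))
    expect_equal(dim(s$z_of)[1], 11L)
    for (k in 1:10) expect_true(all(s$z_of[k, , ] <= s$z_of[k + 1, , ] + 1e-9))
    expect_lte(max(abs(s$z_of - ph$truth$surfaces$z_of)), 1.0)
  }
  # ordering also holds under default speckle
  phn <- generate_phantom(small_phantom_config(seed = 12))
  sn <- segment_surfaces(bilateral_filter_volume(phn$volume))
  for (k in 1:10) expect_true(all(sn$z_of[k, , ] <= sn$z_of[k + 1, , ] + 1e-9))
})

test_that("infeasible separation constraints are reported", {
  ph <- generate_phantom(small_phantom_config(speckle_sd = 0, seed = 1))
  p <- graph_search_params(min_sep = rep(30, 10), max_sep = rep(40, 10))
  expect_error(segment_surfaces(ph$volume, p), "min separations")
})

test_that("TPS smoothing reproduces planes and regularization flattens", {
  nx <- 24; ny <- 10
  plane <- outer(seq_len(nx) * 0.2, rep(1, ny)) +
           outer(rep(1, nx), seq_len(ny) * 0.5) + 20
  z <- array(0, c(11, nx, ny))
  for (s in 1:11) z[s, , ] <- plane + 3 * (s - 1)
  ss <- surface_set(z)
  sm <- smooth_surfaces_tps(ss, robust_iter = 0)
  expect_lt(max(abs(sm$z_of - ss$z_of)), 1e-6)

  # curved surface pushed toward its best-fit plane as regularization grows
  set.seed(13)
  curved <- plane + 4 * sin(outer(seq_len(nx) / 3, rep(1, ny)))
  z2 <- z
  z2[5, , ] <- curved
  z2 <- aperm(apply(z2, c(2, 3), sort), c(1, 2, 3))  # keep ordering
  dim(z2) <- c(11, nx, ny)
  ss2 <- surface_set(z2)
  sm2 <- smooth_surfaces_tps(ss2, regularization = 1e8, robust_iter = 0)
  df <- data.frame(x = as.vector(row(curved)), y = as.vector(col(curved)),
                   z = as.vector(z2[5, , ]))
  planefit <- predict(lm(z ~ x + y, df))
  expect_lt(max(abs(as.vector(sm2$z_of[5, , ]) - planefit)), 0.05)
})

test_that("TPS smoothing reduces noise on a sampled sinusoid surface", {
  set.seed(14)
  nx <- 40; ny <- 12
  truth <- 30 + 3 * outer(sin(seq_len(nx) / 6), cos(seq_len(ny) / 4))
  z <- array(0, c(11, nx, ny))
  for (s in 1:11) z[s, , ] <- truth + 4 * (s - 1)
  noisy <- z + array(rnorm(length(z), sd = 0.8), dim(z))
  noisy <- aperm(apply(noisy, c(2, 3), sort), c(1, 2, 3))
  dim(noisy) <- c(11, nx, ny)
  sm <- smooth_surfaces_tps(surface_set(noisy))
  rms <- function(a, b) sqrt(mean((a - b)^2))
  expect_lt(rms(sm$z_of[5, , ], truth + 16), rms(noisy[5, , ], truth + 16))
})

test_that("flattening aligns surface 11 and is idempotent", {
  ph <- generate_phantom(small_phantom_config(speckle_sd = 0, seed = 15))
  fl <- flatten(ph$volume, ph$truth$surfaces)
  r11 <- round(fl$surfaces$z_of[11, , ])
  expect_equal(length(unique(as.vector(r11))), 1L)
  expect_equal(dim(fl$volume), dim(ph$volume))
  # second flattening is the identity
  fl2 <- flatten(fl$volume, fl$surfaces)
  expect_true(all(fl2$shifts == 0))
  expect_identical(fl2$volume$intensities, fl$volume$intensities)
})

test_that("VOI follows the half-open [round(z7), round(z8)) convention", {
  nx <- 4; ny <- 3; nz <- 20
  z <- array(0, c(11, nx, ny))
  for (s in 1:11) z[s, , ] <- s
  z[7, , ] <- 10; z[8, , ] <- 14
  z[9, , ] <- 15; z[10, , ] <- 16; z[11, , ] <- 17
  vol <- oct_volume(array(0, c(nx, ny, nz)), c(1, 1, 1))
  voi <- extract_voi(vol, surface_set(z, nz = nz))
  expect_true(all(voi$values[1, 1, 10:13]))
  expect_false(any(voi$values[1, 1, c(1:9, 14:20)]))
  # degenerate column keeps one voxel
  z[8, , ] <- 10.2
  z[9, , ] <- 10.2; z[10, , ] <- 10.4; z[11, , ] <- 17
  voi2 <- extract_voi(vol, surface_set(z, nz = nz))
  expect_equal(sum(voi2$values[2, 2, ]), 1L)
  expect_true(voi2$values[2, 2, 10])
})

test_that("VOI contains the planted disruption and has consistent physical volume", {
  cfg <- small_phantom_config(seed = 16)
  ph <- generate_phantom(cfg)
  voi <- extract_voi(ph$volume, ph$truth$surfaces)
  expect_true(all(voi$values[ph$truth$disruption_mask$values]))
  vol_mm3 <- disruption_volume(voi, cfg$voxel_size_um)
  z <- ph$truth$surfaces$z_of
  expected <- sum(z[8, , ] - z[7, , ]) * prod(cfg$voxel_size_um) * 1e-9
  one_layer <- cfg$nx * cfg$ny * prod(cfg$voxel_size_um) * 1e-9
  expect_lt(abs(vol_mm3 - expected), one_layer)
})
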