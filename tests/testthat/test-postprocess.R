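make_flat_surfaces <- function(nx, ny, depths) {
  z <- array(0, c(11, nx, ny))
  for (s in 1:11) z[s, , ] <- depths[s]
  surface_set(z)
}

test_that("en face projection averages the half-open band", {
  nx <- 6; ny <- 4; nz <- 30
  depths <- seq(4, 24, by = 2)
  s <- make_flat_surfaces(nx, ny, depths)
  vol <- oct_volume(array(0.3, c(nx, ny, nz)), c(1, 1, 1))
  pr <- en_face_projection(vol, s, c(8, 11))
  expect_true(all(pr$values == 0.3))
  # band of height 2 with values 1 and 3 averages to 2
  v2 <- array(0, c(nx, ny, nz))
  v2[, , depths[8]] <- 1; v2[, , depths[8] + 1] <- 3
  s2 <- s; s2$z_of[9:11, , ] <- depths[8] + 2
  s2$z_of[9, , ] <- depths[8] + 2
  pr2 <- en_face_projection(oct_volume(v2, c(1, 1, 1)), s2, c(8, 9))
  expect_true(all(pr2$values == 2))
  expect_error(en_face_projection(vol, s, c(11, 8)), "ordered")
  # degenerate band falls back to the single voxel and flags the column
  s3 <- s; s3$z_of[9, , ] <- depths[8]
  pr3 <- en_face_projection(oct_volume(v2, c(1, 1, 1)), s3, c(8, 9))
  expect_true(all(attr(pr3, "empty_columns")))
  expect_true(all(pr3$values == 1))
})

test_that("projection under a vessel shadow is markedly darker", {
  ph <- generate_phantom(phantom_config(seed = 21, n_disruptions = 0))
  den <- bilateral_filter_volume(ph$volume)
  fl <- flatten(den, ph$truth$surfaces)
  pr <- en_face_projection(fl$volume, fl$surfaces, c(8, 11))
  vm <- ph$truth$vessel_map
  expect_lt(median(pr$values[vm]), 0.8 * median(pr$values[!vm]))
})

test_that("the KNN vessel detector finds planted vessels with few false alarms", {
  ph <- generate_phantom(phantom_config(seed = 21, n_disruptions = 0))
  den <- bilateral_filter_volume(ph$volume)
  fl <- flatten(den, ph$truth$surfaces)
  pr <- en_face_projection(fl$volume, fl$surfaces, c(8, 11))
  vm <- detect_vessels(pr)
  truth <- ph$truth$vessel_map
  expect_equal(dim(vm), dim(truth))
  expect_gte(sum(vm & truth) / sum(truth), 0.8)
  expect_lte(sum(vm & !truth) / sum(!truth), 0.05)
  # constant image has no vessels
  expect_false(any(detect_vessels(en_face_image(matrix(0.5, 40, 20)))))
  # adaptive fallback also finds the planted paths
  va <- detect_vessels(pr, vessel_detector_config(method = "adaptive"))
  expect_gte(sum(va & truth) / sum(truth), 0.8)
})

test_that("vessel-based removal clears shadows but keeps off-vessel lesions", {
  nx <- 40; ny <- 20; nz <- 10
  m <- array(FALSE, c(nx, ny, nz))
  vessel <- matrix(FALSE, nx, ny); vessel[18:20, ] <- TRUE
  # detections exactly under the vessel vanish
  m[18:20, , 5] <- TRUE
  expect_false(any(remove_vessel_detections(m, vessel)))
  # empty vessel map leaves the mask unchanged
  expect_identical(remove_vessel_detections(m, matrix(FALSE, nx, ny)), m)
  # an off-vessel blob crossed by the vessel keeps its non-overlap part
  m2 <- array(FALSE, c(nx, ny, nz))
  m2[10:30, 8:12, 5] <- TRUE
  out <- remove_vessel_detections(m2, vessel)
  expect_false(any(out[18:20, , ]))
  expect_true(all(out[10:17, 8:12, 5]))
  expect_true(all(out[21:30, 8:12, 5]))
  # with clear_overlap = FALSE the crossing lesion is left intact
  keep <- remove_vessel_detections(m2, vessel, clear_overlap = FALSE)
  expect_identical(keep, m2)
  # the columns rule clears exactly the overlap
  cols <- remove_vessel_detections(m2, vessel, rule = "columns")
  expect_identical(cols, out)
  # removal never adds voxels
  expect_true(all(which(out) %in% which(m2)))
})

test_that("morphological cleanup removes specks, keeps cores, and is idempotent", {
  nx <- 48; ny <- 48; nz <- 8
  voi <- array(FALSE, c(nx, ny, nz)); voi[, , 4:5] <- TRUE
  # an isolated en face pixel is erased
  m <- array(FALSE, c(nx, ny, nz)); m[10, 10, 4] <- TRUE
  expect_false(any(morphological_cleanup(m, radius = 5, voi = voi)))
  # a solid disk of radius 12 keeps every pixel at distance >= 5 from its rim
  d2 <- outer((seq_len(nx) - 24)^2, (seq_len(ny) - 24)^2, "+")
  disk <- d2 <= 12^2
  m2 <- voi & array(rep(disk, nz), c(nx, ny, nz))
  out <- morphological_cleanup(m2, radius = 5, voi = voi)
  core <- d2 <= 7^2
  fp <- apply(out, c(1, 2), any)
  expect_true(all(fp[core]))
  # idempotence
  out2 <- morphological_cleanup(out, radius = 5, voi = voi)
  expect_identical(out2, out)
  # closing fills an isolated hole inside a large detection
  m3 <- m2
  m3[24, 24, ] <- FALSE
  out3 <- morphological_cleanup(m3, radius = 5, voi = voi)
  expect_true(all(out3[24, 24, 4:5]))
  expect_error(morphological_cleanup(m2, radius = 5), "voi")
})

test_that("the 3D ball element behaves like a volumetric opening/closing", {
  a <- array(FALSE, c(20, 20, 20))
  a[5:16, 5:16, 5:16] <- TRUE      # 12-cube survives radius-2 ball opening
  a[2, 2, 2] <- TRUE               # isolated voxel does not
  out <- morphological_cleanup(a, element = "ball3d", radius = 2)
  expect_false(out[2, 2, 2])
  expect_true(all(out[7:14, 7:14, 7:14]))
  expect_identical(morphological_cleanup(out, element = "ball3d", radius = 2), out)
})

test_that("post-processing never increases false positives on vessel-only phantoms", {
  ph <- generate_phantom(phantom_config(seed = 22, n_disruptions = 0))
  den <- bilateral_filter_volume(ph$volume)
  fl <- flatten(den, ph$truth$surfaces)
  voi <- extract_voi(fl$volume, fl$surfaces)
  # plant false positives exactly at the vessel columns
  fake <- voi$values & array(rep(ph$truth$vessel_map, 128), dim(voi$values))
  pr <- en_face_projection(fl$volume, fl$surfaces, c(8, 11))
  vm <- detect_vessels(pr)
  cleaned <- remove_vessel_detections(voxel_mask(fake, "disruption"), vm)
  expect_lte(sum(cleaned$values), sum(fake))
  expect_lte(sum(cleaned$values) / max(sum(fake), 1), 0.2)
})
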