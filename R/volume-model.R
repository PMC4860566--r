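#' @useDynLib ezdetect, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median prcomp qt rgamma rnorm runif sd t.test cor.test
#' @importFrom utils head tail
NULL

# ---- OCT volume -------------------------------------------------------------

#' Construct an OCT volume
#'
#' An `oct_volume` holds a 3D intensity grid indexed `[x, y, z]`, where `x` is
#' the lateral position within a B-scan, `y` the B-scan index and `z` the
#' axial depth increasing toward the choroid. Intensities are stored as reals
#' in their native range; no rescaling is applied.
#'
#' @param intensities 3D numeric array, dimensions `(nx, ny, nz)`, all finite.
#' @param voxel_size_um length-3 positive numeric: physical voxel size
#'   (dx, dy, dz) in micrometres.
#' @param id character label for the volume.
#' @return An object of class `oct_volume` with elements `intensities`,
#'   `nx`, `ny`, `nz`, `voxel_size_um`, `id`.
#' @export
oct_volume <- function(intensities, voxel_size_um, id = "volume") {
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    stop("intensities must be a 3D array")
  if (!all(is.finite(intensities)))
    stop("intensities must be finite")
  check_voxel_size(voxel_size_um)
  d <- dim(intensities)
  structure(
    list(intensities = intensities,
         nx = d[1L], ny = d[2L], nz = d[3L],
         voxel_size_um = as.numeric(voxel_size_um),
         id = as.character(id)[1L]),
    class = "oct_volume")
}

check_voxel_size <- function(v) {
  if (length(v) != 3L || !is.numeric(v) || any(!is.finite(v)) || any(v <= 0))
    stop("voxel_size_um must be three positive finite numbers")
  invisible(v)
}

#' @export
print.oct_volume <- function(x, ...) {
  cat(sprintf("<oct_volume '%s'> %d x %d x %d voxels, %.2f x %.2f x %.2f um\n",
              x$id, x$nx, x$ny, x$nz,
              x$voxel_size_um[1], x$voxel_size_um[2], x$voxel_size_um[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' @export
dim.oct_volume <- function(x) c(x$nx, x$ny, x$nz)

# ---- surface set ------------------------------------------------------------

#' Construct a set of 11 retinal surfaces
#'
#' Surfaces are stored at sub-voxel precision as axial positions (in voxel
#' index units, 1-based like R arrays) over the en face grid. Surface 1 is the
#' shallowest (inner limiting membrane), surface 11 the deepest (bottom of the
#' retinal pigment epithelium). The ordering invariant
#' `z[s] <= z[s+1]` is checked on every construction.
#'
#' @param z_of numeric array of shape `(11, nx, ny)`: axial position of each
#'   surface at each en face location.
#' @param nz optional axial extent; if given, positions must lie in `[1, nz]`.
#' @return An object of class `surface_set`.
#' @export
surface_set <- function(z_of, nz = NULL) {
  if (!is.array(z_of) || length(dim(z_of)) != 3L || dim(z_of)[1L] != 11L)
    stop("z_of must be an array of shape (11, nx, ny)")
  if (any(!is.finite(z_of))) stop("surface positions must be finite")
  for (s in 1:10)
    if (any(z_of[s, , ] > z_of[s + 1L, , ] + 1e-9))
      stop(sprintf("surface ordering violated between surfaces %d and %d", s, s + 1L))
  if (!is.null(nz) && (min(z_of) < 1 - 1e-9 || max(z_of) > nz + 1e-9))
    stop("surface positions outside [1, nz]")
  structure(list(z_of = z_of, nx = dim(z_of)[2L], ny = dim(z_of)[3L]),
            class = "surface_set")
}

#' @export
print.surface_set <- function(x, ...) {
  cat(sprintf("<surface_set> 11 surfaces on a %d x %d en face grid\n", x$nx, x$ny))
  rng <- apply(x$z_of, 1, range)
  cat(sprintf("  axial span per surface: %s\n",
              paste(sprintf("[%.1f,%.1f]", rng[1, ], rng[2, ]), collapse = " ")))
  invisible(x)
}

# ---- voxel masks ------------------------------------------------------------

#' Construct a binary voxel mask
#'
#' @param values 3D logical array congruent with its parent volume.
#' @param role one of "voi", "disruption", "ground_truth".
#' @return An object of class `voxel_mask`.
#' @export
voxel_mask <- function(values, role = c("voi", "disruption", "ground_truth")) {
  role <- match.arg(role)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("values must be a 3D array")
  storage.mode(values) <- "logical"
  if (any(is.na(values))) stop("mask values must not contain NA")
  structure(list(values = values, role = role), class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_mask role='%s'> %d x %d x %d, %d voxels set\n",
              x$role, d[1], d[2], d[3], sum(x$values)))
  invisible(x)
}

#' Construct an en face image
#'
#' A 2D real image over the `(x, y)` en face grid of a parent volume, e.g. a
#' depth-averaged projection.
#'
#' @param values 2D numeric matrix `(nx, ny)`.
#' @return An object of class `en_face_image`.
#' @export
en_face_image <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  structure(list(values = values, nx = nrow(values), ny = ncol(values)),
            class = "en_face_image")
}

# ---- volume I/O -------------------------------------------------------------

#' Read an OCT volume from TIFF or NIfTI
#'
#' Supported containers are multipage TIFF (one page per B-scan, page order =
#' y index, each page an X-Z image with rows = x and columns = z) and NIfTI-1
#' (array stored directly as `(nx, ny, nz)`). Physical voxel size comes from a
#' JSON sidecar of the form `{"voxel_size_um": [dx, dy, dz], "id": "..."}`.
#' Intensities are cast to double without rescaling.
#'
#' @param path volume file (`.tif`, `.tiff`, `.nii`, `.nii.gz`).
#' @param metadata_path JSON sidecar; defaults to `<path>.json`.
#' @return An [oct_volume].
#' @export
read_volume <- function(path, metadata_path = paste0(path, ".json")) {
  if (!file.exists(path)) stop(sprintf("volume file not found: %s", path))
  if (!file.exists(metadata_path))
    stop(sprintf("metadata sidecar not found: %s", metadata_path))
  meta <- jsonlite::fromJSON(metadata_path)
  if (is.null(meta$voxel_size_um))
    stop("metadata is missing field voxel_size_um")
  vs <- as.numeric(meta$voxel_size_um)
  if (length(vs) != 3L || any(!is.finite(vs)) || any(vs <= 0))
    stop("invalid voxel_size_um in metadata: must be 3 positive numbers")
  id <- if (!is.null(meta$id)) meta$id else sub("\\.[^.]*$", "", basename(path))

  arr <- if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    a <- RNifti::readNifti(path)
    a <- unclass(a)[, , , drop = FALSE]
    attributes(a) <- list(dim = dim(a))
    a
  } else {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
    if (!is.list(pages)) pages <- list(pages)
    nx <- nrow(pages[[1L]]); nz <- ncol(pages[[1L]]); ny <- length(pages)
    a <- array(0, c(nx, ny, nz))
    for (j in seq_len(ny)) {
      pg <- pages[[j]]
      if (nrow(pg) != nx || ncol(pg) != nz)
        stop("TIFF pages have inconsistent dimensions")
      a[, j, ] <- pg
    }
    a
  }
  storage.mode(arr) <- "double"
  if (!is.null(meta$shape)) {
    if (!all(as.integer(meta$shape) == dim(arr)))
      stop(sprintf("metadata field shape %s does not match volume dimensions %s",
                   paste(meta$shape, collapse = "x"),
                   paste(dim(arr), collapse = "x")))
  }
  oct_volume(arr, vs, id = id)
}

#' Write an OCT volume to TIFF or NIfTI with a JSON sidecar
#'
#' NIfTI output stores doubles and round-trips bit-for-bit. TIFF output
#' requires intensities in `[0, 1]` and stores samples at 32-bit depth, so a
#' TIFF round trip is exact to about 2.4e-10; use NIfTI where bit-exactness
#' matters.
#'
#' @param vol an [oct_volume].
#' @inheritParams read_volume
#' @return Invisibly, `path`.
#' @export
write_volume <- function(vol, path, metadata_path = paste0(path, ".json")) {
  stopifnot(inherits(vol, "oct_volume"))
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::asNifti(vol$intensities, datatype = "double")
    ok <- suppressWarnings(try(RNifti::writeNifti(img, path, datatype = "double"),
                               silent = TRUE))
    if (inherits(ok, "try-error") || !file.exists(path))
      stop(sprintf("failed to write NIfTI to %s", path))
  } else {
    if (min(vol$intensities) < 0 || max(vol$intensities) > 1)
      stop("TIFF output requires intensities in [0, 1]; use NIfTI for native-range data")
    pages <- lapply(seq_len(vol$ny), function(j) vol$intensities[, j, ])
    ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = 32L), silent = TRUE)
    if (inherits(ok, "try-error"))
      stop(sprintf("failed to write TIFF to %s", path))
  }
  meta <- list(voxel_size_um = vol$voxel_size_um, id = vol$id,
               shape = c(vol$nx, vol$ny, vol$nz))
  ok <- try(jsonlite::write_json(meta, metadata_path, auto_unbox = TRUE, digits = NA),
            silent = TRUE)
  if (inherits(ok, "try-error"))
    stop(sprintf("failed to write metadata to %s", metadata_path))
  invisible(path)
}

#' Read / write a binary mask
#'
#' Masks use the same containers as volumes, stored as 0/1.
#'
#' @param path,metadata_path as in [read_volume].
#' @param role mask role, see [voxel_mask].
#' @return A [voxel_mask].
#' @export
read_mask <- function(path, metadata_path = paste0(path, ".json"),
                      role = "disruption") {
  vol <- read_volume(path, metadata_path)
  voxel_mask(vol$intensities > 0.5, role = role)
}

#' @rdname read_mask
#' @param mask a [voxel_mask].
#' @param voxel_size_um voxel size recorded in the sidecar.
#' @export
write_mask <- function(mask, path, metadata_path = paste0(path, ".json"),
                       voxel_size_um = c(1, 1, 1)) {
  stopifnot(inherits(mask, "voxel_mask"))
  vol <- oct_volume(array(as.numeric(mask$values), dim(mask$values)),
                    voxel_size_um, id = mask$role)
  write_volume(vol, path, metadata_path)
}

#' Read / write a surface set as long-form CSV
#'
#' Columns `surface, x, y, z` with `surface` in 1..11 and `z` the (possibly
#' sub-voxel) axial position.
#'
#' @param path CSV file path.
#' @return A [surface_set].
#' @export
read_surfaces <- function(path) {
  df <- utils::read.csv(path)
  need <- c("surface", "x", "y", "z")
  if (!all(need %in% names(df))) stop("surface CSV must have columns surface, x, y, z")
  nx <- max(df$x); ny <- max(df$y)
  z_of <- array(NA_real_, c(11L, nx, ny))
  z_of[cbind(df$surface, df$x, df$y)] <- df$z
  if (any(is.na(z_of))) stop("surface CSV does not cover the full (surface, x, y) grid")
  surface_set(z_of)
}

#' @rdname read_surfaces
#' @param s a [surface_set].
#' @export
write_surfaces <- function(s, path) {
  stopifnot(inherits(s, "surface_set"))
  grid <- expand.grid(surface = 1:11, x = seq_len(s$nx), y = seq_len(s$ny))
  grid$z <- as.vector(s$z_of)
  utils::write.csv(grid, path, row.names = FALSE)
  invisible(path)
}

# ---- disruption volume ------------------------------------------------------

#' Physical volume of a disruption mask
#'
#' The disruption volume is the number of set voxels times the physical voxel
#' volume, reported in cubic millimetres (full precision, no rounding).
#'
#' @param mask a [voxel_mask] or 3D logical array.
#' @param voxel_size_um length-3 positive numeric (dx, dy, dz) in micrometres.
#' @return Volume in mm^3 (non-negative scalar).
#' @export
disruption_volume <- function(mask, voxel_size_um) {
  v <- if (inherits(mask, "voxel_mask")) mask$values else mask
  if (!is.logical(v)) stop("mask must be logical")
  check_voxel_size(voxel_size_um)
  sum(v) * prod(as.numeric(voxel_size_um)) * 1e-9
}
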