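# Post-processing: en face projection of the outer retina, vessel-silhouette
# detection (KNN on hand-crafted pixel features trained on synthetic
# fixtures), removal of detections under vessels, and morphological cleanup of
# isolated detections.

# ---- en face projection -----------------------------------------------------

#' En face mean projection between two surfaces
#'
#' Each pixel is the mean intensity along z over voxels with
#' `z in [round(z_a), round(z_b))` at that (x, y). Columns whose rounded band
#' is empty fall back to the single voxel at `round(z_a)` and are flagged in
#' `attr(, "empty_columns")`.
#'
#' @param vol a flattened [oct_volume].
#' @param s the matching [surface_set].
#' @param band surface index pair `(a, b)` with `a < b`; the default 8 to 11
#'   projects the EZ-to-RPE slab where vessel silhouettes contrast best.
#' @return An [en_face_image].
#' @export
en_face_projection <- function(vol, s, band = c(8L, 11L)) {
  stopifnot(inherits(vol, "oct_volume"), inherits(s, "surface_set"))
  if (band[1] >= band[2]) stop("band surfaces must be ordered (a < b)")
  nz <- vol$nz
  za <- pmin(pmax(round(s$z_of[band[1], , ]), 1L), nz)
  zb <- pmin(pmax(round(s$z_of[band[2], , ]), 1L), nz)
  img <- matrix(0, vol$nx, vol$ny)
  empty <- matrix(FALSE, vol$nx, vol$ny)
  for (j in seq_len(vol$ny)) for (i in seq_len(vol$nx)) {
    lo <- za[i, j]; hi <- zb[i, j] - 1L
    if (hi < lo) { img[i, j] <- vol$intensities[i, j, lo]; empty[i, j] <- TRUE }
    else img[i, j] <- mean(vol$intensities[i, j, lo:hi])
  }
  out <- en_face_image(img)
  attr(out, "empty_columns") <- empty
  out
}

# ---- pixel features for vessel detection ------------------------------------

# Sum of mat over a set of (dx, dy) offsets with edge-replicated indexing.
offset_filter <- function(mat, offs, weights = rep(1, nrow(offs))) {
  nx <- nrow(mat); ny <- ncol(mat)
  out <- matrix(0, nx, ny)
  for (i in seq_len(nrow(offs))) {
    rows <- pmin(pmax(seq_len(nx) + offs[i, 1], 1L), nx)
    cols <- pmin(pmax(seq_len(ny) + offs[i, 2], 1L), ny)
    out <- out + weights[i] * mat[rows, cols]
  }
  out
}

# Per-pixel features: normalized intensity, 9x9 local mean, 9x9 local std, and
# the maximum dark-line filter response over four orientations (local mean
# minus the mean along a length-9 line through the pixel; vessels are dark
# lines, so the response is positive on them).
vessel_pixel_features <- function(img) {
  v <- normalize_intensity(as.vector(img))
  m <- matrix(v, nrow(img), ncol(img))
  box <- as.matrix(expand.grid(dx = -4:4, dy = -4:4))
  n_box <- nrow(box)
  mu <- offset_filter(m, box) / n_box
  mu2 <- offset_filter(m^2, box) / n_box
  sdv <- sqrt(pmax(mu2 - mu^2, 0))
  lines <- list(cbind(-4:4, 0), cbind(0, -4:4), cbind(-4:4, -4:4), cbind(-4:4, 4:-4))
  resp <- matrix(-Inf, nrow(img), ncol(img))
  for (ln in lines) {
    lm <- offset_filter(m, ln) / nrow(ln)
    resp <- pmax(resp, mu - lm)
  }
  cbind(intensity = as.vector(m), local_mean = as.vector(mu),
        local_std = as.vector(sdv), line_response = as.vector(resp))
}

#' Vessel detector configuration
#'
#' @param band projection surface pair (deeper slab), default 8 to 11.
#' @param k KNN neighbour count (odd, >= 1).
#' @param threshold vote fraction required to call a pixel vessel.
#' @param n_train number of synthetic training projections.
#' @param train_seed seed for the synthetic training fixtures.
#' @param component_min detected components smaller than this many pixels are
#'   discarded.
#' @param method "knn" (default) or the parameter-free "adaptive" threshold
#'   fallback.
#' @return A list of class `vessel_detector_config`.
#' @export
vessel_detector_config <- function(band = c(8L, 11L), k = 15L, threshold = 0.5,
                                   n_train = 4L, train_seed = 42L,
                                   component_min = 5L,
                                   method = c("knn", "adaptive")) {
  method <- match.arg(method)
  if (k < 1L || k %% 2L == 0L) stop("k must be odd and >= 1")
  if (band[1] >= band[2]) stop("band surfaces must be ordered")
  structure(list(band = band, k = as.integer(k), threshold = threshold,
                 n_train = as.integer(n_train), train_seed = as.integer(train_seed),
                 component_min = as.integer(component_min), method = method),
            class = "vessel_detector_config")
}

# Synthetic labelled projection fixtures: smooth bright background crossed by
# dark vessel paths, with mild multiplicative noise — the en face appearance
# of the outer-retina slab.
vessel_training_set <- function(cfg) {
  with_seed(cfg$train_seed, {
    X <- NULL; y <- NULL
    for (i in seq_len(cfg$n_train)) {
      pc <- phantom_config(nx = 96L, ny = 32L, n_vessels = sample(2:4, 1),
                           vessel_width = runif(1, 2, 4), seed = sample.int(1e6, 1))
      vm <- phantom_vessel_map(pc)
      xs <- seq_len(pc$nx); ys <- seq_len(pc$ny)
      bg <- 0.55 + 0.1 * outer(sin(2 * pi * xs / pc$nx), cos(2 * pi * ys / pc$ny))
      img <- bg
      img[vm] <- img[vm] * pc$vessel_attenuation
      img <- img * matrix(rgamma(length(img), 60, 60), nrow(img))
      f <- vessel_pixel_features(img)
      lab <- as.vector(vm)
      bgp <- which(!lab)
      keep <- c(which(lab), sample(bgp, min(length(bgp), 3L * sum(lab))))
      X <- rbind(X, f[keep, ]); y <- c(y, lab[keep])
    }
    list(X = X, y = y)
  })
}

#' Detect vessel silhouettes in an en face projection
#'
#' KNN classification of per-pixel features (intensity, 9x9 local mean and
#' std, max directional dark-line response), trained on labelled synthetic
#' projection fixtures generated from the detector seed. Connected components
#' smaller than `component_min` pixels are removed. The "adaptive" method is a
#' parameter-free fallback thresholding at 70% of the image median.
#'
#' @param img an [en_face_image] or numeric matrix.
#' @param cfg a [vessel_detector_config].
#' @return Logical matrix of the same shape (TRUE = vessel).
#' @export
detect_vessels <- function(img, cfg = vessel_detector_config()) {
  m <- if (inherits(img, "en_face_image")) img$values else img
  if (max(m) - min(m) <= 0) return(matrix(FALSE, nrow(m), ncol(m)))
  vm <- if (cfg$method == "adaptive") {
    matrix(as.vector(m) < 0.7 * median(m), nrow(m), ncol(m))
  } else {
    tr <- vessel_training_set(cfg)
    f <- vessel_pixel_features(m)
    ctr <- colMeans(tr$X); scl <- apply(tr$X, 2, sd); scl[scl <= 0] <- 1
    ztr <- sweep(sweep(tr$X, 2, ctr), 2, scl, "/")
    zte <- sweep(sweep(f, 2, ctr), 2, scl, "/")
    pred <- class::knn(ztr, zte, factor(tr$y), k = cfg$k, prob = TRUE)
    frac <- attr(pred, "prob")
    vote_vessel <- ifelse(pred == "TRUE", frac, 1 - frac)
    matrix(vote_vessel >= cfg$threshold, nrow(m), ncol(m))
  }
  drop_small_components(vm, cfg$component_min)
}

drop_small_components <- function(mask, min_size) {
  if (!any(mask) || min_size <= 1L) return(mask)
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_size)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

# ---- vessel-based removal ---------------------------------------------------

#' Remove detections that coincide with vessel silhouettes
#'
#' Each en face connected component of the detection that touches the vessel
#' map is removed entirely when it lies wholly inside the vessel map dilated
#' by `dilate_radius`; otherwise only the overlapping columns are cleared.
#' Never adds voxels.
#'
#' @param mask3d detection [voxel_mask] (or 3D logical array).
#' @param vessel_map nx x ny logical vessel map.
#' @param dilate_radius dilation radius for the whole-component rule.
#' @param rule "component" (default) or "columns" (clear only the overlap).
#' @param clear_overlap with the component rule, also clear the overlapping
#'   columns of components that are not wholly inside the dilated vessel map
#'   (default TRUE). The pipeline sets this to FALSE before morphological
#'   cleanup so that a vessel crossing a large lesion does not fragment its
#'   footprint ahead of the size filtering, and clears the overlap afterwards.
#' @return The filtered detection mask (same class as the input).
#' @export
remove_vessel_detections <- function(mask3d, vessel_map, dilate_radius = 2L,
                                     rule = c("component", "columns"),
                                     clear_overlap = TRUE) {
  rule <- match.arg(rule)
  was_mask <- inherits(mask3d, "voxel_mask")
  m <- if (was_mask) mask3d$values else mask3d
  if (!all(dim(m)[1:2] == dim(vessel_map)))
    stop("vessel map shape does not match the mask's en face grid")
  if (any(vessel_map) && any(m)) {
    fp <- apply(m, c(1, 2), any)
    clear <- matrix(FALSE, nrow(fp), ncol(fp))
    if (rule == "columns") {
      clear <- fp & vessel_map
    } else {
      vdil <- if (dilate_radius > 0)
        EBImage::dilate(vessel_map + 0,
                        EBImage::makeBrush(2L * dilate_radius + 1L, "disc")) > 0
      else vessel_map
      lab <- EBImage::bwlabel(fp)
      for (cmp in seq_len(max(lab))) {
        px <- lab == cmp
        if (!any(px & vessel_map)) next
        clear <- clear | (if (all(vdil[px])) px
                          else if (clear_overlap) px & vessel_map
                          else matrix(FALSE, nrow(fp), ncol(fp)))
      }
    }
    m <- m & !array(rep(clear, times = dim(m)[3]), dim(m))
  }
  if (was_mask) voxel_mask(m, mask3d$role) else m
}

# ---- morphological cleanup --------------------------------------------------

shift3_logical <- function(a, o) {
  d <- dim(a)
  out <- array(FALSE, d)
  src <- lapply(1:3, function(ax) {
    s <- seq_len(d[ax]) + o[ax]
    s[s < 1L | s > d[ax]] <- NA
    s
  })
  ok1 <- !is.na(src[[1]]); ok2 <- !is.na(src[[2]]); ok3 <- !is.na(src[[3]])
  out[ok1, ok2, ok3] <- a[src[[1]][ok1], src[[2]][ok2], src[[3]][ok3]]
  out
}

ball_offsets <- function(r) {
  g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  as.matrix(g[g$dx^2 + g$dy^2 + g$dz^2 <= r^2, ])
}

erode3 <- function(a, offs) {
  out <- array(TRUE, dim(a))
  for (i in seq_len(nrow(offs))) out <- out & shift3_logical(a, offs[i, ])
  out
}

dilate3 <- function(a, offs) {
  out <- array(FALSE, dim(a))
  for (i in seq_len(nrow(offs))) out <- out | shift3_logical(a, -offs[i, ])
  out
}

#' Morphological cleanup of a detection mask
#'
#' Opening (removes isolated detections) followed by closing (fills isolated
#' holes) with the same structuring element. The default element is a 2D disk
#' of radius 5 applied to the mask's en face footprint: the EZ slab is only a
#' few voxels thick, so a literal 3D ball of that radius would erase
#' everything; in the footprint mode each column's VOI voxels are set or
#' cleared together. A 3D ball element is available via `element = "ball3d"`.
#'
#' @param mask detection [voxel_mask] (or 3D logical array).
#' @param element "disk2d" (default) or "ball3d".
#' @param radius element radius in voxels (default 5).
#' @param voi [voxel_mask] for the EZ slab; required for "disk2d" to know
#'   which voxels a column contributes.
#' @return The cleaned mask (same class as the input).
#' @export
morphological_cleanup <- function(mask, element = c("disk2d", "ball3d"),
                                  radius = 5L, voi = NULL) {
  element <- match.arg(element)
  was_mask <- inherits(mask, "voxel_mask")
  m <- if (was_mask) mask$values else mask
  if (element == "disk2d") {
    if (is.null(voi)) stop("disk2d cleanup needs the VOI mask (voi)")
    v <- if (inherits(voi, "voxel_mask")) voi$values else voi
    fp <- apply(m, c(1, 2), any)
    brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, "disc")
    fp2 <- EBImage::closing(EBImage::opening(fp + 0, brush), brush) > 0
    keep <- array(rep(fp2, times = dim(m)[3]), dim(m))
    out <- v & keep
  } else {
    offs <- ball_offsets(as.integer(radius))
    out <- dilate3(erode3(m, offs), offs)          # opening
    out <- erode3(dilate3(out, offs), offs)        # then closing
  }
  if (was_mask) voxel_mask(out, mask$role) else out
}
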