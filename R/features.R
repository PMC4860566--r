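# Per-voxel 57-feature descriptor over the EZ VOI: normalized intensity, 5x5x5
# block statistics, directional absolute differences (steps 1 and 2), and
# GLCM contrast / correlation / energy / homogeneity over 13 3D directions,
# plus PCA reduction to 10 scores. Scalar reference implementations live here;
# the full-matrix build is an Rcpp loop checked against them in the tests.

#' The 13 co-occurrence directions
#'
#' Directions are parameterised by angles (alpha1, alpha2): `alpha1` is the
#' angle between the X axis and the direction's projection onto the X-Y
#' plane, `alpha2` the elevation of the direction from the Z axis
#' (`alpha2 = 90` degrees is in-plane, `alpha2 = 0` the pure axial
#' direction). Twelve canonical angle pairs plus the completing half-axis
#' (alpha1, alpha2) = (-45, 45) give the 13 distinct, pairwise
#' non-antiparallel offsets covering every 26-neighbourhood axis once.
#'
#' @return A 13 x 3 integer matrix of (dx, dy, dz) offsets, each component in
#'   {-1, 0, 1}.
#' @export
direction_offsets <- function() {
  ang <- rbind(
    c(0, 90), c(45, 90), c(90, 90), c(135, 90),
    c(0, 45), c(180, 45), c(90, 45), c(-90, 45),
    c(0, 0),
    c(45, 45), c(135, 45), c(-135, 45),
    c(-45, 45))
  rad <- pi / 180
  d <- cbind(cos(ang[, 1] * rad) * sin(ang[, 2] * rad),
             sin(ang[, 1] * rad) * sin(ang[, 2] * rad),
             cos(ang[, 2] * rad))
  offs <- sign(round(d, 10))
  storage.mode(offs) <- "integer"
  colnames(offs) <- c("dx", "dy", "dz")
  offs
}

#' Min-max normalize intensities
#'
#' Normalizes to `[0, 1]` over the supplied values (one volume's VOI voxels).
#' A constant input maps to all zeros.
#'
#' @param values numeric vector.
#' @return Values rescaled to `[0, 1]`.
#' @export
normalize_intensity <- function(values) {
  lo <- min(values); hi <- max(values)
  if (hi - lo <= 0) return(rep(0, length(values)))
  (values - lo) / (hi - lo)
}

#' Local block mean and standard deviation
#'
#' Statistics of the block of `2*half+1` voxels per side centred on a voxel,
#' cropped to the volume at edges. The standard deviation is the population
#' form (divisor N).
#'
#' @param vol 3D numeric array or [oct_volume].
#' @param centre length-3 integer voxel index (x, y, z), 1-based.
#' @param half block half-width (default 2, i.e. a 5 x 5 x 5 block).
#' @return `c(mean, std)`.
#' @export
block_stats <- function(vol, centre, half = 2L) {
  a <- if (inherits(vol, "oct_volume")) vol$intensities else vol
  d <- dim(a)
  xs <- max(1L, centre[1] - half):min(d[1], centre[1] + half)
  ys <- max(1L, centre[2] - half):min(d[2], centre[2] + half)
  zs <- max(1L, centre[3] - half):min(d[3], centre[3] + half)
  b <- a[xs, ys, zs]
  m <- mean(b)
  c(mean = m, std = sqrt(mean((b - m)^2)))
}

#' Mean absolute intensity difference over the 13 directions
#'
#' For a centre voxel v and step s, the mean over the 13 directions d of
#' `|I(v) - I(v + s*d)|`; neighbours outside the volume are clamped to the
#' nearest voxel.
#'
#' @inheritParams block_stats
#' @param step 1 or 2.
#' @param agg aggregation over directions: "mean" (default), "max" or "sum".
#' @return A scalar.
#' @export
abs_diff_feature <- function(vol, centre, step = 1L, agg = c("mean", "max", "sum")) {
  agg <- match.arg(agg)
  stopifnot(step %in% c(1L, 2L))
  a <- if (inherits(vol, "oct_volume")) vol$intensities else vol
  d <- dim(a)
  offs <- direction_offsets()
  v0 <- a[centre[1], centre[2], centre[3]]
  diffs <- apply(offs, 1, function(o) {
    nb <- pmin(pmax(centre + step * o, 1L), d)
    abs(v0 - a[nb[1], nb[2], nb[3]])
  })
  switch(agg, mean = mean(diffs), max = max(diffs), sum = sum(diffs))
}

#' Grey-level co-occurrence matrix of a quantized block
#'
#' Counts co-occurring level pairs at the given integer offset (distance one
#' grid step along the direction triple), accumulated in both orientations
#' (symmetric) and normalized to sum 1. Pairs whose partner falls outside the
#' block are skipped. A block/direction with no valid pair returns an all-zero
#' matrix flagged with `attr(, "degenerate") = TRUE`.
#'
#' @param block 3D integer array of quantized levels in `[0, n_levels)`.
#' @param direction length-3 integer offset, e.g. a row of
#'   [direction_offsets()].
#' @param n_levels number of grey levels.
#' @return An `n_levels x n_levels` matrix summing to 1 (or 0 if degenerate).
#' @export
glcm <- function(block, direction, n_levels) {
  stopifnot(length(dim(block)) == 3L, length(direction) == 3L)
  if (min(block) < 0 || max(block) >= n_levels)
    stop("block levels must lie in [0, n_levels)")
  d <- dim(block)
  p <- matrix(0, n_levels, n_levels)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    nb <- c(x, y, z) + direction
    if (any(nb < 1L) || any(nb > d)) next
    l1 <- block[x, y, z] + 1L
    l2 <- block[nb[1], nb[2], nb[3]] + 1L
    p[l1, l2] <- p[l1, l2] + 1
    p[l2, l1] <- p[l2, l1] + 1
  }
  tot <- sum(p)
  if (tot == 0) {
    attr(p, "degenerate") <- TRUE
    return(p)
  }
  p / tot
}

#' Haralick properties of a normalized GLCM
#'
#' Contrast `sum p(x,y) (x-y)^2`, correlation
#' `sum (x-mux)(y-muy) p(x,y) / (sigx sigy)` (0 when either marginal is
#' degenerate), energy `sum p^2`, homogeneity `sum p / (1 + |x-y|)`.
#'
#' @param p normalized GLCM (sums to 1), e.g. from [glcm()]. An all-zero
#'   matrix flagged degenerate yields all-zero properties.
#' @return Named numeric vector `(contrast, correlation, energy, homogeneity)`.
#' @export
glcm_props <- function(p) {
  if (isTRUE(attr(p, "degenerate")) && sum(p) == 0)
    return(c(contrast = 0, correlation = 0, energy = 0, homogeneity = 0))
  if (abs(sum(p) - 1) > 1e-8) stop("GLCM must be normalized to sum 1")
  n <- nrow(p)
  lv <- seq_len(n) - 1
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(lv * px); muy <- sum(lv * py)
  sigx <- sqrt(sum((lv - mux)^2 * px)); sigy <- sqrt(sum((lv - muy)^2 * py))
  dx <- outer(lv, lv, "-")
  contrast <- sum(p * dx^2)
  corr <- if (sigx * sigy > 0)
    sum(outer(lv - mux, lv - muy) * p) / (sigx * sigy) else 0
  c(contrast = contrast, correlation = corr,
    energy = sum(p^2), homogeneity = sum(p / (1 + abs(dx))))
}

#' Names of the 57 descriptor columns, in table order
#' @return Character vector of length 57.
#' @export
feature_names <- function() {
  c("norm_intensity", "block_mean", "block_std",
    "abs_diff_step1", "abs_diff_step2",
    sprintf("glcm_contrast_d%02d", 1:13),
    sprintf("glcm_correlation_d%02d", 1:13),
    sprintf("glcm_energy_d%02d", 1:13),
    sprintf("glcm_homogeneity_d%02d", 1:13))
}

#' Extract the 57-feature descriptor for every VOI voxel
#'
#' Intensities are first min-max normalized over the volume's VOI voxels; all
#' features are computed on the normalized volume. GLCM quantization uses
#' `n_levels` equal bins over the VOI's normalized range `[0, 1]` (values
#' outside are clamped into the end bins). Voxels are ordered x-major, then y,
#' then z; columns follow the fixed table order of [feature_names()].
#'
#' @param vol an [oct_volume] (flattened recommended).
#' @param voi a [voxel_mask] with at least one voxel set.
#' @param n_levels GLCM grey-level count (default 8).
#' @param half block half-width (default 2).
#' @param abs_diff_agg aggregation for the directional difference features.
#' @return A list of class `ez_feature_matrix` with `X` (n x 57 matrix),
#'   `voxels` (n x 3 integer coordinates) and `dim` (volume extents).
#' @export
extract_features <- function(vol, voi, n_levels = 8L, half = 2L,
                             abs_diff_agg = c("mean", "max", "sum")) {
  stopifnot(inherits(vol, "oct_volume"), inherits(voi, "voxel_mask"))
  abs_diff_agg <- match.arg(abs_diff_agg)
  if (!any(voi$values)) stop("VOI is empty")
  if (!all(dim(voi$values) == dim(vol$intensities)))
    stop("VOI shape does not match volume")
  I <- vol$intensities
  vvals <- I[voi$values]
  lo <- min(vvals); hi <- max(vvals)
  In <- if (hi - lo > 0) (I - lo) / (hi - lo) else array(0, dim(I))
  q <- pmin(floor(pmin(pmax(In, 0), 1) * n_levels), n_levels - 1L)
  storage.mode(q) <- "integer"

  lin <- which(voi$values)
  vox <- arrayInd(lin, dim(I))
  agg_code <- match(abs_diff_agg, c("mean", "max", "sum")) - 1L
  X <- cpp_extract_features(In, q, vox - 1L, direction_offsets(),
                            as.integer(n_levels), as.integer(half), agg_code)
  colnames(X) <- feature_names()
  structure(list(X = X, voxels = vox, dim = dim(I)),
            class = "ez_feature_matrix")
}

#' @export
print.ez_feature_matrix <- function(x, ...) {
  cat(sprintf("<ez_feature_matrix> %d voxels x %d features\n",
              nrow(x$X), ncol(x$X)))
  invisible(x)
}

# ---- PCA --------------------------------------------------------------------

#' Fit a standardized PCA retaining the first 10 components
#'
#' Features are standardized to zero mean and unit variance (zero-variance
#' columns pass through as zeros) before the eigendecomposition. A warning is
#' emitted if the 10-component cumulative explained-variance ratio falls below
#' 0.90.
#'
#' @param X numeric matrix (n voxels x 57 features) or an `ez_feature_matrix`.
#' @param n_components number of retained components (default 10).
#' @return An object of class `ez_pca` with `center`, `scale`, `rotation`
#'   (p x 10) and `explained_variance_ratio`.
#' @export
fit_pca <- function(X, n_components = 10L) {
  if (inherits(X, "ez_feature_matrix")) X <- X$X
  n <- nrow(X); p <- ncol(X)
  if (n < n_components + 1L)
    stop(sprintf("PCA needs at least %d samples, got %d", n_components + 1L, n))
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  zero <- !is.finite(scl) | scl <= 0
  scl[zero] <- 1
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  Z[, zero] <- 0
  pc <- prcomp(Z, center = FALSE, scale. = FALSE)
  k <- min(n_components, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(n_components), drop = FALSE] * 0
  rot[, seq_len(k)] <- pc$rotation[, seq_len(k)]
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  evr10 <- sum(evr[seq_len(k)])
  if (evr10 < 0.90)
    warning(sprintf("first %d components explain only %.1f%% of the variance",
                    n_components, 100 * evr10))
  structure(list(center = ctr, scale = scl, zero_variance = zero,
                 rotation = rot, explained_variance_ratio = evr,
                 n_components = as.integer(n_components)),
            class = "ez_pca")
}

#' Project features onto a fitted PCA basis
#'
#' @param m an `ez_pca` from [fit_pca()].
#' @param X matrix with the same columns as the training features.
#' @return An `n x n_components` score matrix.
#' @export
apply_pca <- function(m, X) {
  stopifnot(inherits(m, "ez_pca"))
  if (inherits(X, "ez_feature_matrix")) X <- X$X
  if (ncol(X) != length(m$center)) stop("feature count does not match PCA model")
  Z <- sweep(sweep(X, 2, m$center), 2, m$scale, "/")
  Z[, m$zero_variance] <- 0
  Z %*% m$rotation
}

#' @export
print.ez_pca <- function(x, ...) {
  cat(sprintf("<ez_pca> %d features -> %d components (%.1f%% variance)\n",
              length(x$center), x$n_components,
              100 * sum(x$explained_variance_ratio[seq_len(x$n_components)])))
  invisible(x)
}
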