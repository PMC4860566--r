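# Pre-processing: per-B-scan fast bilateral denoising, 11-surface segmentation
# by coarse-to-fine column-wise dynamic programming, thin-plate-spline surface
# smoothing, flattening to surface 11, and EZ VOI extraction.

# ---- bilateral filtering ----------------------------------------------------

#' Bilateral filter parameters
#'
#' @param sigma_spatial spatial Gaussian width, pixels.
#' @param sigma_range range Gaussian width, intensity units; `NULL` means 10%
#'   of each slice's dynamic range.
#' @param downsample_spatial grid cell edge in pixels (>= 1); larger is faster
#'   and coarser. Default follows the spatial sigma.
#' @param downsample_range range cell size as a multiple of `sigma_range / 4`
#'   (>= 1); the default of 4 makes the range cell one sigma wide.
#' @return A list of class `bilateral_params`.
#' @export
bilateral_params <- function(sigma_spatial = 3, sigma_range = NULL,
                             downsample_spatial = max(1, floor(sigma_spatial)),
                             downsample_range = 4) {
  if (sigma_spatial <= 0) stop("sigma_spatial must be > 0")
  if (!is.null(sigma_range) && sigma_range <= 0) stop("sigma_range must be > 0")
  if (downsample_spatial < 1 || downsample_range < 1)
    stop("downsampling factors must be >= 1")
  structure(list(sigma_spatial = sigma_spatial, sigma_range = sigma_range,
                 downsample_spatial = downsample_spatial,
                 downsample_range = downsample_range),
            class = "bilateral_params")
}

gaussian_kernel1d <- function(sigma) {
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# Blur a 3D array along one axis with a 1D kernel, zero padding.
blur_axis <- function(a, k, axis) {
  r <- (length(k) - 1L) / 2L
  d <- dim(a)
  out <- array(0, d)
  n <- d[axis]
  for (i in seq_along(k)) {
    o <- i - r - 1L
    src <- seq_len(n) + o
    ok <- src >= 1L & src <= n
    if (!any(ok)) next
    dst <- which(ok)
    idx_src <- src[ok]
    if (axis == 1L) out[dst, , ] <- out[dst, , ] + k[i] * a[idx_src, , ]
    else if (axis == 2L) out[, dst, ] <- out[, dst, ] + k[i] * a[, idx_src, ]
    else out[, , dst] <- out[, , dst] + k[i] * a[, , idx_src]
  }
  out
}

# Fast bilateral filter of one 2D slice via the bilateral grid: accumulate
# (intensity sum, weight) in a downsampled space x space x range grid, blur the
# grid with separable Gaussians, and read the ratio back by trilinear
# interpolation. With unit downsampling factors this reduces to the exact
# bilateral sum up to range binning.
bilateral_slice <- function(img, p) {
  lo <- min(img); hi <- max(img)
  if (hi - lo <= 0) return(img)
  sr <- if (is.null(p$sigma_range)) 0.1 * (hi - lo) else p$sigma_range
  cs <- p$downsample_spatial
  cr <- p$downsample_range * sr / 4

  gx_f <- (row(img) - 1) / cs + 1
  gz_f <- (col(img) - 1) / cs + 1
  gr_f <- (img - lo) / cr + 1
  pad <- 2L
  gx_f <- gx_f + pad; gz_f <- gz_f + pad; gr_f <- gr_f + pad
  GX <- as.integer(max(gx_f)) + pad + 1L
  GZ <- as.integer(max(gz_f)) + pad + 1L
  GR <- as.integer(max(gr_f)) + pad + 1L

  # trilinear splatting of (intensity, weight) into the grid
  wsum <- array(0, c(GX, GZ, GR)); w <- array(0, c(GX, GZ, GR))
  x0 <- floor(gx_f); z0 <- floor(gz_f); r0 <- floor(gr_f)
  fx <- gx_f - x0; fz <- gz_f - z0; fr <- gr_f - r0
  for (dx in 0:1) for (dz in 0:1) for (dr in 0:1) {
    wt <- (if (dx) fx else 1 - fx) * (if (dz) fz else 1 - fz) *
          (if (dr) fr else 1 - fr)
    idx <- (x0 + dx) + (z0 + dz - 1) * GX + (r0 + dr - 1) * GX * GZ
    acc <- rowsum(cbind(as.vector(wt * img), as.vector(wt)),
                  group = as.vector(idx))
    cells <- as.integer(rownames(acc))
    wsum[cells] <- wsum[cells] + acc[, 1L]
    w[cells] <- w[cells] + acc[, 2L]
  }

  ks <- gaussian_kernel1d(p$sigma_spatial / cs)
  kr <- gaussian_kernel1d(sr / cr)
  for (ax in 1:2) { wsum <- blur_axis(wsum, ks, ax); w <- blur_axis(w, ks, ax) }
  wsum <- blur_axis(wsum, kr, 3L); w <- blur_axis(w, kr, 3L)

  tri <- function(a) {
    x0 <- floor(gx_f); z0 <- floor(gz_f); r0 <- floor(gr_f)
    fx <- gx_f - x0; fz <- gz_f - z0; fr <- gr_f - r0
    v <- 0
    for (dx in 0:1) for (dz in 0:1) for (dr in 0:1) {
      wt <- (if (dx) fx else 1 - fx) * (if (dz) fz else 1 - fz) *
            (if (dr) fr else 1 - fr)
      v <- v + wt * a[cbind(as.vector(x0 + dx), as.vector(z0 + dz),
                            as.vector(r0 + dr))]
    }
    matrix(v, nrow(img), ncol(img))
  }
  num <- tri(wsum); den <- tri(w)
  out <- ifelse(den > 1e-12, num / den, img)
  pmin(pmax(out, lo), hi)
}

#' Denoise an OCT volume by per-B-scan fast bilateral filtering
#'
#' Each B-scan (X-Z slice) is filtered independently with a grid-based fast
#' bilateral approximation. The output never widens a slice's intensity range
#' (each filtered value is a convex combination of slice intensities).
#'
#' @param vol an [oct_volume] with finite intensities.
#' @param p a [bilateral_params].
#' @return A denoised [oct_volume] of the same shape.
#' @export
bilateral_filter_volume <- function(vol, p = bilateral_params()) {
  stopifnot(inherits(vol, "oct_volume"), inherits(p, "bilateral_params"))
  if (!all(is.finite(vol$intensities))) stop("intensities must be finite")
  out <- vol$intensities
  for (j in seq_len(vol$ny)) out[, j, ] <- bilateral_slice(vol$intensities[, j, ], p)
  oct_volume(out, vol$voxel_size_um, id = vol$id)
}

# ---- surface segmentation ---------------------------------------------------

# Surface gradient polarity derived from the nominal layer reflectivity model:
# +1 where the layer below is brighter (dark-to-bright boundary), -1 otherwise.
default_polarities <- function(reflectivities = default_reflectivities(),
                               vitreous = 0.04, choroid = 0.12) {
  prof <- c(vitreous, reflectivities, choroid)
  sign(diff(prof))
}

#' Surface-search parameters
#'
#' Separation bounds default to half and twice the nominal layer thicknesses
#' of the package's anatomical layer model (the same model the phantom
#' generator renders), an anatomy-derived prior on plausible layer geometry.
#'
#' @param smoothness max allowed axial change between laterally adjacent
#'   columns, voxels (>= 0).
#' @param min_sep,max_sep length-10 per-layer separation bounds between
#'   consecutive surfaces, voxels.
#' @param levels multi-resolution levels (>= 1); level `l` works on a grid
#'   downsampled by `2^(l-1)` in x and z.
#' @param polarity length-11 vector in {-1, +1}: expected axial gradient sign
#'   at each surface (+1 dark above, bright below).
#' @param anchor_penalty weight of the dark-above term in surface 1's cost and
#'   the dark-below term in surface 11's cost. The inner limiting membrane is
#'   the only strong boundary with vitreous (near-zero signal) above it, and
#'   the RPE bottom the only one with choroid below, so penalising mean
#'   intensity on the far side anchors the two reference surfaces before the
#'   interior ones are searched.
#' @return A list of class `graph_search_params`.
#' @export
graph_search_params <- function(smoothness = 1,
                                min_sep = floor(0.5 * default_thicknesses()),
                                max_sep = ceiling(2 * default_thicknesses()),
                                levels = 2L,
                                polarity = default_polarities(),
                                anchor_penalty = 2) {
  if (smoothness < 0) stop("smoothness must be >= 0")
  if (length(min_sep) != 10L || length(max_sep) != 10L)
    stop("min_sep and max_sep must have length 10")
  if (any(min_sep < 0) || any(max_sep < min_sep))
    stop("separations must satisfy 0 <= min_sep <= max_sep")
  if (levels < 1L) stop("levels must be >= 1")
  if (length(polarity) != 11L || !all(polarity %in% c(-1, 1)))
    stop("polarity must be 11 values in {-1, +1}")
  if (anchor_penalty < 0) stop("anchor_penalty must be >= 0")
  structure(list(smoothness = smoothness, min_sep = min_sep, max_sep = max_sep,
                 levels = as.integer(levels), polarity = polarity,
                 anchor_penalty = anchor_penalty),
            class = "graph_search_params")
}

# Tighten per-column bounds so that every column's band is reachable from its
# neighbours under the smoothness slope: lo2[x] = max_x' (lo[x'] - d|x - x'|),
# hi2[x] = min_x' (hi[x'] + d|x - x'|). Where conflicting constraints empty a
# band, it collapses to the midpoint (ordering is re-enforced downstream).
slope_consistent_bounds <- function(lo, hi, delta) {
  n <- length(lo)
  if (n > 1L) {
    for (x in 2:n) lo[x] <- max(lo[x], lo[x - 1L] - delta)
    for (x in (n - 1L):1L) lo[x] <- max(lo[x], lo[x + 1L] - delta)
    for (x in 2:n) hi[x] <- min(hi[x], hi[x - 1L] + delta)
    for (x in (n - 1L):1L) hi[x] <- min(hi[x], hi[x + 1L] + delta)
  }
  bad <- lo > hi
  if (any(bad)) {
    mid <- round((lo[bad] + hi[bad]) / 2)
    lo[bad] <- mid; hi[bad] <- mid
  }
  list(lo = lo, hi = hi)
}

# Dynamic programming along x for one B-scan: maximise sum of cost[x, z]
# subject to |z(x) - z(x-1)| <= delta and lo[x] <= z(x) <= hi[x].
dp_scanline <- function(cost, lo, hi, delta) {
  nx <- nrow(cost); nz <- ncol(cost)
  NEG <- -1e18
  b <- slope_consistent_bounds(lo, hi, delta)
  lo <- b$lo; hi <- b$hi
  D <- matrix(NEG, nx, nz)
  P <- matrix(0L, nx, nz)
  zr <- seq_len(nz)
  allowed <- function(x) zr >= lo[x] & zr <= hi[x]
  a1 <- allowed(1L)
  if (!any(a1)) stop("surface search band empty (separation constraints infeasible)")
  D[1L, a1] <- cost[1L, a1]
  # offsets ordered flat-first so cost ties keep the flattest path
  offs <- as.integer(c(0, if (delta > 0) as.vector(rbind(-seq_len(delta), seq_len(delta)))))
  for (x in 2:nx) {
    ax <- allowed(x)
    if (!any(ax)) stop("surface search band empty (separation constraints infeasible)")
    best <- rep(NEG, nz); arg <- rep(0L, nz)
    prev <- D[x - 1L, ]
    for (o in offs) {
      src <- zr + o
      cand <- rep(NEG, nz)
      ok <- src >= 1L & src <= nz
      cand[ok] <- prev[src[ok]]
      upd <- cand > best
      best[upd] <- cand[upd]; arg[upd] <- o
    }
    # collapsed bands can still be unreachable under the slope; jump to the
    # best previous state rather than walking through forbidden ones
    if (all(best[ax] <= NEG / 2)) {
      jb <- which.max(prev)
      best[ax] <- prev[jb]
      arg[ax] <- NA_integer_
      P[x, ] <- arg
      D[x, ax] <- cost[x, ax] + best[ax]
      attr(P, "jump") <- c(attr(P, "jump"), x)
      next
    }
    D[x, ax] <- cost[x, ax] + best[ax]
    P[x, ] <- arg
  }
  z <- integer(nx)
  ax <- allowed(nx)
  z[nx] <- which(ax)[which.max(D[nx, ax])]
  for (x in nx:2) {
    o <- P[x, z[x]]
    z[x - 1L] <- if (is.na(o)) which.max(D[x - 1L, ]) else z[x] + o
  }
  list(z = z, total = D[nx, z[nx]])
}

# Block-mean downsample a matrix by integer factors along rows and columns.
downsample2 <- function(m, fx, fz) {
  if (fx == 1L && fz == 1L) return(m)
  nx <- nrow(m); nz <- ncol(m)
  cx <- ceiling(nx / fx); cz <- ceiling(nz / fz)
  gx <- rep(seq_len(cx), each = fx)[seq_len(nx)]
  gz <- rep(seq_len(cz), each = fz)[seq_len(nz)]
  s <- rowsum(m, gx)                       # sum rows within blocks
  s <- t(rowsum(t(s), gz))                 # then columns
  cnt <- outer(tabulate(gx, cx), tabulate(gz, cz))
  s / cnt
}

# Locate one surface over the whole en face grid by coarse-to-fine DP per
# B-scan, within per-column integer bounds [lo, hi] (matrices nx x ny).
search_surface <- function(cost_vol, lo, hi, p) {
  nx <- dim(cost_vol)[1L]; ny <- dim(cost_vol)[2L]; nz <- dim(cost_vol)[3L]
  delta <- as.integer(ceiling(p$smoothness))
  z <- matrix(0, nx, ny)
  for (j in seq_len(ny)) {
    cost_full <- cost_vol[, j, ]
    lo_j <- pmax(1L, round(lo[, j])); hi_j <- pmin(nz, round(hi_j <- hi[, j]))
    if (any(lo_j > hi_j))
      stop(sprintf("infeasible surface constraints at B-scan %d: min/max separations leave no band", j))
    zprev <- NULL
    for (lev in seq(p$levels, 1L)) {
      f <- 2L^(lev - 1L)
      cost <- downsample2(cost_full, f, f)
      ncx <- nrow(cost); ncz <- ncol(cost)
      xmap <- rep(seq_len(ncx), each = f)[seq_len(nx)]
      # bound aggregation per coarse column: conservative (cells wholly inside
      # the fine band) where possible, permissive where the band is too narrow
      lo_c <- vapply(split(lo_j, xmap), min, 0)
      hi_c <- vapply(split(hi_j, xmap), max, 0)
      loc_p <- as.integer(floor((lo_c - 1) / f) + 1)
      hic_p <- as.integer(floor((hi_c - 1) / f) + 1)
      loc <- as.integer(ceiling((lo_c - 1) / f) + 1)
      hic <- as.integer(floor(hi_c / f))
      narrow <- loc > hic
      loc[narrow] <- loc_p[narrow]; hic[narrow] <- hic_p[narrow]
      loc0 <- pmax(1L, pmin(loc, ncz)); hic0 <- pmax(loc0, pmin(hic, ncz))
      loc <- loc0; hic <- hic0
      if (!is.null(zprev)) {
        # band around the coarser solution mapped into this level's z units
        # (coarse cell c covers fine cells 2c-1 and 2c)
        zup <- rep(zprev, each = 2L)[seq_len(ncx)] * 2L
        band <- 3L + 2L * delta
        loc <- pmax(loc, zup - band); hic <- pmin(hic, zup + band)
        bad <- loc > hic
        loc[bad] <- loc0[bad]; hic[bad] <- hic0[bad]
      }
      zprev <- dp_scanline(cost, loc, hic, delta)$z
    }
    z[, j] <- zprev
  }
  z
}

#' Segment the 11 intra-retinal surfaces
#'
#' Each surface maximises a polarity-signed axial forward-difference gradient
#' cost under a hard lateral smoothness bound, solved coarse-to-fine by
#' column-wise dynamic programming per B-scan. The two anchor surfaces are
#' found first — surface 1 (dark vitreous above) and surface 11 (the robust
#' RPE-bottom reference, dark choroid below). The outer surfaces 10, 9, 8, 7
#' are then searched bottom-up, each within one layer's separation band of the
#' surface below, which keeps every search band local and makes the EZ
#' boundaries recoverable even across disrupted (dark) EZ patches; the inner
#' surfaces 2..6 follow top-down. Previously found surfaces act as hard bounds
#' through the min/max separation constraints.
#'
#' @param vol an [oct_volume] (denoising first is recommended).
#' @param p a [graph_search_params].
#' @return A [surface_set] with 11 ordered surfaces.
#' @export
segment_surfaces <- function(vol, p = graph_search_params()) {
  stopifnot(inherits(vol, "oct_volume"), inherits(p, "graph_search_params"))
  nx <- vol$nx; ny <- vol$ny; nz <- vol$nz
  if (sum(p$min_sep) + 2 > nz)
    stop("infeasible surface constraints: min separations sum beyond nz")
  I <- vol$intensities
  grad <- array(0, c(nx, ny, nz))
  grad[, , 2:nz] <- I[, , 2:nz] - I[, , 1:(nz - 1L)]

  # running means of intensity strictly above / strictly below each depth,
  # used to anchor the two reference surfaces (dark vitreous above surface 1,
  # dark choroid below surface 11)
  csum <- apply(I, c(1, 2), cumsum)              # nz x nx x ny
  csum <- aperm(csum, c(2, 3, 1))
  zcount <- array(rep(seq_len(nz), each = nx * ny), c(nx, ny, nz))
  total <- array(rep(csum[, , nz], times = nz), c(nx, ny, nz))
  mean_above <- array(0, c(nx, ny, nz))
  mean_above[, , 2:nz] <- csum[, , 1:(nz - 1L)] / (zcount[, , 2:nz] - 1)
  mean_below <- array(0, c(nx, ny, nz))
  mean_below[, , 1:(nz - 1L)] <-
    (total[, , 1:(nz - 1L)] - csum[, , 1:(nz - 1L)]) /
    (nz - zcount[, , 1:(nz - 1L)])

  ones <- matrix(1, nx, ny)
  z_of <- array(NA_real_, c(11L, nx, ny))
  msum <- sum(p$min_sep)

  # surface 1 over the full feasible range, anchored by darkness above
  z1 <- search_surface(p$polarity[1L] * grad - p$anchor_penalty * mean_above,
                       2 * ones, (nz - msum - 1) * ones, p)
  z_of[1L, , ] <- z1
  # surface 11 below surface 1, anchored by darkness below
  z11 <- search_surface(p$polarity[11L] * grad - p$anchor_penalty * mean_below,
                        pmin(z1 + msum, nz - 1),
                        pmin(z1 + sum(p$max_sep), nz - 1), p)
  z_of[11L, , ] <- z11
  # outer chain bottom-up from the robust RPE floor: each surface is searched
  # within one layer's separation band of the surface below it, so every band
  # is local and contains exactly one boundary of the expected polarity even
  # where the EZ is disrupted (the EZ-top gradient weakens there but stays the
  # only dark-to-bright transition inside its band)
  for (s in c(10L, 9L, 8L, 7L)) {
    below <- z_of[s + 1L, , ]
    lo <- pmax(below - p$max_sep[s], z1 + sum(p$min_sep[1:(s - 1L)]))
    hi <- below - p$min_sep[s]
    z_of[s, , ] <- search_surface(p$polarity[s] * grad, lo, hi, p)
  }
  # inner chain top-down between surfaces 1 and 7
  for (s in 2:6) {
    above <- z_of[s - 1L, , ]
    lo <- above + p$min_sep[s - 1L]
    hi <- pmin(above + p$max_sep[s - 1L], z_of[7L, , ] - sum(p$min_sep[s:6]))
    z_of[s, , ] <- search_surface(p$polarity[s] * grad, lo, hi, p)
  }
  for (s in 2:11) z_of[s, , ] <- pmax(z_of[s, , ], z_of[s - 1L, , ])
  surface_set(z_of, nz = nz)
}

# ---- thin-plate-spline smoothing --------------------------------------------

#' Smooth surfaces with thin-plate splines
#'
#' Each surface is replaced by a thin-plate regression spline fit (basis on a
#' subsampled knot grid) evaluated over the full en face grid. With
#' `robust_iter > 0`, the fit is repeated with columns whose residual exceeds
#' an adaptive threshold excluded, so localized segmentation blunders (e.g. a
#' boundary snapping to a deeper layer inside a large dark lesion) are
#' interpolated across from the reliable columns instead of being smoothed
#' into the surface. Ordering is re-checked afterwards and enforced by minimal
#' axial shifts.
#'
#' @param s a [surface_set].
#' @param regularization fixed smoothing parameter (>= 0) passed to the
#'   spline fit; larger values pull each surface toward its best-fit plane.
#' @param k basis dimension (knot budget), default 64 (an 8 x 8 grid's worth).
#' @param max_fit_points fit-grid budget; larger en face grids are subsampled
#'   regularly down to about this many points before fitting (the smooth is
#'   still evaluated on the full grid).
#' @param robust_iter outlier-rejection refits (default 2; 0 disables).
#' @param robust_min minimum residual (voxels) treated as an outlier.
#' @param nz optional axial extent used to clip the result.
#' @return A smoothed [surface_set].
#' @export
smooth_surfaces_tps <- function(s, regularization = 0.1, k = 64L,
                                max_fit_points = 1200L, robust_iter = 2L,
                                robust_min = 2, nz = NULL) {
  stopifnot(inherits(s, "surface_set"))
  if (regularization < 0) stop("regularization must be >= 0")
  grid <- expand.grid(x = seq_len(s$nx), y = seq_len(s$ny))
  step <- max(1L, ceiling(sqrt(s$nx * s$ny / max_fit_points)))
  fit_grid <- expand.grid(x = unique(c(seq(1L, s$nx, by = step), s$nx)),
                          y = unique(c(seq(1L, s$ny, by = step), s$ny)))
  n <- nrow(fit_grid)
  kk <- max(3L, min(as.integer(k), n - 1L))
  z_of <- s$z_of
  sp_detect <- max(10 * regularization, 10)
  for (surf in 1:11) {
    df <- fit_grid
    df$z <- z_of[surf, , ][cbind(fit_grid$x, fit_grid$y)]
    keep <- rep(TRUE, nrow(df))
    # detection passes: a stiff fit cannot follow localized excursions, so
    # their residuals stand out; iterate so partially masked outliers surface
    for (it in seq_len(max(0L, robust_iter))) {
      fit <- try(mgcv::gam(z ~ s(x, y, bs = "tp", k = kk), data = df[keep, ],
                           sp = sp_detect), silent = TRUE)
      if (inherits(fit, "try-error")) break
      res <- abs(df$z - mgcv::predict.gam(fit, newdata = df))
      thr <- max(robust_min, 3 * stats::mad(res[keep], center = 0))
      keep_new <- res <= thr
      if (sum(keep_new) < max(kk + 5L, 0.25 * nrow(df))) break
      if (all(keep_new == keep)) break
      keep <- keep_new
    }
    fit <- try(mgcv::gam(z ~ s(x, y, bs = "tp", k = kk), data = df[keep, ],
                         sp = regularization), silent = TRUE)
    if (inherits(fit, "try-error")) next   # grid too small to smooth
    z_of[surf, , ] <- matrix(mgcv::predict.gam(fit, newdata = grid), s$nx, s$ny)
  }
  for (surf in 2:11) z_of[surf, , ] <- pmax(z_of[surf, , ], z_of[surf - 1L, , ])
  if (!is.null(nz)) z_of <- pmin(pmax(z_of, 1), nz)
  surface_set(z_of)
}

# ---- flattening and VOI -----------------------------------------------------

#' Flatten a volume to surface 11
#'
#' Shifts each A-scan by an integer so that the rounded position of surface 11
#' (the bottom of the retinal pigment epithelium) lies at a common depth, the
#' median of its rounded positions. Out-of-range voxels are padded with the
#' A-scan's edge value; surfaces are shifted consistently.
#'
#' @param vol an [oct_volume].
#' @param s the matching [surface_set].
#' @return A list with elements `volume`, `surfaces` and the integer `shifts`
#'   matrix.
#' @export
flatten <- function(vol, s) {
  stopifnot(inherits(vol, "oct_volume"), inherits(s, "surface_set"))
  nz <- vol$nz
  r11 <- round(s$z_of[11L, , ])
  ref <- median(r11)
  shifts <- r11 - ref
  out <- vol$intensities
  for (j in seq_len(vol$ny)) for (i in seq_len(vol$nx)) {
    d <- shifts[i, j]
    if (d == 0) next
    src <- pmin(pmax(seq_len(nz) + d, 1L), nz)
    out[i, j, ] <- vol$intensities[i, j, src]
  }
  z_of <- s$z_of - rep(shifts, each = 11L)
  z_of <- pmin(pmax(z_of, 1), nz)
  list(volume = oct_volume(out, vol$voxel_size_um, id = vol$id),
       surfaces = surface_set(z_of, nz = nz),
       shifts = shifts)
}

#' Extract the EZ volume of interest between surfaces 7 and 8
#'
#' A voxel at column (x, y) belongs to the VOI iff its axial index lies in the
#' half-open interval `[round(z7), round(z8))`; when the rounded positions
#' coincide the single voxel at `round(z7)` is included, so every column
#' contributes at least one voxel.
#'
#' @param vol an [oct_volume] (flattened recommended).
#' @param s the matching [surface_set].
#' @return A [voxel_mask] with role `"voi"`.
#' @export
extract_voi <- function(vol, s) {
  stopifnot(inherits(vol, "oct_volume"), inherits(s, "surface_set"))
  nx <- vol$nx; ny <- vol$ny; nz <- vol$nz
  r7 <- pmin(pmax(round(s$z_of[7L, , ]), 1L), nz)
  r8 <- pmin(pmax(round(s$z_of[8L, , ]), 1L), nz)
  r8 <- pmax(r8, r7 + 1L)   # degenerate column keeps the single voxel at r7
  zidx <- array(rep(seq_len(nz), each = nx * ny), c(nx, ny, nz))
  lo <- array(rep(r7, times = nz), c(nx, ny, nz))
  hi <- array(rep(r8, times = nz), c(nx, ny, nz))
  voxel_mask(zidx >= lo & zidx < hi, role = "voi")
}
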