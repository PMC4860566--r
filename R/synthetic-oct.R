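# Seeded synthetic OCT phantoms: 10 stacked layers with distinct mean
# reflectivities, smooth surface geometry with a foveal dip, a thin bright EZ
# band, planted dark EZ disruption blobs, vessel shadow columns, and
# multiplicative gamma speckle. Every downstream stage is testable against the
# recorded ground truth.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded helpers do not disturb the
#' caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Default per-layer mean reflectivities, vitreous to choroid. Layer 7 (between
# surfaces 7 and 8) is the ellipsoid zone and ranks brightest; consecutive
# layers alternate enough to give every boundary a clear axial gradient.
default_reflectivities <- function() {
  c(0.50,  # 1 NFL
    0.22,  # 2 GCL
    0.42,  # 3 IPL
    0.20,  # 4 INL
    0.44,  # 5 OPL
    0.14,  # 6 ONL + inner segments
    0.88,  # 7 ellipsoid zone (brightest band)
    0.30,  # 8 outer segments
    0.78,  # 9 RPE complex, inner
    0.60)  # 10 RPE/Bruch complex, outer
}

# Nominal layer thicknesses in voxels (axial), summing with the top margin to
# well under the default nz = 128.
default_thicknesses <- function() c(8, 7, 7, 6, 6, 14, 3.5, 6, 5, 5)

#' Phantom generator configuration
#'
#' Defaults define the package's reference study conditions: a 128 x 32 x 128
#' voxel macular volume at 11.72 x 93.75 x 3.50 um, ten layers with the EZ
#' band brightest, a foveal dip on the inner surfaces, two planted EZ
#' disruption blobs (radius 8-14 voxels en face, intensity drop to 30% of the
#' EZ reflectivity), two vessel shadow columns attenuating everything below
#' the inner retina to 35%, and multiplicative gamma speckle with standard
#' deviation 0.2. The default blob sizes reproduce trauma-scale disruption:
#' per-eye disrupted fractions of the EZ slab around 10-25%, matching the
#' disruption-to-EZ volume ratios reported for real trauma eyes (roughly 2%
#' to 50%, mean near 14%); per-eye imbalance across a cohort is heavy-tailed
#' (normal eyes are all-majority), and far more skewed ratios are reachable
#' by shrinking the blob radii.
#'
#' @param nx,ny,nz volume extents (positive integers).
#' @param voxel_size_um physical voxel size (dx, dy, dz), micrometres.
#' @param reflectivities 10 layer mean reflectivities in `[0, 1]`.
#' @param vitreous,choroid reflectivities above surface 1 / below surface 11.
#' @param top_margin nominal depth of surface 1 (voxels).
#' @param thicknesses 10 nominal layer thicknesses (voxels).
#' @param tilt_amplitude,tilt_periods amplitude (voxels) and number of periods
#'   of the low-frequency sinusoidal geometry shared by all surfaces.
#' @param dip_depth,dip_sigma foveal dip depth (voxels) and radius (fraction
#'   of nx); the dip deepens inner surfaces and fades to zero at surface 7.
#' @param n_disruptions planted EZ disruption blob count (0 for normal eyes).
#' @param disruption_radius_range en face blob radius range, voxels.
#' @param disruption_drop intensity drop factor in `(0, 1]` applied to the EZ
#'   reflectivity inside a blob.
#' @param n_vessels vessel shadow path count.
#' @param vessel_width en face path width, voxels.
#' @param vessel_attenuation multiplicative attenuation in `(0, 1)` applied to
#'   all voxels deeper than surface 4 under a vessel path.
#' @param speckle_sd standard deviation of the mean-1 multiplicative gamma
#'   speckle (0 disables noise).
#' @param seed integer seed; the phantom is a deterministic function of it.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(nx = 128L, ny = 32L, nz = 128L,
                           voxel_size_um = c(11.72, 93.75, 3.50),
                           reflectivities = default_reflectivities(),
                           vitreous = 0.04, choroid = 0.12,
                           top_margin = 26,
                           thicknesses = default_thicknesses(),
                           tilt_amplitude = 4, tilt_periods = 1.5,
                           dip_depth = 10, dip_sigma = 0.12,
                           n_disruptions = 2L,
                           disruption_radius_range = c(8, 14),
                           disruption_drop = 0.3,
                           n_vessels = 2L,
                           vessel_width = 3,
                           vessel_attenuation = 0.35,
                           speckle_sd = 0.2,
                           seed = 1L) {
  stopifnot(nx >= 8, ny >= 2, nz >= 16)
  check_voxel_size(voxel_size_um)
  if (length(reflectivities) != 10L || any(reflectivities < 0) || any(reflectivities > 1))
    stop("reflectivities must be 10 values in [0, 1]")
  if (length(thicknesses) != 10L || any(thicknesses <= 0))
    stop("thicknesses must be 10 positive values")
  if (disruption_drop <= 0 || disruption_drop > 1)
    stop("disruption_drop must be in (0, 1]")
  if (vessel_attenuation <= 0 || vessel_attenuation >= 1)
    stop("vessel_attenuation must be in (0, 1)")
  if (speckle_sd < 0) stop("speckle_sd must be >= 0")
  if (n_disruptions < 0 || n_vessels < 0) stop("counts must be >= 0")
  structure(list(
    nx = as.integer(nx), ny = as.integer(ny), nz = as.integer(nz),
    voxel_size_um = as.numeric(voxel_size_um),
    reflectivities = reflectivities, vitreous = vitreous, choroid = choroid,
    top_margin = top_margin, thicknesses = thicknesses,
    tilt_amplitude = tilt_amplitude, tilt_periods = tilt_periods,
    dip_depth = dip_depth, dip_sigma = dip_sigma,
    n_disruptions = as.integer(n_disruptions),
    disruption_radius_range = disruption_radius_range,
    disruption_drop = disruption_drop,
    n_vessels = as.integer(n_vessels),
    vessel_width = vessel_width,
    vessel_attenuation = vessel_attenuation,
    speckle_sd = speckle_sd,
    seed = as.integer(seed)), class = "phantom_config")
}

# Smooth ground-truth surfaces: shared sinusoidal tilt, per-layer constant
# thickness, inner surfaces depressed by a radial Gaussian foveal dip that
# fades to zero at the EZ. Errors out before rendering if the geometry cannot
# fit inside nz with ordered surfaces.
phantom_surfaces <- function(cfg) {
  nx <- cfg$nx; ny <- cfg$ny; nz <- cfg$nz
  xs <- seq_len(nx); ys <- seq_len(ny)
  tilt <- cfg$tilt_amplitude *
    outer(sin(2 * pi * cfg$tilt_periods * xs / nx),
          cos(2 * pi * 0.5 * ys / ny))
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  r2 <- outer((xs - cx)^2, ((ys - cy) * nx / ny)^2, "+")
  dip <- cfg$dip_depth * exp(-r2 / (2 * (cfg$dip_sigma * nx)^2))
  dip_weight <- c(1, 0.85, 0.7, 0.55, 0.4, 0.2, 0, 0, 0, 0, 0)

  z_of <- array(0, c(11L, nx, ny))
  depth <- cfg$top_margin
  for (s in 1:11) {
    z_of[s, , ] <- depth + tilt + dip_weight[s] * dip
    if (s <= 10) depth <- depth + cfg$thicknesses[s]
  }
  for (s in 1:10)
    if (any(z_of[s, , ] > z_of[s + 1L, , ]))
      stop(sprintf("phantom geometry infeasible: surfaces %d and %d cross (dip too deep)",
                   s, s + 1L))
  if (min(z_of) < 2 || max(z_of) > nz - 1)
    stop("phantom geometry infeasible: surface amplitudes too large for nz")
  surface_set(z_of, nz = nz)
}

# En face disruption footprint: n random disk blobs inside the central region.
phantom_disruption_footprint <- function(cfg) {
  fp <- matrix(FALSE, cfg$nx, cfg$ny)
  blobs <- list()
  if (cfg$n_disruptions > 0) {
    rr <- cfg$disruption_radius_range
    for (b in seq_len(cfg$n_disruptions)) {
      r <- runif(1, rr[1], rr[2])
      x0 <- runif(1, 1 + r, cfg$nx - r)
      y0 <- runif(1, 1 + min(r, cfg$ny / 4), cfg$ny - min(r, cfg$ny / 4))
      d2 <- outer((seq_len(cfg$nx) - x0)^2,
                  ((seq_len(cfg$ny) - y0) * 1)^2, "+")
      fp <- fp | (d2 <= r^2)
      blobs[[b]] <- list(x = x0, y = y0, radius = r)
    }
  }
  list(footprint = fp, blobs = blobs)
}

# En face vessel map: smooth sinusoidal paths crossing the scan in y, with
# constant width.
phantom_vessel_map <- function(cfg) {
  vm <- matrix(FALSE, cfg$nx, cfg$ny)
  if (cfg$n_vessels > 0) {
    ys <- seq_len(cfg$ny)
    for (v in seq_len(cfg$n_vessels)) {
      x0 <- runif(1, 0.15 * cfg$nx, 0.85 * cfg$nx)
      amp <- runif(1, 0.02, 0.06) * cfg$nx
      ph <- runif(1, 0, 2 * pi)
      slope <- runif(1, -0.3, 0.3) * cfg$nx / cfg$ny
      xc <- x0 + amp * sin(2 * pi * ys / cfg$ny + ph) + slope * (ys - cfg$ny / 2) / cfg$ny
      for (j in ys) {
        hit <- abs(seq_len(cfg$nx) - xc[j]) <= cfg$vessel_width / 2
        vm[hit, j] <- TRUE
      }
    }
  }
  vm
}

#' Generate a synthetic OCT phantom with ground truth
#'
#' Renders the layered volume from the ground-truth surfaces (voxel `z`
#' belongs to layer `s` iff `round(z_s) <= z < round(z_s+1)`, matching the
#' half-open VOI convention), plants disruption blobs in the EZ band
#' (intensity replaced by `disruption_drop` times the EZ reflectivity),
#' attenuates all voxels deeper than surface 4 under vessel paths, and applies
#' mean-1 multiplicative gamma speckle last. Deterministic given `cfg$seed`.
#'
#' @param cfg a [phantom_config].
#' @return A list with elements `volume` (an [oct_volume]) and `truth`, where
#'   `truth` holds `surfaces` (a [surface_set]), `disruption_mask` and
#'   `voi_mask` ([voxel_mask]s), `vessel_map` (nx x ny logical), planted blob
#'   records, and the realised within-EZ class `imbalance`
#'   (non-disrupted : disrupted; `Inf` when nothing is planted).
#' @export
generate_phantom <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  with_seed(cfg$seed, {
    surfaces <- phantom_surfaces(cfg)
    dis <- phantom_disruption_footprint(cfg)
    vessel_map <- phantom_vessel_map(cfg)

    nx <- cfg$nx; ny <- cfg$ny; nz <- cfg$nz
    zidx <- array(rep(seq_len(nz), each = nx * ny), c(nx, ny, nz))
    layer_id <- array(0L, c(nx, ny, nz))
    for (s in 1:11) {
      bound <- array(rep(round(surfaces$z_of[s, , ]), times = nz), c(nx, ny, nz))
      layer_id <- layer_id + (zidx >= bound)
    }
    refl <- c(cfg$vitreous, cfg$reflectivities, cfg$choroid)
    intens <- array(refl[layer_id + 1L], c(nx, ny, nz))

    ez_band <- layer_id == 7L
    dis_mask <- ez_band & array(rep(dis$footprint, times = nz), c(nx, ny, nz))
    intens[dis_mask] <- cfg$disruption_drop * cfg$reflectivities[7L]

    if (any(vessel_map)) {
      below_inner <- layer_id >= 4L
      shadow <- below_inner & array(rep(vessel_map, times = nz), c(nx, ny, nz))
      intens[shadow] <- intens[shadow] * cfg$vessel_attenuation
    }

    if (cfg$speckle_sd > 0) {
      shape <- 1 / cfg$speckle_sd^2
      intens <- intens * array(rgamma(length(intens), shape = shape, rate = shape),
                               dim(intens))
    }
    intens <- pmin(intens, 1)

    n_ez <- sum(ez_band); n_dis <- sum(dis_mask)
    truth <- list(
      surfaces = surfaces,
      disruption_mask = voxel_mask(dis_mask, "ground_truth"),
      voi_mask = voxel_mask(ez_band, "voi"),
      vessel_map = vessel_map,
      blobs = dis$blobs,
      disruption_footprint = dis$footprint,
      imbalance = if (n_dis > 0) (n_ez - n_dis) / n_dis else Inf,
      n_ez_voxels = n_ez, n_disrupted_voxels = n_dis)
    list(volume = oct_volume(intens, cfg$voxel_size_um,
                             id = sprintf("phantom-seed%d", cfg$seed)),
         truth = truth)
  })
}

#' Generate a cohort of trauma and normal phantoms
#'
#' Trauma phantoms use the template's disruption settings (forced to at least
#' one blob); normal phantoms have no planted disruption and hence empty
#' ground-truth masks. Per-eye seeds are drawn reproducibly from the master
#' seed, so the whole cohort is a deterministic function of `seed`.
#'
#' @param n_trauma,n_normal non-negative eye counts.
#' @param cfg_template a [phantom_config] supplying all other settings.
#' @param seed master integer seed.
#' @return A list of per-eye lists, each with `id`, `group` ("trauma" or
#'   "normal"), `seed`, `volume`, `truth`.
#' @export
generate_cohort <- function(n_trauma, n_normal, cfg_template = phantom_config(),
                            seed = 1L) {
  stopifnot(n_trauma >= 0, n_normal >= 0)
  n <- n_trauma + n_normal
  if (n == 0L) return(list())
  eye_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  groups <- c(rep("trauma", n_trauma), rep("normal", n_normal))
  lapply(seq_len(n), function(i) {
    cfg <- cfg_template
    cfg$seed <- eye_seeds[i]
    if (groups[i] == "normal") cfg$n_disruptions <- 0L
    else cfg$n_disruptions <- max(1L, cfg$n_disruptions)
    ph <- generate_phantom(cfg)
    ph$volume$id <- sprintf("%s-%02d", groups[i], i)
    c(list(id = ph$volume$id, group = groups[i], seed = eye_seeds[i]), ph)
  })
}

#' Write a cohort manifest CSV
#'
#' @param cohort result of [generate_cohort].
#' @param path output CSV (columns id, group, seed).
#' @export
write_cohort_manifest <- function(cohort, path) {
  df <- data.frame(id = vapply(cohort, `[[`, "", "id"),
                   group = vapply(cohort, `[[`, "", "group"),
                   seed = vapply(cohort, `[[`, 0L, "seed"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
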