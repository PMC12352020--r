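#' Specification for a synthetic tomogram
#'
#' Describes a tomogram-like volume with dark globular particles of
#' ribosome-like size (20-30 nm) on a noisy light background, optional large
#' dark distractors (vesicle/membrane stand-ins) and optional beam-collapse
#' along Z by a known factor. The requested particle density times the
#' physical volume, rounded, *is* the ground-truth particle count, so
#' downstream recovery can be measured against construction.
#'
#' @param shape_voxels integer triple `(nz, ny, nx)`.
#' @param pixel_size_nm isotropic voxel size in nm (default 2.572, the
#'   tomographic pixel size the defaults of the whole pipeline assume).
#' @param particle_density_per_um3 requested particle density (per um^3).
#' @param diameter_range_nm particle diameter range `(low, high)` in nm,
#'   sampled uniformly; default `c(20, 30)`, the reported size range of
#'   eukaryotic ribosomes.
#' @param particle_contrast intensity decrement of a particle relative to the
#'   background (particles are darker, matching post-stain TEM).
#' @param background background intensity level.
#' @param noise_sd standard deviation of additive Gaussian noise. The
#'   nominal SNR of the volume is `particle_contrast / noise_sd`.
#' @param distractor_count number of large dark ellipsoids (60-150 nm) mixed
#'   in as organelle-like distractors.
#' @param collapse_factor Z-collapse factor >= 1 applied to the clean
#'   rendering before noise (1 = no collapse).
#' @param edge_particles if `FALSE` (default) particles are placed fully
#'   inside the volume.
#' @param seed integer RNG seed; generation is deterministic given the spec.
#' @return An object of class `SyntheticTomoSpec`.
#' @export
synthetic_tomo_spec <- function(shape_voxels = c(52L, 150L, 150L),
                                pixel_size_nm = 2.572,
                                particle_density_per_um3 = 10000,
                                diameter_range_nm = c(20, 30),
                                particle_contrast = 60,
                                background = 150,
                                noise_sd = 12,
                                distractor_count = 0L,
                                collapse_factor = 1,
                                edge_particles = FALSE,
                                seed = 1L) {
  shape_voxels <- as.integer(shape_voxels)
  stopifnot(length(shape_voxels) == 3L, all(shape_voxels > 0),
            pixel_size_nm > 0, particle_density_per_um3 >= 0,
            length(diameter_range_nm) == 2L,
            diameter_range_nm[1] <= diameter_range_nm[2],
            diameter_range_nm[1] > 0,
            particle_contrast > 0, noise_sd >= 0, distractor_count >= 0,
            collapse_factor >= 1)
  structure(
    list(shape_voxels = shape_voxels, pixel_size_nm = pixel_size_nm,
         particle_density_per_um3 = particle_density_per_um3,
         diameter_range_nm = as.numeric(diameter_range_nm),
         particle_contrast = particle_contrast, background = background,
         noise_sd = noise_sd, distractor_count = as.integer(distractor_count),
         collapse_factor = collapse_factor,
         edge_particles = isTRUE(edge_particles), seed = as.integer(seed)),
    class = "SyntheticTomoSpec")
}

# draw non-overlapping sphere centres by rejection sampling
place_particles <- function(n, shape, pixel_nm, diam_range, edge_ok,
                            max_attempts = 100L * max(n, 1L)) {
  if (n == 0L)
    return(data.frame(z = numeric(0), y = numeric(0), x = numeric(0),
                      diameter_nm = numeric(0)))
  diam <- stats::runif(n, diam_range[1], diam_range[2])
  r_vox <- diam / 2 / pixel_nm
  z <- y <- x <- numeric(n)
  placed <- 0L
  attempts <- 0L
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("particle placement failed: density too high for non-overlapping ",
           "placement after ", max_attempts, " attempts")
    i <- placed + 1L
    m <- if (edge_ok) 0 else r_vox[i]
    cand <- c(stats::runif(1, m, shape[1] - 1 - m),
              stats::runif(1, m, shape[2] - 1 - m),
              stats::runif(1, m, shape[3] - 1 - m))
    ok <- TRUE
    if (placed > 0L) {
      d2 <- (z[seq_len(placed)] - cand[1])^2 +
            (y[seq_len(placed)] - cand[2])^2 +
            (x[seq_len(placed)] - cand[3])^2
      min_sep <- (r_vox[seq_len(placed)] + r_vox[i])^2
      ok <- all(d2 >= min_sep)
    }
    if (ok) {
      z[i] <- cand[1]; y[i] <- cand[2]; x[i] <- cand[3]
      placed <- i
    }
  }
  data.frame(z = z, y = y, x = x, diameter_nm = diam)
}

# subtract a solid (possibly anisotropic) ellipsoid from the canvas
stamp_ellipsoid <- function(canvas, center, radii_vox, depth) {
  d <- dim(canvas)
  lo <- pmax(1L, floor(center - radii_vox) + 1L)
  hi <- pmin(d, ceiling(center + radii_vox) + 1L)
  if (any(lo > hi)) return(canvas)
  zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
  fz <- ((zi - 1 - center[1]) / radii_vox[1])^2
  fy <- ((yi - 1 - center[2]) / radii_vox[2])^2
  fx <- ((xi - 1 - center[3]) / radii_vox[3])^2
  inside <- outer(outer(fz, fy, "+"), fx, "+") <= 1
  sub <- canvas[zi, yi, xi, drop = FALSE]
  sub[inside] <- sub[inside] - depth
  canvas[zi, yi, xi] <- sub
  canvas
}

#' Generate a synthetic tomogram with ground truth
#'
#' Renders solid dark spheres at rejection-sampled non-overlapping positions,
#' smooths them with a ~1-voxel Gaussian (soft-edged, stain-like appearance),
#' optionally squashes the clean rendering along Z by `collapse_factor`, and
#' finally adds Gaussian noise. Ground-truth particle coordinates are
#' reported in pre-collapse voxel coordinates; `physical_volume_um3` is the
#' true (pre-collapse) physical volume.
#'
#' @param spec a [synthetic_tomo_spec()].
#' @return A list with elements `volume` (a [volume_image()]) and
#'   `ground_truth` (class `GroundTruth`: `particles` data frame with 0-based
#'   `z, y, x` centres and `diameter_nm`, plus `count` and
#'   `physical_volume_um3`).
#' @export
generate_tomogram <- function(spec) {
  stopifnot(inherits(spec, "SyntheticTomoSpec"))
  set.seed(spec$seed)
  shape <- spec$shape_voxels
  vol_um3 <- prod(shape) * spec$pixel_size_nm^3 / 1e9
  n <- round(spec$particle_density_per_um3 * vol_um3)
  particles <- place_particles(n, shape, spec$pixel_size_nm,
                               spec$diameter_range_nm, spec$edge_particles)
  canvas <- array(spec$background, dim = shape)
  if (n > 0L) {
    r_vox <- particles$diameter_nm / 2 / spec$pixel_size_nm
    for (i in seq_len(n))
      canvas <- stamp_ellipsoid(canvas,
                                c(particles$z[i], particles$y[i], particles$x[i]),
                                rep(r_vox[i], 3L), spec$particle_contrast)
  }
  if (spec$distractor_count > 0L) {
    for (i in seq_len(spec$distractor_count)) {
      radii_nm <- stats::runif(3L, 30, 75)
      center <- c(stats::runif(1, 0, shape[1] - 1),
                  stats::runif(1, 0, shape[2] - 1),
                  stats::runif(1, 0, shape[3] - 1))
      canvas <- stamp_ellipsoid(canvas, center,
                                radii_nm / spec$pixel_size_nm,
                                spec$particle_contrast * 0.8)
    }
  }
  blurred <- gaussian_blur_3d_cpp(as.numeric(canvas), dim(canvas),
                                  rep(1, 3L))
  canvas <- array(blurred, dim = shape)
  vol <- volume_image(canvas, spec$pixel_size_nm,
                      provenance = sprintf("synthetic:seed=%d", spec$seed))
  if (spec$collapse_factor > 1)
    vol <- apply_collapse(vol, spec$collapse_factor)
  if (spec$noise_sd > 0)
    vol$data <- vol$data + array(stats::rnorm(length(vol$data), 0,
                                              spec$noise_sd), dim(vol$data))
  gt <- structure(
    list(particles = particles, count = nrow(particles),
         physical_volume_um3 = vol_um3),
    class = "GroundTruth")
  list(volume = vol, ground_truth = gt)
}

#' Simulate beam-induced section collapse along Z
#'
#' Resamples the stack along Z by linear interpolation so that the stored
#' volume has `round(nz / factor)` planes. The voxel-size metadata is *not*
#' changed: exactly as for a real collapsed section, a naive physical
#' interpretation of the stored stack underestimates the section thickness
#' by `factor`, which is the defect the shrinkage correction repairs.
#'
#' @param vol a [volume_image()].
#' @param factor collapse factor, >= 1.
#' @return A collapsed [volume_image()] (identical to the input when
#'   `factor == 1`).
#' @export
apply_collapse <- function(vol, factor) {
  stopifnot(inherits(vol, "VolumeImage"))
  if (!is.numeric(factor) || length(factor) != 1L || factor < 1)
    stop("`factor` must be a single number >= 1")
  if (factor == 1) return(vol)
  d <- dim(vol$data)
  new_nz <- max(2L, as.integer(round(d[1] / factor)))
  # voxel-centre positions of the output planes in input coordinates
  pos <- ((seq_len(new_nz) - 1) + 0.5) * d[1] / new_nz - 0.5
  pos <- pmin(pmax(pos, 0), d[1] - 1)
  lo <- pmin(floor(pos), d[1] - 2)
  w <- pos - lo
  out <- array(0, dim = c(new_nz, d[2], d[3]))
  for (j in seq_len(new_nz))
    out[j, , ] <- (1 - w[j]) * vol$data[lo[j] + 1, , ] +
                  w[j] * vol$data[lo[j] + 2, , ]
  volume_image(out, vol$voxel_size_nm,
               provenance = c(vol$provenance,
                              sprintf("collapse:factor=%.6g", factor)))
}

#' Generate a synthetic electropherogram
#'
#' Builds a fluorescence-versus-migration-position trace as a baseline plus
#' Gaussian peaks with the requested *integrated* areas, plus optional noise.
#' Pairs of peaks closer than the sum of their widths set an overlap warning
#' flag in the result's metadata.
#'
#' @param peaks data frame with columns `position`, `area` (>= 0) and
#'   `width` (> 0; Gaussian sigma in position units).
#' @param baseline constant baseline level.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param seed integer RNG seed.
#' @param positions optional explicit position grid; by default an evenly
#'   spaced grid covering all peaks plus or minus five widths.
#' @param n_points number of grid points when `positions` is not given.
#' @return An object of class `Electropherogram`: list with `trace`
#'   (data frame `position`, `fluorescence`) and `overlap_warning` flag.
#' @export
generate_electropherogram <- function(peaks, baseline = 0, noise_sd = 0,
                                      seed = 1L, positions = NULL,
                                      n_points = 2000L) {
  peaks <- as.data.frame(peaks)
  if (nrow(peaks) > 0) {
    stopifnot(all(c("position", "area", "width") %in% names(peaks)),
              all(peaks$width > 0), all(peaks$area >= 0))
  }
  set.seed(seed)
  if (is.null(positions)) {
    if (nrow(peaks) == 0) positions <- seq(0, 100, length.out = n_points)
    else positions <- seq(min(peaks$position - 5 * peaks$width),
                          max(peaks$position + 5 * peaks$width),
                          length.out = n_points)
  }
  y <- rep(baseline, length(positions))
  for (i in seq_len(nrow(peaks)))
    y <- y + peaks$area[i] / (peaks$width[i] * sqrt(2 * pi)) *
      exp(-0.5 * ((positions - peaks$position[i]) / peaks$width[i])^2)
  if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
  overlap <- FALSE
  if (nrow(peaks) > 1) {
    for (i in seq_len(nrow(peaks) - 1))
      for (j in (i + 1):nrow(peaks))
        if (abs(peaks$position[i] - peaks$position[j]) <
            peaks$width[i] + peaks$width[j]) overlap <- TRUE
  }
  if (overlap)
    warning("peaks overlap (separation < sum of widths); ",
            "integration bounds may not isolate them")
  electropherogram(positions, y, overlap_warning = overlap)
}

#' Electropherogram container
#'
#' @param position strictly increasing numeric vector of migration positions.
#' @param fluorescence numeric vector of the same length.
#' @param overlap_warning logical metadata flag set by the generator.
#' @return An object of class `Electropherogram`.
#' @export
electropherogram <- function(position, fluorescence, overlap_warning = FALSE) {
  position <- as.numeric(position); fluorescence <- as.numeric(fluorescence)
  if (length(position) != length(fluorescence))
    stop("`position` and `fluorescence` must have equal length")
  if (any(diff(position) <= 0))
    stop("`position` must be strictly increasing")
  structure(list(trace = data.frame(position = position,
                                    fluorescence = fluorescence),
                 overlap_warning = isTRUE(overlap_warning)),
            class = "Electropherogram")
}
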