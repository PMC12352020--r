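#' Segmentation parameters for the particle-detection chain
#'
#' Defaults mirror the tomographic ribosome-segmentation protocol: a median
#' denoise with a 7.72 nm kernel (3 voxels at a 2.572 nm pixel), blob
#' detection up to 30 nm with a 30% response threshold and 70% split
#' sensitivity, removal of objects touching the top or bottom Z section,
#' a plane count > 1, and voxel-count gating between an empirical lower
#' bound (25/50/100) and the geometric ceiling of 830 voxels.
#'
#' @param median_diameter_nm median-filter kernel diameter in nm.
#' @param blob_diameter_nm maximum particle diameter in nm.
#' @param probability_threshold blob-response threshold in `[0, 1]`,
#'   a fraction of the volume's maximum normalised response.
#' @param split_sensitivity watershed split sensitivity in `[0, 1]`;
#'   0 never splits touching particles, 1 splits at every regional maximum.
#' @param exclude_z_top,exclude_z_bottom drop objects touching the first /
#'   last Z plane.
#' @param min_plane_count minimum number of distinct Z planes an object must
#'   occupy (default 2, i.e. "count > 1").
#' @param voxel_count_lower vector of lower voxel-count thresholds to report
#'   (default `c(25, 50, 100)`); the final label volume is gated at the
#'   smallest.
#' @param voxel_count_upper upper voxel-count bound (default 830).
#' @return An object of class `SegmentationParams`.
#' @export
segmentation_params <- function(median_diameter_nm = 7.72,
                                blob_diameter_nm = 30,
                                probability_threshold = 0.30,
                                split_sensitivity = 0.70,
                                exclude_z_top = TRUE,
                                exclude_z_bottom = TRUE,
                                min_plane_count = 2L,
                                voxel_count_lower = c(25L, 50L, 100L),
                                voxel_count_upper = 830L) {
  voxel_count_lower <- sort(as.integer(voxel_count_lower))
  voxel_count_upper <- as.integer(voxel_count_upper)
  stopifnot(median_diameter_nm > 0, blob_diameter_nm > 0,
            probability_threshold >= 0, probability_threshold <= 1,
            split_sensitivity >= 0, split_sensitivity <= 1,
            min_plane_count >= 1,
            length(voxel_count_lower) >= 1, all(voxel_count_lower > 0),
            all(voxel_count_lower < voxel_count_upper))
  structure(
    list(median_diameter_nm = median_diameter_nm,
         blob_diameter_nm = blob_diameter_nm,
         probability_threshold = probability_threshold,
         split_sensitivity = split_sensitivity,
         exclude_z_top = isTRUE(exclude_z_top),
         exclude_z_bottom = isTRUE(exclude_z_bottom),
         min_plane_count = as.integer(min_plane_count),
         voxel_count_lower = voxel_count_lower,
         voxel_count_upper = voxel_count_upper),
    class = "SegmentationParams")
}

#' Invert a volume's intensities
#'
#' Reverses the intensity order within the volume's own range
#' (`out = min + max - in`), so dark stained particles become the brightest
#' local maxima. Applying the operation twice restores the input exactly.
#'
#' @param vol a [volume_image()].
#' @return The inverted [volume_image()].
#' @export
invert_volume <- function(vol) {
  stopifnot(inherits(vol, "VolumeImage"))
  rng <- range(vol$data)
  vol$data <- rng[1] + rng[2] - vol$data
  vol$provenance <- c(vol$provenance, "invert")
  vol
}

#' Kernel diameter (voxels) of the median denoise filter
#'
#' The physical kernel diameter is converted to voxels by rounding against
#' the in-plane pixel size and snapping to the nearest odd integer >= 1
#' (a rank filter needs a centred neighbourhood). At the default 7.72 nm and
#' 2.572 nm pixel this gives exactly 3 voxels.
#'
#' @param diameter_nm kernel diameter in nm.
#' @param pixel_size_nm in-plane pixel size in nm.
#' @return odd integer kernel diameter in voxels.
#' @export
median_kernel_diameter <- function(diameter_nm, pixel_size_nm) {
  stopifnot(diameter_nm > 0, pixel_size_nm > 0)
  d <- max(1L, as.integer(round(diameter_nm / pixel_size_nm)))
  if (d %% 2L == 0L) d <- d - 1L
  max(1L, d)
}

#' Median (rank 50%) denoise filter
#'
#' True median over a cubic neighbourhood whose diameter in voxels derives
#' from the physical diameter via [median_kernel_diameter()]. Removes
#' single-voxel impulse noise while preserving particles larger than the
#' kernel.
#'
#' @param vol a [volume_image()].
#' @param diameter_nm kernel diameter in nm (default 7.72).
#' @return The filtered [volume_image()].
#' @export
denoise_median <- function(vol, diameter_nm = 7.72) {
  stopifnot(inherits(vol, "VolumeImage"))
  d_vox <- median_kernel_diameter(diameter_nm, vol$voxel_size_nm[["x"]])
  radius <- (d_vox - 1L) %/% 2L
  out <- median_filter_3d_cpp(as.numeric(vol$data), dim(vol$data), radius)
  vol$data <- array(out, dim(vol$data))
  vol$provenance <- c(vol$provenance,
                      sprintf("median:diameter_nm=%.4g,voxels=%d",
                              diameter_nm, d_vox))
  vol
}

# multiscale difference-of-Gaussians blob response (bright blobs positive)
blob_response <- function(data, sigma_max) {
  sigmas <- 1
  while (sigmas[length(sigmas)] * 1.6 < sigma_max)
    sigmas <- c(sigmas, sigmas[length(sigmas)] * 1.6)
  d <- dim(data)
  v <- as.numeric(data)
  resp <- NULL
  for (s in sigmas) {
    g1 <- gaussian_blur_3d_cpp(v, d, rep(s, 3L))
    g2 <- gaussian_blur_3d_cpp(v, d, rep(1.6 * s, 3L))
    dog <- g1 - g2
    resp <- if (is.null(resp)) dog else pmax(resp, dog)
  }
  array(resp, d)
}

# per-label object table from a label array (0-based coordinates)
build_object_table <- function(labels) {
  d <- dim(labels)
  idx <- which(labels > 0L)
  empty <- data.frame(label = integer(0), z = numeric(0), y = numeric(0),
                      x = numeric(0), voxel_count = integer(0),
                      plane_count = integer(0), touches_z_top = logical(0),
                      touches_z_bottom = logical(0),
                      z0 = integer(0), z1 = integer(0), y0 = integer(0),
                      y1 = integer(0), x0 = integer(0), x1 = integer(0))
  if (length(idx) == 0L) return(empty)
  lab <- labels[idx]
  co <- arrayInd(idx, d) - 1L          # 0-based (z, y, x)
  f <- factor(lab)
  n <- as.integer(table(f))
  zs <- split(co[, 1], f)
  obj <- data.frame(
    label = as.integer(levels(f)),
    z = as.numeric(tapply(co[, 1], f, mean)),
    y = as.numeric(tapply(co[, 2], f, mean)),
    x = as.numeric(tapply(co[, 3], f, mean)),
    voxel_count = n,
    plane_count = vapply(zs, function(u) length(unique(u)), integer(1)),
    touches_z_top = vapply(zs, function(u) any(u == 0L), logical(1)),
    touches_z_bottom = vapply(zs, function(u) any(u == d[1] - 1L), logical(1)),
    z0 = as.integer(tapply(co[, 1], f, min)),
    z1 = as.integer(tapply(co[, 1], f, max)),
    y0 = as.integer(tapply(co[, 2], f, min)),
    y1 = as.integer(tapply(co[, 2], f, max)),
    x0 = as.integer(tapply(co[, 3], f, min)),
    x1 = as.integer(tapply(co[, 3], f, max)))
  rownames(obj) <- NULL
  obj
}

label_volume <- function(labels, objects) {
  structure(list(labels = labels, objects = objects), class = "LabelVolume")
}

#' @export
print.LabelVolume <- function(x, ...) {
  cat(sprintf("<LabelVolume> %d objects in a %s voxel array\n",
              nrow(x$objects), paste(dim(x$labels), collapse = " x ")))
  invisible(x)
}

#' Detect globular particles with a multiscale blob response
#'
#' Open reimplementation of a diameter/threshold/split-sensitivity blob
#' detector. The volume (already inverted and denoised, so particles are
#' bright) is scored with a multiscale difference-of-Gaussians response with
#' scales from 1 voxel up to the blob radius. The response is normalised to
#' robust z-scores; voxels above
#' `max(z_floor, probability_threshold * max(z))` (z_floor = 12) are kept, so
#' a pure-noise volume yields no objects. Connected regions are then split
#' by a flooding watershed: two candidate particles are kept separate when
#' the saddle between them dips below the shallower peak by more than
#' `(1 - split_sensitivity)` times that peak's height above the region's
#' response floor. Sensitivity 0 never splits; higher sensitivity separates
#' ever-shallower saddles between touching particles.
#'
#' @param vol an inverted, denoised [volume_image()].
#' @param params a [segmentation_params()].
#' @return A `LabelVolume`: integer label array plus an object table with
#'   one row per detected object (0-based centroid, voxel count, plane
#'   count, Z-edge flags, bounding box).
#' @export
detect_blobs <- function(vol, params = segmentation_params()) {
  stopifnot(inherits(vol, "VolumeImage"),
            inherits(params, "SegmentationParams"))
  d <- dim(vol$data)
  pix <- vol$voxel_size_nm[["x"]]
  if (params$blob_diameter_nm < pix)
    stop("`blob_diameter_nm` (", params$blob_diameter_nm,
         " nm) is smaller than one voxel (", pix, " nm)")
  sigma_max <- max(1, (params$blob_diameter_nm / pix) / 2 / sqrt(3))
  resp <- blob_response(vol$data, sigma_max)
  # background-noise scale from lower quantiles of the response, which stay
  # uncontaminated even when particles occupy a large volume fraction
  q <- stats::quantile(resp, c(0.10, 0.30), names = FALSE)
  sc <- (q[2] - q[1]) / (stats::qnorm(0.30) - stats::qnorm(0.10))
  if (sc == 0) sc <- stats::sd(resp)
  if (!is.finite(sc) || sc == 0)
    return(label_volume(array(0L, d), build_object_table(array(0L, d))))
  ctr <- q[2] - stats::qnorm(0.30) * sc  # implied background mean
  z <- (resp - ctr) / sc
  # no-signal gate: the largest z over a pure-noise volume of desk-scale
  # size stays well below 12, while particles at SNR >= 5 score far above
  z_floor <- 12
  zmax <- max(z)
  if (zmax < z_floor)
    return(label_volume(array(0L, d), build_object_table(array(0L, d))))
  thr <- params$probability_threshold * zmax
  mask <- z >= thr
  comp <- label_components_3d_cpp(as.logical(mask), d)
  ncomp <- max(comp)
  if (ncomp == 0L)
    return(label_volume(array(0L, d), build_object_table(array(0L, d))))
  # per-component response floor anchors the split-depth criterion
  fg <- comp > 0L
  rng_min <- tapply(resp[fg], comp[fg], min)
  comp_min <- as.numeric(rng_min)[order(as.integer(names(rng_min)))]
  labels <- watershed_split_cpp(as.numeric(resp), comp, d, comp_min,
                                1 - params$split_sensitivity)
  labels <- array(labels, d)
  label_volume(labels, build_object_table(labels))
}

# keep only the listed labels; relabelling is not performed so object ids
# remain stable across the filter chain
subset_label_volume <- function(lv, keep) {
  drop <- setdiff(lv$objects$label, keep)
  if (length(drop)) lv$labels[lv$labels %in% drop] <- 0L
  lv$objects <- lv$objects[lv$objects$label %in% keep, , drop = FALSE]
  rownames(lv$objects) <- NULL
  lv
}

#' Remove objects touching the top/bottom Z section
#'
#' Objects with any voxel in the first or last Z plane are truncated by the
#' section surface and are removed; objects touching only XY faces are
#' retained.
#'
#' @param lv a `LabelVolume`.
#' @param exclude_top,exclude_bottom which Z faces to enforce.
#' @return The filtered `LabelVolume` (a subset of the input objects).
#' @export
filter_touching_edge <- function(lv, exclude_top = TRUE,
                                 exclude_bottom = TRUE) {
  stopifnot(inherits(lv, "LabelVolume"))
  bad <- rep(FALSE, nrow(lv$objects))
  if (exclude_top) bad <- bad | lv$objects$touches_z_top
  if (exclude_bottom) bad <- bad | lv$objects$touches_z_bottom
  subset_label_volume(lv, lv$objects$label[!bad])
}

#' Remove flat objects by plane count
#'
#' Drops objects occupying fewer than `min_planes` distinct Z planes;
#' the default 2 removes single-plane (flat) artefacts.
#'
#' @param lv a `LabelVolume`.
#' @param min_planes minimum number of occupied Z planes.
#' @return The filtered `LabelVolume`.
#' @export
filter_plane_count <- function(lv, min_planes = 2L) {
  stopifnot(inherits(lv, "LabelVolume"), min_planes >= 1)
  keep <- lv$objects$label[lv$objects$plane_count >= min_planes]
  subset_label_volume(lv, keep)
}

#' Gate objects by voxel count
#'
#' Keeps objects with `lower <= voxel_count <= upper`. The defaults bracket
#' ribosome-sized objects: an empirical lower bound and the geometric
#' ceiling of 830 voxels for a 30 nm sphere at a 2.572 nm pixel.
#'
#' @param lv a `LabelVolume`.
#' @param lower,upper inclusive voxel-count bounds, `lower < upper`.
#' @return The filtered `LabelVolume`.
#' @export
filter_voxel_bounds <- function(lv, lower = 25L, upper = 830L) {
  stopifnot(inherits(lv, "LabelVolume"), lower < upper)
  keep <- lv$objects$label[lv$objects$voxel_count >= lower &
                           lv$objects$voxel_count <= upper]
  subset_label_volume(lv, keep)
}

#' Run the full particle-segmentation chain
#'
#' Executes invert, median denoise, blob detection, touching-edge filter,
#' plane-count filter and voxel-count gating in that fixed order, and
#' reports object counts at every requested lower voxel-count threshold
#' (default 25/50/100) against the shared upper bound. The returned label
#' volume is gated at the smallest lower threshold, so the exported object
#' table can be re-gated at stricter thresholds without re-segmentation.
#'
#' @param vol a raw (dark-particle) [volume_image()].
#' @param params a [segmentation_params()].
#' @return An object of class `segmentation_result`: list with
#'   `label_volume`, `counts` (named integer vector, one per lower
#'   threshold), `objects` (the object table after the edge/plane/upper
#'   filters, before lower-bound gating) and `params`.
#' @export
run_pipeline <- function(vol, params = segmentation_params()) {
  stopifnot(inherits(vol, "VolumeImage"),
            inherits(params, "SegmentationParams"))
  v <- invert_volume(vol)
  v <- denoise_median(v, params$median_diameter_nm)
  lv <- detect_blobs(v, params)
  lv <- filter_touching_edge(lv, params$exclude_z_top, params$exclude_z_bottom)
  lv <- filter_plane_count(lv, params$min_plane_count)
  lv <- subset_label_volume(
    lv, lv$objects$label[lv$objects$voxel_count <= params$voxel_count_upper])
  objects <- lv$objects
  counts <- vapply(params$voxel_count_lower,
                   function(L) sum(objects$voxel_count >= L), integer(1))
  names(counts) <- as.character(params$voxel_count_lower)
  lv <- filter_voxel_bounds(lv, min(params$voxel_count_lower),
                            params$voxel_count_upper)
  structure(list(label_volume = lv, counts = counts, objects = objects,
                 params = params),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat("<segmentation_result>\n  counts by lower voxel threshold:\n")
  for (nm in names(x$counts))
    cat(sprintf("    >= %s voxels: %d\n", nm, x$counts[[nm]]))
  invisible(x)
}

#' Write an object table as TSV
#'
#' @param objects object table from a `LabelVolume` or
#'   `segmentation_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_object_table <- function(objects, path) {
  utils::write.table(objects, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
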