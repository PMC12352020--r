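#' Default Epon/Araldite shrinkage factor
#'
#' Mean beam-collapse shrinkage factor over 77 stitched Epon/Araldite
#' serial-section datasets; used whenever no per-dataset thickness records
#' are available. The factor is resin-specific and should be re-measured
#' for other embedding media.
#'
#' @export
EPON_ARALDITE_SHRINKAGE <- 1.575

#' Avogadro constant (1/mol)
#' @export
AVOGADRO <- 6.02214e23

#' Beam-collapse shrinkage factor from thickness records
#'
#' Plastic sections collapse along Z in the electron beam, so the
#' reconstructed thickness is smaller than the nominal cut thickness. The
#' per-dataset shrinkage factor is the ratio of initial (ultramicrotome)
#' thickness to calculated (reconstructed) thickness, so that multiplying
#' the collapsed Z extent by the factor recovers the initial thickness;
#' the returned value is the mean over records. With no records the
#' resin-level default [EPON_ARALDITE_SHRINKAGE] is returned with a notice.
#'
#' @param records data frame with columns `calculated_thickness_nm` and
#'   `initial_thickness_nm`, or `NULL`.
#' @return numeric shrinkage factor (warns, without failing, if < 1).
#' @export
shrinkage_factor <- function(records = NULL) {
  if (is.null(records) || nrow(as.data.frame(records)) == 0L) {
    message("no thickness records supplied; using default Epon/Araldite ",
            "shrinkage factor ", EPON_ARALDITE_SHRINKAGE)
    return(EPON_ARALDITE_SHRINKAGE)
  }
  records <- as.data.frame(records)
  stopifnot(all(c("calculated_thickness_nm", "initial_thickness_nm") %in%
                  names(records)),
            all(records$calculated_thickness_nm > 0),
            all(records$initial_thickness_nm > 0))
  f <- mean(records$initial_thickness_nm / records$calculated_thickness_nm)
  if (f < 1)
    warning("shrinkage factor ", signif(f, 4),
            " < 1: sections appear thicker after reconstruction than cut")
  f
}

#' Volume of a sphere in cubic nanometres
#'
#' @param diameter_nm sphere diameter in nm.
#' @return `(4/3) * pi * (d/2)^3` in nm^3; ~14,137 nm^3 for a 30 nm
#'   ribosome.
#' @export
sphere_volume_nm3 <- function(diameter_nm) {
  stopifnot(all(diameter_nm >= 0))
  (4 / 3) * pi * (diameter_nm / 2)^3
}

#' Volume of a cubic voxel in cubic nanometres
#'
#' @param pixel_size_nm isotropic pixel size in nm.
#' @return `pixel_size_nm^3`; ~17 nm^3 at 2.572 nm.
#' @export
voxel_volume_nm3 <- function(pixel_size_nm) {
  stopifnot(all(pixel_size_nm > 0))
  pixel_size_nm^3
}

#' Ribosome geometry assumptions
#'
#' @param diameter_min_nm,diameter_max_nm reported eukaryotic ribosome
#'   diameter range (defaults 20 and 30 nm).
#' @param pixel_size_nm tomographic pixel size (default 2.572 nm).
#' @return An object of class `RibosomeGeometry`.
#' @export
ribosome_geometry <- function(diameter_min_nm = 20, diameter_max_nm = 30,
                              pixel_size_nm = 2.572) {
  stopifnot(diameter_min_nm > 0, diameter_min_nm <= diameter_max_nm,
            pixel_size_nm > 0)
  structure(list(diameter_min_nm = diameter_min_nm,
                 diameter_max_nm = diameter_max_nm,
                 pixel_size_nm = pixel_size_nm),
            class = "RibosomeGeometry")
}

#' Theoretical voxel-count bounds for a ribosome-sized object
#'
#' The ceiling is the maximum ribosome volume divided by the voxel volume;
#' the theoretical floor additionally divides the minimum ribosome volume by
#' the Z shrinkage factor (a collapsed particle occupies fewer stored
#' voxels). Both are reported as integer floors of the real-valued
#' quotients: with the defaults this gives 830 and 156. In practice the
#' floor is relaxed empirically (to 150, then stepwise to 100/50/25) and is
#' carried by [segmentation_params()]; this function reports the geometric
#' values.
#'
#' @param geom a [ribosome_geometry()].
#' @param shrink shrinkage factor >= 1.
#' @return list with `upper` and `lower_theoretical` (integers).
#' @export
voxel_count_bounds <- function(geom = ribosome_geometry(),
                               shrink = EPON_ARALDITE_SHRINKAGE) {
  stopifnot(inherits(geom, "RibosomeGeometry"), shrink >= 1)
  vox <- voxel_volume_nm3(geom$pixel_size_nm)
  upper <- floor(sphere_volume_nm3(geom$diameter_max_nm) / vox)
  lower <- floor(sphere_volume_nm3(geom$diameter_min_nm) / shrink / vox)
  list(upper = as.integer(upper), lower_theoretical = as.integer(lower))
}

#' Shrinkage-corrected particle density per cubic micrometre
#'
#' Converts a raw object count in a subvolume to a density per um^3 of
#' cytoplasm, divided once by the shrinkage factor to repair the
#' beam-collapse underestimate of the subvolume's Z extent. Dividing the
#' density by the factor is algebraically identical to multiplying the Z
#' voxel size by it; to prevent the ~1.575^2 error of applying both forms,
#' volumes whose Z voxel size has already been corrected are refused.
#'
#' @param raw_count nonnegative integer object count.
#' @param subvolume either the measured subvolume in um^3 (numeric) or a
#'   [volume_image()] whose physical volume is used.
#' @param shrink shrinkage factor >= 1.
#' @param lower_threshold optional lower voxel-count threshold the count was
#'   gated at (bookkeeping only).
#' @return A one-row data frame (class `DensityResult`) with columns
#'   `raw_count`, `subvolume_um3`, `shrinkage_factor`, `density_per_um3`,
#'   `lower_threshold`.
#' @export
density_per_um3 <- function(raw_count, subvolume,
                            shrink = EPON_ARALDITE_SHRINKAGE,
                            lower_threshold = NA_integer_) {
  stopifnot(raw_count >= 0, shrink >= 1)
  if (inherits(subvolume, "VolumeImage")) {
    if (subvolume$z_corrected && shrink > 1)
      stop("volume metadata records a shrinkage-corrected Z voxel size; ",
           "applying `shrink` again would double-correct")
    subvolume <- physical_volume_um3(subvolume)
  }
  stopifnot(is.numeric(subvolume), subvolume > 0)
  res <- data.frame(raw_count = as.integer(raw_count),
                    subvolume_um3 = subvolume,
                    shrinkage_factor = shrink,
                    density_per_um3 = raw_count / subvolume / shrink,
                    lower_threshold = as.integer(lower_threshold))
  class(res) <- c("DensityResult", class(res))
  res
}

#' Correct a collapsed volume's Z voxel size
#'
#' Alternative, metadata-level formulation of the shrinkage correction:
#' multiplies the Z voxel size by the factor and stamps the volume so that
#' [density_per_um3()] refuses to correct it a second time.
#'
#' @param vol a [volume_image()].
#' @param shrink shrinkage factor >= 1.
#' @return The corrected [volume_image()].
#' @export
correct_z_voxel_size <- function(vol, shrink = EPON_ARALDITE_SHRINKAGE) {
  stopifnot(inherits(vol, "VolumeImage"), shrink >= 1)
  if (vol$z_corrected)
    stop("Z voxel size already shrinkage-corrected")
  vol$voxel_size_nm["z"] <- vol$voxel_size_nm["z"] * shrink
  vol$z_corrected <- TRUE
  vol$provenance <- c(vol$provenance,
                      sprintf("z_corrected:factor=%.6g", shrink))
  vol
}

#' Whole-cell ribosome total
#'
#' @param density_per_um3 shrinkage-corrected ribosome density (per um^3).
#' @param cytoplasmic_volume_um3 cytoplasmic volume (um^3).
#' @return their product: the estimated number of ribosomes per cell.
#' @export
total_ribosomes <- function(density_per_um3, cytoplasmic_volume_um3) {
  stopifnot(all(density_per_um3 >= 0), all(cytoplasmic_volume_um3 >= 0))
  density_per_um3 * cytoplasmic_volume_um3
}

#' Welch's two-sided t-test between two conditions
#'
#' Compares per-subvolume densities (or any measurements) between two
#' groups with Welch's unequal-variance two-sided t-test and reports the
#' conventional significance tier (*** p < 0.001, ** p < 0.01, * p < 0.05,
#' n.s. otherwise).
#'
#' @param densities_a,densities_b numeric vectors, each of length >= 2.
#' @return An object of class `welch_comparison`: list with `statistic`,
#'   `df`, `p_value`, `mean_a`, `mean_b`, `tier`.
#' @export
compare_conditions <- function(densities_a, densities_b) {
  if (length(densities_a) < 2 || length(densities_b) < 2)
    stop("each group needs at least 2 values")
  tt <- stats::t.test(densities_a, densities_b, var.equal = FALSE,
                      alternative = "two.sided")
  p <- tt$p.value
  tier <- if (p < 0.001) "***" else if (p < 0.01) "**" else
    if (p < 0.05) "*" else "n.s."
  structure(list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = p, mean_a = mean(densities_a),
                 mean_b = mean(densities_b), tier = tier),
            class = "welch_comparison")
}

#' @export
print.welch_comparison <- function(x, ...) {
  cat(sprintf("Welch two-sided t-test: t = %.4g, df = %.3g, p = %.4g [%s]\n",
              x$statistic, x$df, x$p_value, x$tier))
  cat(sprintf("  group means: %.6g vs %.6g\n", x$mean_a, x$mean_b))
  invisible(x)
}
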