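#' 3D intensity volume with physical voxel metadata
#'
#' The pipeline's carrier type: a 3D array in (Z, Y, X) order together with
#' the physical voxel size along each axis in nanometres and a free-text
#' provenance trail (source file, crop offsets, applied operations).
#' Coordinates used throughout the package are 0-based; crop boxes are
#' half-open.
#'
#' @param data 3D numeric array, dimensions `(nz, ny, nx)`.
#' @param voxel_size_nm positive numeric of length 1 or 3 `(z, y, x)`, in nm.
#' @param provenance character vector of provenance lines.
#' @param z_corrected logical; `TRUE` once the Z voxel size has been rescaled
#'   by a shrinkage factor, which arms the double-correction guard in
#'   [density_per_um3()].
#' @return An object of class `VolumeImage`.
#' @seealso [read_volume()], [write_volume()], [crop_subvolume()]
#' @export
volume_image <- function(data, voxel_size_nm, provenance = character(),
                         z_corrected = FALSE) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array in (Z, Y, X) order")
  voxel_size_nm <- as.numeric(voxel_size_nm)
  if (length(voxel_size_nm) == 1L) voxel_size_nm <- rep(voxel_size_nm, 3L)
  if (length(voxel_size_nm) != 3L || any(!is.finite(voxel_size_nm)) ||
      any(voxel_size_nm <= 0))
    stop("`voxel_size_nm` must be positive, length 1 or 3")
  names(voxel_size_nm) <- c("z", "y", "x")
  structure(
    list(data = data, voxel_size_nm = voxel_size_nm,
         provenance = as.character(provenance),
         z_corrected = isTRUE(z_corrected)),
    class = "VolumeImage")
}

#' @export
print.VolumeImage <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<VolumeImage> %d x %d x %d voxels (Z,Y,X), voxel %.4g x %.4g x %.4g nm\n",
              d[1], d[2], d[3], x$voxel_size_nm[1], x$voxel_size_nm[2],
              x$voxel_size_nm[3]))
  cat(sprintf("  physical volume: %.5g um^3%s\n", physical_volume_um3(x),
              if (x$z_corrected) " (Z size shrinkage-corrected)" else ""))
  if (length(x$provenance))
    cat("  provenance:", paste(x$provenance, collapse = " | "), "\n")
  invisible(x)
}

#' @export
dim.VolumeImage <- function(x) dim(x$data)

#' Physical volume of a VolumeImage in cubic micrometres
#'
#' @param vol a [volume_image()].
#' @return numeric scalar, product of extents and voxel sizes, in um^3.
#' @export
physical_volume_um3 <- function(vol) {
  stopifnot(inherits(vol, "VolumeImage"))
  prod(dim(vol$data) * vol$voxel_size_nm) / 1e9
}

## ---- MRC (modes 0/1/2) -----------------------------------------------------
## Minimal MRC2014 subset: 1024-byte header, voxel size from cella/mx in
## Angstrom, data in x-fastest order. Sufficient for tomogram exchange.

read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 10L, size = 4L, endian = "little")
  nx <- hdr_int[1]; ny <- hdr_int[2]; nz <- hdr_int[3]; mode <- hdr_int[4]
  mx <- hdr_int[8]; my <- hdr_int[9]; mz <- hdr_int[10]
  cella <- readBin(con, "numeric", n = 3L, size = 4L, endian = "little")
  seek(con, 23 * 4)
  nsymbt <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (any(c(nx, ny, nz) <= 0)) stop("corrupt MRC header: nonpositive extents")
  voxel_nm <- rep(NA_real_, 3L)
  if (all(c(mx, my, mz) > 0) && all(cella > 0))
    voxel_nm <- c(cella[3] / mz, cella[2] / my, cella[1] / mx) / 10  # A -> nm
  seek(con, 1024 + nsymbt)
  n <- as.double(nx) * ny * nz
  raw <- switch(as.character(mode),
    "0" = readBin(con, "integer", n = n, size = 1L, signed = TRUE,
                  endian = "little"),
    "1" = readBin(con, "integer", n = n, size = 2L, signed = TRUE,
                  endian = "little"),
    "2" = readBin(con, "numeric", n = n, size = 4L, endian = "little"),
    stop("unsupported MRC mode: ", mode))
  if (length(raw) < n) stop("truncated MRC data block")
  arr <- aperm(array(as.numeric(raw), dim = c(nx, ny, nz)), c(3L, 2L, 1L))
  list(data = arr, voxel_size_nm = voxel_nm)
}

write_mrc <- function(vol, path) {
  d <- dim(vol$data)                      # (nz, ny, nx)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(c(d[3], d[2], d[1], 2L, 0L, 0L, 0L, d[3], d[2], d[1])),
           con, size = 4L, endian = "little")
  cella <- c(d[3] * vol$voxel_size_nm["x"], d[2] * vol$voxel_size_nm["y"],
             d[1] * vol$voxel_size_nm["z"]) * 10  # nm -> A
  writeBin(as.numeric(cella), con, size = 4L, endian = "little")
  writeBin(as.numeric(c(90, 90, 90)), con, size = 4L, endian = "little")
  writeBin(as.integer(c(1L, 2L, 3L)), con, size = 4L, endian = "little")
  rng <- range(vol$data)
  writeBin(as.numeric(c(rng[1], rng[2], mean(vol$data))), con, size = 4L,
           endian = "little")
  writeBin(as.integer(c(1L, 0L)), con, size = 4L, endian = "little")  # ispg, nsymbt
  writeBin(raw(25 * 4), con)                       # extra
  writeBin(as.numeric(c(0, 0, 0)), con, size = 4L, endian = "little")  # origin
  writeChar("MAP ", con, nchars = 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  writeBin(as.numeric(stats::sd(vol$data)), con, size = 4L, endian = "little")
  writeBin(raw(1024 - 220), con)                   # nlabl + labels
  writeBin(as.numeric(aperm(vol$data, c(3L, 2L, 1L))), con, size = 4L,
           endian = "little")
  invisible(path)
}

## ---- TIFF stacks -----------------------------------------------------------
## Stored as 16-bit multi-page TIFF; intensities must lie in [0, 65535] so the
## round trip is exact for integer-valued data. Plain TIFF carries no voxel
## size, so reading requires an explicit override.

write_tiff_stack <- function(vol, path) {
  rng <- range(vol$data)
  if (rng[1] < 0 || rng[2] > 65535)
    stop("TIFF output requires intensities in [0, 65535]; rescale first")
  pages <- lapply(seq_len(dim(vol$data)[1]),
                  function(k) vol$data[k, , , drop = TRUE] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

read_tiff_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (k in seq_along(pages)) arr[k, , ] <- pages[[k]] * 65535
  r <- round(arr)
  if (max(abs(arr - r)) < 1e-6) arr <- r
  list(data = arr, voxel_size_nm = rep(NA_real_, 3L))
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("mrc", "rec", "st")) return("mrc")
  if (ext %in% c("tif", "tiff")) return("tiff")
  stop("cannot infer volume format from extension: ", path)
}

#' Read a 3D volume from MRC or multi-page TIFF
#'
#' Voxel size is taken from the MRC header when present; plain TIFF stacks
#' carry no physical calibration, so `voxel_size_override` is then required.
#'
#' @param path file path (`.mrc`/`.rec` or `.tif`/`.tiff`).
#' @param voxel_size_override optional voxel size in nm (length 1 or 3,
#'   `(z, y, x)`), used when the file has no usable size metadata.
#' @param format `"auto"` (by extension), `"mrc"` or `"tiff"`.
#' @return A [volume_image()].
#' @export
read_volume <- function(path, voxel_size_override = NULL,
                        format = c("auto", "mrc", "tiff")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  raw <- if (format == "mrc") read_mrc(path) else read_tiff_stack(path)
  vs <- raw$voxel_size_nm
  if (any(!is.finite(vs)) || any(vs <= 0)) {
    if (is.null(voxel_size_override))
      stop("no voxel size in file metadata and no `voxel_size_override` given: ",
           path)
    vs <- voxel_size_override
  }
  volume_image(raw$data, vs, provenance = paste0("read:", path))
}

#' Write a 3D volume as MRC or multi-page TIFF
#'
#' MRC output (mode 2, float32) stores the voxel size in the header; TIFF
#' output is 16-bit and carries no physical calibration.
#'
#' @inheritParams read_volume
#' @param vol a [volume_image()].
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, format = c("auto", "mrc", "tiff")) {
  stopifnot(inherits(vol, "VolumeImage"))
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (format == "mrc") write_mrc(vol, path) else write_tiff_stack(vol, path)
}

#' Crop a subvolume
#'
#' Extracts a half-open, 0-based crop box `[origin, origin + shape)` in
#' (Z, Y, X) voxel coordinates. Voxel size is unchanged; the offsets are
#' recorded in the provenance, mirroring the workflow of selecting
#' organelle-free cytoplasmic subregions from a tomogram.
#'
#' @param vol a [volume_image()].
#' @param origin integer triple `(z, y, x)`, 0-based.
#' @param shape integer triple `(nz, ny, nx)`, all positive.
#' @return A [volume_image()] of dimensions `shape`.
#' @export
crop_subvolume <- function(vol, origin, shape) {
  stopifnot(inherits(vol, "VolumeImage"))
  origin <- as.integer(origin); shape <- as.integer(shape)
  d <- dim(vol$data)
  if (length(origin) != 3L || length(shape) != 3L || any(shape <= 0) ||
      any(origin < 0) || any(origin + shape > d))
    stop("crop box [", paste(origin, collapse = ","), ") + (",
         paste(shape, collapse = ","), ") not fully inside volume of dim (",
         paste(d, collapse = ","), ")")
  data <- vol$data[origin[1] + seq_len(shape[1]),
                   origin[2] + seq_len(shape[2]),
                   origin[3] + seq_len(shape[3]), drop = FALSE]
  volume_image(data, vol$voxel_size_nm,
               provenance = c(vol$provenance,
                              sprintf("crop:origin=%s,shape=%s",
                                      paste(origin, collapse = ","),
                                      paste(shape, collapse = ","))),
               z_corrected = vol$z_corrected)
}
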