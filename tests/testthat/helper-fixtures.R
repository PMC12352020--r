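# shared fixture builders; everything is generated in code at test time

# subtract a solid sphere from a canvas (dark particle on light background)
stamp_sphere <- function(canvas, center, radius_vox, depth = 60) {
  d <- dim(canvas)
  f <- outer(outer((seq_len(d[1]) - 1 - center[1])^2,
                   (seq_len(d[2]) - 1 - center[2])^2, "+"),
             (seq_len(d[3]) - 1 - center[3])^2, "+") <= radius_vox^2
  canvas[f] <- canvas[f] - depth
  canvas
}

# two 25 nm spheres fused into a dumbbell (centres `sep_nm` apart, noise-free)
make_dumbbell <- function(sep_nm = 24, pixel_nm = 2.572) {
  canvas <- array(150, c(30, 60, 60))
  r <- 12.5 / pixel_nm
  sep <- sep_nm / pixel_nm
  canvas <- stamp_sphere(canvas, c(14.5, 30, 30 - sep / 2), r)
  canvas <- stamp_sphere(canvas, c(14.5, 30, 30 + sep / 2), r)
  volume_image(canvas, pixel_nm)
}

# spec whose ground-truth count is exactly `n` in the given shape
spec_with_count <- function(n, shape = c(40L, 120L, 120L), ...) {
  vol_um3 <- prod(shape) * 2.572^3 / 1e9
  synthetic_tomo_spec(shape_voxels = shape,
                      particle_density_per_um3 = n / vol_um3, ...)
}

# greedy matching of detections to ground truth within one particle radius
match_detections <- function(objects, gt, pixel_nm = 2.572) {
  used <- rep(FALSE, nrow(objects))
  matched <- 0L
  for (i in seq_len(nrow(gt$particles))) {
    r_vox <- gt$particles$diameter_nm[i] / 2 / pixel_nm
    d2 <- (objects$z - gt$particles$z[i])^2 +
      (objects$y - gt$particles$y[i])^2 +
      (objects$x - gt$particles$x[i])^2
    d2[used] <- Inf
    j <- which.min(d2)
    if (length(j) && d2[j] <= r_vox^2) {
      used[j] <- TRUE
      matched <- matched + 1L
    }
  }
  matched
}

# label volume built directly from a hand-drawn label array
lv_from_labels <- function(labels) {
  ribotomo:::label_volume(labels, ribotomo:::build_object_table(labels))
}
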