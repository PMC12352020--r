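test_that("ground-truth count is the requested density times volume", {
  spec0 <- synthetic_tomo_spec(shape_voxels = c(20, 40, 40),
                               particle_density_per_um3 = 0)
  sim0 <- generate_tomogram(spec0)
  expect_identical(sim0$ground_truth$count, 0L)
  expect_equal(nrow(sim0$ground_truth$particles), 0L)

  shape <- c(80L, 200L, 200L)
  vol_um3 <- prod(shape) * 2.572^3 / 1e9
  spec <- synthetic_tomo_spec(shape_voxels = shape,
                              particle_density_per_um3 = 50 / vol_um3)
  sim <- generate_tomogram(spec)
  expect_equal(sim$ground_truth$count, 50)
  expect_equal(sim$ground_truth$physical_volume_um3, vol_um3)
  expect_equal(nrow(sim$ground_truth$particles), sim$ground_truth$count)
  # density linearity: doubling the density doubles the count
  spec2 <- synthetic_tomo_spec(shape_voxels = shape,
                               particle_density_per_um3 = 100 / vol_um3)
  expect_equal(generate_tomogram(spec2)$ground_truth$count, 100)
})

test_that("generation is deterministic given spec and seed", {
  spec <- spec_with_count(30, seed = 42L)
  a <- generate_tomogram(spec)
  b <- generate_tomogram(spec)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$ground_truth$particles, b$ground_truth$particles)
  c <- generate_tomogram(spec_with_count(30, seed = 43L))
  expect_false(identical(a$volume$data, c$volume$data))
})

test_that("particles lie fully inside the volume and do not overlap", {
  spec <- spec_with_count(60, seed = 8L)
  gt <- generate_tomogram(spec)$ground_truth$particles
  r <- gt$diameter_nm / 2 / 2.572
  d <- spec$shape_voxels
  expect_true(all(gt$z >= r & gt$z <= d[1] - 1 - r))
  expect_true(all(gt$y >= r & gt$y <= d[2] - 1 - r))
  expect_true(all(gt$x >= r & gt$x <= d[3] - 1 - r))
  dist2 <- as.matrix(stats::dist(gt[, c("z", "y", "x")]))^2
  min_sep2 <- outer(r, r, "+")^2
  diag(dist2) <- Inf
  expect_true(all(dist2 >= min_sep2 - 1e-9))
})

test_that("impossible packing raises an explicit placement error", {
  vol_um3 <- prod(c(12, 14, 14)) * 2.572^3 / 1e9
  spec <- synthetic_tomo_spec(shape_voxels = c(12, 14, 14),
                              particle_density_per_um3 = 60 / vol_um3)
  expect_error(generate_tomogram(spec), "placement failed")
})

test_that("rendered particle sizes match the sampled diameters", {
  shape <- c(60L, 220L, 220L)
  vol_um3 <- prod(shape) * 2.572^3 / 1e9
  spec <- synthetic_tomo_spec(shape_voxels = shape,
                              particle_density_per_um3 = 500 / vol_um3,
                              noise_sd = 0, seed = 21L)
  sim <- generate_tomogram(spec)
  expect_equal(sim$ground_truth$count, 500)
  # threshold the noise-free rendering at half contrast and compare the mean
  # equivalent-sphere diameter against the sampled mean
  mask <- sim$volume$data < spec$background - spec$particle_contrast / 2
  mean_eq_vox <- (6 * sum(mask) / 500 / pi)^(1 / 3)
  mean_sampled_vox <- mean(sim$ground_truth$particles$diameter_nm) / 2.572
  expect_lt(abs(mean_eq_vox - mean_sampled_vox), 1)
})

test_that("Z-collapse resamples the stack and preserves content", {
  spec <- spec_with_count(20, seed = 3L, noise_sd = 0)
  vol <- generate_tomogram(spec)$volume
  expect_identical(apply_collapse(vol, 1)$data, vol$data)
  expect_error(apply_collapse(vol, 0.8), ">= 1")

  big <- volume_image(array(stats::rnorm(315 * 4 * 4), c(315, 4, 4)), 2.572)
  expect_identical(dim(apply_collapse(big, 1.575)$data)[1], 200L)
  # voxel-size metadata is deliberately left stale: the naive physical
  # volume underestimates the true one by the collapse factor
  col <- apply_collapse(big, 1.575)
  expect_equal(physical_volume_um3(big) / physical_volume_um3(col),
               315 / 200, tolerance = 1e-12)
})

test_that("ground-truth centres map onto detections after collapse", {
  shape <- c(63L, 100L, 100L)
  vol_um3 <- prod(shape) * 2.572^3 / 1e9
  spec <- synthetic_tomo_spec(shape_voxels = shape,
                              particle_density_per_um3 = 60 / vol_um3,
                              noise_sd = 0, collapse_factor = 1.575,
                              seed = 9L)
  sim <- generate_tomogram(spec)
  lv <- detect_blobs(denoise_median(invert_volume(sim$volume)))
  gt <- sim$ground_truth$particles
  nz_out <- dim(sim$volume$data)[1]
  gz <- (gt$z + 0.5) * nz_out / shape[1] - 0.5  # voxel-centre mapping
  err <- vapply(seq_len(nrow(gt)), function(i) {
    sqrt(min((lv$objects$z - gz[i])^2 + (lv$objects$y - gt$y[i])^2 +
               (lv$objects$x - gt$x[i])^2))
  }, numeric(1))
  expect_gte(nrow(lv$objects), 0.9 * nrow(gt))
  expect_lt(stats::median(err), 1)
})

test_that("synthetic electropherograms integrate to the requested areas", {
  flat <- generate_electropherogram(data.frame(position = numeric(0),
                                               area = numeric(0),
                                               width = numeric(0)))
  expect_true(all(flat$trace$fluorescence == 0))

  one <- generate_electropherogram(
    data.frame(position = 40, area = 12.5, width = 1.5))
  area <- pracma::trapz(one$trace$position, one$trace$fluorescence)
  expect_equal(area, 12.5, tolerance = 0.005)

  two <- generate_electropherogram(
    data.frame(position = c(30, 60), area = c(10, 5), width = c(1.5, 2)),
    positions = seq(15, 80, length.out = 4000))
  a1 <- integrate_peak(two, 20, 45, baseline = "none")
  a2 <- integrate_peak(two, 45, 75, baseline = "none")
  expect_equal(a1 / a2, 2, tolerance = 0.01)

  expect_warning(
    ov <- generate_electropherogram(
      data.frame(position = c(30, 32), area = c(1, 1), width = c(2, 2))),
    "overlap")
  expect_true(ov$overlap_warning)
})

test_that("electropherogram generation is deterministic given seed", {
  pk <- data.frame(position = 40, area = 10, width = 2)
  a <- generate_electropherogram(pk, noise_sd = 1, seed = 5L)
  b <- generate_electropherogram(pk, noise_sd = 1, seed = 5L)
  expect_identical(a$trace, b$trace)
})
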