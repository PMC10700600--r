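make_test_volume <- function(seed = 1) {
  generate_phantom(desk_phantom_spec(grid_shape = c(32L, 32L, 32L),
                                     voxel_size = c(1, 1, 1),
                                     icv_semiaxes = c(12, 12, 12),
                                     target_volume = 300,
                                     target_center = c(0, 2, 0),
                                     noise_sd = 0, seed = seed))
}

angle_to_z <- function(u) {
  acos(abs(sum(u * c(0, 0, 1))) / sqrt(sum(u^2))) * 180 / pi
}

test_that("axis-aligned landmarks give the identity transform", {
  v <- make_test_volume()
  lm <- landmark_pair(c(0, 0, -5), c(0, 0, 5))
  out <- align_to_axis(v, lm)
  expect_identical(out$intensity, v$intensity)
  expect_equal(attr(out, "rotation"), diag(3))
})

test_that("tilted landmarks end up parallel to the slice normal", {
  v <- make_test_volume()
  th <- 10 * pi / 180
  lm <- landmark_pair(c(0, -5 * sin(th), -5 * cos(th)),
                      c(0, 5 * sin(th), 5 * cos(th)))
  out <- align_to_axis(v, lm)
  la <- attr(out, "landmarks_aligned")
  u <- la$posterior - la$anterior
  expect_lt(angle_to_z(u), 0.1)
})

test_that("rigid rotation preserves mask volume within interpolation tolerance", {
  v <- make_test_volume()
  th <- 10 * pi / 180
  lm <- landmark_pair(c(0, -5 * sin(th), -5 * cos(th)),
                      c(0, 5 * sin(th), 5 * cos(th)))
  out <- align_to_axis(v, lm)
  n0 <- sum(v$target_mask); n1 <- sum(out$target_mask)
  expect_lt(abs(n1 - n0) / n0, 0.05)
})

test_that("alignment followed by its inverse recovers mask volume (<= 5%)", {
  v <- make_test_volume(2)
  th <- 12 * pi / 180
  lm <- landmark_pair(c(0, -5 * sin(th), -5 * cos(th)),
                      c(0, 5 * sin(th), 5 * cos(th)))
  fwd <- align_to_axis(v, lm)
  # inverse: landmarks that rotate back by the same angle the other way
  lm_inv <- landmark_pair(c(0, 5 * sin(th), -5 * cos(th)),
                          c(0, -5 * sin(th), 5 * cos(th)))
  back <- align_to_axis(fwd, lm_inv)
  expect_lt(abs(sum(back$target_mask) - sum(v$target_mask)) /
              sum(v$target_mask), 0.05)
})

test_that("degenerate landmarks are rejected", {
  expect_error(landmark_pair(c(1, 2, 3), c(1, 2, 3)), "degenerate")
})

test_that("identity-spacing resampling is a voxel-identical crop", {
  v <- make_test_volume()
  spec <- resample_spec(in_plane_spacing = 1, slice_thickness = 1,
                        block_slices = 8L, block_plane_size = 16L)
  out <- resample_block(v, spec, block_center = c(0, 0, 0))
  expect_equal(dim(out$intensity), c(16L, 16L, 8L))
  expect_equal(out$intensity, v$intensity[9:24, 9:24, 13:20],
               ignore_attr = TRUE)
  expect_identical(out$target_mask, v$target_mask[9:24, 9:24, 13:20],
                   ignore_attr = TRUE)
})

test_that("2x in-plane upsampling of a cuboid mask scales voxel counts by 4", {
  img <- array(0, c(16, 16, 8))
  tgt <- array(FALSE, c(16, 16, 8))
  tgt[5:12, 5:12, 3:6] <- TRUE
  img[tgt] <- 1
  v <- labeled_volume(img, target_mask = tgt, voxel_size = c(1, 1, 1))
  spec <- resample_spec(in_plane_spacing = 0.5, slice_thickness = 1,
                        block_slices = 4L, block_plane_size = 24L)
  out <- resample_block(v, spec, block_center = c(0, 0, 0))
  per_slice_in <- sum(tgt[, , 4])
  per_slice_out <- sum(out$target_mask[, , 2])
  expect_equal(per_slice_out, 4L * per_slice_in)
})

test_that("full-scale block spec yields a 512 x 512 x 50 grid", {
  # coarse whole-head stand-in large enough to contain the 64 mm block
  v <- generate_phantom(desk_phantom_spec(grid_shape = c(40L, 40L, 32L),
                                          voxel_size = c(2, 2, 1),
                                          noise_sd = 0, seed = 5))
  spec <- resample_spec()  # defaults: 0.125 mm in-plane, 0.5 mm, 50 x 512^2
  out <- resample_block(v, spec, block_center = c(0, 0, 0))
  expect_equal(dim(out$intensity), c(512L, 512L, 50L))
  expect_equal(out$voxel_size, c(0.125, 0.125, 0.5))
  # physical target volume preserved within 5% despite upsampling
  v_in <- sum(v$target_mask) * prod(v$voxel_size)
  v_out <- sum(out$target_mask) * prod(out$voxel_size)
  expect_lt(abs(v_out - v_in) / v_in, 0.05)
})

test_that("a block exceeding the volume bounds names the offending axis", {
  v <- make_test_volume()
  spec <- resample_spec(in_plane_spacing = 1, slice_thickness = 2,
                        block_slices = 40L, block_plane_size = 16L)
  expect_error(resample_block(v, spec, block_center = c(0, 0, 0)), "axis z")
})

test_that("upsampling a mask preserves physical volume (<= 5%)", {
  set.seed(31)
  v <- make_test_volume(3)
  for (i in 1:4) {
    # genuine spatial upsampling at the pipeline's 5-8x factors;
    # nearest-neighbour resampling at spacing ratios near 1 aliases and is
    # not volume-safe for small structures
    sp <- resample_spec(in_plane_spacing = runif(1, 0.13, 0.2),
                        slice_thickness = runif(1, 0.13, 0.2),
                        block_slices = 64L, block_plane_size = 96L)
    out <- resample_block(v, sp)  # centred on the target centroid
    v_in <- sum(v$target_mask) * prod(v$voxel_size)
    v_out <- sum(out$target_mask) * prod(out$voxel_size)
    expect_lt(abs(v_out - v_in) / v_in, 0.05)
  }
})
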