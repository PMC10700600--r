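#' Landmark pair defining the alignment axis
#'
#' Anterior/posterior landmark coordinates (mm, in the volume's centred world
#' frame) defining the axis the slice normal is aligned to — the stand-in for
#' the anterior commissure / posterior commissure axis used to standardize
#' head orientation.
#'
#' @param anterior,posterior numeric length-3 mm coordinates; must differ.
#' @return Object of class `landmark_pair`.
#' @export
landmark_pair <- function(anterior, posterior) {
  stopifnot(length(anterior) == 3L, length(posterior) == 3L)
  if (sqrt(sum((posterior - anterior)^2)) < 1e-8)
    stop_param("degenerate landmarks: anterior and posterior coincide")
  structure(list(anterior = as.numeric(anterior),
                 posterior = as.numeric(posterior)),
            class = "landmark_pair")
}

# rotation matrix mapping unit vector u onto unit vector v (Rodrigues)
rotation_between <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  c_ <- sum(u * v)
  if (c_ > 1 - 1e-12) return(diag(3))
  axis <- c(u[2] * v[3] - u[3] * v[2],
            u[3] * v[1] - u[1] * v[3],
            u[1] * v[2] - u[2] * v[1])
  s <- sqrt(sum(axis^2))
  if (s < 1e-12) {  # anti-parallel: rotate pi about any perpendicular axis
    p <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- p - sum(p * u) * u
    axis <- axis / sqrt(sum(axis^2))
    K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                  axis[2], -axis[1], 0), 3, 3)
    return(diag(3) + 2 * K %*% K)
  }
  axis <- axis / s
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + s * K + (1 - c_) * K %*% K
}

# world-mm coordinates (centred) of every voxel centre; n x 3 matrix
grid_world_coords <- function(grid_shape, voxel_size) {
  xs <- voxel_centers(grid_shape[1], voxel_size[1])
  ys <- voxel_centers(grid_shape[2], voxel_size[2])
  zs <- voxel_centers(grid_shape[3], voxel_size[3])
  cbind(rep(xs, times = grid_shape[2] * grid_shape[3]),
        rep(rep(ys, each = grid_shape[1]), times = grid_shape[3]),
        rep(zs, each = grid_shape[1] * grid_shape[2]))
}

world_to_index <- function(w, grid_shape, voxel_size) {
  sweep(sweep(w, 2, voxel_size, "/"), 2, (grid_shape + 1) / 2, "+")
}

# resample a labeled volume's arrays at world coordinates `w` (n x 3, mm),
# returning arrays of shape `out_shape`
resample_at <- function(volume, w, out_shape, chunk = 2e6) {
  gs <- dim(volume$intensity); vs <- volume$voxel_size
  n <- nrow(w)
  intensity <- numeric(n)
  tgt <- if (!is.null(volume$target_mask)) numeric(n)
  icv <- if (!is.null(volume$icv_mask)) numeric(n)
  tm <- if (!is.null(volume$target_mask)) volume$target_mask + 0
  im <- if (!is.null(volume$icv_mask)) volume$icv_mask + 0
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1, n)
    ijk <- world_to_index(w[idx, , drop = FALSE], gs, vs)
    intensity[idx] <- interp_trilinear(volume$intensity, ijk)
    if (!is.null(tgt)) tgt[idx] <- interp_nearest(tm, ijk)
    if (!is.null(icv)) icv[idx] <- interp_nearest(im, ijk)
  }
  shape_arr <- function(x) { dim(x) <- out_shape; x }
  list(intensity = shape_arr(intensity),
       target_mask = if (!is.null(tgt)) shape_arr(tgt) > 0,
       icv_mask = if (!is.null(icv)) shape_arr(icv) > 0)
}

#' Rigidly align a volume's slice axis to a landmark axis
#'
#' Rotates the volume (about its centre) so that the third (slice-normal) axis
#' becomes parallel to the axis through the two landmarks, emulating rigid
#' normalization along the AC--PC axis so coronal cutting planes are
#' perpendicular to it. Intensities are interpolated trilinearly; masks with
#' nearest-neighbour, so labels stay binary and volumes are preserved up to
#' interpolation.
#'
#' @param volume a [labeled_volume()].
#' @param landmarks a [landmark_pair()] in the volume's centred mm frame.
#' @return The aligned [labeled_volume()]; attribute `"rotation"` carries the
#'   applied rotation matrix and `"landmarks_aligned"` the transformed
#'   landmark coordinates.
#' @export
align_to_axis <- function(volume, landmarks) {
  stopifnot(inherits(volume, "labeled_volume"),
            inherits(landmarks, "landmark_pair"))
  gs <- dim(volume$intensity); vs <- volume$voxel_size
  half <- gs * vs / 2
  for (p in list(landmarks$anterior, landmarks$posterior))
    if (any(abs(p) > half))
      stop_param("landmark outside the volume bounds")
  u <- landmarks$posterior - landmarks$anterior
  R <- rotation_between(u, c(0, 0, 1))
  if (max(abs(R - diag(3))) < 1e-12) {
    out <- volume
    attr(out, "rotation") <- diag(3)
    attr(out, "landmarks_aligned") <- landmarks
    return(out)
  }
  # output voxel at world w takes the input value at R^{-1} w
  w <- grid_world_coords(gs, vs)
  res <- resample_at(volume, w %*% R, gs)  # w %*% R == t(t(R) %*% t(w)), R^{-1}=R^T
  out <- labeled_volume(res$intensity, target_mask = res$target_mask,
                        icv_mask = res$icv_mask, voxel_size = vs,
                        subject_id = volume$subject_id, group = volume$group)
  attr(out, "rotation") <- R
  la <- landmark_pair(as.numeric(R %*% landmarks$anterior),
                      as.numeric(R %*% landmarks$posterior))
  attr(out, "landmarks_aligned") <- la
  out
}

#' Resampling specification for the analysis block
#'
#' Geometry of the fixed coronal block extracted around the target: plane size
#' in pixels, in-plane spacing, slice count and thickness. Defaults follow the
#' full-scale analysis geometry (512 x 512 pixels at 0.125 mm, 50 slices of
#' 0.5 mm).
#'
#' @param in_plane_spacing mm (> 0).
#' @param slice_thickness mm (> 0).
#' @param block_slices number of slices (>= 1).
#' @param block_plane_size plane size in pixels.
#' @return Object of class `resample_spec`.
#' @export
resample_spec <- function(in_plane_spacing = 0.125, slice_thickness = 0.5,
                          block_slices = 50L, block_plane_size = 512L) {
  if (in_plane_spacing <= 0 || slice_thickness <= 0)
    stop_param("spacings must be positive")
  if (block_slices < 1L || block_plane_size < 1L)
    stop_param("block dimensions must be >= 1")
  structure(list(in_plane_spacing = in_plane_spacing,
                 slice_thickness = slice_thickness,
                 block_slices = as.integer(block_slices),
                 block_plane_size = as.integer(block_plane_size)),
            class = "resample_spec")
}

# world centroid (mm, centred frame) of a binary mask
mask_centroid <- function(mask, voxel_size) {
  idx <- which(mask > 0, arr.ind = TRUE)
  gs <- dim(mask)
  colMeans(sweep(sweep(idx, 2, (gs + 1) / 2, "-"), 2, voxel_size, "*"))
}

#' Extract and resample the analysis block
#'
#' Crops a block of `block_plane_size^2 x block_slices` voxels at the
#' requested spacings, centred on `block_center` (defaults to the target-mask
#' centroid when ground truth is present). Intensity is interpolated linearly,
#' masks nearest-neighbour (spatial upsampling of the structure region).
#'
#' @param volume a [labeled_volume()].
#' @param spec a [resample_spec()].
#' @param block_center optional mm coordinates of the block centre in the
#'   volume's centred frame.
#' @return A [labeled_volume()] on the block grid.
#' @export
resample_block <- function(volume, spec, block_center = NULL) {
  stopifnot(inherits(volume, "labeled_volume"),
            inherits(spec, "resample_spec"))
  if (is.null(block_center)) {
    if (is.null(volume$target_mask) || sum(volume$target_mask) == 0)
      stop_param("no target mask present: supply block_center explicitly")
    block_center <- mask_centroid(volume$target_mask, volume$voxel_size)
  }
  np <- spec$block_plane_size; ns <- spec$block_slices
  sp <- c(spec$in_plane_spacing, spec$in_plane_spacing, spec$slice_thickness)
  out_shape <- c(np, np, ns)
  gs <- dim(volume$intensity); vs <- volume$voxel_size
  half <- gs * vs / 2
  ext <- out_shape * sp / 2
  for (ax in 1:3) {
    if (block_center[ax] - ext[ax] < -half[ax] - vs[ax] / 2 ||
        block_center[ax] + ext[ax] > half[ax] + vs[ax] / 2)
      stop_param("block exceeds volume bounds along axis %s",
                 c("x", "y", "z")[ax])
  }
  xs <- voxel_centers(np, sp[1]) + block_center[1]
  ys <- voxel_centers(np, sp[2]) + block_center[2]
  zs <- voxel_centers(ns, sp[3]) + block_center[3]
  w <- cbind(rep(xs, times = np * ns),
             rep(rep(ys, each = np), times = ns),
             rep(zs, each = np * np))
  res <- resample_at(volume, w, out_shape)
  out <- labeled_volume(res$intensity, target_mask = res$target_mask,
                        icv_mask = res$icv_mask, voxel_size = sp,
                        subject_id = volume$subject_id, group = volume$group)
  attr(out, "block_center") <- block_center
  out
}
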