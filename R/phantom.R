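#' Specification of a single synthetic head phantom
#'
#' Describes the geometry and intensity model of one synthetic T1-weighted
#' volume: a bright ellipsoidal intracranial compartment on a dark background,
#' containing a small bilateral midline target structure (two mirrored
#' half-ellipsoids flanking a midline gap, emulating the hypothalamus).
#'
#' The full-scale default geometry corresponds to the preprocessed coronal
#' analysis block: 512 x 512 pixels at 0.125 x 0.125 mm in-plane and 50 slices
#' of 0.5 mm. Use [desk_phantom_spec()] for a small grid suitable for fast
#' experiments.
#'
#' @param grid_shape integer vector of 3 voxel counts.
#' @param voxel_size numeric vector of 3 voxel spacings in mm (all > 0).
#' @param icv_semiaxes ellipsoid semi-axes of the intracranial compartment, mm.
#' @param target_center mm offset of the target structure from the grid centre.
#' @param target_volume intended true target volume in mm^3.
#' @param intensity_levels named vector `background`, `tissue`, `target`
#'   (target is a contrast *offset* added on top of tissue).
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param contrast_gain,contrast_offset per-scan global affine intensity
#'   transform applied before noise.
#' @param bias_gradient strength of a simple multiplicative intensity gradient
#'   along the first axis (0 disables).
#' @param target_gap midline separation between the two target halves, mm.
#' @param seed integer seed; identical seeds give bit-identical phantoms.
#' @return An object of class `phantom_spec`.
#' @seealso [generate_phantom()], [cohort_spec()]
#' @export
phantom_spec <- function(grid_shape = c(512L, 512L, 50L),
                         voxel_size = c(0.125, 0.125, 0.5),
                         icv_semiaxes = c(30, 26, 11),
                         target_center = c(0, 2, 0),
                         target_volume = 820,
                         intensity_levels = c(background = 0.1, tissue = 0.6,
                                              target = 0.25),
                         noise_sd = 0.03,
                         contrast_gain = 1,
                         contrast_offset = 0,
                         bias_gradient = 0,
                         target_gap = 0.5,
                         seed = 1L) {
  spec <- list(grid_shape = as.integer(grid_shape), voxel_size = voxel_size,
               icv_semiaxes = icv_semiaxes, target_center = target_center,
               target_volume = target_volume,
               intensity_levels = intensity_levels, noise_sd = noise_sd,
               contrast_gain = contrast_gain,
               contrast_offset = contrast_offset,
               bias_gradient = bias_gradient, target_gap = target_gap,
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

#' @rdname phantom_spec
#' @export
desk_phantom_spec <- function(grid_shape = c(64L, 64L, 24L),
                              voxel_size = c(1, 1, 1),
                              icv_semiaxes = c(26, 24, 10), ...) {
  phantom_spec(grid_shape = grid_shape, voxel_size = voxel_size,
               icv_semiaxes = icv_semiaxes, ...)
}

validate_phantom_spec <- function(spec) {
  if (length(spec$grid_shape) != 3L || any(spec$grid_shape < 4L))
    stop_param("grid_shape must be 3 voxel counts >= 4")
  if (length(spec$voxel_size) != 3L || any(spec$voxel_size <= 0))
    stop_param("voxel_size must be 3 positive spacings (mm)")
  if (any(spec$icv_semiaxes <= 0))
    stop_param("icv_semiaxes must be positive (mm)")
  if (spec$target_volume <= 0)
    stop_param("target_volume must be positive (mm^3)")
  if (spec$noise_sd < 0) stop_param("noise_sd must be >= 0")
  if (spec$target_gap < 0) stop_param("target_gap must be >= 0")
  req <- c("background", "tissue", "target")
  if (!all(req %in% names(spec$intensity_levels)))
    stop_param("intensity_levels needs names: %s", paste(req, collapse = ", "))
  half <- spec$grid_shape * spec$voxel_size / 2
  if (any(spec$icv_semiaxes >= half))
    stop_param("icv_semiaxes exceed the physical grid half-extent")
  invisible(spec)
}

# semi-axes of an ellipsoid of volume v with fixed anisotropy ratios
ellipsoid_semiaxes <- function(v, ratios = c(1.25, 1, 0.75)) {
  s <- (v / (4 / 3 * pi * prod(ratios)))^(1 / 3)
  s * ratios
}

# ICV ellipsoid semi-axes from a target ICV volume, 2:2:1 anisotropy
icv_semiaxes_from_volume <- function(v) ellipsoid_semiaxes(v, c(2, 2, 1))

#' Construct a labelled volume
#'
#' Carrier for one subject's image data: the intensity grid, optional binary
#' target / intracranial masks, voxel geometry and provenance. True volumes are
#' always recomputed as mask voxel count times voxel volume.
#'
#' @param intensity 3-D numeric array.
#' @param target_mask,icv_mask optional binary arrays of the same shape.
#' @param voxel_size voxel spacings in mm.
#' @param subject_id character id.
#' @param group `"control"` or `"case"`.
#' @return An object of class `labeled_volume`.
#' @export
labeled_volume <- function(intensity, target_mask = NULL, icv_mask = NULL,
                           voxel_size, subject_id = NA_character_,
                           group = NA_character_) {
  stopifnot(length(dim(intensity)) == 3L)
  vv <- prod(voxel_size)
  for (m in list(target_mask, icv_mask)) {
    if (!is.null(m)) {
      if (!identical(dim(m), dim(intensity)))
        stop_param("mask shape differs from intensity shape")
      if (!is_binary_array(m)) stop_param("masks must be binary")
    }
  }
  vol <- list(
    intensity = intensity,
    target_mask = target_mask,
    icv_mask = icv_mask,
    voxel_size = voxel_size,
    true_target_volume = if (!is.null(target_mask)) sum(target_mask) * vv else NA_real_,
    true_icv_volume = if (!is.null(icv_mask)) sum(icv_mask) * vv else NA_real_,
    subject_id = subject_id,
    group = group
  )
  class(vol) <- "labeled_volume"
  vol
}

#' @export
print.labeled_volume <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("<labeled_volume> %s  grid %dx%dx%d @ %s mm\n",
              ifelse(is.na(x$subject_id), "(unnamed)", x$subject_id),
              d[1], d[2], d[3],
              paste(signif(x$voxel_size, 3), collapse = "x")))
  if (!is.na(x$group)) cat("  group:", x$group, "\n")
  if (!is.na(x$true_target_volume))
    cat(sprintf("  target volume: %.1f mm^3\n", x$true_target_volume))
  if (!is.na(x$true_icv_volume))
    cat(sprintf("  ICV volume: %.1f mm^3\n", x$true_icv_volume))
  invisible(x)
}

# Voxelize the bilateral target: two mirrored half-ellipsoids flanking the
# midline plane x = cx, separated by `gap` mm. The semi-axis scale is
# calibrated by binary search so the realized voxel count matches
# target_volume / voxel volume as closely as the grid allows.
voxelize_bilateral_target <- function(xs, ys, zs, center, volume, gap,
                                      voxvol, ratios = c(1.25, 1, 0.75)) {
  semi <- ellipsoid_semiaxes(volume, ratios)
  cx <- center[1]; cy <- center[2]; cz <- center[3]
  # crop the search to a bounding box around the target (max scale 1.35)
  bb <- semi * 1.35 + c(gap / 2, 0, 0)
  ix <- which(xs >= cx - bb[1] & xs <= cx + bb[1])
  iy <- which(ys >= cy - bb[2] & ys <= cy + bb[2])
  iz <- which(zs >= cz - bb[3] & zs <= cz + bb[3])
  xs_c <- xs[ix]; ys_c <- ys[iy]; zs_c <- zs[iz]
  crop_mask <- function(s) {
    a <- semi * s
    cxl <- cx - gap / 2; cxr <- cx + gap / 2
    exl <- ((xs_c - cxl) / a[1])^2
    exr <- ((xs_c - cxr) / a[1])^2
    ey <- ((ys_c - cy) / a[2])^2
    ez <- ((zs_c - cz) / a[3])^2
    qyz <- outer(ey, ez, "+")
    left <- outer(exl, c(qyz), "+") <= 1 & (xs_c <= cxl)
    right <- outer(exr, c(qyz), "+") <= 1 & (xs_c >= cxr)
    m <- left | right
    dim(m) <- c(length(xs_c), length(ys_c), length(zs_c))
    m
  }
  n_target <- volume / voxvol
  lo <- 0.75; hi <- 1.35
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (sum(crop_mask(mid)) < n_target) lo <- mid else hi <- mid
  }
  m_lo <- crop_mask(lo); m_hi <- crop_mask(hi)
  best <- if (abs(sum(m_hi) - n_target) < abs(sum(m_lo) - n_target)) m_hi else m_lo
  full <- array(FALSE, c(length(xs), length(ys), length(zs)))
  full[ix, iy, iz] <- best
  full
}

#' Generate one synthetic head phantom
#'
#' Builds the intensity volume and ground-truth masks described by a
#' [phantom_spec()]. Deterministic per seed: the same spec yields bit-identical
#' output.
#'
#' @param spec a `phantom_spec`.
#' @return A [labeled_volume()] with both masks populated and true volumes
#'   recorded.
#' @export
#' @examples
#' vol <- generate_phantom(desk_phantom_spec(target_volume = 500, seed = 7))
#' vol
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  gs <- spec$grid_shape; vs <- spec$voxel_size
  xs <- voxel_centers(gs[1], vs[1])
  ys <- voxel_centers(gs[2], vs[2])
  zs <- voxel_centers(gs[3], vs[3])
  a <- spec$icv_semiaxes
  ex <- (xs / a[1])^2; ey <- (ys / a[2])^2; ez <- (zs / a[3])^2
  icv <- outer(outer(ex, ey, "+"), ez, "+") <= 1

  # target must plausibly fit before voxelization
  tsemi <- ellipsoid_semiaxes(spec$target_volume)
  reach <- abs(spec$target_center) + tsemi + c(spec$target_gap / 2, 0, 0)
  if (any(reach >= a))
    stop_param(paste("target_volume too large: target extent (%.1f, %.1f, %.1f) mm",
                     "does not fit strictly inside icv_semiaxes (%.1f, %.1f, %.1f) mm"),
               reach[1], reach[2], reach[3], a[1], a[2], a[3])

  target <- voxelize_bilateral_target(xs, ys, zs, spec$target_center,
                                      spec$target_volume, spec$target_gap,
                                      prod(vs))
  if (any(target & !icv))
    stop_param("target_volume too large: target mask extends outside the intracranial compartment")

  lev <- spec$intensity_levels
  img <- lev[["background"]] + (lev[["tissue"]] - lev[["background"]]) * icv +
    lev[["target"]] * target
  if (spec$bias_gradient != 0) {
    gx <- 1 + spec$bias_gradient * (xs - min(xs)) / (max(xs) - min(xs)) -
      spec$bias_gradient / 2
    img <- img * gx  # recycles along first axis (column-major)
  }
  img <- spec$contrast_gain * img + spec$contrast_offset
  img <- with_seed(spec$seed, {
    if (spec$noise_sd > 0)
      img + array(rnorm(length(img), 0, spec$noise_sd), dim(img))
    else img
  })
  labeled_volume(img, target_mask = target, icv_mask = icv, voxel_size = vs)
}

#' Specification of a synthetic study cohort
#'
#' Parameters of a two-group phantom cohort with per-subject volume
#' variability, a group-level atrophy effect on the target structure, and
#' scan-to-scan contrast variation. Per-subject target volumes are drawn
#' log-normal around the group mean and (by default) scale proportionally with
#' the subject's intracranial volume, so that ICV normalization removes
#' head-size variance as in real morphometry.
#'
#' @param n_control,n_case group sizes (>= 1).
#' @param control_mean_target_volume control-group mean target volume, mm^3.
#' @param effect_fraction fractional reduction of the case-group mean
#'   (0 <= f < 1).
#' @param between_subject_cv coefficient of variation of per-subject target
#'   volumes around the group mean.
#' @param icv_mean,icv_sd mean and SD of per-subject intracranial volume, mm^3.
#' @param icv_coupling exponent coupling target volume to relative ICV
#'   (1 = proportional, 0 = independent).
#' @param contrast_gain_range,contrast_offset_range uniform sampling intervals
#'   of the per-scan affine intensity transform.
#' @param noise_sd additive noise SD for every scan.
#' @param grid_shape,voxel_size,target_center,intensity_levels,target_gap
#'   passed to each subject's [phantom_spec()].
#' @param seed integer seed for the whole cohort.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_control = 60L, n_case = 60L,
                        control_mean_target_volume = 240,
                        effect_fraction = 0.10,
                        between_subject_cv = 0.08,
                        icv_mean = 3600, icv_sd = 325,
                        icv_coupling = 1,
                        contrast_gain_range = c(0.9, 1.1),
                        contrast_offset_range = c(-0.05, 0.05),
                        noise_sd = 0.03,
                        grid_shape = c(32L, 32L, 16L),
                        voxel_size = c(1, 1, 1),
                        target_center = c(0, 1, 0),
                        intensity_levels = c(background = 0.1, tissue = 0.6,
                                             target = 0.25),
                        target_gap = 1,
                        seed = 1L) {
  spec <- list(n_control = as.integer(n_control), n_case = as.integer(n_case),
               control_mean_target_volume = control_mean_target_volume,
               effect_fraction = effect_fraction,
               between_subject_cv = between_subject_cv,
               icv_mean = icv_mean, icv_sd = icv_sd,
               icv_coupling = icv_coupling,
               contrast_gain_range = contrast_gain_range,
               contrast_offset_range = contrast_offset_range,
               noise_sd = noise_sd, grid_shape = as.integer(grid_shape),
               voxel_size = voxel_size, target_center = target_center,
               intensity_levels = intensity_levels, target_gap = target_gap,
               seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  if (spec$n_control < 1L || spec$n_case < 1L)
    stop_param("group sizes must be >= 1")
  if (spec$effect_fraction < 0 || spec$effect_fraction >= 1)
    stop_param("effect_fraction must satisfy 0 <= f < 1")
  if (spec$control_mean_target_volume <= 0 || spec$icv_mean <= 0)
    stop_param("volumes must be positive")
  if (spec$between_subject_cv < 0 || spec$icv_sd < 0)
    stop_param("variability parameters must be >= 0")
  invisible(spec)
}

# log-normal draw with arithmetic mean m and sd s
rlnorm_mean_sd <- function(n, m, s) {
  if (s == 0) return(rep(m, n))
  sigma2 <- log(1 + (s / m)^2)
  stats::rlnorm(n, meanlog = log(m) - sigma2 / 2, sdlog = sqrt(sigma2))
}

#' Generate a synthetic two-group cohort
#'
#' Draws per-subject true volumes and contrast parameters per [cohort_spec()]
#' and generates one phantom per subject. Case-group target volumes have mean
#' `control_mean_target_volume * (1 - effect_fraction)`. Fully reproducible
#' per seed. Subjects whose drawn target would not fit inside their
#' intracranial compartment are redrawn (with a message) at a truncation bound
#' of half the ICV volume.
#'
#' @param cohort a `cohort_spec`.
#' @return A list of [labeled_volume()] objects with `subject_id` and `group`
#'   set.
#' @export
generate_cohort <- function(cohort) {
  validate_cohort_spec(cohort)
  with_seed(cohort$seed, {
    groups <- rep(c("control", "case"), c(cohort$n_control, cohort$n_case))
    n <- length(groups)
    ids <- sprintf("%s%03d", ifelse(groups == "control", "con", "als"),
                   stats::ave(seq_len(n), groups, FUN = seq_along))
    vols <- vector("list", n)
    n_redraw <- 0L
    for (i in seq_len(n)) {
      v_icv <- rlnorm_mean_sd(1, cohort$icv_mean, cohort$icv_sd)
      gmean <- cohort$control_mean_target_volume *
        (1 - cohort$effect_fraction * (groups[i] == "case"))
      draw_target <- function() {
        gmean * (v_icv / cohort$icv_mean)^cohort$icv_coupling *
          rlnorm_mean_sd(1, 1, cohort$between_subject_cv)
      }
      v_t <- draw_target()
      tries <- 0L
      while (v_t >= v_icv / 2 && tries < 100L) {
        v_t <- draw_target(); tries <- tries + 1L; n_redraw <- n_redraw + 1L
      }
      spec_i <- phantom_spec(
        grid_shape = cohort$grid_shape, voxel_size = cohort$voxel_size,
        icv_semiaxes = icv_semiaxes_from_volume(v_icv),
        target_center = cohort$target_center, target_volume = v_t,
        intensity_levels = cohort$intensity_levels,
        noise_sd = cohort$noise_sd,
        contrast_gain = runif(1, cohort$contrast_gain_range[1],
                              cohort$contrast_gain_range[2]),
        contrast_offset = runif(1, cohort$contrast_offset_range[1],
                                cohort$contrast_offset_range[2]),
        target_gap = cohort$target_gap,
        seed = sample.int(2147483646L, 1L))
      v <- generate_phantom(spec_i)
      v$subject_id <- ids[i]
      v$group <- groups[i]
      vols[[i]] <- v
    }
    if (n_redraw > 0L)
      message(sprintf("generate_cohort: %d truncated redraws of target volume",
                      n_redraw))
    vols
  })
}

#' Image-count accounting for subject splits
#'
#' Bookkeeping used in study reports: the number of 2-D images contributed by
#' each subject split when every subject contributes a fixed slice block.
#'
#' @param n_subjects named integer vector of subject counts per split.
#' @param slices_per_volume slices contributed per subject (default 50).
#' @return A data.frame with columns `split`, `subjects`, `images`.
#' @export
#' @examples
#' split_image_counts(c(training = 71, validation = 7, test = 30))
split_image_counts <- function(n_subjects, slices_per_volume = 50L) {
  stopifnot(all(n_subjects >= 0), slices_per_volume >= 1)
  data.frame(split = names(n_subjects) %||% as.character(seq_along(n_subjects)),
             subjects = as.integer(n_subjects),
             images = as.integer(n_subjects) * as.integer(slices_per_volume),
             row.names = NULL)
}
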