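#' Contrast-shift augmentation specification
#'
#' Sampling intervals of the per-copy contrast transform (affine gain/offset
#' plus gamma) used to expand a training set so the segmenter tolerates
#' scan-to-scan contrast variation. The transform changes intensities only and
#' never the label masks.
#'
#' @param factor integer number of augmented copies per source image (>= 1).
#' @param gain_range,offset_range,gamma_range finite sampling intervals;
#'   gamma must stay positive.
#' @param seed integer seed.
#' @return Object of class `augment_spec`.
#' @export
augment_spec <- function(factor = 6L, gain_range = c(0.5, 1.5),
                         offset_range = c(-0.2, 0.2),
                         gamma_range = c(0.7, 1.4), seed = 1L) {
  if (length(factor) != 1L || is.na(factor) || factor < 1)
    stop_param("augmentation factor must be an integer >= 1")
  rngs <- list(gain_range = gain_range, offset_range = offset_range,
               gamma_range = gamma_range)
  for (nm in names(rngs)) {
    r <- rngs[[nm]]
    if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2])
      stop_param("%s must be a finite interval", nm)
  }
  if (gamma_range[1] <= 0) stop_param("gamma must be positive")
  structure(list(factor = as.integer(factor), gain_range = gain_range,
                 offset_range = offset_range, gamma_range = gamma_range,
                 seed = as.integer(seed)),
            class = "augment_spec")
}

#' Shift the contrast of one image
#'
#' Normalizes the image to `[0, 1]`, applies `gain * x^gamma + offset`, clips
#' to `[0, 1]` and rescales back to the input range. Monotone in input
#' intensity wherever no clipping occurs, so anatomical structure is
#' preserved.
#'
#' @param image numeric matrix or array.
#' @param gain,offset,gamma transform parameters; `gamma > 0`.
#' @return Transformed image, same shape and intensity range convention.
#' @export
#' @examples
#' img <- matrix(seq(0, 1, length.out = 16), 4, 4)
#' identical(dim(contrast_shift(img, gain = 2)), dim(img))
contrast_shift <- function(image, gain = 1, offset = 0, gamma = 1) {
  if (gamma <= 0) stop_param("gamma must be > 0")
  r <- range(image)
  if (r[2] <= r[1]) return(image)
  z <- (image - r[1]) / (r[2] - r[1])
  z <- gain * z^gamma + offset
  z <- pmin(pmax(z, 0), 1)
  r[1] + z * (r[2] - r[1])
}

#' Build a contrast-augmented training set
#'
#' Returns the original slices followed by `factor` transformed copies of each
#' slice, with gain/offset/gamma sampled uniformly from the spec's intervals.
#' Label masks are carried through untouched. Seeded and reproducible.
#'
#' @param slices list of slices, each `list(x = image matrix, y = label mask)`.
#' @param spec an [augment_spec()].
#' @return List of slices of length `length(slices) * (factor + 1)`.
#' @export
build_augmented_set <- function(slices, spec) {
  stopifnot(inherits(spec, "augment_spec"))
  if (length(slices) == 0) stop_param("empty training set")
  out <- slices
  with_seed(spec$seed, {
    for (f in seq_len(spec$factor)) {
      for (s in slices) {
        g <- runif(1, spec$gain_range[1], spec$gain_range[2])
        o <- runif(1, spec$offset_range[1], spec$offset_range[2])
        gm <- runif(1, spec$gamma_range[1], spec$gamma_range[2])
        s$x <- contrast_shift(s$x, g, o, gm)
        out[[length(out) + 1L]] <- s
      }
    }
  })
  out
}

#' Extract 2-D training slices from labelled volumes
#'
#' Converts volumes into the per-slice representation the segmenter trains on:
#' one element per axial position of the third (slice) axis, holding the
#' intensity plane and the binary label plane for the requested task.
#'
#' @param volumes list of [labeled_volume()] objects.
#' @param task `"target"` or `"icv"`: which mask supplies the labels.
#' @param slice_range optional integer range of slice indices to keep.
#' @return List of `list(x, y, subject_id, slice)`.
#' @export
as_slice_set <- function(volumes, task = c("target", "icv"),
                         slice_range = NULL) {
  task <- match.arg(task)
  out <- list()
  for (v in volumes) {
    mask <- if (task == "target") v$target_mask else v$icv_mask
    if (is.null(mask)) stop_param("volume lacks a %s mask", task)
    nz <- dim(v$intensity)[3]
    idx <- slice_range %||% seq_len(nz)
    for (k in idx) {
      out[[length(out) + 1L]] <- list(x = v$intensity[, , k],
                                      y = (mask[, , k]) + 0L,
                                      subject_id = v$subject_id, slice = k)
    }
  }
  out
}
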