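#' Voxel-wise confusion counts between two binary masks
#'
#' True positives are the intersection of segmentation and ground truth, true
#' negatives the voxels outside their union, false positives segmented voxels
#' not in the truth, false negatives missed truth voxels. Computed per volume.
#'
#' @param pred_mask,truth_mask binary arrays of identical shape.
#' @return Object of class `confusion_counts` with fields `tp`, `fp`, `tn`,
#'   `fn`.
#' @export
confusion <- function(pred_mask, truth_mask) {
  if (!identical(dim(pred_mask), dim(truth_mask)))
    stop_param("mask shape mismatch")
  if (!is_binary_array(pred_mask) || !is_binary_array(truth_mask))
    stop_param("masks must be binary")
  p <- pred_mask > 0; t_ <- truth_mask > 0
  tp <- sum(p & t_)
  fp <- sum(p & !t_)
  fn <- sum(!p & t_)
  tn <- length(p) - tp - fp - fn
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn),
            class = "confusion_counts")
}

#' Overlap metrics from confusion counts
#'
#' IoU (Jaccard), precision, recall and Dice from per-volume voxel counts.
#' Metrics with an undefined denominator are reported as `NA` and flagged in
#' the `"undefined"` attribute rather than coerced to 0.
#'
#' @param counts a [confusion()] result, or a list with `tp`, `fp`, `tn`,
#'   `fn`.
#' @return Named list `iou`, `precision`, `recall`, `dice`, all in `[0, 1]`
#'   where defined.
#' @export
#' @examples
#' overlap_metrics(list(tp = 1, fp = 1, tn = 0, fn = 1))
overlap_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  if (any(c(tp, fp, counts$tn, fn) < 0)) stop_param("counts must be >= 0")
  undef <- character()
  safe <- function(num, den, name) {
    if (den > 0) num / den else { undef <<- c(undef, name); NA_real_ }
  }
  out <- list(iou = safe(tp, tp + fp + fn, "iou"),
              precision = safe(tp, tp + fp, "precision"),
              recall = safe(tp, tp + fn, "recall"),
              dice = safe(2 * tp, 2 * tp + fp + fn, "dice"))
  attr(out, "undefined") <- undef
  out
}

# boundary voxels: foreground voxels with at least one face-neighbour (6-
# connectivity) that is background; voxels on the array border count as
# boundary (outside is background).
boundary_voxels <- function(mask) {
  m <- mask > 0
  d <- dim(m)
  shift <- function(di, dj, dk) {
    out <- array(FALSE, d)
    si <- seq_len(d[1]); sj <- seq_len(d[2]); sk <- seq_len(d[3])
    ti <- si + di; tj <- sj + dj; tk <- sk + dk
    keep_i <- ti >= 1 & ti <= d[1]
    keep_j <- tj >= 1 & tj <= d[2]
    keep_k <- tk >= 1 & tk <= d[3]
    out[si[keep_i], sj[keep_j], sk[keep_k]] <-
      m[ti[keep_i], tj[keep_j], tk[keep_k]]
    out
  }
  nb_all_fg <- shift(1, 0, 0) & shift(-1, 0, 0) & shift(0, 1, 0) &
    shift(0, -1, 0) & shift(0, 0, 1) & shift(0, 0, -1)
  m & !nb_all_fg
}

# directed nearest-neighbour distances (mm) from points A to set B; chunked
directed_nn_dist <- function(A, B, chunk = 1024L) {
  nb <- nrow(B)
  b2 <- rowSums(B^2)
  out <- numeric(nrow(A))
  for (start in seq(1, nrow(A), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(A))
    Ac <- A[idx, , drop = FALSE]
    D2 <- matrix(rowSums(Ac^2), length(idx), nb) +
      matrix(b2, length(idx), nb, byrow = TRUE) - 2 * tcrossprod(Ac, B)
    mn <- D2[, 1]
    if (nb > 1) for (j in 2:nb) mn <- pmin(mn, D2[, j])
    out[idx] <- sqrt(pmax(mn, 0))
  }
  out
}

# Conservative interpolated upper percentile: h = min(n, p*n + 1), linear
# interpolation between order statistics. Equals the maximum for n <= 1/(1-p)
# points and is never above it, so hd95 <= exact Hausdorff always holds.
upper_percentile <- function(x, p = 0.95) {
  n <- length(x)
  s <- sort(x)
  h <- min(n, p * n + 1)
  lo <- floor(h)
  if (lo >= n) return(s[n])
  s[lo] + (h - lo) * (s[lo + 1] - s[lo])
}

#' 95th-percentile Hausdorff distance between mask boundaries
#'
#' Extracts boundary voxels (foreground with a face-connected background
#' neighbour), computes both directed nearest-boundary distance sets in mm
#' (honouring anisotropic voxel spacing), takes the 95th percentile of each
#' directed set and returns the maximum of the two - a robust variant of the
#' maximum Hausdorff distance that ignores a small fraction of outlier
#' boundary points. Symmetric in its mask arguments by construction.
#'
#' @param mask_a,mask_b binary arrays of identical shape.
#' @param voxel_size voxel spacings in mm.
#' @return Distance in mm, or `NA` (attribute `"undefined"`) when either mask
#'   is empty - a segmentation QC failure.
#' @export
hd95 <- function(mask_a, mask_b, voxel_size = c(1, 1, 1)) {
  if (!identical(dim(mask_a), dim(mask_b)))
    stop_param("mask shape mismatch")
  if (sum(mask_a) == 0 || sum(mask_b) == 0) {
    out <- NA_real_
    attr(out, "undefined") <- "empty mask"
    return(out)
  }
  ba <- which(boundary_voxels(mask_a), arr.ind = TRUE)
  bb <- which(boundary_voxels(mask_b), arr.ind = TRUE)
  A <- sweep(ba - 1, 2, voxel_size, "*")
  B <- sweep(bb - 1, 2, voxel_size, "*")
  dab <- directed_nn_dist(A, B)
  dba <- directed_nn_dist(B, A)
  max(upper_percentile(dab), upper_percentile(dba))
}

#' Bland--Altman agreement analysis with approximate confidence intervals
#'
#' Paired-difference method agreement: mean difference (bias), +-1.96 SD
#' limits of agreement, and approximate confidence intervals using the
#' t-based closed forms - CI of the bias `d +- t * SD/sqrt(n)`, CI of each
#' limit `LoA +- t * sqrt(3 SD^2 / n)` with `t = t(0.975, n-1)`.
#'
#' @param values_a,values_b paired numeric vectors (method A, method B),
#'   length `n >= 3`.
#' @return Object of class `bland_altman` with the bias, limits, their CIs
#'   and the per-pair means/differences.
#' @export
bland_altman <- function(values_a, values_b) {
  if (length(values_a) != length(values_b))
    stop_param("paired series must have equal length")
  n <- length(values_a)
  if (n < 3) stop_param("need at least 3 pairs")
  d <- values_a - values_b
  md <- mean(d)
  s <- sd(d)
  tq <- qt(0.975, n - 1)
  loa <- c(lower = md - 1.96 * s, upper = md + 1.96 * s)
  ci_mean <- c(md - tq * s / sqrt(n), md + tq * s / sqrt(n))
  hw_loa <- tq * sqrt(3 * s^2 / n)
  out <- list(n = n, mean_difference = md, sd_difference = s,
              loa = loa,
              ci_mean = ci_mean,
              ci_loa_lower = c(loa[["lower"]] - hw_loa, loa[["lower"]] + hw_loa),
              ci_loa_upper = c(loa[["upper"]] - hw_loa, loa[["upper"]] + hw_loa),
              means = (values_a + values_b) / 2, differences = d)
  class(out) <- "bland_altman"
  out
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman agreement (n = %d pairs)\n", x$n))
  cat(sprintf("  mean difference: %.4g  [%.4g, %.4g]\n", x$mean_difference,
              x$ci_mean[1], x$ci_mean[2]))
  cat(sprintf("  limits of agreement: [%.4g, %.4g]\n", x$loa[["lower"]],
              x$loa[["upper"]]))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ...) {
  plot(x$means, x$differences, pch = 16,
       xlab = "mean of methods", ylab = "difference",
       main = "Bland-Altman plot", ...)
  abline(h = x$mean_difference, col = "blue", lty = 2)
  abline(h = x$loa, col = "red", lty = 2)
  rng <- range(x$means)
  rect(rng[1], x$ci_mean[1], rng[2], x$ci_mean[2],
       col = grDevices::adjustcolor("blue", 0.15), border = NA)
  rect(rng[1], x$ci_loa_lower[1], rng[2], x$ci_loa_lower[2],
       col = grDevices::adjustcolor("red", 0.12), border = NA)
  rect(rng[1], x$ci_loa_upper[1], rng[2], x$ci_loa_upper[2],
       col = grDevices::adjustcolor("red", 0.12), border = NA)
  invisible(x)
}

#' Per-subject segmentation metrics table
#'
#' Convenience wrapper computing the per-volume metric row used in cohort
#' evaluation: overlap metrics plus HD95 and prediction time.
#'
#' @param pred a [predict_volume()] result.
#' @param truth_mask ground-truth binary array.
#' @param voxel_size voxel spacings in mm.
#' @return One-row data.frame.
#' @export
evaluate_prediction <- function(pred, truth_mask, voxel_size = pred$voxel_size) {
  cm <- confusion(pred$mask, truth_mask)
  om <- overlap_metrics(cm)
  data.frame(subject_id = pred$subject_id,
             iou = om$iou, precision = om$precision, recall = om$recall,
             dice = om$dice,
             hd95_mm = as.numeric(hd95(pred$mask, truth_mask, voxel_size)),
             prediction_time_ms = pred$ms_per_image,
             empty_prediction = pred$empty,
             stringsAsFactors = FALSE)
}
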