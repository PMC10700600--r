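#' Volume of a binary mask in mm^3
#'
#' Foreground voxel count times voxel volume; disconnected components (e.g.
#' the left and right halves of a bilateral structure) are summed into one
#' volume. An empty mask gives 0 with attribute `"empty"` set, a QC flag.
#'
#' @param mask binary array.
#' @param voxel_size voxel spacings in mm (all > 0).
#' @return Volume in mm^3.
#' @export
mask_volume <- function(mask, voxel_size) {
  if (any(voxel_size <= 0)) stop_param("voxel sizes must be positive")
  if (!is_binary_array(mask)) stop_param("mask must be binary")
  v <- sum(mask > 0) * prod(voxel_size)
  if (v == 0) attr(v, "empty") <- TRUE
  v
}

#' Normalization reference: mean control-group ICV
#'
#' @param mean_control_icv positive mm^3 value (the average intracranial
#'   volume of the control group).
#' @return Object of class `normalization_reference`.
#' @export
normalization_reference <- function(mean_control_icv) {
  if (!is.finite(mean_control_icv) || mean_control_icv <= 0)
    stop_param("mean control ICV must be positive")
  structure(list(mean_control_icv = mean_control_icv),
            class = "normalization_reference")
}

#' Head-size normalization of a structure volume
#'
#' Rescales an individual structure volume by the ratio of the control-group
#' mean intracranial volume to the subject's intracranial volume:
#' `v_norm = v_target / v_icv * mean_control_icv`. Identity when the
#' subject's ICV equals the reference mean; invariant under joint scaling of
#' both volumes.
#'
#' @param v_target structure volume, mm^3.
#' @param v_icv subject intracranial volume, mm^3 (> 0).
#' @param ref a [normalization_reference()] or a positive number.
#' @return Normalized volume in mm^3.
#' @export
#' @examples
#' normalize_volume(800, 1600000, 1532000)  # 766
normalize_volume <- function(v_target, v_icv, ref) {
  if (is.numeric(ref)) ref <- normalization_reference(ref)
  stopifnot(inherits(ref, "normalization_reference"))
  if (any(v_icv <= 0)) stop_param("v_icv must be positive")
  v_target / v_icv * ref$mean_control_icv
}

#' Interquartile-range outlier fences
#'
#' Tukey fences used as segmentation quality control: any value outside
#' `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` is an outlier. Quartiles by linear
#' interpolation of order statistics (type-7 convention).
#'
#' @param values numeric vector, `n >= 4`.
#' @return Object of class `outlier_fences` with `q1`, `q3`, `iqr`, `lower`,
#'   `upper`.
#' @export
#' @examples
#' f <- iqr_fences(c(1:9, 100))
#' f$upper  # 100 lies above this fence
iqr_fences <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 4) stop_param("need at least 4 values for IQR fences")
  q <- unname(quantile(values, c(0.25, 0.75), type = 7))
  iqr <- q[2] - q[1]
  structure(list(q1 = q[1], q3 = q[2], iqr = iqr,
                 lower = q[1] - 1.5 * iqr, upper = q[2] + 1.5 * iqr,
                 n = length(values)),
            class = "outlier_fences")
}

#' @export
print.outlier_fences <- function(x, ...) {
  cat(sprintf("IQR fences (n = %d): Q1 = %.4g, Q3 = %.4g, keep [%.4g, %.4g]\n",
              x$n, x$q1, x$q3, x$lower, x$upper))
  invisible(x)
}

outside_fences <- function(x, f) x < f$lower | x > f$upper

#' Quality control of a segmented cohort
#'
#' Applies the rejection cascade per group, with all fences frozen from this
#' first pass (pass the returned `fences` back in to re-apply them):
#' \enumerate{
#'   \item empty target or ICV segmentation -> `empty_segmentation`;
#'   \item ICV volume outside its group's IQR fences -> `icv_outlier`;
#'   \item target volume outside its group's fences -> `target_outlier`;
#'   \item normalized volume (computed with the mean accepted-control ICV as
#'     reference) outside its group's fences -> `normalized_outlier`.
#' }
#' Each subject receives the first triggered reason. Acceptance rates are
#' reported overall and per group.
#'
#' @param records data.frame with columns `subject_id`, `group`, `v_target`,
#'   `v_icv` (mm^3).
#' @param fences optional frozen fence set from a previous run.
#' @return The records with `v_norm`, `qc_status`, `qc_reason` filled;
#'   attributes `fences` (frozen fences + normalization reference) and
#'   `summary` (acceptance rates).
#' @export
qc_cohort <- function(records, fences = NULL) {
  need <- c("subject_id", "group", "v_target", "v_icv")
  if (!all(need %in% names(records)))
    stop_param("records need columns: %s", paste(need, collapse = ", "))
  if (any(is.na(records$v_target) | is.na(records$v_icv)))
    stop_param("missing volumes in records: run quantification first")
  n <- nrow(records)
  reason <- rep("none", n)
  groups <- unique(records$group)

  # stage 1: empty segmentations
  empty <- records$v_target <= 0 | records$v_icv <= 0
  reason[empty] <- "empty_segmentation"

  freeze <- is.null(fences)
  if (freeze) fences <- list(groups = list())
  get_fence <- function(grp, var, values) {
    if (freeze) {
      f <- iqr_fences(values)
      fences$groups[[grp]][[var]] <<- f
      f
    } else fences$groups[[grp]][[var]]
  }

  # stage 2: ICV outliers (per group, fences from stage-1 survivors)
  for (g in groups) {
    sel <- records$group == g & reason == "none"
    f <- get_fence(g, "icv", records$v_icv[records$group == g & !empty])
    out <- sel & outside_fences(records$v_icv, f)
    reason[out] <- "icv_outlier"
  }
  # stage 3: raw target-volume outliers
  for (g in groups) {
    sel <- records$group == g & reason == "none"
    f <- get_fence(g, "target", records$v_target[sel])
    out <- sel & outside_fences(records$v_target, f)
    reason[out] <- "target_outlier"
  }
  # normalization reference: mean ICV of accepted controls
  if (freeze) {
    ctl <- records$group == "control" & reason == "none"
    if (!any(ctl)) stop_param("no accepted control subjects to define the ICV reference")
    fences$reference <- normalization_reference(mean(records$v_icv[ctl]))
  }
  v_norm <- rep(NA_real_, n)
  ok <- reason == "none"
  v_norm[ok] <- normalize_volume(records$v_target[ok], records$v_icv[ok],
                                 fences$reference)
  # stage 4: normalized-volume outliers
  for (g in groups) {
    sel <- records$group == g & reason == "none"
    f <- get_fence(g, "norm", v_norm[records$group == g & reason == "none"])
    out <- sel & !is.na(v_norm) & outside_fences(v_norm, f)
    reason[out] <- "normalized_outlier"
  }

  records$v_norm <- v_norm
  records$qc_status <- ifelse(reason == "none", "accepted", "rejected")
  records$qc_reason <- reason
  acc <- function(sel) mean(records$qc_status[sel] == "accepted")
  summary <- list(
    n = n,
    acceptance_rate = acc(rep(TRUE, n)),
    rejection_rate = 1 - acc(rep(TRUE, n)),
    acceptance_by_group = vapply(groups, function(g) acc(records$group == g),
                                 numeric(1)),
    n_rejected = sum(records$qc_status == "rejected"),
    reasons = table(reason[reason != "none"]))
  attr(records, "fences") <- fences
  attr(records, "summary") <- summary
  class(records) <- c("qc_records", "data.frame")
  records
}

#' Acceptance/rejection accounting summary
#' @param records a [qc_cohort()] result.
#' @return The QC summary list (rates, counts, reasons, fences).
#' @export
qc_summary <- function(records) {
  s <- attr(records, "summary")
  if (is.null(s)) stop_param("records have not been through qc_cohort()")
  s
}

#' Pooled rejection rate from per-group rejection counts
#'
#' @param n_rejected integer vector of rejected subjects per group.
#' @param n_total integer vector of group sizes.
#' @return Pooled rejection rate (fraction in `[0, 1]`).
#' @export
#' @examples
#' rejection_rate(c(21, 5), c(432, 112))  # pooled, < 0.05
rejection_rate <- function(n_rejected, n_total) {
  stopifnot(length(n_rejected) == length(n_total), all(n_total > 0),
            all(n_rejected >= 0), all(n_rejected <= n_total))
  sum(n_rejected) / sum(n_total)
}
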