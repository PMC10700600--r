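#' Normality-gated paired comparison
#'
#' Applies a Shapiro--Wilk test to the paired differences; when its p-value is
#' at least `alpha`, a paired t-test is used, otherwise a Wilcoxon
#' signed-rank test. The chosen branch is recorded. Zero-variance differences
#' yield a degenerate-case report without a fabricated p-value.
#'
#' @param values_a,values_b paired numeric vectors, `n >= 3`.
#' @param alpha normality-gate significance level (default 0.05).
#' @return Object of class `hypo_test` with `test_name`, `statistic`,
#'   `p_value`, `n` and `normality_p`.
#' @export
gated_paired_test <- function(values_a, values_b, alpha = 0.05) {
  if (length(values_a) != length(values_b))
    stop_param("paired series must have equal length")
  n <- length(values_a)
  if (n < 3) stop_param("need at least 3 pairs")
  d <- values_a - values_b
  if (sd(d) == 0) {
    return(structure(list(test_name = "degenerate", statistic = NA_real_,
                          p_value = NA_real_, n = n, normality_p = NA_real_,
                          note = "zero-variance differences"),
                     class = "hypo_test"))
  }
  swp <- shapiro.test(d)$p.value
  if (swp >= alpha) {
    tt <- t.test(values_a, values_b, paired = TRUE)
    out <- list(test_name = "paired_t", statistic = unname(tt$statistic),
                p_value = tt$p.value, n = n, normality_p = swp)
  } else {
    wt <- suppressWarnings(wilcox.test(values_a, values_b, paired = TRUE))
    out <- list(test_name = "wilcoxon_signed_rank",
                statistic = unname(wt$statistic),
                p_value = wt$p.value, n = n, normality_p = swp)
  }
  structure(out, class = "hypo_test")
}

#' Unpaired two-group comparison
#'
#' Two-sided pooled-variance (Student) t-test of the group means, the test
#' used for the case-vs-control comparison of normalized volumes.
#'
#' @param group_a,group_b numeric vectors with `n >= 2` each.
#' @return Object of class `hypo_test` with `test_name = "unpaired_t"`.
#' @export
unpaired_test <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop_param("both groups need at least 2 observations")
  if (sd(c(group_a - mean(group_a), group_b - mean(group_b))) == 0) {
    return(structure(list(test_name = "degenerate", statistic = NA_real_,
                          p_value = NA_real_, n1 = length(group_a),
                          n2 = length(group_b),
                          note = "zero within-group variance"),
                     class = "hypo_test"))
  }
  tt <- t.test(group_a, group_b, var.equal = TRUE)
  structure(list(test_name = "unpaired_t", statistic = unname(tt$statistic),
                 p_value = tt$p.value, n1 = length(group_a),
                 n2 = length(group_b)),
            class = "hypo_test")
}

#' @export
print.hypo_test <- function(x, ...) {
  cat(sprintf("<%s>", x$test_name))
  if (!is.na(x$p_value %||% NA))
    cat(sprintf(" statistic = %.4g, p = %.4g", x$statistic, x$p_value))
  if (!is.null(x$normality_p) && !is.na(x$normality_p))
    cat(sprintf(" (Shapiro-Wilk p = %.3g)", x$normality_p))
  if (!is.null(x$note)) cat(" -", x$note)
  cat("\n")
  invisible(x)
}

#' Percent difference of group means
#'
#' Relative reduction of the case mean with respect to the control mean:
#' `(mean_control - mean_case) / mean_control * 100`. Positive values mean
#' the case group is smaller (atrophy). Emitted both to one decimal and
#' rounded to the nearest integer. The denominator is by convention the
#' control mean, so the measure is not antisymmetric under exchanging the
#' groups.
#'
#' @param mean_control control-group mean (> 0).
#' @param mean_case case-group mean.
#' @return List with `percent` (one decimal) and `percent_integer`.
#' @export
#' @examples
#' percent_difference(863, 775)  # 10.2 -> 10
percent_difference <- function(mean_control, mean_case) {
  if (!is.finite(mean_control) || mean_control <= 0)
    stop_param("control mean must be positive")
  p <- (mean_control - mean_case) / mean_control * 100
  list(percent = round(p, 1), percent_integer = as.integer(round(p)))
}

#' Per-group summaries of accepted records
#'
#' Mean, sample SD (n-1 denominator), median and count per group, computed on
#' QC-accepted records only. A single-observation group reports an undefined
#' (NA) SD rather than 0.
#'
#' @param records a data.frame with `group`, a value column and optionally
#'   `qc_status` (only `"accepted"` rows are used when present).
#' @param value name of the value column (default `"v_norm"`).
#' @return data.frame with columns `group`, `n`, `mean`, `sd`, `median`.
#' @export
group_summary <- function(records, value = "v_norm") {
  if (!value %in% names(records)) stop_param("no column '%s'", value)
  if ("qc_status" %in% names(records))
    records <- records[records$qc_status == "accepted", , drop = FALSE]
  groups <- unique(records$group)
  if (length(groups) == 0) stop_param("no accepted records")
  rows <- lapply(groups, function(g) {
    x <- records[[value]][records$group == g]
    x <- x[is.finite(x)]
    if (length(x) == 0) stop_param("group '%s' has no accepted values", g)
    data.frame(group = g, n = length(x), mean = mean(x),
               sd = if (length(x) > 1) sd(x) else NA_real_,
               median = median(x), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
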