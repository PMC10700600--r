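test_that("mask volume is count times voxel volume", {
  m <- array(0L, c(4, 4, 4)); m[2, 2, 2] <- 1L
  expect_equal(as.numeric(mask_volume(m, c(0.125, 0.125, 0.5))), 0.0078125)
  empty <- array(0L, c(4, 4, 4))
  v <- mask_volume(empty, c(1, 1, 1))
  expect_equal(as.numeric(v), 0)
  expect_true(isTRUE(attr(v, "empty")))
  expect_error(mask_volume(array(0.5, c(2, 2, 2)), c(1, 1, 1)), "binary")
  # bilateral components are summed into one volume
  bi <- array(0L, c(6, 6, 2)); bi[2, 2:3, 1] <- 1L; bi[5, 2:3, 1] <- 1L
  expect_equal(as.numeric(mask_volume(bi, c(1, 1, 1))), 4)
})

test_that("mask volume equals a loop-count oracle on random masks", {
  set.seed(21)
  m <- array(rbinom(16^3, 1, 0.2), c(16, 16, 16))
  cnt <- 0L
  for (i in 1:16) for (j in 1:16) for (k in 1:16)
    if (m[i, j, k] == 1) cnt <- cnt + 1L
  expect_equal(as.numeric(mask_volume(m, c(0.5, 0.5, 1))), cnt * 0.25)
})

test_that("normalization identity, worked example and scale invariance", {
  expect_equal(normalize_volume(812, 1500, 1500), 812)
  # printed-scale example: 800 mm^3, ICV 1.6e6 mm^3, reference 1.532e6 mm^3
  expect_equal(normalize_volume(800, 1.6e6, 1.532e6), 766)
  v1 <- normalize_volume(820, 3500, 3600)
  v2 <- normalize_volume(2 * 820, 2 * 3500, 3600)
  expect_equal(v1, v2)
  expect_error(normalize_volume(800, 0, 1500), "positive")
})

test_that("iqr fences follow the type-7 quartile arithmetic", {
  x <- c(1:9, 100)
  f <- iqr_fences(x)
  q <- unname(quantile(x, c(0.25, 0.75), type = 7))
  expect_equal(f$q1, q[1]); expect_equal(f$q3, q[2])
  expect_equal(f$lower, q[1] - 1.5 * (q[2] - q[1]))
  expect_equal(f$upper, q[2] + 1.5 * (q[2] - q[1]))
  expect_true(100 > f$upper)       # the outlier lies above the fence
  expect_true(all(1:9 <= f$upper & 1:9 >= f$lower))
  cst <- iqr_fences(rep(5, 6))
  expect_equal(cst$iqr, 0)
  expect_equal(cst$lower, cst$upper)
  # symmetric data give fences symmetric about the median
  s <- c(-3, -2, -1, 0, 1, 2, 3)
  fs <- iqr_fences(s)
  expect_equal(fs$lower, -fs$upper)
  expect_error(iqr_fences(1:3), "at least 4")
})

# uniform draws put no mass beyond the Tukey fences, so these cohorts are
# clean by construction and every rejection is an injected one
make_records <- function(n_per = 30, seed = 1) {
  set.seed(seed)
  data.frame(
    subject_id = sprintf("s%03d", 1:(2 * n_per)),
    group = rep(c("control", "case"), each = n_per),
    v_target = c(runif(n_per, 220, 260), runif(n_per, 196, 236)),
    v_icv = rep(3600, 2 * n_per))
}

test_that("clean cohorts are fully accepted", {
  rec <- qc_cohort(make_records(seed = 3))
  expect_true(all(rec$qc_status == "accepted"))
  expect_equal(qc_summary(rec)$acceptance_rate, 1)
})

test_that("empty segmentations get the dedicated rejection reason", {
  r <- make_records(seed = 4)
  r$v_target[5] <- 0
  rec <- qc_cohort(r)
  expect_equal(rec$qc_reason[5], "empty_segmentation")
  expect_equal(rec$qc_status[5], "rejected")
})

test_that("gross ICV and target under-segmentations are rejected below 5%", {
  # cohort of 544 with 26 injected aberrant records, mirroring the pooled
  # rejection accounting 26/544 = 4.78%
  set.seed(6)
  rec <- data.frame(
    subject_id = sprintf("s%03d", 1:544),
    group = rep(c("case", "control"), c(432, 112)),
    v_target = c(runif(432, 700, 860), runif(112, 760, 920)),
    v_icv = rep(c(1481000, 1532000), c(432, 112)))
  bad_icv <- c(1:3, 433:434)          # gross ICV under-segmentation (3 + 2)
  bad_tgt <- c(4:21, 435:437)         # gross target under-segmentation (18 + 3)
  rec$v_icv[bad_icv] <- rec$v_icv[bad_icv] * 0.5
  rec$v_target[bad_tgt] <- rec$v_target[bad_tgt] * 0.55
  out <- qc_cohort(rec)
  s <- qc_summary(out)
  expect_equal(s$n_rejected, 26)
  expect_lt(s$rejection_rate, 0.05)
  expect_equal(s$rejection_rate, 26 / 544)
  expect_true(all(out$qc_reason[bad_icv] == "icv_outlier"))
  expect_true(all(out$qc_reason[bad_tgt] == "target_outlier"))
})

test_that("QC is idempotent when fences are frozen from the first pass", {
  r <- make_records(seed = 7)
  r$v_target[c(3, 40)] <- c(120, 340)   # two injected outliers
  first <- qc_cohort(r)
  expect_gt(qc_summary(first)$n_rejected, 0)
  acc <- first[first$qc_status == "accepted",
               c("subject_id", "group", "v_target", "v_icv")]
  second <- qc_cohort(acc, fences = attr(first, "fences"))
  expect_equal(qc_summary(second)$n_rejected, 0)
})

test_that("acceptance accounting is consistent between pooled and per group", {
  r <- make_records(seed = 8)
  r$v_target[c(2, 35)] <- c(100, 400)
  rec <- qc_cohort(r)
  s <- qc_summary(rec)
  n_g <- table(rec$group)
  pooled <- sum(s$acceptance_by_group[names(n_g)] * as.numeric(n_g)) / sum(n_g)
  expect_equal(pooled, s$acceptance_rate)
  expect_equal(s$acceptance_rate, 1 - s$n_rejected / s$n)
})

test_that("pooled rejection-rate helper handles grouped counts", {
  expect_equal(rejection_rate(c(21, 5), c(432, 112)), 26 / 544)
  expect_lt(rejection_rate(c(21, 5), c(432, 112)), 0.05)
})
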