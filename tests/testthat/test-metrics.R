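test_that("confusion counts match trivial cases", {
  m <- array(c(1, 0, 1, 0, 1, 0, 1, 0), c(2, 2, 2))
  cm <- confusion(m, m)
  expect_equal(cm$fp, 0); expect_equal(cm$fn, 0)
  expect_equal(cm$tp, sum(m))
  disj <- array(c(0, 1, 0, 1, 0, 1, 0, 1), c(2, 2, 2))
  expect_equal(confusion(m, disj)$tp, 0)
  expect_error(confusion(m, array(0, c(2, 2, 3))), "mismatch")
})

test_that("confusion counts match a brute-force loop oracle on random masks", {
  set.seed(11)
  for (i in 1:10) {
    a <- array(rbinom(8^3, 1, 0.3), c(8, 8, 8))
    b <- array(rbinom(8^3, 1, 0.3), c(8, 8, 8))
    cm <- confusion(a, b)
    or <- oracle_confusion(a, b)
    expect_equal(cm$tp, or$tp); expect_equal(cm$fp, or$fp)
    expect_equal(cm$tn, or$tn); expect_equal(cm$fn, or$fn)
    expect_equal(cm$tp + cm$fp + cm$tn + cm$fn, length(a))
  }
})

test_that("overlap metrics reproduce closed forms and the dice-iou identity", {
  om <- overlap_metrics(list(tp = 1, fp = 1, tn = 0, fn = 1))
  expect_equal(om$iou, 1 / 3)
  expect_equal(om$dice, 1 / 2)
  expect_equal(om$precision, 1 / 2)
  expect_equal(om$recall, 1 / 2)
  perfect <- overlap_metrics(list(tp = 10, fp = 0, tn = 5, fn = 0))
  expect_true(all(unlist(perfect[c("iou", "precision", "recall", "dice")]) == 1))
  set.seed(12)
  for (i in 1:50) {
    cm <- list(tp = rpois(1, 20), fp = rpois(1, 5), tn = 50, fn = rpois(1, 5))
    if (cm$tp + cm$fp + cm$fn == 0) next
    om <- overlap_metrics(cm)
    expect_equal(om$dice, 2 * om$iou / (1 + om$iou), tolerance = 1e-12)
  }
})

test_that("undefined denominators are flagged, not coerced to zero", {
  om <- overlap_metrics(list(tp = 0, fp = 0, tn = 10, fn = 0))
  expect_true(is.na(om$iou))
  expect_true("precision" %in% attr(om, "undefined"))
})

test_that("hd95 handles trivial geometry exactly", {
  m <- array(0L, c(8, 8, 8)); m[3:5, 3:5, 3:5] <- 1L
  expect_equal(hd95(m, m, c(1, 1, 1)), 0)
  # two single-voxel masks 3 voxels apart along a 0.5 mm axis -> 1.5 mm
  a <- array(0L, c(8, 8, 8)); b <- array(0L, c(8, 8, 8))
  a[2, 2, 2] <- 1L; b[2, 2, 5] <- 1L
  expect_equal(hd95(a, b, c(1, 1, 0.5)), 1.5)
  # empty mask is undefined
  expect_true(is.na(hd95(a, array(0L, c(8, 8, 8)))))
})

test_that("hd95 matches the all-pairs oracle and is symmetric", {
  set.seed(13)
  for (i in 1:6) {
    a <- random_blob(c(10, 10, 10))
    b <- random_blob(c(10, 10, 10))
    vs <- c(0.7, 1, 1.3)
    h1 <- hd95(a, b, vs)
    h2 <- hd95(b, a, vs)
    expect_equal(h1, h2)
    expect_equal(h1, oracle_hd95(a, b, vs), tolerance = 1e-12)
    expect_lte(h1, oracle_hd_exact(a, b, vs) + 1e-12)
  }
})

test_that("hd95 equals the exact Hausdorff distance for tiny boundaries", {
  # boundary sets of <= 20 points: the 95th percentile is the maximum
  a <- array(0L, c(6, 6, 4)); a[3:4, 3:4, 2] <- 1L   # 4 boundary points? all fg are boundary
  b <- array(0L, c(6, 6, 4)); b[2:3, 4:5, 3] <- 1L
  vs <- c(1, 0.8, 1.2)
  expect_equal(hd95(a, b, vs), oracle_hd_exact(a, b, vs), tolerance = 1e-12)
})

test_that("bland-altman reproduces trivial and closed-form cases", {
  x <- c(1, 2, 3, 4, 5)
  ba <- bland_altman(x, x)
  expect_equal(ba$mean_difference, 0)
  expect_equal(unname(ba$loa), c(0, 0))
  ba2 <- bland_altman(x + 2, x)
  expect_equal(ba2$mean_difference, 2)
  expect_equal(ba2$sd_difference, 0)
  set.seed(14)
  a <- rnorm(20); b <- rnorm(20)
  ba3 <- bland_altman(a, b)
  d <- a - b; n <- 20; s <- sd(d); tq <- qt(0.975, n - 1)
  expect_equal(ba3$mean_difference, mean(d))
  expect_equal(unname(ba3$loa),
               c(mean(d) - 1.96 * s, mean(d) + 1.96 * s))
  expect_equal(diff(ba3$ci_mean) / 2, tq * s / sqrt(n), tolerance = 1e-12)
  expect_equal(diff(ba3$ci_loa_lower) / 2, tq * sqrt(3 * s^2 / n),
               tolerance = 1e-12)
  expect_lte(ba3$loa[["lower"]], ba3$mean_difference)
  expect_gte(ba3$loa[["upper"]], ba3$mean_difference)
})

test_that("bland-altman requires at least 3 pairs", {
  expect_error(bland_altman(1:2, 2:3), "3")
})
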