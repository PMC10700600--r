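test_that("normality gate picks the paired t-test for normal differences", {
  hits <- 0L
  for (s in 1:30) {
    set.seed(s)
    a <- rnorm(50, 10, 1); b <- a - rnorm(50, 0.2, 0.5)
    r <- gated_paired_test(a, b)
    if (r$test_name == "paired_t") hits <- hits + 1L
  }
  expect_gte(hits / 30, 0.9)
})

test_that("normality gate routes skewed differences to the signed-rank test", {
  hits <- 0L
  for (s in 1:30) {
    set.seed(s + 100)
    b <- rnorm(50, 10, 0.1)
    a <- b + rexp(50, 1)     # heavily right-skewed differences
    r <- gated_paired_test(a, b)
    if (r$test_name == "wilcoxon_signed_rank") hits <- hits + 1L
  }
  expect_gte(hits / 30, 0.9)
})

test_that("identical paired series give a degenerate report, not a p-value", {
  x <- c(1, 2, 3, 4)
  r <- gated_paired_test(x, x)
  expect_equal(r$test_name, "degenerate")
  expect_true(is.na(r$p_value))
})

test_that("gate decision is a deterministic function of the differences", {
  set.seed(5)
  a <- rnorm(20); b <- rnorm(20)
  r1 <- gated_paired_test(a, b)
  r2 <- gated_paired_test(a, b)
  expect_identical(r1$test_name, r2$test_name)
  expect_equal(r1$normality_p, shapiro.test(a - b)$p.value)
})

test_that("unpaired test: identical groups, sign flip, pooled variance", {
  g <- c(10, 11, 12, 13)
  r <- unpaired_test(g, g)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  set.seed(6)
  a <- rnorm(15, 10); b <- rnorm(12, 9)
  r1 <- unpaired_test(a, b); r2 <- unpaired_test(b, a)
  expect_equal(r1$statistic, -r2$statistic)
  expect_equal(r1$p_value, r2$p_value)
  # matches stats::t.test with var.equal = TRUE
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(r1$statistic, unname(tt$statistic))
  expect_equal(r1$p_value, tt$p.value)
  expect_error(unpaired_test(1, c(2, 3)), "at least 2")
})

test_that("a 10% atrophy effect is detected in phantom cohorts (power)", {
  detected <- 0L
  for (s in 1:5) {
    co <- cohort_spec(n_control = 30, n_case = 30, effect_fraction = 0.10,
                      between_subject_cv = 0.08, seed = s)
    vols <- generate_cohort(co)
    grp <- vapply(vols, function(v) v$group, character(1))
    tv <- vapply(vols, function(v) v$true_target_volume, numeric(1))
    icv <- vapply(vols, function(v) v$true_icv_volume, numeric(1))
    vn <- normalize_volume(tv, icv, mean(icv[grp == "control"]))
    r <- unpaired_test(vn[grp == "control"], vn[grp == "case"])
    if (r$p_value < 0.05) detected <- detected + 1L
  }
  expect_gte(detected / 5, 0.8)
})

test_that("power grows with group size on phantom cohorts", {
  pvals <- sapply(c(10, 30, 100), function(n) {
    co <- cohort_spec(n_control = n, n_case = n, effect_fraction = 0.10,
                      between_subject_cv = 0.08, seed = 17)
    vols <- generate_cohort(co)
    grp <- vapply(vols, function(v) v$group, character(1))
    tv <- vapply(vols, function(v) v$true_target_volume, numeric(1))
    icv <- vapply(vols, function(v) v$true_icv_volume, numeric(1))
    vn <- normalize_volume(tv, icv, mean(icv[grp == "control"]))
    unpaired_test(vn[grp == "control"], vn[grp == "case"])$p_value
  })
  expect_true(all(diff(pvals) < 0))
})

test_that("percent difference reproduces the printed group-mean arithmetic", {
  pd <- percent_difference(863, 775)
  expect_equal(pd$percent, 10.2)
  expect_equal(pd$percent_integer, 10L)
  pd2 <- percent_difference(852, 823)
  expect_equal(pd2$percent, 3.4)
  expect_equal(pd2$percent_integer, 3L)
  expect_equal(percent_difference(500, 500)$percent, 0)
  expect_error(percent_difference(0, 10), "positive")
})

test_that("group summaries use accepted records and the sample SD", {
  rec <- data.frame(group = c("a", "a", "b"),
                    v_norm = c(800, 820, 700),
                    qc_status = c("accepted", "accepted", "accepted"))
  gs <- group_summary(rec)
  a <- gs[gs$group == "a", ]
  expect_equal(a$mean, 810)
  expect_equal(a$sd, sd(c(800, 820)), tolerance = 1e-12)
  expect_equal(round(a$sd, 2), 14.14)
  b <- gs[gs$group == "b", ]
  expect_true(is.na(b$sd))      # single value: SD undefined, not zero
  # rejected records are excluded
  rec2 <- rbind(rec, data.frame(group = "a", v_norm = 5000,
                                qc_status = "rejected"))
  expect_equal(group_summary(rec2)[1, "mean"], 810)
})

test_that("summaries match a spreadsheet-style recomputation", {
  set.seed(9)
  rec <- data.frame(group = rep(c("control", "case"), each = 5),
                    v_norm = c(855, 870, 910, 820, 840, 760, 790, 805, 772, 768),
                    qc_status = "accepted")
  gs <- group_summary(rec)
  ctrl <- c(855, 870, 910, 820, 840)
  expect_equal(gs$mean[gs$group == "control"], sum(ctrl) / 5)
  expect_equal(gs$sd[gs$group == "control"],
               sqrt(sum((ctrl - mean(ctrl))^2) / 4))
  expect_equal(gs$median[gs$group == "case"], 772)
})
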