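test_that("two_sample_ttest matches the closed-form pooled oracle", {
  r <- two_sample_ttest(c(1, 2, 3), c(4, 5, 6))
  # hand: means 2, 5; pooled var = 1; se = sqrt(2/3); t = -3/se; df = 4
  expect_equal(r$df, 4)
  expect_equal(r$t, -3 / sqrt(2 / 3), tolerance = 1e-12)
  ref <- stats::t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(r$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r$p, ref$p.value, tolerance = 1e-12)
  same <- two_sample_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(two_sample_ttest(1, c(1, 2)), "at least 2")
})

test_that("raw-data and summary-statistic t-tests agree exactly", {
  set.seed(14)
  for (i in 1:10) {
    a <- rnorm(sample(5:40, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(5:40, 1), mean = runif(1, -1, 1))
    r1 <- two_sample_ttest(a, b)
    r2 <- ttest_from_summary(mean(a), sd(a), length(a),
                             mean(b), sd(b), length(b))
    expect_equal(r1$t, r2$t, tolerance = 1e-12)
    expect_equal(r1$p, r2$p, tolerance = 1e-12)
  }
  expect_equal(ttest_from_summary(5, 0, 10, 5, 0, 10)$p, 1)
})

test_that("Welch variant matches stats::t.test", {
  set.seed(15)
  a <- rnorm(20, sd = 3); b <- rnorm(35)
  r <- two_sample_ttest(a, b, var_equal = FALSE)
  ref <- stats::t.test(a, b)
  expect_equal(r$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r$df, unname(ref$parameter), tolerance = 1e-12)
  expect_equal(r$p, ref$p.value, tolerance = 1e-12)
})

test_that("chi_square_2x2 is uncorrected Pearson", {
  expect_equal(chi_square_2x2(10, 10, 10, 10)$chi2, 0)
  expect_equal(chi_square_2x2(10, 10, 10, 10)$p, 1)
  set.seed(16)
  for (i in 1:10) {
    cells <- sample(1:50, 4, replace = TRUE)
    r <- do.call(chi_square_2x2, as.list(cells))
    ref <- suppressWarnings(
      stats::chisq.test(matrix(cells, 2, byrow = TRUE), correct = FALSE))
    expect_equal(r$chi2, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(r$p, ref$p.value, tolerance = 1e-10)
  }
  expect_error(chi_square_2x2(0, 0, 3, 4), "margins")
  expect_error(chi_square_2x2(1.5, 2, 3, 4), "integers")
})

test_that("fdr_bh reproduces the hand-stepped procedure", {
  expect_equal(fdr_bh(0.03)$p_adjusted, 0.03)
  all_same <- fdr_bh(rep(0.004, 6), q = 0.01)
  expect_true(all(all_same$significant))
  expect_equal(all_same$p_adjusted, rep(0.004, 6))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205)
  # hand step-up: n/i * p_(i), then running min from the largest rank
  hand <- c(0.008, 0.032, 0.0672, 0.0672, 0.0672, 0.08,
            8 / 7 * 0.074, 0.205)
  r <- fdr_bh(p, q = 0.05)
  expect_equal(r$p_adjusted, hand, tolerance = 1e-12)
  expect_equal(r$p_adjusted, stats::p.adjust(p, "BH"), tolerance = 1e-12)
  # monotone in raw-p rank order and adjusted >= raw
  shuffled <- sample(p)
  ra <- fdr_bh(shuffled)$p_adjusted
  expect_true(all(diff(ra[order(shuffled)]) >= -1e-15))
  expect_true(all(ra >= shuffled))
  expect_error(fdr_bh(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("roi_group_analysis finds nothing on identical groups and
           excludes incomplete regions", {
  prof <- expand.grid(subject_id = sprintf("s%02d", 1:20), roi_id = 1:5,
                      stringsAsFactors = FALSE)
  prof$mean_aape <- rep(seq(2, 3, length.out = 5), each = 20)
  groups <- setNames(rep(c("NA", "SCD"), each = 10), sprintf("s%02d", 1:20))
  # identical groups: t = 0, p = 1 everywhere, nothing significant
  res0 <- roi_group_analysis(prof, groups)
  expect_true(all(res0$t == 0) && all(res0$p == 1))
  expect_false(any(res0$significant))
  set.seed(17)
  prof2 <- prof
  prof2$mean_aape <- prof2$mean_aape + rnorm(100, sd = 1e-3)
  res <- roi_group_analysis(prof2, groups)
  expect_equal(nrow(res), 5)
  expect_true(all(res$p_adjusted >= res$p))
  prof3 <- prof2
  prof3$mean_aape[prof3$roi_id == 2 & prof3$subject_id == "s01"] <- NA
  expect_message(res3 <- roi_group_analysis(prof3, groups), "excluded")
  expect_equal(attr(res3, "excluded_rois"), 2)
  expect_equal(nrow(res3), 4)
})

test_that("per-region test is calibrated and power rises with effect", {
  set.seed(18)
  # type-I: null rejection rate at alpha = 0.05 within 2 binomial SE
  B <- 1500
  rej <- mean(replicate(B, two_sample_ttest(rnorm(43), rnorm(43))$p < 0.05))
  expect_lt(abs(rej - 0.05), 2 * sqrt(0.05 * 0.95 / B))
  # power monotone in d
  pow <- sapply(c(0.3, 0.8, 1.5), function(d)
    mean(replicate(200, two_sample_ttest(rnorm(43, d), rnorm(43))$p < 0.01)))
  expect_true(all(diff(pow) > 0))
})

test_that("demographics_table mirrors the published layout", {
  set.seed(19)
  co <- test_cohort()$cohort
  tab <- demographics_table(co[, setdiff(names(co), "subject_id")])
  expect_true("sex" %in% tab$variable)
  expect_true(all(c("age", "education", "CDRSB", "MMSE") %in% tab$variable))
  age_p <- tab$p[tab$variable == "age"]
  a <- co$age[co$group == "NA"]; b <- co$age[co$group == "SCD"]
  expect_equal(age_p, two_sample_ttest(a, b)$p)
})
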