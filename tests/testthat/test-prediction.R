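test_that("residualize matches the normal-equation oracle and is
           orthogonal to the design", {
  set.seed(20)
  n <- 43
  X <- cbind(age = rnorm(n, 75, 5), sex = rbinom(n, 1, 0.4),
             fd = runif(n, 0.05, 0.3))
  y <- 0.2 * X[, 1] - 1.5 * X[, 2] + rnorm(n)
  r <- residualize(y, X)
  D <- cbind(1, X)
  beta <- solve(t(D) %*% D, t(D) %*% y)
  expect_equal(r, as.vector(y - D %*% beta), tolerance = 1e-10)
  expect_lt(max(abs(t(D) %*% r)), 1e-8)
  # exact linear dependence -> zero residuals
  y2 <- 3 + X %*% c(1, 2, 3)
  expect_equal(residualize(as.vector(y2), X), rep(0, n), tolerance = 1e-8)
  # constant columns are absorbed by the intercept
  expect_equal(residualize(y, cbind(const = rep(2, n))), y - mean(y),
               tolerance = 1e-12)
  expect_error(residualize(y, cbind(a = X[, 1], b = 2 * X[, 1])),
               "collinear")
})

test_that("fit_predict_cv recovers a noiseless linear map in both modes", {
  set.seed(22)
  x <- rnorm(43)
  y <- 2 * x + 1
  for (mode in c("refit", "out_of_fold")) {
    fit <- fit_predict_cv(x, y, seed = 5, prediction = mode)
    expect_equal(cor(fit$predicted, y), 1, tolerance = 1e-6)
    expect_lt(mean((fit$predicted - y)^2), 1e-3)
  }
})

test_that("fit_predict_cv is deterministic given a seed and respects
           fold structure", {
  set.seed(23)
  x <- rnorm(50); y <- x + rnorm(50)
  f1 <- fit_predict_cv(x, y, seed = 9, prediction = "out_of_fold")
  f2 <- fit_predict_cv(x, y, seed = 9, prediction = "out_of_fold")
  expect_identical(f1, f2)
  expect_equal(sort(unique(f1$fold)), 1:10)
  expect_true(all(table(f1$fold) == 5))
  # leakage guard: in out_of_fold mode, altering one subject's y changes
  # no prediction in OTHER folds (its own row is never in their training)
  y2 <- y; y2[7] <- y2[7] + 50
  f3 <- fit_predict_cv(x, y2, seed = 9, prediction = "out_of_fold")
  same_fold <- f1$fold == f1$fold[7]
  expect_equal(f3$predicted[same_fold], f1$predicted[same_fold],
               tolerance = 1e-9)  # own fold unaffected by own y
  expect_error(fit_predict_cv(rnorm(5), rnorm(5), folds = 10),
               "reduce the number of folds")
})

test_that("refit-mode null p-values are approximately uniform", {
  # the calibration property behind 'null pairs flagged <= alpha':
  # under independence the two-tailed p of the prediction correlation is
  # ~U(0,1). 200 permutations (scaled down from 500 for runtime).
  set.seed(24)
  x <- rnorm(43)
  ps <- replicate(200, {
    y <- rnorm(43)
    fit <- fit_predict_cv(x, y, seed = sample.int(1e6, 1))
    correlate_predictions(fit$predicted, y)$p
  })
  expect_lt(abs(mean(ps < 0.05) - 0.05), 2.5 * sqrt(0.05 * 0.95 / 200))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("refit mode recovers a generating correlation of ~0.5", {
  set.seed(25)
  rr <- replicate(60, {
    x <- rnorm(43)
    y <- 0.5 * scale(x)[, 1] + sqrt(1 - 0.25) * rnorm(43)
    fit <- fit_predict_cv(x, y, seed = sample.int(1e6, 1))
    correlate_predictions(fit$predicted, y)$r
  })
  expect_lt(abs(mean(rr) - 0.5), 0.1)
})

test_that("correlate_predictions matches the closed form", {
  expect_equal(correlate_predictions(1:10, 1:10)$r, 1)
  expect_equal(correlate_predictions(1:10, 10:1)$r, -1)
  r <- correlate_predictions(c(1, 2, 3, 4), c(1, 2, 4, 3))
  expect_equal(r$r, 0.8)                 # hand: 4 / sqrt(5 * 5)
  t_hand <- 0.8 * sqrt(2 / (1 - 0.64))
  expect_equal(r$p, 2 * pt(-t_hand, 2), tolerance = 1e-12)
  expect_equal(r$r, cor(c(1, 2, 3, 4), c(1, 2, 4, 3)), tolerance = 1e-12)
  expect_error(correlate_predictions(rep(1, 5), 1:5), "constant")
  expect_error(correlate_predictions(1:2, 1:2), "at least 3")
})

test_that("bonferroni_threshold", {
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 32), 0.0015625)
  thr <- vapply(c(1, 2, 8, 32, 100),
                function(k) bonferroni_threshold(0.05, k), numeric(1))
  expect_true(all(diff(thr) < 0))
  expect_error(bonferroni_threshold(0.05, 0), "n_tests")
  expect_error(bonferroni_threshold(1.2, 4), "alpha")
})

test_that("run_prediction_battery crosses regions x measures and flags
           the designed link", {
  co <- test_cohort()
  scd_ids <- co$cohort$subject_id[co$cohort$group == "SCD"]
  prof <- co$profiles[co$profiles$subject_id %in% scd_ids, ]
  tbl <- co$cohort[co$cohort$group == "SCD", ]
  rois <- c(3L, 7L, 12L, 18L, 1L, 5L, 10L, 15L)
  bat <- run_prediction_battery(prof, tbl, rois, seed = 2)
  expect_equal(nrow(bat), 32L)           # 8 regions x 4 measures
  expect_equal(attr(bat, "threshold"), 0.05 / 32)
  expect_true(all(abs(bat$r) <= 1))
  expect_identical(bat$significant, bat$p < 0.05 / 32)
  # the generator links region 3 to CDRSB at r = 0.6
  linked <- bat[bat$roi_id == 3 & bat$measure == "CDRSB", ]
  expect_gt(linked$r, 0.3)
  pm <- attr(bat, "predictions")
  expect_equal(dim(pm), c(43L, 32L))
  expect_error(run_prediction_battery(prof, tbl, integer(0)), "non-empty")
  expect_error(run_prediction_battery(prof, tbl[, -3], rois),
               "lacks column")
})
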