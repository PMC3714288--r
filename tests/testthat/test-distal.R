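# Distal-outcome stage: class means, Wald equality test, posterior
# regression, and the five-outcome suite.

test_that("class means reduce correctly under hard posteriors and constants", {
  set.seed(1)
  y <- rnorm(100)
  lab <- rep(1:2, each = 50)
  hard <- cbind(as.numeric(lab == 1), as.numeric(lab == 2))
  plain <- class_outcome_means(lab, y)
  weighted <- class_outcome_means(NULL, y, weights = hard)
  expect_equal(plain$mean, weighted$mean, tolerance = 1e-12)
  # constant outcome: equal means, zero Wald statistic
  yc <- rep(1.7, 100)
  cm <- class_outcome_means(lab, yc)
  wt <- wald_equality_test(cm)
  expect_equal(wt$chisq, 0)
  expect_equal(wt$p_value, 1)
  expect_error(class_outcome_means(c(rep(1L, 9), 2L), rnorm(10)),
               "per class")
})

test_that("the Wald statistic matches hand arithmetic and is invariant", {
  wt <- wald_equality_test(c(0.5, 0), c(0.1, 0.1))
  expect_equal(wt$chisq, 12.5)
  expect_equal(wt$p_value, 4.07e-4, tolerance = 1e-2)
  expect_identical(wt$df, 1L)
  # invariant to class order and constant shifts
  wt_rev <- wald_equality_test(c(0, 0.5), c(0.1, 0.1))
  wt_shift <- wald_equality_test(c(10.5, 10), c(0.1, 0.1))
  expect_equal(wt$chisq, wt_rev$chisq)
  expect_equal(wt$chisq, wt_shift$chisq)
  # degenerate zero-SE case is flagged, not silently finite
  inf <- wald_equality_test(c(1, 0), c(0, 0))
  expect_true(inf$infinite)
  expect_identical(inf$p_value, 0)
  expect_error(wald_equality_test(c(1, 2, 3), c(1, 1, 1)), "K = 2")
})

test_that("Wald test type-I error is nominal under the null", {
  set.seed(2)
  rej <- replicate(500, {
    y <- rnorm(200)
    lab <- rep(1:2, each = 100)
    wald_equality_test(class_outcome_means(lab, y))$p_value < 0.05
  })
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("posterior regression reduces to the group contrast and flags collinearity", {
  set.seed(3)
  y <- rnorm(80)
  lab <- rep(1:2, 40)
  p_high <- as.numeric(lab == 2)
  pr <- posterior_regression(y, p_high)
  cm <- class_outcome_means(lab, y)
  expect_equal(pr$coefficient, cm$mean[2] - cm$mean[1], tolerance = 1e-10)
  expect_error(posterior_regression(y, rep(0.4, 80)), "collinear")
  # slope recovery with a known negative effect
  set.seed(4)
  p2 <- runif(500)
  y2 <- -0.8 * p2 + rnorm(500, 0, 0.5)
  pr2 <- posterior_regression(y2, p2)
  expect_lt(pr2$coefficient, 0)
  expect_lt(abs(pr2$coefficient + 0.8), 2 * pr2$se)
})

test_that("the distal suite flags the class-shifted outcomes", {
  fits <- recovery_fits(25L)[seq_len(10)]
  flags <- sapply(fits, function(r) {
    ds <- run_distal_suite(r$cohort[, paste0("fs_", FACTORS)],
                           r$fit$posterior,
                           covariates = r$cohort[, c("age", "education")])
    ds$significant
  })
  rownames(flags) <- paste0("fs_", FACTORS)
  # the two genuinely shifted outcomes dominate the flags; the three null
  # factors stay near the nominal error rate
  expect_gt(mean(flags["fs_global", ]), 0.5)
  expect_lt(mean(flags["fs_verbal", ]), 0.3)
  expect_lt(mean(flags["fs_auditory", ]), 0.3)
  expect_lt(mean(flags["fs_visual", ]), 0.3)
  shifted <- colMeans(flags[c("fs_global", "fs_speeded"), , drop = FALSE])
  null_fac <- colMeans(flags[c("fs_verbal", "fs_auditory", "fs_visual"), ,
                             drop = FALSE])
  expect_gt(mean(shifted), mean(null_fac))
})

test_that("suite input checks catch misalignment and support single outcomes", {
  r <- recovery_fits(25L)[[1]]
  expect_error(run_distal_suite(r$cohort[1:10, paste0("fs_", FACTORS)],
                                r$fit$posterior), "misaligned")
  one <- run_distal_suite(r$cohort[, "fs_speeded", drop = FALSE],
                          r$fit$posterior)
  expect_identical(nrow(one), 1L)
  expect_true(all(c("wald_p", "regression_p", "bonferroni_p") %in%
                    names(one)))
})

test_that("posterior weighting gives results close to modal assignment here", {
  r <- recovery_fits(25L)[[2]]
  y <- r$cohort$fs_speeded
  modal <- class_outcome_means(r$fit$labels, y)
  wgt <- class_outcome_means(NULL, y, weights = r$fit$posterior)
  expect_equal(modal$mean, wgt$mean, tolerance = 0.08)
})
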