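# Synthetic cohort generator: calibration and structural invariants.

test_that("default parameters carry the published class structure", {
  p <- default_params()
  expect_equal(unname(p$class_prevalence), c(0.62, 0.38))
  expect_equal(p$class_indicator_means["high", "bmi"], 28.97)
  expect_equal(p$class_indicator_means["low", "hdl"], 74.13)
  expect_equal(p$class_indicator_sds["high", "triglycerides"], 60.24)
  # prevalence-weighted cognitive class means are near zero
  cen <- drop(p$class_prevalence %*% p$cognitive_class_means)
  expect_true(all(abs(cen) < 0.02))
  expect_equal(p$missing_rate, 0.22)
  expect_silent(validate_params(p))
})

test_that("intercept calibration hits closed-form cases and the MC marginal", {
  p <- default_params(calibrate = FALSE)
  p$within_class_corr <- diag(7)
  p0 <- p
  p0$concomitant_coefs[-1] <- 0
  p0 <- calibrate_intercept(p0)
  expect_equal(unname(p0$concomitant_coefs["intercept"]),
               log(0.38 / 0.62), tolerance = 1e-3)
  p5 <- p
  p5$class_prevalence <- c(low = 0.5, high = 0.5)
  p5$concomitant_coefs[-1] <- 0
  p5 <- calibrate_intercept(p5)
  expect_equal(unname(p5$concomitant_coefs["intercept"]), 0,
               tolerance = 1e-3)
  # with the published slopes, the simulated marginal matches the target
  pc <- default_params()
  cohort <- simulate_cohort(pc, n = 50000, seed = 123)
  expect_equal(mean(cohort$true_class == "high"), 0.38, tolerance = 0.01)
})

test_that("correlation calibration solves the mixture-moment identity", {
  p <- default_params()
  # frozen value verified against a 1e6-draw Monte-Carlo oracle
  expect_equal(p$within_class_corr["hdl", "triglycerides"], -0.221,
               tolerance = 0.005)
  expect_lt(p$corr_adjustment, 0.05)
  # identical class moments: no between-class part, rho_w = pooled target
  pe <- default_params(calibrate = FALSE)
  pe$class_indicator_means["high", ] <- pe$class_indicator_means["low", ]
  pe$class_indicator_sds["high", ] <- pe$class_indicator_sds["low", ]
  target <- diag(7)
  target[1, 2] <- target[2, 1] <- 0.3
  dimnames(target) <- dimnames(pe$within_class_corr)
  pe <- calibrate_correlations(pe, target)
  expect_equal(pe$within_class_corr[1, 2], 0.3, tolerance = 1e-10)
  # identity target with separated means: a pair with positive
  # between-class covariance (bmi, triglycerides) needs a compensating
  # negative within-class correlation
  pi_ <- default_params(calibrate = FALSE)
  pi_ <- calibrate_correlations(pi_, diag(7))
  expect_lt(pi_$within_class_corr[1, 5], 0)
})

test_that("infeasible pooled targets are reported with the offending pair", {
  p <- default_params(calibrate = FALSE)
  target <- diag(7)
  target[4, 5] <- target[5, 4] <- 0.95   # hdl-triglycerides, unreachable
  expect_error(calibrate_correlations(p, target), "hdl, triglycerides")
})

test_that("simulated cohorts reproduce the calibrated pooled moments", {
  p <- default_params()
  big <- simulate_cohort(p, n = 100000, seed = 11)
  expect_equal(cor(big$hdl, big$triglycerides), -0.486, tolerance = 0.015)
  expect_equal(mean(big$bmi), sum(p$class_prevalence *
                                    p$class_indicator_means[, "bmi"]),
               tolerance = 0.05)
  # full pooled correlation matrix close to the calibration target
  emp <- cor(as.matrix(big[, INDICATORS]))
  target <- cvlpa:::.pooled_corr_target()
  expect_lt(max(abs(emp - target)), 0.03)
})

test_that("cohorts are reproducible and respect basic value constraints", {
  p <- default_params()
  a <- simulate_cohort(p, seed = 5)
  b <- simulate_cohort(p, seed = 5)
  expect_identical(a, b)
  expect_true(all(a$hdl > 0 & a$triglycerides > 0 & a$bmi > 0))
  expect_true(all(is.finite(as.matrix(a[, INDICATORS]))))
  expect_true(all(a$age >= 42 & a$age <= 58))
  expect_error(simulate_cohort(p, n = 3), "degenerate")
})

test_that("the concomitant slopes are recovered by logistic regression at large n", {
  p <- default_params()
  big <- simulate_cohort(p, n = 100000, seed = 21)
  g <- stats::glm(I(true_class == "high") ~ age + education +
                    I(ethnicity == "non-Hispanic Black") +
                    I(ethnicity == "Hispanic") + apoe4,
                  data = big, family = stats::binomial())
  est <- coef(g)[["age"]]
  se <- summary(g)$coefficients["age", "Std. Error"]
  expect_lt(abs(est - log(1.140)), 2 * se)
})

test_that("missingness is MAR on covariates/cognition at the target rate", {
  p <- default_params()
  cohort <- simulate_cohort(p, seed = 31)
  m <- apply_missingness(cohort, p, seed = 32)
  n_inc <- sum(!stats::complete.cases(m))
  expected <- 0.22 * nrow(m)
  se3 <- 3 * sqrt(nrow(m) * 0.22 * 0.78)
  expect_lt(abs(n_inc - expected), se3)
  # indicators are never made missing
  expect_false(anyNA(m[, INDICATORS]))
  # rate 0 is the identity
  p0 <- p; p0$missing_rate <- 0
  expect_identical(apply_missingness(cohort, p0, seed = 1), cohort)
  p_bad <- p; p_bad$missing_rate <- 1
  expect_error(apply_missingness(cohort, p_bad, seed = 1), "missing_rate")
})

test_that("parameter validation rejects broken inputs", {
  p <- default_params()
  p_bad <- p; p_bad$class_prevalence <- c(low = 0.7, high = 0.4)
  expect_error(validate_params(p_bad), "sum to 1")
  p_bad <- p; p_bad$within_class_corr[1, 2] <- 0.5
  expect_error(validate_params(p_bad), "symmetric")
  p_bad <- p
  p_bad$cognitive_class_means[, "speeded"] <- c(0.5, 0.5)
  expect_error(validate_params(p_bad), "cognitive")
})
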