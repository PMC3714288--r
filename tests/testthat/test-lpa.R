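# Latent profile engine: standardization, EM, likelihood, entropy,
# ordering, and oracle cross-checks.

test_that("standardization round-trips and rejects degenerate columns", {
  set.seed(1)
  d <- as.data.frame(matrix(rnorm(50 * 7, 10, 2), 50, 7))
  names(d) <- INDICATORS
  X <- standardize(d)
  expect_lt(max(abs(colMeans(X$x))), 1e-8)
  expect_lt(max(abs(apply(X$x, 2, sd) - 1)), 1e-8)
  expect_equal(back_transform(X, X$x), as.matrix(d), tolerance = 1e-10,
               ignore_attr = TRUE)
  d$bmi <- 5
  expect_error(standardize(d), "zero-variance")
})

test_that("K=1 reduces to the closed-form Gaussian fit", {
  set.seed(2)
  x <- matrix(rnorm(200 * 3, c(1, 2, 3), 0.5), 200, 3, byrow = TRUE)
  colnames(x) <- c("a", "b", "hdl")
  f <- fit_lpa(x, 1)
  expect_equal(drop(f$mu), colMeans(x), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(drop(f$sigma2),
               apply(x, 2, function(v) mean((v - mean(v))^2)),
               tolerance = 1e-10, ignore_attr = TRUE)
  ll_closed <- sum(vapply(1:3, function(j) {
    sum(stats::dnorm(x[, j], mean(x[, j]),
                     sqrt(mean((x[, j] - mean(x[, j]))^2)), log = TRUE))
  }, 1))
  expect_equal(f$loglik, ll_closed, tolerance = 1e-8)
  expect_equal(bic(f), -2 * ll_closed + 6 * log(200), tolerance = 1e-8)
})

test_that("the observed-data loglik matches a naive density-sum oracle", {
  set.seed(3)
  x <- matrix(rnorm(12 * 3), 12, 3)
  x[cbind(c(2, 5, 9), c(1, 3, 2))] <- NA   # FIML over observed cells
  colnames(x) <- c("a", "b", "c")
  model <- list(pi = c(0.3, 0.7),
                mu = rbind(c(-1, 0, 1), c(1, 0.5, -0.5)),
                sigma2 = rbind(c(1, 2, 0.5), c(0.7, 1.2, 2)))
  expect_equal(lpa_loglik(model, x),
               naive_mixture_loglik(x, model$pi, model$mu, model$sigma2),
               tolerance = 1e-10)
  # single standard-normal cell at its mode
  m1 <- list(pi = 1, mu = matrix(0), sigma2 = matrix(1))
  expect_equal(lpa_loglik(m1, matrix(0)), log(1 / sqrt(2 * pi)),
               tolerance = 1e-10)
  # additivity under dataset duplication
  expect_equal(lpa_loglik(model, rbind(x, x)), 2 * lpa_loglik(model, x),
               tolerance = 1e-10)
  bad <- model; bad$sigma2[1, 1] <- -1
  expect_error(lpa_loglik(bad, x), "positive")
})

test_that("relative entropy hits its boundary and hand-computed values", {
  hard <- matrix(c(1, 0, 0, 1, 1, 0), 3, 2, byrow = TRUE)
  expect_equal(relative_entropy(hard), 1)
  unif <- matrix(0.5, 4, 2)
  expect_equal(relative_entropy(unif), 0)
  # hand arithmetic: two rows of (0.9, 0.1)
  two <- matrix(c(0.9, 0.1, 0.9, 0.1), 2, 2, byrow = TRUE)
  expect_equal(relative_entropy(two), 0.5310, tolerance = 1e-4)
  expect_error(relative_entropy(matrix(c(0.5, 0.6), 1)), "sum to 1")
  expect_error(relative_entropy(matrix(1, 2, 1)), "K >= 2")
})

test_that("EM matches an exhaustive grid-search oracle on toy data", {
  set.seed(4)
  x <- toy_two_cluster()
  f <- fit_lpa(x, 2, n_starts = 10, seed = 1)
  # oracle: exhaustive grid over (pi, mu1, mu2, sigma2), invariant variance
  grid_ll <- -Inf
  for (pi1 in seq(0.1, 0.9, by = 0.05)) {
    for (m1 in seq(-5, -3, by = 0.1)) {
      for (m2 in seq(3, 5, by = 0.1)) {
        for (s2 in c(0.05, 0.09, 0.15, 0.25, 0.5, 1)) {
          ll <- naive_mixture_loglik(x, c(pi1, 1 - pi1),
                                     matrix(c(m1, m2), 2), matrix(s2, 2))
          if (ll > grid_ll) grid_ll <- ll
        }
      }
    }
  }
  expect_gte(f$loglik, grid_ll - 1e-3)
  # well-separated masses: hard posteriors, observed split recovered
  expect_gt(relative_entropy(f$posterior), 0.999)
  expect_equal(sort(f$pi), c(8, 12) / 20, tolerance = 1e-6)
})

test_that("the fit agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))
  res <- recovery_fits(25L)[[1]]
  x <- res$X$x
  f <- fit_lpa(res$X, 2, seed = 1, variance = "varying")
  mc <- mclust::Mclust(x, G = 2, modelNames = "VVI", verbose = FALSE)
  expect_equal(f$loglik, mc$loglik, tolerance = 1e-4)
  f_inv <- res$fit
  mc_eei <- mclust::Mclust(x, G = 2, modelNames = "EEI", verbose = FALSE)
  expect_equal(f_inv$loglik, mc_eei$loglik, tolerance = 1e-4)
})

test_that("EM is monotone, posteriors normalize, and pi is the posterior mean", {
  res <- recovery_fits(25L)[[2]]
  f <- res$fit
  expect_lt(max(abs(rowSums(f$posterior) - 1)), 1e-10)
  expect_equal(colMeans(f$posterior), f$pi, tolerance = 1e-5)
  # loglik reported equals loglik recomputed at the returned parameters
  expect_equal(lpa_loglik(f, res$X), f$loglik, tolerance = 1e-6)
  # monotonicity: rerunning EM from the solution cannot decrease loglik
  mask <- is.finite(res$X$x)
  again <- cvlpa:::.lpa_em(res$X$x, mask, f$pi, f$mu, f$sigma2,
                           "invariant", 1e-7, 50)
  expect_gte(again$loglik, f$loglik - 1e-6)
})

test_that("classes are ordered by descending HDL-C mean, idempotently", {
  res <- recovery_fits(25L)[[3]]
  f <- res$fit
  expect_gt(f$mu[1, "hdl"], f$mu[2, "hdl"])
  once <- order_classes(f)
  twice <- order_classes(once$model, once$posterior)
  expect_identical(once$model$mu, twice$model$mu)
  expect_identical(once$posterior, twice$posterior)
  # deliberately scrambled model gets restored
  scr <- f
  scr$pi <- rev(f$pi); scr$mu <- f$mu[2:1, ]; scr$sigma2 <- f$sigma2[2:1, ]
  scr$posterior <- f$posterior[, 2:1]
  fixed <- order_classes(scr, scr$posterior)
  expect_equal(fixed$model$mu, f$mu)
  expect_equal(fixed$posterior, f$posterior)
})

test_that("subject order permutation changes nothing but row order", {
  res <- recovery_fits(25L)[[4]]
  set.seed(9)
  perm <- sample(nrow(res$X$x))
  xp <- res$X$x[perm, ]
  fp <- fit_lpa(xp, 2, seed = 4)
  expect_equal(fp$loglik, res$fit$loglik, tolerance = 1e-4)
  expect_equal(fp$mu, res$fit$mu, tolerance = 1e-3)
})

test_that("FIML on complete data equals the complete-data likelihood and handles holes", {
  set.seed(10)
  x <- matrix(rnorm(300 * 4), 300, 4)
  colnames(x) <- c("a", "b", "c", "hdl")
  x[, 1] <- x[, 1] + rep(c(-2, 2), each = 150)
  f_complete <- fit_lpa(x, 2, n_starts = 10, seed = 1)
  xm <- x
  xm[sample(length(xm), 120)] <- NA
  f_fiml <- fit_lpa(xm, 2, n_starts = 10, seed = 1)
  expect_true(f_fiml$converged)
  expect_equal(f_fiml$mu[order(f_fiml$mu[, 1]), 1],
               f_complete$mu[order(f_complete$mu[, 1]), 1],
               tolerance = 0.25, ignore_attr = TRUE)
  expect_lt(max(abs(rowSums(f_fiml$posterior) - 1)), 1e-10)
})

test_that("class means are recovered on default synthetic cohorts", {
  p <- default_params()
  truth_std <- {
    pooled_mu <- drop(p$class_prevalence %*% p$class_indicator_means)
    between <- sweep(p$class_indicator_means, 2, pooled_mu)
    pooled_sd <- sqrt(drop(p$class_prevalence %*% p$class_indicator_sds^2) +
                        drop(p$class_prevalence %*% between^2))
    sweep(between, 2, pooled_sd, "/")
  }
  fits <- recovery_fits(25L)
  err <- sapply(fits, function(r) mean(abs(r$fit$mu - truth_std)))
  expect_lt(mean(err), 0.15)
  # class-conditional standardized BMI means near the published estimates
  bmi_means <- sapply(fits, function(r) r$fit$mu[, "bmi"])
  expect_equal(rowMeans(bmi_means), c(-0.324, 0.630), tolerance = 0.1,
               ignore_attr = TRUE)
})

test_that("predict and simulate methods are consistent with the fit", {
  res <- recovery_fits(25L)[[5]]
  f <- res$fit
  post <- predict(f, res$X)
  expect_equal(post, f$posterior, tolerance = 1e-10, ignore_attr = TRUE)
  lab <- predict(f, res$cohort, type = "class")
  expect_identical(lab, f$labels)
  sim <- simulate(f, seed = 1, n = 500)
  expect_identical(dim(sim), c(500L, 7L))
  mask <- matrix(TRUE, 500, 7); mask[1, 1] <- FALSE
  sim2 <- simulate(f, seed = 1, n = 500, mask = mask)
  expect_true(is.na(sim2[1, 1]))
})
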