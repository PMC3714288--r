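# Bi-factor measurement model: structure, ML fit, indices, scores.

bf_simulate <- function(n, structure = default_bifactor_structure(),
                        seed = 1) {
  set.seed(seed)
  L <- structure$loadings
  theta <- structure$residuals
  eta <- matrix(rnorm(n * ncol(L)), n)
  eta %*% t(L) + matrix(rnorm(n * nrow(L)), n) %*% diag(sqrt(theta))
}

test_that("the default structure satisfies the bi-factor constraints", {
  bs <- default_bifactor_structure()
  expect_identical(nrow(bs$loadings), 18L)
  expect_true(all(bs$loadings[, 1] != 0))
  spec <- bs$loadings[, -1] != 0
  expect_true(all(rowSums(spec) == 1L))          # disjoint and covering
  expect_true(all(colSums(spec) >= 2L))          # >= 2 indicators each
  expect_true(all(bs$residuals > 0))
})

test_that("loadings are recovered from data simulated at n = 5000", {
  bs <- default_bifactor_structure()
  y <- bf_simulate(5000, bs, seed = 42)
  colnames(y) <- bs$indicators
  fit <- fit_bifactor(y)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$loadings - bs$loadings)), 0.05)
  expect_lt(max(abs(fit$residuals - bs$residuals)), 0.05)
  # implied covariance is symmetric positive definite, zeros preserved
  sigma <- tcrossprod(fit$loadings) + diag(fit$residuals)
  expect_true(isSymmetric(sigma))
  expect_gt(min(eigen(sigma, symmetric = TRUE)$values), 0)
  expect_true(all(fit$loadings[bs$loadings == 0] == 0))
})

test_that("identity-covariance data drive loadings and discrepancy to zero", {
  bs <- default_bifactor_structure()
  set.seed(8)
  y <- matrix(rnorm(4000 * 18), 4000, 18,
              dimnames = list(NULL, bs$indicators))
  fit <- fit_bifactor(y)
  # near a zero-loading truth the likelihood surface is flat, so single
  # loadings can absorb sampling noise; the bulk must still shrink
  expect_lt(mean(abs(fit$loadings[, 1])), 0.1)
  expect_lt(fit$F_ml, 0.05)
})

test_that("structures with singleton specific factors are rejected", {
  bs <- default_bifactor_structure()
  bs$factor_of[bs$factor_of == "auditory"][-1] <- "verbal"
  expect_error(fit_bifactor(matrix(0, 100, 18), bs), "at least 2")
})

test_that("fit indices follow their definitions at the boundaries", {
  bs <- default_bifactor_structure()
  y <- bf_simulate(1000, bs, seed = 3)
  colnames(y) <- bs$indicators
  fit <- fit_bifactor(y)
  fi <- fit_indices(fit)
  expect_identical(fi$df, 18 * 19 / 2 - fit$q)
  expect_lte(fi$CFI, 1); expect_gte(fi$RMSEA, 0)
  # exact-fit boundary: T == df
  fake <- fit; fake$F_ml <- fi$df / (fit$n - 1)
  fb <- fit_indices(fake)
  expect_equal(fb$RMSEA, 0)
  expect_equal(fb$CFI, 1)
  # df <= 0 is an explicit error
  fake$q <- 200
  expect_error(fit_indices(fake), "degrees of freedom")
  # BIC is the standard closed form
  expect_equal(fi$BIC, -2 * fit$loglik + fit$q * log(fit$n))
})

test_that("well-specified simulations meet the conventional thresholds", {
  bs <- default_bifactor_structure()
  hits <- sapply(1:10, function(s) {
    y <- bf_simulate(1000, bs, seed = 100 + s)
    colnames(y) <- bs$indicators
    fi <- fit_indices(fit_bifactor(y))
    fi$CFI > 0.95 && fi$RMSEA < 0.05
  })
  expect_gte(mean(hits), 0.9)
})

test_that("factor scores center at zero, shrink, and track the truth", {
  bs <- default_bifactor_structure()
  set.seed(77)
  n <- 2000
  eta <- matrix(rnorm(n * 5), n)
  # strong general loadings for the tracking check
  Lh <- bs$loadings
  Lh[, 1] <- 0.75
  th <- 1 - rowSums(Lh^2)
  y <- eta %*% t(Lh) + matrix(rnorm(n * 18), n) %*% diag(sqrt(th))
  colnames(y) <- bs$indicators
  fit <- fit_bifactor(y)
  sc <- factor_scores(fit, y)
  expect_lt(max(abs(colMeans(sc))), 1e-10)
  expect_true(all(apply(sc, 2, var) <= 1 + 1e-8))   # regression shrinkage
  expect_gt(cor(sc[, "global"], eta[, 1]), 0.9)
  # rows with missing cells are excluded and counted
  y2 <- y; y2[3, 5] <- NA
  sc2 <- factor_scores(fit, y2)
  expect_identical(attr(sc2, "n_excluded"), 1L)
  expect_identical(nrow(sc2), as.integer(n) - 1L)
  # Bartlett scores track the truth too (noisier: no shrinkage, and the
  # general factor competes with the specifics)
  scb <- factor_scores(fit, y, method = "bartlett")
  expect_gt(cor(scb[, "global"], eta[, 1]), 0.5)
})

test_that("model comparison ranks the true bi-factor above one-factor", {
  bs <- default_bifactor_structure()
  y <- bf_simulate(1500, bs, seed = 5)
  colnames(y) <- bs$indicators
  one <- bs
  one$loadings[, -1] <- 0
  fits <- list(bifactor = fit_bifactor(y),
               onefactor = fit_bifactor(y, one))
  tab <- compare_models(fits)
  expect_identical(tab$model[1], "bifactor")
  expect_true(tab$meets_thresholds[tab$model == "bifactor"])
  expect_error(compare_models(list()), "no models")
  y2 <- bf_simulate(1500, bs, seed = 6)
  colnames(y2) <- bs$indicators
  expect_error(compare_models(list(fits[[1]], fit_bifactor(y2))),
               "different data")
})
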