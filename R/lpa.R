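# Gaussian latent profile engine: K-class finite mixture over standardized
# continuous indicators under local independence (diagonal within-class
# covariance), fitted by EM on the observed-data likelihood. Missing cells
# contribute nothing to a subject's likelihood product (full-information ML
# under MAR); indicators are never imputed.

#' Standardize cohort indicators into a risk matrix
#'
#' Column-wise z-scores of the seven risk indicators using the analysis
#' sample's mean and SD. The standardization constants are retained so that
#' estimates can be back-transformed to raw units.
#'
#' @param cohort a `cvlpa_cohort` data frame, or any data frame / matrix
#'   containing the indicator columns.
#' @param columns indicator column names (default the seven risk
#'   indicators).
#' @return object of class `risk_matrix`: list with `x` (n x p z-score
#'   matrix, `NA` for missing), `center`, `scale`.
#' @export
standardize <- function(cohort, columns = INDICATORS) {
  x <- as.matrix(as.data.frame(cohort)[, columns, drop = FALSE])
  storage.mode(x) <- "double"
  center <- colMeans(x, na.rm = TRUE)
  scale_ <- apply(x, 2L, stats::sd, na.rm = TRUE)
  if (any(!is.finite(scale_)) || any(scale_ < 1e-12)) {
    stop("zero-variance indicator column: ",
         paste(columns[scale_ < 1e-12 | !is.finite(scale_)], collapse = ", "))
  }
  z <- sweep(sweep(x, 2L, center), 2L, scale_, "/")
  structure(list(x = z, center = center, scale = scale_),
            class = "risk_matrix")
}

#' Back-transform standardized values to raw units
#'
#' @param X a `risk_matrix`.
#' @param z matrix or vector of standardized values (columns aligned with
#'   `X`).
#' @return values on the original measurement scale.
#' @export
back_transform <- function(X, z) {
  stopifnot(inherits(X, "risk_matrix"))
  if (is.null(dim(z))) return(z * X$scale + X$center)
  sweep(sweep(z, 2L, X$scale, "*"), 2L, X$center, "+")
}

.as_risk_matrix <- function(X) {
  if (inherits(X, "risk_matrix")) return(X)
  x <- as.matrix(X)
  storage.mode(x) <- "double"
  structure(list(x = x, center = rep(0, ncol(x)),
                 scale = rep(1, ncol(x))), class = "risk_matrix")
}

# Per-class log-density matrix (n x K) under local independence, product
# over observed cells only (compiled kernel).
.lpa_logdens <- function(x, mask, mu, sigma2) {
  x0 <- x; x0[!mask] <- 0
  lpa_logdens_cpp(x0, mask * 1, mu, sigma2)
}

# One EM run from given starting values (compiled kernel). sigma2 is
# stored K x p internally; under the class-invariant structure all rows
# are kept equal.
.lpa_em <- function(x, mask, pi0, mu0, s20, variance, tol, max_iter) {
  x0 <- x; x0[!mask] <- 0
  res <- lpa_em_cpp(x0, mask * 1, as.numeric(pi0), mu0, s20,
                    identical(variance, "invariant"), tol, max_iter)
  res$pi <- as.numeric(res$pi)
  res
}

# Random start: class means drawn from random subjects (observed cells,
# missing filled from pooled), pooled variances.
.lpa_start <- function(x, mask, K) {
  p <- ncol(x)
  pooled_mu <- colSums(ifelse(mask, x, 0)) / colSums(mask)
  pooled_s2 <- colSums(ifelse(mask, sweep(x, 2L, pooled_mu)^2, 0)) /
    colSums(mask)
  rows <- sample(nrow(x), K)
  mu <- x[rows, , drop = FALSE]
  for (k in seq_len(K)) {
    miss <- !mask[rows[k], ]
    mu[k, miss] <- pooled_mu[miss]
  }
  list(pi = rep(1 / K, K), mu = mu,
       s2 = matrix(pooled_s2, K, p, byrow = TRUE))
}

#' Fit a K-class Gaussian latent profile model
#'
#' EM on the observed-data likelihood
#' \deqn{f(y_i) = \sum_k \pi_k \prod_{j \in obs(i)} N(y_{ij}; \mu_{jk},
#' \sigma^2_{jk})} with local independence. Multiple random starts are run
#' for a short burn-in and the most promising continued to convergence;
#' classes are relabeled by descending HDL-C mean (see [order_classes()])
#' when the indicator is present, so class 1 is always the lower-risk
#' (higher HDL-C) profile.
#'
#' @param X a `risk_matrix` (or plain numeric matrix).
#' @param K number of classes (>= 1).
#' @param n_starts random initializations (default 50).
#' @param tol absolute log-likelihood gain declaring convergence.
#' @param max_iter EM iteration cap per start.
#' @param seed RNG seed for the starts.
#' @param variance `"invariant"` (one residual variance per indicator,
#'   default) or `"varying"` (class-specific diagonal).
#' @param burn_iter short-run iterations per random start.
#' @param top_starts number of best short runs continued to convergence.
#' @return an object of class `lpa`; see Details.
#' @details The returned object carries the mixing weights `pi`, class
#'   means `mu` (K x p, standardized scale), residual variances `sigma2`,
#'   the maximized `loglik`, free-parameter count `q`, the posterior
#'   membership matrix `posterior` with modal `labels`, and the
#'   standardization constants for back-transformation.
#' @export
fit_lpa <- function(X, K, n_starts = 50L, tol = 1e-7, max_iter = 2000L,
                    seed = NULL, variance = c("invariant", "varying"),
                    burn_iter = 20L, top_starts = 5L) {
  variance <- match.arg(variance)
  X <- .as_risk_matrix(X)
  x <- X$x
  n <- nrow(x); p <- ncol(x)
  if (K < 1L) stop("K must be >= 1")
  if (n < 10L * K) stop("need n >= 10*K subjects")
  mask <- is.finite(x)
  if (any(colSums(mask) == 0L)) stop("an indicator column is fully missing")
  if (!is.null(seed)) set.seed(seed)

  if (K == 1L) {
    # closed form: observed-cell ML means and variances
    mu <- matrix(colSums(ifelse(mask, x, 0)) / colSums(mask), 1L, p)
    s2 <- matrix(colSums(ifelse(mask, sweep(x, 2L, mu[1, ])^2, 0)) /
                   colSums(mask), 1L, p)
    fit <- list(pi = 1, mu = mu, sigma2 = s2,
                loglik = sum(.lpa_logdens(x, mask, mu, s2)),
                converged = TRUE, empty = FALSE)
    n_used <- 0L
  } else {
    short <- vector("list", n_starts)
    for (s in seq_len(n_starts)) {
      st <- .lpa_start(x, mask, K)
      short[[s]] <- .lpa_em(x, mask, st$pi, st$mu, st$s2, variance,
                            tol, burn_iter)
    }
    lls <- vapply(short, function(f) if (f$empty) -Inf else f$loglik, 1)
    keep <- order(lls, decreasing = TRUE)[seq_len(min(top_starts, n_starts))]
    best <- NULL
    for (s in keep) {
      f0 <- short[[s]]
      if (f0$empty) next
      f <- .lpa_em(x, mask, f0$pi, f0$mu, f0$sigma2, variance, tol, max_iter)
      if (f$empty) next
      if (is.null(best) || f$loglik > best$loglik) best <- f
    }
    if (is.null(best)) {
      # all promising starts collapsed: retry from fresh starts once
      warning("empty class encountered; restarting")
      for (s in seq_len(n_starts)) {
        st <- .lpa_start(x, mask, K)
        f <- .lpa_em(x, mask, st$pi, st$mu, st$s2, variance, tol, max_iter)
        if (!f$empty && (is.null(best) || f$loglik > best$loglik)) best <- f
      }
    }
    if (is.null(best)) stop("all EM starts failed or collapsed")
    if (!best$converged) warning("EM did not converge within max_iter")
    fit <- best
    n_used <- n_starts
  }

  q <- (K - 1L) + K * p + if (variance == "invariant") p else K * p
  dimnames(fit$mu) <- list(NULL, colnames(x))
  dimnames(fit$sigma2) <- list(NULL, colnames(x))
  model <- structure(list(
    K = K, pi = fit$pi, mu = fit$mu, sigma2 = fit$sigma2,
    variance = variance, loglik = fit$loglik, q = q, n = n,
    converged = fit$converged, n_starts_used = n_used,
    center = X$center, scale = X$scale,
    indicator_names = colnames(x)
  ), class = "lpa")
  post <- .posterior_matrix(model, x, mask)
  om <- order_classes(model, post)
  om$model$posterior <- om$posterior
  om$model$labels <- .modal_labels(om$posterior)
  om$model
}

.posterior_matrix <- function(model, x, mask = is.finite(x)) {
  lg <- sweep(.lpa_logdens(x, mask, model$mu, model$sigma2), 2L,
              log(model$pi), "+")
  exp(lg - logsumexp_rows(lg))
}

# Modal label with deterministic tie-break at the lowest class index.
.modal_labels <- function(post) max.col(post, ties.method = "first")

#' Observed-data log-likelihood of an LPA model
#'
#' Computes \eqn{\sum_i \ln \sum_k \pi_k \prod_{j \in obs(i)}
#' N(y_{ij}; \mu_{jk}, \sigma^2_{jk})} stably via log-sum-exp.
#'
#' @param model an `lpa` model (or any list with `pi`, `mu`, `sigma2`).
#' @param X a `risk_matrix` or matrix on the model's (standardized) scale.
#' @return scalar log-likelihood.
#' @export
lpa_loglik <- function(model, X) {
  x <- .as_risk_matrix(X)$x
  if (ncol(x) != ncol(model$mu)) stop("dimension mismatch")
  if (any(model$sigma2 <= 0)) stop("variances must be positive")
  mask <- is.finite(x)
  lg <- sweep(.lpa_logdens(x, mask, model$mu, model$sigma2), 2L,
              log(model$pi), "+")
  sum(logsumexp_rows(lg))
}

#' Relative entropy of a posterior classification
#'
#' \eqn{E = 1 - \sum_i \sum_k (-p_{ik} \ln p_{ik}) / (n \ln K)}, with
#' `0 * log(0) := 0`. 1 means perfectly separated classes; 0 means
#' posteriors carry no information.
#'
#' @param P n x K posterior matrix; rows must sum to 1.
#' @return scalar in `[0, 1]`.
#' @export
relative_entropy <- function(P) {
  P <- as.matrix(P)
  K <- ncol(P)
  if (K < 2L) stop("relative entropy needs K >= 2")
  if (any(abs(rowSums(P) - 1) > 1e-8)) stop("posterior rows must sum to 1")
  terms <- ifelse(P > 0, -P * log(P), 0)
  1 - sum(terms) / (nrow(P) * log(K))
}

#' Bayesian information criterion
#'
#' `-2 loglik + q log(n)`.
#'
#' @param model an `lpa` (or similar) model with `loglik` and `q`.
#' @param n sample size (defaults to the model's).
#' @return scalar BIC.
#' @export
bic <- function(model, n = model$n) {
  -2 * model$loglik + model$q * log(n)
}

#' Resolve label switching by the risk ordering
#'
#' Classes are permuted so the HDL-C class mean is descending: class 1 is
#' the lower-risk (higher HDL-C) profile. Exact HDL-C ties are broken by
#' ascending triglycerides mean. Without an HDL-C column, classes are
#' ordered by the first indicator's mean ascending.
#'
#' @param model an `lpa` model.
#' @param posterior optional n x K posterior matrix permuted consistently.
#' @return list with `model` and `posterior`.
#' @export
order_classes <- function(model, posterior = model$posterior) {
  nm <- model$indicator_names
  if (!is.null(nm) && "hdl" %in% nm) {
    hdl <- model$mu[, "hdl"]
    tg <- if ("triglycerides" %in% nm) model$mu[, "triglycerides"] else
      seq_len(model$K)
    ord <- order(-hdl, tg)
  } else {
    ord <- order(model$mu[, 1])
  }
  model$pi <- model$pi[ord]
  model$mu <- model$mu[ord, , drop = FALSE]
  model$sigma2 <- model$sigma2[ord, , drop = FALSE]
  if (!is.null(model$posterior)) {
    model$posterior <- model$posterior[, ord, drop = FALSE]
    model$labels <- .modal_labels(model$posterior)
  }
  if (!is.null(posterior)) posterior <- posterior[, ord, drop = FALSE]
  list(model = model, posterior = posterior)
}

# ---- S3 methods -----------------------------------------------------------

#' Fit a latent profile model to cohort data
#'
#' User-facing wrapper: standardizes the indicator columns of a cohort and
#' fits either the unconditional K-class model ([fit_lpa()]) or, when
#' `covariates` are supplied, the concomitant-covariate model
#' ([fit_conditional()]).
#'
#' @param data cohort data frame containing the indicator columns.
#' @param K number of latent classes.
#' @param covariates optional character vector of covariate column names
#'   (subset of `age`, `education`, `ethnicity`, `apoe4`).
#' @param indicators indicator column names.
#' @param ... passed to [fit_lpa()] / [fit_conditional()].
#' @return an `lpa` or `lpa_conditional` model.
#' @export
lpa <- function(data, K = 2L, covariates = NULL, indicators = INDICATORS,
                ...) {
  X <- standardize(data, indicators)
  if (is.null(covariates)) {
    fit_lpa(X, K = K, ...)
  } else {
    fit_conditional(X, covariates = data[, covariates, drop = FALSE],
                    K = K, ...)
  }
}

#' @export
print.lpa <- function(x, ...) {
  cat(sprintf("%d-class Gaussian latent profile model (%s variances)\n",
              x$K, x$variance))
  cat(sprintf("  n = %d   logLik = %.2f   q = %d   BIC = %.1f\n",
              x$n, x$loglik, x$q, bic(x)))
  if (x$K >= 2L) {
    cat(sprintf("  prevalence: %s   entropy = %.3f\n",
                paste(sprintf("%.3f", x$pi), collapse = " / "),
                relative_entropy(x$posterior)))
  }
  invisible(x)
}

#' @export
summary.lpa <- function(object, ...) {
  raw <- sweep(sweep(object$mu, 2L, object$scale, "*"), 2L, object$center,
               "+")
  out <- list(K = object$K, pi = object$pi, mu_std = object$mu,
              mu_raw = raw, sigma2 = object$sigma2,
              loglik = object$loglik, q = object$q, n = object$n,
              BIC = bic(object),
              entropy = if (object$K >= 2L)
                relative_entropy(object$posterior) else NA_real_,
              class_counts = tabulate(object$labels, object$K))
  class(out) <- "summary.lpa"
  out
}

#' @export
print.summary.lpa <- function(x, ...) {
  cat(sprintf("%d-class latent profile model: n = %d, BIC = %.1f", x$K,
              x$n, x$BIC))
  if (!is.na(x$entropy)) cat(sprintf(", entropy = %.3f", x$entropy))
  cat("\n\nClass means (raw units):\n")
  print(round(x$mu_raw, 2))
  cat("\nPrevalence:", sprintf("%.3f", x$pi), "\n")
  invisible(x)
}

#' @export
coef.lpa <- function(object, ...) {
  list(pi = object$pi, mu = object$mu, sigma2 = object$sigma2)
}

#' @export
logLik.lpa <- function(object, ...) {
  structure(object$loglik, df = object$q, nobs = object$n, class = "logLik")
}

#' Posterior class probabilities for new data
#'
#' @param object an `lpa` model.
#' @param newdata matrix/data frame of indicators on the raw scale (the
#'   model's standardization constants are applied), or a `risk_matrix`
#'   already standardized.
#' @param type `"posterior"` (n x K matrix) or `"class"` (modal labels).
#' @param ... unused.
#' @export
predict.lpa <- function(object, newdata,
                        type = c("posterior", "class"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "risk_matrix")) {
    x <- newdata$x
  } else {
    x <- as.matrix(as.data.frame(newdata)[, object$indicator_names,
                                          drop = FALSE])
    x <- sweep(sweep(x, 2L, object$center), 2L, object$scale, "/")
  }
  post <- .posterior_matrix(object, x)
  if (type == "class") .modal_labels(post) else post
}

#' Simulate data from a fitted LPA model
#'
#' Parametric draws from the fitted mixture on the standardized scale,
#' optionally replaying a missingness mask (used by the bootstrap LRT to
#' match the observed missingness pattern).
#'
#' @param object an `lpa` model.
#' @param nsim number of datasets.
#' @param seed optional RNG seed.
#' @param n rows per dataset (default the fitted n).
#' @param mask optional logical n x p observedness mask to replay.
#' @param ... unused.
#' @return a matrix (if `nsim = 1`) or list of matrices.
#' @export
simulate.lpa <- function(object, nsim = 1, seed = NULL, n = object$n,
                         mask = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- ncol(object$mu)
  one <- function() {
    cls <- sample.int(object$K, n, replace = TRUE, prob = object$pi)
    x <- matrix(stats::rnorm(n * p), n, p)
    x <- x * sqrt(object$sigma2[cls, , drop = FALSE]) +
      object$mu[cls, , drop = FALSE]
    colnames(x) <- object$indicator_names
    if (!is.null(mask)) x[!mask] <- NA_real_
    x
  }
  if (nsim == 1) one() else replicate(nsim, one(), simplify = FALSE)
}

#' Residuals of an LPA model
#'
#' Posterior-weighted standardized residuals: for each subject,
#' \eqn{(y_{ij} - \sum_k p_{ik}\mu_{jk}) / sd_j} on the model scale.
#'
#' @param object an `lpa` model with stored posterior.
#' @param newdata data on the raw scale (optional; defaults cannot be
#'   reconstructed, so `newdata` is required).
#' @param ... unused.
#' @export
residuals.lpa <- function(object, newdata, ...) {
  if (missing(newdata)) stop("supply the data the model was fitted to")
  if (inherits(newdata, "risk_matrix")) {
    x <- newdata$x
  } else {
    x <- as.matrix(as.data.frame(newdata)[, object$indicator_names,
                                          drop = FALSE])
    x <- sweep(sweep(x, 2L, object$center), 2L, object$scale, "/")
  }
  post <- .posterior_matrix(object, x)
  fitted_ <- post %*% object$mu
  (x - fitted_) / sqrt(rep(1, nrow(x)) %o% colMeans(object$sigma2))
}

#' Profile plot of class means
#'
#' Plots the standardized class-conditional indicator means by class, the
#' conventional way of displaying a latent profile solution.
#'
#' @param x an `lpa` model.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.lpa <- function(x, ...) {
  graphics::matplot(t(x$mu), type = "b", pch = 19, lty = 1,
                    xaxt = "n", xlab = "", ylab = "standardized mean",
                    main = sprintf("%d-class latent profile solution", x$K),
                    ...)
  graphics::axis(1, at = seq_along(x$indicator_names),
                 labels = x$indicator_names, las = 2)
  graphics::abline(h = 0, col = "grey70", lty = 2)
  graphics::legend("topleft",
                   legend = sprintf("class %d (%.0f%%)", seq_len(x$K),
                                    100 * x$pi),
                   col = seq_len(x$K), lty = 1, pch = 19, bty = "n")
  invisible(x)
}
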