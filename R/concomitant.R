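# Conditional (concomitant-covariate) latent profile model: class
# membership regressed on age, education, ethnicity and APOE4 inside the
# mixture likelihood. The E-step uses subject-specific logistic priors;
# the M-step for the membership coefficients solves a weighted logistic
# regression with the posteriors as fractional responses.

# Design matrix with the reference coding used throughout: below-college
# education and non-Hispanic White are the reference categories.
.concomitant_design <- function(covariates) {
  cv <- as.data.frame(covariates)
  need <- c("age", "education", "ethnicity", "apoe4")
  miss <- setdiff(need, names(cv))
  if (length(miss)) stop("covariates missing: ", paste(miss, collapse = ", "))
  eth <- factor(cv$ethnicity, levels = ETHNICITIES)
  X <- cbind(
    intercept = 1,
    age = as.numeric(cv$age),
    education = as.numeric(cv$education),
    ethnicity_black = as.numeric(eth == "non-Hispanic Black"),
    ethnicity_hispanic = as.numeric(eth == "Hispanic"),
    apoe4 = as.numeric(cv$apoe4))
  X
}

# Newton step(s) for the weighted logistic M-step, ridge-stabilized when
# the curvature matrix is near-singular or the step diverges (separation).
.logistic_mstep <- function(D, p2, gamma, steps = 3L, ridge = 1e-8) {
  for (s in seq_len(steps)) {
    eta <- drop(D %*% gamma)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    score <- drop(crossprod(D, p2 - mu))
    H <- crossprod(D * w, D)
    step <- tryCatch(solve(H + ridge * diag(ncol(D)), score),
                     error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step)) || max(abs(step)) > 10) {
      warning("possible separation in the concomitant sub-model; ",
              "ridge-stabilized step")
      step <- solve(H + 1e-2 * diag(ncol(D)), score)
      step <- step * min(1, 2 / max(abs(step)))
    }
    gamma <- gamma + step
  }
  gamma
}

# Observed-data log-likelihood of the conditional model at a parameter
# vector; used both by the EM loop and the numerical information matrix.
.cond_loglik <- function(gamma, mu, sigma2, x, mask, D, complete) {
  eta <- drop(D[complete, , drop = FALSE] %*% gamma)
  p_high <- stats::plogis(eta)
  prior <- matrix(NA_real_, nrow(x), 2)
  prior[complete, 2] <- p_high
  prior[!complete, 2] <- mean(p_high)
  prior[, 1] <- 1 - prior[, 2]
  lg <- .lpa_logdens(x, mask, mu, sigma2) + log(prior)
  sum(logsumexp_rows(lg))
}

#' Fit the conditional (concomitant-covariate) 2-class LPA
#'
#' EM in which the prior class probabilities are subject-specific,
#' \eqn{\pi_i(high) = logit^{-1}(\gamma_0 + \gamma' x_i)}, and the
#' membership coefficients are updated each cycle by Newton iterations on
#' a weighted logistic regression with the posteriors as responses.
#' Indicator means and variances are updated exactly as in the
#' unconditional model. Subjects with missing covariates still contribute
#' to the measurement part (their prior is the marginal over
#' complete-covariate subjects); only complete-covariate subjects drive the
#' coefficient update. Standard errors come from the numerically
#' differentiated observed information at the optimum.
#'
#' @param X a `risk_matrix` (or matrix) of standardized indicators.
#' @param covariates data frame with columns `age`, `education`,
#'   `ethnicity`, `apoe4`.
#' @param K number of classes; only `K = 2` is supported.
#' @param n_starts starts for the unconditional initialization fit.
#' @param tol absolute log-likelihood gain declaring convergence.
#' @param max_iter EM iteration cap.
#' @param seed RNG seed for the initialization.
#' @param se compute standard errors (numerical observed information).
#' @param variance variance structure, as in [fit_lpa()].
#' @return object of class `c("lpa_conditional", "lpa")` with concomitant
#'   coefficients `gamma` (for the high-risk class), their `gamma_se`, and
#'   the usual LPA fields.
#' @export
fit_conditional <- function(X, covariates, K = 2L, n_starts = 50L,
                            tol = 1e-7, max_iter = 500L, seed = NULL,
                            se = TRUE,
                            variance = c("invariant", "varying")) {
  variance <- match.arg(variance)
  if (K != 2L) stop("the concomitant model supports K = 2 only")
  X <- .as_risk_matrix(X)
  x <- X$x
  mask <- is.finite(x)
  n <- nrow(x); p <- ncol(x)
  D <- .concomitant_design(covariates)
  if (nrow(D) != n) stop("covariates and indicators are misaligned")
  complete <- stats::complete.cases(D)
  if (sum(complete) < 10L * K) stop("too few complete-covariate subjects")

  init <- fit_lpa(X, K, n_starts = n_starts, seed = seed,
                  variance = variance)
  mu <- init$mu
  sigma2 <- init$sigma2
  # class 2 of the ordered unconditional fit is the high-risk class
  p2 <- init$posterior[, 2]
  gamma <- c(stats::qlogis(max(min(mean(p2), 1 - 1e-6), 1e-6)),
             rep(0, ncol(D) - 1L))
  names(gamma) <- colnames(D)
  gamma <- .logistic_mstep(D[complete, , drop = FALSE], p2[complete], gamma,
                           steps = 10L)

  x0 <- x; x0[!mask] <- 0
  ll_old <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    eta_c <- drop(D[complete, , drop = FALSE] %*% gamma)
    prior2 <- rep(mean(stats::plogis(eta_c)), n)
    prior2[complete] <- stats::plogis(eta_c)
    lg <- .lpa_logdens(x, mask, mu, sigma2) +
      cbind(log1p(-prior2), log(prior2))
    ll <- sum(logsumexp_rows(lg))
    post <- exp(lg - logsumexp_rows(lg))
    # measurement M-step
    for (k in 1:2) {
      wobs <- as.vector(crossprod(mask, post[, k]))
      mu[k, ] <- as.vector(crossprod(x0, post[, k])) / pmax(wobs, 1e-8)
    }
    if (variance == "invariant") {
      num <- rep(0, p); den <- rep(0, p)
      for (k in 1:2) {
        dev2 <- sweep(x0, 2L, mu[k, ])^2 * mask
        num <- num + as.vector(crossprod(dev2, post[, k]))
        den <- den + as.vector(crossprod(mask, post[, k]))
      }
      sigma2[] <- rep(pmax(num / pmax(den, 1e-8), 1e-8), each = 2L)
    } else {
      for (k in 1:2) {
        dev2 <- sweep(x0, 2L, mu[k, ])^2 * mask
        wobs <- as.vector(crossprod(mask, post[, k]))
        sigma2[k, ] <- pmax(as.vector(crossprod(dev2, post[, k])) /
                              pmax(wobs, 1e-8), 1e-8)
      }
    }
    # concomitant M-step on complete-covariate subjects
    gamma <- .logistic_mstep(D[complete, , drop = FALSE],
                             post[complete, 2], gamma)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  if (!converged) warning("conditional EM did not converge within max_iter")

  # enforce the risk ordering: class 2 must be the lower-HDL class
  hdl <- match("hdl", colnames(mu))
  flip <- if (!is.na(hdl)) mu[2, hdl] > mu[1, hdl] else FALSE
  if (flip) {
    mu <- mu[2:1, , drop = FALSE]
    sigma2 <- sigma2[2:1, , drop = FALSE]
    gamma <- -gamma
  }

  ll <- .cond_loglik(gamma, mu, sigma2, x, mask, D, complete)
  q <- ncol(D) + 2L * p + if (variance == "invariant") p else 2L * p

  gamma_se <- rep(NA_real_, length(gamma))
  vcov_gamma <- NULL
  if (se) {
    d <- length(gamma)
    pack <- function(g, m, s2) c(g, as.vector(m), log(as.vector(s2[1, ])))
    unpack <- function(th) {
      g <- th[seq_len(d)]
      m <- matrix(th[d + seq_len(2L * p)], 2L, p)
      s2v <- exp(th[d + 2L * p + seq_len(p)])
      list(g = g, m = m, s2 = matrix(s2v, 2L, p, byrow = TRUE))
    }
    nll <- function(th) {
      pr <- unpack(th)
      -.cond_loglik(pr$g, pr$m, pr$s2, x, mask, D, complete)
    }
    H <- tryCatch(stats::optimHess(pack(gamma, mu, sigma2), nll),
                  error = function(e) NULL)
    if (!is.null(H)) {
      Vc <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(Vc)) {
        gamma_se <- sqrt(pmax(diag(Vc)[seq_len(d)], 0))
        vcov_gamma <- Vc[seq_len(d), seq_len(d), drop = FALSE]
      }
    }
    if (anyNA(gamma_se)) warning("observed information not invertible; ",
                                 "standard errors unavailable")
  }
  names(gamma_se) <- names(gamma)

  eta_c <- drop(D[complete, , drop = FALSE] %*% gamma)
  prior2 <- rep(mean(stats::plogis(eta_c)), n)
  prior2[complete] <- stats::plogis(eta_c)
  lg <- .lpa_logdens(x, mask, mu, sigma2) + cbind(log1p(-prior2),
                                                  log(prior2))
  post <- exp(lg - logsumexp_rows(lg))

  structure(list(
    K = 2L, gamma = gamma, gamma_se = gamma_se, vcov_gamma = vcov_gamma,
    pi = colMeans(post), mu = mu, sigma2 = sigma2, variance = variance,
    loglik = ll, q = q, n = n, n_complete_covariates = sum(complete),
    converged = converged, posterior = post,
    labels = .modal_labels(post), prior = cbind(1 - prior2, prior2),
    center = X$center, scale = X$scale, indicator_names = colnames(x),
    reference = c(education = "below college",
                  ethnicity = "non-Hispanic White")
  ), class = c("lpa_conditional", "lpa"))
}

#' Odds-ratio table for a conditional LPA model
#'
#' Exponentiated concomitant coefficients for high-risk class membership
#' with Wald 95% confidence limits, two-sided p-values and the confidence
#' limit ratio (upper/lower). The education effect is additionally reported
#' in the low-risk direction (reciprocal odds ratio).
#'
#' @param model a fitted `lpa_conditional` with standard errors.
#' @param conf_level confidence level (default 0.95).
#' @return data frame of class `or_table`.
#' @export
odds_ratios <- function(model, conf_level = 0.95) {
  if (anyNA(model$gamma_se)) stop("model has no standard errors")
  zcrit <- stats::qnorm(1 - (1 - conf_level) / 2)
  keep <- names(model$gamma) != "intercept"
  g <- model$gamma[keep]
  s <- model$gamma_se[keep]
  z <- g / s
  tab <- data.frame(
    term = names(g),
    log_odds = unname(g),
    se = unname(s),
    odds_ratio = exp(unname(g)),
    ci_lower = exp(unname(g - zcrit * s)),
    ci_upper = exp(unname(g + zcrit * s)),
    p_value = 2 * stats::pnorm(-abs(unname(z))))
  tab$clr <- tab$ci_upper / tab$ci_lower
  attr(tab, "education_low_risk_or") <-
    unname(exp(-g["education"]))
  attr(tab, "reference") <- model$reference
  class(tab) <- c("or_table", "data.frame")
  tab
}

#' @export
print.or_table <- function(x, digits = 3, ...) {
  cat("Conditional odds ratios (high-risk class membership)\n")
  print.data.frame(cbind(x["term"],
                         round(x[, c("odds_ratio", "ci_lower", "ci_upper",
                                     "p_value", "clr")], digits)),
                   row.names = FALSE)
  cat(sprintf("education, low-risk direction: OR = %.3f\n",
              attr(x, "education_low_risk_or")))
  invisible(x)
}

#' Marginal class prevalences of a fitted model
#'
#' Reports both the model-implied prevalence (mean of the subject-specific
#' prior probabilities) and the posterior prevalence (column means of the
#' posterior matrix).
#'
#' @param model an `lpa` or `lpa_conditional` model.
#' @param P posterior matrix (defaults to the model's).
#' @return data frame with one row per class.
#' @export
report_prevalence <- function(model, P = model$posterior) {
  model_implied <- if (!is.null(model$prior)) {
    colMeans(model$prior)
  } else {
    model$pi
  }
  data.frame(class = seq_len(ncol(P)),
             model_implied = model_implied,
             posterior = colMeans(P))
}

#' @export
print.lpa_conditional <- function(x, ...) {
  cat("2-class latent profile model with concomitant covariates\n")
  cat(sprintf("  n = %d (%d with complete covariates)   logLik = %.2f   BIC = %.1f\n",
              x$n, x$n_complete_covariates, x$loglik, bic(x)))
  cat(sprintf("  marginal prevalence (low/high): %.3f / %.3f   entropy = %.3f\n",
              colMeans(x$prior)[1], colMeans(x$prior)[2],
              relative_entropy(x$posterior)))
  ors <- exp(x$gamma[names(x$gamma) != "intercept"])
  cat("  odds ratios (high-risk):",
      paste(sprintf("%s=%.3f", names(ors), ors), collapse = " "), "\n")
  invisible(x)
}

#' @export
coef.lpa_conditional <- function(object, ...) {
  list(gamma = object$gamma, mu = object$mu, sigma2 = object$sigma2)
}
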