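# Bi-factor confirmatory factor model for the cognitive battery: one
# general factor loading on all 18 test variables plus four orthogonal
# specific factors loading on disjoint subsets (verbal learning & memory,
# auditory attention & working memory, visual attention & executive
# function, speeded language & mental flexibility). Fitted by maximum
# likelihood on the sample covariance.

#' Default 18-indicator bi-factor structure
#'
#' The packaged stand-in structure for the cognitive battery: 18 test
#' variables in four domains, each loading on the general factor and on
#' exactly one specific factor. Loadings and residual variances are on the
#' standardized-test metric and are also used by the synthetic-data
#' generator as the true measurement model.
#'
#' @return list with `indicators`, `factor_of` (specific-factor assignment),
#'   `loadings` (18x5 matrix, column 1 = general) and `residuals`
#'   (18-vector; `1 - general^2 - specific^2`).
#' @export
default_bifactor_structure <- function() {
  spec <- list(
    verbal = c(ravlt_total = 0.55, ravlt_immediate = 0.60,
               ravlt_delayed = 0.60, ravlt_recognition = 0.45,
               paragraph_recall = 0.50),
    auditory = c(digit_span_forward = 0.50, digit_span_backward = 0.55,
                 letter_number_seq = 0.50, mental_control = 0.40),
    visual = c(trails_a = 0.45, trails_b = 0.50, digit_symbol = 0.45,
               stroop_interference = 0.40),
    speeded = c(letter_fluency_f = 0.55, letter_fluency_a = 0.55,
                letter_fluency_s = 0.50, category_fluency_animals = 0.50,
                category_fluency_vegetables = 0.45))
  general <- c(0.65, 0.70, 0.68, 0.55, 0.60,       # verbal items
               0.55, 0.60, 0.58, 0.50,             # auditory
               0.60, 0.62, 0.58, 0.52,             # visual
               0.62, 0.60, 0.58, 0.60, 0.55)       # speeded

  indicators <- unlist(lapply(spec, names), use.names = FALSE)
  factor_of <- rep(names(spec), lengths(spec))
  names(factor_of) <- indicators

  L <- matrix(0, 18, 5,
              dimnames = list(indicators,
                              c("global", "verbal", "auditory", "visual",
                                "speeded")))
  L[, "global"] <- general
  for (f in names(spec)) L[names(spec[[f]]), f] <- spec[[f]]
  theta <- 1 - rowSums(L^2)
  stopifnot(all(theta > 0.05))
  list(indicators = indicators, factor_of = factor_of,
       loadings = L, residuals = theta)
}

# Free-parameter template from a structure: positions of free loadings.
.bf_free <- function(structure) {
  L <- structure$loadings
  which(L != 0)
}

.bf_sigma <- function(L, theta) tcrossprod(L) + diag(theta)

# ML discrepancy F = log|Sigma| + tr(S Sigma^-1) - log|S| - p, with its
# analytic gradient over free loadings and residual variances.
.bf_objective <- function(par, free_idx, dims, S, logdetS) {
  p <- dims[1]
  L <- matrix(0, p, dims[2])
  L[free_idx] <- par[seq_along(free_idx)]
  theta <- par[-seq_along(free_idx)]
  sigma <- .bf_sigma(L, theta)
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) return(list(value = 1e10, gradient = NULL))
  logdet <- 2 * sum(log(diag(ch)))
  sigma_inv <- chol2inv(ch)
  val <- logdet + sum(sigma_inv * S) - logdetS - p
  G <- sigma_inv %*% (sigma - S) %*% sigma_inv
  grad_L <- 2 * (G %*% L)
  list(value = val, gradient = c(grad_L[free_idx], diag(G)))
}

#' Fit a bi-factor model by maximum likelihood
#'
#' Minimizes the normal-theory ML discrepancy
#' \eqn{F_{ML} = \ln|\Sigma(\theta)| + tr(S\Sigma(\theta)^{-1}) - \ln|S| - p}
#' over the structurally free loadings and residual variances, with
#' orthogonal unit-variance factors (\eqn{\Sigma = \Lambda\Lambda' +
#' \Theta}). Optimization is quasi-Newton (L-BFGS-B) with analytic
#' gradients; loadings start from the leading principal component (general)
#' and per-domain residual components (specific), with jittered restarts on
#' non-convergence. Residual variances are floored at `heywood_floor`, with
#' a warning naming any indicator driven to the floor (Heywood case).
#'
#' @param data n x 18 matrix or data frame of test scores (complete rows
#'   are used for the covariance).
#' @param structure a structure list, see [default_bifactor_structure()].
#' @param tol convergence tolerance on the discrepancy.
#' @param max_iter optimizer iteration cap.
#' @param heywood_floor lower bound for residual variances.
#' @param restarts number of jittered restarts if the first fit fails.
#' @return an object of class `bifactor_model`.
#' @export
fit_bifactor <- function(data, structure = default_bifactor_structure(),
                         tol = 1e-9, max_iter = 2000L,
                         heywood_floor = 1e-3, restarts = 3L) {
  if (any(table(structure$factor_of) < 2L)) {
    stop("each specific factor needs at least 2 indicators")
  }
  data <- as.matrix(data[, structure$indicators, drop = FALSE])
  cc <- stats::complete.cases(data)
  data <- data[cc, , drop = FALSE]
  n <- nrow(data)
  p <- ncol(data)
  q <- length(.bf_free(structure)) + p
  if (n <= q) stop("need more rows than free parameters (n > ", q, ")")
  S <- stats::cov(data)
  ch_S <- tryCatch(chol(S), error = function(e) {
    stop("sample covariance is not positive definite")
  })
  logdetS <- 2 * sum(log(diag(ch_S)))

  free_idx <- .bf_free(structure)
  dims <- dim(structure$loadings)

  start_par <- function(jitter = 0) {
    ei <- eigen(S, symmetric = TRUE)
    g <- ei$vectors[, 1] * sqrt(ei$values[1])
    if (sum(g) < 0) g <- -g
    L0 <- structure$loadings
    L0[, 1] <- g
    # residual covariance after removing the general part; per-domain
    # leading component seeds the specific loadings
    R <- S - tcrossprod(g)
    for (f in unique(structure$factor_of)) {
      rows <- which(structure$factor_of == f)
      er <- eigen(R[rows, rows, drop = FALSE], symmetric = TRUE)
      s <- er$vectors[, 1] * sqrt(max(er$values[1], 0.01))
      if (sum(s) < 0) s <- -s
      L0[rows, match(f, colnames(L0))] <- s
    }
    theta0 <- pmax(diag(S) - rowSums(L0^2), 0.05)
    par <- c(L0[free_idx], theta0)
    if (jitter > 0) par <- par + stats::rnorm(length(par), 0, jitter)
    par
  }

  fit_once <- function(par0) {
    stats::optim(
      par0,
      fn = function(p_) .bf_objective(p_, free_idx, dims, S, logdetS)$value,
      gr = function(p_) .bf_objective(p_, free_idx, dims, S, logdetS)$gradient,
      method = "L-BFGS-B",
      lower = c(rep(-Inf, length(free_idx)), rep(heywood_floor, p)),
      control = list(maxit = max_iter, factr = tol / .Machine$double.eps))
  }

  best <- fit_once(start_par())
  tries <- 0L
  while (best$convergence != 0L && tries < restarts) {
    tries <- tries + 1L
    cand <- fit_once(start_par(jitter = 0.05 * tries))
    if (cand$value < best$value || best$convergence != 0L) best <- cand
  }
  converged <- best$convergence == 0L
  if (!converged) warning("bi-factor fit did not converge")

  L <- matrix(0, dims[1], dims[2], dimnames = dimnames(structure$loadings))
  L[free_idx] <- best$par[seq_along(free_idx)]
  theta <- best$par[-seq_along(free_idx)]
  names(theta) <- rownames(L)
  at_floor <- theta <= heywood_floor * (1 + 1e-6)
  if (any(at_floor)) {
    warning("Heywood case: residual variance at floor for ",
            paste(names(theta)[at_floor], collapse = ", "))
  }
  # sign convention: each factor's loading column sums positive
  for (f in seq_len(ncol(L))) if (sum(L[, f]) < 0) L[, f] <- -L[, f]

  sigma <- .bf_sigma(L, theta)
  S_ml <- S * (n - 1) / n
  sigma_inv <- chol2inv(chol(sigma))
  loglik <- -n / 2 * (p * log(2 * pi) +
                        2 * sum(log(diag(chol(sigma)))) +
                        sum(sigma_inv * S_ml))

  structure(list(
    loadings = L, residuals = theta, structure = structure,
    S = S, n = n, means = colMeans(data), F_ml = best$value,
    loglik = loglik, q = q, converged = converged,
    n_dropped = sum(!cc)
  ), class = "bifactor_model")
}

#' Fit indices for a fitted covariance-structure model
#'
#' Computes the chi-square statistic `T = (n-1) F_ML`, CFI, TLI, RMSEA and
#' BIC against the independence baseline model (diagonal covariance).
#'
#' @param model a `bifactor_model`.
#' @param S sample covariance (defaults to the one stored in the model).
#' @param n sample size (defaults to the model's).
#' @return list of class `cvlpa_fit_indices` with `F_ml`, `T`, `df`, `CFI`,
#'   `TLI`, `RMSEA`, `BIC`.
#' @export
fit_indices <- function(model, S = model$S, n = model$n) {
  p <- nrow(S)
  df <- p * (p + 1) / 2 - model$q
  if (df <= 0) stop("degrees of freedom must be positive (df = ", df, ")")
  T_stat <- (n - 1) * model$F_ml
  logdetS <- determinant(S, logarithm = TRUE)$modulus
  F_b <- sum(log(diag(S))) - as.numeric(logdetS)
  T_b <- (n - 1) * F_b
  df_b <- p * (p - 1) / 2
  cfi <- 1 - max(T_stat - df, 0) / max(T_b - df_b, T_stat - df, 0)
  tli <- ((T_b / df_b) - (T_stat / df)) / ((T_b / df_b) - 1)
  rmsea <- sqrt(max(T_stat - df, 0) / (df * (n - 1)))
  bic <- -2 * model$loglik + model$q * log(n)
  structure(list(F_ml = model$F_ml, T = T_stat, df = df, CFI = cfi,
                 TLI = tli, RMSEA = rmsea, BIC = bic, n = n),
            class = "cvlpa_fit_indices")
}

#' Factor scores from a fitted bi-factor model
#'
#' Regression-method scores \eqn{\hat\eta = \Lambda'\Sigma(\theta)^{-1}
#' (y - \bar y)} (default), or Bartlett scores
#' \eqn{(\Lambda'\Theta^{-1}\Lambda)^{-1}\Lambda'\Theta^{-1}(y - \bar y)}.
#' Rows with any missing test score are excluded; the count of excluded
#' rows is attached as an attribute.
#'
#' @param model a converged `bifactor_model`.
#' @param data n x 18 test-score matrix or data frame.
#' @param method `"regression"` (default) or `"bartlett"`.
#' @return n_complete x 5 matrix of scores with attribute `n_excluded` and
#'   `rows` (the row indices scored).
#' @export
factor_scores <- function(model, data, method = c("regression", "bartlett")) {
  method <- match.arg(method)
  if (!model$converged) warning("scoring a non-converged model")
  data <- as.matrix(data[, rownames(model$loadings), drop = FALSE])
  cc <- stats::complete.cases(data)
  yc <- sweep(data[cc, , drop = FALSE], 2L, colMeans(data[cc, , drop = FALSE]))
  L <- model$loadings
  A <- if (method == "regression") {
    t(L) %*% chol2inv(chol(.bf_sigma(L, model$residuals)))
  } else {
    Ti <- diag(1 / model$residuals)
    solve(t(L) %*% Ti %*% L) %*% t(L) %*% Ti
  }
  scores <- yc %*% t(A)
  colnames(scores) <- colnames(L)
  attr(scores, "n_excluded") <- sum(!cc)
  attr(scores, "rows") <- which(cc)
  attr(scores, "method") <- method
  scores
}

#' Rank competing measurement models
#'
#' Orders fitted models by BIC (ascending) and reports which meet the
#' conventional thresholds CFI > 0.95, TLI > 0.95 and RMSEA < 0.05.
#' Models must have been fitted to the same data.
#'
#' @param fits a non-empty named or unnamed list of `bifactor_model`s (or
#'   any objects with `loglik`, `q`, `F_ml`, `S`, `n`).
#' @return data frame with one row per model, ranked.
#' @export
compare_models <- function(fits) {
  if (!length(fits)) stop("no models to compare")
  ns <- vapply(fits, function(m) m$n, 1)
  if (length(unique(ns)) != 1L ||
      any(vapply(fits, function(m) !isTRUE(all.equal(m$S, fits[[1]]$S)),
                 TRUE))) {
    stop("models were fitted to different data")
  }
  idx <- lapply(fits, fit_indices)
  tab <- data.frame(
    model = if (is.null(names(fits))) seq_along(fits) else names(fits),
    BIC = vapply(idx, `[[`, 1, "BIC"),
    CFI = vapply(idx, `[[`, 1, "CFI"),
    TLI = vapply(idx, `[[`, 1, "TLI"),
    RMSEA = vapply(idx, `[[`, 1, "RMSEA"),
    df = vapply(idx, `[[`, 1, "df"))
  tab$meets_thresholds <- tab$CFI > 0.95 & tab$TLI > 0.95 & tab$RMSEA < 0.05
  tab[order(tab$BIC), , drop = FALSE]
}

#' @export
print.bifactor_model <- function(x, ...) {
  cat("Bi-factor measurement model (ML)\n")
  cat(sprintf("  indicators: %d   factors: 1 general + %d specific\n",
              nrow(x$loadings), ncol(x$loadings) - 1L))
  cat(sprintf("  n = %d (%d rows dropped)   F_ML = %.5f   logLik = %.2f\n",
              x$n, x$n_dropped, x$F_ml, x$loglik))
  cat(sprintf("  converged: %s\n", x$converged))
  invisible(x)
}

#' @export
logLik.bifactor_model <- function(object, ...) {
  structure(object$loglik, df = object$q, nobs = object$n, class = "logLik")
}

#' @export
coef.bifactor_model <- function(object, ...) {
  cbind(object$loadings, residual = object$residuals)
}

#' @export
print.cvlpa_fit_indices <- function(x, ...) {
  cat(sprintf(
    "chi-sq T = %.2f on df = %d | CFI %.3f  TLI %.3f  RMSEA %.3f  BIC %.1f\n",
    x$T, x$df, x$CFI, x$TLI, x$RMSEA, x$BIC))
  invisible(x)
}
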