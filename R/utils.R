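# Small numeric helpers shared across modules.

#' Row-wise log-sum-exp
#'
#' Stable computation of `log(rowSums(exp(M)))` for a matrix of log-values.
#' Rows that are entirely `-Inf` return `-Inf`.
#'
#' @param m numeric matrix of log-values.
#' @return numeric vector, one entry per row.
#' @keywords internal
logsumexp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  out <- mx + log(rowSums(exp(m - mx)))
  out[!is.finite(mx)] <- -Inf
  out
}

#' Derive a stage seed from a global seed
#'
#' Deterministic hash of `(seed, stage)` so that toggling one pipeline stage
#' never shifts another stage's random stream. Result is a valid 32-bit
#' integer seed.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- as.double(seed) %% 2147483647
  for (code in utf8ToInt(stage)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

# Inverse-CDF sampler for a truncated normal on [a, b].
rtruncnorm <- function(n, mean, sd, a = -Inf, b = Inf) {
  lo <- stats::pnorm(a, mean, sd)
  hi <- stats::pnorm(b, mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

# Draw from N(mu, Sigma) given a Cholesky factor of Sigma (upper triangular).
rmvnorm_chol <- function(n, mu, chol_sigma) {
  p <- length(mu)
  z <- matrix(stats::rnorm(n * p), n, p)
  sweep(z %*% chol_sigma, 2L, mu, "+")
}

# Project a symmetric matrix to the nearest positive semi-definite
# correlation matrix. Returns the projected matrix plus the max absolute
# adjustment applied.
nearest_corr <- function(m) {
  stopifnot(isSymmetric(m, tol = 1e-8))
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) >= -1e-10) {
    diag(m) <- 1
    return(list(corr = m, adjustment = 0))
  }
  pd <- Matrix::nearPD(m, corr = TRUE, do2eigen = TRUE)
  out <- as.matrix(pd$mat)
  list(corr = out, adjustment = max(abs(out - m)))
}
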