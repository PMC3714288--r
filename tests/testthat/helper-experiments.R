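# Shared fixtures: the recovery experiment (default synthetic cohorts,
# unconditional 2-class fits) is computed once per session and reused by
# the module and acceptance tests.

.exp_cache <- new.env(parent = emptyenv())

recovery_fits <- function(n_seeds = 25L) {
  key <- paste0("rec", n_seeds)
  if (is.null(.exp_cache[[key]])) {
    params <- default_params()
    .exp_cache[[key]] <- lapply(seq_len(n_seeds), function(s) {
      cohort <- simulate_cohort(params, seed = s)
      X <- standardize(cohort)
      fit <- fit_lpa(X, 2L, seed = s)
      list(cohort = cohort, X = X, fit = fit)
    })
  }
  .exp_cache[[key]]
}

conditional_fits <- function(n_seeds = 25L) {
  key <- paste0("cond", n_seeds)
  if (is.null(.exp_cache[[key]])) {
    params <- default_params()
    .exp_cache[[key]] <- lapply(seq_len(n_seeds), function(s) {
      cohort <- simulate_cohort(params, seed = s)
      cohort <- apply_missingness(cohort, params, seed = 10000L + s)
      X <- standardize(cohort)
      fit <- suppressWarnings(fit_conditional(
        X, cohort[, c("age", "education", "ethnicity", "apoe4")],
        seed = s, se = FALSE))
      list(fit = fit)
    })
  }
  .exp_cache[[key]]
}

# Tiny two-class 1-indicator dataset with well-separated point clusters,
# for comparing EM against an exhaustive grid-search oracle.
toy_two_cluster <- function(n1 = 12L, n2 = 8L, c = 4) {
  matrix(c(rnorm(n1, -c, 0.3), rnorm(n2, c, 0.3)), ncol = 1,
         dimnames = list(NULL, "y"))
}

# Naive mixture log-likelihood oracle: direct density summation over
# observed cells, no log-sum-exp tricks.
naive_mixture_loglik <- function(x, pi_k, mu, s2) {
  n <- nrow(x)
  out <- 0
  for (i in seq_len(n)) {
    dens <- 0
    for (k in seq_along(pi_k)) {
      prod_k <- pi_k[k]
      for (j in seq_len(ncol(x))) {
        if (!is.na(x[i, j])) {
          prod_k <- prod_k * stats::dnorm(x[i, j], mu[k, j],
                                          sqrt(s2[k, j]))
        }
      }
      dens <- dens + prod_k
    }
    out <- out + log(dens)
  }
  unname(out)
}
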