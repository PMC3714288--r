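# Class enumeration: parametric bootstrap likelihood-ratio test comparing
# K-1 vs K classes, and the enumeration table combining BIC, relative
# entropy, the BLRT p-value and the minimum-class-size rule.

# Fit helper used inside the BLRT: includes one deterministic "nested"
# start built by duplicating a component of the (K-1)-class solution, which
# guarantees loglik(K) >= loglik(K-1).
.fit_with_nested_start <- function(x, K, smaller, n_starts, tol, max_iter,
                                   variance) {
  Xrm <- .as_risk_matrix(x)
  fit <- fit_lpa(Xrm, K, n_starts = n_starts, tol = tol,
                 max_iter = max_iter, variance = variance)
  mask <- is.finite(Xrm$x)
  split_k <- which.max(smaller$pi)
  pi0 <- c(smaller$pi, smaller$pi[split_k] / 2)
  pi0[split_k] <- pi0[split_k] / 2
  mu0 <- rbind(smaller$mu, smaller$mu[split_k, ])
  s20 <- rbind(smaller$sigma2, smaller$sigma2[split_k, ])
  nested <- .lpa_em(Xrm$x, mask, pi0, mu0, s20, variance, tol, max_iter)
  if (!nested$empty && nested$loglik > fit$loglik) {
    fit$pi <- nested$pi; fit$mu <- nested$mu; fit$sigma2 <- nested$sigma2
    fit$loglik <- nested$loglik
    post <- .posterior_matrix(fit, Xrm$x, mask)
    om <- order_classes(fit, post)
    fit <- om$model
    fit$posterior <- om$posterior
    fit$labels <- .modal_labels(om$posterior)
  }
  fit
}

#' Parametric bootstrap likelihood-ratio test for K vs K-1 classes
#'
#' The observed statistic is `LR = 2 (loglik_K - loglik_{K-1})`. Its null
#' distribution is built by simulating `B` datasets from the fitted
#' (K-1)-class model — with matching n and missingness pattern — and
#' refitting both models to each; `p = (1 + #\{LR_b >= LR\}) / (B + 1)`.
#' The K-class fit always includes a start nested in the (K-1)-class
#' solution, so `LR >= 0` by construction.
#'
#' @param X a `risk_matrix` or matrix.
#' @param K the larger class count (>= 2).
#' @param B bootstrap replicates (>= 19).
#' @param seed RNG seed.
#' @param n_starts random starts for the outer fits.
#' @param inner_starts random starts for each bootstrap refit (smaller for
#'   speed; the nested start is always added).
#' @param variance variance structure, as in [fit_lpa()].
#' @param tol,max_iter EM controls for refits.
#' @return list with `LR`, `p_value`, `B`, `loglik_K`, `loglik_Km1`,
#'   `LR_boot`, and the two fitted models.
#' @export
bootstrap_lrt <- function(X, K, B = 99L, seed = 1L, n_starts = 20L,
                          inner_starts = 5L,
                          variance = c("invariant", "varying"),
                          tol = 1e-6, max_iter = 500L) {
  variance <- match.arg(variance)
  if (K < 2L) stop("K must be >= 2")
  if (B < 19L) stop("B must be >= 19")
  X <- .as_risk_matrix(X)
  mask <- is.finite(X$x)
  set.seed(seed)

  fit_small <- fit_lpa(X, K - 1L, n_starts = n_starts, tol = tol,
                       max_iter = max_iter, variance = variance)
  fit_big <- .fit_with_nested_start(X, K, fit_small, n_starts, tol,
                                    max_iter, variance)
  LR <- 2 * (fit_big$loglik - fit_small$loglik)
  if (LR < -1e-6) stop("negative LR despite nested start; EM failure")
  LR <- max(LR, 0)

  LR_boot <- rep(NA_real_, B)
  failures <- 0L
  for (b in seq_len(B)) {
    yb <- simulate.lpa(fit_small, n = nrow(X$x), mask = mask)
    res <- tryCatch({
      fs <- fit_lpa(yb, K - 1L, n_starts = inner_starts, tol = tol,
                    max_iter = max_iter, variance = variance)
      fb <- .fit_with_nested_start(yb, K, fs, inner_starts, tol, max_iter,
                                   variance)
      max(2 * (fb$loglik - fs$loglik), 0)
    }, error = function(e) NA_real_, warning = function(w) {
      # collapsed or non-converged inner fits count as failures only if
      # they error; warnings are tolerated
      tryCatch(suppressWarnings({
        fs <- fit_lpa(yb, K - 1L, n_starts = inner_starts, tol = tol,
                      max_iter = max_iter, variance = variance)
        fb <- .fit_with_nested_start(yb, K, fs, inner_starts, tol,
                                     max_iter, variance)
        max(2 * (fb$loglik - fs$loglik), 0)
      }), error = function(e) NA_real_)
    })
    if (is.na(res)) failures <- failures + 1L
    LR_boot[b] <- res
  }
  if (failures > 0.10 * B) {
    stop(sprintf("bootstrap LRT aborted: %d/%d inner fits failed",
                 failures, B))
  }
  p <- (1 + sum(LR_boot >= LR, na.rm = TRUE)) / (B + 1)
  list(K = K, LR = LR, p_value = p, B = B, n_failures = failures,
       loglik_K = fit_big$loglik, loglik_Km1 = fit_small$loglik,
       LR_boot = LR_boot, fit_K = fit_big, fit_Km1 = fit_small)
}

#' Enumerate latent classes
#'
#' Fits models with 1..`K_max` classes and reports log-likelihood,
#' parameter count, BIC, relative entropy and (optionally) the bootstrap
#' LRT p-value per step. The selected solution is the smallest K whose
#' (K+1 vs K) test is non-significant at `alpha`, subject to every class
#' holding at least `min_class_frac` of the sample; the full table is
#' returned so the selection can be overridden on interpretability grounds.
#'
#' @param X a `risk_matrix` or matrix.
#' @param K_max largest class count to consider (>= 2).
#' @param B bootstrap LRT replicates; `B = 0` skips the test and selection
#'   falls back to the BIC minimum among admissible models.
#' @param alpha significance level for the LRT stopping rule.
#' @param min_class_frac minimum admissible class share (default 5%).
#' @param entropy_drop maximum tolerated fall in relative entropy when
#'   moving to a richer solution: a significant (K+1 vs K) test is honored
#'   only if the (K+1)-class entropy is no more than this much below the
#'   K-class entropy (classification quality must stay acceptable).
#' @param n_starts,seed,variance as in [fit_lpa()].
#' @return list of class `lpa_enumeration`: `table` (data frame),
#'   `selected_K`, `rationale`, `fits`.
#' @export
enumerate_classes <- function(X, K_max = 3L, B = 99L, alpha = 0.05,
                              min_class_frac = 0.05, entropy_drop = 0.1,
                              n_starts = 50L, seed = 1L,
                              variance = c("invariant", "varying")) {
  variance <- match.arg(variance)
  if (K_max < 2L) stop("K_max must be >= 2")
  X <- .as_risk_matrix(X)
  set.seed(seed)
  fits <- vector("list", K_max)
  rows <- vector("list", K_max)
  blrt_p <- rep(NA_real_, K_max)
  for (K in seq_len(K_max)) {
    fits[[K]] <- fit_lpa(X, K, n_starts = n_starts, variance = variance)
    if (K >= 2L && B > 0L) {
      bl <- bootstrap_lrt(X, K, B = B, seed = derive_seed(seed,
                                                          paste0("blrt", K)),
                          n_starts = n_starts, variance = variance)
      blrt_p[K] <- bl$p_value
      # keep the better of the two big-model fits
      if (bl$fit_K$loglik > fits[[K]]$loglik) fits[[K]] <- bl$fit_K
    }
    m <- fits[[K]]
    rows[[K]] <- data.frame(
      K = K, loglik = m$loglik, q = m$q, BIC = bic(m),
      entropy = if (K >= 2L) relative_entropy(m$posterior) else NA_real_,
      min_class_share = min(m$pi),
      blrt_p = blrt_p[K])
  }
  tab <- do.call(rbind, rows)

  admissible <- tab$min_class_share >= min_class_frac | tab$K == 1L
  selected <- NA_integer_
  rationale <- ""
  if (B > 0L) {
    # walk upward from K = 1; a significant (K+1 vs K) test is honored
    # only if the richer solution keeps every class above the minimum
    # share and does not degrade classification entropy unacceptably
    selected <- 1L
    rationale <- "no significant improvement over 1 class"
    while (selected < K_max) {
      nxt <- selected + 1L
      sig <- !is.na(tab$blrt_p[nxt]) && tab$blrt_p[nxt] <= alpha
      ent_ok <- is.na(tab$entropy[selected]) ||
        tab$entropy[nxt] >= tab$entropy[selected] - entropy_drop
      if (sig && admissible[nxt] && ent_ok) {
        selected <- nxt
        rationale <- sprintf(
          "bootstrap LRT favors %d over %d classes (p = %.3g)",
          nxt, nxt - 1L, tab$blrt_p[nxt])
      } else {
        rationale <- if (!sig) {
          sprintf("(%d vs %d)-class bootstrap LRT non-significant (p = %.3g)",
                  nxt, selected, tab$blrt_p[nxt])
        } else if (!admissible[nxt]) {
          sprintf("%d-class solution holds a class below %.0f%%",
                  nxt, 100 * min_class_frac)
        } else {
          sprintf("%d-class entropy %.3f degrades classification (vs %.3f)",
                  nxt, tab$entropy[nxt], tab$entropy[selected])
        }
        break
      }
    }
  }
  if (is.na(selected)) {
    cand <- which(admissible)
    selected <- cand[which.min(tab$BIC[cand])]
    rationale <- "BIC minimum among admissible class counts"
  }
  structure(list(table = tab, selected_K = selected,
                 rationale = rationale, fits = fits),
            class = "lpa_enumeration")
}

#' @export
print.lpa_enumeration <- function(x, ...) {
  cat("Latent class enumeration\n")
  print(transform(x$table, loglik = round(loglik, 1), BIC = round(BIC, 1),
                  entropy = round(entropy, 3),
                  min_class_share = round(min_class_share, 3)),
        row.names = FALSE)
  cat(sprintf("selected K = %d (%s)\n", x$selected_K, x$rationale))
  invisible(x)
}
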