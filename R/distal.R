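# Distal-outcome stage: class-specific means of the cognitive factor
# scores with a Wald chi-square equality test (the chi-square analog of a
# one-way F test), and the post-hoc regression of each outcome on the
# posterior probability of high-risk membership adjusting for age and
# education.

#' Class-specific outcome means and standard errors
#'
#' With modal labels (`weights = NULL`): ordinary per-class means and
#' standard errors. With posterior weights: posterior-weighted means
#' \eqn{m_k = \sum_i p_{ik} y_i / \sum_i p_{ik}} with linearized standard
#' errors.
#'
#' @param classes integer modal labels (1..K), or `NULL` when `weights`
#'   are supplied.
#' @param y outcome vector; `NA`s are dropped pairwise.
#' @param weights optional n x K posterior matrix.
#' @return data frame with `class`, `mean`, `se`, `n`.
#' @export
class_outcome_means <- function(classes, y, weights = NULL) {
  if (is.null(weights)) {
    keep <- !is.na(y) & !is.na(classes)
    y <- y[keep]; classes <- classes[keep]
    K <- max(classes)
    cnt <- tabulate(classes, K)
    if (any(cnt < 2L)) stop("need >= 2 observed subjects per class")
    m <- tapply(y, classes, mean)
    s <- tapply(y, classes, stats::sd) / sqrt(cnt)
    data.frame(class = seq_len(K), mean = as.vector(m), se = as.vector(s),
               n = cnt)
  } else {
    weights <- as.matrix(weights)
    keep <- !is.na(y) & stats::complete.cases(weights)
    y <- y[keep]; W <- weights[keep, , drop = FALSE]
    K <- ncol(W)
    wsum <- colSums(W)
    if (any(wsum < 2)) stop("effective class size below 2")
    m <- as.vector(crossprod(W, y)) / wsum
    # linearized variance of a ratio estimator with fixed weights
    se <- vapply(seq_len(K), function(k) {
      r <- W[, k] * (y - m[k])
      sqrt(sum(r^2)) / wsum[k]
    }, 1)
    data.frame(class = seq_len(K), mean = m, se = se, n = wsum)
  }
}

#' Wald equality test of two class means
#'
#' \eqn{\chi^2 = (m_1 - m_2)^2 / (SE_1^2 + SE_2^2)} on 1 df, the
#' chi-square analog of a two-group F test.
#'
#' @param means length-2 vector of class means (or the data frame from
#'   [class_outcome_means()]).
#' @param ses length-2 vector of standard errors.
#' @return list with `chisq`, `df`, `p_value`, and `infinite` flag for the
#'   degenerate zero-SE case.
#' @export
wald_equality_test <- function(means, ses) {
  if (is.data.frame(means)) {
    ses <- means$se; means <- means$mean
  }
  if (length(means) != 2L) stop("the Wald equality test requires K = 2")
  v <- sum(ses^2)
  if (v == 0) {
    if (means[1] == means[2]) {
      return(list(chisq = 0, df = 1L, p_value = 1, infinite = FALSE))
    }
    return(list(chisq = Inf, df = 1L, p_value = 0, infinite = TRUE))
  }
  chisq <- (means[1] - means[2])^2 / v
  list(chisq = chisq, df = 1L,
       p_value = stats::pchisq(chisq, 1L, lower.tail = FALSE),
       infinite = FALSE)
}

#' Regression of an outcome on the posterior high-risk probability
#'
#' Least-squares fit of `y` on `P(high-risk)` plus covariates (age,
#' education by default), the post-hoc sensitivity analysis for the
#' class--outcome association. Complete rows only.
#'
#' @param y outcome vector.
#' @param p_high posterior probability of high-risk membership.
#' @param covariates optional data frame of adjustment covariates.
#' @return list of class `posterior_regression` with the `p_high`
#'   coefficient, its SE and p-value, the covariate coefficient table, and
#'   `n`.
#' @export
posterior_regression <- function(y, p_high, covariates = NULL) {
  df <- data.frame(y = y, p_high = p_high)
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  df <- df[stats::complete.cases(df), , drop = FALSE]
  X <- stats::model.matrix(~ ., df[, -1, drop = FALSE])
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("collinear design; offending columns: ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::lm(y ~ ., data = df)
  sm <- summary(fit)$coefficients
  structure(list(
    coefficient = sm["p_high", "Estimate"],
    se = sm["p_high", "Std. Error"],
    p_value = sm["p_high", "Pr(>|t|)"],
    covariate_coefs = sm[!rownames(sm) %in% c("p_high"), , drop = FALSE],
    n = nrow(df), fit = fit
  ), class = "posterior_regression")
}

#' @export
print.posterior_regression <- function(x, ...) {
  cat(sprintf(
    "P(high-risk) coefficient = %.4f (SE %.4f), p = %.4g, n = %d\n",
    x$coefficient, x$se, x$p_value, x$n))
  invisible(x)
}

#' Run the distal-outcome suite over the five cognitive factors
#'
#' For each outcome column: class-specific means with the Wald equality
#' test (modal assignment by default, posterior weighting optionally), and
#' the posterior-probability regression adjusted for the supplied
#' covariates. Flags outcomes significant at `alpha` (unadjusted; a
#' Bonferroni column is printed for transparency but not used for flags).
#'
#' @param scores data frame or matrix of outcomes (columns = factors).
#' @param posterior n x 2 posterior matrix from the class model.
#' @param covariates data frame with `age` and `education` for the
#'   regression adjustment.
#' @param weighting `"modal"` (default) or `"posterior"` for the
#'   class-mean stage.
#' @param alpha flagging level.
#' @return data frame of class `distal_suite` with one row per outcome,
#'   plus a list-attribute `details` carrying the per-outcome results.
#' @export
run_distal_suite <- function(scores, posterior, covariates = NULL,
                             weighting = c("modal", "posterior"),
                             alpha = 0.05) {
  weighting <- match.arg(weighting)
  scores <- as.data.frame(scores)
  posterior <- as.matrix(posterior)
  if (nrow(scores) != nrow(posterior)) {
    stop("scores and posterior are misaligned")
  }
  labels <- .modal_labels(posterior)
  details <- vector("list", ncol(scores))
  names(details) <- colnames(scores)
  rows <- vector("list", ncol(scores))
  for (j in seq_along(scores)) {
    y <- scores[[j]]
    cm <- if (weighting == "modal") {
      class_outcome_means(labels, y)
    } else {
      class_outcome_means(NULL, y, weights = posterior)
    }
    wt <- wald_equality_test(cm)
    pr <- posterior_regression(y, posterior[, 2], covariates)
    details[[j]] <- list(class_means = cm, wald = wt, regression = pr)
    rows[[j]] <- data.frame(
      outcome = colnames(scores)[j],
      mean_low = cm$mean[1], mean_high = cm$mean[2],
      wald_chisq = wt$chisq, wald_p = wt$p_value,
      regression_coef = pr$coefficient, regression_p = pr$p_value,
      n = sum(cm$n))
  }
  tab <- do.call(rbind, rows)
  tab$significant <- tab$wald_p < alpha
  tab$bonferroni_p <- pmin(tab$wald_p * nrow(tab), 1)
  attr(tab, "details") <- details
  attr(tab, "weighting") <- weighting
  class(tab) <- c("distal_suite", "data.frame")
  tab
}

#' @export
print.distal_suite <- function(x, digits = 4, ...) {
  cat(sprintf("Distal cognitive outcomes by latent class (%s assignment)\n",
              attr(x, "weighting")))
  cols <- c("outcome", "mean_low", "mean_high", "wald_chisq", "wald_p",
            "regression_p", "significant")
  print.data.frame(cbind(x["outcome"],
                         round(x[, setdiff(cols, "outcome")[-6]], digits),
                         significant = x$significant), row.names = FALSE)
  invisible(x)
}
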