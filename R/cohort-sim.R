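# Synthetic cohort generator emulating the baseline structure of a
# multisite cohort of recently menopausal women: a two-class Gaussian
# mixture over seven vascular-risk indicators, demographic/genetic
# covariates steering class membership through a logistic concomitant
# model, bi-factor-structured cognitive scores with class-dependent means,
# and MAR missingness on covariates and cognitive outcomes.

INDICATORS <- c("bmi", "cimt", "ldl", "hdl", "triglycerides", "fbg", "fps")
FACTORS <- c("global", "verbal", "auditory", "visual", "speeded")
ETHNICITIES <- c("non-Hispanic White", "non-Hispanic Black", "Hispanic")

# Pooled zero-order correlations among the seven indicators (calibration
# target for the within-class correlation).
.pooled_corr_target <- function() {
  r <- diag(7)
  dimnames(r) <- list(INDICATORS, INDICATORS)
  # column-major lower triangle: correlations of each variable with bmi,
  # then cimt, ldl, hdl, triglycerides, fbg
  lower <- c(
    0.057, 0.157, -0.336, 0.330, 0.276, 0.376,   # with bmi
    0.030, -0.046, 0.073, -0.018, 0.152,         # with cimt
    -0.129, 0.231, 0.068, 0.399,                 # with ldl
    -0.486, -0.200, -0.485,                      # with hdl
    0.214, 0.458,                                # with triglycerides
    0.238                                        # with fbg
  )
  r[lower.tri(r)] <- lower
  r[upper.tri(r)] <- t(r)[upper.tri(r)]
  r
}

.params_cache <- new.env(parent = emptyenv())

#' Default generator parameters
#'
#' Returns the calibrated default `cvlpa_params`: two latent risk classes at
#' 62%/38% prevalence with the published class-conditional indicator means
#' and SDs, concomitant log-odds for age, education, ethnicity and APOE4,
#' covariate marginals matching the cohort's baseline table, cognitive
#' class-mean shifts on the speeded-language and global factors, a shared
#' within-class correlation solved from the pooled correlation targets, and
#' a 22% subject-level missingness rate.
#'
#' @param calibrate if `TRUE` (default) the within-class correlation matrix
#'   and the concomitant intercept are calibrated; the calibrated result is
#'   cached for the session.
#' @return an object of class `cvlpa_params`.
#' @examples
#' p <- default_params()
#' p$class_prevalence
#' @export
default_params <- function(calibrate = TRUE) {
  key <- if (calibrate) "calibrated" else "raw"
  if (!is.null(.params_cache[[key]])) return(.params_cache[[key]])

  means <- rbind(
    low  = c(24.80, 0.70, 121.89, 74.13,  66.73, 87.31, 2.16),
    high = c(28.97, 0.74, 138.35, 51.22, 129.26, 92.73, 6.89))
  sds <- rbind(
    low  = c(3.88, 0.07, 28.91, 15.20, 25.74, 8.46, 2.25),
    high = c(3.73, 0.10, 28.23,  9.80, 60.24, 9.78, 2.14))
  colnames(means) <- colnames(sds) <- INDICATORS

  cog <- rbind(low  = c(0.072, 0, 0, 0, 0.068),
               high = c(-0.110, 0, 0, 0, -0.139))
  colnames(cog) <- FACTORS

  eth_p <- c(0.80490, 0.07803, 0.07659)
  eth_p <- eth_p / sum(eth_p)

  params <- structure(list(
    n_subjects = 727L,
    class_prevalence = c(low = 0.62, high = 0.38),
    class_indicator_means = means,
    class_indicator_sds = sds,
    within_class_corr = diag(7),
    corr_adjustment = 0,
    concomitant_coefs = c(intercept = NA_real_,
                          age = log(1.140),
                          education = log(0.627),
                          ethnicity_black = log(0.951),
                          ethnicity_hispanic = log(2.621),
                          apoe4 = log(1.521)),
    covariate_dists = list(
      age = list(mean = 52.68, sd = 2.60, lower = 42, upper = 58),
      education = 0.735,
      ethnicity = stats::setNames(eth_p, ETHNICITIES),
      apoe4 = 0.262),
    cognitive_class_means = cog,
    factor_score_sds = stats::setNames(c(0.88, 0.87, 0.75, 0.73, 0.79),
                                       FACTORS),
    bifactor_loadings = NULL,   # filled below from the default structure
    missing_rate = 0.22,
    fps_mode = "direct",
    seed = 1L
  ), class = "cvlpa_params")

  bs <- default_bifactor_structure()
  params$bifactor_loadings <- bs$loadings
  params$bifactor_residuals <- bs$residuals
  params$bifactor_structure <- bs

  if (calibrate) {
    params <- calibrate_correlations(params, .pooled_corr_target())
    params <- calibrate_intercept(params)
  }
  validate_params(params)
  .params_cache[[key]] <- params
  params
}

#' Validate generator parameters
#'
#' Checks the structural invariants of a `cvlpa_params` object: prevalences
#' positive and summing to one, a symmetric positive semi-definite unit
#' diagonal within-class correlation, approximately centered cognitive
#' class means, and a properly structured bi-factor loading matrix.
#'
#' @param params a `cvlpa_params` object.
#' @return `params`, invisibly, if valid; otherwise an error.
#' @export
validate_params <- function(params) {
  stopifnot(inherits(params, "cvlpa_params"))
  pr <- params$class_prevalence
  if (any(pr <= 0) || abs(sum(pr) - 1) > 1e-12) {
    stop("class_prevalence must be positive and sum to 1")
  }
  w <- params$within_class_corr
  if (!isSymmetric(w, tol = 1e-8) || any(abs(diag(w) - 1) > 1e-8)) {
    stop("within_class_corr must be symmetric with unit diagonal")
  }
  if (min(eigen(w, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("within_class_corr must be positive semi-definite")
  }
  # Factor scores are centered overall; the printed class means leave a
  # small residual imbalance, so centering is enforced loosely.
  cen <- drop(pr %*% params$cognitive_class_means)
  if (any(abs(cen) > 0.02)) {
    stop("prevalence-weighted cognitive class means must be ~0 (|.| <= 0.02)")
  }
  L <- params$bifactor_loadings
  if (!is.null(L)) {
    if (any(L[, 1] == 0)) stop("general factor must load on all indicators")
    spec <- L[, -1, drop = FALSE] != 0
    if (any(rowSums(spec) != 1L)) {
      stop("each indicator must load on exactly one specific factor")
    }
  }
  invisible(params)
}

#' Calibrate the concomitant intercept
#'
#' Adjusts the intercept of the logistic concomitant model by root-finding
#' on the Monte-Carlo-integrated marginal so that the expected probability
#' of high-risk membership over the covariate distribution matches the
#' target class prevalence.
#'
#' @param params a `cvlpa_params` object with slopes and covariate
#'   marginals set.
#' @param tol tolerance on the marginal prevalence (default 1e-4).
#' @param mc_n Monte-Carlo sample size for the marginal integral.
#' @return `params` with the calibrated intercept.
#' @export
calibrate_intercept <- function(params, tol = 1e-4, mc_n = 200000L) {
  stopifnot(inherits(params, "cvlpa_params"))
  target <- unname(params$class_prevalence["high"])
  co <- params$concomitant_coefs
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(derive_seed(20130717L, "calibrate_intercept"))
  X <- .draw_covariates(mc_n, params)
  eta <- .concomitant_lp(X, co, include_intercept = FALSE)

  f <- function(b0) mean(stats::plogis(b0 + eta)) - target
  sol <- tryCatch(
    stats::uniroot(f, c(-40, 20), tol = tol / 10, maxiter = 200L),
    error = function(e) stop("intercept calibration failed: ",
                             conditionMessage(e)))
  params$concomitant_coefs["intercept"] <- sol$root
  if (abs(f(sol$root)) > tol) stop("intercept calibration did not converge")
  params
}

#' Calibrate the shared within-class correlation
#'
#' Solves, per indicator pair, the mixture-moment identity
#' \deqn{\mathrm{cov}_{pool} = \sum_k \pi_k \rho_w \sigma_{jk}\sigma_{lk}
#'   + \sum_k \pi_k (\mu_{jk}-\bar\mu_j)(\mu_{lk}-\bar\mu_l)}
#' for the shared within-class correlation \eqn{\rho_w} that reproduces a
#' target pooled correlation, then projects the matrix to the nearest
#' positive semi-definite correlation matrix if needed.
#'
#' @param params a `cvlpa_params` object with class moments set.
#' @param target_pooled_corr 7x7 target pooled correlation matrix.
#' @return `params` with `within_class_corr` set and `corr_adjustment`
#'   recording the max absolute PSD-projection adjustment.
#' @export
calibrate_correlations <- function(params,
                                   target_pooled_corr = .pooled_corr_target()) {
  stopifnot(inherits(params, "cvlpa_params"))
  pi_k <- params$class_prevalence
  mu <- params$class_indicator_means
  sd_k <- params$class_indicator_sds
  p <- ncol(mu)
  mu_bar <- drop(pi_k %*% mu)
  dev <- sweep(mu, 2L, mu_bar)             # K x p deviations
  between <- t(dev) %*% (pi_k * dev)       # p x p between-class covariance
  within_scale <- t(sd_k) %*% (pi_k * sd_k)  # sum_k pi_k sigma_jk sigma_lk
  pooled_var <- drop(pi_k %*% sd_k^2) + diag(between)

  rho_w <- diag(p)
  for (j in seq_len(p - 1)) {
    for (l in seq((j + 1), p)) {
      cov_target <- target_pooled_corr[j, l] *
        sqrt(pooled_var[j] * pooled_var[l])
      r <- (cov_target - between[j, l]) / within_scale[j, l]
      if (abs(r) >= 1) {
        stop(sprintf(
          "infeasible within-class correlation for pair (%s, %s): %.3f",
          INDICATORS[j], INDICATORS[l], r))
      }
      rho_w[j, l] <- rho_w[l, j] <- r
    }
  }
  proj <- nearest_corr(rho_w)
  params$within_class_corr <- proj$corr
  dimnames(params$within_class_corr) <- dimnames(target_pooled_corr)
  params$corr_adjustment <- proj$adjustment
  params
}

# Covariate draws from the marginal distributions: data.frame with age,
# education (0/1), ethnicity (factor), apoe4 (0/1).
.draw_covariates <- function(n, params) {
  cd <- params$covariate_dists
  data.frame(
    age = rtruncnorm(n, cd$age$mean, cd$age$sd, cd$age$lower, cd$age$upper),
    education = stats::rbinom(n, 1L, cd$education),
    ethnicity = factor(
      sample(ETHNICITIES, n, replace = TRUE, prob = cd$ethnicity),
      levels = ETHNICITIES),
    apoe4 = stats::rbinom(n, 1L, cd$apoe4)
  )
}

# Linear predictor of the concomitant logistic model for the high-risk
# class.
.concomitant_lp <- function(X, coefs, include_intercept = TRUE) {
  lp <- coefs["age"] * X$age +
    coefs["education"] * X$education +
    coefs["ethnicity_black"] * (X$ethnicity == "non-Hispanic Black") +
    coefs["ethnicity_hispanic"] * (X$ethnicity == "Hispanic") +
    coefs["apoe4"] * X$apoe4
  if (include_intercept) lp <- lp + coefs["intercept"]
  unname(lp)
}

#' Simulate a synthetic cohort
#'
#' Draws covariates from their marginals, latent risk class from the
#' logistic concomitant model, the seven indicators from the
#' class-conditional multivariate normal (shared within-class correlation),
#' blood pressure / total cholesterol / smoking consistently with the
#' class's risk level, five class-mean-shifted cognitive factor scores, and
#' eighteen test scores from the bi-factor measurement model. Returns a
#' complete table; apply [apply_missingness()] afterwards.
#'
#' @param params a calibrated `cvlpa_params` object.
#' @param n number of subjects (default `params$n_subjects`).
#' @param seed RNG seed (default `params$seed`).
#' @return a `data.frame` of class `cvlpa_cohort`; `true_class` retains the
#'   generating label and is excluded from analysis inputs.
#' @export
simulate_cohort <- function(params = default_params(),
                            n = params$n_subjects, seed = params$seed) {
  validate_params(params)
  K <- length(params$class_prevalence)
  if (n < 2L * K) stop("degenerate cohort: need n >= ", 2L * K)
  if (is.na(params$concomitant_coefs["intercept"])) {
    stop("params not calibrated: run calibrate_intercept() first")
  }
  set.seed(seed)

  X <- .draw_covariates(n, params)
  p_high <- stats::plogis(.concomitant_lp(X, params$concomitant_coefs))
  cls <- 1L + stats::rbinom(n, 1L, p_high)   # 1 = low, 2 = high

  # Class-conditional indicators with shared within-class correlation.
  R <- params$within_class_corr
  cR <- chol(R)
  Y <- matrix(NA_real_, n, 7, dimnames = list(NULL, INDICATORS))
  for (k in 1:2) {
    idx <- which(cls == k)
    if (!length(idx)) next
    z <- matrix(stats::rnorm(length(idx) * 7), ncol = 7) %*% cR
    Y[idx, ] <- sweep(sweep(z, 2L, params$class_indicator_sds[k, ], "*"),
                      2L, params$class_indicator_means[k, ], "+")
  }
  # Physiological floors; affects a negligible fraction of draws.
  for (cn in c("bmi", "cimt", "ldl", "hdl", "triglycerides", "fbg")) {
    Y[, cn] <- pmax(Y[, cn], 0.01)
  }

  # Blood pressure, total cholesterol, smoking: class-conditional draws
  # whose prevalence-weighted moments match the baseline table.
  sbp_m <- c(113, 124.5); dbp_m <- c(73, 79); tc_m <- c(200, 221)
  smoke_p <- c(0.042, 0.115)
  sbp <- stats::rnorm(n, sbp_m[cls], 13.5)
  dbp <- stats::rnorm(n, dbp_m[cls], 8.5)
  dbp <- pmin(dbp, sbp - 5)
  tc <- stats::rnorm(n, tc_m[cls], 32)
  smoker <- stats::rbinom(n, 1L, smoke_p[cls])

  fps <- if (identical(params$fps_mode, "derived")) {
    framingham_points(X$age, tc, Y[, "hdl"], sbp, dbp, smoker)
  } else {
    as.integer(round(Y[, "fps"]))
  }

  # Cognitive factor scores: class-shifted, scaled to the published
  # factor-score SDs; then 18 test scores from the bi-factor model on the
  # unit-variance factor metric.
  eta <- matrix(NA_real_, n, 5, dimnames = list(NULL, FACTORS))
  for (f in seq_along(FACTORS)) {
    eta[, f] <- stats::rnorm(n, params$cognitive_class_means[cls, f],
                             params$factor_score_sds[f])
  }
  eta_std <- sweep(eta, 2L, params$factor_score_sds, "/")
  L <- params$bifactor_loadings
  theta <- params$bifactor_residuals
  tests <- eta_std %*% t(L) +
    matrix(stats::rnorm(n * nrow(L)), n) %*% diag(sqrt(theta))
  colnames(tests) <- rownames(L)

  out <- data.frame(
    subject_id = seq_len(n),
    X,
    true_class = factor(c("low", "high")[cls], levels = c("low", "high")),
    as.data.frame(Y[, INDICATORS != "fps", drop = FALSE]),
    fps = fps,
    sbp = sbp, dbp = dbp, total_cholesterol = tc, smoker = smoker,
    stats::setNames(as.data.frame(eta), paste0("fs_", FACTORS)),
    as.data.frame(tests),
    check.names = FALSE
  )
  class(out) <- c("cvlpa_cohort", "data.frame")
  attr(out, "seed") <- seed
  out
}

#' Apply MAR missingness to a cohort
#'
#' Each subject's probability of carrying missing cells depends only on the
#' always-observed covariates age and education (missing at random). Cells
#' are blanked among APOE4, ethnicity and the cognitive block; the seven
#' risk indicators are never made missing. The expected fraction of
#' subjects with at least one missing cell equals `params$missing_rate`.
#'
#' @param cohort a complete `cvlpa_cohort`.
#' @param params a `cvlpa_params` object.
#' @param seed RNG seed.
#' @return the cohort with `NA` cells inserted.
#' @export
apply_missingness <- function(cohort, params = default_params(),
                              seed = attr(cohort, "seed") + 1L) {
  rate <- params$missing_rate
  if (rate < 0 || rate >= 1) stop("missing_rate must be in [0, 1)")
  if (rate == 0) return(cohort)
  set.seed(seed)
  n <- nrow(cohort)

  # MAR: older and less-educated subjects are more likely to be incomplete;
  # the intercept is solved so the marginal rate matches.
  z_age <- (cohort$age - mean(cohort$age)) / stats::sd(cohort$age)
  lp <- 0.30 * z_age - 0.40 * cohort$education
  a <- stats::uniroot(function(a) mean(stats::plogis(a + lp)) - rate,
                      c(-20, 20))$root
  flagged <- stats::runif(n) < stats::plogis(a + lp)

  cog_cols <- c(paste0("fs_", FACTORS),
                rownames(default_bifactor_structure()$loadings))
  cog_cols <- intersect(cog_cols, names(cohort))
  for (i in which(flagged)) {
    drop_apoe <- stats::runif(1) < 0.80
    drop_cog <- stats::runif(1) < 0.45
    drop_eth <- stats::runif(1) < 0.15
    if (!drop_apoe && !drop_cog && !drop_eth) drop_apoe <- TRUE
    if (drop_apoe) cohort$apoe4[i] <- NA
    if (drop_eth) cohort$ethnicity[i] <- NA
    if (drop_cog) cohort[i, cog_cols] <- NA
  }
  cohort
}

#' @export
print.cvlpa_params <- function(x, ...) {
  cat("Synthetic cohort generator parameters\n")
  cat(sprintf("  n_subjects: %d   prevalence: %s\n", x$n_subjects,
              paste(sprintf("%s=%.2f", names(x$class_prevalence),
                            x$class_prevalence), collapse = " ")))
  cat(sprintf("  concomitant intercept: %s\n",
              ifelse(is.na(x$concomitant_coefs["intercept"]), "uncalibrated",
                     sprintf("%.3f", x$concomitant_coefs["intercept"]))))
  cat(sprintf("  within-class corr: HDL-trig = %.3f (PSD adjustment %.2g)\n",
              x$within_class_corr["hdl", "triglycerides"],
              x$corr_adjustment))
  cat(sprintf("  missing_rate: %.2f   fps_mode: %s\n",
              x$missing_rate, x$fps_mode))
  invisible(x)
}
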