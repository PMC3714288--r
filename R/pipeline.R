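# Orchestration: simulate or ingest a cohort, fit the measurement model,
# run class enumeration and the conditional model, test distal cognitive
# outcomes, and cross-validate with a random forest, with per-stage seeds
# derived from one global seed and a consolidated report.

.numeric_cohort_cols <- c("age", "education", "apoe4", INDICATORS,
                          "sbp", "dbp", "total_cholesterol", "smoker")

#' Read a cohort CSV
#'
#' Reads a cohort written by [write_cohort()] (UTF-8, header row, empty
#' string = missing). Unknown columns are preserved. Malformed numeric
#' cells raise an error naming the row and column.
#'
#' @param path CSV path.
#' @return a `cvlpa_cohort` data frame.
#' @export
read_cohort <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = "", check.names = FALSE,
                         fileEncoding = "UTF-8")
  if ("." %in% unlist(raw)) stop("'.' is not a valid missing-value token")
  out <- raw
  num_cols <- intersect(c(.numeric_cohort_cols,
                          paste0("fs_", FACTORS),
                          default_bifactor_structure()$indicators,
                          "subject_id"), names(raw))
  for (cn in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[cn]]))
    bad <- which(!is.na(raw[[cn]]) & is.na(v))
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' in column '%s', row %d",
                   raw[[cn]][bad[1]], cn, bad[1]))
    }
    out[[cn]] <- v
  }
  if ("ethnicity" %in% names(out)) {
    out$ethnicity <- factor(out$ethnicity, levels = ETHNICITIES)
  }
  if ("true_class" %in% names(out)) {
    out$true_class <- factor(out$true_class, levels = c("low", "high"))
  }
  class(out) <- c("cvlpa_cohort", "data.frame")
  out
}

#' Write a cohort CSV with a provenance sidecar
#'
#' UTF-8 CSV with a header row and the empty string as the missing-value
#' token, plus a JSON sidecar (`<path>.json`) recording the generator seed
#' and key parameters.
#'
#' @param cohort a `cvlpa_cohort`.
#' @param path output CSV path.
#' @param params optional `cvlpa_params` for the sidecar.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, params = NULL) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  sidecar <- list(seed = attr(cohort, "seed"), n = nrow(cohort))
  if (!is.null(params)) {
    sidecar$class_prevalence <- as.list(params$class_prevalence)
    sidecar$missing_rate <- params$missing_rate
    sidecar$concomitant_coefs <- as.list(params$concomitant_coefs)
  }
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Pipeline configuration
#'
#' @param input `NULL` to simulate a default cohort, or a cohort CSV path.
#' @param n subjects when simulating.
#' @param seed global seed; every stage derives its own stream from it.
#' @param stages character vector of stages to run, in dependency order.
#' @param K class count for the profile model.
#' @param K_max enumeration upper bound.
#' @param n_starts EM starts.
#' @param blrt_B bootstrap LRT replicates in enumeration (0 = skip BLRT).
#' @param n_tree,folds random-forest settings.
#' @param out_dir optional directory for artifacts.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, n = 727L, seed = 1L,
                            stages = c("simulate", "bifactor", "lpa",
                                       "conditional", "distal", "rf"),
                            K = 2L, K_max = 3L, n_starts = 50L,
                            blrt_B = 0L, n_tree = 1000L, folds = 10L,
                            out_dir = NULL) {
  allowed <- c("simulate", "enumerate", "bifactor", "lpa", "conditional",
               "distal", "rf")
  bad <- setdiff(stages, allowed)
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 4L, K >= 1L)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order — simulate/ingest,
#' bi-factor measurement model, latent profile model (optionally with
#' class enumeration), concomitant-covariate model, distal cognitive
#' outcomes, random-forest validation — persisting per-stage summaries in
#' a consolidated report. Deterministic under a fixed global seed.
#'
#' @param config a [pipeline_config()].
#' @return list of class `analysis_report` with one element per stage run.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  st <- config$stages
  report <- list(seed = config$seed, stages = st,
                 version = as.character(utils::packageVersion("cvlpa")),
                 warnings = character())
  note <- function(w) report$warnings <<- c(report$warnings, w)

  # --- cohort ---------------------------------------------------------
  params <- default_params()
  cohort <- if (!is.null(config$input)) {
    read_cohort(config$input)
  } else {
    cc <- simulate_cohort(params, n = config$n,
                          seed = derive_seed(config$seed, "simulate"))
    apply_missingness(cc, params, seed = derive_seed(config$seed,
                                                     "missingness"))
  }
  report$cohort <- list(n = nrow(cohort),
                        n_incomplete = sum(!stats::complete.cases(cohort)),
                        simulated = is.null(config$input))

  # --- bi-factor measurement model ------------------------------------
  scores <- NULL
  if ("bifactor" %in% st) {
    bs <- default_bifactor_structure()
    bf <- withCallingHandlers(
      fit_bifactor(cohort[, bs$indicators]),
      warning = function(w) { note(conditionMessage(w))
        invokeRestart("muffleWarning") })
    fi <- fit_indices(bf)
    fscores <- factor_scores(bf, cohort[, bs$indicators])
    scores <- matrix(NA_real_, nrow(cohort), ncol(fscores),
                     dimnames = list(NULL, colnames(fscores)))
    scores[attr(fscores, "rows"), ] <- fscores
    report$bifactor <- list(
      converged = bf$converged, n_used = bf$n, n_dropped = bf$n_dropped,
      fit_indices = unclass(fi)[c("T", "df", "CFI", "TLI", "RMSEA", "BIC")],
      loadings = bf$loadings)
  }

  # --- latent profile model -------------------------------------------
  X <- standardize(cohort)
  fit <- NULL
  if ("enumerate" %in% st) {
    en <- enumerate_classes(X, K_max = config$K_max, B = config$blrt_B,
                            n_starts = config$n_starts,
                            seed = derive_seed(config$seed, "enumerate"))
    report$enumeration <- list(table = en$table, selected_K = en$selected_K,
                               rationale = en$rationale)
    fit <- en$fits[[en$selected_K]]
  }
  if ("lpa" %in% st) {
    if (is.null(fit) || fit$K != config$K) {
      fit <- fit_lpa(X, config$K, n_starts = config$n_starts,
                     seed = derive_seed(config$seed, "lpa"))
    }
    raw_mu <- back_transform(X, fit$mu)
    report$lpa <- list(
      K = fit$K, prevalence = fit$pi, BIC = bic(fit),
      entropy = if (fit$K >= 2L) relative_entropy(fit$posterior)
                else NA_real_,
      class_means_std = fit$mu, class_means_raw = raw_mu,
      converged = fit$converged)
  }

  # --- conditional model ----------------------------------------------
  cond <- NULL
  if ("conditional" %in% st) {
    cond <- withCallingHandlers(
      fit_conditional(X, cohort[, c("age", "education", "ethnicity",
                                    "apoe4")],
                      n_starts = config$n_starts,
                      seed = derive_seed(config$seed, "conditional")),
      warning = function(w) { note(conditionMessage(w))
        invokeRestart("muffleWarning") })
    ors <- odds_ratios(cond)
    report$conditional <- list(
      odds_ratios = as.data.frame(ors),
      education_low_risk_or = attr(ors, "education_low_risk_or"),
      prevalence = report_prevalence(cond),
      entropy = relative_entropy(cond$posterior),
      BIC = bic(cond), converged = cond$converged)
  }

  # --- distal outcomes -------------------------------------------------
  if ("distal" %in% st && "lpa" %in% st) {
    y <- if (!is.null(scores)) {
      stats::setNames(as.data.frame(scores), paste0("fs_", FACTORS))
    } else {
      cohort[, paste0("fs_", FACTORS)]
    }
    ds <- run_distal_suite(y, fit$posterior,
                           covariates = cohort[, c("age", "education")])
    report$distal <- list(table = as.data.frame(ds),
                          scores = if (!is.null(scores)) "estimated"
                                   else "generator")
  }

  # --- random-forest validation ---------------------------------------
  if ("rf" %in% st && "lpa" %in% st) {
    rv <- rf_cross_validate(X, fit$labels,
                            rf_config(n_tree = config$n_tree,
                                      folds = config$folds,
                                      seed = derive_seed(config$seed,
                                                         "rf")))
    report$rf <- list(cv_accuracy = rv$cv_accuracy,
                      oob_error = rv$oob_error,
                      importance = rv$importance,
                      ranking = rv$ranking)
  }

  class(report) <- "analysis_report"
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Write a consolidated analysis report
#'
#' Serializes the report to `report.json` plus a short human-readable
#' `report.txt` in `dir`. Written atomically (temp file then rename).
#'
#' @param report an `analysis_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tmp <- tempfile(tmpdir = dir)
  jsonlite::write_json(report, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE, na = "null")
  file.rename(tmp, file.path(dir, "report.json"))
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(dir, "report.txt"))
  invisible(dir)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Analysis report (seed", x$seed, ")\n")
  cat(sprintf("cohort: n = %d, %d incomplete rows%s\n", x$cohort$n,
              x$cohort$n_incomplete,
              if (x$cohort$simulated) " (simulated)" else ""))
  if (!is.null(x$bifactor)) {
    fi <- x$bifactor$fit_indices
    cat(sprintf("bi-factor: CFI %.3f TLI %.3f RMSEA %.3f (n = %d)\n",
                fi$CFI, fi$TLI, fi$RMSEA, x$bifactor$n_used))
  }
  if (!is.null(x$enumeration)) {
    cat(sprintf("enumeration: selected K = %d\n",
                x$enumeration$selected_K))
  }
  if (!is.null(x$lpa)) {
    cat(sprintf("profile model: K = %d, prevalence %s, entropy %.3f\n",
                x$lpa$K, paste(sprintf("%.3f", x$lpa$prevalence),
                               collapse = "/"),
                x$lpa$entropy))
  }
  if (!is.null(x$conditional)) {
    ors <- x$conditional$odds_ratios
    cat("conditional ORs:",
        paste(sprintf("%s=%.3f", ors$term, ors$odds_ratio),
              collapse = " "), "\n")
  }
  if (!is.null(x$distal)) {
    sig <- x$distal$table$outcome[x$distal$table$significant]
    cat("distal outcomes significant:",
        if (length(sig)) paste(sig, collapse = ", ") else "none", "\n")
  }
  if (!is.null(x$rf)) {
    cat(sprintf("random forest: CV accuracy %.3f, top importance %s\n",
                x$rf$cv_accuracy, x$rf$ranking[1]))
  }
  if (length(x$warnings)) {
    cat("warnings:", length(x$warnings), "\n")
  }
  invisible(x)
}
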