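# Orchestration of the full workflow: corpus (simulated or read from disk)
# -> fixed-effects pooling -> exploratory criteria and bass-ackwards
# hierarchy -> catalogue of confirmatory fits -> per-group invariance
# comparison. Every report cell is copied from a fit object; nothing is
# computed at formatting time.

#' Fit every model of a catalogue to one pooled matrix
#'
#' @param catalog a [build_catalog()] result (or named list of
#'   [model_spec()]).
#' @param pooled a [pooled_correlation()].
#' @param models optional character vector selecting catalogue entries.
#' @param ... passed to [fit_wls()].
#' @return object of class `catalog_fits`: `fits` (named list) and `table`
#'   (one row per model: chi-square, df, CFI, RMSEA, SRMR, AIC, BIC).
#' @export
fit_catalog <- function(catalog, pooled, models = NULL, ...) {
  specs <- if (inherits(catalog, "model_catalog")) catalog$specs else catalog
  if (!is.null(models)) {
    missing <- setdiff(models, names(specs))
    if (length(missing)) stop("unknown models: ", paste(missing, collapse = ", "))
    specs <- specs[models]
  }
  fits <- lapply(specs, fit_wls, pooled = pooled, ...)
  structure(list(fits = fits, table = fit_table(fits)), class = "catalog_fits")
}

fit_table <- function(fits) {
  rows <- lapply(fits, function(f) data.frame(
    model = f$model_name, chisq = f$chi_square, df = f$df, cfi = f$cfi,
    rmsea = f$rmsea, rmsea_lo = f$rmsea_ci[1], rmsea_hi = f$rmsea_ci[2],
    srmr = f$srmr, aic = f$aic, bic = f$bic, converged = f$converged,
    heywood = f$heywood, stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.catalog_fits <- function(x, ...) {
  print(x$table, digits = 4)
  invisible(x)
}

#' Run configuration for the full pipeline
#'
#' @param seed master seed; every stochastic stage derives its seed from
#'   it.
#' @param corpus either `"simulate"` (default; uses the packaged population
#'   specification) or a path to a coding-sheet CSV.
#' @param models catalogue entries to fit (default: all nine).
#' @param invariance_by grouping keys for the invariance stage.
#' @param reference reference group for loading deltas.
#' @param min_samples minimum samples per invariance group.
#' @param efa_max_factors,efa_reps,bass_levels exploratory-stage settings.
#' @param censor_threshold reporting threshold of the simulated corpus.
#' @param n_starts optimisation starts per confirmatory fit.
#' @param fit_cutoffs named vector of conventional cutoffs, stored in the
#'   report header for provenance.
#' @return object of class `run_config`.
#' @export
run_config <- function(seed = 1L, corpus = "simulate", models = NULL,
                       invariance_by = c("language", "clinical_status"),
                       reference = "English", min_samples = 5,
                       efa_max_factors = 8, efa_reps = 100, bass_levels = 4,
                       censor_threshold = 0.40, n_starts = 5,
                       fit_cutoffs = c(cfi = 0.95, rmsea = 0.08, srmr = 0.10)) {
  structure(list(seed = as.integer(seed), corpus = corpus, models = models,
                 invariance_by = invariance_by, reference = reference,
                 min_samples = min_samples, efa_max_factors = efa_max_factors,
                 efa_reps = efa_reps, bass_levels = bass_levels,
                 censor_threshold = censor_threshold, n_starts = n_starts,
                 fit_cutoffs = fit_cutoffs),
            class = "run_config")
}

#' Run the full meta-analytic workflow
#'
#' Deterministic given the configuration seed. Stages: obtain the corpus
#' (simulate, or read from a coding sheet), pool it, run the exploratory
#' criteria and bass-ackwards hierarchy, fit the selected confirmatory
#' models, and run the per-group invariance comparisons with loading
#' deltas against the reference group.
#'
#' @param config a [run_config()].
#' @return object of class `masem_report` with fields `config`, `summary`,
#'   `pooled`, `efa`, `bass`, `cfa` ([fit_catalog()] result), `invariance`
#'   (per grouping key: [group_analysis()] table and [loading_deltas()]),
#'   `truth` (when simulated).
#' @export
run_full <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  scheme <- tas20_scheme()
  truth <- NULL
  if (identical(config$corpus, "simulate")) {
    pspec <- population_spec(seed = child_seed(config$seed, "corpus"))
    pspec$censor_threshold <- config$censor_threshold
    gen <- generate_corpus(pspec, scheme)
    records <- gen$records
    truth <- gen$truth
  } else {
    records <- read_corpus(config$corpus)
  }
  summary <- summarize_corpus(records)
  pooled <- pool_corpus(records)
  efa <- factor_number_report(pooled$R_pooled, pooled$total_N,
                              max_factors = config$efa_max_factors,
                              n_reps = config$efa_reps,
                              seed = child_seed(config$seed, "parallel"))
  bass <- bass_ackwards(pooled$R_pooled, config$bass_levels)
  catalog <- build_catalog(scheme)
  cfa <- fit_catalog(catalog, pooled, models = config$models,
                     n_starts = config$n_starts,
                     seed = child_seed(config$seed, "fit"))
  spec3a <- catalog$specs[["3a"]]
  invariance <- list()
  for (key in config$invariance_by) {
    ga <- group_analysis(records, key, spec3a,
                         min_samples = config$min_samples,
                         n_starts = config$n_starts,
                         seed = child_seed(config$seed, paste0("inv-", key)))
    ref <- if (config$reference %in% names(ga$fits)) config$reference
           else names(ga$fits)[1]
    deltas <- if (length(ga$fits) >= 1) loading_deltas(ga$fits, ref) else NULL
    invariance[[key]] <- list(groups = ga, deltas = deltas)
  }
  structure(list(config = config, summary = summary, pooled = pooled,
                 efa = efa, bass = bass, cfa = cfa,
                 invariance = invariance, truth = truth),
            class = "masem_report")
}

#' @export
print.masem_report <- function(x, ...) {
  cat("== Meta-analytic CFA report ==\n")
  print(x$summary)
  print(x$efa)
  cat("\nModel comparison:\n")
  print(x$cfa$table, digits = 4)
  for (key in names(x$invariance)) {
    cat("\nInvariance by", key, ":\n")
    print(x$invariance[[key]]$groups$table, digits = 3)
  }
  invisible(x)
}

#' Write a report bundle to a directory
#'
#' Emits delimited-text tables (model comparison, per-group invariance,
#' loading deltas, bass-ackwards edges), JSON traces, the pooled matrix,
#' and a MANIFEST recording configuration, seeds, and completion state.
#'
#' @param report a [run_full()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "masem_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(report$cfa$table, file.path(dir, "model_comparison.csv"),
                   row.names = FALSE)
  write_matrix_csv(report$pooled$R_pooled, file.path(dir, "pooled_correlations.csv"))
  jsonlite::write_json(
    list(map = as.list(report$efa$traces$map),
         suggestions = list(map = report$efa$map_suggestion,
                            parallel = report$efa$parallel_suggestion,
                            sabic = report$efa$sabic_suggestion,
                            seq_chisq = report$efa$seq_chisq_suggestion)),
    file.path(dir, "efa_report.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(bass_ackwards_edges(report$bass),
                   file.path(dir, "bass_ackwards_edges.csv"), row.names = FALSE)
  for (key in names(report$invariance)) {
    inv <- report$invariance[[key]]
    utils::write.csv(inv$groups$table,
                     file.path(dir, paste0("invariance_", key, ".csv")),
                     row.names = FALSE)
    if (!is.null(inv$deltas))
      utils::write.csv(data.frame(item = rownames(inv$deltas$deltas),
                                  inv$deltas$deltas, check.names = FALSE),
                       file.path(dir, paste0("loading_deltas_", key, ".csv")),
                       row.names = FALSE)
  }
  manifest <- list(package = "metacfa",
                   version = as.character(utils::packageVersion("metacfa")),
                   seed = report$config$seed,
                   fit_cutoffs = as.list(report$config$fit_cutoffs),
                   k = report$summary$k, total_N = report$summary$total_N,
                   complete = TRUE)
  jsonlite::write_json(manifest, file.path(dir, "MANIFEST.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
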