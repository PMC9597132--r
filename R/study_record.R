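#' A single primary-study sample record
#'
#' One sample contributes either a full item correlation matrix
#' (`source_kind = "raw_correlations"`) or a reported factor solution
#' (`"efa_pattern"` / `"cfa_pattern"`): a loading pattern, possibly censored
#' below a reporting threshold, plus the factor correlation matrix when the
#' rotation was oblique.
#'
#' @param study_id,sample_id identifiers; `sample_id` must be unique in a
#'   corpus.
#' @param n sample size (participants); must exceed the number of items.
#' @param language language label of the administered version.
#' @param clinical_status `"clinical"` or `"nonclinical"`.
#' @param source_kind one of `"raw_correlations"`, `"efa_pattern"`,
#'   `"cfa_pattern"`.
#' @param correlation symmetric unit-diagonal item correlation matrix
#'   (required for `"raw_correlations"`).
#' @param pattern numeric items-by-factors loading matrix; censored entries
#'   are `NA` with the companion `censored` mask set.
#' @param censored logical mask, same shape as `pattern`, marking loadings
#'   suppressed by the primary study; `NULL` means none.
#' @param factor_corr factor correlation matrix (identity for orthogonal
#'   rotations; must be supplied for oblique ones).
#' @param censor_threshold reporting threshold of the source, if known.
#' @param already_recoded logical; correlations computed on recoded items so
#'   that reverse-keyed items correlate positively with their factor.
#' @param n_items expected number of items.
#' @return an object of class `study_record`.
#' @export
study_record <- function(study_id, sample_id, n, language, clinical_status,
                         source_kind = c("raw_correlations", "efa_pattern", "cfa_pattern"),
                         correlation = NULL, pattern = NULL, censored = NULL,
                         factor_corr = NULL, censor_threshold = NA_real_,
                         already_recoded = TRUE, n_items = 20L) {
  source_kind <- match.arg(source_kind)
  n <- as.integer(n)
  if (is.na(n) || n < n_items + 1L)
    stop("sample '", sample_id, "': n too small (n = ", n,
         ", need at least ", n_items + 1L, ")")
  clinical_status <- match.arg(clinical_status, c("clinical", "nonclinical"))

  has_corr <- !is.null(correlation)
  has_pat <- !is.null(pattern)
  if (has_corr == has_pat)
    stop("sample '", sample_id,
         "': exactly one of a correlation matrix or a pattern must be given")
  if (source_kind == "raw_correlations" && !has_corr)
    stop("sample '", sample_id, "': raw_correlations record without a matrix")
  if (source_kind != "raw_correlations" && !has_pat)
    stop("sample '", sample_id, "': pattern record without a pattern")

  if (has_corr) {
    if (nrow(correlation) != n_items)
      stop("sample '", sample_id, "': matrix is not ", n_items, "x", n_items)
    correlation <- validate_correlation(correlation,
                                        paste0("sample '", sample_id, "' correlation"))
  } else {
    pattern <- as.matrix(pattern)
    if (nrow(pattern) != n_items)
      stop("sample '", sample_id, "': pattern must have ", n_items, " rows")
    m <- ncol(pattern)
    if (m < 1) stop("sample '", sample_id, "': pattern has no factors")
    if (is.null(censored)) censored <- is.na(pattern) & FALSE
    censored <- as.matrix(censored)
    if (!identical(dim(censored), dim(pattern)))
      stop("sample '", sample_id, "': censored mask shape mismatch")
    if (any(is.na(pattern) & !censored))
      stop("sample '", sample_id, "': NA loadings that are not marked censored")
    if (any(abs(pattern[!censored]) > 1 + 1e-8))
      stop("sample '", sample_id, "': loadings outside [-1, 1]")
    if (is.null(factor_corr)) factor_corr <- diag(m)
    if (nrow(factor_corr) != m)
      stop("sample '", sample_id, "': factor_corr dimension != number of factors")
    factor_corr <- validate_correlation(factor_corr,
                                        paste0("sample '", sample_id, "' factor_corr"))
  }

  structure(
    list(study_id = as.character(study_id), sample_id = as.character(sample_id),
         n = n, language = as.character(language),
         clinical_status = clinical_status, source_kind = source_kind,
         correlation = correlation, pattern = pattern, censored = censored,
         factor_corr = factor_corr,
         censor_threshold = as.numeric(censor_threshold),
         already_recoded = isTRUE(already_recoded), n_items = as.integer(n_items)),
    class = "study_record"
  )
}

#' @export
print.study_record <- function(x, ...) {
  cat(sprintf("<study_record %s/%s: n = %d, %s, %s, %s>\n",
              x$study_id, x$sample_id, x$n, x$language, x$clinical_status,
              x$source_kind))
  invisible(x)
}

#' Summarise a corpus of study records
#'
#' @param records non-empty list of [study_record()] objects.
#' @return object of class `corpus_summary`: number of samples `k`, number
#'   of studies, `total_N`, `median_n`, and per-language / per-status /
#'   per-source counts.
#' @export
summarize_corpus <- function(records) {
  if (length(records) == 0) stop("empty corpus")
  stopifnot(all(vapply(records, inherits, logical(1), "study_record")))
  ns <- vapply(records, `[[`, numeric(1), "n")
  structure(
    list(k = length(records),
         n_studies = length(unique(vapply(records, `[[`, character(1), "study_id"))),
         total_N = sum(ns),
         median_n = stats::median(ns),
         language_counts = table(vapply(records, `[[`, character(1), "language")),
         status_counts = table(vapply(records, `[[`, character(1), "clinical_status")),
         source_counts = table(vapply(records, `[[`, character(1), "source_kind"))),
    class = "corpus_summary"
  )
}

#' @export
print.corpus_summary <- function(x, ...) {
  cat(sprintf("Corpus: k = %d samples in %d studies, total N = %d, median n = %g\n",
              x$k, x$n_studies, x$total_N, x$median_n))
  cat("  languages:", paste(sprintf("%s (%d)", names(x$language_counts),
                                    x$language_counts), collapse = ", "), "\n")
  cat("  status:   ", paste(sprintf("%s (%d)", names(x$status_counts),
                                    x$status_counts), collapse = ", "), "\n")
  cat("  source:   ", paste(sprintf("%s (%d)", names(x$source_counts),
                                    x$source_counts), collapse = ", "), "\n")
  invisible(x)
}
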