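# Shared fixtures, built in code at test time.

# wrap a correlation matrix as a pooled_correlation at sample size N
as_pooled <- function(R, N) {
  structure(list(R_pooled = R, total_N = as.integer(N), k = 1L,
                 acov = asymptotic_covariance(R, N), group_label = NULL),
            class = "pooled_correlation")
}

# population matrix of the default three-factor population, unperturbed
default_population <- function() {
  population_matrix(population_spec(seed = 1, perturb = FALSE), "English")
}

# a tiny scheme with one factor over n items (toy CFA problems)
toy_scheme <- function(n = 3) {
  item_scheme(n, negative_keyed = 1, factor_assignments = list(F1 = seq_len(n)))
}

# raw-correlation study record from a matrix
raw_record <- function(id, n, R, language = "English",
                       status = "nonclinical") {
  study_record(id, id, n, language, status, "raw_correlations",
               correlation = R, n_items = nrow(R))
}

# small synthetic corpora are reused across files; cache per seed/options
corpus_cache <- new.env(parent = emptyenv())
cached_corpus <- function(seed, ...) {
  key <- paste(seed, ..., sep = "|")
  if (is.null(corpus_cache[[key]])) {
    ps <- population_spec(seed = seed, ...)
    corpus_cache[[key]] <- generate_corpus(ps)
  }
  corpus_cache[[key]]
}
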