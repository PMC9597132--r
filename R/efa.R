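# Exploratory analyses on a pooled correlation matrix: factor-number
# criteria and the bass-ackwards hierarchy of varimax-rotated principal
# component solutions.

#' Velicer's minimum average partial (MAP) test
#'
#' For m = 0, 1, ... principal components partialled out of `R`, computes
#' the average squared partial correlation; the suggested number of factors
#' minimises this criterion over m >= 1. When the minimum over all m
#' (including m = 0) is attained at m = 0, the matrix shows no common
#' structure and the result is flagged.
#'
#' @param R positive-definite correlation matrix.
#' @param max_factors largest number of components partialled out.
#' @return list: `suggestion`, `trace` (criterion value for m = 0..max),
#'   `no_common_factors` flag.
#' @export
map_test <- function(R, max_factors = min(nrow(R) - 2L, 10L)) {
  R <- validate_correlation(R)
  p <- nrow(R)
  eg <- eigen(R, symmetric = TRUE)
  off <- row(R) != col(R)
  trace <- rep(NA_real_, max_factors + 1)
  names(trace) <- 0:max_factors
  trace[1] <- mean(R[off]^2)
  for (m in seq_len(max_factors)) {
    L <- eg$vectors[, seq_len(m), drop = FALSE] %*%
      diag(sqrt(eg$values[seq_len(m)]), m)
    C <- R - tcrossprod(L)
    d <- diag(C)
    if (any(d < 1e-10)) break  # residual variance exhausted
    P <- C / sqrt(outer(d, d))
    trace[m + 1] <- mean(P[off]^2)
  }
  ok <- which(!is.na(trace))
  m_all <- as.integer(names(trace)[ok[which.min(trace[ok])]])
  pos <- ok[ok > 1]
  suggestion <- as.integer(names(trace)[pos[which.min(trace[pos])]])
  list(suggestion = suggestion, trace = trace,
       no_common_factors = m_all == 0L)
}

#' Horn's parallel analysis
#'
#' Compares the eigenvalues of `R` with those of correlation matrices of
#' `N x p` standard-normal data over `n_reps` replications; components are
#' retained while the observed eigenvalue exceeds the reference eigenvalue
#' (mean rule by default, or an upper quantile) at the matched position.
#'
#' @param R correlation matrix.
#' @param N sample size generating the reference data.
#' @param n_reps number of random replications.
#' @param quantile_rule `"mean"` (Horn's original) or a probability such as
#'   `0.95` for the quantile variant.
#' @param seed RNG seed.
#' @return list: `suggestion`, `trace` (data frame of observed and
#'   reference eigenvalues).
#' @export
parallel_analysis <- function(R, N, n_reps = 100, quantile_rule = "mean",
                              seed = 1L) {
  R <- validate_correlation(R)
  p <- nrow(R)
  stopifnot(N > p, n_reps > 0)
  obs <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  set.seed(as.integer(seed))
  ev <- matrix(0, n_reps, p)
  for (b in seq_len(n_reps)) {
    X <- matrix(stats::rnorm(N * p), N, p)
    ev[b, ] <- eigen(stats::cor(X), symmetric = TRUE, only.values = TRUE)$values
  }
  ref <- if (identical(quantile_rule, "mean")) colMeans(ev)
         else apply(ev, 2, stats::quantile, probs = as.numeric(quantile_rule))
  keep <- obs > ref
  suggestion <- if (!keep[1]) 0L else sum(cumprod(keep))
  list(suggestion = as.integer(suggestion),
       trace = data.frame(component = seq_len(p), observed = obs,
                          reference = ref))
}

#' Sample-size-adjusted BIC and sequential chi-square criteria
#'
#' Fits maximum-likelihood exploratory factor models with m = 1..max
#' factors (via [stats::factanal()]) to the pooled matrix. The SABIC
#' criterion is `chi2_m - df_m * ln((N + 2) / 24)`, minimised over m; the
#' sequential test suggests the smallest m whose exact-fit chi-square test
#' is non-significant at `alpha` (if none is, the largest fitted m is
#' returned, flagged).
#'
#' @param R positive-definite correlation matrix.
#' @param N sample size.
#' @param max_factors largest m attempted.
#' @param alpha significance level of the sequential exact-fit test.
#' @return list: `sabic_suggestion`, `seq_chisq_suggestion`, `trace`
#'   (data frame with chi-square, df, p, SABIC per converged m, NA rows for
#'   failures), `seq_capped` flag.
#' @export
sequential_criteria <- function(R, N, max_factors = 8, alpha = 0.05) {
  R <- validate_correlation(R)
  p <- nrow(R)
  trace <- data.frame(m = seq_len(max_factors), chisq = NA_real_,
                      df = NA_real_, p_value = NA_real_, sabic = NA_real_,
                      converged = FALSE)
  for (m in seq_len(max_factors)) {
    if (((p - m)^2 - (p + m)) / 2 < 0) break  # over-parameterised
    fa <- tryCatch(
      stats::factanal(covmat = R, factors = m, n.obs = N, rotation = "none"),
      error = function(e) NULL)
    if (is.null(fa) || is.null(fa$STATISTIC)) next
    trace$chisq[m] <- unname(fa$STATISTIC)
    trace$df[m] <- unname(fa$dof)
    trace$p_value[m] <- unname(fa$PVAL)
    trace$sabic[m] <- unname(fa$STATISTIC) - unname(fa$dof) * log((N + 2) / 24)
    trace$converged[m] <- TRUE
  }
  conv <- which(trace$converged)
  if (!length(conv)) stop("no exploratory factor model converged")
  sabic_suggestion <- trace$m[conv[which.min(trace$sabic[conv])]]
  nonsig <- conv[trace$p_value[conv] > alpha]
  seq_capped <- length(nonsig) == 0
  seq_suggestion <- if (seq_capped) max(conv) else min(nonsig)
  list(sabic_suggestion = as.integer(sabic_suggestion),
       seq_chisq_suggestion = as.integer(seq_suggestion),
       trace = trace, seq_capped = seq_capped)
}

#' Bass-ackwards hierarchy of varimax-rotated component solutions
#'
#' For each level l = 1..L_max extracts l principal components of `R`,
#' rotates them by varimax (no rotation at l = 1), fixes signs so each
#' component's largest-magnitude loading is positive, and links adjacent
#' levels by the correlations of regression-estimated component scores:
#' with `W_l = R^{-1} Lambda_l` the scores have exactly unit variance and
#' zero within-level correlation, and the cross-level correlations are
#' `t(W_l) R W_{l+1}`.
#'
#' @param R positive-definite correlation matrix.
#' @param L_max deepest level (number of components at the bottom).
#' @return object of class `bass_ackwards`: `levels` (list of loading
#'   matrices), `cross_level_corr` (list; entry l links level l to l + 1),
#'   `variance_explained` (per level, proportion of total variance).
#' @export
bass_ackwards <- function(R, L_max = 4) {
  R <- validate_correlation(R)
  p <- nrow(R)
  stopifnot(L_max >= 1, L_max <= p)
  eg <- eigen(R, symmetric = TRUE)
  levels <- vector("list", L_max)
  W <- vector("list", L_max)
  varexp <- numeric(L_max)
  for (l in seq_len(L_max)) {
    L <- eg$vectors[, seq_len(l), drop = FALSE] %*%
      diag(sqrt(eg$values[seq_len(l)]), l)
    if (l >= 2) L <- L %*% stats::varimax(L)$rotmat
    # sign convention + order components by explained variance
    sgn <- apply(L, 2, function(v) sign(v[which.max(abs(v))]))
    L <- sweep(L, 2, ifelse(sgn == 0, 1, sgn), `*`)
    ord <- order(colSums(L^2), decreasing = TRUE)
    L <- L[, ord, drop = FALSE]
    colnames(L) <- paste0("C", l, ".", seq_len(l))
    rownames(L) <- rownames(R) %||% sprintf("item%02d", seq_len(p))
    levels[[l]] <- L
    W[[l]] <- solve(R, L)
    varexp[l] <- sum(L^2) / p
  }
  cross <- vector("list", max(L_max - 1, 0))
  if (L_max > 1)
    for (l in seq_len(L_max - 1))
      cross[[l]] <- crossprod(W[[l]], R %*% W[[l + 1]])
  structure(list(levels = levels, cross_level_corr = cross,
                 variance_explained = varexp, score_weights = W),
            class = "bass_ackwards")
}

#' @export
print.bass_ackwards <- function(x, ...) {
  cat("Bass-ackwards hierarchy:", length(x$levels), "levels; variance explained:",
      paste(sprintf("%.1f%%", 100 * x$variance_explained), collapse = ", "), "\n")
  invisible(x)
}

#' Edge list of a bass-ackwards hierarchy for plotting
#'
#' Emits the cross-level component-score correlations as a data frame of
#' edges, dropping magnitudes below `omit_below` and marking magnitudes
#' below `dash_below` as dashed (the conventional rendering thresholds).
#'
#' @param ba a [bass_ackwards()] result.
#' @param omit_below edges with |r| below this are omitted.
#' @param dash_below edges with |r| below this are styled dashed.
#' @return data frame with columns `from`, `to`, `r`, `style`.
#' @export
bass_ackwards_edges <- function(ba, omit_below = 0.30, dash_below = 0.50) {
  stopifnot(inherits(ba, "bass_ackwards"))
  out <- list()
  for (l in seq_along(ba$cross_level_corr)) {
    C <- ba$cross_level_corr[[l]]
    from <- colnames(ba$levels[[l]])
    to <- colnames(ba$levels[[l + 1]])
    for (a in seq_along(from)) for (b in seq_along(to)) {
      r <- C[a, b]
      if (abs(r) < omit_below) next
      out[[length(out) + 1]] <- data.frame(
        from = from[a], to = to[b], r = r,
        style = if (abs(r) < dash_below) "dashed" else "solid",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(data.frame(from = character(0), to = character(0),
                                      r = numeric(0), style = character(0)))
  do.call(rbind, out)
}

#' All factor-number criteria in one report
#'
#' @param R pooled correlation matrix.
#' @param N total sample size.
#' @param max_factors largest number of factors considered.
#' @param n_reps parallel-analysis replications.
#' @param seed RNG seed for parallel analysis.
#' @return object of class `factor_number_report` with the four suggestions
#'   and per-criterion traces.
#' @export
factor_number_report <- function(R, N, max_factors = 8, n_reps = 100,
                                 seed = 1L) {
  mp <- map_test(R, max_factors)
  pa <- parallel_analysis(R, N, n_reps = n_reps, seed = seed)
  sq <- sequential_criteria(R, N, max_factors)
  structure(list(map_suggestion = mp$suggestion,
                 parallel_suggestion = pa$suggestion,
                 sabic_suggestion = sq$sabic_suggestion,
                 seq_chisq_suggestion = sq$seq_chisq_suggestion,
                 traces = list(map = mp$trace, parallel = pa$trace,
                               sequential = sq$trace),
                 flags = list(map_no_common_factors = mp$no_common_factors,
                              seq_capped = sq$seq_capped)),
            class = "factor_number_report")
}

#' @export
print.factor_number_report <- function(x, ...) {
  cat("Factor-number criteria:\n")
  cat(sprintf("  MAP: %d | parallel analysis: %d | SABIC: %d | sequential chi2: %d\n",
              x$map_suggestion, x$parallel_suggestion, x$sabic_suggestion,
              x$seq_chisq_suggestion))
  invisible(x)
}
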