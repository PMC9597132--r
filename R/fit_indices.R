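#' Incremental and absolute fit indices from chi-square statistics
#'
#' Computes CFI (relative to the independence baseline fitted to the same
#' pooled input), RMSEA with a 90% confidence interval from the
#' noncentral-chi-square inversion, and the information criteria in the
#' chi-square parameterisation used throughout the package:
#' `AIC = chi2 - 2 df`, `BIC = chi2 - ln(N) df`.
#'
#' \itemize{
#'   \item `cfi = 1 - max(chi2 - df, 0) / max(chi2_0 - df_0, chi2 - df, eps)`
#'   \item `rmsea = sqrt(max(chi2 - df, 0) / (df (N - 1)))`
#' }
#' The RMSEA interval bounds solve `P(chi2; df, ncp) = .95` (lower) and
#' `.05` (upper) for the noncentrality `ncp`; when the inversion fails the
#' interval is flagged not computable rather than raising an error.
#'
#' @param chi_square,df target-model statistic and degrees of freedom.
#' @param chi_square_baseline,df_baseline independence-model statistic and
#'   degrees of freedom (`NULL` skips CFI).
#' @param N total sample size behind the pooled correlations.
#' @param ci_level confidence level of the RMSEA interval.
#' @param eps floor protecting the CFI denominator at a perfect fit.
#' @return list with `cfi`, `rmsea`, `rmsea_ci` (length-2 vector, `NA` when
#'   not computable), `rmsea_ci_computable`, `aic`, `bic`.
#' @export
fit_indices <- function(chi_square, df, chi_square_baseline = NULL,
                        df_baseline = NULL, N, ci_level = 0.90,
                        eps = 1e-10) {
  stopifnot(chi_square >= 0, df >= 0, N > 1)
  dev_t <- max(chi_square - df, 0)
  cfi <- NA_real_
  if (!is.null(chi_square_baseline)) {
    dev_0 <- max(chi_square_baseline - df_baseline, 0)
    cfi <- 1 - dev_t / max(dev_0, dev_t, eps)
  }
  if (df == 0) {
    rmsea <- NA_real_
    ci <- c(NA_real_, NA_real_)
    ci_ok <- FALSE
  } else {
    rmsea <- sqrt(dev_t / (df * (N - 1)))
    ci <- rmsea_ci(chi_square, df, N, ci_level)
    ci_ok <- !anyNA(ci)
  }
  list(cfi = cfi, rmsea = rmsea, rmsea_ci = ci, rmsea_ci_computable = ci_ok,
       aic = chi_square - 2 * df, bic = chi_square - log(N) * df)
}

# invert the noncentral chi-square cdf in the noncentrality parameter
ncp_solve <- function(chi_square, df, prob) {
  f <- function(ncp) stats::pchisq(chi_square, df, ncp = ncp) - prob
  # pchisq is decreasing in ncp: if even ncp = 0 lies below the target
  # probability the bound collapses to 0
  if (f(0) < 0) return(0)
  upper <- max(chi_square, df) + 10
  it <- 0
  while (f(upper) > 0 && it < 60) { upper <- upper * 2; it <- it + 1 }
  if (f(upper) > 0) return(NA_real_)
  out <- tryCatch(stats::uniroot(f, c(0, upper), tol = 1e-8)$root,
                  error = function(e) NA_real_)
  out
}

rmsea_ci <- function(chi_square, df, N, level = 0.90) {
  alpha <- (1 - level) / 2
  lo_ncp <- ncp_solve(chi_square, df, 1 - alpha)
  hi_ncp <- ncp_solve(chi_square, df, alpha)
  if (is.na(lo_ncp) || is.na(hi_ncp)) return(c(NA_real_, NA_real_))
  c(sqrt(max(lo_ncp, 0) / (df * (N - 1))),
    sqrt(max(hi_ncp, 0) / (df * (N - 1))))
}
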