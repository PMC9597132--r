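#' Factor solution reported by a primary study
#'
#' @param Lambda items-by-factors loading (pattern) matrix; censored entries
#'   are `NA` and flagged in `censored`.
#' @param Phi factor correlation matrix; identity for orthogonal rotations.
#' @param censored logical mask of censored loadings (same shape as
#'   `Lambda`), or `NULL` for none.
#' @param censor_threshold magnitude below which the source suppressed
#'   loadings, if known.
#' @return object of class `factor_solution`.
#' @export
factor_solution <- function(Lambda, Phi = NULL, censored = NULL,
                            censor_threshold = NA_real_) {
  Lambda <- as.matrix(Lambda)
  m <- ncol(Lambda)
  if (m < 1) stop("factor solution needs at least one factor")
  if (is.null(Phi)) Phi <- diag(m)
  Phi <- validate_correlation(Phi, "factor correlation matrix")
  if (nrow(Phi) != m) stop("Phi dimension does not match number of factors")
  if (is.null(censored)) censored <- matrix(FALSE, nrow(Lambda), m)
  censored <- as.matrix(censored)
  if (!identical(dim(censored), dim(Lambda)))
    stop("censored mask shape mismatch")
  if (any(is.na(Lambda) & !censored))
    stop("NA loadings that are not marked censored")
  structure(list(Lambda = Lambda, Phi = Phi, censored = censored,
                 censor_threshold = censor_threshold),
            class = "factor_solution")
}

#' Impute zeros for censored loadings
#'
#' Primary studies sometimes omit loadings below a reporting threshold
#' (typically .40). Replacing the suppressed entries with zero before
#' reconstruction yields approximately unbiased pooled factor patterns.
#' Non-censored entries are untouched.
#'
#' @param solution a [factor_solution()].
#' @return the solution with every censored loading set to 0 and the mask
#'   cleared.
#' @export
impute_censored <- function(solution) {
  stopifnot(inherits(solution, "factor_solution"))
  L <- solution$Lambda
  L[solution$censored] <- 0
  factor_solution(L, solution$Phi,
                  censored = matrix(FALSE, nrow(L), ncol(L)),
                  censor_threshold = solution$censor_threshold)
}

#' Model-implied item correlations from a reported factor solution
#'
#' Computes the common-factor part Lambda Phi Lambda' of the correlation
#' matrix, forces the diagonal to exactly 1 (only the off-diagonal elements
#' enter pooling; uniquenesses are not re-estimated), and symmetrises. Any
#' off-diagonal magnitude above 1 — possible for oblique reported patterns —
#' is clipped to +/- 0.999 with a warning.
#'
#' @param solution a [factor_solution()] with no remaining censored entries
#'   (apply [impute_censored()] first).
#' @return symmetric unit-diagonal matrix of implied correlations.
#' @export
implied_correlations <- function(solution) {
  stopifnot(inherits(solution, "factor_solution"))
  if (any(solution$censored))
    stop("censored loadings present; apply impute_censored() first")
  L <- solution$Lambda
  R <- L %*% solution$Phi %*% t(L)
  off <- row(R) != col(R)
  if (any(abs(R[off]) > 1)) {
    warning("implied correlations outside [-1, 1]; clipped to +/-0.999",
            call. = FALSE)
    R[off & R > 1] <- 0.999
    R[off & R < -1] <- -0.999
  }
  diag(R) <- 1
  (R + t(R)) / 2
}

# Resolve a study record to a 20x20 correlation matrix: either the reported
# matrix itself or the reconstruction from its (zero-imputed) pattern.
resolve_correlation <- function(record) {
  stopifnot(inherits(record, "study_record"))
  if (record$source_kind == "raw_correlations") return(record$correlation)
  sol <- factor_solution(record$pattern, record$factor_corr,
                         censored = record$censored,
                         censor_threshold = record$censor_threshold)
  implied_correlations(impute_censored(sol))
}
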