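#' @keywords internal
"_PACKAGE"

#' Index of the unique off-diagonal correlations
#'
#' Fixed ordering used for every vectorised correlation quantity in the
#' package: row-major lower triangle, i.e. (2,1), (3,1), (3,2), (4,1), ...
#' For p = 20 items this yields p(p-1)/2 = 190 pairs.
#'
#' @param p number of variables.
#' @return integer matrix with columns `row` and `col`, one row per pair.
#' @export
corr_pair_index <- function(p) {
  stopifnot(is.numeric(p), length(p) == 1L, p >= 2)
  out <- do.call(rbind, lapply(2:p, function(i) cbind(row = i, col = seq_len(i - 1L))))
  storage.mode(out) <- "integer"
  out
}

#' Extract the unique correlations of a matrix in the package ordering
#'
#' @param R square symmetric matrix.
#' @return numeric vector of length `p(p-1)/2` in `corr_pair_index()` order.
#' @export
vech_corr <- function(R) {
  idx <- corr_pair_index(nrow(R))
  R[idx]
}

#' Rebuild a symmetric unit-diagonal matrix from its unique correlations
#'
#' Inverse of [vech_corr()].
#'
#' @param v vector of unique correlations in `corr_pair_index()` order.
#' @param labels optional row/column names.
#' @return symmetric matrix with unit diagonal.
#' @export
unvech_corr <- function(v, labels = NULL) {
  p <- (1 + sqrt(1 + 8 * length(v))) / 2
  if (abs(p - round(p)) > 1e-8)
    stop("length of 'v' is not p(p-1)/2 for integer p")
  p <- as.integer(round(p))
  R <- diag(p)
  idx <- corr_pair_index(p)
  R[idx] <- v
  R[idx[, c(2, 1)]] <- v
  if (!is.null(labels)) dimnames(R) <- list(labels, labels)
  R
}

is_symmetric_tol <- function(M, tol = 1e-8) {
  is.matrix(M) && nrow(M) == ncol(M) && max(abs(M - t(M))) <= tol
}

#' Validate a correlation matrix
#'
#' Checks symmetry (tolerance 1e-8), unit diagonal, and |r| <= 1. Positive
#' definiteness is checked separately because reconstructed matrices may
#' legitimately be indefinite before pooling.
#'
#' @param R matrix to validate.
#' @param what label used in error messages.
#' @param tol symmetry tolerance.
#' @return `R`, invisibly, with symmetry enforced exactly.
#' @export
validate_correlation <- function(R, what = "correlation matrix", tol = 1e-8) {
  if (!is.matrix(R) || nrow(R) != ncol(R))
    stop(what, " must be a square matrix")
  if (max(abs(R - t(R))) > tol)
    stop(what, " is not symmetric (tolerance ", format(tol), ")")
  if (max(abs(diag(R) - 1)) > tol)
    stop(what, " does not have a unit diagonal")
  if (max(abs(R)) > 1 + tol)
    stop(what, " has entries outside [-1, 1]")
  R <- (R + t(R)) / 2
  diag(R) <- 1
  invisible(R)
}

is_positive_definite <- function(M, tol = 1e-10) {
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  min(ev) > tol * max(abs(ev))
}

#' Nearest-correlation-matrix repair
#'
#' Projects an indefinite symmetric matrix onto the set of positive-definite
#' correlation matrices (wrapper around [Matrix::nearPD()]).
#'
#' @param R symmetric matrix with unit diagonal.
#' @return repaired positive-definite correlation matrix.
#' @export
repair_correlation <- function(R) {
  out <- as.matrix(Matrix::nearPD(R, corr = TRUE)$mat)
  dimnames(out) <- dimnames(R)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a reproducible child seed from a base seed and a tag; kept below
# 2^31 so it is always a valid R integer.
child_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 10007 + h) %% 2147483629)
}
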