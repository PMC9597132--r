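# Stage 1 of the two-stage meta-analytic SEM: fixed-effects pooling of item
# correlation matrices and the normal-theory asymptotic covariance of the
# pooled unique correlations (the stage-2 WLS weight matrix).

#' Fixed-effects pooling of study correlation matrices
#'
#' Each unique correlation is pooled as the sample-size-weighted mean
#' across studies, r_jk = sum_i n_i r_ijk / sum_i n_i — the fixed-effects
#' estimator assuming a single common population matrix. Records reporting
#' factor patterns are first reconstructed via [implied_correlations()].
#' The asymptotic covariance of the pooled unique correlations is then
#' evaluated at the pooled matrix with N = sum_i n_i (weights must match the
#' point at which the stage-2 discrepancy is evaluated).
#'
#' @param records non-empty list of [study_record()] objects.
#' @param group_label optional label stored with the result.
#' @param compute_acov logical; set `FALSE` to skip the covariance (cheaper
#'   when only the pooled matrix is needed).
#' @return object of class `pooled_correlation`: `R_pooled` (symmetric,
#'   unit diagonal), `total_N`, `k`, `acov` (190 x 190 for 20 items, in
#'   [corr_pair_index()] order), `group_label`.
#' @export
pool_corpus <- function(records, group_label = NULL, compute_acov = TRUE) {
  if (length(records) == 0) stop("empty corpus: nothing to pool")
  p <- records[[1]]$n_items
  acc <- matrix(0, p, p)
  total_N <- 0
  for (rec in records) {
    R <- tryCatch(resolve_correlation(rec), error = function(e)
      stop("sample '", rec$sample_id, "' could not be resolved to a ",
           "correlation matrix: ", conditionMessage(e)))
    acc <- acc + rec$n * R
    total_N <- total_N + rec$n
  }
  R_pooled <- acc / total_N
  diag(R_pooled) <- 1
  labels <- sprintf("item%02d", seq_len(p))
  dimnames(R_pooled) <- list(labels, labels)
  acov <- if (compute_acov) asymptotic_covariance(R_pooled, total_N) else NULL
  structure(list(R_pooled = R_pooled, total_N = as.integer(total_N),
                 k = length(records), acov = acov,
                 group_label = group_label),
            class = "pooled_correlation")
}

#' @export
print.pooled_correlation <- function(x, ...) {
  cat(sprintf("<pooled_correlation%s: k = %d, total N = %d, %d items>\n",
              if (is.null(x$group_label)) "" else paste0(" [", x$group_label, "]"),
              x$k, x$total_N, nrow(x$R_pooled)))
  invisible(x)
}

#' Normal-theory asymptotic covariance of sample correlations
#'
#' Delta-method (Pearson-Filon / Olkin-Siotani) covariance of the vector of
#' unique Pearson correlations of multivariate-normal data, evaluated at a
#' population matrix `R` and scaled by `1/N`:
#' \deqn{N\,\mathrm{cov}(r_{ij}, r_{kl}) =
#'   \tfrac12 \rho_{ij}\rho_{kl}(\rho_{ik}^2+\rho_{il}^2+\rho_{jk}^2+\rho_{jl}^2)
#'   + \rho_{ik}\rho_{jl} + \rho_{il}\rho_{jk}
#'   - \rho_{ij}(\rho_{ik}\rho_{il}+\rho_{jk}\rho_{jl})
#'   - \rho_{kl}(\rho_{ik}\rho_{jk}+\rho_{il}\rho_{jl})}
#' The diagonal reduces to the familiar \eqn{(1-\rho_{jk}^2)^2 / N}.
#'
#' @param R positive-definite correlation matrix.
#' @param N total sample size (> number of variables).
#' @return symmetric matrix of order `p(p-1)/2` in [corr_pair_index()]
#'   order.
#' @export
asymptotic_covariance <- function(R, N) {
  R <- validate_correlation(R)
  p <- nrow(R)
  if (N <= p) stop("N must exceed the number of variables")
  if (!is_positive_definite(R))
    stop("R is not positive definite; repair it (see repair_correlation) first")
  idx <- corr_pair_index(p)
  q <- nrow(idx)
  i <- idx[, 1]; j <- idx[, 2]
  V <- matrix(0, q, q)
  for (a in seq_len(q)) {
    ia <- i[a]; ja <- j[a]
    rij <- R[ia, ja]
    rik <- R[ia, i]; ril <- R[ia, j]
    rjk <- R[ja, i]; rjl <- R[ja, j]
    rkl <- R[idx]
    V[a, ] <- 0.5 * rij * rkl * (rik^2 + ril^2 + rjk^2 + rjl^2) +
      rik * rjl + ril * rjk -
      rij * (rik * ril + rjk * rjl) -
      rkl * (rik * rjk + ril * rjl)
  }
  V <- (V + t(V)) / (2 * N)
  V
}
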