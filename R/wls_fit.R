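# Stage 2 of the two-stage meta-analytic SEM: weighted least squares fit of
# a measurement model to the pooled correlation vector, with the asymptotic
# covariance of the pooled correlations as weight matrix.
#
# F(theta) = (r - rho(theta))' V^-1 (r - rho(theta)) over the unique
# off-diagonal correlations; V already carries 1/N, so the minimum of F is
# the model chi-square.

# --- parameter packing -----------------------------------------------------

theta_template <- function(spec) {
  n_l <- sum(spec$lambda_free)
  n_p <- NROW(spec$phi_pairs)
  n_r <- NROW(spec$resid_pairs)
  list(n_l = n_l, n_p = n_p, n_r = n_r, n = n_l + n_p + n_r)
}

theta_start <- function(spec) {
  tpl <- theta_template(spec)
  c(rep(0.5, tpl$n_l), rep(0.3, tpl$n_p), rep(0, tpl$n_r))
}

unpack_theta <- function(theta, spec) {
  tpl <- theta_template(spec)
  p <- spec$scheme$n_items
  nf <- length(spec$factors)
  L <- matrix(0, p, nf, dimnames = dimnames(spec$lambda_free))
  L[spec$lambda_free] <- theta[seq_len(tpl$n_l)]
  Phi <- diag(nf)
  dimnames(Phi) <- list(spec$factors, spec$factors)
  if (tpl$n_p > 0) {
    v <- theta[tpl$n_l + seq_len(tpl$n_p)]
    for (k in seq_len(tpl$n_p)) {
      Phi[spec$phi_pairs[k, 1], spec$phi_pairs[k, 2]] <- v[k]
      Phi[spec$phi_pairs[k, 2], spec$phi_pairs[k, 1]] <- v[k]
    }
  }
  resid <- if (tpl$n_r > 0) theta[tpl$n_l + tpl$n_p + seq_len(tpl$n_r)] else numeric(0)
  list(Lambda = L, Phi = Phi, resid = resid)
}

# model-implied unique off-diagonal correlations, in corr_pair_index order
implied_rho <- function(theta, spec, pair_idx, resid_pos) {
  par <- unpack_theta(theta, spec)
  S <- par$Lambda %*% par$Phi %*% t(par$Lambda)
  rho <- S[pair_idx]
  if (length(par$resid)) rho[resid_pos] <- rho[resid_pos] + par$resid
  rho
}

# analytic Jacobian d rho / d theta  (q x n_par)
implied_jacobian <- function(theta, spec, pair_idx, resid_pos) {
  par <- unpack_theta(theta, spec)
  tpl <- theta_template(spec)
  q <- nrow(pair_idx)
  J <- matrix(0, q, tpl$n)
  M <- par$Lambda %*% par$Phi          # p x nf
  free_pos <- which(spec$lambda_free, arr.ind = TRUE)
  ri <- pair_idx[, 1]; ci <- pair_idx[, 2]
  for (k in seq_len(tpl$n_l)) {
    i <- free_pos[k, 1]; f <- free_pos[k, 2]
    col <- numeric(q)
    hit_r <- ri == i
    hit_c <- ci == i
    col[hit_r] <- col[hit_r] + M[ci[hit_r], f]
    col[hit_c] <- col[hit_c] + M[ri[hit_c], f]
    J[, k] <- col
  }
  if (tpl$n_p > 0) {
    for (k in seq_len(tpl$n_p)) {
      f <- spec$phi_pairs[k, 1]; g <- spec$phi_pairs[k, 2]
      J[, tpl$n_l + k] <- par$Lambda[ri, f] * par$Lambda[ci, g] +
        par$Lambda[ri, g] * par$Lambda[ci, f]
    }
  }
  if (tpl$n_r > 0)
    for (k in seq_len(tpl$n_r))
      J[resid_pos[k], tpl$n_l + tpl$n_p + k] <- 1
  J
}

# --- fitting ---------------------------------------------------------------

#' Fit a measurement model to a pooled correlation matrix by WLS
#'
#' Minimises the weighted least squares discrepancy
#' \eqn{F(\theta) = (r - \rho(\theta))' V^{-1} (r - \rho(\theta))}
#' over the unique off-diagonal correlations, with `V` the asymptotic
#' covariance of the pooled correlations. Because `V` carries the factor
#' `1/N`, the minimised discrepancy is the model chi-square. Factors have
#' unit variance and all loadings are free (standardized solution);
#' uniquenesses are implied by the correlation metric.
#'
#' Optimisation is quasi-Newton (BFGS) with an analytic gradient and
#' multi-start: the default start (loadings .5, factor correlations .3,
#' residual correlations 0) plus `n_starts - 1` jittered starts with fixed
#' seeds. Convergence requires the largest gradient element to fall below
#' `tol_gradient * max(1, chi_square)`.
#'
#' @param spec a [model_spec()].
#' @param pooled a [pooled_correlation()] from [pool_corpus()] (its `acov`
#'   must be present).
#' @param n_starts number of optimisation starts (>= 1).
#' @param tol_gradient relative gradient tolerance for declaring
#'   convergence.
#' @param seed seed for the start-value jitter.
#' @param compute_baseline logical; also fit the independence baseline
#'   (needed for CFI). The baseline chi-square `r' V^-1 r` is closed-form.
#' @return object of class `cfa_fit`: parameter matrices `Lambda`, `Phi`,
#'   `resid` (residual correlations with their item pairs), `uniquenesses`,
#'   `chi_square`, `df`, fit indices (`cfi`, `rmsea` + CI, `srmr`, `aic`,
#'   `bic`), `omegas` per base factor, convergence diagnostics, and flags
#'   (`heywood`, `rmsea_ci_computable`).
#' @export
fit_wls <- function(spec, pooled, n_starts = 5, tol_gradient = 1e-6,
                    seed = 1L, compute_baseline = TRUE) {
  stopifnot(inherits(spec, "model_spec"), inherits(pooled, "pooled_correlation"))
  if (is.null(pooled$acov)) stop("pooled correlation lacks an acov matrix")
  p <- nrow(pooled$R_pooled)
  pair_idx <- corr_pair_index(p)
  r <- pooled$R_pooled[pair_idx]
  W <- chol2inv(chol(pooled$acov))   # V^-1; errors if acov not PD

  resid_pos <- integer(0)
  if (NROW(spec$resid_pairs) > 0) {
    key <- paste(pair_idx[, 1], pair_idx[, 2])
    resid_pos <- match(paste(spec$resid_pairs[, 1], spec$resid_pairs[, 2]), key)
    if (anyNA(resid_pos)) stop("residual pair not found in index (internal)")
  }

  fn <- function(theta) {
    e <- r - implied_rho(theta, spec, pair_idx, resid_pos)
    drop(crossprod(e, W %*% e))
  }
  gr <- function(theta) {
    e <- r - implied_rho(theta, spec, pair_idx, resid_pos)
    J <- implied_jacobian(theta, spec, pair_idx, resid_pos)
    drop(-2 * crossprod(J, W %*% e))
  }

  starts <- list(theta_start(spec))
  if (n_starts > 1) {
    for (s in seq_len(n_starts - 1)) {
      set.seed(child_seed(seed, paste0(spec$name, "-start-", s)))
      starts[[s + 1]] <- theta_start(spec) +
        stats::runif(theta_template(spec)$n, -0.15, 0.15)
    }
  }

  best <- NULL
  n_evals <- 0L
  for (th0 in starts) {
    opt <- stats::optim(th0, fn, gr, method = "BFGS",
                        control = list(maxit = 1000, reltol = 1e-14))
    n_evals <- n_evals + opt$counts[["function"]]
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  theta_hat <- best$par
  chi_square <- max(best$value, 0)
  g <- gr(theta_hat)
  gnorm <- max(abs(g))
  converged <- gnorm < tol_gradient * max(1, chi_square)

  par <- unpack_theta(theta_hat, spec)
  communality <- diag(par$Lambda %*% par$Phi %*% t(par$Lambda))
  uniq <- 1 - communality
  heywood <- any(abs(par$Lambda) > 1) || any(uniq < 0)
  if (heywood)
    warning("model '", spec$name, "': Heywood case (loading > 1 or negative ",
            "uniqueness)", call. = FALSE)

  e <- r - implied_rho(theta_hat, spec, pair_idx, resid_pos)
  srmr_val <- srmr(e)

  chi0 <- df0 <- NULL
  if (compute_baseline) {
    chi0 <- drop(crossprod(r, W %*% r))
    df0 <- length(r)
  }
  fi <- fit_indices(chi_square, spec$df, chi0, df0, pooled$total_N)

  omegas <- omegas_for(spec, par$Lambda, uniq)

  resid_tab <- NULL
  if (NROW(spec$resid_pairs) > 0) {
    ia <- spec$resid_pairs[, 1]; ib <- spec$resid_pairs[, 2]
    # the free parameter is the additive residual covariance on the
    # correlation metric; the conventional report is the residual
    # correlation, standardized by the two uniquenesses
    denom <- sqrt(pmax(uniq[ia], 1e-12) * pmax(uniq[ib], 1e-12))
    resid_tab <- data.frame(
      item_a = spec$scheme$item_labels[ia],
      item_b = spec$scheme$item_labels[ib],
      covariance = par$resid,
      estimate = par$resid / denom, stringsAsFactors = FALSE)
  }

  structure(list(model_name = spec$name, spec = spec,
                 theta = theta_hat, Lambda = par$Lambda, Phi = par$Phi,
                 resid = resid_tab, uniquenesses = uniq,
                 chi_square = chi_square, df = spec$df,
                 chi_square_baseline = chi0, df_baseline = df0,
                 cfi = fi$cfi, rmsea = fi$rmsea,
                 rmsea_ci = fi$rmsea_ci,
                 rmsea_ci_computable = fi$rmsea_ci_computable,
                 srmr = srmr_val, aic = fi$aic, bic = fi$bic,
                 omegas = omegas, total_N = pooled$total_N,
                 converged = converged, gradient_norm = gnorm,
                 n_function_evals = n_evals, heywood = heywood),
            class = "cfa_fit")
}

#' @export
print.cfa_fit <- function(x, ...) {
  cat(sprintf("<cfa_fit %s: chi2 = %.1f, df = %d, CFI = %.3f, RMSEA = %.3f, SRMR = %.3f%s>\n",
              x$model_name, x$chi_square, x$df, x$cfi, x$rmsea, x$srmr,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

# omega per base content factor from the standardized solution
omegas_for <- function(spec, Lambda, uniq) {
  out <- numeric(0)
  for (f in spec$specific_factors) {
    items <- scheme_items(spec$scheme, f)
    lam <- Lambda[items, f]
    out[f] <- omega(lam, uniq[items])
  }
  out
}

#' McDonald's omega from standardized loadings and uniquenesses
#'
#' \eqn{\omega = (\sum \lambda)^2 / ((\sum \lambda)^2 + \sum \psi)} for one
#' factor's items, with \eqn{\psi_i = 1 - } communality of item i.
#'
#' @param lambda loadings of the factor's items.
#' @param psi their uniquenesses.
#' @return scalar reliability in `[0, 1]` (for admissible solutions).
#' @export
omega <- function(lambda, psi) {
  if (length(lambda) == 0) stop("omega: empty item set")
  if (length(psi) != length(lambda)) stop("omega: lambda/psi length mismatch")
  s <- sum(lambda)^2
  s / (s + sum(psi))
}

#' Standardized root mean square residual
#'
#' Root of the mean squared residual over the unique off-diagonal
#' correlation residuals (the diagonal is exactly reproduced on the
#' correlation metric).
#'
#' @param residuals vector of `r - rho(theta_hat)` over the unique pairs.
#' @return non-negative scalar.
#' @export
srmr <- function(residuals) {
  sqrt(mean(residuals^2))
}

#' Summary of estimated residual correlations (correlated-uniqueness model)
#'
#' @param fit a converged [fit_wls()] result for a model with free residual
#'   correlations (model 7 in the TAS-20 catalogue).
#' @return named vector `min`, `max`, `median` over the estimated residual
#'   correlations.
#' @export
residual_correlation_summary <- function(fit) {
  stopifnot(inherits(fit, "cfa_fit"))
  if (is.null(fit$resid))
    stop("model '", fit$model_name, "' has no free residual correlations")
  v <- fit$resid$estimate
  c(min = min(v), max = max(v), median = stats::median(v))
}

#' Chi-square of the saturated and independence reference points
#'
#' The saturated model reproduces `r` exactly (chi-square 0, df 0); the
#' independence baseline sets every implied correlation to 0, giving the
#' closed form `r' V^-1 r` with df p(p-1)/2.
#'
#' @param pooled a [pooled_correlation()].
#' @return list with `saturated` and `independence` entries (`chi_square`,
#'   `df`).
#' @export
reference_fits <- function(pooled) {
  r <- vech_corr(pooled$R_pooled)
  W <- chol2inv(chol(pooled$acov))
  list(saturated = list(chi_square = 0, df = 0L),
       independence = list(chi_square = drop(crossprod(r, W %*% r)),
                           df = length(r)))
}
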