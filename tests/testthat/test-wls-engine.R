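test_that("the engine recovers generating parameters from a population matrix", {
  ps <- population_spec(seed = 1, perturb = FALSE)
  R <- population_matrix(ps, "English")
  pooled <- as_pooled(R, 69722)
  cat20 <- build_catalog(tas20_scheme())
  fit <- fit_wls(cat20$specs[["3a"]], pooled)
  expect_true(fit$converged)
  expect_lt(fit$chi_square, 1e-6)
  expect_equal(fit$Lambda[fit$spec$lambda_free],
               ps$Lambda[ps$Lambda != 0], tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_equal(c(fit$Phi["DIF", "DDF"], fit$Phi["DDF", "EOT"], fit$Phi["DIF", "EOT"]),
               c(.77, .47, .32), tolerance = 1e-4)
  expect_equal(fit$cfi, 1)
  expect_equal(fit$rmsea, 0)
  expect_lt(fit$srmr, 1e-6)
})

test_that("saturated and independence reference points behave as limits", {
  gen <- cached_corpus(5, k = 10)
  pooled <- pool_corpus(gen$records)
  ref <- reference_fits(pooled)
  expect_equal(ref$saturated$chi_square, 0)
  expect_equal(ref$independence$df, 190L)
  # CFI of the baseline itself is 0 by construction
  fi <- fit_indices(ref$independence$chi_square, ref$independence$df,
                    ref$independence$chi_square, ref$independence$df,
                    pooled$total_N)
  expect_equal(fi$cfi, 0)
})

test_that("chi-square is monotone over the nested model chain", {
  gen <- cached_corpus(42)
  pooled <- pool_corpus(gen$records)
  cat20 <- build_catalog(tas20_scheme())
  fits <- suppressWarnings(
    fit_catalog(cat20, pooled, models = c("1", "2", "3a", "6", "7")))
  chi <- setNames(fits$table$chisq, fits$table$model)
  expect_gte(chi[["1"]], chi[["2"]])
  expect_gte(chi[["2"]], chi[["3a"]])
  expect_gte(chi[["3a"]], chi[["6"]])
  expect_gte(chi[["3a"]], chi[["7"]])
  expect_true(all(fits$table$cfi >= 0 & fits$table$cfi <= 1))
})

test_that("residual-correlation models recover a planted correlated-uniqueness structure", {
  ps <- population_spec(seed = 8, residual_correlation = 0.15,
                        reporting_mix = "all_raw", perturb = FALSE)
  R <- population_matrix(ps, "English")
  pooled <- as_pooled(R, 50000)
  cat20 <- build_catalog(tas20_scheme())
  fit7 <- fit_wls(cat20$specs[["7"]], pooled)
  expect_true(fit7$converged)
  s <- residual_correlation_summary(fit7)
  # planted residual correlations of .15, reported on the correlation
  # scale after standardizing by the uniquenesses
  expect_lt(abs(s[["median"]] - 0.15), 0.03)
  fit3a <- fit_wls(cat20$specs[["3a"]], pooled)
  expect_error(residual_correlation_summary(fit3a), "no free residual")
  # all residual correlations equal: min = max = median
  expect_lt(diff(range(fit7$resid$estimate)), 0.05)
})

test_that("omega follows its closed form", {
  expect_equal(omega(c(.8, .8, .8), c(.36, .36, .36)), 5.76 / 6.84)
  expect_equal(omega(rep(0, 4), rep(1, 4)), 0)
  expect_equal(omega(1, 0), 1)
  expect_error(omega(numeric(0), numeric(0)), "empty")
})

test_that("srmr is the RMS of the unique residuals", {
  expect_equal(srmr(rep(0, 190)), 0)
  expect_equal(srmr(rep(-0.03, 190)), 0.03)
  set.seed(4)
  e <- rnorm(190, 0, 0.05)
  expect_equal(srmr(e), sqrt(mean(e^2)))
})

test_that("the engine matches a brute-force grid oracle on a one-factor toy", {
  # 3 items, 1 factor, correlations perturbed away from exact fit
  r <- c(0.51, 0.38, 0.28)  # (2,1), (3,1), (3,2)
  Rt <- unvech_corr(r)
  N <- 500
  V <- asymptotic_covariance(Rt, N)
  W <- chol2inv(chol(V))
  Fq <- function(l1, l2, l3) {
    e <- cbind(r[1] - l1 * l2, r[2] - l1 * l3, r[3] - l2 * l3)
    rowSums((e %*% W) * e)
  }
  # independent two-stage grid search: coarse 0.05, then full 1e-3 grid in
  # a box around the coarse optimum
  g <- seq(0.05, 0.99, by = 0.05)
  gg <- expand.grid(l1 = g, l2 = g, l3 = g)
  b <- gg[which.min(Fq(gg$l1, gg$l2, gg$l3)), ]
  fine <- function(x) seq(max(0, x - 0.06), min(0.999, x + 0.06), by = 1e-3)
  gg2 <- expand.grid(l1 = fine(b$l1), l2 = fine(b$l2), l3 = fine(b$l3))
  v2 <- Fq(gg2$l1, gg2$l2, gg2$l3)
  grid_theta <- as.numeric(gg2[which.min(v2), ])
  grid_F <- min(v2)

  spec <- model_spec("toy", toy_scheme(3), "F1")
  fit <- fit_wls(spec, as_pooled(Rt, N), compute_baseline = FALSE)
  expect_true(fit$converged)
  expect_equal(sort(abs(fit$theta)), sort(grid_theta), tolerance = 2e-3)
  expect_lte(fit$chi_square, grid_F + 1e-8)
  expect_equal(fit$chi_square, grid_F, tolerance = 1e-4)
})

test_that("estimates are essentially unbiased across replicated corpora", {
  # fixed-effects recovery study: corpora of k = 30 raw-matrix studies
  cat20 <- build_catalog(tas20_scheme())
  spec3a <- cat20$specs[["3a"]]
  ps0 <- population_spec(seed = 1, perturb = FALSE)
  lam_true <- ps0$Lambda[ps0$Lambda != 0]
  phi_true <- c(.77, .32, .47)  # packing order (1,2),(1,3),(2,3)
  n_rep <- 50
  lam_bias <- matrix(NA_real_, n_rep, length(lam_true))
  phi_bias <- matrix(NA_real_, n_rep, 3)
  for (b in seq_len(n_rep)) {
    ps <- population_spec(seed = 1000 + b, k = 30,
                          reporting_mix = "all_raw", perturb = FALSE)
    gen <- generate_corpus(ps)
    pooled <- pool_corpus(gen$records)
    fit <- fit_wls(spec3a, pooled, n_starts = 1)
    lam_bias[b, ] <- fit$Lambda[spec3a$lambda_free] - lam_true
    tpl_phi <- fit$theta[sum(spec3a$lambda_free) + 1:3]
    phi_bias[b, ] <- tpl_phi - phi_true
  }
  expect_lt(max(abs(colMeans(lam_bias))), 0.01)
  expect_lt(max(abs(colMeans(phi_bias))), 0.01)
})

test_that("Heywood solutions are flagged, not silent", {
  # two nearly collinear indicators of a weak factor push loadings past 1
  r <- c(0.985, 0.30, 0.29)
  Rt <- unvech_corr(r)
  spec <- model_spec("toy", toy_scheme(3), "F1")
  expect_warning(fit <- fit_wls(spec, as_pooled(Rt, 200), compute_baseline = FALSE),
                 "Heywood")
  expect_true(fit$heywood)
})
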