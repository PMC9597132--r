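test_that("population matrices follow the loading structure", {
  ps <- population_spec(seed = 1, perturb = FALSE)
  # hand product for a DIF x DDF pair: lambda_i phi lambda_j
  R <- population_matrix(ps, "English")
  expect_equal(R["item01", "item02"],
               ps$Lambda["item01", "DIF"] * ps$Phi["DIF", "DDF"] *
                 ps$Lambda["item02", "DDF"])
  # same-factor pair
  expect_equal(R["item01", "item03"],
               ps$Lambda["item01", "DIF"] * ps$Lambda["item03", "DIF"])
  expect_equal(diag(R), rep(1, 20), ignore_attr = TRUE)
  expect_true(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) > 0)
})

test_that("group perturbations are local to the perturbed items", {
  ps <- population_spec(seed = 1, perturb = TRUE)
  R_en <- population_matrix(ps, "English")
  R_de <- population_matrix(ps, "German")
  moved <- which(abs(R_en - R_de) > 1e-12, arr.ind = TRUE)
  touched <- match(c("item05", "item12"), rownames(R_en))
  expect_true(all(moved[, 1] %in% touched | moved[, 2] %in% touched))
  # the planted offsets raise item 5 and lower item 12 correlations with
  # their own factor's items
  expect_gt(R_de["item05", "item08"], R_en["item05", "item08"])
  expect_lt(R_de["item12", "item02"], R_en["item12", "item02"])
})

test_that("sample correlation matrices converge to the population", {
  R_pop <- default_population()
  Rs <- sample_study(R_pop, 1e6, seed = 2)
  expect_lt(max(abs(Rs - R_pop)), 0.005)
  # determinism and contract at small n
  expect_identical(sample_study(R_pop, 500, seed = 9),
                   sample_study(R_pop, 500, seed = 9))
  R30 <- sample_study(R_pop, 30, seed = 9)
  expect_equal(diag(R30), rep(1, 20), ignore_attr = TRUE)
  expect_equal(R30, t(R30))
})

test_that("degrade_to_pattern censors below the threshold and keeps Phi consistent", {
  R_pop <- default_population()
  Rs <- sample_study(R_pop, 5000, seed = 4)
  # threshold 0: nothing censored
  sol0 <- degrade_to_pattern(Rs, 3, "promax", censor_threshold = 0)
  expect_false(any(sol0$censored))
  # threshold 1: everything censored, reconstruction is the identity, and
  # pooling must still run on such a record
  sol1 <- degrade_to_pattern(Rs, 3, "promax", censor_threshold = 1)
  expect_true(all(sol1$censored))
  expect_equal(implied_correlations(impute_censored(sol1)), diag(20),
               ignore_attr = TRUE)
  rec <- study_record("s", "s", 5000, "English", "nonclinical", "efa_pattern",
                      pattern = sol1$Lambda, censored = sol1$censored,
                      factor_corr = sol1$Phi)
  pooled <- pool_corpus(list(rec), compute_acov = FALSE)
  expect_equal(pooled$R_pooled, diag(20), ignore_attr = TRUE)
  # censored cells are exactly those below the threshold
  sol <- degrade_to_pattern(Rs, 3, "promax", censor_threshold = 0.40)
  expect_true(all(is.na(sol$Lambda[sol$censored])))
  reconstructed <- implied_correlations(impute_censored(sol))
  expect_gt(cor(vech_corr(reconstructed), vech_corr(Rs)), 0.90)
})

test_that("generated corpora match the configured composition and are reproducible", {
  gen <- cached_corpus(42)
  s <- summarize_corpus(gen$records)
  expect_equal(s$k, 88L)
  expect_equal(unname(s$language_counts[["English"]]), 34L)
  expect_equal(unname(s$status_counts[["clinical"]]), 20L)
  expect_equal(unname(s$source_counts[["raw_correlations"]]), 3L)
  expect_equal(unname(s$source_counts[["efa_pattern"]]), 27L)
  expect_equal(unname(s$source_counts[["cfa_pattern"]]), 58L)
  expect_true(all(vapply(gen$records, `[[`, numeric(1), "n") >= 99))

  # same seed: byte-identical serialisations
  gen2 <- generate_corpus(population_spec(seed = 42))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_corpus(gen$records, d1); write_corpus(gen2$records, d2)
  for (f in dir(d1)) expect_identical(readLines(file.path(d1, f)),
                                      readLines(file.path(d2, f)),
                                      label = f)
})

test_that("end-to-end recovery on an all-raw corpus is essentially exact", {
  ps <- population_spec(seed = 11, reporting_mix = "all_raw", perturb = FALSE)
  gen <- generate_corpus(ps)
  pooled <- pool_corpus(gen$records)
  fit <- fit_wls(build_catalog(tas20_scheme())$specs[["3a"]], pooled,
                 n_starts = 1)
  expect_gte(fit$cfi, 0.99)
  expect_lte(fit$rmsea, 0.01)
  lam_err <- abs(fit$Lambda[fit$spec$lambda_free] -
                   gen$truth$Lambda[gen$truth$Lambda != 0])
  expect_lt(max(lam_err), 0.02)
})

test_that("censored pattern reporting degrades fit by a bounded amount", {
  gen <- cached_corpus(44, perturb = FALSE)
  pooled <- pool_corpus(gen$records)
  fit <- fit_wls(build_catalog(tas20_scheme())$specs[["3a"]], pooled,
                 n_starts = 1)
  # zero-imputed censoring introduces visible but bounded structural error
  expect_gte(fit$cfi, 0.95)
  lam_err <- abs(fit$Lambda[fit$spec$lambda_free] -
                   gen$truth$Lambda[gen$truth$Lambda != 0])
  expect_lt(mean(lam_err), 0.06)
})
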