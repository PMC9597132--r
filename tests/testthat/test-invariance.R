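test_that("a single all-inclusive group reproduces the global fit", {
  gen <- cached_corpus(5, k = 10)
  recs <- lapply(gen$records, function(r) { r$language <- "English"; r })
  spec <- build_catalog(tas20_scheme())$specs[["3a"]]
  ga <- group_analysis(recs, "language", spec, min_samples = 1, n_starts = 1)
  global <- fit_wls(spec, pool_corpus(recs), n_starts = 1)
  expect_equal(nrow(ga$table), 1L)
  expect_equal(ga$table$chisq, global$chi_square, tolerance = 1e-6)
  expect_equal(ga$fits[["English"]]$Lambda, global$Lambda, tolerance = 1e-6)
})

test_that("groups below the sample threshold are excluded with a message", {
  gen <- cached_corpus(42)
  spec <- build_catalog(tas20_scheme())$specs[["3a"]]
  expect_message(
    ga <- group_analysis(gen$records, "language", spec, min_samples = 5,
                         n_starts = 1),
    "excluding")
  expect_setequal(ga$table$group,
                  c("English", "French", "German", "Farsi", "Portuguese",
                    "Japanese"))
  expect_true(all(ga$table$k >= 5))
  # each row reproduces a standalone pool + fit on that group's records
  g <- "French"
  langs <- vapply(gen$records, `[[`, character(1), "language")
  solo <- fit_wls(spec, pool_corpus(gen$records[langs == g]), n_starts = 1)
  row <- ga$table[ga$table$group == g, ]
  expect_equal(row$chisq, solo$chi_square, tolerance = 1e-6)
  expect_equal(row$srmr, solo$srmr, tolerance = 1e-8)
})

test_that("fixed-effects consistency: group pools recombine to the global pool", {
  gen <- cached_corpus(42)
  recs <- gen$records
  langs <- vapply(recs, `[[`, character(1), "language")
  global <- pool_corpus(recs, compute_acov = FALSE)
  acc <- matrix(0, 20, 20); Ntot <- 0
  for (g in unique(langs)) {
    pg <- pool_corpus(recs[langs == g], compute_acov = FALSE)
    acc <- acc + pg$total_N * pg$R_pooled
    Ntot <- Ntot + pg$total_N
  }
  expect_equal(acc / Ntot, global$R_pooled, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("loading deltas are zero against self and antisymmetric under reference swap", {
  gen <- cached_corpus(5, k = 10)
  spec <- build_catalog(tas20_scheme())$specs[["3a"]]
  recs <- gen$records
  half <- seq_along(recs) %% 2 == 0
  fits <- list(
    A = fit_wls(spec, pool_corpus(recs[half]), n_starts = 1),
    B = fit_wls(spec, pool_corpus(recs[!half]), n_starts = 1))
  dAB <- loading_deltas(fits, reference = "A")
  dBA <- loading_deltas(fits, reference = "B")
  expect_equal(unname(dAB$deltas[, "A"]), rep(0, 20))
  expect_equal(dAB$deltas[, "B"], -dBA$deltas[, "A"], tolerance = 1e-12)
  expect_true(all(abs(dAB$deltas) <= 2))
})

test_that("null group differences vanish and planted ones are recovered", {
  # two languages generated from identical populations: deltas ~ 0
  ps <- population_spec(seed = 77, k = 20, reporting_mix = "all_raw",
                        perturb = FALSE)
  gen <- generate_corpus(ps)
  recs <- gen$records
  for (i in seq_along(recs)) recs[[i]]$language <-
    if (i %% 2 == 0) "English" else "German"
  spec <- build_catalog(tas20_scheme())$specs[["3a"]]
  ga <- suppressMessages(group_analysis(recs, "language", spec,
                                        min_samples = 5, n_starts = 1))
  d <- loading_deltas(ga$fits, "English")
  expect_lt(mean(abs(d$deltas[, "German"])), 0.03)

  # planted +.14 on item 5 in translated groups, raw reporting
  ps2 <- population_spec(seed = 78, reporting_mix = "all_raw", perturb = TRUE)
  gen2 <- generate_corpus(ps2)
  ga2 <- suppressMessages(group_analysis(gen2$records, "language", spec,
                                         min_samples = 5, n_starts = 1))
  d2 <- loading_deltas(ga2$fits, "English")
  expect_lt(abs(d2$item_mean_delta[["item05"]] - 0.14), 0.04)
  expect_lt(abs(d2$item_mean_delta[["item12"]] + 0.11), 0.04)
})

test_that("clinical-status analysis runs through the same machinery", {
  gen <- cached_corpus(42)
  spec <- build_catalog(tas20_scheme())$specs[["3a"]]
  ga <- suppressMessages(group_analysis(gen$records, "clinical_status", spec,
                                        min_samples = 5, n_starts = 1))
  expect_setequal(ga$table$group, c("clinical", "nonclinical"))
  expect_true(all(is.finite(ga$table$cfi)))
})
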