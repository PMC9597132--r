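# Configural measurement-invariance comparisons: per-group fixed-effects
# pooling and model fitting, plus loading-difference tables against a
# reference group. Groups are analysed separately (no equality constraints
# across groups), matching a configural comparison of standardized
# solutions.

#' Per-group pooling and model fit
#'
#' Splits the corpus by a grouping key (`"language"` or
#' `"clinical_status"`), drops groups with fewer than `min_samples`
#' samples (with a message), and for each remaining group runs the full
#' machinery: fixed-effects pooling, then a WLS fit of `spec`. A group
#' whose pooled weight matrix is numerically singular is flagged in the
#' table rather than aborting the analysis.
#'
#' @param records list of [study_record()] objects.
#' @param grouping_key record field to split by.
#' @param spec a [model_spec()] to fit in every group.
#' @param min_samples minimum number of samples per group.
#' @param ... passed to [fit_wls()].
#' @return object of class `group_fit_table`: `table` (one row per group:
#'   k, n, chi-square, df, CFI, RMSEA + CI, SRMR, omega per factor),
#'   `fits` (named list of `cfa_fit`), `excluded` (groups below the
#'   threshold).
#' @export
group_analysis <- function(records, grouping_key = c("language", "clinical_status"),
                           spec, min_samples = 5, ...) {
  grouping_key <- match.arg(grouping_key)
  stopifnot(length(records) > 0, min_samples >= 1)
  keys <- vapply(records, `[[`, character(1), grouping_key)
  counts <- sort(table(keys), decreasing = TRUE)
  keep <- names(counts)[counts >= min_samples]
  excluded <- setdiff(names(counts), keep)
  if (length(excluded))
    message("group_analysis: excluding groups below ", min_samples,
            " samples: ", paste(excluded, collapse = ", "))
  fits <- list()
  rows <- list()
  for (g in keep) {
    recs_g <- records[keys == g]
    row <- data.frame(group = g, k = length(recs_g),
                      n = sum(vapply(recs_g, `[[`, numeric(1), "n")),
                      chisq = NA_real_, df = NA_integer_, cfi = NA_real_,
                      rmsea = NA_real_, rmsea_lo = NA_real_, rmsea_hi = NA_real_,
                      srmr = NA_real_, flagged = FALSE,
                      stringsAsFactors = FALSE)
    fit <- tryCatch({
      pooled <- pool_corpus(recs_g, group_label = g)
      fit_wls(spec, pooled, ...)
    }, error = function(e) {
      warning("group '", g, "' could not be fitted: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (is.null(fit)) {
      row$flagged <- TRUE
    } else {
      fits[[g]] <- fit
      row$chisq <- fit$chi_square; row$df <- fit$df; row$cfi <- fit$cfi
      row$rmsea <- fit$rmsea
      row$rmsea_lo <- fit$rmsea_ci[1]; row$rmsea_hi <- fit$rmsea_ci[2]
      row$srmr <- fit$srmr
      for (f in names(fit$omegas)) row[[paste0("omega_", f)]] <- fit$omegas[[f]]
    }
    rows[[g]] <- row
  }
  tab <- do.call(rbind, lapply(rows, function(r) {
    # align columns across flagged/unflagged rows
    all_cols <- unique(unlist(lapply(rows, names)))
    for (cn in setdiff(all_cols, names(r))) r[[cn]] <- NA_real_
    r[all_cols]
  }))
  rownames(tab) <- NULL
  structure(list(table = tab, fits = fits, excluded = excluded,
                 grouping_key = grouping_key, spec_name = spec$name),
            class = "group_fit_table")
}

#' @export
print.group_fit_table <- function(x, ...) {
  cat("Per-group fits of model", x$spec_name, "by", x$grouping_key, "\n")
  print(x$table, digits = 3)
  invisible(x)
}

#' Loading differences against a reference group
#'
#' For every item, the difference between its primary (content-factor)
#' standardized loading in each group and in the reference group,
#' Delta-lambda = lambda_group - lambda_reference, plus per-group summaries
#' (mean absolute difference, range) and the per-item mean difference
#' across non-reference groups.
#'
#' @param fits named list of [fit_wls()] results on the same model
#'   specification (e.g. the `fits` field of [group_analysis()]).
#' @param reference name of the reference group (must be in `fits`).
#' @return object of class `loading_delta_table`: `deltas` (items x
#'   groups), `lambda` (items x groups primary loadings), `group_summary`
#'   (mean |Delta| and range per group), `item_mean_delta`.
#' @export
loading_deltas <- function(fits, reference = "English") {
  stopifnot(length(fits) >= 1, reference %in% names(fits))
  spec <- fits[[reference]]$spec
  same <- vapply(fits, function(f)
    identical(f$spec$lambda_free, spec$lambda_free), logical(1))
  if (!all(same))
    stop("all fits must share the same factor assignment")
  items <- spec$scheme$item_labels
  # primary loading: the item's loading on its assigned content factor
  primary <- function(fit) {
    vapply(seq_along(items), function(i) {
      f <- spec$specific_factors[vapply(spec$specific_factors, function(fc)
        items[i] %in% spec$scheme$factor_assignments[[fc]], logical(1))][1]
      fit$Lambda[i, f]
    }, numeric(1))
  }
  lam <- vapply(fits, primary, numeric(length(items)))
  rownames(lam) <- items
  deltas <- lam - lam[, reference]
  others <- setdiff(colnames(deltas), reference)
  group_summary <- data.frame(
    group = others,
    mean_abs_delta = vapply(others, function(g) mean(abs(deltas[, g])), numeric(1)),
    min_delta = vapply(others, function(g) min(deltas[, g]), numeric(1)),
    max_delta = vapply(others, function(g) max(deltas[, g]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  item_mean_delta <- if (length(others))
    rowMeans(deltas[, others, drop = FALSE]) else stats::setNames(rep(0, length(items)), items)
  structure(list(deltas = deltas, lambda = lam, reference = reference,
                 group_summary = group_summary,
                 item_mean_delta = item_mean_delta),
            class = "loading_delta_table")
}

#' @export
print.loading_delta_table <- function(x, ...) {
  cat("Loading differences vs reference group '", x$reference, "'\n", sep = "")
  print(x$group_summary, digits = 2)
  invisible(x)
}
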