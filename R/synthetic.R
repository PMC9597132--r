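# Seeded generator of synthetic meta-analytic corpora with the statistical
# structure the pipeline assumes: a three-factor population, group-specific
# loading perturbations for translated versions, lognormal sample sizes,
# and primary-study reporting that returns raw correlation matrices, EFA
# patterns censored at a threshold, or CFA patterns.

#' Population specification for the synthetic corpus
#'
#' Defaults are read from the packaged configuration, which encodes a
#' three-factor population (DIF-DDF-EOT) with factor correlations
#' .77/.47/.32, loadings in the ranges typical for the English TAS-20
#' version, a corpus of k = 88 samples with median n = 327, the 16-language
#' mix, 20 clinical samples, a reporting mix of 3 raw / 27 EFA / 58 CFA
#' samples, and a .40 censoring threshold for EFA patterns.
#'
#' @param config path to a population YAML file.
#' @param seed integer seed governing every random draw of the generator.
#' @param residual_correlation overrides the residual-correlation overlay
#'   among the reverse-keyed items (`NULL` keeps the configured value).
#' @param k overrides the number of samples.
#' @param reporting_mix overrides the reporting mix, a named vector of
#'   counts (`raw_correlations`, `efa_pattern`, `cfa_pattern`) summing to
#'   `k`, or the string `"all_raw"`.
#' @param perturb logical; apply the configured cross-group loading
#'   perturbations (set `FALSE` for a homogeneous population, e.g. in
#'   parameter-recovery studies).
#' @return object of class `population_spec`.
#' @export
population_spec <- function(config = system.file("extdata", "tas20_population.yaml",
                                                 package = "metacfa"),
                            seed = 1L, residual_correlation = NULL,
                            k = NULL, reporting_mix = NULL, perturb = TRUE) {
  cfg <- yaml::read_yaml(config)
  items <- names(cfg$loadings)
  factors <- unique(vapply(cfg$loadings, function(x) x[[1]], character(1)))
  Lambda <- matrix(0, length(items), length(factors),
                   dimnames = list(items, factors))
  for (it in items)
    Lambda[it, cfg$loadings[[it]][[1]]] <- as.numeric(cfg$loadings[[it]][[2]])
  Phi <- diag(length(factors))
  dimnames(Phi) <- list(factors, factors)
  for (nm in names(cfg$factor_correlations)) {
    fg <- strsplit(nm, "_", fixed = TRUE)[[1]]
    Phi[fg[1], fg[2]] <- Phi[fg[2], fg[1]] <- as.numeric(cfg$factor_correlations[[nm]])
  }
  neg <- tas20_negative_from_config()
  resid_val <- residual_correlation %||% as.numeric(cfg$residual_correlation_negative_keyed)
  corp <- cfg$corpus
  if (!is.null(k)) corp$k <- k
  mix <- unlist(corp$reporting_mix)
  if (!is.null(reporting_mix)) {
    mix <- if (identical(reporting_mix, "all_raw"))
      c(raw_correlations = corp$k, efa_pattern = 0L, cfa_pattern = 0L)
    else reporting_mix
  }
  if (sum(mix) != corp$k && is.null(k)) {
    stop("reporting mix must sum to k")
  } else if (sum(mix) != corp$k) {
    # k was overridden: rescale the configured mix proportionally
    mix <- round(mix / sum(mix) * corp$k)
    mix[1] <- corp$k - sum(mix[-1])
  }
  langs <- unlist(corp$languages)
  if (!is.null(k) && sum(langs) != corp$k) {
    langs <- round(langs / sum(langs) * corp$k)
    langs[1] <- corp$k - sum(langs[-1])
    langs <- langs[langs > 0]
  }
  structure(list(Lambda = Lambda, Phi = Phi,
                 residual_correlation = resid_val, negative_keyed = neg,
                 k = as.integer(corp$k), n_median = corp$n_median,
                 n_sdlog = corp$n_sdlog, n_min = corp$n_min,
                 languages = langs,
                 clinical_k = min(as.integer(corp$clinical_k), as.integer(corp$k)),
                 reporting_mix = mix,
                 censor_threshold = as.numeric(corp$censor_threshold),
                 group_perturbations = if (perturb) cfg$group_perturbations else list(),
                 seed = as.integer(seed)),
            class = "population_spec")
}

tas20_negative_from_config <- function() {
  cfg <- yaml::read_yaml(system.file("extdata", "tas20_models.yaml",
                                     package = "metacfa"))
  sprintf("item%02d", cfg$negative_keyed)
}

#' @export
print.population_spec <- function(x, ...) {
  cat(sprintf("<population_spec: %d items, %d factors, k = %d, seed = %d>\n",
              nrow(x$Lambda), ncol(x$Lambda), x$k, x$seed))
  invisible(x)
}

#' Population correlation matrix for one group
#'
#' Lambda Phi Lambda' with the group's additive loading offsets applied,
#' plus the residual-correlation overlay among the reverse-keyed items;
#' diagonal forced to 1. Errors if the perturbed matrix is not positive
#' definite, naming the group.
#'
#' @param pspec a [population_spec()].
#' @param group language label; any label other than `"English"` receives
#'   the `translated` perturbation set (unless a group-specific set is
#'   configured).
#' @return positive-definite correlation matrix.
#' @export
population_matrix <- function(pspec, group = "English") {
  L <- pspec$Lambda
  pert <- pspec$group_perturbations[[group]] %||%
    (if (!identical(group, "English")) pspec$group_perturbations[["translated"]] else NULL)
  if (!is.null(pert)) {
    for (it in names(pert)) {
      f <- which(L[it, ] != 0)[1]
      L[it, f] <- L[it, f] + as.numeric(pert[[it]])
    }
  }
  R <- L %*% pspec$Phi %*% t(L)
  if (pspec$residual_correlation != 0) {
    neg <- match(pspec$negative_keyed, rownames(L))
    uni <- 1 - diag(R)
    for (a in seq_along(neg)) for (b in seq_len(a - 1)) {
      i <- neg[a]; j <- neg[b]
      add <- pspec$residual_correlation * sqrt(uni[i] * uni[j])
      R[i, j] <- R[i, j] + add
      R[j, i] <- R[i, j]
    }
  }
  diag(R) <- 1
  if (!is_positive_definite(R))
    stop("population matrix for group '", group,
         "' is not positive definite; check the loading perturbations")
  R
}

#' Sample correlation matrix of one synthetic study
#'
#' Pearson correlations of `n` multivariate-normal draws with population
#' correlation `R_pop`; deterministic given the seed.
#'
#' @param R_pop positive-definite population matrix.
#' @param n sample size (> number of items + 1).
#' @param seed RNG seed.
#' @return sample correlation matrix (symmetric, unit diagonal).
#' @export
sample_study <- function(R_pop, n, seed = 1L) {
  p <- nrow(R_pop)
  stopifnot(n > p + 1)
  set.seed(as.integer(seed))
  X <- matrix(stats::rnorm(n * p), n, p) %*% chol(R_pop)
  R <- stats::cor(X)
  dimnames(R) <- dimnames(R_pop)
  R
}

# principal-axis factoring with iterated communalities
principal_axis <- function(R, m, max_iter = 500, tol = 1e-6) {
  p <- nrow(R)
  h2 <- 1 - 1 / diag(solve(R))
  for (it in seq_len(max_iter)) {
    Rh <- R
    diag(Rh) <- h2
    eg <- eigen(Rh, symmetric = TRUE)
    d <- pmax(eg$values[seq_len(m)], 0)
    L <- eg$vectors[, seq_len(m), drop = FALSE] %*% diag(sqrt(d), m)
    h2_new <- pmin(rowSums(L^2), 1)
    if (max(abs(h2_new - h2)) < tol) {
      rownames(L) <- rownames(R)
      return(L)
    }
    h2 <- h2_new
  }
  stop("principal-axis factoring did not converge in ", max_iter, " iterations")
}

#' Degrade a sample matrix to a reported factor solution
#'
#' Emulates primary-study reporting: principal-axis EFA with the named
#' rotation on the sample matrix, then censoring of loadings whose
#' magnitude falls below the reporting threshold. For the oblique promax
#' rotation the factor correlation matrix is attached (as primary studies
#' reporting oblique patterns must do for reconstruction to be possible).
#'
#' @param R_sample sample correlation matrix.
#' @param m number of factors extracted.
#' @param rotation `"promax"`, `"varimax"`, or `"none"`.
#' @param censor_threshold loadings with |value| below this are marked
#'   censored (0 disables censoring).
#' @return a [factor_solution()] with the censoring mask set.
#' @export
degrade_to_pattern <- function(R_sample, m, rotation = c("promax", "varimax", "none"),
                               censor_threshold = 0.40) {
  rotation <- match.arg(rotation)
  stopifnot(m >= 1)
  L <- principal_axis(R_sample, m)
  Phi <- diag(m)
  if (m > 1 && rotation != "none") {
    v <- stats::varimax(L)
    L <- L %*% v$rotmat
    if (rotation == "promax") {
      pm <- stats::promax(L)
      rot <- pm$rotmat
      Phi <- solve(crossprod(rot))
      # renormalise so factors have exactly unit variance
      s <- sqrt(diag(Phi))
      Phi <- Phi / outer(s, s)
      L <- unclass(pm$loadings) %*% diag(s, m)
    }
  }
  # sign convention: largest-magnitude loading positive
  sgn <- apply(L, 2, function(v) sign(v[which.max(abs(v))]))
  sgn[sgn == 0] <- 1
  L <- sweep(L, 2, sgn, `*`)
  Phi <- Phi * outer(sgn, sgn)
  diag(Phi) <- 1
  cens <- abs(L) < censor_threshold
  L_out <- L
  L_out[cens] <- NA_real_
  rownames(L_out) <- rownames(R_sample)
  colnames(L_out) <- paste0("F", seq_len(m))
  dimnames(Phi) <- list(colnames(L_out), colnames(L_out))
  factor_solution(L_out, Phi, censored = cens,
                  censor_threshold = censor_threshold)
}

#' Generate a synthetic meta-analytic corpus
#'
#' Draws `k` study records: language and clinical labels according to the
#' configured counts, sample sizes from a lognormal distribution (median
#' `n_median`, log-scale spread `n_sdlog`, clamped at `n_min`), sample
#' correlation matrices from the group's population matrix, and reporting
#' per the configured mix — raw matrices, censored promax EFA patterns, or
#' CFA patterns obtained by fitting the three-factor model with the
#' package's own WLS engine to the sample matrix. Fully reproducible from
#' `pspec$seed`.
#'
#' @param pspec a [population_spec()].
#' @param scheme the [item_scheme()] used for the CFA reporting route.
#' @return list with `records` (list of [study_record()]) and `truth`
#'   (population parameters, group matrices, and the per-sample assignment
#'   table).
#' @export
generate_corpus <- function(pspec, scheme = tas20_scheme()) {
  stopifnot(inherits(pspec, "population_spec"))
  k <- pspec$k
  set.seed(pspec$seed)
  languages <- rep(names(pspec$languages), times = pspec$languages)
  clinical <- rep("nonclinical", k)
  clinical[sample.int(k, pspec$clinical_k)] <- "clinical"
  kinds <- sample(rep(names(pspec$reporting_mix), times = pspec$reporting_mix))
  ns <- pmax(round(stats::rlnorm(k, meanlog = log(pspec$n_median),
                                 sdlog = pspec$n_sdlog)), pspec$n_min)
  group_matrices <- lapply(unique(languages), function(g) population_matrix(pspec, g))
  names(group_matrices) <- unique(languages)
  spec3 <- model_spec("truth3", scheme,
                      intersect(colnames(pspec$Lambda),
                                names(scheme$factor_assignments)))
  records <- vector("list", k)
  for (i in seq_len(k)) {
    g <- languages[i]
    Rs <- sample_study(group_matrices[[g]], ns[i],
                       seed = child_seed(pspec$seed, paste0("study-", i)))
    sid <- sprintf("S%03d", i)
    rec <- switch(
      kinds[i],
      raw_correlations = study_record(sid, sid, ns[i], g, clinical[i],
                                      "raw_correlations", correlation = Rs),
      efa_pattern = {
        sol <- degrade_to_pattern(Rs, m = ncol(pspec$Lambda),
                                  rotation = "promax",
                                  censor_threshold = pspec$censor_threshold)
        study_record(sid, sid, ns[i], g, clinical[i], "efa_pattern",
                     pattern = sol$Lambda, censored = sol$censored,
                     factor_corr = sol$Phi,
                     censor_threshold = pspec$censor_threshold)
      },
      cfa_pattern = {
        # Heywood warnings are expected occasionally at small n and are a
        # property of the emulated primary study, not of this corpus
        fit <- suppressWarnings(
          fit_wls(spec3, pool_corpus(list(study_record(sid, sid, ns[i], g,
                                                       clinical[i],
                                                       "raw_correlations",
                                                       correlation = Rs))),
                  n_starts = 1, compute_baseline = FALSE))
        study_record(sid, sid, ns[i], g, clinical[i], "cfa_pattern",
                     pattern = fit$Lambda[, spec3$specific_factors, drop = FALSE],
                     factor_corr = fit$Phi[spec3$specific_factors,
                                           spec3$specific_factors, drop = FALSE])
      })
    records[[i]] <- rec
  }
  truth <- list(Lambda = pspec$Lambda, Phi = pspec$Phi,
                residual_correlation = pspec$residual_correlation,
                group_matrices = group_matrices,
                assignment = data.frame(sample_id = sprintf("S%03d", seq_len(k)),
                                        language = languages,
                                        clinical_status = clinical,
                                        source_kind = kinds, n = ns,
                                        stringsAsFactors = FALSE),
                seed = pspec$seed)
  list(records = records, truth = truth)
}
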