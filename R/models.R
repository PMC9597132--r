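# Declarative catalogue of the competing measurement models for the TAS-20.
#
# Each model is expressed as: a set of free loading positions (items x
# factors), a set of free factor correlations, and optional overlays (a
# general factor, a method factor over the reverse-keyed items, or free
# residual correlations among item pairs). Identification is by
# unit-variance factors with all loadings free (standardized solution);
# uniquenesses are implied by the correlation metric, not free parameters,
# so df = p(p-1)/2 - (number of free parameters).

#' Construct a measurement-model specification
#'
#' @param name model name (e.g. `"3a"`).
#' @param scheme an [item_scheme()].
#' @param base_factors character vector of base (content) factor names from
#'   the scheme; together they must partition the items (a bifactor general
#'   factor or method factor is an overlay, not part of the partition).
#' @param correlated logical; free correlations among all base factor pairs
#'   (otherwise the base factors are orthogonal).
#' @param general_factor logical; add a general factor loading on all items,
#'   orthogonal to every other factor (bifactor overlay). `general_skip`
#'   names base factors to drop from the partition's specific factors
#'   (reference-factor bifactor variants).
#' @param general_skip character vector of base factors whose specific
#'   factor is removed (its items load only on the general factor).
#' @param method_items item labels loading on an orthogonal method factor
#'   (`NULL` for none).
#' @param residual_items item labels among which all pairwise residual
#'   correlations are freed (`NULL` for none).
#' @return object of class `model_spec` with the free-parameter layout and
#'   computed degrees of freedom.
#' @export
model_spec <- function(name, scheme, base_factors,
                       correlated = TRUE,
                       general_factor = FALSE, general_skip = character(0),
                       method_items = NULL, residual_items = NULL) {
  stopifnot(inherits(scheme, "item_scheme"))
  p <- scheme$n_items
  check_partition(scheme, base_factors)
  specific_factors <- setdiff(base_factors, if (general_factor) general_skip else character(0))
  factors <- c(if (general_factor) "G", specific_factors,
               if (!is.null(method_items)) "METH")
  nf <- length(factors)
  lambda_free <- matrix(FALSE, p, nf, dimnames = list(scheme$item_labels, factors))
  if (general_factor) lambda_free[, "G"] <- TRUE
  for (f in specific_factors)
    lambda_free[scheme_items(scheme, f), f] <- TRUE
  if (!is.null(method_items)) {
    bad <- setdiff(method_items, scheme$item_labels)
    if (length(bad)) stop("method-factor items not in scheme: ",
                          paste(bad, collapse = ", "))
    lambda_free[method_items, "METH"] <- TRUE
  }
  if (any(rowSums(lambda_free) == 0))
    stop("model '", name, "': some items load on no factor")

  # free factor correlations: among base content factors only, when requested;
  # overlay factors (G, METH) are orthogonal to everything
  phi_pairs <- NULL
  if (correlated && length(specific_factors) > 1 && !general_factor) {
    cmb <- utils::combn(match(specific_factors, factors), 2)
    phi_pairs <- t(cmb)
  }

  resid_pairs <- NULL
  if (!is.null(residual_items)) {
    bad <- setdiff(residual_items, scheme$item_labels)
    if (length(bad)) stop("residual-correlation items not in scheme: ",
                          paste(bad, collapse = ", "))
    ix <- match(residual_items, scheme$item_labels)
    cmb <- utils::combn(sort(ix), 2)
    resid_pairs <- t(cmb)[, c(2, 1), drop = FALSE]  # (row > col) convention
  }

  n_par <- sum(lambda_free) + NROW(phi_pairs) + NROW(resid_pairs)
  df <- p * (p - 1) / 2 - n_par
  if (df < 0) stop("model '", name, "' is not identified: df = ", df)
  structure(list(name = name, scheme = scheme, factors = factors,
                 base_factors = base_factors,
                 specific_factors = specific_factors,
                 general_factor = general_factor,
                 lambda_free = lambda_free, phi_pairs = phi_pairs,
                 resid_pairs = resid_pairs,
                 n_par = as.integer(n_par), df = as.integer(df)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec %s: %d free loadings on {%s}, %d factor corr, %d residual corr, df = %d>\n",
              x$name, sum(x$lambda_free), paste(x$factors, collapse = ", "),
              NROW(x$phi_pairs), NROW(x$resid_pairs), x$df))
  invisible(x)
}

#' Build the TAS-20 measurement-model catalogue
#'
#' Returns the standard competing models:
#' \describe{
#'   \item{1}{unidimensional (all items on one alexithymia factor), df 170}
#'   \item{2}{two factors DIF/DDF merged + EOT, df 169}
#'   \item{3a}{original three factors DIF-DDF-EOT, df 167}
#'   \item{3b}{DIF/DDF merged + PT + IOE, df 167}
#'   \item{3c}{alternative allocation DIF/DDF-EOT-IOE, df 167}
#'   \item{4}{four factors DIF-DDF-PT-IOE, df 164}
#'   \item{5}{bifactor: general + three orthogonal specific factors, df 150}
#'   \item{5b}{reference-factor bifactor with DDF as reference (flagged
#'     variant, only with `include_5b = TRUE`)}
#'   \item{6}{3a + orthogonal method factor on the five reverse-keyed items,
#'     df 162}
#'   \item{7}{3a + free residual correlations among the five reverse-keyed
#'     items (correlated-trait correlated-uniqueness), df 157}
#' }
#' The `independence` baseline (df 190) and `saturated` reference points
#' are closed-form and provided by [reference_fits()] rather than as
#' catalogue entries.
#'
#' @param scheme an [item_scheme()]; defaults to [tas20_scheme()].
#' @param include_5b include the reference-factor bifactor variant.
#' @return object of class `model_catalog` (named list of [model_spec()]).
#' @export
build_catalog <- function(scheme = tas20_scheme(), include_5b = FALSE) {
  neg <- scheme$negative_keyed
  # merged DIF+DDF partition factor is expressed through a merged scheme entry
  scheme2 <- scheme
  scheme2$factor_assignments$DIFDDF <-
    sort(unique(c(scheme$factor_assignments$DIF, scheme$factor_assignments$DDF)))
  scheme2$factor_assignments$ALEX <- scheme$item_labels
  specs <- list(
    "1"  = model_spec("1", scheme2, "ALEX"),
    "2"  = model_spec("2", scheme2, c("DIFDDF", "EOT")),
    "3a" = model_spec("3a", scheme2, c("DIF", "DDF", "EOT")),
    "3b" = model_spec("3b", scheme2, c("DIFDDF", "PT", "IOE")),
    "3c" = model_spec("3c", scheme2, c("DIFDDF", "EOT_3c", "IOE_3c")),
    "4"  = model_spec("4", scheme2, c("DIF", "DDF", "PT", "IOE")),
    "5"  = model_spec("5", scheme2, c("DIF", "DDF", "EOT"),
                      correlated = FALSE, general_factor = TRUE),
    "6"  = model_spec("6", scheme2, c("DIF", "DDF", "EOT"),
                      method_items = neg),
    "7"  = model_spec("7", scheme2, c("DIF", "DDF", "EOT"),
                      residual_items = neg)
  )
  if (include_5b)
    specs[["5b"]] <- model_spec("5b", scheme2, c("DIF", "DDF", "EOT"),
                                correlated = FALSE, general_factor = TRUE,
                                general_skip = "DDF")
  structure(list(specs = specs, scheme = scheme),
            class = "model_catalog")
}

#' @export
print.model_catalog <- function(x, ...) {
  cat("Model catalogue:\n")
  for (s in x$specs)
    cat(sprintf("  %-3s df = %3d  (%d parameters)\n", s$name, s$df, s$n_par))
  invisible(x)
}
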