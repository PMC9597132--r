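#' Item scheme for a fixed-length instrument
#'
#' An item scheme records the ordered item labels, the reverse-keyed item
#' set, and the named item-to-factor partitions used by the measurement-model
#' catalogue. The default scheme describes the 20-item Toronto Alexithymia
#' Scale: three content factors (DIF, DDF, EOT), five reverse-keyed items
#' (four of which belong to EOT), and the sub-facet splits of EOT used by
#' the alternative models.
#'
#' @param n_items number of items.
#' @param negative_keyed integer item numbers of the reverse-worded items.
#' @param factor_assignments named list mapping factor name to integer item
#'   numbers. Partitions used as base models must cover every item once.
#' @return object of class `item_scheme` with fields `n_items`,
#'   `item_labels`, `negative_keyed` (labels), `factor_assignments`
#'   (label lists).
#' @export
item_scheme <- function(n_items, negative_keyed, factor_assignments) {
  stopifnot(n_items >= 2)
  labels <- sprintf("item%02d", seq_len(n_items))
  if (anyDuplicated(labels)) stop("item labels must be unique")
  if (any(negative_keyed < 1 | negative_keyed > n_items))
    stop("negative_keyed items outside 1..n_items")
  fa <- lapply(factor_assignments, function(ix) {
    if (any(ix < 1 | ix > n_items)) stop("factor assignment outside 1..n_items")
    labels[sort(unique(as.integer(ix)))]
  })
  structure(
    list(
      n_items = as.integer(n_items),
      item_labels = labels,
      negative_keyed = labels[sort(unique(as.integer(negative_keyed)))],
      factor_assignments = fa
    ),
    class = "item_scheme"
  )
}

#' The TAS-20 item scheme
#'
#' Reads the packaged assignment configuration (standard DIF/DDF/EOT scoring
#' key, reverse-keyed items, and the PT/IOE sub-facet splits) and returns the
#' corresponding [item_scheme()]. The assignments live in a configuration
#' file rather than in code so alternative allocations can be studied by
#' editing configuration only.
#'
#' @param config path to a YAML assignment file; defaults to the packaged
#'   TAS-20 configuration.
#' @return an `item_scheme` with factors DIF, DDF, EOT, PT, IOE, EOT_3c,
#'   IOE_3c and exactly five reverse-keyed items.
#' @export
tas20_scheme <- function(config = system.file("extdata", "tas20_models.yaml",
                                              package = "metacfa")) {
  cfg <- yaml::read_yaml(config)
  sch <- item_scheme(cfg$n_items, cfg$negative_keyed, cfg$factors)
  if (sch$n_items == 20L && length(sch$negative_keyed) != 5L)
    stop("TAS-20 scheme must have exactly 5 reverse-keyed items")
  sch
}

#' @export
print.item_scheme <- function(x, ...) {
  cat("Item scheme:", x$n_items, "items;",
      length(x$negative_keyed), "reverse-keyed (",
      paste(x$negative_keyed, collapse = ", "), ")\n")
  for (f in names(x$factor_assignments))
    cat(sprintf("  %-7s %s\n", f, paste(x$factor_assignments[[f]], collapse = " ")))
  invisible(x)
}

# indices of a factor's items within the scheme's label order
scheme_items <- function(scheme, factor) {
  match(scheme$factor_assignments[[factor]], scheme$item_labels)
}

# check that a set of factors partitions all items exactly once
check_partition <- function(scheme, factors) {
  ix <- unlist(lapply(factors, function(f) scheme_items(scheme, f)))
  if (length(ix) != scheme$n_items || anyDuplicated(ix) ||
      !setequal(ix, seq_len(scheme$n_items)))
    stop("factors {", paste(factors, collapse = ", "),
         "} do not partition the ", scheme$n_items, " items exactly once")
  invisible(TRUE)
}
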