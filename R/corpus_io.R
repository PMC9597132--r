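# Delimited-text storage for a meta-analytic corpus.
#
# Layout: one coding sheet (CSV, one row per sample) plus one matrix file
# per sample under the same directory. Correlation matrices are stored as
# labelled square CSV tables with both triangles populated; factor patterns
# as items-by-factors CSV tables in which censored loadings appear as the
# marker "c"; oblique factor correlations in a companion *_phi.csv file.

CODING_COLUMNS <- c("study_id", "sample_id", "n", "language", "clinical_status",
                    "source_kind", "matrix_file", "phi_file",
                    "censor_threshold", "already_recoded")

write_matrix_csv <- function(M, path) {
  df <- data.frame(label = rownames(M), M, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  labs <- df[[1]]
  M <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(M) <- "double"
  rownames(M) <- labs
  M
}

#' Write a corpus to a directory
#'
#' Emits the coding sheet (`coding_sheet.csv`), one matrix file per sample,
#' and a JSON manifest. The representation is lossless: [read_corpus()] on
#' the result reproduces every record field by field.
#'
#' @param records list of [study_record()] objects.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(records, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  labels <- sprintf("item%02d", seq_len(records[[1]]$n_items))
  rows <- lapply(records, function(rec) {
    base <- paste0(rec$sample_id)
    if (rec$source_kind == "raw_correlations") {
      mf <- paste0(base, "_cor.csv")
      M <- rec$correlation
      dimnames(M) <- list(labels, labels)
      write_matrix_csv(M, file.path(dir, mf))
      pf <- ""
    } else {
      mf <- paste0(base, "_pattern.csv")
      P <- rec$pattern
      chr <- matrix(vapply(P, function(x) format(x, digits = 15), character(1)),
                    nrow = nrow(P))
      chr[rec$censored] <- "c"
      df <- data.frame(label = labels, chr, check.names = FALSE,
                       stringsAsFactors = FALSE)
      colnames(df) <- c("label", colnames(P) %||% paste0("F", seq_len(ncol(P))))
      utils::write.csv(df, file.path(dir, mf), row.names = FALSE, quote = FALSE)
      pf <- paste0(base, "_phi.csv")
      Phi <- rec$factor_corr
      dimnames(Phi) <- rep(list(colnames(df)[-1]), 2)
      write_matrix_csv(Phi, file.path(dir, pf))
    }
    data.frame(study_id = rec$study_id, sample_id = rec$sample_id, n = rec$n,
               language = rec$language, clinical_status = rec$clinical_status,
               source_kind = rec$source_kind, matrix_file = mf, phi_file = pf,
               censor_threshold = rec$censor_threshold,
               already_recoded = rec$already_recoded,
               stringsAsFactors = FALSE)
  })
  sheet <- do.call(rbind, rows)
  utils::write.csv(sheet, file.path(dir, "coding_sheet.csv"),
                   row.names = FALSE, quote = FALSE)
  manifest <- list(format = "metacfa-corpus", version = 1L,
                   k = length(records), n_items = records[[1]]$n_items)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a corpus from a coding sheet and matrix directory
#'
#' Each row of the coding sheet is validated into a [study_record()]. Rows
#' that fail validation are collected and reported in a single error (not
#' silently dropped); a missing matrix file is a hard error naming the
#' sample. Non-positive-definite correlation matrices are accepted with a
#' warning (fixed-effects pooling restores definiteness in practice) unless
#' `repair = TRUE`, in which case they are projected to the nearest
#' correlation matrix.
#'
#' @param coding_sheet path to the coding-sheet CSV.
#' @param matrix_dir directory holding the per-sample matrix files; defaults
#'   to the directory of `coding_sheet`.
#' @param repair logical; repair indefinite correlation matrices via
#'   [repair_correlation()].
#' @param n_items expected instrument length.
#' @return list of `study_record` objects.
#' @export
read_corpus <- function(coding_sheet, matrix_dir = dirname(coding_sheet),
                        repair = FALSE, n_items = 20L) {
  sheet <- utils::read.csv(coding_sheet, stringsAsFactors = FALSE)
  missing_cols <- setdiff(CODING_COLUMNS, names(sheet))
  if (length(missing_cols))
    stop("coding sheet lacks required columns: ", paste(missing_cols, collapse = ", "))
  failures <- character(0)
  records <- vector("list", nrow(sheet))
  for (i in seq_len(nrow(sheet))) {
    row <- sheet[i, ]
    rec <- tryCatch(
      read_one_record(row, matrix_dir, repair = repair, n_items = n_items),
      error = function(e) {
        failures <<- c(failures, paste0(row$sample_id, ": ", conditionMessage(e)))
        NULL
      })
    records[[i]] <- rec
  }
  if (length(failures))
    stop("corpus validation failed for ", length(failures), " sample(s):\n  ",
         paste(failures, collapse = "\n  "))
  records
}

read_one_record <- function(row, matrix_dir, repair, n_items) {
  path <- file.path(matrix_dir, row$matrix_file)
  if (!file.exists(path))
    stop("matrix file '", row$matrix_file, "' not found")
  if (row$source_kind == "raw_correlations") {
    R <- read_matrix_csv(path)
    R <- validate_correlation(R, paste0("sample '", row$sample_id, "' correlation"))
    if (!is_positive_definite(R)) {
      if (repair) {
        R <- repair_correlation(R)
      } else {
        warning("sample '", row$sample_id,
                "': correlation matrix is not positive definite", call. = FALSE)
      }
    }
    study_record(row$study_id, row$sample_id, row$n, row$language,
                 row$clinical_status, row$source_kind, correlation = R,
                 censor_threshold = as.numeric(row$censor_threshold),
                 already_recoded = as.logical(row$already_recoded),
                 n_items = n_items)
  } else {
    df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
    P <- as.matrix(df[, -1, drop = FALSE])
    cens <- P == "c"
    P[cens] <- NA
    storage.mode(P) <- "double"
    rownames(P) <- df[[1]]
    Phi <- NULL
    if (nzchar(row$phi_file %||% "")) {
      phi_path <- file.path(matrix_dir, row$phi_file)
      if (!file.exists(phi_path))
        stop("factor-correlation file '", row$phi_file, "' not found")
      Phi <- read_matrix_csv(phi_path)
    }
    study_record(row$study_id, row$sample_id, row$n, row$language,
                 row$clinical_status, row$source_kind,
                 pattern = P, censored = cens, factor_corr = Phi,
                 censor_threshold = as.numeric(row$censor_threshold),
                 already_recoded = as.logical(row$already_recoded),
                 n_items = n_items)
  }
}
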