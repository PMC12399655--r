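#' Read and write the pipeline's tabular formats
#'
#' Thin TSV wrappers around readr with the column layouts the pipeline
#' expects: expression tables carry genes as rows with a leading `gene`
#' column; sample metadata has `sample_id`, `patient_id`, `region_id`;
#' survival tables have `sample_id`, `time`, `event` plus free covariate
#' columns; cell counts travel as MatrixMarket with side files for gene and
#' cell identifiers.
#'
#' @param expr Gene x sample matrix.
#' @param path,dir File or directory paths.
#' @name evosig-io
NULL

#' @rdname evosig-io
#' @export
write_expression_tsv <- function(expr, path) {
  m <- as_expr_matrix(expr)
  df <- dplyr::bind_cols(tibble(gene = rownames(m)), as_tibble(m))
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname evosig-io
#' @export
read_expression_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  as_expr_matrix(df)
}

#' @rdname evosig-io
#' @param meta Tibble of sample or cell metadata.
#' @export
write_metadata_tsv <- function(meta, path) {
  readr::write_tsv(meta, path)
  invisible(path)
}

#' @rdname evosig-io
#' @export
read_metadata_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname evosig-io
#' @param surv Survival tibble (`sample_id`, `time`, `event`, covariates).
#' @export
write_survival_tsv <- function(surv, path) {
  readr::write_tsv(surv, path)
  invisible(path)
}

#' @rdname evosig-io
#' @export
read_survival_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("sample_id", "time", "event") %in% names(out))) {
    abort("Survival TSV must have sample_id, time and event columns.")
  }
  out
}

#' @rdname evosig-io
#' @param counts Gene x cell count matrix.
#' @export
write_cell_counts <- function(counts, meta, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sp <- Matrix::Matrix(as.matrix(counts), sparse = TRUE)
  Matrix::writeMM(sp, file.path(dir, "counts.mtx"))
  readr::write_lines(rownames(counts), file.path(dir, "genes.tsv"))
  readr::write_lines(colnames(counts), file.path(dir, "cells.tsv"))
  readr::write_tsv(meta, file.path(dir, "cell_metadata.tsv"))
  invisible(dir)
}

#' @rdname evosig-io
#' @export
read_cell_counts <- function(dir) {
  counts <- as.matrix(Matrix::readMM(file.path(dir, "counts.mtx")))
  rownames(counts) <- readr::read_lines(file.path(dir, "genes.tsv"))
  colnames(counts) <- readr::read_lines(file.path(dir, "cells.tsv"))
  meta <- readr::read_tsv(file.path(dir, "cell_metadata.tsv"),
                          show_col_types = FALSE)
  list(counts = counts, meta = meta)
}

#' Serialize a fitted signature to JSON
#'
#' Writes the portable part of an `evosig_model` (genes, coefficients,
#' standardization parameters, training median, selection frequencies, and
#' build metadata) as JSON. The underlying Cox fit object is not
#' serialized: a reloaded model can score cohorts but not predict absolute
#' survival probabilities.
#'
#' @param model An `evosig_model`.
#' @param path Output path.
#' @export
write_signature_json <- function(model, path) {
  stopifnot(inherits(model, "evosig_model"))
  payload <- list(
    genes = model$genes,
    beta = as.list(model$beta),
    center = as.list(model$center),
    scale = as.list(model$scale),
    train_median_score = model$train_median_score,
    n = model$n, n_events = model$n_events,
    selection_frequencies = model$selection_frequencies,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_signature_json
#' @export
read_signature_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(genes = p$genes,
         beta = stats::setNames(unlist(p$beta), names(p$beta)),
         center = stats::setNames(unlist(p$center), names(p$center)),
         scale = stats::setNames(unlist(p$scale), names(p$scale)),
         train_median_score = p$train_median_score,
         selection_frequencies = if (!is.null(p$selection_frequencies))
           as_tibble(p$selection_frequencies) else NULL,
         fit = NULL, n = p$n, n_events = p$n_events),
    class = "evosig_model")
}
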