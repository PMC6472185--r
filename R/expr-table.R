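#' Expression tables
#'
#' Throughout the package an expression matrix travels as a tibble with a
#' `gene_name` column, a `code_class` column, and one numeric column per
#' sample, carrying a `stage` attribute that records where in the pipeline the
#' values stand: `"flat"` (raw instrument counts), `"background_corrected"`,
#' `"normalized"` or `"zscored"`.
#'
#' @param cartridge A `cartridge` object.
#' @param classes Code classes to keep as rows (default: all).
#' @param stage Stage label to attach.
#' @return A tibble of class `expr_tbl`.
#' @export
expr_table <- function(cartridge, classes = NULL, stage = "flat") {
  long <- tidy.cartridge(cartridge)
  if (!is.null(classes)) long <- dplyr::filter(long, .data$code_class %in% classes)
  wide <- tidyr::pivot_wider(
    dplyr::select(long, "gene_name", "code_class", "sample_id", "count"),
    names_from = "sample_id", values_from = "count"
  )
  new_expr_tbl(wide, stage)
}

new_expr_tbl <- function(tbl, stage) {
  stopifnot(all(c("gene_name", "code_class") %in% names(tbl)))
  tbl <- tibble::as_tibble(tbl)
  attr(tbl, "stage") <- stage
  class(tbl) <- c("expr_tbl", class(tbl))
  tbl
}

#' Build an expression table from a plain matrix
#'
#' @param values Numeric matrix, genes x samples, with dimnames.
#' @param code_class Code class per gene (recycled).
#' @param stage Pipeline stage label.
#' @return An `expr_tbl`.
#' @export
as_expr_table <- function(values, code_class = "Endogenous", stage = "normalized") {
  stopifnot(is.matrix(values), !is.null(rownames(values)), !is.null(colnames(values)))
  tbl <- tibble::tibble(
    gene_name = rownames(values),
    code_class = rep_len(code_class, nrow(values))
  )
  tbl <- dplyr::bind_cols(tbl, tibble::as_tibble(values, .name_repair = "minimal"))
  new_expr_tbl(tbl, stage)
}

#' @export
#' @rdname expr_table
#' @param x An `expr_tbl`.
expr_stage <- function(x) attr(x, "stage")

#' @export
#' @rdname expr_table
expr_values <- function(x) {
  cols <- setdiff(names(x), c("gene_name", "code_class"))
  m <- as.matrix(x[, cols, drop = FALSE])
  rownames(m) <- x$gene_name
  m
}

#' @export
#' @rdname expr_table
expr_samples <- function(x) setdiff(names(x), c("gene_name", "code_class"))

# replace the numeric block, keeping annotation columns
expr_replace <- function(x, values, stage = expr_stage(x)) {
  tbl <- dplyr::select(tibble::as_tibble(x), "gene_name", "code_class")
  tbl <- dplyr::bind_cols(tbl, tibble::as_tibble(values, .name_repair = "minimal"))
  new_expr_tbl(tbl, stage)
}

#' @export
print.expr_tbl <- function(x, ...) {
  cat(sprintf("# expression table: %d genes x %d samples, stage '%s'\n",
              nrow(x), length(expr_samples(x)), expr_stage(x)))
  NextMethod()
}

#' Write an expression table to TSV
#'
#' Genes as rows; first column the gene name, second the code class, then one
#' column per sample.
#'
#' @param x An `expr_tbl`.
#' @param path Output path.
#' @export
write_expr_tsv <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path, progress = FALSE)
  invisible(path)
}
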