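#' Rank genes by expression instability
#'
#' Applies the same pairwise log-ratio stability model used for housekeeper
#' selection, but in reverse: a single pass computes the M statistic of every
#' gene against all others, and genes are returned most-unstable first. No
#' iterative elimination is performed — filtering is a selection, not a
#' reference search. Ties on M are broken lexicographically ascending on the
#' gene name.
#'
#' @param x An `expr_tbl` with strictly positive values (stage
#'   `"normalized"`), or a positive matrix genes x samples.
#' @return A tibble sorted by decreasing instability with columns
#'   `gene_name`, `stability_M`, `rank`.
#' @export
instability_ranking <- function(x) {
  M <- genorm_stability(x)
  ord <- order(-M, names(M))
  tibble::tibble(
    gene_name = names(M)[ord],
    stability_M = unname(M)[ord],
    rank = seq_along(M)
  )
}

#' Keep the k most variable genes
#'
#' Subsets an expression table to its least stable genes, either as an
#' absolute count (`k`) or as a percentage of the panel — the two
#' parameterizations of the same filter. Selections are nested: the top-k set
#' is always a prefix of the top-(k+1) set.
#'
#' @param x An `expr_tbl` with positive values.
#' @param k Number of genes to keep (count mode).
#' @param percent Percentage in (0, 100\] of genes to keep; resolves to
#'   `ceiling(percent/100 * n_genes)`. Give exactly one of `k` and `percent`.
#' @return An `expr_tbl` with the selected genes, ordered most variable
#'   first; sample columns untouched.
#' @export
#' @examples
#' \dontrun{
#' norm$matrix |> apply_filter(k = 100)
#' norm$matrix |> apply_filter(percent = 10)
#' }
apply_filter <- function(x, k = NULL, percent = NULL) {
  if (is.null(k) == is.null(percent)) {
    rlang::abort("Give exactly one of `k` and `percent`",
                 class = "nanolane_validation_error")
  }
  n_genes <- nrow(x)
  if (!is.null(percent)) {
    if (percent <= 0 || percent > 100) {
      rlang::abort("`percent` must be in (0, 100]", class = "nanolane_validation_error")
    }
    k <- ceiling(percent / 100 * n_genes)
  }
  if (k < 1 || k > n_genes) {
    rlang::abort(sprintf("`k` must be in 1..%d (the number of genes)", n_genes),
                 class = "nanolane_validation_error")
  }
  ranking <- instability_ranking(x)
  keep <- ranking$gene_name[seq_len(k)]
  out <- x[match(keep, x$gene_name), , drop = FALSE]
  new_expr_tbl(out, expr_stage(x))
}
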