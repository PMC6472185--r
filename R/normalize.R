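#' Negative-control background threshold
#'
#' The per-lane detection background is the geometric mean of the lane's
#' negative-control counts plus two sample standard deviations of those
#' counts. Zero counts enter the geometric mean as 1, so the threshold is
#' always at least 1 and downstream log-ratio work stays defined.
#'
#' @param negative_counts Non-negative integer counts of the lane's negative
#'   control probes (at least 2).
#' @return The threshold (a single positive number).
#' @export
#' @examples
#' background_threshold(c(8, 12, 10, 14, 6, 9, 11, 10))
background_threshold <- function(negative_counts) {
  if (length(negative_counts) < 2) {
    rlang::abort("At least 2 negative-control counts are required",
                 class = "nanolane_controls_error")
  }
  if (any(negative_counts < 0)) {
    rlang::abort("Negative-control counts must be non-negative",
                 class = "nanolane_domain_error")
  }
  gm <- geomean(pmax(negative_counts, 1))
  gm + 2 * stats::sd(negative_counts)
}

#' Floor counts at the per-lane background threshold
#'
#' Background correction is thresholding, not subtraction: within each sample
#' every count below that sample's threshold is raised to the threshold, so
#' the corrected matrix is strictly positive.
#'
#' @param x An `expr_tbl` at stage `"flat"`.
#' @param thresholds Numeric vector, one threshold per sample; a named vector
#'   is matched by sample id.
#' @return An `expr_tbl` at stage `"background_corrected"`.
#' @export
apply_background <- function(x, thresholds) {
  samples <- expr_samples(x)
  if (!is.null(names(thresholds))) {
    missing <- setdiff(samples, names(thresholds))
    if (length(missing) > 0) {
      rlang::abort(sprintf("No threshold for sample(s): %s",
                           paste(missing, collapse = ", ")),
                   class = "nanolane_dimension_error")
    }
    thresholds <- thresholds[samples]
  } else if (length(thresholds) != length(samples)) {
    rlang::abort(sprintf("Got %d thresholds for %d samples",
                         length(thresholds), length(samples)),
                 class = "nanolane_dimension_error")
  }
  m <- expr_values(x)
  m <- pmax(m, matrix(thresholds, nrow = nrow(m), ncol = ncol(m), byrow = TRUE))
  expr_replace(x, m, stage = "background_corrected")
}

#' geNorm expression-stability statistic
#'
#' For gene *j* the stability value M is the mean, over every other gene *k*,
#' of the standard deviation across samples of the pairwise log2 expression
#' ratio log2(x_j / x_k). Genes whose expression moves in lockstep with the
#' rest of the panel have low M; genes that vary independently have high M.
#' Because ratios within a sample are untouched by any per-sample scaling, M
#' can be computed before lane normalization — which is exactly why it is
#' used to pick the normalization references.
#'
#' @param x An `expr_tbl` with strictly positive values (background-corrected
#'   or normalized), or a plain positive matrix genes x samples.
#' @return A named numeric vector of M values, one per gene, in input order.
#' @export
genorm_stability <- function(x) {
  m <- if (inherits(x, "expr_tbl")) expr_values(x) else x
  if (nrow(m) < 2 || ncol(m) < 2) {
    rlang::abort("Stability needs at least 2 genes and 2 samples",
                 class = "nanolane_domain_error")
  }
  if (any(m <= 0)) {
    rlang::abort("Stability requires strictly positive values; run background correction first",
                 class = "nanolane_domain_error")
  }
  L <- log2(m)
  # sd(L_j - L_k)^2 = var_j + var_k - 2 cov_jk, all with the n-1 denominator
  C <- stats::cov(t(L))
  v <- diag(C)
  g <- nrow(m)
  sd_pair <- sqrt(pmax(outer(v, v, "+") - 2 * C, 0))
  M <- (rowSums(sd_pair)) / (g - 1)  # diagonal is 0, so sum/(g-1) = mean over k != j
  stats::setNames(M, rownames(m))
}

#' Iteratively select the most stable housekeeping genes
#'
#' Classic geNorm elimination: compute M for all candidates, drop the gene
#' with the highest M, recompute, and repeat until `n_keep` genes remain.
#' Ties on M are broken by removing the lexicographically last gene name
#' first, so selection is fully deterministic.
#'
#' @param x Positive `expr_tbl` (housekeeping rows) or matrix, candidates x
#'   samples.
#' @param n_keep How many genes to retain; at least 3.
#' @return A list with `selected` (surviving gene names in input order),
#'   `stability_M` (M values of the survivors at the final iteration) and
#'   `initial_M` (single-pass M of all candidates).
#' @export
select_housekeepers <- function(x, n_keep = 3) {
  m <- if (inherits(x, "expr_tbl")) expr_values(x) else x
  if (n_keep < 3) {
    rlang::abort("n_keep must be at least 3", class = "nanolane_validation_error")
  }
  if (nrow(m) < n_keep) {
    rlang::abort(sprintf("Only %d candidate housekeepers for n_keep = %d",
                         nrow(m), n_keep),
                 class = "nanolane_validation_error")
  }
  initial_M <- genorm_stability(m)
  cur <- m
  while (nrow(cur) > n_keep) {
    M <- genorm_stability(cur)
    worst <- max(M)
    ties <- names(M)[M >= worst - 1e-15]
    drop <- sort(ties)[length(ties)]  # lexicographically last among ties
    cur <- cur[rownames(cur) != drop, , drop = FALSE]
  }
  final_M <- genorm_stability(cur)
  selected <- rownames(m)[rownames(m) %in% rownames(cur)]
  list(selected = selected, stability_M = final_M[selected], initial_M = initial_M)
}

#' Lane scaling factors from housekeeper geometric means
#'
#' Let g_l be the geometric mean of the selected housekeepers' counts in lane
#' l and A the arithmetic mean of the g_l across lanes. The scaling factor of
#' lane l is SF_l = A / g_l, so after multiplying each lane by its factor the
#' housekeeper geometric mean is the same constant A in every lane.
#'
#' @param hk Positive `expr_tbl` or matrix of the selected housekeepers
#'   (genes x samples).
#' @return A tibble with columns `sample_id`, `lane_geomean`,
#'   `scaling_factor`.
#' @export
scaling_factors <- function(hk) {
  m <- if (inherits(hk, "expr_tbl")) expr_values(hk) else hk
  if (any(m <= 0)) {
    rlang::abort("Scaling factors require strictly positive housekeeper values",
                 class = "nanolane_domain_error")
  }
  g <- apply(m, 2, geomean)
  A <- mean(g)
  tibble::tibble(
    sample_id = colnames(m) %||% as.character(seq_along(g)),
    lane_geomean = unname(g),
    scaling_factor = unname(A / g)
  )
}

#' Normalize a cartridge (background, housekeepers, lane scaling)
#'
#' Runs the three computational normalization steps in order: (i) a
#' background threshold is computed from each lane's negative controls and
#' all counts are floored at it; (ii) the most stable housekeeping genes are
#' selected by iterative geNorm elimination on the corrected counts; (iii)
#' per-lane scaling factors equalizing the selected housekeepers' geometric
#' means are computed and applied to the corrected counts. Endogenous and
#' housekeeping probes make up the output matrix; control probes are dropped
#' from it but their corrected counts are kept on the result object.
#'
#' @param cartridge A `cartridge`.
#' @param n_keep Number of housekeepers to retain (default 3, the method's
#'   minimum).
#' @return A `nanolane_norm` object; see [tidy.nanolane_norm()] and
#'   [glance.nanolane_norm()]. Fields: `background_thresholds`,
#'   `selected_housekeepers`, `stability_M`, `lane_geomeans`,
#'   `scaling_factors`, `matrix` (an `expr_tbl` at stage `"normalized"`),
#'   `controls` (corrected control counts).
#' @export
normalize_cartridge <- function(cartridge, n_keep = 3) {
  stopifnot(inherits(cartridge, "cartridge"))
  flat <- expr_table(cartridge, stage = "flat")
  samples <- expr_samples(flat)

  neg <- dplyr::filter(flat, .data$code_class == "Negative")
  if (nrow(neg) < 2) {
    rlang::abort("Cartridge has fewer than 2 negative-control probes",
                 class = "nanolane_controls_error")
  }
  thresholds <- vapply(samples, function(s) {
    tryCatch(background_threshold(neg[[s]]),
             error = function(e) {
               rlang::abort(sprintf("Lane '%s': %s", s, conditionMessage(e)),
                            class = "nanolane_controls_error")
             })
  }, numeric(1))

  corrected <- apply_background(flat, thresholds)

  hk <- dplyr::filter(corrected, .data$code_class == "Housekeeping")
  if (nrow(hk) < 3) {
    rlang::abort("Cartridge has fewer than 3 housekeeping probes",
                 class = "nanolane_controls_error")
  }
  if (length(samples) == 1) {
    # pairwise ratio stability is undefined on one lane; keep all candidates
    sel <- list(selected = hk$gene_name,
                initial_M = stats::setNames(rep(NA_real_, nrow(hk)), hk$gene_name))
  } else {
    sel <- select_housekeepers(new_expr_tbl(hk, "background_corrected"),
                               n_keep = n_keep)
  }

  hk_sel <- expr_values(hk)[sel$selected, , drop = FALSE]
  sf <- scaling_factors(hk_sel)

  keep <- dplyr::filter(corrected, .data$code_class %in% c("Endogenous", "Housekeeping"))
  mat <- expr_values(new_expr_tbl(keep, "background_corrected"))
  mat <- sweep(mat, 2, sf$scaling_factor[match(colnames(mat), sf$sample_id)], `*`)
  out <- expr_replace(new_expr_tbl(keep, "background_corrected"), mat,
                      stage = "normalized")

  controls <- dplyr::filter(corrected, .data$code_class %in% c("Positive", "Negative"))

  structure(
    list(
      background_thresholds = thresholds,
      selected_housekeepers = sel$selected,
      stability_M = sel$initial_M,
      lane_geomeans = stats::setNames(sf$lane_geomean, sf$sample_id),
      scaling_factors = stats::setNames(sf$scaling_factor, sf$sample_id),
      matrix = out,
      controls = new_expr_tbl(controls, "background_corrected"),
      n_keep = n_keep
    ),
    class = "nanolane_norm"
  )
}

#' @export
print.nanolane_norm <- function(x, ...) {
  cat(sprintf(
    "<nanolane_norm: %d genes x %d lanes; housekeepers [%s]; SF range %.3f-%.3f>\n",
    nrow(x$matrix), length(x$scaling_factors),
    paste(x$selected_housekeepers, collapse = ", "),
    min(x$scaling_factors), max(x$scaling_factors)
  ))
  invisible(x)
}

#' Per-lane summary of a normalization result
#'
#' @param x A `nanolane_norm`.
#' @param ... Unused.
#' @return A tibble with one row per lane: `sample_id`,
#'   `background_threshold`, `lane_geomean`, `scaling_factor`.
#' @export
tidy.nanolane_norm <- function(x, ...) {
  tibble::tibble(
    sample_id = names(x$scaling_factors),
    background_threshold = unname(x$background_thresholds[names(x$scaling_factors)]),
    lane_geomean = unname(x$lane_geomeans),
    scaling_factor = unname(x$scaling_factors)
  )
}

#' One-row summary of a normalization result
#'
#' @param x A `nanolane_norm`.
#' @param ... Unused.
#' @return A one-row tibble: lane and gene counts, number of selected
#'   housekeepers, their worst (largest) stability M, and the scaling-factor
#'   range.
#' @export
glance.nanolane_norm <- function(x, ...) {
  tibble::tibble(
    n_lanes = length(x$scaling_factors),
    n_genes = nrow(x$matrix),
    n_housekeepers = length(x$selected_housekeepers),
    max_M = max(x$stability_M[x$selected_housekeepers]),
    sf_min = min(x$scaling_factors),
    sf_max = max(x$scaling_factors)
  )
}

#' Write normalization artifacts to a directory
#'
#' Emits `normalized.tsv` (the matrix), `normalization.tsv` (per-lane
#' thresholds/geomeans/factors) and `housekeepers.txt`.
#'
#' @param x A `nanolane_norm`.
#' @param dir Output directory (created if needed).
#' @export
write_normalization <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expr_tsv(x$matrix, file.path(dir, "normalized.tsv"))
  readr::write_tsv(tidy.nanolane_norm(x), file.path(dir, "normalization.tsv"),
                   progress = FALSE)
  writeLines(x$selected_housekeepers, file.path(dir, "housekeepers.txt"))
  invisible(dir)
}

geomean <- function(x) exp(mean(log(x)))
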