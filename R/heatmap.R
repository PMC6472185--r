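#' Z-score genes across samples
#'
#' Standardizes each gene row to mean 0 and standard deviation 1 across the
#' selected samples, balancing the color scale before visualization. A gene
#' with zero variance cannot be standardized; its row becomes all zeros and a
#' warning is raised.
#'
#' @param x An `expr_tbl` (any positive stage) or numeric matrix with at
#'   least 2 sample columns.
#' @return An `expr_tbl` at stage `"zscored"` (or a matrix if a matrix was
#'   given).
#' @export
zscore_rows <- function(x) {
  m <- if (inherits(x, "expr_tbl")) expr_values(x) else x
  if (ncol(m) < 2) {
    rlang::abort("Z-scoring needs at least 2 samples",
                 class = "nanolane_domain_error")
  }
  mu <- rowMeans(m)
  s <- apply(m, 1, stats::sd)
  flat <- s == 0
  if (any(flat)) {
    rlang::warn(sprintf("%d constant gene row(s) z-scored to all zeros: %s",
                        sum(flat),
                        paste(utils::head(rownames(m)[flat], 5), collapse = ", ")))
    s[flat] <- 1
  }
  z <- (m - mu) / s
  if (inherits(x, "expr_tbl")) expr_replace(x, z, stage = "zscored") else z
}

#' Agglomerative clustering of genes or samples
#'
#' Average-linkage hierarchical clustering on Euclidean distances between the
#' rows (genes) or columns (samples) of a z-scored matrix; both choices are
#' configurable. Deterministic for a given input.
#'
#' @param x An `expr_tbl` or numeric matrix.
#' @param axis `"genes"` (rows) or `"samples"` (columns).
#' @param method Linkage passed to [stats::hclust()].
#' @param distance Distance passed to [stats::dist()].
#' @return An `hclust` object; its `order` gives the leaf order.
#' @export
hcluster <- function(x, axis = c("genes", "samples"),
                     method = "average", distance = "euclidean") {
  axis <- match.arg(axis)
  m <- if (inherits(x, "expr_tbl")) expr_values(x) else x
  if (axis == "samples") m <- t(m)
  if (nrow(m) < 2) {
    rlang::abort(sprintf("Clustering needs at least 2 %s", axis),
                 class = "nanolane_domain_error")
  }
  stats::hclust(stats::dist(m, method = distance), method = method)
}

#' Order samples for the four comparison modes
#'
#' The heatmap supports four clinically motivated sample orderings:
#' \describe{
#'   \item{I}{one patient's samples in chronological order (patient
#'     evolution, e.g. t1..t4 around a treatment);}
#'   \item{II}{each patient's first (basal) sample only;}
#'   \item{III}{each patient's second sample only (post-treatment
#'     comparison);}
#'   \item{IV}{all first samples in patient order, then all second samples in
#'     the same patient order.}
#' }
#'
#' @param meta A tibble with columns `sample_id`, `patient_id`,
#'   `sample_order` (chronological position within the patient; missing
#'   values fall back to `collection_date`, then to row order).
#' @param analysis_type One of `"I"`, `"II"`, `"III"`, `"IV"`.
#' @return Character vector of sample ids in display order.
#' @export
order_samples <- function(meta, analysis_type = c("I", "II", "III", "IV")) {
  analysis_type <- match.arg(analysis_type)
  meta <- tibble::as_tibble(meta)
  stopifnot(all(c("sample_id", "patient_id") %in% names(meta)))
  if (!"sample_order" %in% names(meta)) meta$sample_order <- NA_integer_
  chron <- meta$sample_order
  if (anyNA(chron) && "collection_date" %in% names(meta)) {
    d <- suppressWarnings(as.numeric(as.Date(meta$collection_date)))
    chron <- ifelse(is.na(chron), d, chron)
  }
  chron[is.na(chron)] <- seq_len(nrow(meta))[is.na(chron)]
  meta$.chron <- chron

  patients <- unique(meta$patient_id)

  if (analysis_type == "I") {
    if (length(patients) != 1) {
      rlang::abort(sprintf("Type I compares samples of a single patient; got %d patients",
                           length(patients)),
                   class = "nanolane_metadata_error")
    }
    return(meta$sample_id[order(meta$.chron)])
  }

  by_patient <- lapply(patients, function(p) {
    rows <- meta[meta$patient_id == p, , drop = FALSE]
    rows$sample_id[order(rows$.chron)]
  })
  names(by_patient) <- patients

  if (analysis_type == "II") {
    return(unname(vapply(by_patient, `[`, character(1), 1)))
  }

  short <- patients[vapply(by_patient, length, integer(1)) < 2]
  if (length(short) > 0) {
    rlang::abort(sprintf("Type %s needs a second sample for every patient; missing for: %s",
                         analysis_type, paste(short, collapse = ", ")),
                 class = "nanolane_metadata_error")
  }
  seconds <- vapply(by_patient, `[`, character(1), 2)
  if (analysis_type == "III") return(unname(seconds))
  firsts <- vapply(by_patient, `[`, character(1), 1)
  unname(c(firsts, seconds))
}

#' Build a clustered, z-scored heatmap data product
#'
#' The full visualization pipeline over a normalized matrix: keep the most
#' variable genes, arrange the sample axis for the requested comparison mode,
#' z-score each gene across the displayed samples, and cluster. Genes are
#' always clustered; the sample axis is clustered only in `"free"` mode —
#' the Type I--IV orderings are fixed comparisons that clustering would
#' destroy.
#'
#' @param x An `expr_tbl` at stage `"normalized"` (positive values).
#' @param meta Sample metadata tibble (see [order_samples()]); required for
#'   Types I--IV.
#' @param analysis_type `"free"` (cluster both axes) or `"I"`..`"IV"`.
#' @param k,percent Gene filter, forwarded to [apply_filter()]; `NULL` keeps
#'   all genes.
#' @param method,distance Clustering parameters, see [hcluster()].
#' @return A `clustered_heatmap` object: `zmatrix` (genes x displayed
#'   samples, z-scored, original order), `gene_order` and `sample_order`
#'   (display permutations as names), `gene_hclust`, `sample_hclust` (NULL
#'   for fixed orderings) and `analysis_type`.
#' @export
build_heatmap <- function(x, meta = NULL, analysis_type = "free",
                          k = NULL, percent = NULL,
                          method = "average", distance = "euclidean") {
  stopifnot(inherits(x, "expr_tbl"))
  if (!analysis_type %in% c("free", "I", "II", "III", "IV")) {
    rlang::abort("analysis_type must be one of free, I, II, III, IV",
                 class = "nanolane_validation_error")
  }
  if (!is.null(k) || !is.null(percent)) {
    x <- apply_filter(x, k = k, percent = percent)
  }

  if (analysis_type != "free") {
    if (is.null(meta)) {
      rlang::abort(sprintf("Type %s ordering requires sample metadata", analysis_type),
                   class = "nanolane_metadata_error")
    }
    wanted <- order_samples(meta, analysis_type)
    missing <- setdiff(wanted, expr_samples(x))
    if (length(missing) > 0) {
      rlang::abort(sprintf("Metadata names samples absent from the matrix: %s",
                           paste(missing, collapse = ", ")),
                   class = "nanolane_metadata_error")
    }
    x <- new_expr_tbl(x[, c("gene_name", "code_class", wanted)], expr_stage(x))
  }

  z <- zscore_rows(x)
  zm <- expr_values(z)

  gene_hc <- hcluster(z, "genes", method = method, distance = distance)
  sample_hc <- NULL
  if (analysis_type == "free" && ncol(zm) >= 2) {
    sample_hc <- hcluster(z, "samples", method = method, distance = distance)
  }

  sample_order <- if (is.null(sample_hc)) colnames(zm) else colnames(zm)[sample_hc$order]

  structure(
    list(zmatrix = zm,
         gene_order = rownames(zm)[gene_hc$order],
         sample_order = sample_order,
         gene_hclust = gene_hc,
         sample_hclust = sample_hc,
         analysis_type = analysis_type),
    class = "clustered_heatmap"
  )
}

#' @export
print.clustered_heatmap <- function(x, ...) {
  cat(sprintf("<clustered_heatmap type %s: %d genes x %d samples>\n",
              x$analysis_type, nrow(x$zmatrix), ncol(x$zmatrix)))
  invisible(x)
}

#' Tidy a clustered heatmap into plotting-ready long form
#'
#' @param x A `clustered_heatmap`.
#' @param ... Unused.
#' @return A long tibble (`gene_name`, `sample_id`, `z`) with both axes as
#'   factors in display order.
#' @export
tidy.clustered_heatmap <- function(x, ...) {
  long <- tibble::as_tibble(x$zmatrix, rownames = "gene_name")
  long <- tidyr::pivot_longer(long, -"gene_name",
                              names_to = "sample_id", values_to = "z")
  long$gene_name <- factor(long$gene_name, levels = rev(x$gene_order))
  long$sample_id <- factor(long$sample_id, levels = x$sample_order)
  long
}

#' Plot a clustered heatmap
#'
#' Tile heatmap with a diverging scale symmetric about z = 0, rows and
#' columns in dendrogram (or comparison-type) order. The data product — not
#' the rendering — is what the rest of the package consumes; this is a thin
#' convenience layer.
#'
#' @param object A `clustered_heatmap`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.clustered_heatmap <- function(object, ...) {
  long <- tidy.clustered_heatmap(object)
  lim <- max(abs(long$z), 1e-9)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id, y = .data$gene_name,
                                     fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white", high = "#B2182B",
                                  limits = c(-lim, lim), name = "z") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Export a heatmap data product to a directory
#'
#' Writes the reordered z-matrix (`heatmap_z.tsv`), the gene and sample
#' display orders, and Newick dendrograms whose branch lengths are the merge
#' heights (`genes.nwk`, and `samples.nwk` in free mode).
#'
#' @param x A `clustered_heatmap`.
#' @param dir Output directory.
#' @param image Optional path of a PNG to render via [autoplot.clustered_heatmap()].
#' @export
write_heatmap <- function(x, dir, image = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  zm <- x$zmatrix[x$gene_order, x$sample_order, drop = FALSE]
  readr::write_tsv(tibble::as_tibble(zm, rownames = "gene_name"),
                   file.path(dir, "heatmap_z.tsv"), progress = FALSE)
  writeLines(x$gene_order, file.path(dir, "gene_order.txt"))
  writeLines(x$sample_order, file.path(dir, "sample_order.txt"))
  ape::write.tree(ape::as.phylo(x$gene_hclust), file.path(dir, "genes.nwk"))
  if (!is.null(x$sample_hclust)) {
    ape::write.tree(ape::as.phylo(x$sample_hclust), file.path(dir, "samples.nwk"))
  }
  if (!is.null(image)) {
    ggplot2::ggsave(image, autoplot.clustered_heatmap(x),
                    width = 6, height = 8, dpi = 150)
  }
  invisible(dir)
}
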