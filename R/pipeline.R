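#' Configuration for a full pipeline run
#'
#' Collects every stage's parameters with the module defaults. Values read
#' from a config file (see [read_run_config()]) are overridden by arguments
#' given here, mirroring the flags-over-file precedence of the command line.
#'
#' @param input_dir Directory scanned for `*.RCC` files (ignored when
#'   `rcc_files` is given).
#' @param rcc_files Explicit RCC file paths.
#' @param metadata Sample metadata: a path to a TSV or a tibble (see
#'   [read_sample_metadata()]).
#' @param out_dir Output directory for all artifacts.
#' @param qc A [qc_config()].
#' @param n_keep Housekeepers to retain in normalization.
#' @param k,percent Gene filter (see [apply_filter()]); `NULL` keeps all.
#' @param heatmap Build the heatmap data product?
#' @param analysis_type Sample ordering for the heatmap (`"free"` or
#'   `"I"`..`"IV"`).
#' @param grn_algorithm `"none"`, `"genie3-rf"`, `"genie3-et"` or
#'   `"grnboost2"`.
#' @param grn_params Named list of overrides for the chosen inference
#'   function.
#' @param top_n Keep only the n strongest network links (`NULL` = all).
#' @param seed Seed forwarded to every stochastic stage.
#' @return A `run_config` list.
#' @export
run_config <- function(input_dir = NULL, rcc_files = NULL, metadata = NULL,
                       out_dir = "nanolane_out", qc = qc_config(), n_keep = 3,
                       k = NULL, percent = NULL, heatmap = TRUE,
                       analysis_type = "free",
                       grn_algorithm = c("none", "genie3-rf", "genie3-et", "grnboost2"),
                       grn_params = list(), top_n = NULL, seed = 42) {
  grn_algorithm <- match.arg(grn_algorithm)
  structure(
    list(input_dir = input_dir, rcc_files = rcc_files, metadata = metadata,
         out_dir = out_dir, qc = qc, n_keep = n_keep, k = k, percent = percent,
         heatmap = heatmap, analysis_type = analysis_type,
         grn_algorithm = grn_algorithm, grn_params = grn_params,
         top_n = top_n, seed = seed),
    class = "run_config"
  )
}

#' Read a flat key=value run configuration file
#'
#' Recognized keys mirror the [run_config()] arguments (`input_dir`,
#' `out_dir`, `metadata`, `n_keep`, `k`, `percent`, `analysis_type`,
#' `grn_algorithm`, `top_n`, `seed`, `heatmap`). Lines starting with `#` are
#' comments.
#'
#' @param path Config file path.
#' @return A named list suitable for splicing into [run_config()].
#' @export
read_run_config <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- stringr::str_split_fixed(lines, "=", 2)
  vals <- stats::setNames(trimws(kv[, 2]), trimws(kv[, 1]))
  out <- as.list(vals)
  for (key in intersect(names(out), c("n_keep", "k", "top_n", "seed"))) {
    out[[key]] <- as.integer(out[[key]])
  }
  if ("percent" %in% names(out)) out$percent <- as.numeric(out$percent)
  if ("heatmap" %in% names(out)) out$heatmap <- toupper(out$heatmap) %in% c("TRUE", "1", "YES")
  out
}

#' Run the full analysis pipeline
#'
#' Executes QC, normalization, gene filtering and the requested analyses
#' over a set of RCC lane files, writing every stage's artifact plus a
#' machine-readable `manifest.json` (inputs, parameters, package version,
#' seed, outputs) into `config$out_dir`. Lanes failing QC are processed with
#' warnings, never dropped. Given the same inputs, config and seed, artifact
#' files are byte-identical across runs.
#'
#' @param config A [run_config()].
#' @return Invisibly, the manifest as a list. Stage failures abort with a
#'   stage-tagged message.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  files <- config$rcc_files %||%
    list.files(config$input_dir, pattern = "\\.RCC$", full.names = TRUE,
               ignore.case = TRUE)
  missing <- files[!file.exists(files)]
  if (length(files) == 0 || length(missing) > 0) {
    rlang::abort(sprintf("[stage input] no readable RCC files (%s)",
                         if (length(missing)) paste(missing, collapse = ", ")
                         else paste0("none found in ", config$input_dir)),
                 class = "nanolane_io_error")
  }

  meta <- config$metadata
  if (is.character(meta)) meta <- read_sample_metadata(meta)

  samples <- pipeline_stage("parse", lapply(files, read_rcc))
  cartridge <- pipeline_stage("assemble",
                              assemble_experiment(samples, metadata = meta))

  qc <- pipeline_stage("qc", qc_report(cartridge, config$qc))
  write_qc_tsv(qc, file.path(out_dir, "qc.tsv"))
  for (msg in unlist(qc$messages)) rlang::warn(msg)

  norm <- pipeline_stage("normalize",
                         normalize_cartridge(cartridge, n_keep = config$n_keep))
  write_normalization(norm, out_dir)

  mat <- norm$matrix
  if (!is.null(config$k) || !is.null(config$percent)) {
    mat <- pipeline_stage("filter",
                          apply_filter(mat, k = config$k, percent = config$percent))
    write_expr_tsv(mat, file.path(out_dir, "filtered.tsv"))
  }

  if (isTRUE(config$heatmap)) {
    hm_meta <- if (config$analysis_type == "free") NULL else {
      meta %||% cartridge_metadata(cartridge)
    }
    hm <- pipeline_stage("heatmap",
                         build_heatmap(mat, meta = hm_meta,
                                       analysis_type = config$analysis_type))
    write_heatmap(hm, out_dir)
  }

  grn_out <- NULL
  if (config$grn_algorithm != "none") {
    fn <- switch(config$grn_algorithm,
                 "genie3-rf" = function(m, ...) infer_genie3(m, variant = "RF", ...),
                 "genie3-et" = function(m, ...) infer_genie3(m, variant = "ET", ...),
                 "grnboost2" = infer_grnboost2)
    args <- c(list(mat), config$grn_params, list(seed = config$seed))
    grn_out <- pipeline_stage("grn", do.call(fn, args))
    if (!is.null(config$top_n)) grn_out <- top_n_links(grn_out, config$top_n)
    write_grn_tsv(grn_out, file.path(out_dir, "grn_edges.tsv"))
  }

  manifest <- list(
    package = "nanolane",
    version = as.character(utils::packageVersion("nanolane")),
    inputs = files,
    seed = config$seed,
    parameters = list(
      n_keep = config$n_keep, k = config$k, percent = config$percent,
      analysis_type = config$analysis_type,
      grn_algorithm = config$grn_algorithm, top_n = config$top_n
    ),
    selected_housekeepers = norm$selected_housekeepers,
    scaling_factors = as.list(norm$scaling_factors),
    qc_messages = unlist(qc$messages) %||% character(),
    outputs = list.files(out_dir)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    rlang::abort(sprintf("[stage %s] %s", stage, conditionMessage(e)),
                 class = "nanolane_pipeline_error", parent = e)
  })
}
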