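#' Default QC configuration
#'
#' Bundles the tunable QC thresholds. Binding-density bounds default to the
#' instrument's published 0.1--2.25 spots/µm² window (a closed interval).
#' The positive-control ladder defaults to the standard six-point serial
#' dilution POS_A..POS_F = 128, 32, 8, 2, 0.5, 0.125 fM; the
#' limit-of-detection probe defaults to POS_E (0.5 fM), the lowest
#' concentration expected to clear background. Linearity passes at
#' r-squared >= 0.95.
#'
#' @param bd_low,bd_high Binding-density bounds (spots/µm²).
#' @param ladder Named numeric vector, positive-control probe base name to
#'   concentration in fM.
#' @param lod_probe Base name of the positive control compared to background.
#' @param r2_min Linearity pass threshold.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(bd_low = 0.1, bd_high = 2.25,
                      ladder = c(POS_A = 128, POS_B = 32, POS_C = 8,
                                 POS_D = 2, POS_E = 0.5, POS_F = 0.125),
                      lod_probe = "POS_E", r2_min = 0.95) {
  structure(list(bd_low = bd_low, bd_high = bd_high, ladder = ladder,
                 lod_probe = lod_probe, r2_min = r2_min),
            class = "qc_config")
}

#' Binding-density flag
#'
#' Binding density is the imaged spot density reported by the instrument in
#' the lane attributes; values outside the supported window indicate lane
#' under- or over-loading. The bounds form a closed interval.
#'
#' @param sample An `rcc_sample`.
#' @param low,high Bounds in spots/µm².
#' @return A list: `pass` (logical), `value`, `message` (NULL when passing).
#' @export
binding_density_flag <- function(sample, low = 0.1, high = 2.25) {
  bd <- sample$binding_density
  if (is.null(bd) || is.na(bd)) {
    return(list(pass = FALSE, value = NA_real_,
                message = sprintf("Sample '%s': binding density missing from lane attributes",
                                  sample$sample_id)))
  }
  pass <- bd >= low && bd <= high
  list(pass = pass, value = bd,
       message = if (!pass) {
         sprintf("Sample '%s': binding density %.3g outside [%g, %g]",
                 sample$sample_id, bd, low, high)
       })
}

#' Positive-control linearity (r-squared)
#'
#' The positive-control probes are spiked at known concentrations, so their
#' counts should scale linearly with the spike-in amounts. Linearity is the
#' squared Pearson correlation between log2(count + 1) and
#' log2(concentration) over the ladder. A ladder with zero count variance
#' (degenerate) returns 0 with a warning.
#'
#' @param sample An `rcc_sample`.
#' @param known_concentrations Named vector mapping positive-control base
#'   names (e.g. `POS_A`) to concentrations in fM.
#' @return The r-squared value in \[0, 1\].
#' @export
positive_control_linearity <- function(sample,
                                       known_concentrations = qc_config()$ladder) {
  pos <- dplyr::filter(sample$codes, .data$code_class == "Positive")
  base <- pos_base_name(pos$gene_name)
  keep <- base %in% names(known_concentrations)
  if (sum(keep) < 3) {
    rlang::abort(sprintf("Sample '%s': only %d positive controls with known concentrations (need >= 3)",
                         sample$sample_id, sum(keep)),
                 class = "nanolane_controls_error")
  }
  x <- log2(known_concentrations[base[keep]])
  y <- log2(pos$count[keep] + 1)
  if (stats::sd(y) == 0) {
    rlang::warn(sprintf("Sample '%s': positive-control counts are constant; r-squared set to 0",
                        sample$sample_id))
    return(0)
  }
  unname(stats::cor(x, y)^2)
}

#' Limit-of-detection flag
#'
#' Checks that a low-concentration positive control clears the lane's
#' negative-control background (geometric mean of the negatives plus two
#' standard deviations, as in [background_threshold()]).
#'
#' @param sample An `rcc_sample`.
#' @param probe_name Base name of the positive control (default `POS_E`).
#' @return A list: `pass`, `count`, `threshold`, `message`.
#' @export
limit_of_detection_flag <- function(sample, probe_name = "POS_E") {
  pos <- dplyr::filter(sample$codes, .data$code_class == "Positive")
  hit <- pos_base_name(pos$gene_name) == probe_name
  if (!any(hit)) {
    rlang::abort(sprintf("Sample '%s': positive control '%s' not found",
                         sample$sample_id, probe_name),
                 class = "nanolane_controls_error")
  }
  negs <- dplyr::filter(sample$codes, .data$code_class == "Negative")$count
  thr <- background_threshold(negs)
  cnt <- pos$count[hit][1]
  pass <- cnt >= thr
  list(pass = pass, count = cnt, threshold = thr,
       message = if (!pass) {
         sprintf("Sample '%s': LOD probe %s count %d below background threshold %.2f",
                 sample$sample_id, probe_name, cnt, thr)
       })
}

#' Per-lane quality-control report
#'
#' Aggregates the three lane flags — binding density, positive-control
#' linearity and limit of detection — for every sample of a cartridge (or a
#' single sample). QC failures are reported, never fatal: counts are not
#' touched and normalization proceeds identically whether or not flags fail.
#'
#' @param x A `cartridge` or a single `rcc_sample`.
#' @param config A [qc_config()].
#' @return A tibble with one row per sample: `sample_id`, `binding_density`,
#'   `bd_flag`, `linearity_r2`, `lin_flag`, `lod_count`, `lod_threshold`,
#'   `lod_flag`, `n_messages`, and a `messages` list-column of warnings (one
#'   entry per failed flag).
#' @export
qc_report <- function(x, config = qc_config()) {
  samples <- if (inherits(x, "cartridge")) x$samples else list(x)
  purrr::map_dfr(samples, function(s) {
    msgs <- character()

    bd <- binding_density_flag(s, config$bd_low, config$bd_high)
    if (!bd$pass) msgs <- c(msgs, bd$message)

    r2 <- tryCatch(positive_control_linearity(s, config$ladder),
                   error = function(e) NA_real_)
    lin_pass <- !is.na(r2) && r2 >= config$r2_min
    if (!lin_pass) {
      msgs <- c(msgs, sprintf(
        "Sample '%s': positive-control linearity %s below %.2f",
        s$sample_id, ifelse(is.na(r2), "unavailable", sprintf("r2 = %.3f", r2)),
        config$r2_min))
    }

    lod <- tryCatch(limit_of_detection_flag(s, config$lod_probe),
                    error = function(e) list(pass = FALSE, count = NA_integer_,
                                             threshold = NA_real_,
                                             message = conditionMessage(e)))
    if (!lod$pass && !is.null(lod$message)) msgs <- c(msgs, lod$message)

    tibble::tibble(
      sample_id = s$sample_id,
      binding_density = bd$value, bd_flag = bd$pass,
      linearity_r2 = r2, lin_flag = lin_pass,
      lod_count = lod$count, lod_threshold = lod$threshold, lod_flag = lod$pass,
      n_messages = length(msgs), messages = list(msgs)
    )
  })
}

#' Write a QC report as TSV
#'
#' @param report Output of [qc_report()].
#' @param path Destination.
#' @export
write_qc_tsv <- function(report, path) {
  flat <- dplyr::mutate(report,
                        messages = purrr::map_chr(.data$messages, paste, collapse = "; "))
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}

# "POS_A(128)" -> "POS_A"; plain names pass through
pos_base_name <- function(x) sub("\\(.*\\)$", "", x)
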