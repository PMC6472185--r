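#' Parse a NanoString RCC lane file
#'
#' An RCC (Reporter Code Count) file is the per-lane text export of an
#' nCounter run: a sectioned CSV with `<Header>`, `<Sample_Attributes>`,
#' `<Lane_Attributes>` and `<Code_Summary>` blocks, the last holding one
#' `CodeClass,Name,Accession,Count` row per probe. One cartridge yields up to
#' twelve such files, one per flow-cell lane.
#'
#' @param text The file content: either a single string or a character vector
#'   of lines. Both LF and CRLF line endings are accepted.
#'
#' @return An `rcc_sample` object: a list with
#'   \describe{
#'     \item{sample_id}{the `ID` row of `Sample_Attributes`}
#'     \item{lane_id}{integer lane position 1--12}
#'     \item{binding_density}{spots/µm² from `Lane_Attributes`, or `NA`}
#'     \item{codes}{a tibble with columns `code_class`, `gene_name`,
#'       `accession`, `count`, in file order}
#'     \item{sample_attrs, lane_attrs}{named character vectors of the raw
#'       attribute rows}
#'     \item{patient_id, sample_order, collection_date}{optional clinical
#'       metadata, read from `PatientID`/`SampleOrder`/`Date` attribute rows
#'       when present}
#'     \item{extra_sections}{unrecognized sections, preserved verbatim for
#'       round-tripping}
#'   }
#'
#' @seealso [write_rcc()], [read_rcc()], [assemble_experiment()]
#' @export
#' @examples
#' txt <- paste(
#'   "<Header>", "FileVersion,1.7", "</Header>",
#'   "<Sample_Attributes>", "ID,S1", "</Sample_Attributes>",
#'   "<Lane_Attributes>", "ID,1", "BindingDensity,0.51", "</Lane_Attributes>",
#'   "<Code_Summary>", "CodeClass,Name,Accession,Count",
#'   "Positive,POS_A(128),POS_A,10000",
#'   "Endogenous,CCL2,NM_002982.3,742",
#'   "</Code_Summary>",
#'   sep = "\n"
#' )
#' s <- parse_rcc(txt)
#' s$binding_density
#' s$codes
parse_rcc <- function(text) {
  lines <- rcc_split_lines(text)
  sections <- rcc_sections(lines)

  required <- c("Header", "Sample_Attributes", "Lane_Attributes", "Code_Summary")
  missing <- setdiff(required, names(sections))
  if (length(missing) > 0) {
    rlang::abort(
      sprintf("RCC stream is missing required section(s): %s",
              paste(missing, collapse = ", ")),
      class = "nanolane_format_error"
    )
  }

  header_attrs <- rcc_parse_attrs(sections[["Header"]]$body)
  sample_attrs <- rcc_parse_attrs(sections[["Sample_Attributes"]]$body)
  lane_attrs <- rcc_parse_attrs(sections[["Lane_Attributes"]]$body)

  cs <- sections[["Code_Summary"]]
  codes <- rcc_parse_code_summary(cs$body, cs$start_line)

  dup <- duplicated(paste(codes$code_class, codes$gene_name, sep = "\r"))
  if (any(dup)) {
    rlang::abort(
      sprintf("Duplicate (code_class, gene_name) entries in Code_Summary: %s",
              paste(unique(codes$gene_name[dup]), collapse = ", ")),
      class = "nanolane_duplicate_error"
    )
  }

  extra <- sections[!names(sections) %in% required]

  new_rcc_sample(
    sample_id = attr_chr(sample_attrs, "ID"),
    lane_id = suppressWarnings(as.integer(attr_chr(lane_attrs, "ID"))),
    binding_density = suppressWarnings(as.numeric(attr_chr(lane_attrs, "BindingDensity"))),
    codes = codes,
    header_attrs = header_attrs,
    sample_attrs = sample_attrs,
    lane_attrs = lane_attrs,
    patient_id = attr_chr(sample_attrs, "PatientID"),
    sample_order = suppressWarnings(as.integer(attr_chr(sample_attrs, "SampleOrder"))),
    collection_date = attr_chr(sample_attrs, "Date"),
    extra_sections = lapply(extra, `[[`, "body")
  )
}

#' Read an RCC file from disk
#'
#' @param path Path to a `.RCC` file.
#' @return An `rcc_sample`; see [parse_rcc()].
#' @export
read_rcc <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("RCC file not found: %s", path),
                 class = "nanolane_io_error")
  }
  parse_rcc(readr::read_lines(path))
}

#' Serialize an RCC sample back to the lane file format
#'
#' Emits the four canonical sections (plus any preserved unknown sections) so
#' that `parse_rcc(write_rcc(x))` reproduces `x` field for field. Clinical
#' metadata attached to the sample (`patient_id`, `sample_order`) is written
#' as extra `Sample_Attributes` rows.
#'
#' @param sample An `rcc_sample`.
#' @param path Optional path; when given the text is written there and the
#'   path returned invisibly.
#' @return A single string in RCC format (invisibly, if `path` is given).
#' @export
write_rcc <- function(sample, path = NULL) {
  validate_rcc_sample(sample)

  sa <- sample$sample_attrs
  sa[["ID"]] <- sample$sample_id
  if (!is.na(sample$patient_id)) sa[["PatientID"]] <- sample$patient_id
  if (!is.na(sample$sample_order)) sa[["SampleOrder"]] <- as.character(sample$sample_order)
  if (!is.na(sample$collection_date)) sa[["Date"]] <- sample$collection_date

  la <- sample$lane_attrs
  la[["ID"]] <- as.character(sample$lane_id)
  if (!is.na(sample$binding_density)) {
    la[["BindingDensity"]] <- format(sample$binding_density, scientific = FALSE, trim = TRUE)
  }

  body <- c(
    rcc_format_section("Header", rcc_format_attrs(sample$header_attrs)),
    rcc_format_section("Sample_Attributes", rcc_format_attrs(sa)),
    rcc_format_section("Lane_Attributes", rcc_format_attrs(la)),
    rcc_format_section("Code_Summary", c(
      "CodeClass,Name,Accession,Count",
      if (nrow(sample$codes) > 0) {
        paste(sample$codes$code_class, sample$codes$gene_name,
              sample$codes$accession, sample$codes$count, sep = ",")
      }
    ))
  )
  for (nm in names(sample$extra_sections)) {
    body <- c(body, rcc_format_section(nm, sample$extra_sections[[nm]]))
  }
  out <- paste0(paste(body, collapse = "\n"), "\n")
  if (!is.null(path)) {
    readr::write_file(out, path)
    return(invisible(path))
  }
  out
}

#' Assemble RCC lane samples into a cartridge-level experiment
#'
#' Verifies that every lane carries the identical probe panel and orders the
#' samples by `(patient_id, sample_order)` where that metadata is available
#' (falling back to `collection_date`, then input order).
#'
#' @param samples A list of `rcc_sample` objects (1--12).
#' @param metadata Optional tibble/data frame with columns `sample_id` (or
#'   `sample_file`), `patient_id`, `sample_order`, `collection_date`; values
#'   are attached to the matching samples before ordering.
#' @param cartridge_id Identifier for the assembled cartridge.
#' @return A `cartridge` object (list of samples + id).
#' @export
assemble_experiment <- function(samples, metadata = NULL, cartridge_id = "cartridge") {
  stopifnot(is.list(samples), length(samples) >= 1)
  for (s in samples) validate_rcc_sample(s)

  if (!is.null(metadata)) {
    metadata <- tibble::as_tibble(metadata)
    key <- if ("sample_id" %in% names(metadata)) "sample_id" else "sample_file"
    for (i in seq_along(samples)) {
      row <- metadata[metadata[[key]] == samples[[i]]$sample_id, , drop = FALSE]
      if (nrow(row) == 1) {
        if ("patient_id" %in% names(row)) samples[[i]]$patient_id <- as.character(row$patient_id)
        if ("sample_order" %in% names(row)) samples[[i]]$sample_order <- as.integer(row$sample_order)
        if ("collection_date" %in% names(row)) samples[[i]]$collection_date <- as.character(row$collection_date)
      }
    }
  }

  panels <- lapply(samples, function(s) paste(s$codes$code_class, s$codes$gene_name, sep = "\r"))
  ref <- panels[[1]]
  for (i in seq_along(panels)[-1]) {
    if (!setequal(panels[[i]], ref)) {
      diff <- c(setdiff(ref, panels[[i]]), setdiff(panels[[i]], ref))
      diff <- sub("^.*\r", "", diff)
      rlang::abort(
        sprintf("Gene panels differ between lanes '%s' and '%s': %s",
                samples[[1]]$sample_id, samples[[i]]$sample_id,
                paste(unique(diff), collapse = ", ")),
        class = "nanolane_panel_error"
      )
    }
  }

  ord <- rcc_sample_order(samples)
  structure(
    list(samples = samples[ord], cartridge_id = cartridge_id),
    class = "cartridge"
  )
}

#' Read experiment-level sample metadata from TSV
#'
#' Expected columns: `sample_file` (or `sample_id`), `patient_id`,
#' `sample_order`, `collection_date`.
#'
#' @param path TSV path.
#' @return A tibble.
#' @export
read_sample_metadata <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @export
print.cartridge <- function(x, ...) {
  cat(sprintf("<cartridge '%s': %d lane(s), %d probes/lane>\n",
              x$cartridge_id, length(x$samples),
              nrow(x$samples[[1]]$codes)))
  invisible(x)
}

#' @export
print.rcc_sample <- function(x, ...) {
  cat(sprintf("<rcc_sample '%s' lane %s: %d probes, binding density %s>\n",
              x$sample_id, x$lane_id, nrow(x$codes),
              format(x$binding_density)))
  invisible(x)
}

#' Tidy a cartridge into a long count tibble
#'
#' @param x A `cartridge`.
#' @param ... Unused.
#' @return A tibble with columns `sample_id`, `lane_id`, `patient_id`,
#'   `sample_order`, `code_class`, `gene_name`, `accession`, `count` — one row
#'   per probe per lane.
#' @export
tidy.cartridge <- function(x, ...) {
  purrr::map_dfr(x$samples, function(s) {
    dplyr::mutate(s$codes,
                  sample_id = s$sample_id,
                  lane_id = s$lane_id,
                  patient_id = s$patient_id,
                  sample_order = s$sample_order,
                  .before = 1)
  })
}

#' Per-sample metadata of a cartridge
#'
#' @param cartridge A `cartridge`.
#' @return A tibble with one row per lane: `sample_id`, `lane_id`,
#'   `patient_id`, `sample_order`, `collection_date`, `binding_density`.
#' @export
cartridge_metadata <- function(cartridge) {
  purrr::map_dfr(cartridge$samples, function(s) {
    tibble::tibble(
      sample_id = s$sample_id, lane_id = s$lane_id,
      patient_id = s$patient_id, sample_order = s$sample_order,
      collection_date = s$collection_date, binding_density = s$binding_density
    )
  })
}

# ---- internal ---------------------------------------------------------------

new_rcc_sample <- function(sample_id, lane_id, binding_density, codes,
                           header_attrs = c(FileVersion = "1.7"),
                           sample_attrs = character(),
                           lane_attrs = character(),
                           patient_id = NA_character_,
                           sample_order = NA_integer_,
                           collection_date = NA_character_,
                           extra_sections = list()) {
  structure(
    list(sample_id = sample_id, lane_id = lane_id,
         binding_density = binding_density, codes = codes,
         header_attrs = header_attrs, sample_attrs = sample_attrs,
         lane_attrs = lane_attrs, patient_id = patient_id,
         sample_order = sample_order, collection_date = collection_date,
         extra_sections = extra_sections),
    class = "rcc_sample"
  )
}

validate_rcc_sample <- function(sample) {
  if (!inherits(sample, "rcc_sample")) {
    rlang::abort("Expected an rcc_sample object", class = "nanolane_validation_error")
  }
  if (!is.na(sample$lane_id) && (sample$lane_id < 1 || sample$lane_id > 12)) {
    rlang::abort(sprintf("lane_id must be in 1..12, got %d", sample$lane_id),
                 class = "nanolane_validation_error")
  }
  if (any(sample$codes$count < 0)) {
    rlang::abort("Counts must be non-negative", class = "nanolane_validation_error")
  }
  if (any(!nzchar(sample$codes$gene_name))) {
    rlang::abort("Gene names must be non-empty", class = "nanolane_validation_error")
  }
  invisible(sample)
}

rcc_split_lines <- function(text) {
  if (length(text) == 1 && grepl("\n", text, fixed = TRUE)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  sub("\r$", "", text)
}

# Split tagged sections; returns list(name -> list(body, start_line)).
rcc_sections <- function(lines) {
  open <- grep("^<[A-Za-z_]+>$", lines)
  out <- list()
  for (i in open) {
    nm <- sub("^<([A-Za-z_]+)>$", "\\1", lines[i])
    close_tag <- paste0("</", nm, ">")
    j <- which(lines == close_tag)
    j <- j[j > i][1]
    if (is.na(j)) {
      rlang::abort(sprintf("Section '%s' opened at line %d is never closed", nm, i),
                   class = "nanolane_format_error")
    }
    body <- if (j > i + 1) lines[(i + 1):(j - 1)] else character()
    out[[nm]] <- list(body = body, start_line = i)
  }
  out
}

rcc_parse_attrs <- function(body) {
  body <- body[nzchar(body)]
  if (length(body) == 0) return(character())
  key <- sub(",.*$", "", body)
  val <- sub("^[^,]*,?", "", body)
  stats::setNames(val, key)
}

rcc_format_attrs <- function(attrs) {
  if (length(attrs) == 0) return(character())
  paste(names(attrs), attrs, sep = ",")
}

rcc_format_section <- function(name, body) {
  c(paste0("<", name, ">"), body, paste0("</", name, ">"))
}

rcc_parse_code_summary <- function(body, start_line) {
  body_lines <- seq_along(body) + start_line  # file line numbers
  keep <- nzchar(body)
  body <- body[keep]; body_lines <- body_lines[keep]
  if (length(body) == 0 || !grepl("^CodeClass,", body[1])) {
    rlang::abort("Code_Summary section lacks the CodeClass,Name,Accession,Count header",
                 class = "nanolane_format_error")
  }
  rows <- body[-1]; row_lines <- body_lines[-1]
  if (length(rows) == 0) {
    return(tibble::tibble(code_class = character(), gene_name = character(),
                          accession = character(), count = integer()))
  }
  parts <- stringr::str_split_fixed(rows, ",", 4)
  counts <- suppressWarnings(as.numeric(parts[, 4]))
  bad <- is.na(counts) | counts != floor(counts)
  if (any(bad)) {
    rlang::abort(
      sprintf("Non-integer count '%s' at line %d", parts[bad, 4][1], row_lines[bad][1]),
      class = "nanolane_parse_error"
    )
  }
  tibble::tibble(
    code_class = parts[, 1],
    gene_name = parts[, 2],
    accession = parts[, 3],
    count = as.integer(counts)
  )
}

# (patient_id, sample_order) ordering with date and input-order fallbacks
rcc_sample_order <- function(samples) {
  pid <- purrr::map_chr(samples, "patient_id")
  so <- purrr::map_int(samples, "sample_order")
  dt <- purrr::map_chr(samples, "collection_date")
  if (all(is.na(pid)) && all(is.na(so)) && all(is.na(dt))) return(seq_along(samples))
  chron <- ifelse(!is.na(so), as.numeric(so),
                  as.numeric(suppressWarnings(as.Date(dt))))
  order(pid, chron, seq_along(samples), na.last = TRUE)
}

attr_chr <- function(attrs, key) {
  if (key %in% names(attrs)) unname(attrs[[key]]) else NA_character_
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a
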