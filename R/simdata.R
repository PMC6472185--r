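#' Specify a synthetic nCounter cartridge
#'
#' Describes a simulated cartridge in the image of a 770-gene immune-profiling
#' panel run: up to 12 lanes, each carrying the same panel of endogenous and
#' housekeeping probes plus the six-point positive-control dilution ladder and
#' eight negative controls. Counts are log-normal around per-gene base levels,
#' scaled by a per-lane multiplicative lane effect; negative controls are
#' truncated-normal background. Ground truth (lane effects, housekeeper noise,
#' planted structure) is recorded so downstream estimates can be checked
#' against it.
#'
#' @param n_lanes Lanes in the cartridge (1--12; default 12).
#' @param n_endogenous,n_housekeeping Panel composition; the defaults
#'   730 + 40 = 770 gene probes.
#' @param pos_ladder Named fM concentrations of the positive controls
#'   (default the standard POS_A..POS_F = 128..0.125 ladder).
#' @param n_neg Negative-control probes (default 8).
#' @param lane_effects Per-lane positive multipliers; `NULL` (default) draws
#'   them log-normally with a log2-scale SD of 0.25, i.e. typical inter-lane
#'   variation of some tens of percent.
#' @param hk_noise_sd Log2-scale biological noise SD of each housekeeping
#'   gene (recycled; default 0.15).
#' @param endo_noise_sd Log2-scale noise SD of endogenous genes (default 0.5).
#' @param background_mean,background_sd Negative-control count distribution
#'   (normal, floored at 0; defaults 10 and 3).
#' @param pos_scale Counts per fM for the positive-control ladder (default
#'   200, putting POS_A around 26k counts).
#' @param planted_clusters `NULL`, or `list(genes_per_block, amplitude)`: two
#'   anti-correlated endogenous blocks whose log2 levels move by
#'   `+/- amplitude/2` between the first and second half of the lanes — a
#'   known structure heatmap clustering should recover.
#' @param planted_regulators `NULL`, or a tibble with columns `regulator`,
#'   `target` (endogenous gene names) plus `noise_sd`: each target copies its
#'   regulator's log2 deviation up to that noise.
#' @param seed Integer seed; simulation is fully deterministic given it.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(n_lanes = 12, n_endogenous = 730,
                            n_housekeeping = 40,
                            pos_ladder = c(POS_A = 128, POS_B = 32, POS_C = 8,
                                           POS_D = 2, POS_E = 0.5, POS_F = 0.125),
                            n_neg = 8, lane_effects = NULL,
                            hk_noise_sd = 0.15, endo_noise_sd = 0.5,
                            background_mean = 10, background_sd = 3,
                            pos_scale = 200,
                            planted_clusters = NULL, planted_regulators = NULL,
                            seed = 1) {
  if (n_lanes < 1 || n_lanes > 12) {
    rlang::abort("n_lanes must be in 1..12", class = "nanolane_validation_error")
  }
  if (!is.null(lane_effects)) {
    if (length(lane_effects) != n_lanes || any(lane_effects <= 0)) {
      rlang::abort("lane_effects must be n_lanes positive multipliers",
                   class = "nanolane_validation_error")
    }
  }
  if (n_housekeeping < 3) {
    rlang::abort("At least 3 housekeeping probes are required",
                 class = "nanolane_validation_error")
  }
  structure(
    list(n_lanes = n_lanes, n_endogenous = n_endogenous,
         n_housekeeping = n_housekeeping, pos_ladder = pos_ladder,
         n_neg = n_neg, lane_effects = lane_effects,
         hk_noise_sd = rep_len(hk_noise_sd, n_housekeeping),
         endo_noise_sd = endo_noise_sd,
         background_mean = background_mean, background_sd = background_sd,
         pos_scale = pos_scale,
         planted_clusters = planted_clusters,
         planted_regulators = planted_regulators,
         seed = as.integer(seed)),
    class = "simulation_spec"
  )
}

#' Simulate a cartridge with known ground truth
#'
#' @param spec A [simulation_spec()].
#' @return A list with `cartridge` (a `cartridge` of `rcc_sample`s) and
#'   `truth`, a record of the generating parameters: `lane_effects` (named by
#'   sample id), `base_expression`, `hk_noise_sd` (named by housekeeper),
#'   `stable_housekeepers` (the housekeepers at the minimum noise level), and
#'   any planted cluster/regulator structure.
#' @export
#' @examples
#' sim <- simulate_cartridge(simulation_spec(seed = 7))
#' sim$cartridge
simulate_cartridge <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  withr::with_seed(spec$seed, simulate_cartridge_impl(spec))
}

simulate_cartridge_impl <- function(spec) {
  L <- spec$n_lanes
  endo_names <- sprintf("ENDO_%03d", seq_len(spec$n_endogenous))
  hk_names <- sprintf("HK_%02d", seq_len(spec$n_housekeeping))
  neg_names <- sprintf("NEG_%s(0)", LETTERS[seq_len(spec$n_neg)])
  pos_names <- sprintf("%s(%s)", names(spec$pos_ladder),
                       format(spec$pos_ladder, trim = TRUE, scientific = FALSE))

  lane_effects <- spec$lane_effects %||% 2^stats::rnorm(L, 0, 0.25)
  base_endo <- 2^stats::runif(spec$n_endogenous, 4, 12)
  base_hk <- 2^stats::runif(spec$n_housekeeping, 7, 11)

  # per-gene log2 deviations, lanes in columns
  eps_endo <- matrix(stats::rnorm(spec$n_endogenous * L, 0, spec$endo_noise_sd),
                     nrow = spec$n_endogenous)
  eps_hk <- matrix(stats::rnorm(spec$n_housekeeping * L), nrow = spec$n_housekeeping)
  eps_hk <- eps_hk * spec$hk_noise_sd

  if (!is.null(spec$planted_clusters)) {
    gpb <- spec$planted_clusters$genes_per_block
    amp <- spec$planted_clusters$amplitude
    half <- seq_len(ceiling(L / 2))
    shift <- ifelse(seq_len(L) %in% half, amp / 2, -amp / 2)
    eps_endo[seq_len(gpb), ] <-
      eps_endo[seq_len(gpb), , drop = FALSE] + rep(shift, each = gpb)
    eps_endo[gpb + seq_len(gpb), ] <-
      eps_endo[gpb + seq_len(gpb), , drop = FALSE] - rep(shift, each = gpb)
  }

  if (!is.null(spec$planted_regulators)) {
    pr <- spec$planted_regulators
    for (i in seq_len(nrow(pr))) {
      ri <- match(pr$regulator[i], endo_names)
      ti <- match(pr$target[i], endo_names)
      eps_endo[ti, ] <- eps_endo[ri, ] + stats::rnorm(L, 0, pr$noise_sd[i])
    }
  }

  samples <- vector("list", L)
  for (l in seq_len(L)) {
    counts_endo <- round(base_endo * lane_effects[l] * 2^eps_endo[, l])
    counts_hk <- round(base_hk * lane_effects[l] * 2^eps_hk[, l])
    counts_pos <- round(spec$pos_scale * spec$pos_ladder * lane_effects[l])
    counts_neg <- pmax(0, round(stats::rnorm(spec$n_neg, spec$background_mean,
                                             spec$background_sd)))
    codes <- tibble::tibble(
      code_class = c(rep("Positive", length(counts_pos)),
                     rep("Negative", spec$n_neg),
                     rep("Housekeeping", spec$n_housekeeping),
                     rep("Endogenous", spec$n_endogenous)),
      gene_name = c(pos_names, neg_names, hk_names, endo_names),
      accession = c(rep("ERCC", length(counts_pos) + spec$n_neg),
                    sprintf("NM_%06d", seq_len(spec$n_housekeeping + spec$n_endogenous))),
      count = as.integer(c(counts_pos, counts_neg, counts_hk, counts_endo))
    )
    sid <- sprintf("SIM%02d", l)
    samples[[l]] <- new_rcc_sample(
      sample_id = sid, lane_id = l,
      binding_density = round(stats::runif(1, 0.3, 1.8), 2),
      codes = codes,
      sample_attrs = c(ID = sid, Owner = "simulated", GeneRLF = "SIM_PANEL_770"),
      lane_attrs = c(ID = as.character(l), FovCount = "555", FovCounted = "550"),
      patient_id = sprintf("P%02d", (l + 1) %/% 2),
      sample_order = ((l - 1) %% 2) + 1L
    )
  }

  cartridge <- structure(
    list(samples = samples, cartridge_id = sprintf("SIMCART%04d", spec$seed)),
    class = "cartridge"
  )
  sample_ids <- vapply(samples, `[[`, character(1), "sample_id")
  truth <- list(
    lane_effects = stats::setNames(lane_effects, sample_ids),
    base_expression = stats::setNames(c(base_hk, base_endo), c(hk_names, endo_names)),
    hk_noise_sd = stats::setNames(spec$hk_noise_sd, hk_names),
    stable_housekeepers = hk_names[spec$hk_noise_sd == min(spec$hk_noise_sd)],
    planted_clusters = if (!is.null(spec$planted_clusters)) {
      gpb <- spec$planted_clusters$genes_per_block
      list(block_a = endo_names[seq_len(gpb)],
           block_b = endo_names[gpb + seq_len(gpb)])
    },
    planted_regulators = spec$planted_regulators
  )
  list(cartridge = cartridge, truth = truth)
}

#' Write a simulated cartridge as RCC fixture files
#'
#' One `.RCC` file per lane, plus plain-text ground-truth sidecars:
#' `ground_truth.tsv` (per-lane effects), `housekeeper_truth.tsv` (per-gene
#' noise), `metadata.tsv` (file, patient, sample order).
#'
#' @param spec A [simulation_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths of the RCC files written.
#' @export
write_fixture_set <- function(spec, dir) {
  sim <- simulate_cartridge(spec)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(sim$cartridge$samples, function(s) {
    p <- file.path(dir, paste0(s$sample_id, ".RCC"))
    write_rcc(s, p)
    p
  }, character(1))

  meta <- cartridge_metadata(sim$cartridge)
  readr::write_tsv(
    tibble::tibble(sample_id = names(sim$truth$lane_effects),
                   lane_effect = unname(sim$truth$lane_effects)),
    file.path(dir, "ground_truth.tsv"), progress = FALSE)
  readr::write_tsv(
    tibble::tibble(gene_name = names(sim$truth$hk_noise_sd),
                   hk_noise_sd = unname(sim$truth$hk_noise_sd)),
    file.path(dir, "housekeeper_truth.tsv"), progress = FALSE)
  readr::write_tsv(
    dplyr::mutate(meta, sample_file = paste0(.data$sample_id, ".RCC"), .before = 1),
    file.path(dir, "metadata.tsv"), progress = FALSE)
  invisible(paths)
}

#' Simulate a gene matrix with planted regulator-target edges
#'
#' Network-inference benchmarks need more samples than one cartridge holds,
#' so this generator emits a standalone genes x samples matrix: most genes
#' are independent standard-normal series, but each designated target is a
#' noisy linear copy of its regulator (noise SD = `noise_frac` of the signal
#' SD). Values are shifted to a positive expression-like scale.
#'
#' @param n_genes Total genes (default 20; named G01..).
#' @param n_samples Samples (default 30).
#' @param n_edges Planted regulator -> target pairs (default 5; regulators
#'   G01.., targets following).
#' @param noise_frac Target noise SD relative to the regulator's SD.
#' @param seed Integer seed.
#' @return A list: `matrix` (genes x samples, positive), `edges` tibble of
#'   the true regulator/target pairs.
#' @export
simulate_regulatory_matrix <- function(n_genes = 20, n_samples = 30,
                                       n_edges = 5, noise_frac = 0.1,
                                       seed = 1) {
  stopifnot(2 * n_edges <= n_genes)
  withr::with_seed(seed, {
    genes <- sprintf("G%02d", seq_len(n_genes))
    m <- matrix(stats::rnorm(n_genes * n_samples), nrow = n_genes,
                dimnames = list(genes, sprintf("S%02d", seq_len(n_samples))))
    edges <- tibble::tibble(regulator = genes[seq_len(n_edges)],
                            target = genes[n_edges + seq_len(n_edges)])
    for (i in seq_len(n_edges)) {
      m[edges$target[i], ] <- m[edges$regulator[i], ] +
        stats::rnorm(n_samples, 0, noise_frac)
    }
    list(matrix = m + 8, edges = edges)
  })
}
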