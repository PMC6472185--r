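make_qc_sample <- function(pos_counts, neg_counts, binding_density = 0.5,
                           ladder = c(128, 32, 8, 2, 0.5, 0.125)) {
  codes <- tibble::tibble(
    code_class = c(rep("Positive", length(pos_counts)),
                   rep("Negative", length(neg_counts)), "Endogenous"),
    gene_name = c(sprintf("POS_%s(%s)", LETTERS[seq_along(pos_counts)],
                          format(ladder[seq_along(pos_counts)], trim = TRUE)),
                  sprintf("NEG_%s(0)", LETTERS[seq_along(neg_counts)]), "GENE1"),
    accession = "X",
    count = as.integer(c(pos_counts, neg_counts, 100))
  )
  txt <- paste(c(
    "<Header>", "FileVersion,1.7", "</Header>",
    "<Sample_Attributes>", "ID,QC1", "</Sample_Attributes>",
    "<Lane_Attributes>", "ID,1", paste0("BindingDensity,", binding_density),
    "</Lane_Attributes>",
    "<Code_Summary>", "CodeClass,Name,Accession,Count",
    paste(codes$code_class, codes$gene_name, codes$accession, codes$count, sep = ","),
    "</Code_Summary>"), collapse = "\n")
  parse_rcc(txt)
}

test_that("binding density is flagged on a closed interval", {
  s <- make_qc_sample(c(26000, 6700, 1680, 430, 110, 30), rep(10, 8))
  expect_true(binding_density_flag(s, 0.1, 2.25)$pass)   # interior, 0.5
  s$binding_density <- 2.30
  expect_false(binding_density_flag(s, 0.1, 2.25)$pass)
  s$binding_density <- 2.25
  expect_true(binding_density_flag(s, 0.1, 2.25)$pass)   # boundary included
  s$binding_density <- NA_real_
  flag <- binding_density_flag(s)
  expect_false(flag$pass)
  expect_match(flag$message, "missing")
})

test_that("linearity is 1 for a proportional ladder and 0 for a flat one", {
  ladder <- c(POS_A = 128, POS_B = 32, POS_C = 8, POS_D = 2,
              POS_E = 0.5, POS_F = 0.125)
  # counts chosen so count + 1 is exactly proportional to concentration
  s <- make_qc_sample(800 * c(128, 32, 8, 2, 0.5, 0.125) - 1, rep(10, 8))
  expect_equal(positive_control_linearity(s, ladder), 1.0, tolerance = 1e-12)

  flat <- make_qc_sample(rep(500, 6), rep(10, 8))
  expect_warning(r2 <- positive_control_linearity(flat, ladder), "constant")
  expect_equal(r2, 0)

  few <- make_qc_sample(c(100, 50), rep(10, 8), ladder = c(128, 32))
  expect_error(positive_control_linearity(few, ladder),
               class = "nanolane_controls_error")
})

test_that("linearity on a realistic ladder matches an independent Pearson computation", {
  ladder <- c(POS_A = 128, POS_B = 32, POS_C = 8, POS_D = 2,
              POS_E = 0.5, POS_F = 0.125)
  counts <- c(26000, 6700, 1680, 430, 110, 30)
  s <- make_qc_sample(counts, rep(10, 8))
  x <- log2(unname(ladder))
  y <- log2(counts + 1)
  mx <- mean(x); my <- mean(y)
  r <- sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
  expect_equal(positive_control_linearity(s, ladder), r^2, tolerance = 1e-9)
})

test_that("linearity is invariant under rescaling all counts", {
  ladder <- c(POS_A = 128, POS_B = 32, POS_C = 8, POS_D = 2,
              POS_E = 0.5, POS_F = 0.125)
  counts <- c(26000, 6700, 1680, 430, 110, 30)
  s1 <- make_qc_sample(counts, rep(10, 8))
  s2 <- make_qc_sample(counts * 4, rep(10, 8))
  # +1 breaks exact log-shift invariance at tiny counts; near-invariance holds
  expect_equal(positive_control_linearity(s1, ladder),
               positive_control_linearity(s2, ladder), tolerance = 1e-3)
})

test_that("limit of detection compares the probe against the lane background", {
  s <- make_qc_sample(c(26000, 6700, 1680, 430, 200, 30), rep(10, 8))
  lod <- limit_of_detection_flag(s, "POS_E")
  expect_equal(lod$threshold, 10)  # zero-variance negatives
  expect_true(lod$pass)

  s$codes$count[5] <- 5L
  expect_false(limit_of_detection_flag(s, "POS_E")$pass)

  negs <- c(8, 12, 10, 14, 6, 9, 11, 10)
  s2 <- make_qc_sample(c(26000, 6700, 1680, 430, 120, 30), negs)
  lod2 <- limit_of_detection_flag(s2, "POS_E")
  expect_equal(lod2$threshold, oracle_threshold(negs), tolerance = 1e-9)
  expect_equal(lod2$pass, lod2$count >= oracle_threshold(negs))

  expect_error(limit_of_detection_flag(s2, "POS_Z"), "POS_Z",
               class = "nanolane_controls_error")
})

test_that("qc_report aggregates flags with one message per failure", {
  good <- make_qc_sample(c(26000, 6700, 1680, 430, 110, 30), rep(10, 8))
  rep1 <- qc_report(good)
  expect_equal(nrow(rep1), 1)
  expect_true(all(rep1$bd_flag, rep1$lin_flag, rep1$lod_flag))
  expect_equal(rep1$n_messages, 0)

  bd_only <- make_qc_sample(c(26000, 6700, 1680, 430, 110, 30), rep(10, 8),
                            binding_density = 3.0)
  rep2 <- qc_report(bd_only)
  expect_false(rep2$bd_flag)
  expect_equal(rep2$n_messages, 1)

  # injected low ladder: linearity intact but LOD probe under background
  low <- make_qc_sample(c(260, 67, 17, 4, 1, 0), rep(30, 8))
  rep3 <- qc_report(low)
  expect_false(rep3$lod_flag)
  expect_gte(rep3$n_messages, 1)
})

test_that("QC never mutates counts: normalization is identical with QC run or not", {
  sim <- simulate_cartridge(small_sim_spec(seed = 9))
  before <- tidy(sim$cartridge)
  invisible(qc_report(sim$cartridge))
  expect_identical(tidy(sim$cartridge), before)
  n1 <- normalize_cartridge(sim$cartridge)
  invisible(qc_report(sim$cartridge))
  n2 <- normalize_cartridge(sim$cartridge)
  expect_identical(n1$matrix, n2$matrix)
})
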