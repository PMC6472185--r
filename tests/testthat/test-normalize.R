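new_expr_tbl_for_test <- function(tbl) {
  attr(tbl, "stage") <- "normalized"
  class(tbl) <- unique(c("expr_tbl", class(tbl)))
  tbl
}

test_that("background threshold is geomean + 2 SD with a floor of 1", {
  expect_equal(background_threshold(rep(10, 6)), 10)        # zero variance
  expect_equal(background_threshold(c(0, 0, 0, 0)), 1)      # zeros floored
  negs <- c(8, 12, 10, 14, 6, 9, 11, 10)
  expect_equal(background_threshold(negs), oracle_threshold(negs),
               tolerance = 1e-9)
  expect_error(background_threshold(5), class = "nanolane_controls_error")
})

test_that("background correction floors counts per lane and never lowers them", {
  m <- matrix(c(3, 50, 7, 20), nrow = 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  x <- as_expr_table(m, stage = "flat")
  out <- apply_background(x, c(s1 = 10, s2 = 5))
  expect_equal(unname(expr_values(out)), matrix(c(10, 50, 7, 20), nrow = 2))
  expect_equal(expr_stage(out), "background_corrected")

  # identity when everything clears the threshold
  out2 <- apply_background(x, c(s1 = 1, s2 = 1))
  expect_equal(expr_values(out2), m)

  # random matrices: per-column minimum is at least that column's threshold
  rm <- random_expr_matrix(25, 6, seed = 4)
  thr <- withr::with_seed(8, stats::runif(6, 5, 60))
  names(thr) <- colnames(rm)
  corr <- apply_background(as_expr_table(rm, stage = "flat"), thr)
  expect_true(all(apply(expr_values(corr), 2, min) >= thr - 1e-12))

  expect_error(apply_background(x, 1), class = "nanolane_dimension_error")
})

test_that("stability M matches the brute-force pairwise oracle", {
  m <- random_expr_matrix(4, 6, seed = 2)
  expect_equal(genorm_stability(m), oracle_M(m), tolerance = 1e-9)
  m20 <- random_expr_matrix(20, 8, seed = 3)
  expect_equal(genorm_stability(m20), oracle_M(m20), tolerance = 1e-9)
})

test_that("stability M is 0 for perfectly proportional genes and maximal for noise", {
  # powers of two make the pairwise log2 ratios exactly constant in floating point
  s <- 2^c(1, 3, 2, 5, 4, 0)
  m <- rbind(a = 4 * s, b = 32 * s)
  colnames(m) <- paste0("x", 1:6)
  expect_equal(unname(genorm_stability(m)), c(0, 0), tolerance = 1e-12)

  prop <- rbind(a = 4 * s, b = 32 * s, c = 2 * s)
  noisy <- rbind(prop, z = withr::with_seed(1, 2^(5 + 3 * stats::rnorm(6))))
  colnames(noisy) <- paste0("x", 1:6)
  M <- genorm_stability(noisy)
  expect_equal(names(which.max(M)), "z")
})

test_that("stability M is invariant under per-lane rescaling", {
  m <- random_expr_matrix(10, 5, seed = 6)
  scaled <- sweep(m, 2, c(0.2, 1, 3, 10, 0.5), `*`)
  expect_equal(genorm_stability(m), genorm_stability(scaled), tolerance = 1e-9)
})

test_that("housekeeper selection reproduces an independent elimination loop", {
  m <- random_expr_matrix(6, 8, seed = 7)
  sel <- select_housekeepers(m, n_keep = 3)
  expect_equal(sort(sel$selected), sort(oracle_select(m, 3)))
  expect_equal(sel$selected, rownames(m)[rownames(m) %in% sel$selected]) # input order

  # nothing to remove when candidates == n_keep
  m3 <- random_expr_matrix(3, 5, seed = 8)
  expect_equal(select_housekeepers(m3, 3)$selected, rownames(m3))

  expect_error(select_housekeepers(m3, 4), class = "nanolane_validation_error")
})

test_that("a noisy gene is eliminated before covarying ones", {
  s <- withr::with_seed(20, 2^stats::rnorm(7))
  m <- rbind(g1 = 50 * s, g2 = 100 * s, g3 = 200 * s, g4 = 400 * s, g5 = 800 * s,
             noisy = withr::with_seed(21, 2^stats::rnorm(7, 8, 2)))
  colnames(m) <- paste0("x", 1:7)
  expect_false("noisy" %in% select_housekeepers(m, 5)$selected)
})

test_that("stability M is 0 when ratios are constant across proportionally scaled genes", {
  s <- withr::with_seed(22, 2^stats::rnorm(6))
  m <- rbind(a = 100 * s, b = 350 * s)
  colnames(m) <- paste0("x", 1:6)
  expect_lt(max(genorm_stability(m)), 1e-6)  # floating-point ratios: near zero
})

test_that("scaling factors equalize housekeeper geometric means", {
  # identical profiles -> all factors 1
  prof <- c(100, 200, 400)
  m <- matrix(rep(prof, 4), nrow = 3, dimnames = list(letters[1:3], paste0("s", 1:4)))
  expect_equal(scaling_factors(m)$scaling_factor, rep(1, 4))

  # hand computation: lane geomeans 100 and 400 -> A = 250 -> SF 2.5, 0.625
  m2 <- matrix(c(100, 100, 400, 400), nrow = 2,
               dimnames = list(c("a", "b"), c("s1", "s2")))
  sf <- scaling_factors(m2)
  expect_equal(sf$lane_geomean, c(100, 400))
  expect_equal(sf$scaling_factor, c(2.5, 0.625))

  # algebraic identity: g_l * SF_l is the same constant in every lane
  m3 <- random_expr_matrix(5, 9, seed = 10)
  sf3 <- scaling_factors(m3)
  prods <- sf3$lane_geomean * sf3$scaling_factor
  expect_lt(diff(range(prods)) / mean(prods), 1e-12)
})

test_that("cartridge normalization runs the steps in order and equalizes lanes", {
  sim <- simulate_cartridge(small_sim_spec(seed = 21))
  norm <- normalize_cartridge(sim$cartridge)

  expect_gte(length(norm$selected_housekeepers), 3)
  expect_true(all(norm$scaling_factors > 0))
  expect_setequal(unique(norm$matrix$code_class), c("Endogenous", "Housekeeping"))
  expect_equal(expr_stage(norm$matrix), "normalized")

  hk <- norm$matrix[norm$matrix$gene_name %in% norm$selected_housekeepers, ]
  g <- apply(expr_values(new_expr_tbl_for_test(hk)), 2, function(v) exp(mean(log(v))))
  expect_lt(diff(range(g)) / mean(g), 1e-9)

  # mean of per-lane geomeans is preserved by scaling
  expect_equal(unname(g), rep(mean(norm$lane_geomeans), length(g)))
})


test_that("single-lane cartridges get scaling factor 1", {
  sim <- simulate_cartridge(small_sim_spec(seed = 2))
  one <- structure(list(samples = sim$cartridge$samples[1],
                        cartridge_id = "one"), class = "cartridge")
  norm <- normalize_cartridge(one)
  expect_equal(unname(norm$scaling_factors), 1)
})

test_that("planted lane effects are recovered as inverse scaling factors", {
  spec <- simulation_spec(n_lanes = 3, n_endogenous = 30, n_housekeeping = 8,
                          lane_effects = c(0.5, 1, 2), hk_noise_sd = 0.01,
                          seed = 31)
  sim <- simulate_cartridge(spec)
  norm <- normalize_cartridge(sim$cartridge)
  r <- stats::cor(norm$scaling_factors, 1 / sim$truth$lane_effects)
  expect_gt(r, 0.99)
})

test_that("tidy and glance summarize a normalization result", {
  sim <- simulate_cartridge(small_sim_spec(seed = 13))
  norm <- normalize_cartridge(sim$cartridge)
  td <- tidy(norm)
  expect_equal(names(td), c("sample_id", "background_threshold",
                            "lane_geomean", "scaling_factor"))
  expect_equal(nrow(td), 4)
  gl <- glance(norm)
  expect_equal(gl$n_housekeepers, 3)
  expect_equal(gl$n_genes, 38)
})
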