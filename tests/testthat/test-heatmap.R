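test_that("z-scoring standardizes rows and flags constant genes", {
  m <- matrix(c(1, 2, 3), nrow = 1, dimnames = list("g", c("a", "b", "c")))
  expect_equal(unname(zscore_rows(m)), matrix(c(-1, 0, 1), nrow = 1))

  const <- matrix(5, nrow = 1, ncol = 3,
                  dimnames = list("flat", c("a", "b", "c")))
  expect_warning(z <- zscore_rows(const), "constant")
  expect_equal(unname(z), matrix(0, 1, 3))

  rm <- random_expr_matrix(40, 9, seed = 16)
  z <- zscore_rows(rm)
  expect_true(all(abs(rowMeans(z)) <= 1e-9))
  expect_true(all(abs(apply(z, 1, stats::sd) - 1) <= 1e-9))

  expect_error(zscore_rows(rm[, 1, drop = FALSE]),
               class = "nanolane_domain_error")
})

test_that("z-scoring commutes with row/column permutation", {
  m <- random_expr_matrix(8, 6, seed = 17)
  pr <- sample(nrow(m)); pc <- sample(ncol(m))
  expect_equal(zscore_rows(m)[pr, pc], zscore_rows(m[pr, pc]))
})

test_that("clustering merges identical rows first and handles 2 items", {
  m <- rbind(a = c(0, 0, 0), b = c(5, 5, 1), c = c(5, 5, 1), d = c(9, 0, 4))
  colnames(m) <- paste0("s", 1:3)
  hc <- hcluster(m, "genes")
  expect_equal(hc$height[1], 0)
  expect_setequal(rownames(m)[-hc$merge[1, ]], c("b", "c"))

  hc2 <- hcluster(m[1:2, ], "genes")
  expect_equal(hc2$order, 1:2)

  expect_error(hcluster(m[1, , drop = FALSE], "genes"),
               class = "nanolane_domain_error")
})

test_that("average-linkage clustering matches a naive agglomeration oracle", {
  for (seed in c(3, 4, 5)) {
    m <- matrix(stats::rnorm(8 * 5), nrow = 8,
                dimnames = list(paste0("g", 1:8), paste0("s", 1:5)))
    hc <- hcluster(m, "genes")
    coph <- as.matrix(stats::cophenetic(hc))
    oracle <- oracle_upgma_cophenetic(m)
    dimnames(oracle) <- dimnames(coph)
    expect_equal(coph, oracle, tolerance = 1e-9)
  }
})

test_that("clustering is permutation-equivariant", {
  m <- random_expr_matrix(7, 5, seed = 19)
  perm <- c(3, 1, 7, 5, 2, 6, 4)
  hc1 <- hcluster(m, "genes")
  hc2 <- hcluster(m[perm, ], "genes")
  expect_equal(as.matrix(stats::cophenetic(hc1))[rownames(m), rownames(m)],
               as.matrix(stats::cophenetic(hc2))[rownames(m), rownames(m)],
               tolerance = 1e-12)
})

sample_meta <- function() {
  tibble::tibble(
    sample_id = c("a1", "a2", "b1", "b2", "c1"),
    patient_id = c("P1", "P1", "P2", "P2", "P3"),
    sample_order = c(1L, 2L, 1L, 2L, 1L)
  )
}

test_that("the four comparison orderings follow the patient metadata", {
  meta <- sample_meta()[1:4, ]

  one <- tibble::tibble(sample_id = paste0("t", 4:1), patient_id = "P",
                        sample_order = 4:1)
  expect_equal(order_samples(one, "I"), paste0("t", 1:4))
  expect_error(order_samples(meta, "I"), "single patient",
               class = "nanolane_metadata_error")

  expect_equal(order_samples(meta, "II"), c("a1", "b1"))
  expect_equal(order_samples(sample_meta(), "II"), c("a1", "b1", "c1"))
  expect_equal(order_samples(meta, "III"), c("a2", "b2"))
  expect_equal(order_samples(meta, "IV"), c("a1", "b1", "a2", "b2"))

  # P3 has no second sample
  expect_error(order_samples(sample_meta(), "IV"), "P3",
               class = "nanolane_metadata_error")
  expect_error(order_samples(sample_meta(), "III"), "P3",
               class = "nanolane_metadata_error")
})

test_that("build_heatmap chains filter, ordering, z-score and clustering", {
  m <- random_expr_matrix(60, 4, seed = 20)
  colnames(m) <- c("a1", "a2", "a3", "a4")
  x <- as_expr_table(m, stage = "normalized")
  meta <- tibble::tibble(sample_id = paste0("a", 1:4), patient_id = "P1",
                         sample_order = 1:4)

  hm <- build_heatmap(x, meta = meta, analysis_type = "I", k = 30)
  expect_equal(dim(hm$zmatrix), c(30, 4))
  expect_equal(colnames(hm$zmatrix), paste0("a", 1:4))
  expect_equal(hm$sample_order, paste0("a", 1:4))  # fixed, not clustered
  expect_null(hm$sample_hclust)
  expect_true(all(abs(rowMeans(hm$zmatrix)) <= 1e-9))

  # free mode keeps all genes and clusters both axes
  hm2 <- build_heatmap(x, analysis_type = "free")
  expect_equal(dim(hm2$zmatrix), c(60, 4))
  expect_s3_class(hm2$sample_hclust, "hclust")
  expect_setequal(hm2$gene_order, rownames(m))
})

test_that("planted anti-correlated gene blocks are recovered as the top split", {
  spec <- simulation_spec(n_lanes = 8, n_endogenous = 60, n_housekeeping = 8,
                          endo_noise_sd = 0.05,
                          planted_clusters = list(genes_per_block = 10,
                                                  amplitude = 4),
                          seed = 23)
  sim <- simulate_cartridge(spec)
  norm <- normalize_cartridge(sim$cartridge)
  hm <- build_heatmap(norm$matrix, k = 20)

  # with low noise, the 20 most variable genes are the planted ones and the
  # top dendrogram split separates block A from block B
  planted <- sim$truth$planted_clusters
  expect_setequal(rownames(hm$zmatrix), c(planted$block_a, planted$block_b))
  top2 <- stats::cutree(hm$gene_hclust, k = 2)
  expect_equal(length(unique(top2[planted$block_a])), 1)
  expect_equal(length(unique(top2[planted$block_b])), 1)
  expect_false(top2[planted$block_a[1]] == top2[planted$block_b[1]])
})

test_that("heatmap tidy/autoplot and artifact export work end to end", {
  m <- random_expr_matrix(10, 4, seed = 25)
  hm <- build_heatmap(as_expr_table(m, stage = "normalized"))
  long <- tidy(hm)
  expect_equal(nrow(long), 40)
  p <- autoplot(hm)
  expect_s3_class(p, "ggplot")

  dir <- withr::local_tempdir()
  write_heatmap(hm, dir)
  expect_true(all(file.exists(file.path(
    dir, c("heatmap_z.tsv", "gene_order.txt", "sample_order.txt",
           "genes.nwk", "samples.nwk")))))
  tree <- ape::read.tree(file.path(dir, "genes.nwk"))
  expect_setequal(tree$tip.label, rownames(m))
})
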