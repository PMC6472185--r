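# Independent brute-force oracles used to pin down expected values.
# These deliberately share no code with the package internals.

# geomean + 2 * sample SD, written out longhand
oracle_threshold <- function(neg) {
  g <- prod(pmax(neg, 1))^(1 / length(neg))
  n <- length(neg)
  v <- sum((neg - mean(neg))^2) / (n - 1)
  g + 2 * sqrt(v)
}

# pairwise-ratio stability by explicit double loop
oracle_M <- function(m) {
  g <- nrow(m)
  M <- numeric(g)
  for (j in seq_len(g)) {
    sds <- numeric(0)
    for (k in seq_len(g)) {
      if (k == j) next
      sds <- c(sds, stats::sd(log2(m[j, ] / m[k, ])))
    }
    M[j] <- mean(sds)
  }
  stats::setNames(M, rownames(m))
}

# iterative removal loop re-implemented independently
oracle_select <- function(m, n_keep) {
  while (nrow(m) > n_keep) {
    M <- oracle_M(m)
    worst <- max(M)
    ties <- names(M)[M >= worst - 1e-15]
    m <- m[rownames(m) != sort(ties)[length(ties)], , drop = FALSE]
  }
  rownames(m)
}

# naive O(n^3) average-linkage agglomeration; returns the cophenetic matrix
oracle_upgma_cophenetic <- function(m) {
  n <- nrow(m)
  d <- as.matrix(stats::dist(m))
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  active <- rep(TRUE, n)
  cd <- d
  while (sum(active) > 1) {
    best <- c(NA, NA)
    best_d <- Inf
    idx <- which(active)
    for (a in idx) for (b in idx) {
      if (a < b && cd[a, b] < best_d) { best_d <- cd[a, b]; best <- c(a, b) }
    }
    a <- best[1]; b <- best[2]
    for (i in clusters[[a]]) for (j in clusters[[b]]) {
      coph[i, j] <- coph[j, i] <- best_d
    }
    # average linkage: distance of the union to any cluster is the mean of
    # all inter-point distances
    merged <- c(clusters[[a]], clusters[[b]])
    for (k in idx) {
      if (k == a || k == b) next
      cd[a, k] <- cd[k, a] <- mean(d[merged, clusters[[k]], drop = FALSE])
    }
    clusters[[a]] <- merged
    active[b] <- FALSE
  }
  coph
}

# positive expression-like matrix with reproducible values
random_expr_matrix <- function(n_genes, n_samples, seed = 1, sd = 0.5) {
  withr::with_seed(seed, {
    base <- 2^stats::runif(n_genes, 4, 10)
    m <- base * 2^matrix(stats::rnorm(n_genes * n_samples, 0, sd), n_genes)
    dimnames(m) <- list(sprintf("g%02d", seq_len(n_genes)),
                        sprintf("s%02d", seq_len(n_samples)))
    m
  })
}

small_sim_spec <- function(seed = 1, ...) {
  simulation_spec(n_lanes = 4, n_endogenous = 30, n_housekeeping = 8,
                  seed = seed, ...)
}

rcc_text_minimal <- function(counts = c("Positive,POS_A(128),ERCC,10000",
                                        "Endogenous,CCL2,NM_002982.3,742"),
                             binding_density = "0.51") {
  paste(c(
    "<Header>", "FileVersion,1.7", "</Header>",
    "<Sample_Attributes>", "ID,S1", "Date,20240101", "</Sample_Attributes>",
    "<Lane_Attributes>", "ID,1", paste0("BindingDensity,", binding_density),
    "</Lane_Attributes>",
    "<Code_Summary>", "CodeClass,Name,Accession,Count", counts,
    "</Code_Summary>"
  ), collapse = "\n")
}
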