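#' Infer a gene regulatory network with random-forest / extra-trees ensembles
#'
#' Classic tree-ensemble network inference: each gene in turn is the target
#' of a regression of its (unit-variance-standardized) expression on all
#' candidate regulator genes across samples, and the weight of the directed
#' edge regulator -> target is the regulator's importance in the target's
#' ensemble — the mean, over trees, of the total variance reduction achieved
#' by splits on that regulator. Samples are treated as exchangeable
#' observations. Note that tree-ensemble regressors want many more samples
#' than a single 12-lane cartridge provides; a warning is raised below 10.
#'
#' @param x An `expr_tbl` (stage `"normalized"` or `"zscored"`) or a numeric
#'   matrix genes x samples, at least 3 of each.
#' @param n_trees Trees per target ensemble (default 1000).
#' @param mtry Candidate predictors per split; default `round(sqrt(p))` for
#'   `p` regulators.
#' @param variant `"RF"` (bootstrap rows, exhaustive split search) or `"ET"`
#'   (all rows, one random cutpoint per candidate feature).
#' @param regulators Optional character vector restricting candidate
#'   regulators (default: all genes).
#' @param min_split Minimum node size eligible for splitting (trees are
#'   otherwise grown to purity).
#' @param seed Integer seed; the full edge list is bit-reproducible given it.
#' @return A `grn_result`: `edges` tibble (`regulator`, `target`, `weight`),
#'   `algorithm`, `seed`, `params`.
#' @seealso [infer_grnboost2()], [top_n_links()]
#' @export
infer_genie3 <- function(x, n_trees = 1000, mtry = NULL,
                         variant = c("RF", "ET"), regulators = NULL,
                         min_split = 2, seed = 42) {
  variant <- match.arg(variant)
  m <- grn_input_matrix(x)
  withr::with_seed(seed, {
    edges <- grn_per_target(m, regulators, function(X, y, p) {
      nl_ensemble_importance(
        X, y, ntrees = as.integer(n_trees),
        mtry = as.integer(mtry %||% max(1L, round(sqrt(p)))),
        min_split = as.integer(min_split), max_depth = 100000L,
        extra = variant == "ET", bootstrap = variant == "RF")
    })
  })
  new_grn_result(edges,
                 algorithm = if (variant == "ET") "genie3_et" else "genie3_rf",
                 seed = seed,
                 params = list(n_trees = n_trees, mtry = mtry,
                               min_split = min_split, variant = variant))
}

#' Infer a gene regulatory network with stochastic gradient boosting
#'
#' Per target, shallow regression trees are fit to the residuals of the
#' running prediction, each round on a random subsample of the samples; the
#' rows left out of a round give an out-of-sample loss, and boosting stops
#' early once that loss has not improved on its best value for
#' `early_stop_window` consecutive rounds. Edge weights are the regulators'
#' variance-reduction importances accumulated over the executed rounds. With
#' `subsample = 1` (or a window larger than `max_rounds`) this reduces to
#' fixed-round boosting.
#'
#' @inheritParams infer_genie3
#' @param max_rounds Maximum boosting rounds per target (default 500).
#' @param learning_rate Shrinkage applied to each tree's contribution.
#' @param early_stop_window Rounds without out-of-sample improvement before
#'   stopping.
#' @param subsample Fraction of samples drawn (without replacement) per
#'   round.
#' @param max_depth Depth of each boosted tree.
#' @return A `grn_result`; see [infer_genie3()].
#' @export
infer_grnboost2 <- function(x, max_rounds = 500, learning_rate = 0.01,
                            early_stop_window = 25, subsample = 0.9,
                            max_depth = 3, regulators = NULL, seed = 42) {
  m <- grn_input_matrix(x)
  withr::with_seed(seed, {
    edges <- grn_per_target(m, regulators, function(X, y, p) {
      grn_boost_target(X, y, max_rounds, learning_rate, early_stop_window,
                       subsample, max_depth)
    })
  })
  new_grn_result(edges, algorithm = "grnboost2", seed = seed,
                 params = list(max_rounds = max_rounds,
                               learning_rate = learning_rate,
                               early_stop_window = early_stop_window,
                               subsample = subsample, max_depth = max_depth))
}

#' Keep the n strongest links of a network
#'
#' Large inferred networks are unreadable; this filter keeps the
#' `min(n, number of positive-weight edges)` edges of highest weight (ties
#' broken by regulator, then target, lexicographically) and, implicitly, the
#' nodes those edges touch. Top-n sets are nested in n.
#'
#' @param result A `grn_result`.
#' @param n Number of links to keep (>= 1).
#' @return A `grn_result` with the filtered edge list.
#' @export
top_n_links <- function(result, n) {
  stopifnot(inherits(result, "grn_result"), n >= 1)
  kept <- result$edges |>
    dplyr::filter(.data$weight > 0) |>
    dplyr::arrange(dplyr::desc(.data$weight), .data$regulator, .data$target) |>
    utils::head(n)
  out <- result
  out$edges <- kept
  out
}

#' @export
print.grn_result <- function(x, ...) {
  cat(sprintf("<grn_result %s (seed %d): %d edges over %d nodes>\n",
              x$algorithm, x$seed, nrow(x$edges),
              length(union(x$edges$regulator, x$edges$target))))
  invisible(x)
}

#' Edge list of an inferred network
#'
#' @param x A `grn_result`.
#' @param ... Unused.
#' @return Tibble `regulator`, `target`, `weight`, `rank` (1 = strongest;
#'   ties resolved by regulator then target).
#' @export
tidy.grn_result <- function(x, ...) {
  x$edges |>
    dplyr::arrange(dplyr::desc(.data$weight), .data$regulator, .data$target) |>
    dplyr::mutate(rank = dplyr::row_number())
}

#' One-row summary of an inferred network
#'
#' @param x A `grn_result`.
#' @param ... Unused.
#' @export
glance.grn_result <- function(x, ...) {
  tibble::tibble(
    algorithm = x$algorithm, seed = x$seed,
    n_edges = nrow(x$edges),
    n_positive = sum(x$edges$weight > 0),
    n_nodes = length(union(x$edges$regulator, x$edges$target)),
    max_weight = if (nrow(x$edges)) max(x$edges$weight) else NA_real_
  )
}

#' Plot the strongest links of a network
#'
#' @param object A `grn_result`.
#' @param n How many links to show.
#' @param ... Unused.
#' @return A ggplot bar chart of edge weights, strongest on top.
#' @export
autoplot.grn_result <- function(object, n = 20, ...) {
  edges <- tidy.grn_result(top_n_links(object, n))
  edges$link <- factor(paste(edges$regulator, "→", edges$target),
                       levels = rev(paste(edges$regulator, "→", edges$target)))
  ggplot2::ggplot(edges, ggplot2::aes(x = .data$weight, y = .data$link)) +
    ggplot2::geom_col(fill = "#2166AC") +
    ggplot2::labs(x = "importance", y = NULL, title = object$algorithm) +
    ggplot2::theme_minimal(base_size = 9)
}

#' Write a network edge list as TSV
#'
#' Columns: regulator, target, weight, rank.
#'
#' @param result A `grn_result`.
#' @param path Destination.
#' @export
write_grn_tsv <- function(result, path) {
  readr::write_tsv(tidy.grn_result(result), path, progress = FALSE)
  invisible(path)
}

# ---- internal ---------------------------------------------------------------

grn_input_matrix <- function(x) {
  m <- if (inherits(x, "expr_tbl")) expr_values(x) else x
  if (!is.matrix(m) || nrow(m) < 3 || ncol(m) < 3) {
    rlang::abort("Network inference needs a matrix of at least 3 genes and 3 samples",
                 class = "nanolane_domain_error")
  }
  if (is.null(rownames(m))) rownames(m) <- paste0("G", seq_len(nrow(m)))
  if (ncol(m) < 10) {
    rlang::warn(sprintf(
      "Only %d samples: tree-ensemble regression is unreliable at this size; interpret edges with caution",
      ncol(m)))
  }
  m
}

# Shared target loop: fit_fun(X, y, p) -> importance vector over candidates.
grn_per_target <- function(m, regulators, fit_fun) {
  genes <- rownames(m)
  regulators <- regulators %||% genes
  unknown <- setdiff(regulators, genes)
  if (length(unknown) > 0) {
    rlang::abort(sprintf("Unknown regulator gene(s): %s",
                         paste(unknown, collapse = ", ")),
                 class = "nanolane_validation_error")
  }
  constant <- character()
  res <- purrr::map_dfr(genes, function(target) {
    cand <- setdiff(regulators, target)
    if (length(cand) == 0) return(NULL)
    y <- m[target, ]
    s <- stats::sd(y)
    if (s == 0) {
      constant <<- c(constant, target)
      w <- rep(0, length(cand))
    } else {
      X <- t(m[cand, , drop = FALSE])
      w <- as.numeric(fit_fun(X, y / s, length(cand)))
    }
    tibble::tibble(regulator = cand, target = target, weight = w)
  })
  if (length(constant) > 0) {
    rlang::warn(sprintf("Constant target gene(s) %s: incoming edge weights set to 0",
                        paste(constant, collapse = ", ")))
  }
  res
}

grn_boost_target <- function(X, y, max_rounds, learning_rate,
                             early_stop_window, subsample, max_depth) {
  n <- nrow(X)
  p <- ncol(X)
  n_sub <- max(2L, min(n, floor(subsample * n)))
  fit <- rep(0, n)
  imp <- rep(0, p)
  best_oos <- Inf
  since_best <- 0L
  for (r in seq_len(max_rounds)) {
    train <- if (n_sub < n) sort(sample.int(n, n_sub)) else seq_len(n)
    step <- nl_tree_fit(X, y - fit, train - 1L,
                        mtry = p, min_split = 2L,
                        max_depth = as.integer(max_depth), extra = FALSE)
    fit <- fit + learning_rate * step$pred
    imp <- imp + step$importance
    oos <- setdiff(seq_len(n), train)
    if (length(oos) > 0) {
      loss <- mean((y[oos] - fit[oos])^2)
      if (loss < best_oos) {
        best_oos <- loss
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
      }
      if (since_best >= early_stop_window) break
    }
  }
  imp
}

new_grn_result <- function(edges, algorithm, seed, params) {
  dup <- duplicated(paste(edges$regulator, edges$target, sep = "\r"))
  stopifnot(!any(dup), all(edges$regulator != edges$target))
  structure(list(edges = edges, algorithm = algorithm,
                 seed = seed, params = params),
            class = "grn_result")
}
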