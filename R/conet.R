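# Sparse co-abundance network over MSPs: CLR transform, per-node
# neighborhood-selection lasso over a penalty grid, StARS stability
# selection, OR-rule symmetrization with signed edges; geodesic distances
# from the product-strain nodes; and the distance vs shared-function
# association.

clr_matrix <- function(counts, pseudocount = 1) {
  lx <- log(counts + pseudocount)
  sweep(lx, 2, colMeans(lx), "-")   # per-sample centering (samples = columns)
}

# Directed adjacency (p x p x n_lambda, logical) from per-node lasso paths.
mb_adjacency <- function(X, lambda_grid) {
  p <- ncol(X)
  adj <- array(FALSE, c(p, p, length(lambda_grid)))
  for (j in seq_len(p)) {
    fit <- glmnet::glmnet(X[, -j, drop = FALSE], X[, j],
                          lambda = lambda_grid, standardize = TRUE)
    beta <- as.matrix(fit$beta)   # (p-1) x n_fitted
    # glmnet may drop trailing lambdas; align by value
    cols <- match(round(lambda_grid, 12), round(fit$lambda, 12))
    for (l in seq_along(lambda_grid)) {
      if (!is.na(cols[l])) adj[j, -j, l] <- beta[, cols[l]] != 0
    }
  }
  adj
}

#' Build a co-abundance network by neighborhood selection with StARS
#'
#' Counts are centered log-ratio transformed per sample (pseudocount 1). For
#' each node, a lasso regression on all other nodes is fit over a decreasing
#' penalty grid (Meinshausen-Buhlmann neighborhood selection); StARS selects
#' the penalty: edge-selection frequencies across random subsamples give a
#' mean edge instability per penalty, the instability path is monotonized
#' from the sparse end, and the densest graph whose monotonized instability
#' stays at or below `stars_threshold` is kept. Edges are symmetrized by the
#' OR rule; an edge's sign is the sign of the mean of its directed lasso
#' coefficients and its weight their mean absolute value.
#'
#' @param counts MSP abundance matrix (MSP x sample), nonnegative.
#' @param product_nodes Character vector of product-species node ids (kept on
#'   the object for downstream distance computations).
#' @param lambda_grid Decreasing penalty grid; NULL builds a 15-point
#'   log-spaced grid from the largest empirical cross-covariance down two
#'   decades.
#' @param stars_threshold StARS instability threshold (default 0.05).
#' @param n_subsamples Number of random subsamples (default 20).
#' @param subsample_ratio Fraction of samples per subsample (default 0.8).
#' @param seed Seed for the subsampling (results are deterministic given it).
#' @return A `co_network` list: `nodes`, `edges` (from, to, sign, weight,
#'   stability), `lambda_selected`, `instability` path, `product_nodes`.
#' @export
build_network <- function(counts, product_nodes = character(0),
                          lambda_grid = NULL, stars_threshold = 0.05,
                          n_subsamples = 20L, subsample_ratio = 0.8,
                          seed = 1L) {
  if (!is.matrix(counts) || any(counts < 0)) {
    stop("counts must be a nonnegative matrix (MSP x sample)")
  }
  n <- ncol(counts); p <- nrow(counts)
  if (is.null(rownames(counts))) stop("counts must carry MSP rownames")
  if (!all(product_nodes %in% rownames(counts))) {
    stop("product node(s) absent from the matrix")
  }
  sub_size <- floor(subsample_ratio * n)
  if (sub_size < 2L || sub_size >= n) stop("too few samples for subsampling")
  raw_sds <- apply(counts, 1, stats::sd)
  if (any(raw_sds == 0)) {
    stop("all-constant node(s): ",
         paste(rownames(counts)[raw_sds == 0], collapse = ", "))
  }
  X <- t(clr_matrix(counts))   # samples x MSPs
  sds <- apply(X, 2, stats::sd)
  if (is.null(lambda_grid)) {
    # largest penalty at which every neighborhood is empty, then two decades
    cors <- stats::cor(X); diag(cors) <- 0
    lam_max <- max(max(abs(cors)) * max(sds), 0.1)
    lambda_grid <- exp(seq(log(lam_max), log(lam_max * 0.01), length.out = 15))
  }
  if (is.unsorted(rev(lambda_grid))) stop("lambda grid must be decreasing")

  with_substream(seed, "stars", {
    nl <- length(lambda_grid)
    freq <- array(0, c(p, p, nl))
    for (b in seq_len(n_subsamples)) {
      idx <- sample.int(n, sub_size)
      adj <- mb_adjacency(X[idx, , drop = FALSE], lambda_grid)
      for (l in seq_len(nl)) {
        und <- adj[, , l] | t(adj[, , l])
        freq[, , l] <- freq[, , l] + und
      }
    }
    freq <- freq / n_subsamples
    upper <- upper.tri(matrix(0, p, p))
    instability <- vapply(seq_len(nl), function(l) {
      th <- freq[, , l][upper]
      mean(2 * th * (1 - th))
    }, 0)
    inst_mono <- cummax(instability)   # monotone from the sparse end
    ok <- which(inst_mono <= stars_threshold)
    sel <- if (length(ok) > 0) max(ok) else 1L
    lambda_sel <- lambda_grid[sel]

    # final fit on the full data at the selected penalty
    coefs <- matrix(0, p, p, dimnames = list(rownames(counts), rownames(counts)))
    for (j in seq_len(p)) {
      fit <- glmnet::glmnet(X[, -j, drop = FALSE], X[, j],
                            lambda = lambda_grid, standardize = TRUE)
      l <- which.min(abs(fit$lambda - lambda_sel))
      coefs[j, -j] <- as.matrix(fit$beta)[, l]
    }
    sel_adj <- (coefs != 0) | t(coefs != 0)   # OR rule
    edges <- which(sel_adj & upper, arr.ind = TRUE)
    mean_coef <- (coefs + t(coefs)) / 2
    edge_df <- data.frame(
      from = rownames(counts)[edges[, 1]],
      to = rownames(counts)[edges[, 2]],
      sign = ifelse(mean_coef[edges] > 0, "+", "-"),
      weight = abs(mean_coef[edges]),
      stability = freq[, , sel][edges],
      stringsAsFactors = FALSE
    )
    structure(
      list(
        nodes = rownames(counts), edges = edge_df,
        lambda_selected = lambda_sel, lambda_grid = lambda_grid,
        instability = instability, product_nodes = product_nodes
      ),
      class = "co_network"
    )
  })
}

#' @export
print.co_network <- function(x, ...) {
  cat(sprintf("co-abundance network: %d nodes, %d edges (lambda = %.4g)\n",
              length(x$nodes), nrow(x$edges), x$lambda_selected))
  invisible(x)
}

network_igraph <- function(network, edge_filter = c("all", "positive", "negative")) {
  edge_filter <- match.arg(edge_filter)
  edges <- network$edges
  edges <- switch(edge_filter,
    all = edges,
    positive = edges[edges$sign == "+", , drop = FALSE],
    negative = edges[edges$sign == "-", , drop = FALSE]
  )
  igraph::graph_from_data_frame(edges[, c("from", "to")],
                                directed = FALSE,
                                vertices = network$nodes)
}

#' Geodesic hop distances from the product-strain nodes
#'
#' Minimum edge count from each node to the nearest source node (breadth
#' first); unreachable nodes are `Inf`.
#'
#' @param network A `co_network`.
#' @param source_nodes Nonempty character vector of node ids.
#' @param edge_filter Restrict to positive-sign or negative-sign edges before
#'   computing distances.
#' @return Named numeric vector over all nodes.
#' @export
geodesic_distances <- function(network, source_nodes = network$product_nodes,
                               edge_filter = "all") {
  if (length(source_nodes) == 0L) stop("source node set is empty")
  if (!all(source_nodes %in% network$nodes)) stop("unknown source node(s)")
  g <- network_igraph(network, edge_filter)
  d <- igraph::distances(g, v = source_nodes, weights = NA)
  apply(d, 2, min)[network$nodes]
}

#' Association between network distance and shared contributed functions
#'
#' Spearman correlation between each resident node's geodesic distance from
#' the product-strain nodes and its count of shared contributive KOs, over
#' resident nodes at finite distance. The edge filter (all / positive-only /
#' negative-only edges) is applied before the distance computation.
#'
#' @param network A `co_network` with `product_nodes` set.
#' @param shared_counts Named integer vector (see [msp_shared_ko_counts()]);
#'   must cover the resident nodes.
#' @param edge_filter `"all"`, `"positive"`, or `"negative"`.
#' @return A list: `rho`, `p`, `n_used`, `n_unreachable`, `edge_filter`.
#' @export
distance_function_association <- function(network, shared_counts,
                                          edge_filter = c("all", "positive", "negative")) {
  edge_filter <- match.arg(edge_filter)
  dist <- geodesic_distances(network, edge_filter = edge_filter)
  resident <- setdiff(network$nodes, network$product_nodes)
  missing <- setdiff(resident, names(shared_counts))
  if (length(missing) > 0L) {
    stop("shared_counts missing node(s): ", paste(missing, collapse = ", "))
  }
  d <- dist[resident]
  finite <- is.finite(d)
  if (sum(finite) < 3L) stop("fewer than 3 resident nodes at finite distance")
  tst <- spearman_correlation(unname(d[finite]),
                              unname(shared_counts[resident][finite]))
  list(
    rho = tst$statistic, p = tst$p_value,
    n_used = sum(finite), n_unreachable = sum(!finite),
    edge_filter = edge_filter
  )
}
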