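# Helper: a network object built directly from an edge list (distance and
# association code paths do not need a fitted network).
manual_network <- function(nodes, edges, product_nodes = character(0)) {
  structure(list(nodes = nodes, edges = edges, product_nodes = product_nodes),
            class = "co_network")
}

test_that("network estimation is deterministic and invariant to sample order", {
  cfg <- synth_config(seed = 12, n_msps = 10, n_network_samples = 150)
  nd <- gen_network_data(cfg)
  n1 <- build_network(nd$counts, seed = 4)
  n2 <- build_network(nd$counts, seed = 4)
  expect_identical(n1$edges, n2$edges)
  n3 <- build_network(nd$counts[, sample(ncol(nd$counts))], seed = 4)
  expect_setequal(edge_key(n1$edges$from, n1$edges$to),
                  edge_key(n3$edges$from, n3$edges$to))
})

test_that("chain graphs are recovered with correct signs", {
  cfg <- synth_config(seed = 21, n_msps = 15, n_network_samples = 500)
  nd <- gen_network_data(cfg)
  net <- build_network(nd$counts, product_nodes = nd$product_nodes, seed = 2)
  expect_gte(network_f1(net, nd$ground_truth$true_edges), 0.8)
  # negative partial correlations surface as negative co-abundance edges
  tru <- edge_key(nd$ground_truth$true_edges$from, nd$ground_truth$true_edges$to)
  est <- edge_key(net$edges$from, net$edges$to)
  expect_true(all(net$edges$sign[est %in% tru] == "-"))
  expect_error(build_network(nd$counts[, 1:2]), "too few samples")
  bad <- nd$counts; bad["MSP001", ] <- 5
  expect_error(build_network(bad, seed = 1), "MSP001")
})

test_that("geodesic hop distances match the brute-force oracle", {
  set.seed(14)
  for (rep in 1:30) {
    p <- sample(5:12, 1)
    adj <- matrix(0, p, p)
    m <- sample(3:(p * 2), 1)
    for (e in seq_len(m)) {
      ij <- sample(p, 2)
      adj[ij[1], ij[2]] <- adj[ij[2], ij[1]] <- 1
    }
    nodes <- paste0("n", seq_len(p))
    idx <- which(adj == 1 & upper.tri(adj), arr.ind = TRUE)
    edges <- data.frame(from = nodes[idx[, 1]], to = nodes[idx[, 2]],
                        sign = "+", weight = 1, stability = 1,
                        stringsAsFactors = FALSE)
    src <- sample(p, sample(1:2, 1))
    net <- manual_network(nodes, edges)
    got <- geodesic_distances(net, source_nodes = nodes[src])
    want <- brute_hops(adj, src)
    expect_equal(unname(got[nodes]), want)
  }
  expect_error(geodesic_distances(manual_network("a", data.frame()), character(0)),
               "empty")
})

test_that("geodesics honor the source, isolation, and triangle inequality", {
  nodes <- c("P", "a", "b", "c", "iso")
  edges <- data.frame(from = c("P", "a", "b"), to = c("a", "b", "c"),
                      sign = c("+", "+", "-"), weight = 1, stability = 1)
  net <- manual_network(nodes, edges, product_nodes = "P")
  d <- geodesic_distances(net)
  expect_equal(unname(d[c("P", "a", "b", "c")]), c(0, 1, 2, 3))
  expect_equal(unname(d["iso"]), Inf)
  # restricting to positive edges disconnects c
  dpos <- geodesic_distances(net, edge_filter = "positive")
  expect_equal(unname(dpos["c"]), Inf)
})

test_that("distance vs shared-function association finds planted structure", {
  # 50 nodes adjacent to the product species carry twice the shared KOs of
  # 50 nodes at distance 2
  near <- paste0("near", 1:50)
  far <- paste0("far", 1:50)
  edges <- rbind(
    data.frame(from = "P", to = near, sign = "+", weight = 1, stability = 1),
    data.frame(from = near, to = far, sign = "+", weight = 1, stability = 1)
  )
  net <- manual_network(c("P", near, far), edges, product_nodes = "P")
  set.seed(3)
  shared <- c(stats::setNames(rpois(50, 20), near), stats::setNames(rpois(50, 10), far))
  res <- distance_function_association(net, shared)
  expect_lt(res$rho, 0)
  expect_lt(res$p, 0.05)
  expect_equal(res$n_used, 100)

  # two distances, counts constant within each level: rho sign = count ordering
  shared2 <- c(stats::setNames(rep(5, 50), near), stats::setNames(rep(9, 50), far))
  expect_gt(distance_function_association(net, shared2)$rho, 0)
  shared3 <- c(stats::setNames(rep(9, 50), near), stats::setNames(rep(5, 50), far))
  expect_lt(distance_function_association(net, shared3)$rho, 0)

  # unreachable nodes are excluded and counted
  net2 <- manual_network(c("P", near, far, "lost"), edges, product_nodes = "P")
  res2 <- distance_function_association(net2, c(shared, lost = 3))
  expect_equal(res2$n_unreachable, 1)
  expect_equal(res2$n_used, 100)

  # constant counts are an explicit error
  expect_error(
    distance_function_association(net, stats::setNames(rep(4, 100), c(near, far))),
    "constant"
  )
})

test_that("shuffled shared counts show no association", {
  near <- paste0("near", 1:30)
  far <- paste0("far", 1:30)
  edges <- rbind(
    data.frame(from = "P", to = near, sign = "+", weight = 1, stability = 1),
    data.frame(from = near, to = far, sign = "+", weight = 1, stability = 1)
  )
  net <- manual_network(c("P", near, far), edges, product_nodes = "P")
  set.seed(19)
  ok <- 0
  for (rep in 1:50) {
    shared <- stats::setNames(sample(rpois(60, 12)), c(near, far))
    res <- distance_function_association(net, shared)
    if (abs(res$rho) < 0.3 && res$p > 0.05) ok <- ok + 1
  }
  expect_gte(ok / 50, 0.9)
})
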