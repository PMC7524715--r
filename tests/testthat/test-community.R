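toy_counts <- function(m) {
  counts <- as.matrix(m)
  rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  counts
}

test_that("alpha diversity matches closed forms", {
  counts <- toy_counts(cbind(c(25, 25, 25, 25), c(100, 0, 0, 0), c(50, 25, 25, 0)))
  expect_equal(unname(alpha_diversity(counts, "shannon")[1]), log(4))
  expect_equal(unname(alpha_diversity(counts, "shannon")[2]), 0)
  expect_equal(unname(alpha_diversity(counts, "observed")[2]), 1)
  expect_equal(unname(alpha_diversity(counts, "simpson")[2]), 0)
  expect_equal(unname(alpha_diversity(counts, "simpson")[3]), 0.625)
  expect_error(alpha_diversity(counts, "chao1"))
})

test_that("Bray-Curtis and JSD match definitions and brute-force oracles", {
  counts <- toy_counts(cbind(c(2, 0), c(1, 1), c(2, 0), c(0, 5)))
  bc <- beta_diversity_matrix(counts, "bray_curtis")
  js <- beta_diversity_matrix(counts, "jsd")
  expect_equal(bc["s1", "s3"], 0)
  expect_equal(js["s1", "s3"], 0)
  expect_equal(bc["s1", "s4"], 1)            # disjoint supports
  expect_equal(js["s1", "s4"], log(2))
  expect_equal(bc["s1", "s2"], 0.5)          # (1+1)/(3+1) on relative abundances

  set.seed(17)
  for (rep in 1:25) {
    counts <- toy_counts(matrix(rpois(12, 8) + 1, nrow = 4))
    p <- sweep(counts, 2, colSums(counts), "/")
    bc <- beta_diversity_matrix(counts, "bray_curtis")
    js <- beta_diversity_matrix(counts, "jsd")
    expect_equal(bc["s1", "s2"], brute_bray(p[, 1], p[, 2]), tolerance = 1e-12)
    expect_equal(js["s1", "s3"], brute_jsd(p[, 1], p[, 3]), tolerance = 1e-12)
    expect_true(isSymmetric(bc) && isSymmetric(js))
    expect_true(all(diag(bc) == 0) && all(bc >= 0) && all(bc <= 1))
  }
})

test_that("UniFrac matches the per-branch brute-force oracle on random trees", {
  tree2 <- ape::read.tree(text = "(a:1,b:1);")
  counts <- toy_counts(cbind(c(10, 0), c(0, 10)))
  rownames(counts) <- c("a", "b")
  expect_equal(unifrac_distance(counts, tree2, weighted = FALSE)["s1", "s2"], 1)
  expect_equal(unifrac_distance(counts, tree2, weighted = TRUE)["s1", "s2"], 1)
  same <- toy_counts(cbind(c(3, 7), c(3, 7)))
  rownames(same) <- c("a", "b")
  expect_equal(unifrac_distance(same, tree2, weighted = TRUE)["s1", "s2"], 0)

  set.seed(41)
  for (rep in 1:25) {
    k <- sample(3:6, 1)
    tree <- ape::rtree(k)
    counts <- toy_counts(matrix(rpois(2 * k, 5), nrow = k))
    counts[sample(k, 1), 1] <- counts[sample(k, 1), 1] + 1  # keep totals > 0
    rownames(counts) <- tree$tip.label
    p <- sweep(counts, 2, colSums(counts), "/")
    for (w in c(TRUE, FALSE)) {
      got <- unifrac_distance(counts, tree, weighted = w)["s1", "s2"]
      want <- brute_unifrac(tree, p[, 1], p[, 2], weighted = w)
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
  bad <- toy_counts(matrix(5, 2, 2)); rownames(bad) <- c("a", "zz")
  expect_error(unifrac_distance(bad, tree2), "zz")
})

test_that("group screening delegates to Kruskal-Wallis and detects planted alpha shifts", {
  set.seed(3)
  vals <- stats::setNames(rnorm(30), paste0("s", 1:30))
  grp <- stats::setNames(rep(c("A", "B", "C"), each = 10), names(vals))
  direct <- kruskal_wallis(split(unname(vals), grp[names(vals)]))
  expect_equal(group_difference_test(vals, grp)$statistic, direct$statistic)

  hits <- 0
  for (rep in 1:50) {
    # one arm spread over e^0.5-fold more taxa: Shannon shifted by ~0.5 nats
    a <- replicate(20, {
      x <- rmultinom(1, 5000, rep(1 / 20, 20))
      -sum((x / 5000)[x > 0] * log((x / 5000)[x > 0]))
    })
    b <- replicate(20, {
      x <- rmultinom(1, 5000, rep(1 / 33, 33))
      -sum((x / 5000)[x > 0] * log((x / 5000)[x > 0]))
    })
    vals <- stats::setNames(c(a, b), paste0("s", 1:40))
    grp <- stats::setNames(rep(c("A", "B"), each = 20), names(vals))
    if (group_difference_test(vals, grp)$p_value < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 50, 0.9)
})

test_that("CLR output is centered and matches the two-part example", {
  expect_equal(clr_transform(rep(0.25, 4), pseudocount = 0), rep(0, 4))
  expect_equal(clr_transform(c(1, 3), pseudocount = 0),
               c(-0.5493, 0.5493), tolerance = 1e-4)
  set.seed(9)
  for (rep in 1:10) {
    v <- rpois(12, 20)
    expect_equal(sum(clr_transform(v)), 0, tolerance = 1e-12)
  }
  expect_error(clr_transform(c(0, 1), pseudocount = 0), "pseudocount")
})

test_that("PCA ordination separates constructed clusters and reports variance fractions", {
  set.seed(13)
  base <- matrix(rnorm(40 * 6, sd = 0.05), 40, 6)
  base[1:20, 1] <- base[1:20, 1] + 5      # separation along one direction
  clr <- t(apply(base, 1, function(r) r - mean(r)))
  groups <- rep(c("T", "C"), each = 20)
  ord <- pca_ordination(clr, groups)
  expect_gt(ord$variance_fraction[1], 0.99)
  expect_lt(ord$axis_tests$p_adjusted[1], 0.05)
  expect_equal(sum(ord$variance_fraction), 1, tolerance = 1e-12)
  expect_true(all(diff(ord$variance_fraction) <= 1e-12))
  # sign flip of an axis leaves the tests unchanged
  ord2 <- pca_ordination(-clr, groups)
  expect_equal(ord$axis_tests$p, ord2$axis_tests$p, tolerance = 1e-9)
})
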