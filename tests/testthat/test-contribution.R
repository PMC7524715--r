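toy_ko_counts <- function() {
  counts <- matrix(
    c(3, 4, 2,   # gene1 (KO1, product)
      5, 1, 2,   # gene2 (KO1, resident)
      9, 9, 9,   # gene3 (KO2, product)
      0, 0, 0,   # gene4 (KO3, resident) -> KO3 all-zero, dropped
      7, 2, 1),  # gene5 (no KO, resident)
    nrow = 5, byrow = TRUE,
    dimnames = list(paste0("gene", 1:5), paste0("s", 1:3))
  )
  annotation <- data.frame(
    gene_id = paste0("gene", 1:5),
    ko_id = c("KO1", "KO1", "KO2", "KO3", NA),
    source = c("product_strain", "resident", "product_strain", "resident", "resident"),
    msp_id = c(NA, "MSPa", NA, "MSPa", "MSPb"),
    stringsAsFactors = FALSE
  )
  list(counts = counts, annotation = annotation)
}

test_that("KO aggregation sums totals and product-attributed counts separately", {
  d <- toy_ko_counts()
  agg <- aggregate_to_ko(d$counts, d$annotation)
  expect_equal(agg$total["KO1", ], c(s1 = 8, s2 = 5, s3 = 4))
  expect_equal(agg$product["KO1", ], c(s1 = 3, s2 = 4, s3 = 2))
  expect_equal(agg$product["KO2", ], agg$total["KO2", ])
  expect_true(all(agg$product <= agg$total))
  expect_equal(agg$unassigned_genes, "gene5")
  # permuting gene order changes nothing
  perm <- sample(nrow(d$counts))
  agg2 <- aggregate_to_ko(d$counts[perm, ], d$annotation)
  expect_equal(agg$total, agg2$total)
  expect_equal(agg$product, agg2$product)
  # a matrix with no product genes attributes nothing
  ann0 <- d$annotation; ann0$source <- "resident"
  expect_true(all(aggregate_to_ko(d$counts, ann0)$product == 0))
})

test_that("contribution scores are the pseudocounted count ratio", {
  d <- toy_ko_counts()
  agg <- aggregate_to_ko(d$counts, d$annotation)
  sc <- contribution_scores(agg)
  # product 3, total 8, pc 1 -> 4/9 in s1; summarized = mean over samples
  per <- attr(sc, "per_sample")
  expect_equal(per["KO1", "s1"], 4 / 9)
  expect_equal(per["KO2", "s1"], 1)          # product == total
  expect_equal(sc$score[sc$ko == "KO2"], 1)
  expect_false("KO3" %in% sc$ko)             # zero-total KO dropped...
  expect_equal(attr(sc, "dropped"), "KO3")   # ...and reported
  expect_true(all(sc$score > 0 & sc$score <= 1))
  expect_error(contribution_scores(agg, pseudocount = -1), "positive")

  # direct arithmetic checks of the ratio form
  one <- structure(list(
    total = matrix(c(10, 99), 2, 1, dimnames = list(c("a", "b"), "s")),
    product = matrix(c(9, 0), 2, 1, dimnames = list(c("a", "b"), "s")),
    unassigned_genes = character(0)
  ), class = "ko_counts")
  sc1 <- contribution_scores(one)
  expect_equal(sc1$score[sc1$ko == "a"], 10 / 11)
  expect_equal(sc1$score[sc1$ko == "b"], 0.01)
})

test_that("score monotonicity in the attributed count", {
  base <- structure(list(
    total = matrix(100, 1, 1, dimnames = list("k", "s")),
    product = matrix(10, 1, 1, dimnames = list("k", "s")),
    unassigned_genes = character(0)
  ), class = "ko_counts")
  s_lo <- contribution_scores(base)$score
  base$product[1, 1] <- 60
  expect_gt(contribution_scores(base)$score, s_lo)
})

test_that("marker baseline summarizes marker scores and flags missing markers", {
  sc <- data.frame(ko = c("m1", "m2", "m3", "x"),
                   score = c(0.04, 0.05, 0.06, 0.9))
  expect_equal(marker_baseline(sc, c("m1", "m2", "m3"))$baseline, 0.05)
  expect_equal(marker_baseline(sc, c("m1", "m2", "m3"), "max")$baseline, 0.06)
  expect_equal(marker_baseline(sc, c("m1", "m2", "m3"), "mean")$baseline, 0.05)
  flat <- data.frame(ko = c("m1", "m2"), score = c(0.05, 0.05))
  for (s in c("median", "mean", "max")) {
    expect_equal(marker_baseline(flat, c("m1", "m2"), s)$baseline, 0.05)
  }
  expect_error(marker_baseline(sc, c("m1", "zz")), "zz")
})

test_that("the contributive set uses a strict threshold", {
  sc <- data.frame(ko = c("A", "B", "C"), score = c(0.9, 0.05, 0.04))
  expect_equal(contributive_set(sc, 0.05), "A")
  all_eq <- data.frame(ko = c("A", "B"), score = c(0.05, 0.05))
  expect_length(contributive_set(all_eq, 0.05), 0)
})

test_that("shared-KO counts equal brute-force set intersections", {
  expect_equal(unname(msp_shared_ko_counts(list(m = c("k9")), c("k1", "k2"))), 0L)
  expect_equal(unname(msp_shared_ko_counts(list(m = paste0("k", 1:5)),
                                           c("k1", "k2"))), 2L)
  set.seed(6)
  contrib <- paste0("k", sample(100, 30))
  sets <- lapply(1:10, function(i) paste0("k", sample(100, sample(5:40, 1))))
  names(sets) <- paste0("MSP", 1:10)
  got <- msp_shared_ko_counts(sets, contrib)
  want <- vapply(sets, function(s) sum(unique(s) %in% contrib), 0L)
  expect_equal(got, want)
  expect_error(msp_shared_ko_counts(sets, character(0)), "empty")
})
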