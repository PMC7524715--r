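small_cfg <- function(seed = 1, ...) {
  synth_config(seed = seed, n_subjects_per_arm = 12L, n_taxa = 20L,
               n_consumption_taxa = 2L, n_dose_taxa = 2L, n_both_taxa = 2L, ...)
}

test_that("generators are pure functions of (config, seed)", {
  cfg <- small_cfg(seed = 7)
  expect_identical(gen_cohort_counts(cfg), gen_cohort_counts(cfg))
  expect_identical(gen_metagenome(synth_config(seed = 7, n_kos = 100,
                                               n_planted_kos = 30)),
                   gen_metagenome(synth_config(seed = 7, n_kos = 100,
                                               n_planted_kos = 30)))
  expect_identical(gen_network_data(synth_config(seed = 7, n_msps = 10,
                                                 n_network_samples = 50)),
                   gen_network_data(synth_config(seed = 7, n_msps = 10,
                                                 n_network_samples = 50)))
  expect_identical(gen_ae_table(cfg), gen_ae_table(cfg))
  # a different seed changes the draw
  expect_false(identical(gen_cohort_counts(cfg),
                         gen_cohort_counts(small_cfg(seed = 8))))
})

test_that("invalid configuration fields are rejected by name", {
  expect_error(synth_config(zero_inflation_base = 1.4), "zero_inflation_base")
  expect_error(synth_config(strain_share = 1), "strain_share")
  expect_error(synth_config(n_kos = 20, n_marker_kos = 31), "n_marker_kos")
  expect_error(synth_config(beta_precision = -1), "beta_precision")
  expect_error(synth_config(n_msps = 5,
                            precision_graph = data.frame(from = 1, to = 9,
                                                         pcor = 0.3)),
               "precision_graph")
})

test_that("null planted effects leave arm means indistinguishable at D28", {
  diffs <- sapply(1:50, function(r) {
    cfg <- small_cfg(seed = 300 + r, consumption_effect_logit = 0,
                     dose_effect_logit = 0, presence_effect = 0)
    out <- gen_cohort_counts(cfg)
    rel <- sweep(out$counts, 2, colSums(out$counts), "/")
    md <- out$metadata
    at <- function(arm) mean(rel[, md$arm == arm & md$visit == "D28"])
    at("Test3") - at("Control3")
  })
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * se + 1e-9)
})

test_that("without zero inflation or random effects the table has almost no zeros", {
  cfg <- small_cfg(seed = 5, zero_inflation_base = 0,
                   random_intercept_sd_presence = 0,
                   random_intercept_sd_abundance = 0)
  out <- gen_cohort_counts(cfg)
  expect_lt(mean(out$counts == 0), 0.01)
})

test_that("metagenome attribution respects the subset and strain-share structure", {
  cfg0 <- synth_config(seed = 2, strain_share = 0, n_kos = 150,
                       n_planted_kos = 40, n_resident_genomes = 10,
                       n_metagenome_samples = 4, library_size_metagenome = 1e5)
  mg0 <- gen_metagenome(cfg0)
  agg0 <- aggregate_to_ko(mg0$counts, mg0$annotation)
  expect_true(all(agg0$product == 0))

  cfg <- synth_config(seed = 3, n_kos = 150, n_planted_kos = 40,
                      n_resident_genomes = 10, n_metagenome_samples = 4,
                      library_size_metagenome = 1e5)
  mg <- gen_metagenome(cfg)
  agg <- aggregate_to_ko(mg$counts, mg$annotation)
  expect_true(all(agg$product <= agg$total))
  # every genome carries every marker exactly once
  ann <- mg$annotation
  for (k in mg$markers[1:3]) {
    expect_equal(sum(ann$ko_id == k),
                 cfg$n_resident_genomes + 2L)
  }
})

test_that("logistic-normal samples reflect the configured precision graph", {
  # identity precision: the CLR covariance is I - J/p, so every off-diagonal
  # concentrates at -1/p (within sampling error) and is small in magnitude
  p <- 40
  cfg <- synth_config(seed = 4, n_msps = p, n_network_samples = 1000,
                      precision_graph = data.frame(from = integer(0),
                                                   to = integer(0),
                                                   pcor = numeric(0)))
  nd <- gen_network_data(cfg)
  clr <- t(strainshare:::clr_matrix(nd$counts))
  cv <- cov(clr)
  off <- cv[upper.tri(cv)]
  expect_lt(max(abs(off + 1 / p)), 4.5 / sqrt(1000))
  expect_lt(mean(abs(off)), 0.1)

  # chain with negative partial correlations: empirical precision recovers signs
  ok <- 0
  for (rep in 1:20) {
    cfg <- synth_config(seed = 100 + rep, n_msps = 3, n_network_samples = 500,
                        precision_graph = data.frame(from = c(1, 2),
                                                     to = c(2, 3),
                                                     pcor = c(-0.3, -0.3)))
    nd <- gen_network_data(cfg)
    z <- log(nd$counts + 1)
    om <- solve(cov(t(z)))
    pcor12 <- -om[1, 2] / sqrt(om[1, 1] * om[2, 2])
    pcor23 <- -om[2, 3] / sqrt(om[2, 2] * om[3, 3])
    if (pcor12 < 0 && pcor23 < 0) ok <- ok + 1
  }
  expect_gte(ok / 20, 0.95)
})

test_that("adverse-event draws hit their boundary cases and are unbiased", {
  cfg <- small_cfg(seed = 1, ae_risk_test = 0, ae_risk_control = 0)
  ae <- gen_ae_table(cfg)
  expect_equal(c(ae$events_test, ae$events_control), c(0, 0))
  cfg <- small_cfg(seed = 1, ae_risk_test = 1, ae_risk_control = 1)
  ae <- gen_ae_table(cfg)
  expect_equal(ae$events_test, ae$n_test)
  expect_equal(ae$events_control, ae$n_control)

  rrs <- sapply(1:200, function(r) {
    ae <- gen_ae_table(synth_config(seed = 5000 + r))
    res <- relative_risk_ci(ae$events_test, ae$n_test,
                            ae$events_control, ae$n_control)
    if (res$defined) res$rr else NA
  })
  expect_true(mean(rrs, na.rm = TRUE) > 0.9 && mean(rrs, na.rm = TRUE) < 1.1)
})
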