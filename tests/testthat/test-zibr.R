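test_that("fixed-effect fit matches an independent beta-regression oracle", {
  set.seed(21)
  n <- 200
  X <- cbind(intercept = 1, x = rbinom(n, 1, 0.5))
  mu <- plogis(-2 + 0.8 * X[, 2])
  y <- rbeta(n, mu * 25, (1 - mu) * 25)
  subject <- rep(1:50, each = 4)
  fit <- fit_zibr(y, X, subject, no_random = TRUE)
  oracle <- oracle_beta_reg(y, X)
  expect_equal(unname(fit$beta$coefficients), unname(oracle$coefficients),
               tolerance = 1e-4)
  expect_equal(fit$beta$phi, oracle$phi, tolerance = 1e-4)
  expect_equal(fit$beta$loglik, oracle$loglik, tolerance = 1e-6)
})

test_that("mixed-model parts agree with lme4 and glmmTMB reference fits", {
  skip_if_not_installed("lme4")
  skip_if_not_installed("glmmTMB")
  set.seed(77)
  d <- sim_zibr_genus(n_subjects = 40, consumption_effect = 0.8)
  fit <- fit_zibr(d$y, d$X, d$subject)

  zl <- data.frame(z = as.numeric(d$y > 0), cons = d$X[, 2], dose = d$X[, 3],
                   subj = factor(d$subject))
  ref <- lme4::glmer(z ~ cons + dose + (1 | subj), family = binomial,
                     data = zl, nAGQ = 10)
  expect_equal(unname(fit$logistic$coefficients), unname(lme4::fixef(ref)),
               tolerance = 1e-3)
  expect_equal(fit$logistic$loglik, as.numeric(stats::logLik(ref)),
               tolerance = 1e-4)

  nz <- d$y > 0
  db <- data.frame(y = d$y[nz], cons = d$X[nz, 2], dose = d$X[nz, 3],
                   subj = factor(d$subject[nz]))
  tmb <- glmmTMB::glmmTMB(y ~ cons + dose + (1 | subj),
                          family = glmmTMB::beta_family(), data = db)
  expect_equal(unname(fit$beta$coefficients),
               unname(glmmTMB::fixef(tmb)$cond), tolerance = 0.02)
  # adaptive quadrature must do at least as well as the Laplace approximation
  expect_gte(fit$beta$loglik, as.numeric(stats::logLik(tmb)) - 1e-3)
})

test_that("quadrature order is converged at the default and fits are order invariant", {
  set.seed(31)
  d <- sim_zibr_genus(n_subjects = 30, consumption_effect = 0.5)
  f10 <- fit_zibr(d$y, d$X, d$subject, quad_order = 10)
  f20 <- fit_zibr(d$y, d$X, d$subject, quad_order = 20)
  expect_lt(abs(f10$loglik - f20$loglik), 1e-3)

  perm <- sample(length(d$y))
  fp <- fit_zibr(d$y[perm], d$X[perm, ], d$subject[perm])
  expect_equal(fp$loglik, f10$loglik, tolerance = 1e-6)
  relab <- match(d$subject, sample(unique(d$subject)))
  fr <- fit_zibr(d$y, d$X, relab)
  expect_equal(fr$loglik, f10$loglik, tolerance = 1e-6)
})

test_that("degenerate inputs are flagged or rejected", {
  X <- cbind(intercept = rep(1, 8))
  expect_error(fit_zibr(rep(0, 8), X, rep(1:4, 2)), "degenerate")
  f <- fit_zibr(rep(c(0.2, 0.4), 4), X, rep(1:4, 2))
  expect_true(f$logistic_skipped)
  expect_error(fit_zibr(rep(c(0.2, 1), 4), X, rep(1:4, 2)), "\\[0, 1\\)")
})

test_that("joint LRT behaves at the boundaries", {
  set.seed(10)
  d <- sim_zibr_genus(n_subjects = 24)
  f <- fit_zibr(d$y, d$X, d$subject)
  expect_equal(lrt_joint(f, f, df = 2), 1)
  fake <- f; fake$loglik <- f$loglik + 1
  expect_error(lrt_joint(f, fake, df = 2), "lower likelihood")
})

test_that("response classification follows the adjusted p values", {
  res <- data.frame(p_consumption_adj = c(0.01, 0.01, 0.6, 0.2),
                    p_dose_adj = c(0.2, 0.01, 0.6, 0.01))
  expect_equal(classify_responses(res),
               c("consumption", "both", "none", "dose"))
})

test_that("the genus screen recovers planted response classes", {
  cfg <- synth_config(seed = 42, n_taxa = 20L,
                      n_consumption_taxa = 3L, n_dose_taxa = 3L, n_both_taxa = 3L)
  out <- gen_cohort_counts(cfg)
  scr <- screen_genera(out$counts, out$metadata)
  truth <- out$ground_truth$class[scr$results$genus]
  planted <- truth != "background"
  acc <- mean(scr$results$class[planted] == truth[planted])
  expect_gte(acc, 0.8)
  # low-prevalence genera are reported, not silently dropped
  counts2 <- out$counts
  counts2[1, ] <- 0L
  counts2[1, 1] <- 1L
  scr2 <- screen_genera(counts2[c(1, 5:12, nrow(counts2)), ], out$metadata)
  expect_true(rownames(counts2)[1] %in% scr2$excluded)
})
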