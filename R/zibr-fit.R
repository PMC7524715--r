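# Two-part zero-inflated beta regression with subject random intercepts
# (ZIBR). The presence part is a mixed logistic model on all observations;
# the abundance part is a mixed beta regression (mean mu with logit link,
# precision phi) on the nonzero observations. The parts are fit independently
# by maximum likelihood, integrating each subject's random intercept with
# adaptive Gauss-Hermite quadrature centered at the empirical Bayes mode.

gh_nodes <- function(order) {
  gh <- pracma::gaussHermite(order)
  list(x = gh$x, logw = log(gh$w))
}

# Minimize from several starts, polishing the winner with restarts until the
# objective stops improving; guards against local optima in the marginal
# likelihood surface.
multistart_nlminb <- function(starts, obj, control) {
  best <- NULL
  for (s in starts) {
    opt <- stats::nlminb(s, obj, control = control)
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  for (k in 1:3) {
    again <- stats::nlminb(best$par, obj, control = control)
    if (again$objective < best$objective - 1e-10) best <- again else break
  }
  best
}

# Marginal log-likelihood of one part. `ll_eta` returns the per-observation
# log-likelihood at linear predictor eta; `d1_eta`/`d2_eta` its first and
# second derivatives. All are vectorized. `subject` is an integer index 1..S.
part_loglik <- function(theta_fixed, log_sigma, X, subject, S, gh,
                        ll_eta, d1_eta, d2_eta) {
  sigma <- exp(log_sigma)
  eta_fix <- drop(X %*% theta_fixed)
  inv_s2 <- 1 / max(sigma^2, 1e-12)

  # Newton iterations for the per-subject posterior mode b-hat (vectorized
  # across subjects via rowsum).
  b <- numeric(S)
  for (it in 1:25) {
    eta <- eta_fix + b[subject]
    g1 <- drop(rowsum(d1_eta(eta), subject, reorder = TRUE)) - b * inv_s2
    g2 <- drop(rowsum(d2_eta(eta), subject, reorder = TRUE)) - inv_s2
    if (!all(is.finite(g1)) || !all(is.finite(g2))) return(-Inf)
    step <- g1 / g2
    step <- pmax(pmin(step, 4), -4)
    b <- b - step
    if (max(abs(g1)) < 1e-9) break
  }
  eta <- eta_fix + b[subject]
  curv <- -(drop(rowsum(d2_eta(eta), subject, reorder = TRUE)) - inv_s2)
  tau <- 1 / sqrt(pmax(curv, 1e-12))

  # Adaptive GH: nodes b_iq = b_i + sqrt(2) tau_i x_q, integrand
  # exp(l_i(b) - b^2/(2 sigma^2)) / (sqrt(2 pi) sigma).
  Bq <- outer(b, rep(1, length(gh$x))) +
    sqrt(2) * outer(tau, gh$x)                      # S x Q
  eta_q <- eta_fix + Bq[subject, , drop = FALSE]    # n_obs x Q
  ll_q <- rowsum(ll_eta(eta_q), subject, reorder = TRUE)  # S x Q
  log_integrand <- ll_q - Bq^2 * (inv_s2 / 2) +
    matrix(gh$logw + gh$x^2, nrow = S, ncol = length(gh$x), byrow = TRUE)
  m <- apply(log_integrand, 1, max)
  li <- m + log(rowSums(exp(log_integrand - m))) +
    log(sqrt(2) * tau) - log(sqrt(2 * pi) * sigma)
  sum(li)
}

logistic_terms <- function(z) {
  list(
    ll = function(eta) z * eta - log1p(exp(eta)),
    d1 = function(eta) z - stats::plogis(eta),
    d2 = function(eta) { mu <- stats::plogis(eta); -mu * (1 - mu) }
  )
}

# Beta log-likelihood in the (mu, phi) parameterization at logit(mu) = eta.
beta_terms <- function(y, log_phi) {
  phi <- exp(log_phi)
  ly <- log(y); l1y <- log1p(-y); lodds <- ly - l1y
  list(
    ll = function(eta) {
      mu <- stats::plogis(eta)
      a <- mu * phi; c <- (1 - mu) * phi
      lgamma(phi) - lgamma(a) - lgamma(c) + (a - 1) * ly + (c - 1) * l1y
    },
    d1 = function(eta) {
      mu <- stats::plogis(eta)
      a <- mu * phi; c <- (1 - mu) * phi
      phi * mu * (1 - mu) * (lodds - digamma(a) + digamma(c))
    },
    d2 = function(eta) {
      mu <- stats::plogis(eta)
      m <- mu * (1 - mu)
      a <- mu * phi; c <- (1 - mu) * phi
      tt <- lodds - digamma(a) + digamma(c)
      phi * m * (1 - 2 * mu) * tt - phi^2 * m^2 * (trigamma(a) + trigamma(c))
    }
  )
}

# Build a start vector for a part from a previously fitted part with
# (possibly) different covariates: matched coefficients carry over, new ones
# start at zero, and the dispersion/variance parameters carry over.
carry_start <- function(part, colnames_new, extra) {
  coefs <- stats::setNames(rep(0, length(colnames_new)), colnames_new)
  shared <- intersect(names(part$coefficients), colnames_new)
  coefs[shared] <- part$coefficients[shared]
  c(unname(coefs), extra)
}

fit_part_logistic <- function(z, X, subject, quad_order, control,
                              no_random = FALSE, warm = NULL) {
  S <- length(unique(subject))
  subject <- as.integer(factor(subject))
  gh <- gh_nodes(quad_order)
  start_fix <- tryCatch(
    stats::glm.fit(X, z, family = stats::binomial())$coefficients,
    error = function(e) rep(0, ncol(X))
  )
  start_fix[!is.finite(start_fix)] <- 0
  terms <- logistic_terms(z)
  obj <- if (no_random) {
    function(par) {
      v <- -sum(terms$ll(drop(X %*% par)))
      if (!is.finite(v)) 1e10 else v
    }
  } else {
    function(par) {
      v <- -part_loglik(par[seq_len(ncol(X))], par[ncol(X) + 1L], X, subject, S, gh,
                        terms$ll, terms$d1, terms$d2)
      if (!is.finite(v)) 1e10 else v
    }
  }
  starts <- if (no_random) {
    list(start_fix)
  } else {
    list(c(start_fix, log(0.5)), c(start_fix, log(0.1)))
  }
  if (!is.null(warm) && !no_random) {
    starts <- c(starts, list(carry_start(warm, colnames(X),
                                         log(max(warm$sigma, 1e-3)))))
  }
  opt <- multistart_nlminb(starts, obj, control)
  list(
    coefficients = stats::setNames(opt$par[seq_len(ncol(X))], colnames(X)),
    sigma = if (no_random) 0 else exp(opt$par[ncol(X) + 1L]),
    loglik = -opt$objective,
    converged = opt$convergence == 0,
    par = opt$par,
    objective = obj
  )
}

fit_part_beta <- function(y, X, subject, quad_order, control,
                          no_random = FALSE, warm = NULL) {
  S <- length(unique(subject))
  subject <- as.integer(factor(subject))
  gh <- gh_nodes(quad_order)
  # moment start: regress logit(y) for the mean; phi from the residual scale
  ly <- stats::qlogis(pmin(pmax(y, 1e-10), 1 - 1e-10))
  start_fix <- tryCatch(stats::lm.fit(X, ly)$coefficients,
                        error = function(e) rep(0, ncol(X)))
  start_fix[!is.finite(start_fix)] <- 0
  mu0 <- mean(y); v0 <- stats::var(y)
  phi0 <- if (is.finite(v0) && v0 > 0) max(mu0 * (1 - mu0) / v0 - 1, 2) else 10
  p <- ncol(X)
  obj <- if (no_random) {
    function(par) {
      terms <- beta_terms(y, par[p + 1L])
      v <- -sum(terms$ll(drop(X %*% par[seq_len(p)])))
      if (!is.finite(v)) 1e10 else v
    }
  } else {
    function(par) {
      terms <- beta_terms(y, par[p + 1L])
      v <- -part_loglik(par[seq_len(p)], par[p + 2L], X, subject, S, gh,
                        terms$ll, terms$d1, terms$d2)
      if (!is.finite(v)) 1e10 else v
    }
  }
  starts <- if (no_random) {
    list(c(start_fix, log(phi0)))
  } else {
    list(c(start_fix, log(phi0), log(0.5)),
         c(start_fix, log(phi0), log(0.1)))
  }
  if (!is.null(warm) && !no_random) {
    starts <- c(starts, list(carry_start(warm, colnames(X),
                                         c(log(warm$phi),
                                           log(max(warm$sigma, 1e-3))))))
  }
  opt <- multistart_nlminb(starts, obj, control)
  list(
    coefficients = stats::setNames(opt$par[seq_len(p)], colnames(X)),
    phi = exp(opt$par[p + 1L]),
    sigma = if (no_random) 0 else exp(opt$par[p + 2L]),
    loglik = -opt$objective,
    converged = opt$convergence == 0,
    par = opt$par,
    objective = obj
  )
}

#' Fit a two-part zero-inflated beta mixed regression
#'
#' Presence (y > 0) is modeled as mixed logistic regression over all
#' observations; the conditional abundance as mixed beta regression (logit
#' mean, precision phi) over the nonzero observations. Each part carries a
#' subject random intercept integrated out by adaptive Gauss-Hermite
#' quadrature; the parts are fit independently and their log-likelihoods add.
#'
#' @param y Relative abundances in \[0, 1): zeros allowed, ones not.
#' @param X Design matrix (one row per observation); include an intercept
#'   column.
#' @param subject Subject identifier per observation.
#' @param quad_order Number of quadrature nodes (default 10).
#' @param se Compute standard errors of the beta-part coefficients from the
#'   numerical Hessian (default FALSE; used for effect-recovery intervals).
#' @param no_random Fix both random-intercept SDs at zero (plain fixed-effect
#'   two-part fit, no quadrature).
#' @param start_from Optional `zibr_fit` on the same data with a covariate
#'   subset or superset; its solution is added to the optimizer's start set
#'   (used to keep nested fits on the same likelihood branch).
#' @param control Passed to [stats::nlminb()].
#' @return A `zibr_fit` list: `logistic` and `beta` part fits (`coefficients`,
#'   `sigma`, `phi`, `loglik`, `converged`), total `loglik`, `logistic_skipped`
#'   flag (no zero observations), `quad_order`.
#' @export
fit_zibr <- function(y, X, subject, quad_order = 10L, se = FALSE,
                     no_random = FALSE, start_from = NULL,
                     control = list(rel.tol = 1e-10)) {
  if (any(y < 0 | y >= 1)) stop("y must lie in [0, 1)")
  if (!is.matrix(X)) X <- as.matrix(X)
  if (nrow(X) != length(y) || length(subject) != length(y)) {
    stop("y, X and subject must agree in length")
  }
  nz <- y > 0
  if (!any(nz)) stop("degenerate: no nonzero observations")
  logistic_skipped <- all(nz)
  logistic <- NULL
  warm_log <- if (!is.null(start_from)) start_from$logistic else NULL
  warm_beta <- if (!is.null(start_from)) start_from$beta else NULL
  if (!logistic_skipped) {
    logistic <- fit_part_logistic(as.numeric(nz), X, subject, quad_order,
                                  control, no_random = no_random,
                                  warm = warm_log)
  }
  beta <- fit_part_beta(y[nz], X[nz, , drop = FALSE], subject[nz],
                        quad_order, control, no_random = no_random,
                        warm = warm_beta)
  if (se) {
    H <- stats::optimHess(beta$par, beta$objective)
    V <- tryCatch(solve(H), error = function(e) matrix(NA_real_, nrow(H), ncol(H)))
    beta$se <- sqrt(pmax(diag(V)[seq_len(ncol(X))], 0))
    names(beta$se) <- colnames(X)
  }
  total <- beta$loglik + if (logistic_skipped) 0 else logistic$loglik
  structure(
    list(
      logistic = logistic, beta = beta, loglik = total,
      logistic_skipped = logistic_skipped, quad_order = quad_order,
      converged = beta$converged &&
        (logistic_skipped || logistic$converged),
      n_obs = length(y), n_subjects = length(unique(subject))
    ),
    class = "zibr_fit"
  )
}

#' @export
print.zibr_fit <- function(x, ...) {
  cat(sprintf(
    "ZIBR fit: %d obs, %d subjects, loglik %.3f (%s)\n",
    x$n_obs, x$n_subjects, x$loglik,
    if (x$converged) "converged" else "NOT converged"
  ))
  if (!x$logistic_skipped) {
    cat("  presence part:  ",
        paste(sprintf("%s=%.3f", names(x$logistic$coefficients),
                      x$logistic$coefficients), collapse = ", "),
        sprintf(", sigma=%.3f\n", x$logistic$sigma))
  } else {
    cat("  presence part skipped (no zeros)\n")
  }
  cat("  abundance part: ",
      paste(sprintf("%s=%.3f", names(x$beta$coefficients),
                    x$beta$coefficients), collapse = ", "),
      sprintf(", phi=%.2f, sigma=%.3f\n", x$beta$phi, x$beta$sigma))
  invisible(x)
}

#' Joint test of one covariate via nested two-part fits
#'
#' Fits the full model and the model without `drop`, warm-starting the
#' reduced fit from the full solution (and refitting the full model from the
#' reduced solution in the rare case the optimizer left it on a worse
#' likelihood branch), then applies [lrt_joint()] with df = 2 (1 when the
#' presence part is skipped).
#'
#' @param y,X,subject,quad_order As in [fit_zibr()].
#' @param drop Name of the covariate column to test.
#' @return A list: `p`, `df`, `fit_full`, `fit_reduced`.
#' @export
zibr_lrt <- function(y, X, subject, drop, quad_order = 10L) {
  if (!drop %in% colnames(X)) stop("covariate to drop not found: ", drop)
  full <- fit_zibr(y, X, subject, quad_order = quad_order)
  Xr <- X[, setdiff(colnames(X), drop), drop = FALSE]
  reduced <- fit_zibr(y, Xr, subject, quad_order = quad_order,
                      start_from = full)
  if (full$loglik < reduced$loglik - 1e-8) {
    full <- fit_zibr(y, X, subject, quad_order = quad_order,
                     start_from = reduced)
  }
  df <- if (full$logistic_skipped) 1L else 2L
  list(p = lrt_joint(full, reduced, df = df), df = df,
       fit_full = full, fit_reduced = reduced)
}

#' Joint likelihood-ratio test between nested two-part fits
#'
#' Twice the log-likelihood difference referred to a chi-square with `df`
#' degrees of freedom, where `df` counts the coefficients dropped across both
#' parts (2 for a covariate present in both, 1 if the presence part was
#' skipped).
#'
#' @param fit_full,fit_reduced `zibr_fit` objects, reduced nested in full.
#' @param df Degrees of freedom of the test.
#' @return p value in \[0, 1\].
#' @export
lrt_joint <- function(fit_full, fit_reduced, df) {
  delta <- fit_full$loglik - fit_reduced$loglik
  if (delta < -1e-6) {
    stop("full fit has lower likelihood than reduced fit: non-nested or not converged")
  }
  delta <- max(delta, 0)
  min(1, max(0, stats::pchisq(2 * delta, df = df, lower.tail = FALSE)))
}
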