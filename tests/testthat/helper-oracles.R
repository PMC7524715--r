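# Independent brute-force oracles used across the suite. These deliberately
# share no code with the implementation paths they check.

# Exact two-sided Mann-Whitney p by full enumeration of all C(n1+n2, n1)
# labelings of the pooled sample.
enumerate_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  combs <- utils::combn(length(pooled), n1)
  us <- apply(combs, 2, u_of)
  mu <- n1 * (length(y)) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Brute-force UniFrac: for every edge, find its subtended tip set by walking
# each tip's path to the root, then apply the definitions directly.
brute_unifrac <- function(tree, pa, pb, weighted) {
  ntip <- length(tree$tip.label)
  parent_of <- integer(max(tree$edge))
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  tips_below <- function(node) {
    hits <- logical(ntip)
    for (tip in seq_len(ntip)) {
      v <- tip
      repeat {
        if (v == node) { hits[tip] <- TRUE; break }
        if (v == root) break
        v <- parent_of[v]
      }
    }
    tree$tip.label[hits]
  }
  num <- 0; den <- 0
  for (k in seq_len(nrow(tree$edge))) {
    b <- tree$edge.length[k]
    tips <- tips_below(tree$edge[k, 2])
    wa <- sum(pa[tips]); wb <- sum(pb[tips])
    if (weighted) {
      num <- num + b * abs(wa - wb)
      den <- den + b * (wa + wb)
    } else {
      num <- num + b * ((wa > 0) != (wb > 0))
      den <- den + b * ((wa > 0) || (wb > 0))
    }
  }
  if (den > 0) num / den else 0
}

brute_bray <- function(x, y) sum(abs(x - y)) / sum(x + y)

brute_jsd <- function(x, y) {
  x <- unname(x); y <- unname(y)
  m <- (x + y) / 2
  term <- function(a) {
    s <- 0
    for (i in seq_along(a)) if (a[i] > 0) s <- s + a[i] * log(a[i] / m[i])
    s
  }
  0.5 * term(x) + 0.5 * term(y)
}

# Brute-force hop distances: repeated boolean matrix products.
brute_hops <- function(adj, sources) {
  p <- nrow(adj)
  dist <- rep(Inf, p)
  dist[sources] <- 0
  reach <- sources
  step <- 0
  while (TRUE) {
    step <- step + 1
    nxt <- which(apply(adj[, reach, drop = FALSE] > 0, 1, any))
    nxt <- setdiff(nxt, which(is.finite(dist)))
    if (length(nxt) == 0) break
    dist[nxt] <- step
    reach <- union(reach, nxt)
  }
  dist
}

# Fixed-effect beta regression MLE (logit mean, log precision) by direct
# optimization of the beta likelihood; independent of the package fitter.
oracle_beta_reg <- function(y, X) {
  nll <- function(par) {
    mu <- stats::plogis(drop(X %*% par[seq_len(ncol(X))]))
    phi <- exp(par[ncol(X) + 1])
    -sum(stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
  }
  start <- c(stats::lm.fit(X, stats::qlogis(y))$coefficients, log(10))
  opt <- stats::optim(start, nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  list(coefficients = opt$par[seq_len(ncol(X))],
       phi = exp(opt$par[ncol(X) + 1]),
       loglik = -opt$value)
}

edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))

network_f1 <- function(net, true_edges) {
  est <- edge_key(net$edges$from, net$edges$to)
  tru <- edge_key(true_edges$from, true_edges$to)
  tp <- length(intersect(est, tru))
  if (length(est) + length(tru) == 0) return(1)
  2 * tp / (length(est) + length(tru))
}
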