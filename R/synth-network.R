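# Synthetic MSP abundances from a logistic-normal model with known sparse
# precision matrix, plus the adverse-event 2x2 generator.

# Assemble the precision matrix from the edge list of partial-correlation
# signs/magnitudes. Off-diagonals are -pcor (partial correlation rho_ij =
# -Omega_ij / sqrt(Omega_ii Omega_jj)); the diagonal is inflated to strict
# diagonal dominance, which guarantees positive definiteness.
precision_from_graph <- function(n, graph) {
  omega <- diag(n)
  for (k in seq_len(nrow(graph))) {
    i <- graph$from[k]; j <- graph$to[k]
    omega[i, j] <- omega[j, i] <- -graph$pcor[k]
  }
  rowsum_off <- rowSums(abs(omega)) - diag(omega)
  diag(omega) <- pmax(1, rowsum_off + 0.1)
  if (min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("precision graph does not yield a positive-definite matrix")
  }
  omega
}

#' Generate synthetic MSP abundances with a known co-abundance structure
#'
#' Samples latent log-abundances from a multivariate normal with the
#' configured sparse precision matrix, exponentiates and normalizes
#' (logistic-normal composition), and scales to counts by a multinomial draw
#' at `library_size_msp`. The first two MSPs are designated as the product
#' species nodes.
#'
#' @param config A [synth_config()].
#' @return A list: `counts` (MSP x sample), `product_nodes`, `ground_truth`
#'   (`precision`, `true_edges` data frame with partial-correlation signs).
#' @export
gen_network_data <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_substream(config$seed, "network", {
    p <- config$n_msps
    omega <- precision_from_graph(p, config$precision_graph)
    sigma <- solve(omega)
    ch <- chol(sigma)
    n <- config$n_network_samples
    z <- matrix(stats::rnorm(n * p), n, p) %*% ch
    w <- exp(z)
    comp <- w / rowSums(w)
    # first two nodes are the product species; the rest carry the resident
    # MSP ids used by the metagenome generator
    msps <- c("MSP_L_paracasei", "MSP_L_rhamnosus",
              sprintf("MSP%03d", seq_len(p - 2L)))
    counts <- matrix(0L, p, n, dimnames = list(msps, sprintf("ns_%03d", seq_len(n))))
    for (s in seq_len(n)) {
      counts[, s] <- stats::rmultinom(1, config$library_size_msp, comp[s, ])
    }
    true_edges <- data.frame(
      from = msps[config$precision_graph$from],
      to = msps[config$precision_graph$to],
      sign = ifelse(config$precision_graph$pcor > 0, "+", "-"),
      stringsAsFactors = FALSE
    )
    list(
      counts = counts,
      product_nodes = msps[1:2],
      ground_truth = list(precision = omega, true_edges = true_edges)
    )
  })
}

#' Generate a synthetic adverse-event 2x2 table
#'
#' Binomial draws of subjects-with-event per arm at the configured risks.
#'
#' @param config A [synth_config()].
#' @return A list with `events_test`, `n_test`, `events_control`, `n_control`.
#' @export
gen_ae_table <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_substream(config$seed, "ae", {
    n <- config$n_subjects_per_arm
    list(
      events_test = stats::rbinom(1, n, config$ae_risk_test),
      n_test = n,
      events_control = stats::rbinom(1, n, config$ae_risk_control),
      n_control = n
    )
  })
}
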