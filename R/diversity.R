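# Genus-level community analysis: alpha and beta diversity on relative
# abundances, group screening, and compositional (CLR) ordination.

#' Validate a taxon count table
#'
#' @param counts Numeric matrix, taxa as rows, samples as columns, nonnegative
#'   integers; every sample total must be positive.
#' @param metadata Optional data frame keyed by `sample` with `subject`, `arm`,
#'   `dose`, `visit` columns; must cover every sample.
#' @return The matrix, invisibly.
#' @export
validate_count_table <- function(counts, metadata = NULL) {
  if (!is.matrix(counts) || !is.numeric(counts)) stop("counts must be a numeric matrix")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers")
  }
  if (any(colSums(counts) == 0)) stop("every sample must have a positive total count")
  if (is.null(colnames(counts)) || is.null(rownames(counts))) {
    stop("counts must carry taxon rownames and sample colnames")
  }
  if (!is.null(metadata)) {
    needed <- c("sample", "subject", "arm", "dose", "visit")
    if (!all(needed %in% names(metadata))) {
      stop("metadata must contain columns ", paste(needed, collapse = ", "))
    }
    if (!all(colnames(counts) %in% metadata$sample)) {
      stop("metadata does not cover every sample")
    }
  }
  invisible(counts)
}

rel_abund <- function(counts) sweep(counts, 2, colSums(counts), "/")

#' Per-sample alpha diversity
#'
#' Computed on per-sample relative abundances: `observed` is the number of
#' taxa with nonzero count, `shannon` is entropy in nats, `simpson` is
#' \eqn{1 - \sum p_i^2}.
#'
#' @param counts Taxon count matrix (taxa x samples).
#' @param metric One of `"observed"`, `"shannon"`, `"simpson"`.
#' @return Named numeric vector, one value per sample.
#' @export
alpha_diversity <- function(counts, metric = c("observed", "shannon", "simpson")) {
  metric <- match.arg(metric)
  validate_count_table(counts)
  switch(metric,
    observed = colSums(counts > 0),
    shannon = vegan::diversity(t(counts), index = "shannon"),
    simpson = vegan::diversity(t(counts), index = "simpson")
  )
}

#' Pairwise beta-diversity matrix
#'
#' Bray-Curtis dissimilarity \eqn{\sum_i |x_i-y_i| / \sum_i (x_i+y_i)} or
#' Jensen-Shannon divergence (natural log, with the 0 log 0 = 0 convention),
#' both on per-sample relative abundances.
#'
#' @param counts Taxon count matrix (taxa x samples), >= 2 samples.
#' @param metric `"bray_curtis"` or `"jsd"`.
#' @return Symmetric distance matrix keyed by sample ids.
#' @export
beta_diversity_matrix <- function(counts, metric = c("bray_curtis", "jsd")) {
  metric <- match.arg(metric)
  validate_count_table(counts)
  if (ncol(counts) < 2L) stop("need at least 2 samples")
  p <- rel_abund(counts)
  if (metric == "bray_curtis") {
    d <- as.matrix(vegan::vegdist(t(p), method = "bray"))
  } else {
    n <- ncol(p)
    d <- matrix(0, n, n, dimnames = list(colnames(p), colnames(p)))
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d[i, j] <- d[j, i] <- jsd_pair(p[, i], p[, j])
      }
    }
  }
  d
}

# Jensen-Shannon divergence between two probability vectors, in nats.
jsd_pair <- function(x, y) {
  m <- (x + y) / 2
  kl <- function(a, b) {
    keep <- a > 0
    sum(a[keep] * log(a[keep] / b[keep]))
  }
  0.5 * kl(x, m) + 0.5 * kl(y, m)
}

#' Kruskal-Wallis screen of alpha or beta diversity across arms
#'
#' For per-sample alpha values, a Kruskal-Wallis test across groups. For a
#' beta-diversity matrix, each sample is first reduced to its median distance
#' to all other samples, and those scalars are compared across groups (a
#' per-sample summary compatible with a rank test).
#'
#' @param x Either a named numeric vector of per-sample values, or a square
#'   distance matrix keyed by sample ids.
#' @param grouping Named character vector (or factor) of group labels keyed by
#'   sample id.
#' @return A `ss_test` result.
#' @export
group_difference_test <- function(x, grouping) {
  if (is.matrix(x)) {
    if (nrow(x) != ncol(x)) stop("distance input must be square")
    vals <- vapply(seq_len(nrow(x)), function(i) stats::median(x[i, -i]), 0)
    names(vals) <- rownames(x)
  } else {
    vals <- x
  }
  g <- grouping[names(vals)]
  if (anyNA(g)) stop("grouping does not cover every sample")
  groups <- split(unname(vals), as.character(g))
  if (any(vapply(groups, length, 1L) < 2L)) {
    stop("every group needs at least 2 samples")
  }
  kruskal_wallis(groups)
}

#' Centered log-ratio transform
#'
#' \eqn{\mathrm{clr}(x)_i = \log(x_i + c) - \overline{\log(x + c)}} for
#' pseudocount c; the output sums to zero.
#'
#' @param x Nonnegative numeric vector with at least one positive entry.
#' @param pseudocount Added before taking logs (default 1 count); must be
#'   positive when zeros are present.
#' @return Numeric vector of the same length, summing to 0.
#' @export
clr_transform <- function(x, pseudocount = 1) {
  if (any(x < 0)) stop("input must be nonnegative")
  if (!any(x > 0)) stop("input must have at least one positive entry")
  if (pseudocount <= 0 && any(x == 0)) {
    stop("pseudocount must be positive when zeros are present")
  }
  lx <- log(x + pseudocount)
  lx - mean(lx)
}

#' PCA ordination of CLR-transformed data with per-axis group tests
#'
#' Centered principal component analysis (via singular value decomposition) of
#' a samples x features CLR matrix, followed by a two-sided Mann-Whitney test
#' of the two groups on every axis, Benjamini-Hochberg adjusted across axes.
#'
#' @param clr_matrix Samples x features numeric matrix (e.g. rows of
#'   [clr_transform()] output).
#' @param groups Character/factor vector of length nrow with exactly two
#'   levels.
#' @return A list: `scores` (samples x components), `variance_fraction`
#'   (nonincreasing, sums to 1 over all axes), `axis_tests` (data frame with
#'   per-axis p and adjusted p).
#' @export
pca_ordination <- function(clr_matrix, groups) {
  if (!is.matrix(clr_matrix) || nrow(clr_matrix) < 2L || ncol(clr_matrix) < 2L) {
    stop("need a matrix with >= 2 samples and >= 2 features")
  }
  if (all(apply(clr_matrix, 2, stats::sd) == 0)) stop("constant matrix")
  groups <- as.factor(groups)
  if (length(groups) != nrow(clr_matrix) || nlevels(groups) != 2L) {
    stop("groups must give exactly two levels over the samples")
  }
  pc <- stats::prcomp(clr_matrix, center = TRUE, scale. = FALSE)
  varfrac <- pc$sdev^2 / sum(pc$sdev^2)
  keep <- which(varfrac > 1e-12)
  tests <- lapply(keep, function(k) {
    sc <- pc$x[, k]
    tst <- mann_whitney_u(sc[groups == levels(groups)[1]],
                          sc[groups == levels(groups)[2]])
    data.frame(axis = k, variance_fraction = varfrac[k], p = tst$p_value)
  })
  tests <- do.call(rbind, tests)
  tests$p_adjusted <- bh_adjust(tests$p)
  list(scores = pc$x, variance_fraction = varfrac, axis_tests = tests)
}
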