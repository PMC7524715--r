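#' Two-sided Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples. The exact null distribution
#' (full enumeration over labelings) is used when both groups have at most
#' `exact_max` observations and there are no ties; otherwise the normal
#' approximation with mid-rank tie correction and continuity correction is
#' used, which is appropriate for trial arms of 20-25 subjects.
#'
#' @param x,y Numeric vectors of observations, each nonempty.
#' @param exact_max Largest per-group size for which the exact distribution is
#'   used (default 8).
#' @return A `ss_test` list: `statistic` (U for the first sample), `p_value`,
#'   `method`, `n_per_group`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$p_value  # 0.1
#' @export
mann_whitney_u <- function(x, y, exact_max = 8L) {
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be nonempty")
  x <- as.numeric(x); y <- as.numeric(y)
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported")
  if (length(unique(c(x, y))) == 1L) {
    # fully tied data: the two empirical distributions are identical
    return(new_test(length(x) * length(y) / 2, 1, "mann-whitney-degenerate",
                    c(length(x), length(y)), degenerate = TRUE))
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && length(x) <= exact_max && length(y) <= exact_max
  wt <- suppressWarnings(stats::wilcox.test(
    x, y,
    alternative = "two.sided", exact = exact, correct = TRUE
  ))
  new_test(
    statistic = unname(wt$statistic),
    p_value = min(1, unname(wt$p.value)),
    method = if (exact) "mann-whitney-exact" else "mann-whitney-normal",
    n_per_group = c(length(x), length(y))
  )
}

#' Kruskal-Wallis rank test across groups
#'
#' @param groups A list of two or more nonempty numeric vectors.
#' @return A `ss_test` list with the tie-corrected H statistic and the
#'   chi-square p value on k-1 degrees of freedom. When every observation is
#'   identical H is undefined; the result carries `degenerate = TRUE` and
#'   `p_value = 1`.
#' @examples
#' kruskal_wallis(list(1:3, 4:6, 7:9))$statistic  # 7.2
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) stop("need >= 2 groups")
  if (any(vapply(groups, length, 1L) == 0L)) stop("every group must be nonempty")
  values <- unlist(groups, use.names = FALSE)
  if (anyNA(values)) stop("missing values are not supported")
  n <- vapply(groups, length, 1L)
  if (length(unique(values)) == 1L) {
    return(new_test(NA_real_, 1, "kruskal-wallis", n, degenerate = TRUE))
  }
  g <- factor(rep(seq_along(groups), n))
  kt <- stats::kruskal.test(values, g)
  new_test(unname(kt$statistic), unname(kt$p.value), "kruskal-wallis", n)
}

#' Spearman rank correlation with t-approximation p value
#'
#' Rho is the Pearson correlation of mid-ranks (average ranks for ties); the
#' two-sided p value uses the t approximation on n-2 degrees of freedom.
#'
#' @param a,b Numeric vectors of equal length >= 3, neither constant.
#' @return A `ss_test` list with `statistic` = rho.
#' @export
spearman_correlation <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  n <- length(a)
  if (n < 3L) stop("need at least 3 paired observations")
  if (anyNA(a) || anyNA(b)) stop("missing values are not supported")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("spearman correlation undefined for a constant vector")
  }
  rho <- stats::cor(rank(a), rank(b))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  new_test(rho, p, "spearman", c(n, n))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; output order matches input order.
#'
#' @param p Numeric vector of p values in \[0, 1\].
#' @return Adjusted p values, elementwise >= `p`, capped at 1.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

new_test <- function(statistic, p_value, method, n_per_group, degenerate = FALSE) {
  structure(
    list(
      statistic = statistic, p_value = p_value, method = method,
      n_per_group = n_per_group, degenerate = degenerate
    ),
    class = "ss_test"
  )
}

#' @export
print.ss_test <- function(x, ...) {
  cat(sprintf(
    "%s: statistic = %s, p = %.4g (n = %s)\n",
    x$method, format(x$statistic, digits = 4), x$p_value,
    paste(x$n_per_group, collapse = "/")
  ))
  invisible(x)
}
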