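#' UniFrac distances on a rooted tree
#'
#' Phylogenetic beta diversity between all sample pairs of a taxon count
#' table, given a rooted tree with branch lengths whose tips cover every taxon
#' with nonzero counts. For each branch b with length \eqn{l_b}, let
#' \eqn{p^A_b} be the relative abundance a sample places on the leaves below
#' the branch. Then
#' \itemize{
#'   \item unweighted: \eqn{\sum_b l_b\,[\,\mathbf{1}(p^A_b>0) \ne
#'     \mathbf{1}(p^B_b>0)\,] \,/\, \sum_b l_b\,[\,p^A_b>0 \text{ or } p^B_b>0\,]}
#'   \item weighted (normalized): \eqn{\sum_b l_b |p^A_b - p^B_b| \,/\,
#'     \sum_b l_b (p^A_b + p^B_b)}
#' }
#'
#' @param counts Taxon count matrix (taxa x samples).
#' @param tree An [ape::phylo] rooted tree with branch lengths; tip labels
#'   must include every taxon with a nonzero count.
#' @param weighted Logical; abundance-weighted (normalized) variant when TRUE.
#' @return Symmetric distance matrix keyed by sample ids.
#' @export
unifrac_distance <- function(counts, tree, weighted = FALSE) {
  validate_count_table(counts)
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (is.null(tree$edge.length) || any(tree$edge.length < 0)) {
    stop("tree must carry nonnegative branch lengths")
  }
  present <- rownames(counts)[rowSums(counts) > 0]
  missing <- setdiff(present, tree$tip.label)
  if (length(missing) > 0L) {
    stop("taxa missing from the tree: ", paste(missing, collapse = ", "))
  }
  p <- rel_abund(counts)
  branch <- branch_abundance(tree, p)   # edges x samples matrix of p_b
  len <- tree$edge.length
  n <- ncol(p)
  d <- matrix(0, n, n, dimnames = list(colnames(p), colnames(p)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      pa <- branch[, i]; pb <- branch[, j]
      if (weighted) {
        num <- sum(len * abs(pa - pb))
        den <- sum(len * (pa + pb))
      } else {
        ha <- pa > 0; hb <- pb > 0
        num <- sum(len * (ha != hb))
        den <- sum(len * (ha | hb))
      }
      d[i, j] <- d[j, i] <- if (den > 0) num / den else 0
    }
  }
  d
}

# Relative abundance subtended by each edge of the tree, per sample: one
# postorder pass accumulating tip masses into internal nodes.
branch_abundance <- function(tree, p) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  mass <- matrix(0, nnode, ncol(p))
  idx <- match(tree$tip.label, rownames(p))
  has <- !is.na(idx)
  mass[seq_len(ntip)[has], ] <- p[idx[has], , drop = FALSE]
  ord <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[k, 1]; child <- ord$edge[k, 2]
    mass[parent, ] <- mass[parent, ] + mass[child, ]
  }
  # rows follow tree$edge order (the edge's subtended mass is its child's)
  mass[tree$edge[, 2], , drop = FALSE]
}
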