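# Functional contribution of product strains to the metagenome: KO
# aggregation, pseudocounted contribution scores, the universal-marker
# minimal-contribution baseline, and extraction of the contributive KO set.

#' Aggregate gene counts to KO-level attributed counts
#'
#' Sums gene counts per KO and per sample, once over all genes (`total`) and
#' once over product-strain genes only (`product`), so that
#' `product <= total` holds everywhere by construction. Genes without a KO
#' assignment are pooled in a reserved `"unassigned"` bucket and reported.
#'
#' @param counts Gene count matrix (gene x sample).
#' @param annotation Data frame with `gene_id`, `ko_id` (NA allowed),
#'   `source` in `{"product_strain", "resident"}`; must cover every gene in
#'   the matrix.
#' @return A `ko_counts` list: `total` and `product` (KO x sample matrices),
#'   `unassigned_genes`.
#' @export
aggregate_to_ko <- function(counts, annotation) {
  if (!is.matrix(counts)) stop("counts must be a matrix")
  if (!all(c("gene_id", "ko_id", "source") %in% names(annotation))) {
    stop("annotation needs columns gene_id, ko_id, source")
  }
  if (!all(rownames(counts) %in% annotation$gene_id)) {
    stop("annotation does not cover every gene in the matrix")
  }
  if (!all(annotation$source %in% c("product_strain", "resident"))) {
    stop("source must be 'product_strain' or 'resident'")
  }
  ann <- annotation[match(rownames(counts), annotation$gene_id), ]
  ko <- ifelse(is.na(ann$ko_id) | ann$ko_id == "", "unassigned", ann$ko_id)
  total <- rowsum(counts, ko, reorder = TRUE)
  is_prod <- ann$source == "product_strain"
  product <- matrix(0, nrow(total), ncol(total), dimnames = dimnames(total))
  if (any(is_prod)) {
    prod_sum <- rowsum(counts[is_prod, , drop = FALSE], ko[is_prod], reorder = TRUE)
    product[rownames(prod_sum), ] <- prod_sum
  }
  stopifnot(all(product <= total))
  structure(
    list(
      total = total, product = product,
      unassigned_genes = ann$gene_id[ko == "unassigned"]
    ),
    class = "ko_counts"
  )
}

#' Per-KO contribution scores of the product strains
#'
#' The contribution of the product strains to a KO in a sample is the
#' pseudocounted ratio of the strain-attributed count to the whole-metagenome
#' count, \eqn{(c_{product} + pc) / (c_{total} + pc)}, which lies in (0, 1].
#' Since both relative abundances share the whole-metagenome denominator, the
#' ratio of relative abundances reduces to this ratio of counts. The
#' summarized score is the mean over a designated sample set.
#'
#' @param ko_counts Output of [aggregate_to_ko()].
#' @param pseudocount Positive pseudocount added to both counts (default 1).
#' @param samples Sample ids to summarize over (default: all columns;
#'   typically the Test-arm consumption-period samples).
#' @return A data frame, one row per retained KO: `ko`, `score` (summarized),
#'   per-sample scores as attribute `"per_sample"`; KOs with zero total count
#'   everywhere are dropped and listed in attribute `"dropped"`. The
#'   `"unassigned"` bucket is kept out of the score table.
#' @export
contribution_scores <- function(ko_counts, pseudocount = 1, samples = NULL) {
  stopifnot(inherits(ko_counts, "ko_counts"))
  if (!is.numeric(pseudocount) || pseudocount <= 0) {
    stop("pseudocount must be positive")
  }
  total <- ko_counts$total; product <- ko_counts$product
  keep_ko <- setdiff(rownames(total)[rowSums(total) > 0], "unassigned")
  dropped <- setdiff(rownames(total), c(keep_ko, "unassigned"))
  if (is.null(samples)) samples <- colnames(total)
  if (!all(samples %in% colnames(total))) stop("unknown sample id(s)")
  per_sample <- (product[keep_ko, samples, drop = FALSE] + pseudocount) /
    (total[keep_ko, samples, drop = FALSE] + pseudocount)
  out <- data.frame(
    ko = keep_ko,
    score = rowMeans(per_sample),
    stringsAsFactors = FALSE
  )
  attr(out, "per_sample") <- per_sample
  attr(out, "dropped") <- dropped
  out
}

#' Minimal-contribution baseline from universal single-copy markers
#'
#' Universal single-copy marker KOs are carried once by every genome, so the
#' product strains' contribution to them estimates the strains' share of the
#' community — the contribution expected from strain abundance alone. The
#' baseline is a summary (median by default; max is the conservative choice)
#' of the summarized marker scores.
#'
#' @param scores Output of [contribution_scores()].
#' @param markers Character vector of marker KO ids; each must appear in the
#'   score table.
#' @param summary `"median"`, `"mean"`, or `"max"`.
#' @return A list: `baseline`, `summary`, `marker_scores` (named, for audit).
#' @export
marker_baseline <- function(scores, markers, summary = c("median", "mean", "max")) {
  summary <- match.arg(summary)
  missing <- setdiff(markers, scores$ko)
  if (length(missing) > 0L) {
    stop("marker KO(s) missing from the score table: ",
         paste(missing, collapse = ", "))
  }
  ms <- stats::setNames(scores$score[match(markers, scores$ko)], markers)
  baseline <- switch(summary,
    median = stats::median(ms),
    mean = mean(ms),
    max = max(ms)
  )
  list(baseline = baseline, summary = summary, marker_scores = ms)
}

#' Extract the contributive KO set
#'
#' KOs whose summarized contribution is strictly greater than the minimal
#' (marker) baseline; marker KOs themselves qualify only if strictly above.
#'
#' @param scores Output of [contribution_scores()].
#' @param baseline A number or the output of [marker_baseline()].
#' @return Character vector of contributive KO ids.
#' @export
contributive_set <- function(scores, baseline) {
  if (is.list(baseline)) baseline <- baseline$baseline
  scores$ko[scores$score > baseline]
}

#' Shared contributive KOs per MSP
#'
#' Cardinality of the intersection between each MSP's KO repertoire and the
#' contributive set.
#'
#' @param msp_ko_sets Named list: MSP id -> character vector of KO ids.
#' @param contributive Nonempty character vector of contributive KO ids.
#' @return Named integer vector.
#' @export
msp_shared_ko_counts <- function(msp_ko_sets, contributive) {
  if (length(contributive) == 0L) stop("contributive set is empty")
  vapply(msp_ko_sets, function(ks) length(intersect(unique(ks), contributive)), 0L)
}

#' MSP KO repertoires from a gene annotation table
#'
#' @param annotation Data frame with `ko_id` and `msp_id` columns.
#' @return Named list MSP -> KO ids (genes without MSP or KO are ignored).
#' @export
msp_ko_sets <- function(annotation) {
  keep <- !is.na(annotation$msp_id) & !is.na(annotation$ko_id)
  split(annotation$ko_id[keep], annotation$msp_id[keep])
}
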