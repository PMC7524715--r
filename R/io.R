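# Plain-text interchange: TSV matrices (features as rows, first column the
# feature id), metadata TSV, newick trees, JSON reports.

#' Write a feature x sample matrix as TSV
#'
#' @param m Matrix with feature rownames and sample colnames.
#' @param path Output path.
#' @param id_column Name of the first (feature id) column.
#' @export
write_matrix_tsv <- function(m, path, id_column = "feature_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature x sample TSV matrix
#'
#' @param path TSV path written by [write_matrix_tsv()] (first column is the
#'   feature id).
#' @return Numeric matrix with feature rownames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "numeric"
  m
}

write_df_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_df_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}
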