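# Plain-text interchange: annotation matrices and association tables as
# tab-separated text with a header row.

#' Write / read an annotation matrix as TSV
#'
#' The matrix is stored with a leading `key` column (rownames) and one
#' named column per feature; labels, if given, go in a `label` column.
#'
#' @param x numeric matrix with rownames and colnames.
#' @param path file path.
#' @param labels optional binary labels to store alongside.
#' @return `path` invisibly (write); a list `x`, `labels` (read; `labels`
#'   is NULL when no label column is present).
#' @export
write_annotation_matrix <- function(x, path, labels = NULL) {
  df <- data.frame(key = rownames(x) %||% as.character(seq_len(nrow(x))),
                   x, check.names = FALSE)
  if (!is.null(labels)) df$label <- as.integer(labels)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation_matrix
#' @export
read_annotation_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  labels <- NULL
  if ("label" %in% names(df)) {
    labels <- as.integer(df$label)
    df$label <- NULL
  }
  x <- as.matrix(df[, setdiff(names(df), "key"), drop = FALSE])
  rownames(x) <- df$key
  list(x = x, labels = labels)
}

#' Write / read an association table as TSV
#'
#' @param table data frame (e.g. with `key`, `p_value`, `af` columns).
#' @param path file path.
#' @return `path` invisibly (write); the data frame (read).
#' @export
write_association_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_association_table
#' @export
read_association_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
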