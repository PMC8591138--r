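#' Expression matrix with tumor/normal sample labels
#'
#' Container for a genes-by-samples abundance matrix together with a
#' tumor/normal label per sample. Values are normalized abundances on an
#' arbitrary linear scale; they must be finite and non-negative.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param labels Character vector of "tumor"/"normal", either named by
#'   sample id or in column order.
#' @return An object of class `expr_matrix`: a list with elements
#'   `values` (the matrix) and `labels` (named character vector).
#' @examples
#' m <- matrix(rpois(12, 50), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' expression_matrix(m, c(s1 = "tumor", s2 = "tumor", s3 = "normal", s4 = "normal"))
#' @export
expression_matrix <- function(values, labels) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (any(!is.finite(values)) || any(values < 0))
    stop("expression values must be finite and >= 0")
  if (is.null(names(labels))) {
    if (length(labels) != ncol(values))
      stop("unnamed `labels` must have one entry per sample")
    names(labels) <- colnames(values)
  }
  missing <- setdiff(colnames(values), names(labels))
  if (length(missing))
    stop("unlabeled sample(s): ", paste(missing, collapse = ", "))
  labels <- labels[colnames(values)]
  if (!all(labels %in% c("tumor", "normal")))
    stop("labels must be 'tumor' or 'normal'")
  structure(list(values = values, labels = labels), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples (%d tumor, %d normal)\n",
              nrow(x$values), ncol(x$values),
              sum(x$labels == "tumor"), sum(x$labels == "normal")))
  invisible(x)
}

#' Read an expression matrix from TSV
#'
#' The file holds gene rows and sample columns: first column gene id,
#' remaining columns numeric abundances, with a header row of sample ids.
#'
#' @param path Path to a tab-separated file.
#' @param label_spec Named character vector mapping sample id to
#'   "tumor"/"normal". Every sample in the file must be covered.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, label_spec) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character", quote = "")
  if (ncol(tab) < 2) stop("expression TSV needs a gene column plus >=1 sample column")
  gene_ids <- tab[[1L]]
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids in ", path, ": ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  sample_ids <- colnames(tab)[-1L]
  vals <- matrix(NA_real_, nrow(tab), length(sample_ids),
                 dimnames = list(gene_ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    v <- suppressWarnings(as.numeric(tab[[j + 1L]]))
    bad <- which(is.na(v) & !is.na(tab[[j + 1L]]))
    if (length(bad))
      stop(sprintf("malformed numeric cell at gene '%s', sample '%s' in %s",
                   gene_ids[bad[1L]], sample_ids[j], path))
    vals[, j] <- v
  }
  expression_matrix(vals, label_spec)
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression_matrix()]; full-precision values.
#'
#' @param expr An `expr_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path) {
  stopifnot(inherits(expr, "expr_matrix"))
  df <- data.frame(gene_id = rownames(expr$values),
                   expr$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
  invisible(path)
}

# Plain deterministic TSV writer used by all table outputs.  Numeric
# columns are written with 17 significant digits so read-back is exact.
write_tsv <- function(df, path, comment_lines = character()) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- formatC(df[[j]], digits = 17, format = "g")
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (cl in comment_lines) writeLines(paste0("# ", cl), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE, quote = "", stringsAsFactors = FALSE)
}
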