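#' Construct an expression matrix
#'
#' Log2 expression values, genes x samples, with the replicate structure
#' carried as per-column time point and replicate labels (sample names are
#' `<timepoint>_<replicate>`).
#'
#' @param values Numeric matrix, rownames = gene ids.
#' @param timepoints Character vector, one time-point label per column.
#' @param replicates Integer vector, one replicate index per column.
#' @return An `expression_matrix` object.
#' @export
expression_matrix <- function(values, timepoints, replicates) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            length(timepoints) == ncol(values),
            length(replicates) == ncol(values))
  tab <- table(timepoints)
  if (any(tab < 2L)) {
    stop("need >= 2 replicates per time point for statistics; got ",
         min(tab), " for ", names(tab)[which.min(tab)])
  }
  colnames(values) <- paste0(timepoints, "_", replicates)
  structure(
    list(values = values, timepoints = as.character(timepoints),
         replicates = as.integer(replicates)),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$timepoints), collapse = ", ")))
  invisible(x)
}

#' Per-gene mean expression per time point
#'
#' Averages replicate columns within each time point.
#'
#' @param expr An `expression_matrix`.
#' @return Matrix genes x time points.
#' @export
timepoint_means <- function(expr) {
  tps <- unique(expr$timepoints)
  out <- sapply(tps, function(tp) {
    rowMeans(expr$values[, expr$timepoints == tp, drop = FALSE])
  })
  colnames(out) <- tps
  out
}

#' Read an expression matrix from TSV
#'
#' Genes as rows (first column `gene_id`), sample columns named
#' `<timepoint>_<replicate>`.
#'
#' @param path File path.
#' @return An `expression_matrix`.
#' @export
read_expression <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  gene_ids <- df[[1]]
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids in expression table")
  values <- as.matrix(df[-1])
  rownames(values) <- gene_ids
  labels <- colnames(values)
  m <- regmatches(labels, regexec("^(.+)_([0-9]+)$", labels))
  if (any(lengths(m) != 3L)) {
    stop("sample columns must be named <timepoint>_<replicate>")
  }
  expression_matrix(values,
                    timepoints = vapply(m, `[`, "", 2L),
                    replicates = as.integer(vapply(m, `[`, "", 3L)))
}

#' Write an expression matrix as TSV
#' @param expr An `expression_matrix`.
#' @param path Output path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr$values), expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
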