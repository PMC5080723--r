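#' Read a gene-model table
#'
#' Tab-separated columns `gene_id chrom start end strand` (0-based half-open
#' gene body from 5'-most TSS to last-exon end). The TSS is derived from the
#' strand: `start` for `+` genes, `end - 1` for `-` genes. Duplicate gene ids
#' and unknown strand symbols are rejected.
#'
#' @param path File path.
#' @return Data frame with columns gene_id, chrom, start, end, strand, tss,
#'   gene_length.
#' @export
read_gene_models <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "integer",
                                         "integer", "character"))
  names(df) <- c("gene_id", "chrom", "start", "end", "strand")
  gene_models(df)
}

#' Build and validate a gene-model table
#'
#' @param df Data frame with gene_id, chrom, start, end, strand.
#' @return Validated gene-model data frame with derived tss and gene_length.
#' @export
gene_models <- function(df) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in% names(df)))
  if (anyDuplicated(df$gene_id)) {
    stop("duplicate gene_id: ", df$gene_id[duplicated(df$gene_id)][1])
  }
  if (!all(df$strand %in% c("+", "-"))) {
    stop("unknown strand symbol: ",
         unique(df$strand[!df$strand %in% c("+", "-")])[1])
  }
  if (any(df$start < 0L) || any(df$end <= df$start)) {
    stop("gene intervals must satisfy 0 <= start < end")
  }
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1L)
  df$tss <- as.integer(df$tss)
  df$gene_length <- df$end - df$start
  rownames(df) <- NULL
  df[c("gene_id", "chrom", "start", "end", "strand", "tss", "gene_length")]
}

#' Write a gene-model table
#' @param genes Gene-model data frame.
#' @param path Output path.
#' @export
write_gene_models <- function(genes, path) {
  utils::write.table(genes[c("gene_id", "chrom", "start", "end", "strand")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Gene analysis region
#'
#' The gene body extended by `flank` bp on both sides (strand-independent),
#' clamped at position 0: the region within which peaks count toward a
#' gene's mark status.
#'
#' @param genes Gene-model data frame (one or more rows).
#' @param flank Flank size in bp (default 5000).
#' @return Data frame chrom/start/end (plus gene_id), 0-based half-open.
#' @export
gene_analysis_region <- function(genes, flank = 5000L) {
  stopifnot(flank >= 0L)
  data.frame(
    gene_id = genes$gene_id,
    chrom = genes$chrom,
    start = pmax(0L, genes$start - as.integer(flank)),
    end = genes$end + as.integer(flank),
    stringsAsFactors = FALSE
  )
}

# Strand-aware sub-regions used by the H3K27me3 profile classifier, as
# genomic [start, end) per gene: promoter (-3000/-100), tss (-100/+1000) and
# broad (+1000 to the last-exon end), offsets in transcription orientation.
gene_subregions <- function(gene, params = pipeline_params()) {
  prom <- offset_interval(gene$tss, gene$strand,
                          params$promoter_region[1], params$promoter_region[2])
  tssr <- offset_interval(gene$tss, gene$strand,
                          params$tss_region[1], params$tss_region[2])
  broad <- if (gene$gene_length > params$broad_start_offset_bp) {
    offset_interval(gene$tss, gene$strand,
                    params$broad_start_offset_bp, gene$gene_length)
  } else NULL  # no gene body downstream of +1000; classifier routes TooShort
  list(promoter = prom, tss = tssr, broad = broad)
}

#' Read a gene-ID list (one id per line)
#' @param path File path.
#' @return Character vector of ids.
#' @export
read_gene_list <- function(path) {
  ids <- readLines(path)
  ids[nzchar(trimws(ids))]
}
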