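#' Size-scaled enrichment density of a gene sub-region
#'
#' Sum over above-cutoff peaks of height times overlap width with the
#' region, divided by the region length. Regions (promoter, tss, broad) are
#' strand-aware offsets from the TSS. With `mode = "area"` the peak's area
#' is apportioned by overlap fraction instead of height x overlap.
#'
#' @param gene One-row gene-model data frame.
#' @param peakset A scaled H3K27me3 `peak_set`.
#' @param region One of "promoter", "tss", "broad".
#' @param cutoff Background height cutoff (peaks must be strictly above).
#' @param params A [pipeline_params()].
#' @param mode "height" (default) or "area".
#' @return Density (numeric scalar); NA if the region has no positive
#'   length (gene too short downstream of the TSS).
#' @export
region_density <- function(gene, peakset, region = c("promoter", "tss",
                                                     "broad"),
                           cutoff = 0, params = pipeline_params(),
                           mode = c("height", "area")) {
  region <- match.arg(region)
  mode <- match.arg(mode)
  iv <- gene_subregions(gene, params)[[region]]
  if (is.null(iv)) return(NA_real_)
  pk <- peakset$peaks
  pk <- pk[pk$height > cutoff & pk$chrom == gene$chrom, , drop = FALSE]
  len <- iv[2] - iv[1]
  if (nrow(pk) == 0L) return(0)
  ov <- overlap_bp(pk$start, pk$end, iv[1], iv[2])
  keep <- ov > 0L
  if (!any(keep)) return(0)
  if (mode == "height") {
    sum(pk$height[keep] * ov[keep]) / len
  } else {
    sum(pk$area[keep] * ov[keep] / (pk$end[keep] - pk$start[keep])) / len
  }
}

#' Classify one H3K27me3-marked gene into an enrichment profile
#'
#' Genes shorter than the minimum length are excluded (`TooShort`).
#' Otherwise the gene is `Promoter` (or `TSS`) class when that region's
#' size-scaled density is at least `profile_margin` (default 1.25, i.e.
#' "25% more") times each of the other two densities; `Broad` when neither
#' wins but at least one above-cutoff peak overlaps the broad region; else
#' `Unclassified`.
#'
#' @inheritParams region_density
#' @return One-row data frame: gene_id, timepoint, klass, d_promoter,
#'   d_tss, d_broad.
#' @export
classify_gene <- function(gene, peakset, cutoff = 0,
                          params = pipeline_params(),
                          mode = c("height", "area")) {
  mode <- match.arg(mode)
  res <- data.frame(gene_id = gene$gene_id, timepoint = peakset$timepoint,
                    klass = NA_character_, d_promoter = NA_real_,
                    d_tss = NA_real_, d_broad = NA_real_,
                    stringsAsFactors = FALSE)
  if (gene$gene_length < params$min_gene_length_bp) {
    res$klass <- "TooShort"
    return(res)
  }
  dp <- region_density(gene, peakset, "promoter", cutoff, params, mode)
  dt <- region_density(gene, peakset, "tss", cutoff, params, mode)
  db <- region_density(gene, peakset, "broad", cutoff, params, mode)
  res$d_promoter <- dp; res$d_tss <- dt; res$d_broad <- db
  m <- params$profile_margin
  if (!is.na(db) && dp > 0 && dp >= m * dt && dp >= m * db) {
    res$klass <- "Promoter"
  } else if (!is.na(db) && dt > 0 && dt >= m * dp && dt >= m * db) {
    res$klass <- "TSS"
  } else if (!is.na(db) && db > 0) {
    res$klass <- "Broad"
  } else {
    res$klass <- "Unclassified"
  }
  res
}

#' Classify all H3K27me3-marked genes at one time point
#'
#' @param genes Gene-model data frame (only genes marked at this time point
#'   should be passed; the marked-gene set comes from [call_gene_marks()]).
#' @inheritParams region_density
#' @return Data frame with one [classify_gene()] row per gene.
#' @export
classify_profiles <- function(genes, peakset, cutoff = 0,
                              params = pipeline_params(),
                              mode = c("height", "area")) {
  mode <- match.arg(mode)
  out <- lapply(seq_len(nrow(genes)), function(i) {
    classify_gene(genes[i, ], peakset, cutoff, params, mode)
  })
  do.call(rbind, out)
}
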