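#' Partition peaks into genic and intergenic
#'
#' A peak is genic when it overlaps at least 1 bp of any gene's analysis
#' region (gene body plus flanks); all coordinates half-open, so a peak
#' exactly abutting a region is intergenic.
#'
#' @param peakset A `peak_set` (background cutoff already applied).
#' @param genes Gene-model data frame.
#' @param flank Analysis-region flank in bp.
#' @return List: `genic` and `intergenic` peak data frames, and `fractions`
#'   (named numeric summing to 1; NaN-free only for nonempty sets).
#' @export
partition_peaks <- function(peakset, genes, flank = 5000L) {
  pk <- peakset$peaks
  regions <- gene_analysis_region(genes, flank)
  if (nrow(pk) == 0L) {
    return(list(genic = pk, intergenic = pk,
                fractions = c(genic = NaN, intergenic = NaN)))
  }
  hits <- GenomicRanges::findOverlaps(
    peaks_granges(pk),
    intervals_granges(regions$chrom, regions$start, regions$end)
  )
  genic <- sort(unique(S4Vectors::queryHits(hits)))
  is_genic <- seq_len(nrow(pk)) %in% genic
  list(
    genic = pk[is_genic, , drop = FALSE],
    intergenic = pk[!is_genic, , drop = FALSE],
    fractions = c(genic = mean(is_genic), intergenic = mean(!is_genic))
  )
}

#' Call per-gene mark status
#'
#' A gene is marked when at least one peak strictly above the background
#' cutoff overlaps its analysis region (gene body plus flanks).
#'
#' @param genes Gene-model data frame.
#' @param peakset A scaled `peak_set`.
#' @param cutoff Background height cutoff in scaled units (0 for marks whose
#'   peak caller already filtered background, e.g. H3K4me3).
#' @param flank Analysis-region flank in bp.
#' @return Data frame: gene_id, mark, timepoint, marked,
#'   n_overlapping_peaks, max_height.
#' @export
call_gene_marks <- function(genes, peakset, cutoff = 0, flank = 5000L) {
  pk <- peakset$peaks[peakset$peaks$height > cutoff, , drop = FALSE]
  regions <- gene_analysis_region(genes, flank)
  n_ov <- integer(nrow(genes))
  max_h <- numeric(nrow(genes))
  if (nrow(pk) > 0L) {
    hits <- GenomicRanges::findOverlaps(
      peaks_granges(pk),
      intervals_granges(regions$chrom, regions$start, regions$end)
    )
    if (length(hits) > 0L) {
      s <- S4Vectors::subjectHits(hits)
      cnt <- table(s)
      n_ov[as.integer(names(cnt))] <- as.integer(cnt)
      agg <- tapply(pk$height[S4Vectors::queryHits(hits)], s, max)
      max_h[as.integer(names(agg))] <- as.numeric(agg)
    }
  }
  data.frame(
    gene_id = genes$gene_id,
    mark = peakset$mark,
    timepoint = peakset$timepoint,
    marked = n_ov >= 1L,
    n_overlapping_peaks = n_ov,
    max_height = max_h,
    stringsAsFactors = FALSE
  )
}

# Per-gene step function of peak height over transcription-orientation
# offsets [-half_window, half_window): overlapping peaks contribute the max
# height per position (heights are summit statistics, not additive).
# Returns segments (offset_start, offset_end, height).
gene_offset_segments <- function(gene, pk, half_window) {
  w <- if (gene$strand == "+") {
    c(gene$tss - half_window, gene$tss + half_window)
  } else {
    # minus-strand offsets o map to genomic tss - o, so the offset window
    # [-hw, hw) is the genomic interval [tss - hw + 1, tss + hw + 1)
    c(gene$tss - half_window + 1L, gene$tss + half_window + 1L)
  }
  keep <- pk$chrom == gene$chrom & pk$end > w[1] & pk$start < w[2]
  pk <- pk[keep, , drop = FALSE]
  if (nrow(pk) == 0L) return(NULL)
  s <- pmax(pk$start, w[1]); e <- pmin(pk$end, w[2])
  if (gene$strand == "+") {
    off_s <- s - gene$tss; off_e <- e - gene$tss
  } else {
    off_s <- gene$tss - e + 1L; off_e <- gene$tss - s + 1L
  }
  # sweep to disjoint segments carrying the max height
  bp <- sort(unique(c(off_s, off_e)))
  seg_s <- bp[-length(bp)]; seg_e <- bp[-1]
  h <- vapply(seq_along(seg_s), function(i) {
    cov <- off_s <= seg_s[i] & off_e >= seg_e[i]
    if (any(cov)) max(pk$height[cov]) else 0
  }, numeric(1))
  data.frame(start = seg_s, end = seg_e, height = h)
}

#' TSS-centered average peak-intensity profile
#'
#' All genes are considered in the same orientation (5' to 3'); each gene's
#' per-position peak height (max over overlapping peaks, 0 where none) is
#' averaged within bins of transcription-orientation offsets around the TSS
#' and then across genes.
#'
#' @param peakset A scaled `peak_set`.
#' @param genes Gene-model data frame.
#' @param half_window Half-width of the window around the TSS (bp).
#' @param bin Bin width in bp; must divide `2 * half_window`.
#' @return Data frame of class `tss_profile`: offset (bin start),
#'   mean_intensity, n_genes.
#' @export
tss_profile <- function(peakset, genes, half_window = 5000L, bin = 50L) {
  if (half_window <= 0L) stop("half_window must be positive")
  if ((2L * half_window) %% bin != 0L) {
    stop("bin must divide the window evenly")
  }
  n_bins <- 2L * half_window %/% bin
  bin_start <- as.integer(seq(-half_window, half_window - bin, by = bin))
  acc <- numeric(n_bins)
  pk <- peakset$peaks
  for (i in seq_len(nrow(genes))) {
    seg <- gene_offset_segments(genes[i, ], pk, half_window)
    if (is.null(seg)) next
    for (j in seq_len(nrow(seg))) {
      if (seg$height[j] == 0) next
      b1 <- (seg$start[j] + half_window) %/% bin
      b2 <- (seg$end[j] - 1L + half_window) %/% bin
      for (b in b1:b2) {
        ov <- min(seg$end[j], bin_start[b + 1L] + bin) -
          max(seg$start[j], bin_start[b + 1L])
        acc[b + 1L] <- acc[b + 1L] + seg$height[j] * ov / bin
      }
    }
  }
  structure(
    data.frame(offset = bin_start,
               mean_intensity = acc / nrow(genes),
               n_genes = nrow(genes)),
    class = c("tss_profile", "data.frame")
  )
}
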