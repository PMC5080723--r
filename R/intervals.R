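# Internal interval helpers. All coordinates are 0-based half-open [start,
# end); GRanges conversions add 1 to start. Strand-aware offsets map a
# transcription-orientation offset o to genomic position tss + o (+ strand)
# or tss - o (- strand); interval mapping below keeps per-basepair symmetry
# exact between a gene and its mirrored minus-strand twin.

peaks_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

intervals_granges <- function(chrom, start, end) {
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end)
  )
}

granges_to_df <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

# Genomic [start, end) of the transcription-orientation offset window
# [offset_a, offset_b) around a strand-aware TSS position.
offset_interval <- function(tss, strand, offset_a, offset_b) {
  stopifnot(offset_a < offset_b)
  if (strand == "+") {
    c(tss + offset_a, tss + offset_b)
  } else {
    c(tss - offset_b + 1L, tss - offset_a + 1L)
  }
}

# Overlap width in bp between [s1,e1) and each [s2,e2) (vectorized).
overlap_bp <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

# Total basepairs of each window covered by the union of a set of intervals
# (all on the same chromosome set). windows/intervals are data.frames with
# chrom/start/end.
window_union_coverage <- function(windows, intervals) {
  if (nrow(intervals) == 0L) return(numeric(nrow(windows)))
  red <- GenomicRanges::reduce(intervals_granges(
    intervals$chrom, intervals$start, intervals$end
  ))
  wgr <- intervals_granges(windows$chrom, windows$start, windows$end)
  hits <- GenomicRanges::findOverlaps(wgr, red)
  if (length(hits) == 0L) return(numeric(nrow(windows)))
  pieces <- IRanges::width(GenomicRanges::pintersect(
    wgr[S4Vectors::queryHits(hits)], red[S4Vectors::subjectHits(hits)]
  ))
  cov <- numeric(nrow(windows))
  agg <- tapply(pieces, S4Vectors::queryHits(hits), sum)
  cov[as.integer(names(agg))] <- as.numeric(agg)
  cov
}
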