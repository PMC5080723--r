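#' Pipeline parameters
#'
#' Collects every numeric constant the pipeline uses in one validated list.
#' Region offsets are in transcription orientation relative to the TSS
#' (negative = upstream); all coordinates are 0-based half-open.
#'
#' @param window_size_bp Genome tiling window for invariant-region detection.
#' @param high_peak_percentile Per-sample peak-height percentile above which a
#'   peak counts as high-intensity.
#' @param flank_bp Regulatory flank added up- and downstream of a gene body to
#'   form its analysis region.
#' @param promoter_region,tss_region Offsets (bp) relative to the TSS bounding
#'   the promoter and TSS sub-regions of a gene.
#' @param broad_start_offset_bp Start offset of the broad (gene-body) region;
#'   it extends to the last-exon end.
#' @param min_gene_length_bp Genes shorter than this are excluded from
#'   profile classification.
#' @param profile_margin A region wins a profile class only if its size-scaled
#'   enrichment density is at least this multiple of each competitor's.
#' @param expressed_threshold_units Non-log2 expression level above which a
#'   gene counts as expressed (in at least one time point).
#' @param highly_expressed_percentile Per-sample expression percentile
#'   defining the consistently-highly-expressed validation gene set.
#' @param fc_log2_min Minimum absolute log2 fold change between two time
#'   points for a differential call.
#' @param qvalue_max FDR threshold for differential calls.
#' @param window_test_alpha Per-window significance level for the
#'   high-peak-coverage enrichment test.
#' @param cutoff_clean_fraction Fraction of highly expressed genes that must
#'   be free of above-cutoff H3K27me3 peaks at the chosen background cutoff.
#'
#' @return A named list of class `pipeline_params`.
#' @export
pipeline_params <- function(window_size_bp = 20000L,
                            high_peak_percentile = 90,
                            flank_bp = 5000L,
                            promoter_region = c(-3000L, -100L),
                            tss_region = c(-100L, 1000L),
                            broad_start_offset_bp = 1000L,
                            min_gene_length_bp = 4000L,
                            profile_margin = 1.25,
                            expressed_threshold_units = 100,
                            highly_expressed_percentile = 95,
                            fc_log2_min = 2,
                            qvalue_max = 0.05,
                            window_test_alpha = 0.05,
                            cutoff_clean_fraction = 0.95) {
  p <- list(
    window_size_bp = as.integer(window_size_bp),
    high_peak_percentile = high_peak_percentile,
    flank_bp = as.integer(flank_bp),
    promoter_region = as.integer(promoter_region),
    tss_region = as.integer(tss_region),
    broad_start_offset_bp = as.integer(broad_start_offset_bp),
    min_gene_length_bp = as.integer(min_gene_length_bp),
    profile_margin = profile_margin,
    expressed_threshold_units = expressed_threshold_units,
    highly_expressed_percentile = highly_expressed_percentile,
    fc_log2_min = fc_log2_min,
    qvalue_max = qvalue_max,
    window_test_alpha = window_test_alpha,
    cutoff_clean_fraction = cutoff_clean_fraction
  )
  stopifnot(
    p$window_size_bp > 0L, p$flank_bp >= 0L,
    p$high_peak_percentile > 0, p$high_peak_percentile < 100,
    p$highly_expressed_percentile > 0, p$highly_expressed_percentile < 100,
    length(p$promoter_region) == 2L, diff(p$promoter_region) > 0L,
    length(p$tss_region) == 2L, diff(p$tss_region) > 0L,
    p$min_gene_length_bp > 0L, p$profile_margin > 1,
    p$cutoff_clean_fraction >= 0, p$cutoff_clean_fraction <= 1
  )
  class(p) <- "pipeline_params"
  p
}

#' Time-point labels of the hypoxia/reoxygenation design
#'
#' Normoxia (t0), 8 h and 24 h hypoxia (t8, t24), and 8 h reoxygenation
#' (reox8), in experimental order.
#' @export
TIMEPOINTS <- c("t0", "t8", "t24", "reox8")

#' Mark labels handled by the pipeline
#' @export
MARKS <- c("H3K4me3", "H3K27me3")

#' Per-gene mark states
#'
#' Co-occurrence states of the two marks within a gene's analysis region.
#' @export
MARK_STATES <- c("none", "K4only", "K27only", "bivalent")
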