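#' Tile chromosomes into fixed-size windows
#'
#' Windows start at position 0; the last partial window of each chromosome
#' is dropped so every window has identical size (keeping the binomial
#' expectation of the enrichment test uniform).
#'
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param window_size Window size in bp.
#' @return Data frame chrom/start/end.
#' @export
tile_windows <- function(chrom_lengths, window_size = 20000L) {
  stopifnot(!is.null(names(chrom_lengths)), window_size > 0)
  out <- lapply(names(chrom_lengths), function(ch) {
    n <- floor(chrom_lengths[[ch]] / window_size)
    if (n == 0L) return(NULL)
    start <- as.integer((seq_len(n) - 1L) * window_size)
    data.frame(chrom = ch, start = start,
               end = as.integer(start + window_size),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Chromosome lengths implied by a collection of peak sets (max peak end per
# chromosome), used when no explicit genome is supplied.
implied_chrom_lengths <- function(peaksets) {
  all_pk <- do.call(rbind, lapply(peaksets, function(p) p$peaks))
  tapply(all_pk$end, all_pk$chrom, max)
}

#' Per-window high-intensity peak enrichment
#'
#' For one sample, computes for every genome window the fraction of its
#' basepairs covered by high-intensity peaks (height above the sample's
#' `percentile`-th peak-height percentile) and a one-sided binomial p-value
#' of that coverage against the genome-wide expected fraction. Windows
#' whose coverage significantly exceeds expectation are candidate anchors
#' for between-sample normalization.
#'
#' @param peakset A `peak_set`.
#' @param windows Window tiling from [tile_windows()] (equal-size windows).
#' @param percentile Peak-height percentile defining "high" (default 90).
#' @return Data frame: chrom, start, end, coverage_bp, fraction, p_value.
#' @export
window_high_peak_enrichment <- function(peakset, windows, percentile = 90) {
  pk <- peakset$peaks
  if (nrow(pk) < 10L) {
    stop("sample has fewer than 10 peaks; height percentile is meaningless")
  }
  wsize <- unique(windows$end - windows$start)
  stopifnot(length(wsize) == 1L)
  h_thresh <- stats::quantile(pk$height, percentile / 100, names = FALSE)
  high <- pk[pk$height > h_thresh, , drop = FALSE]
  cov_bp <- window_union_coverage(windows, high)
  p0 <- sum(cov_bp) / (nrow(windows) * wsize)
  # one-sided upper tail: P(X >= observed) for X ~ Binom(window_size, p0);
  # pbinom(-1, upper) = 1, so zero coverage is never enriched
  pv <- stats::pbinom(round(cov_bp) - 1, size = wsize, prob = p0,
                      lower.tail = FALSE)
  data.frame(chrom = windows$chrom, start = windows$start,
             end = windows$end, coverage_bp = cov_bp,
             fraction = cov_bp / wsize, p_value = pv,
             stringsAsFactors = FALSE)
}

#' Find invariant regions across samples
#'
#' A window is invariant when its high-intensity peak coverage is
#' significantly enriched (p below `alpha`) in every sample; neighboring
#' (abutting) invariant windows are merged into maximal regions. Because
#' the height percentile is computed per sample, the detection is invariant
#' under uniform per-sample intensity rescaling.
#'
#' @param samples List of `peak_set` (>= 2), typically the H3K27me3 samples.
#' @param params A [pipeline_params()].
#' @param chrom_lengths Optional named chromosome lengths; defaults to the
#'   lengths implied by the peaks themselves.
#' @return A list of class `invariant_region_set`: `regions` (merged
#'   chrom/start/end data frame), `windows` (per-window p-values per
#'   sample), `window_size`.
#' @export
find_invariant_regions <- function(samples, params = pipeline_params(),
                                   chrom_lengths = NULL) {
  stopifnot(length(samples) >= 2L)
  if (is.null(chrom_lengths)) chrom_lengths <- implied_chrom_lengths(samples)
  windows <- tile_windows(chrom_lengths, params$window_size_bp)
  stats_per_sample <- lapply(samples, window_high_peak_enrichment,
                             windows = windows,
                             percentile = params$high_peak_percentile)
  pmat <- sapply(stats_per_sample, function(s) s$p_value)
  invariant <- rowSums(pmat < params$window_test_alpha) == length(samples)
  if (!any(invariant)) {
    stop("no invariant window found in all samples; cannot normalize ",
         "(relax window_test_alpha or check that samples share ",
         "high-intensity domains)")
  }
  inv_win <- windows[invariant, , drop = FALSE]
  merged <- granges_to_df(GenomicRanges::reduce(
    intervals_granges(inv_win$chrom, inv_win$start, inv_win$end)
  ))
  merged <- merged[order(merged$chrom, merged$start), , drop = FALSE]
  rownames(merged) <- NULL
  structure(
    list(regions = merged,
         windows = cbind(windows, p_value = pmat),
         window_size = params$window_size_bp),
    class = "invariant_region_set"
  )
}

#' Cumulative peak area within invariant regions
#'
#' Peak areas are apportioned by overlap fraction for peaks straddling a
#' region boundary.
#'
#' @param peakset A `peak_set`.
#' @param regions Data frame chrom/start/end.
#' @return Total apportioned area (scalar).
#' @export
invariant_region_auc <- function(peakset, regions) {
  pk <- peakset$peaks
  if (nrow(pk) == 0L) return(0)
  pk_gr <- peaks_granges(pk)
  reg_gr <- intervals_granges(regions$chrom, regions$start, regions$end)
  hits <- GenomicRanges::findOverlaps(pk_gr, reg_gr)
  if (length(hits) == 0L) return(0)
  q <- S4Vectors::queryHits(hits)
  ov <- IRanges::width(GenomicRanges::pintersect(
    pk_gr[q], reg_gr[S4Vectors::subjectHits(hits)]
  ))
  sum(pk$area[q] * ov / (pk$end[q] - pk$start[q]))
}

#' Compute per-sample scale factors from invariant regions
#'
#' The cumulative area under the curve of all peaks within the invariant
#' regions is scaled relative to the smallest value among the samples:
#' `factor_i = min_j(AUC_j) / AUC_i`, so factors lie in (0, 1] and applying
#' them equalizes invariant-region AUC across samples.
#'
#' @param samples Named list of `peak_set`.
#' @param invariant_regions An `invariant_region_set` or a plain
#'   chrom/start/end data frame.
#' @return Named numeric vector of factors.
#' @export
compute_scale_factors <- function(samples, invariant_regions) {
  regions <- if (inherits(invariant_regions, "invariant_region_set")) {
    invariant_regions$regions
  } else invariant_regions
  stopifnot(nrow(regions) > 0L)
  auc <- vapply(samples, invariant_region_auc, numeric(1), regions = regions)
  if (any(auc == 0)) {
    stop("invariant-region AUC is zero for sample(s): ",
         paste(names(samples)[auc == 0], collapse = ", "))
  }
  min(auc) / auc
}

#' Set the background height cutoff from highly expressed genes
#'
#' Defines the consistently-highly-expressed gene set H (expression above
#' the `highly_expressed_percentile` in every sample) and returns the
#' smallest cutoff c such that at least `cutoff_clean_fraction` of H has no
#' H3K27me3 peak with scaled height above c anywhere in its analysis region
#' (gene body plus flanks), across all supplied samples. Any repressive
#' mark in these genes is taken to be background noise.
#'
#' @param k27_samples_scaled List of scaled H3K27me3 `peak_set`s.
#' @param genes Gene-model data frame.
#' @param expression An `expression_matrix` covering (at least) the genes.
#' @param params A [pipeline_params()].
#' @return List: `cutoff`, `achieved_clean_fraction`, `n_high_genes`,
#'   `high_gene_ids`.
#' @export
set_background_cutoff <- function(k27_samples_scaled, genes, expression,
                                  params = pipeline_params()) {
  vals <- expression$values
  q <- apply(vals, 2, stats::quantile,
             probs = params$highly_expressed_percentile / 100, names = FALSE)
  above_all <- rowSums(sweep(vals, 2, q, ">")) == ncol(vals)
  high_ids <- intersect(rownames(vals)[above_all], genes$gene_id)
  if (length(high_ids) == 0L) {
    stop("no gene is above the expression percentile in all samples")
  }
  hg <- genes[match(high_ids, genes$gene_id), , drop = FALSE]
  regions <- gene_analysis_region(hg, params$flank_bp)
  reg_gr <- intervals_granges(regions$chrom, regions$start, regions$end)

  max_h <- numeric(length(high_ids))  # tallest K27 peak per gene, any sample
  for (ps in k27_samples_scaled) {
    pk <- ps$peaks
    if (nrow(pk) == 0L) next
    hits <- GenomicRanges::findOverlaps(peaks_granges(pk), reg_gr)
    if (length(hits) == 0L) next
    agg <- tapply(pk$height[S4Vectors::queryHits(hits)],
                  S4Vectors::subjectHits(hits), max)
    idx <- as.integer(names(agg))
    max_h[idx] <- pmax(max_h[idx], as.numeric(agg))
  }

  n <- length(max_h)
  k <- ceiling(params$cutoff_clean_fraction * n)
  cutoff <- if (k == 0L) 0 else sort(max_h)[k]
  list(cutoff = cutoff,
       achieved_clean_fraction = mean(max_h <= cutoff),
       n_high_genes = n,
       high_gene_ids = high_ids)
}

#' Normalize H3K27me3 samples end to end
#'
#' Finds invariant regions, computes and applies scale factors (anchored so
#' the smallest-AUC sample keeps factor 1), and sets the background cutoff
#' validated on highly expressed genes.
#'
#' @param k27_samples Named list of raw H3K27me3 `peak_set`s.
#' @param genes Gene-model data frame.
#' @param expression An `expression_matrix`.
#' @param params A [pipeline_params()].
#' @param chrom_lengths Optional named chromosome lengths.
#' @return List of class `normalization_result`: `invariant_regions`,
#'   `scale_factors`, `scaled_samples`, `background_cutoff`,
#'   `achieved_clean_fraction`, `n_high_genes`.
#' @export
normalize_h3k27me3 <- function(k27_samples, genes, expression,
                               params = pipeline_params(),
                               chrom_lengths = NULL) {
  inv <- find_invariant_regions(k27_samples, params, chrom_lengths)
  factors <- compute_scale_factors(k27_samples, inv)
  scaled <- mapply(scale_peak_set, k27_samples, factors, SIMPLIFY = FALSE)
  cut <- set_background_cutoff(scaled, genes, expression, params)
  structure(
    list(invariant_regions = inv, scale_factors = factors,
         scaled_samples = scaled, background_cutoff = cut$cutoff,
         achieved_clean_fraction = cut$achieved_clean_fraction,
         n_high_genes = cut$n_high_genes),
    class = "normalization_result"
  )
}

#' @export
print.normalization_result <- function(x, ...) {
  cat(sprintf(paste0("<normalization_result> %d invariant regions, ",
                     "cutoff %.4g (clean fraction %.3f over %d genes)\n"),
              nrow(x$invariant_regions$regions), x$background_cutoff,
              x$achieved_clean_fraction, x$n_high_genes))
  cat("scale factors:",
      paste(sprintf("%s=%.4g", names(x$scale_factors), x$scale_factors),
            collapse = ", "), "\n")
  invisible(x)
}
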