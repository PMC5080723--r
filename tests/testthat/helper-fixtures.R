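# Shared fixtures, built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, build(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Default synthetic study (moderate size) plus its normalization result.
default_study <- function() {
  memo("default_study", function() {
    cfg <- sim_config(n_genes = 600, n_chroms = 4, chrom_length_bp = 12e6,
                      seed = 7)
    st <- simulate_study(cfg)
    k27 <- st$peaksets[grep("^H3K27me3_", names(st$peaksets))]
    st$norm <- normalize_h3k27me3(k27, st$genes, st$expression)
    st
  })
}

# Mark states per time point for the default study, called with the
# generator's designed noise/signal separation cutoff.
default_states <- function() {
  memo("default_states", function() {
    st <- default_study()
    cut <- st$truth$true_cutoff
    out <- lapply(TIMEPOINTS, function(tp) {
      mark_states(
        call_gene_marks(st$genes, st$peaksets[[paste0("H3K4me3_", tp)]],
                        cutoff = 0),
        call_gene_marks(st$genes,
                        st$norm$scaled_samples[[paste0("H3K27me3_", tp)]],
                        cutoff = cut)
      )
    })
    names(out) <- TIMEPOINTS
    out
  })
}

# A one-row gene-model data frame.
toy_gene <- function(gene_id = "g1", chrom = "chr1", start = 10000L,
                     end = 30000L, strand = "+") {
  gene_models(data.frame(gene_id = gene_id, chrom = chrom, start = start,
                         end = end, strand = strand,
                         stringsAsFactors = FALSE))
}

# A peak_set from vectors; heights default to dyadic rationals so
# per-basepair oracles are float-exact.
toy_peaks <- function(chrom, start, end, height, area = NULL,
                      mark = "H3K27me3", timepoint = "t0") {
  if (is.null(area)) area <- height * (end - start) * 0.5
  peak_set(data.frame(chrom = chrom, start = start, end = end,
                      height = height, area = area,
                      stringsAsFactors = FALSE),
           mark, timepoint)
}

# Independent per-basepair oracle for region density: walks every basepair
# of [rs, re) and accumulates the height of each above-cutoff peak covering
# it, one position at a time.
brute_density <- function(peaks_df, rs, re, cutoff = 0) {
  len <- re - rs
  acc <- numeric(len)
  for (i in seq_len(nrow(peaks_df))) {
    if (peaks_df$height[i] <= cutoff) next
    s <- max(peaks_df$start[i], rs)
    e <- min(peaks_df$end[i], re)
    if (e <= s) next
    idx <- (s - rs + 1L):(e - rs)
    acc[idx] <- acc[idx] + peaks_df$height[i]
  }
  sum(acc) / len
}
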