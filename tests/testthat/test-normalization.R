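# A constructed sample on one 400-kb chromosome: 180 width-1 low peaks set
# the height percentile; `high` intervals (height 10) supply the
# above-percentile coverage.
constructed_sample <- function(high_start, high_end, timepoint = "t0") {
  low <- data.frame(chrom = "chr1", start = 0:599, end = 1:600,
                    height = 1, area = 0.5)
  high <- data.frame(chrom = "chr1", start = high_start, end = high_end,
                     height = 10, area = 5 * (high_end - high_start))
  peak_set(rbind(low, high), "H3K27me3", timepoint)
}

test_that("window tiling drops the last partial window", {
  w <- tile_windows(c(chr1 = 50000, chr2 = 19999), 20000L)
  expect_equal(nrow(w), 2L)  # chr2 has no complete window
  expect_equal(w$start, c(0L, 20000L))
  expect_true(all(w$end - w$start == 20000L))
})

test_that("a fully covered window is enriched, an empty one is not", {
  # high peaks tile window 1 completely; genome-wide fraction = 20/400
  ps <- constructed_sample(high_start = seq(0L, 19000L, 1000L),
                           high_end = seq(1000L, 20000L, 1000L))
  w <- tile_windows(c(chr1 = 400000), 20000L)
  st <- window_high_peak_enrichment(ps, w, 90)
  expect_equal(st$fraction[1], 1)
  expect_lt(st$p_value[1], 1e-100)
  expect_equal(st$fraction[2], 0)
  expect_equal(st$p_value[2], 1)
})

test_that("coverage at the genome-wide expectation is not enriched", {
  # both windows half covered -> p0 = 0.5, observed = expectation
  ps <- constructed_sample(high_start = c(seq(0L, 9000L, 1000L),
                                          seq(20000L, 29000L, 1000L)),
                           high_end = c(seq(1000L, 10000L, 1000L),
                                        seq(21000L, 30000L, 1000L)))
  w <- tile_windows(c(chr1 = 40000), 20000L)
  st <- window_high_peak_enrichment(ps, w, 90)
  expect_equal(st$fraction, c(0.5, 0.5))
  expect_gte(min(st$p_value), 0.5)
})

test_that("samples with fewer than 10 peaks are rejected", {
  ps <- toy_peaks("chr1", c(0L, 50L), c(10L, 80L), c(1, 2))
  w <- tile_windows(c(chr1 = 40000), 20000L)
  expect_error(window_high_peak_enrichment(ps, w), "fewer than 10")
})

test_that("a shared 60-kb domain becomes one merged invariant region", {
  dom <- constructed_sample(seq(100000L, 159000L, 1000L),
                            seq(100800L, 159800L, 1000L))
  samples <- list(a = dom, b = dom, c = dom)
  inv <- find_invariant_regions(samples, pipeline_params(),
                                chrom_lengths = c(chr1 = 400000))
  expect_equal(nrow(inv$regions), 1L)
  expect_lte(inv$regions$start, 100000L)
  expect_gte(inv$regions$end, 159800L)
  expect_gte(inv$regions$end - inv$regions$start, 3 * 20000L)
})

test_that("a domain absent from one sample is not invariant", {
  dom <- constructed_sample(seq(100000L, 159000L, 1000L),
                            seq(100800L, 159800L, 1000L))
  # third sample has its high coverage elsewhere
  other <- constructed_sample(seq(300000L, 359000L, 1000L),
                              seq(300800L, 359800L, 1000L))
  expect_error(
    find_invariant_regions(list(dom, dom, other), pipeline_params(),
                           chrom_lengths = c(chr1 = 400000)),
    "no invariant window"
  )
})

test_that("invariant windows split by a gap stay separate regions", {
  two <- constructed_sample(
    c(seq(100000L, 119000L, 1000L), seq(140000L, 159000L, 1000L)),
    c(seq(100800L, 119800L, 1000L), seq(140800L, 159800L, 1000L))
  )
  inv <- find_invariant_regions(list(two, two), pipeline_params(),
                                chrom_lengths = c(chr1 = 400000))
  expect_equal(nrow(inv$regions), 2L)
})

test_that("scale factors follow min(AUC)/AUC", {
  regions <- data.frame(chrom = "chr1", start = 100000L, end = 120000L)
  mk <- function(area, tp) {
    toy_peaks("chr1", 105000L, 110000L, height = area / 2500,
              area = area, timepoint = tp)
  }
  samples <- list(a = mk(100, "t0"), b = mk(200, "t8"), c = mk(400, "t24"))
  f <- compute_scale_factors(samples, regions)
  expect_equal(unname(f), c(1, 0.5, 0.25))
  # identical samples -> all factors 1
  same <- list(a = mk(100, "t0"), b = mk(100, "t8"))
  expect_equal(unname(compute_scale_factors(same, regions)), c(1, 1))
  # zero AUC is an error
  far <- toy_peaks("chr1", 0L, 100L, 1, timepoint = "t8")
  expect_error(compute_scale_factors(list(a = mk(100, "t0"), b = far),
                                     regions), "zero")
})

test_that("areas straddling a region boundary are apportioned by overlap", {
  regions <- data.frame(chrom = "chr1", start = 1000L, end = 2000L)
  # half the peak is inside the region -> half the area counts
  ps <- toy_peaks("chr1", 500L, 1500L, height = 2, area = 800)
  expect_equal(invariant_region_auc(ps, regions), 400)
})

test_that("normalization is idempotent and recovers simulated depths", {
  st <- default_study()
  norm <- st$norm
  expected <- min(st$truth$depth_factors) / st$truth$depth_factors
  got <- norm$scale_factors[paste0("H3K27me3_", names(expected))]
  expect_equal(unname(got), unname(expected), tolerance = 0.01)
  # factors on already-scaled samples are ~1
  f2 <- compute_scale_factors(norm$scaled_samples,
                              norm$invariant_regions$regions)
  expect_equal(unname(f2), rep(1, length(f2)), tolerance = 0.01)
})

test_that("window enrichment is invariant under uniform rescaling", {
  st <- default_study()
  ps <- st$peaksets$H3K27me3_t0
  w <- tile_windows(c(chr1 = 12e6), 20000L)
  a <- window_high_peak_enrichment(ps, w, 90)
  b <- window_high_peak_enrichment(scale_peak_set(ps, 3.7), w, 90)
  expect_equal(a$p_value, b$p_value)
})

test_that("the background cutoff sits in the designed noise/signal gap", {
  st <- default_study()
  norm <- st$norm
  expect_lte(norm$background_cutoff, st$truth$cutoff_bracket[["noise_max"]])
  expect_lt(norm$background_cutoff, st$truth$cutoff_bracket[["signal_min"]])
  expect_gte(norm$achieved_clean_fraction, 0.95)
  expect_gt(norm$n_high_genes, 0L)
})

test_that("the cutoff is monotone in the clean fraction and 0 at fraction 0", {
  st <- default_study()
  k27 <- st$norm$scaled_samples
  cuts <- vapply(c(0, 0.25, 0.5, 0.75, 0.95, 1), function(f) {
    set_background_cutoff(k27, st$genes, st$expression,
                          pipeline_params(cutoff_clean_fraction = f))$cutoff
  }, numeric(1))
  expect_equal(cuts[1], 0)
  expect_true(all(diff(cuts) >= 0))
})

test_that("an empty highly-expressed set is an error", {
  # two genes alternate rank across samples, so neither is above the
  # per-sample percentile in all samples
  vals <- matrix(c(10, 1, 1, 10, 10, 1, 1, 10), nrow = 2,
                 dimnames = list(c("g1", "g2"), NULL))
  em <- expression_matrix(vals, rep(c("t0", "t8"), each = 2),
                          rep(1:2, times = 2))
  g <- toy_gene()
  ps <- list(toy_peaks("chr1", 0L, 100L, 1))
  expect_error(set_background_cutoff(ps, g, em), "no gene")
})
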