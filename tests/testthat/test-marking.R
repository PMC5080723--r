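test_that("genic/intergenic partition uses the half-open >=1 bp rule", {
  g <- toy_gene(start = 10000L, end = 30000L)  # region [5000, 35000)
  ps <- toy_peaks("chr1",
                  start = c(35000L, 34999L, 4000L, 0L),
                  end = c(35500L, 35001L, 5001L, 100L),
                  height = c(1, 1, 1, 1))
  part <- partition_peaks(ps, g, flank = 5000L)
  # abutting peak (start == region end) is intergenic; 1-bp overlaps are genic
  expect_equal(nrow(part$genic), 2L)
  expect_equal(nrow(part$intergenic), 2L)
  expect_equal(sum(part$fractions), 1)
})

test_that("partition fractions match a brute-force overlap count", {
  genes <- gene_models(data.frame(
    gene_id = c("a", "b"), chrom = "chr1", start = c(20000L, 80000L),
    end = c(30000L, 95000L), strand = "+", stringsAsFactors = FALSE))
  # 6 peaks inside the two analysis regions, 4 outside
  ps <- toy_peaks("chr1",
                  start = c(16000L, 21000L, 29000L, 76000L, 90000L, 99000L,
                            50000L, 60000L, 120000L, 140000L),
                  end = c(16500L, 21500L, 29500L, 76500L, 90500L, 99500L,
                          50500L, 60500L, 120500L, 140500L),
                  height = rep(1, 10))
  part <- partition_peaks(ps, genes, flank = 5000L)
  expect_equal(unname(part$fractions["genic"]), 0.6)
})

test_that("mark calls require a peak strictly above the cutoff", {
  g <- toy_gene()
  at_cutoff <- toy_peaks("chr1", 12000L, 12500L, height = 2)
  expect_false(call_gene_marks(g, at_cutoff, cutoff = 2)$marked)
  expect_true(call_gene_marks(g, at_cutoff, cutoff = 1.99)$marked)
  none <- toy_peaks("chr1", 500000L, 500100L, height = 5)
  call0 <- call_gene_marks(g, none, cutoff = 0)
  expect_false(call0$marked)
  expect_equal(call0$n_overlapping_peaks, 0L)
  expect_equal(call0$max_height, 0)
})

test_that("lowering the cutoff never unmarks a gene", {
  st <- default_study()
  ps <- st$norm$scaled_samples$H3K27me3_t8
  cuts <- c(5, 2, 1, 0.5, 0)
  marked <- lapply(cuts, function(cu) {
    call_gene_marks(st$genes, ps, cutoff = cu)$marked
  })
  for (i in seq_len(length(cuts) - 1L)) {
    expect_true(all(marked[[i]] <= marked[[i + 1L]]))
  }
})

test_that("simulated t0 mark calls equal the ground truth", {
  st <- default_study()
  cut <- st$truth$true_cutoff
  k4 <- call_gene_marks(st$genes, st$peaksets$H3K4me3_t0, cutoff = 0)
  expect_identical(k4$marked, unname(st$truth$k4_marked))
  for (tp in TIMEPOINTS) {
    k27 <- call_gene_marks(st$genes,
                           st$norm$scaled_samples[[paste0("H3K27me3_", tp)]],
                           cutoff = cut)
    expect_identical(k27$marked, unname(st$truth$profiles[, tp] != "none"))
  }
})

test_that("a TSS-spanning peak projects directly onto the profile", {
  g <- toy_gene(start = 10000L, end = 30000L, strand = "+")  # tss 10000
  ps <- toy_peaks("chr1", 9900L, 10100L, height = 5)
  pr <- tss_profile(ps, g, half_window = 500L, bin = 50L)
  inside <- pr$offset >= -100L & pr$offset < 100L
  expect_equal(pr$mean_intensity[inside], rep(5, 4))
  expect_equal(pr$mean_intensity[!inside], rep(0, sum(!inside)))
})

test_that("mirrored minus-strand geometry gives the identical profile", {
  gp <- toy_gene("gp", start = 10000L, end = 30000L, strand = "+")
  pp <- toy_peaks("chr1", 10050L, 10400L, height = 3)  # offsets [50, 400)
  gm <- toy_gene("gm", start = 50000L, end = 70000L, strand = "-")
  # tss 69999; offsets [50, 400) map to [69600, 69950)
  pm <- toy_peaks("chr1", 69600L, 69950L, height = 3)
  prof_p <- tss_profile(pp, gp, 1000L, 50L)
  prof_m <- tss_profile(pm, gm, 1000L, 50L)
  expect_equal(prof_p, prof_m)
})

test_that("a strand-balanced symmetric landscape has a symmetric profile", {
  genes <- gene_models(data.frame(
    gene_id = c("p", "m"), chrom = "chr1", start = c(10000L, 50000L),
    end = c(30000L, 70000L), strand = c("+", "-"), stringsAsFactors = FALSE))
  # bin-aligned peaks at offsets [-500,-100) and [100,500) for both genes
  # (minus-strand tss is 69999, so those offsets map to [70100, 70500) and
  # [69500, 69900))
  ps <- toy_peaks("chr1",
                  start = c(9500L, 10100L, 69500L, 70100L),
                  end = c(9900L, 10500L, 69900L, 70500L),
                  height = c(4, 4, 4, 4))
  pr <- tss_profile(ps, genes, 1000L, 50L)
  expect_equal(pr$mean_intensity, rev(pr$mean_intensity))
})

test_that("the simulated H3K4me3 landscape dips directly over the TSS", {
  st <- default_study()
  k4_genes <- st$genes[st$truth$k4_marked, ]
  pr <- tss_profile(st$peaksets$H3K4me3_t0, k4_genes,
                    half_window = 2000L, bin = 50L)
  at_tss <- pr$mean_intensity[pr$offset == 0L]
  up <- pr$mean_intensity[pr$offset == -500L]
  down <- pr$mean_intensity[pr$offset == 450L]
  expect_lt(at_tss, up / 2)
  expect_lt(at_tss, down / 2)
})

test_that("overlapping peaks contribute their maximum per position", {
  g <- toy_gene(start = 10000L, end = 30000L, strand = "+")
  ps <- toy_peaks("chr1", c(10000L, 10000L), c(10100L, 10100L),
                  height = c(2, 6))
  pr <- tss_profile(ps, g, 500L, 50L)
  expect_equal(pr$mean_intensity[pr$offset %in% c(0L, 50L)], c(6, 6))
})

test_that("profile window arguments are validated", {
  g <- toy_gene()
  ps <- toy_peaks("chr1", 9000L, 9100L, 1)
  expect_error(tss_profile(ps, g, half_window = 0L), "positive")
  expect_error(tss_profile(ps, g, half_window = 500L, bin = 300L),
               "divide")
})
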