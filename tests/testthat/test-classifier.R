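test_that("region density matches hand arithmetic", {
  # + strand gene, tss 10000: promoter region is [7000, 9900), length 2900
  g <- toy_gene(start = 10000L, end = 30000L, strand = "+")
  ps <- toy_peaks("chr1", 7000L, 7900L, height = 10)
  expect_equal(region_density(g, ps, "promoter"), 10 * 900 / 2900)
  expect_equal(region_density(g, ps, "tss"), 0)
  expect_equal(region_density(g, ps, "broad"), 0)
})

test_that("region density equals the per-basepair oracle on random genes", {
  set.seed(101)
  params <- pipeline_params()
  for (rep in 1:200) {
    strand <- sample(c("+", "-"), 1)
    len <- sample(4000:12000, 1)
    start <- sample(20000:40000, 1)
    g <- toy_gene(start = start, end = start + len, strand = strand)
    n_pk <- sample(1:6, 1)
    pk_start <- sample((start - 8000L):(start + len + 2000L), n_pk)
    pk_width <- sample(100:2500, n_pk, replace = TRUE)
    heights <- sample(seq(0.25, 12, by = 0.25), n_pk, replace = TRUE)
    ps <- toy_peaks("chr1", pk_start, pk_start + pk_width, heights)
    cutoff <- sample(c(0, 2), 1)
    regs <- hypomark:::gene_subregions(g, params)
    for (region in c("promoter", "tss", "broad")) {
      iv <- regs[[region]]
      expect_identical(
        region_density(g, ps, region, cutoff = cutoff, params = params),
        brute_density(ps$peaks, iv[1], iv[2], cutoff = cutoff)
      )
    }
  }
})

test_that("mirrored minus-strand layouts give identical densities", {
  gp <- toy_gene("gp", start = 10000L, end = 30000L, strand = "+")
  # peak at offsets [-2000, -1000) relative to the + tss (10000)
  pp <- toy_peaks("chr1", 8000L, 9000L, height = 6)
  gm <- toy_gene("gm", start = 50000L, end = 70000L, strand = "-")
  # same offsets for the - tss (69999): genomic [71000, 72000)
  pm <- toy_peaks("chr1", 71000L, 72000L, height = 6)
  for (region in c("promoter", "tss", "broad")) {
    expect_equal(region_density(gp, pp, region),
                 region_density(gm, pm, region))
  }
})

test_that("classification follows the 25%-more rule", {
  g <- toy_gene(start = 10000L, end = 30000L, strand = "+")
  # sole peak inside the TSS window -> TSS class
  tss_only <- toy_peaks("chr1", 10000L, 10800L, height = 5)
  expect_equal(classify_gene(g, tss_only)$klass, "TSS")
  # sole peak inside the promoter window -> Promoter class
  prom_only <- toy_peaks("chr1", 7500L, 9000L, height = 5)
  expect_equal(classify_gene(g, prom_only)$klass, "Promoter")
  # peaks only in the gene body -> Broad
  body_only <- toy_peaks("chr1", c(15000L, 20000L), c(16000L, 21000L),
                         height = c(5, 5))
  expect_equal(classify_gene(g, body_only)$klass, "Broad")
})

test_that("short genes and margin ties are routed out", {
  short <- toy_gene(start = 10000L, end = 13500L)
  ps <- toy_peaks("chr1", 10000L, 10500L, height = 5)
  expect_equal(classify_gene(short, ps)$klass, "TooShort")
  # equal promoter and tss densities, empty broad -> neither wins 1.25x
  g <- toy_gene(start = 10000L, end = 30000L, strand = "+")
  tie <- toy_peaks("chr1", c(7000L, 9900L), c(7000L + 2900L, 11000L),
                   height = c(1, 1))  # full coverage of both regions
  cl <- classify_gene(g, tie)
  expect_equal(cl$d_promoter, cl$d_tss)
  expect_equal(cl$klass, "Unclassified")
  # a winner at exactly the 1.25x boundary is accepted
  m <- toy_peaks("chr1", c(7000L, 9900L), c(9900L, 11000L),
                 height = c(1.25, 1))
  expect_equal(classify_gene(g, m)$klass, "Promoter")
})

test_that("classification is invariant under uniform intensity scaling", {
  st <- default_study()
  cut <- st$truth$true_cutoff
  ps <- st$norm$scaled_samples$H3K27me3_t0
  marked_ids <- rownames(st$truth$profiles)[
    st$truth$profiles[, "t0"] != "none"]
  mg <- st$genes[st$genes$gene_id %in% marked_ids, ][1:20, ]
  a <- classify_profiles(mg, ps, cutoff = cut)
  b <- classify_profiles(mg, scale_peak_set(ps, 3), cutoff = cut * 3)
  expect_equal(a$klass, b$klass)
})

test_that("every marked gene receives exactly one class", {
  st <- default_study()
  cut <- st$truth$true_cutoff
  for (tp in c("t0", "t8")) {
    ps <- st$norm$scaled_samples[[paste0("H3K27me3_", tp)]]
    marked_ids <- rownames(st$truth$profiles)[
      st$truth$profiles[, tp] != "none"]
    mg <- st$genes[st$genes$gene_id %in% marked_ids, ]
    cl <- classify_profiles(mg, ps, cutoff = cut)
    expect_equal(nrow(cl), nrow(mg))
    expect_true(all(cl$klass %in% c("Promoter", "TSS", "Broad",
                                    "Unclassified", "TooShort")))
    expect_identical(cl$klass == "TooShort",
                     mg$gene_length < 4000L)
  }
})

test_that("designed profile classes are recovered", {
  st <- default_study()
  cut <- st$truth$true_cutoff
  for (tp in TIMEPOINTS) {
    ps <- st$norm$scaled_samples[[paste0("H3K27me3_", tp)]]
    truth_tp <- st$truth$profiles[, tp]
    ids <- rownames(st$truth$profiles)[truth_tp != "none"]
    mg <- st$genes[st$genes$gene_id %in% ids &
                     st$genes$gene_length >= 4000L, ]
    cl <- classify_profiles(mg, ps, cutoff = cut)
    truth_cl <- truth_tp[match(cl$gene_id, rownames(st$truth$profiles))]
    expect_gte(mean(cl$klass == truth_cl), 0.95)
  }
})
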