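#' Simulation configuration
#'
#' Parameters of the seeded synthetic-data generator. The generator emulates
#' the features of a hypoxia/reoxygenation ChIP-seq + expression time course
#' that the downstream pipeline depends on: designed Promoter/TSS/Broad
#' H3K27me3 profile classes, shared high-intensity H3K27me3 domains
#' (invariant regions), per-sample multiplicative depth distortions,
#' hypoxia-induced gain of TSS-directed H3K27me3 at H3K4me3-premarked genes
#' with partial retention at reoxygenation, and expression whose median
#' depends on mark state. Every assignment is recorded as ground truth.
#'
#' @param n_genes Number of genes to place.
#' @param n_chroms Number of chromosomes.
#' @param chrom_length_bp Length of each chromosome.
#' @param seed RNG seed; a fixed seed gives byte-identical output.
#' @param depth_factors Named per-time-point multiplicative depth distortions
#'   applied to H3K27me3 heights and areas.
#' @param frac_k4_marked Fraction of genes carrying H3K4me3 (stable over
#'   time).
#' @param frac_k27_profiles Named fractions of genes assigned the Promoter,
#'   TSS and Broad H3K27me3 profile at t0 (the rest are unmarked).
#' @param hypoxia_k27_gain_frac Fraction of K4-marked, K27-free genes that
#'   gain TSS-directed H3K27me3 at t8/t24.
#' @param retention_frac Fraction of gained bivalency retained at reox8.
#' @param n_invariant_domains Number of shared high-intensity domains.
#' @param invariant_domain_bp Width of each shared domain.
#' @param n_noise_peaks Background noise peaks scattered per sample.
#' @param noise_height_range,signal_height_range,domain_height_range Height
#'   ranges (pre-distortion units) for noise, genic signal and domain peaks.
#'   Noise stays strictly below signal unless `hard_mode`.
#' @param hard_mode If TRUE the noise height range is widened to overlap the
#'   signal range (stress testing; cutoff recovery is no longer exact).
#' @param frac_short_genes Fraction of genes shorter than 4 kb, to exercise
#'   the classifier's length exclusion.
#' @param expr_state_medians Named log2 expression medians per mark state.
#' @param expr_gene_sd Between-gene baseline SD (log2 units): a per-gene
#'   offset drawn once and shared by all samples, so gene rank is stable
#'   across samples as on real arrays.
#' @param expr_sd Gaussian replicate noise SD (log2 units).
#' @param n_replicates Replicates per time point.
#' @param n_null_genes Never-expressed genes whose maximum defines the
#'   empirical detection floor (the Y-chromosome-gene device).
#' @param null_median,null_sd Location/SD of null-gene log2 values.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L,
                       n_chroms = 4L,
                       chrom_length_bp = 25e6,
                       seed = 1L,
                       depth_factors = c(t0 = 1.0, t8 = 0.7, t24 = 1.3,
                                         reox8 = 0.9),
                       frac_k4_marked = 0.46,
                       frac_k27_profiles = c(Promoter = 0.02, TSS = 0.02,
                                             Broad = 0.05),
                       hypoxia_k27_gain_frac = 0.4,
                       retention_frac = 0.4,
                       n_invariant_domains = 6L,
                       invariant_domain_bp = 60000L,
                       n_noise_peaks = 3000L,
                       noise_height_range = c(0.5, 1.5),
                       signal_height_range = c(5, 10),
                       domain_height_range = c(40, 60),
                       hard_mode = FALSE,
                       frac_short_genes = 0.02,
                       expr_state_medians = c(none = 6.5, K4only = 9.5,
                                              K27only = 4.5, bivalent = 5.5),
                       expr_gene_sd = 1.5,
                       expr_sd = 0.3,
                       n_replicates = 3L,
                       n_null_genes = 50L,
                       null_median = 3.4,
                       null_sd = 0.15) {
  stopifnot(
    n_genes >= 1L, n_chroms >= 1L, chrom_length_bp > 0,
    all(depth_factors > 0), setequal(names(depth_factors), TIMEPOINTS),
    frac_k4_marked >= 0, frac_k4_marked <= 1,
    all(frac_k27_profiles >= 0), sum(frac_k27_profiles) <= 1,
    setequal(names(frac_k27_profiles), c("Promoter", "TSS", "Broad")),
    hypoxia_k27_gain_frac >= 0, hypoxia_k27_gain_frac <= 1,
    retention_frac >= 0, retention_frac <= 1,
    setequal(names(expr_state_medians), MARK_STATES),
    expr_sd >= 0, n_replicates >= 2L
  )
  if (hard_mode) noise_height_range <- c(noise_height_range[1],
                                         signal_height_range[1] * 1.2)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

# Run `expr` under a private RNG stream (seed), restoring any prior global
# RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a gene catalog
#'
#' Places non-overlapping genes of mixed strand on the configured
#' chromosomes, leaving a gene-free zone per chromosome for the shared
#' high-intensity domains. Gaps between gene bodies are at least twice the
#' 5-kb analysis flank, so analysis regions never overlap. A configurable
#' fraction of genes is shorter than 4 kb.
#'
#' @param config A [sim_config()].
#' @return A validated gene-model data frame (see [gene_models()]).
#' @export
simulate_genome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"), config$n_genes >= 1L)
  with_seed(config$seed, {
    n_chr <- config$n_chroms
    chroms <- sprintf("chr%d", seq_len(n_chr))
    dom_per_chrom <- tabulate(
      rep(seq_len(n_chr), length.out = config$n_invariant_domains), n_chr)
    reserve <- dom_per_chrom * (config$invariant_domain_bp + 40000) + 40000
    gene_chrom <- rep(seq_len(n_chr), length.out = config$n_genes)

    n_short <- round(config$frac_short_genes * config$n_genes)
    lengths <- round(stats::runif(config$n_genes, 5000, 20000))
    if (n_short > 0) {
      lengths[sample.int(config$n_genes, n_short)] <-
        round(stats::runif(n_short, 1500, 3900))
    }
    strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
    gaps <- round(stats::runif(config$n_genes, 10000, 18000))

    start <- integer(config$n_genes)
    for (c_i in seq_len(n_chr)) {
      idx <- which(gene_chrom == c_i)
      if (!length(idx)) next
      pos <- cumsum(gaps[idx] + lengths[idx])
      start[idx] <- pos - lengths[idx]
      avail <- config$chrom_length_bp - reserve[c_i]
      if (pos[length(pos)] + 10000 > avail) {
        stop("genome too small to place ", length(idx), " genes on ",
             chroms[c_i], "; increase chrom_length_bp or n_chroms")
      }
    }
    gene_models(data.frame(
      gene_id = sprintf("G%05d", seq_len(config$n_genes)),
      chrom = chroms[gene_chrom],
      start = start,
      end = start + lengths,
      strand = strand,
      stringsAsFactors = FALSE
    ))
  })
}

# Gene-free intervals reserved for the shared high-intensity domains,
# deterministic in the config (placed at each chromosome's far end).
invariant_domain_positions <- function(config) {
  n_chr <- config$n_chroms
  chrom_of <- rep(seq_len(n_chr), length.out = config$n_invariant_domains)
  slot <- stats::ave(seq_along(chrom_of), chrom_of, FUN = seq_along)
  pitch <- config$invariant_domain_bp + 40000
  start <- config$chrom_length_bp - slot * pitch
  data.frame(
    chrom = sprintf("chr%d", chrom_of),
    start = as.integer(start),
    end = as.integer(start + config$invariant_domain_bp),
    stringsAsFactors = FALSE
  )
}

# One peak row constrained to the strand-aware offset window [a, b) of a
# gene; width clipped to the window.
gene_offset_peak <- function(gene, a, b, width, height, fill = 0.7) {
  width <- min(width, b - a)
  lo <- a + sample.int(max(1L, b - a - width + 1L), 1L) - 1L
  iv <- offset_interval(gene$tss, gene$strand, lo, lo + width)
  data.frame(chrom = gene$chrom, start = iv[1], end = iv[2],
             height = height, area = height * width * fill,
             stringsAsFactors = FALSE)
}

#' Simulate per-sample peak landscapes with ground truth
#'
#' Builds the eight peak sets (two marks x four time points). H3K4me3 peaks
#' flank the TSS of K4-marked genes, leaving a depletion gap directly over
#' the TSS. H3K27me3 peaks realize each gene's assigned profile class:
#' a single peak in the promoter window, in the TSS window, or a tiling of
#' the gene body (Broad). Shared high-intensity domains are identical in all
#' H3K27me3 samples before the per-sample depth distortion is applied, and
#' background noise peaks (heights strictly below the designed cutoff unless
#' `hard_mode`) are scattered per sample.
#'
#' @param genes Gene models from [simulate_genome()].
#' @param config The same [sim_config()].
#' @return A list with `peaksets` (named `<mark>_<timepoint>`) and `truth`
#'   (profile/state assignments per time point, gained/retained flags, depth
#'   factors, designed cutoff bracket, domain coordinates, reassignments).
#' @export
simulate_peaksets <- function(genes, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 1L, {
    n <- nrow(genes)
    k4 <- stats::runif(n) < config$frac_k4_marked

    ## t0 K27 profile assignment
    profile_t0 <- rep("none", n)
    pool <- sample.int(n)
    n_cls <- round(config$frac_k27_profiles * n)
    taken <- 0L
    for (cls in c("Promoter", "TSS", "Broad")) {
      k <- n_cls[[cls]]
      if (k > 0) profile_t0[pool[taken + seq_len(k)]] <- cls
      taken <- taken + k
    }

    ## hypoxia gain: K4-marked, K27-free genes acquire a TSS profile
    eligible <- which(k4 & profile_t0 == "none")
    gained <- rep(FALSE, n)
    n_gain <- round(config$hypoxia_k27_gain_frac * length(eligible))
    if (n_gain > 0) gained[sample(eligible, n_gain)] <- TRUE
    retained <- rep(FALSE, n)
    gain_idx <- which(gained)
    n_ret <- round(config$retention_frac * length(gain_idx))
    if (n_ret > 0) retained[sample(gain_idx, n_ret)] <- TRUE

    profiles <- sapply(TIMEPOINTS, function(tp) {
      p <- profile_t0
      if (tp %in% c("t8", "t24")) p[gained] <- "TSS"
      if (tp == "reox8") p[gained & retained] <- "TSS"
      p
    })
    rownames(profiles) <- genes$gene_id

    ## reassign Broad/Promoter profiles that cannot fit the gene
    reassigned <- character(0)
    for (tp in TIMEPOINTS) {
      idx <- which(profiles[, tp] == "Broad" & genes$gene_length < 2400)
      if (length(idx)) {
        profiles[idx, tp] <- "TSS"
        reassigned <- union(reassigned, genes$gene_id[idx])
      }
    }

    ## shared domain peaks, generated once (identical across K27 samples)
    domains <- invariant_domain_positions(config)
    dom_peaks <- do.call(rbind, lapply(seq_len(nrow(domains)), function(i) {
      s <- seq(domains$start[i], domains$end[i] - 1000L, by = 1000L)
      h <- stats::runif(length(s), config$domain_height_range[1],
                        config$domain_height_range[2])
      data.frame(chrom = domains$chrom[i], start = s, end = s + 800L,
                 height = h, area = h * 800 * 0.7, stringsAsFactors = FALSE)
    }))

    sig <- function() stats::runif(1, config$signal_height_range[1],
                                   config$signal_height_range[2])

    peaksets <- list()
    for (tp in TIMEPOINTS) {
      ## H3K4me3: two peaks flanking the TSS (gap over the TSS itself).
      ## K4 peak files emulate caller output already filtered for
      ## significance, so no sub-threshold noise is added here.
      k4_rows <- lapply(which(k4), function(i) {
        g <- genes[i, ]
        rbind(gene_offset_peak(g, -1000L, -50L, 700L, sig()),
              gene_offset_peak(g, 50L, 1000L, 700L, sig()))
      })
      k4_df <- if (length(k4_rows)) do.call(rbind, k4_rows) else
        noise_peaks(sim_config_zero_noise(config))
      peaksets[[paste0("H3K4me3_", tp)]] <-
        peak_set(k4_df, "H3K4me3", tp)

      ## H3K27me3: profile-consistent signal + shared domains + noise
      k27_rows <- lapply(which(profiles[, tp] != "none"), function(i) {
        g <- genes[i, ]
        switch(profiles[i, tp],
          Promoter = gene_offset_peak(g, -2500L, -500L, 1200L, sig()),
          TSS = gene_offset_peak(g, 0L, 900L, 600L, sig()),
          Broad = {
            s <- seq(1200L, g$gene_length - 1000L, by = 1000L)
            do.call(rbind, lapply(s, function(off) {
              h <- sig()
              iv <- offset_interval(g$tss, g$strand, off, off + 800L)
              data.frame(chrom = g$chrom, start = iv[1], end = iv[2],
                         height = h, area = h * 800 * 0.7,
                         stringsAsFactors = FALSE)
            }))
          })
      })
      k27_df <- do.call(rbind, c(k27_rows, list(dom_peaks),
                                 list(noise_peaks(config))))
      d <- config$depth_factors[[tp]]
      k27_df$height <- k27_df$height * d
      k27_df$area <- k27_df$area * d
      peaksets[[paste0("H3K27me3_", tp)]] <-
        peak_set(k27_df, "H3K27me3", tp)
    }

    states <- sapply(TIMEPOINTS, function(tp) {
      k27 <- profiles[, tp] != "none"
      ifelse(k4 & k27, "bivalent",
             ifelse(k4, "K4only", ifelse(k27, "K27only", "none")))
    })
    rownames(states) <- genes$gene_id

    min_d <- min(config$depth_factors)
    truth <- list(
      k4_marked = stats::setNames(k4, genes$gene_id),
      profiles = profiles,
      states = states,
      gained = stats::setNames(gained, genes$gene_id),
      retained = stats::setNames(retained, genes$gene_id),
      depth_factors = config$depth_factors,
      invariant_domains = domains,
      reassigned = reassigned,
      # designed noise/signal separation, in post-normalization units
      # (normalization rescales every sample to the smallest-depth one)
      cutoff_bracket = c(noise_max = config$noise_height_range[2] * min_d,
                         signal_min = config$signal_height_range[1] * min_d),
      true_cutoff = min_d * (config$noise_height_range[2] +
                               config$signal_height_range[1]) / 2
    )
    list(peaksets = peaksets, truth = truth)
  })
}

sim_config_zero_noise <- function(config) {
  config$n_noise_peaks <- 0L
  config
}

# Background noise peaks scattered uniformly over the genome.
noise_peaks <- function(config) {
  m <- config$n_noise_peaks
  if (m == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), height = numeric(), area = numeric(),
                      stringsAsFactors = FALSE))
  }
  chrom <- sprintf("chr%d", sample.int(config$n_chroms, m, replace = TRUE))
  width <- round(stats::runif(m, 200, 600))
  start <- round(stats::runif(m, 0, config$chrom_length_bp - 700))
  h <- stats::runif(m, config$noise_height_range[1],
                    config$noise_height_range[2])
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(start + width), height = h,
             area = h * width * 0.7, stringsAsFactors = FALSE)
}

#' Simulate an expression matrix tied to mark states
#'
#' Each gene's replicate values at a time point are its state's median log2
#' expression plus Gaussian noise; null genes (detection-floor donors, ids
#' `NULL####`) sit near the floor in every sample.
#'
#' @param genes Gene models.
#' @param truth Ground truth from [simulate_peaksets()].
#' @param config The same [sim_config()].
#' @return An [expression_matrix()] over genes plus null genes.
#' @export
simulate_expression <- function(genes, truth, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 2L, {
    n_rep <- config$n_replicates
    tps <- rep(TIMEPOINTS, each = n_rep)
    reps <- rep(seq_len(n_rep), times = length(TIMEPOINTS))
    n <- nrow(genes)
    gene_effect <- stats::rnorm(n, 0, config$expr_gene_sd)
    vals <- matrix(0, nrow = n + config$n_null_genes, ncol = length(tps))
    for (j in seq_along(tps)) {
      med <- config$expr_state_medians[truth$states[, tps[j]]]
      vals[seq_len(n), j] <- med + gene_effect +
        stats::rnorm(n, 0, config$expr_sd)
    }
    if (config$n_null_genes > 0) {
      vals[n + seq_len(config$n_null_genes), ] <-
        stats::rnorm(config$n_null_genes * length(tps),
                     config$null_median, config$null_sd)
    }
    rownames(vals) <- c(genes$gene_id,
                        sprintf("NULL%04d", seq_len(config$n_null_genes)))
    expression_matrix(vals, tps, reps)
  })
}

#' Generate a complete synthetic study
#'
#' Runs [simulate_genome()], [simulate_peaksets()] and
#' [simulate_expression()] and, optionally, writes the whole fixture set
#' (peak BEDs, gene TSV, expression TSV, ground-truth JSON) to a directory.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional output directory.
#' @return List with genes, peaksets, expression, truth, config.
#' @export
simulate_study <- function(config = sim_config(), out_dir = NULL) {
  genes <- simulate_genome(config)
  ps <- simulate_peaksets(genes, config)
  expr <- simulate_expression(genes, ps$truth, config)
  study <- list(genes = genes, peaksets = ps$peaksets, truth = ps$truth,
                expression = expr, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_gene_models(genes, file.path(out_dir, "genes.tsv"))
    write_expression(expr, file.path(out_dir, "expression.tsv"))
    for (nm in names(ps$peaksets)) {
      write_peaks(ps$peaksets[[nm]], file.path(out_dir, paste0(nm, ".bed")))
    }
    truth_json <- ps$truth
    truth_json$profiles <- as.data.frame(truth_json$profiles)
    truth_json$states <- as.data.frame(truth_json$states)
    jsonlite::write_json(truth_json, file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  study
}
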