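# hypomark

Quantitative analysis of H3K4me3/H3K27me3 histone-mark dynamics across a
hypoxia–reoxygenation time course (normoxia `t0`, 8 h and 24 h hypoxia
`t8`/`t24`, 8 h reoxygenation `reox8`).

Oxygen-dependent demethylases keep the repressive H3K27me3 and activating
H3K4me3 marks in check; under hypoxia both accumulate, and H3K27me3 gained
at H3K4me3-premarked genes creates *bivalent* chromatin of the kind known
from embryonic stem cells. The package is for epigenomics analysts who have
peak-level ChIP-seq data (per mark, per time point) plus a replicated log2
expression matrix and want to quantify where the marks go, which genes turn
bivalent, and what that does to transcription.

## The method

H3K27me3 forms broad blanketing domains and its global level is itself the
signal, so total-count normalization is ruled out. `hypomark` instead:

1. **Invariant-region normalization.** Tiles the genome into 20-kb windows
   and tests each window's basepair coverage by high-intensity peaks
   (height above the per-sample 90th percentile) with a one-sided binomial
   tail against the genome-wide coverage fraction p₀:
   `p = P(X ≥ c), X ~ Binom(20000, p₀)`. Windows enriched (p < 0.05) in
   *all* samples are invariant; neighbors are merged. With AUCᵢ the
   cumulative peak area inside invariant regions, sample *i* is rescaled by
   `factorᵢ = minⱼ(AUCⱼ) / AUCᵢ`.
2. **Expression-validated background cutoff.** The smallest height `c` such
   that ≥95 % of consistently highly expressed genes (above the 95th
   expression percentile in every sample) carry no scaled H3K27me3 peak
   above `c` in their gene body ± 5 kb.
3. **Gene mark calls and bivalency.** A gene (5′-most TSS to last-exon end,
   ±5 kb) is marked if ≥1 above-cutoff peak overlaps it; the four states
   `none / K4only / K27only / bivalent` feed 4×4 transition tables between
   time points and per-gene trajectory labels (`gained-retained`,
   `gained-lost`, ...).
4. **H3K27me3 profile classes.** Size-scaled densities over the promoter
   (−3000, −100), TSS (−100, +1000) and broad (+1000, last exon) regions,
   strand-aware; a sharp class needs ≥1.25× the density of *each* other
   region ("25 % more"), `Broad` needs an above-cutoff gene-body peak,
   genes < 4000 bp are excluded.
5. **Expression integration.** Detection floor = max over designated null
   genes; expressed = time-point mean > 100 units (log2 6.64) at ≥1 time
   point; group medians with rank-sum tests; two one-way ANOVA models
   (hypoxia {t0,t8,t24}, reoxygenation {t24,reox8,t0}) with BH FDR and a
   |log2 FC| ≥ 2 gate.

A seeded generator (`sim_config()`, `simulate_study()`) produces gene
models, peak landscapes (designed profile classes, shared invariant
domains, per-sample depth distortions, hypoxia-induced TSS-directed
H3K27me3 gain with partial retention) and state-dependent expression, with
a full ground-truth ledger — every downstream number can be scored.

## Worked example

```r
library(hypomark)

cfg <- sim_config(n_genes = 600, n_chroms = 4, chrom_length_bp = 12e6, seed = 1)
st  <- simulate_study(cfg)                       # peaks + expression + truth
k27 <- st$peaksets[grep("^H3K27me3_", names(st$peaksets))]
norm <- normalize_h3k27me3(k27, st$genes, st$expression)
norm
#> <normalization_result> 6 invariant regions, cutoff 1.048 (clean fraction 1.000 over 15 genes)
#> scale factors: H3K27me3_t0=0.6999, H3K27me3_t8=1, H3K27me3_t24=0.5383, H3K27me3_reox8=0.7776
```

The six simulated invariant domains are found, and the factors invert the
designed depth distortions {1, 0.7, 1.3, 0.9} (anchored on the smallest
AUC) to four digits. The cutoff 1.048 sits in the designed noise/signal
gap. Mark states and transitions:

```r
states <- lapply(setNames(TIMEPOINTS, TIMEPOINTS), function(tp) {
  mark_states(
    call_gene_marks(st$genes, st$peaksets[[paste0("H3K4me3_", tp)]], cutoff = 0),
    call_gene_marks(st$genes, norm$scaled_samples[[paste0("H3K27me3_", tp)]],
                    cutoff = norm$background_cutoff))
})
transitions(states$t0, states$t24)$summaries
#>  bivalent_by_gain_of_K4  bivalent_by_gain_of_K27 bivalent_by_gain_of_both
#>                       0                      100                        0
#>    bivalent_preexisting
#>                      23

ret <- retention(states)
ret$counts
#>                never preexisting-retained      gained-retained
#>                  475                   22                   40
#>          gained-lost                other
#>                   60                    3
ret$retained_fraction_of_gained
#> [1] 0.4
```

Hypoxic bivalency arises purely by gain of H3K27me3 at K4-marked genes
(100 genes), and 40 % of gained bivalency survives reoxygenation — the
generator's designed retention fraction. Expression tracks mark state:

```r
median_by_group(st$expression,
                list(K4only  = states$t0$gene_id[states$t0$state == "K4only"],
                     K27only = states$t0$gene_id[states$t0$state == "K27only"]),
                "t0")
#> $medians
#>     group   n   median
#> 1  K4only 250 9.501482
#> 2 K27only  33 4.638620
#> $tests
#>   group1  group2      p_value significant
#> 1 K4only K27only 3.340017e-20        TRUE
```

K4-marked genes sit ~4.9 log2 units above K27-only genes (rank-sum
p ≈ 3e-20). `run_pipeline(list(out_dir = "...", seed = 1))` runs all of
the above plus profile classification and differential expression from one
config and writes TSV/JSON outputs with a reproducibility manifest.

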