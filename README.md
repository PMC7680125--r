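# nucshift

Detecting nucleosome repositioning from MNase-seq, and quantifying the
chromatin remodelers that cause it.

ATP-dependent remodelers (the yeast ISW1a complex is the motivating case)
space nucleosomes into regular arrays downstream of promoters. When such a
remodeler is deleted or its DNA-sensing domain truncated, gene-body
nucleosomes — typically +2 and deeper, while +1 stays anchored — settle
~10 bp away from their wild-type positions. nucshift is a tidyverse-style R
package for the complete analysis that detects and quantifies this from
MNase-seq fragment data, for chromatin biologists comparing nucleosome maps
between two strains or conditions.

## What it computes

**MNase-seq shift pipeline.** Paired-end fragments `[start, end)` become
dyads at `floor((start + end − 1)/2)`; per-bp dyad counts are normalized to
mean genome-wide coverage over non-excluded positions (repetitive loci are
masked, not zero-filled). Nucleosomes are called by Gaussian smoothing
(σ = 20 bp) plus greedy peak selection with a 147-bp exclusion zone, each
call carrying its dyad position, dyad SD and occupancy from the raw dyads in
its `[dyad − 73, dyad + 73]` footprint. Calls are matched across conditions
when footprints overlap ≥ 73 bp (|Δdyad| ≤ 74) and each pair is tested with
Welch's t-test on the per-call summaries,

&nbsp;&nbsp;&nbsp;&nbsp;*t* = (m_A − m_B) / √(s²_A/n_A + s²_B/n_B),

significant at p < 0.01. Results are summarized as TSS-signed shifts,
+1-aligned metagene profiles and the median shift per nucleosome position.

**Gene-set statistics.** Exact hypergeometric overlap p-values
(C(D,x)·C(N−D,n−x)/C(N,n), log-space), Venn partitions, and the strict
|FC| > 1.5 / FDR < 10% expression filter that produces the compared sets.

**Binding & kinetics.** Hill fits of EMSA titrations
(f([E]) = [E]^H/(K_D^H + [E]^H)) with profile-likelihood 95% CIs and R²;
initial rates v₀ = A·k from saturating-exponential fits of
remodeling/ATPase time courses with delta-method errors; fold-ratio
comparisons with reporting-style rounding.

**Synthetic data.** A seeded generator for genomes, nucleosome arrays with
programmed condition-specific shifts, MNase fragments, titrations and time
courses, so every stage is verifiable without sequencing data.

## Worked example

Simulate a 200-gene genome whose mutant condition has the +2/+3/+4
nucleosomes moved 10 bp downstream, run the full pipeline, and summarize:

```r
library(nucshift)

res <- run_pipeline(list(
  n_genes = 200L, chromosome_length = 500000L, n_per_gene = 5L,
  shift_spec = c("2" = 10, "3" = 10, "4" = 10), seed = 101L
))
#> [nucshift] simulating genome: 200 genes on 1 chromosome(s)
#> [nucshift] fragments: 300000 wt, 300000 mut
#> [nucshift] calls: 1000 wt, 1000 mut
#> [nucshift] pairs: 1000 matched, 1000 tested, 605 significant at alpha = 0.01

median_shift_by_position(res$shifts, genes = res$shifted_genes)
#> # A tibble: 5 × 4
#>   position_index median_shift mean_shift     n
#>            <int>        <dbl>      <dbl> <int>
#> 1              1            0      0.135   200
#> 2              2           10     10.0     200
#> 3              3           10      9.96    200
#> 4              4           10      9.99    200
#> 5              5            0      0.01    200
```

The +1 nucleosome stays put (median 0 bp) while +2..+4 recover the
programmed 10-bp downstream shift; +5 was not shifted and reads 0. About
60% of pairs are significant — the +2/+3/+4 pairs essentially always, the
unshifted +1/+5 pairs at the false-positive rate. `autoplot(res$profile)`
draws the +1-aligned metagene overlay in which the mutant's +2 peak sits
10 bp downstream of the wild type's.

Binding and kinetics work the same way from tables:

```r
fit <- fit_hill(simulate_titration(kd = 5.29, h = 1.43,
                                   noise_sd = 0.03, replicates = 3, seed = 42))
fit
#> <hill_fit> K_D = 5.16 nM [4.84, 5.51], H = 1.46 [1.35, 1.59], R^2 = 0.993 (profile CI, n = 36)

fold_ratio(0.77, 0.060)   # ISW2 vs ISW1a mononucleosome remodeling rates
#> # A tibble: 1 × 2
#>   exact rounded
#>   <dbl>   <dbl>
#> 1  12.8      13
```

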