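---
title: "Methods: detecting nucleosome repositioning and quantifying remodeler biochemistry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting nucleosome repositioning and quantifying remodeler biochemistry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucshift)
```

## The problem

ATP-dependent chromatin remodelers such as the yeast ISW1a complex space
nucleosomes into regular arrays downstream of promoters. When a remodeler is
deleted or mutated, nucleosomes in gene bodies settle at slightly different
positions — typically shifts of around ten base pairs at the +2 and deeper
nucleosomes, with the +1 largely anchored. MNase-seq measures this: micrococcal
nuclease digests chromatin down to protected ~147 bp mononucleosomal
fragments, and the midpoint of each paired-end fragment estimates the
nucleosome dyad. nucshift implements the complete downstream analysis —
dyad-density maps, nucleosome calling, cross-condition matching and shift
testing, +1-aligned metagene summaries — together with the quantitative
biochemistry used to characterize the remodeler itself (Hill fits of EMSA
binding titrations, initial-rate estimation for remodeling and ATPase time
courses) and a synthetic-data generator that makes every stage testable
without sequencing data.

## Dyad maps

Each fragment `[start, end)` contributes one dyad at
`floor((start + end - 1) / 2)`, the midpoint of the closed base interval.
The floor convention is a package choice ("midpoint" needs a rounding rule for
even lengths); it keeps coordinates integral and strand-free, and the
synthetic fragment generator places fragments with the same convention so
truth and estimate never disagree by construction.

Per-bp dyad counts are normalized to the mean genome-wide coverage over
*non-excluded* positions, so the mean track value is exactly 1. Excluded
regions — e.g. the repetitive rDNA locus on chrXII, whose multi-mapping reads
would otherwise dominate — are masked with a sentinel (`NA`), not zero-filled:
filtering reads out means removing them from the coverage statistics, not
pretending the region is empty. External 1-based inclusive coordinates
(GFF3, published locus bounds) pass through one tested conversion site,
`one_based_to_zero()`.

Replicates of a condition are pooled by summing raw dyads before normalizing
(`pool = "raw"`, the default); `"mean-of-normalized"` normalizes each
replicate first and averages. The two agree exactly for balanced replicate
depths and differ slightly otherwise; both are provided because the order of
pooling and normalization is a genuine free choice in this kind of pipeline.

## Nucleosome calling

The track is convolved with a Gaussian kernel (default `sigma = 20` bp,
truncated at ±4σ, unit sum; masked positions contribute zero and edge values
are renormalized by in-bounds kernel mass). Calls are then made greedily:
take the global maximum of the smoothed signal, record a call, forbid further
calls within 147 bp center-to-center, repeat. With that suppression rule the
147-bp footprints `[dyad − 73, dyad + 73]` of accepted calls are pairwise
disjoint, which makes the 73-bp-overlap matching criterion (below) internally
consistent. Ties are broken toward the smaller coordinate, so the caller is
fully deterministic; a property test proves the fast sorted-candidate
implementation identical to a naive iterate-argmax oracle.

Each call is completed from the raw dyads in its footprint: `occupancy`
(count), `dyad_mean`, and `dyad_sd` (n−1 sample SD; zero below two dyads,
with such calls flagged untestable). Calls below `min_occupancy` (default 10)
are dropped; raising the threshold can only remove calls. The reported
nucleosome position is the smoothed-signal argmax — GeneTrack-style peak
picking — while the footprint dyad mean is kept alongside for testing
(see below). The smoothing sigma, exclusion width and occupancy floor are
package defaults; 147 bp matches the nucleosome footprint.

## Shift testing

Calls from two conditions are matched one-to-one when their footprints
overlap by ≥ 73 bp — exactly half a footprint, equivalent to
`|Δdyad| ≤ 74` — choosing greedily by smallest `|Δdyad|`. Each matched pair
is tested with Welch's unequal-variance t-test, treating every raw dyad in a
call's footprint as one observation of the nucleosome's position, so the
call's dyad mean, dyad SD and occupancy are the sample mean, SD and n:

t = (m_A − m_B) / sqrt(s_A²/n_A + s_B²/n_B),

with Welch–Satterthwaite degrees of freedom and a two-sided p-value.
Significance is a raw `p < 0.01` cutoff; a Benjamini–Hochberg FDR column is
emitted for users but never drives the flag.

Two design points deserve emphasis:

* **The test statistic uses the footprint dyad mean, not the smoothed
  argmax.** The argmax is a mode-type estimator whose sampling variance
  exceeds `s²/n`; a 3000-replicate null simulation (300 dyads, SD 20 bp,
  σ = 20 kernel) shows argmax-based t-statistics reject 3.3% at α = 0.01,
  while mean-based testing is calibrated (0.93%) and is exactly a two-sample
  Welch test on the underlying dyad multisets. Matching, reported deltas and
  the displayed positions still use the argmax.
* **Occupancy-as-n makes p-values coverage-dependent.** Doubling sequencing
  depth doubles n and shrinks standard errors; at high coverage even 1–2 bp
  shifts become "significant". This is inherent to using the dyad count as
  sample size — the only reading that uses occupancy, dyad SD and shift
  together — and users should interpret significance jointly with the shift
  magnitude. A sensitivity cap on n can be applied by pre-truncating the
  occupancy columns before `welch_test()`.

Pairs with fewer than two dyads on a side, or zero spread on both sides (as
happens on noise-free synthetic data), are counted as untestable and never
marked significant.

Shifts are reported TSS-signed: positive = downstream, away from the TSS
along the gene's strand, so a `-` strand gene converts a genomic −10 bp into
+10.

## Metagene summaries

Calls are assigned to genes as +1, +2, … : within each gene, calls from
`TSS − 30 bp` (a configurable slack for promoter-proximal +1 calls; the
window is a package choice) to the TES, ordered by distance from the TSS.
Genes qualify for metagene averaging when longer than 560 bp (strict) with at
least four assigned nucleosomes and defined TSS/TES — short sparse genes only
add background noise. Genes "shifted" are those with ≥ 1 significant shift at
positions +1..+4.

Profiles align every gene on its *condition-A* (wild-type) +1 dyad for both
conditions, so mutant repositioning appears as peak displacement on a shared
axis; per-offset means are taken over the gene set with per-offset
bookkeeping of how many genes contributed (offsets running off a chromosome
are skipped, not zero-filled). The summary statistic per nucleosome position
is the median signed shift — robust to the occasional spurious match — with
means and counts emitted alongside; empty cells are absent from the table
rather than reported as 0.

## Gene-set overlap statistics

The overlap of two gene sets from a universe of N genes is scored with the
exact hypergeometric law, `C(D, x) · C(N − D, n − x) / C(N, n)`, computed via
log-binomial coefficients (stable for N in the thousands), with the
enrichment-direction upper tail as the default p-value and a depletion tail
by flag. Input sets come from expression tables filtered with strict
thresholds: |fold change| > 1.5 and FDR < 10%, on either signed-ratio or log2
scale (declared by the caller, since published tables use both).

## Binding and kinetics

EMSA titrations are fit with the Hill model
`f([E]) = [E]^H / (K_D^H + [E]^H)` by unweighted least squares with a
multi-start over a log-spaced K_D grid (the surface can hold shallow local
minima on sparse titrations). Confidence intervals are profile-likelihood by
default — deterministic on small replicate counts — with asymptotic Wald
intervals as fallback; R² is `1 − SS_res/SS_tot`. Free enzyme is approximated
by total enzyme: no ligand-depletion correction, mirroring standard EMSA
practice, although nucleosome (~20 nM) and remodeler (up to 60 nM)
concentrations are comparable — K_D estimates are therefore apparent
constants. Weighting schemes of the original curve-fitting software are not
published; unweighted is the neutral choice.

Time courses are fit with a saturating exponential `A(1 − e^{−kt})` whose
analytic slope at zero, `v0 = A·k`, is the initial rate, with a delta-method
standard error; when the data never saturate the fit falls back (with a
warning flag) to ordinary regression over the early points below 30% of the
maximum signal — the 30% cutoff is the package's operationalization of
"initial". The ±2·se interval has slightly sub-normal coverage (~89% in a
1000-seed simulation at 8 time points) because the residual variance carries
only 6 degrees of freedom; this is a property of small-sample nonlinear
regression, not of the data.

Fold ratios between rates are reported exactly and with reporting-style
rounding: nearest integer for ratios ≥ 10, one decimal below. Published
comparisons occasionally round more aggressively (e.g. a ratio of 8.1 printed
as "8-times"), and one published pair ("5.4 and 10 times") is not exactly
reproducible from its own printed rates (0.23 / 1.2 / 2.8 nM s⁻¹ give 5.2 and
12.2); the package reports the arithmetic and leaves such roundings to the
caller.

## The synthetic-data generator

The generator is first-class, tested code that defines the study conditions
for every recovery test:

* `make_genome()` — non-overlapping genes on both strands, seeded.
* `place_nucleosomes()` — an NFR (140 bp default) then a regular array:
  +k dyad at `TSS + NFR/2 + (k−1)·spacing`, spacing 165 bp by default
  (a typical yeast nucleosomal repeat).
* `apply_shifts()` — strand-relative programmed displacements, e.g.
  `c("2" = 10, "3" = 10, "4" = 10)` for a mutant with the +2 and deeper
  nucleosomes moved 10 bp downstream.
* `simulate_fragments()` — per-nucleosome fragment counts proportional to
  occupancy weight; fragment dyads i.i.d. Normal(true dyad, fuzziness SD) —
  matching the per-call dyad-SD statistic the pipeline estimates — and
  lengths Normal(147, 10) floored at 50 bp. The digestion level of real MNase
  experiments has no published fragment-length distribution; 147 ± 10 bp is a
  configurable default.
* `simulate_titration()` / `simulate_timecourse()` — Hill curves and
  saturating exponentials with Gaussian noise; noiseless output lies exactly
  on the model curve, and the time-course functional form is chosen so its
  analytic initial slope equals the programmed v0 (only the initial rate is
  compared downstream, so any smooth saturating form would do).

Every simulator takes one integer seed and is bit-reproducible. What the
generator does **not** emulate — sequence-dependent MNase bias, mappability,
GC effects, sub- and di-nucleosomal fragments, replicate-level biological
variability, irregular inter-gene spacing of real chromatin — bounds what
passing recovery tests show: they validate the statistical machinery under
its own model assumptions, not robustness to the full messiness of real
MNase-seq. The pipeline deliberately applies no bias corrections either, so
synthetic recovery is the appropriate like-for-like check.

## Problem sizes and numerical choices

The shipped analyses use a 200-gene, 500-kb genome with five-nucleosome
arrays and 300 fragments per nucleosome (~300k fragments per condition) for
shift recovery, and a 400-gene, 1-Mb genome for null calibration (≥ 2000
matched pairs) — sizes chosen so the whole suite runs in minutes on a laptop
while keeping Monte-Carlo error well inside the asserted tolerances. Hill
recovery uses 100 seeded titrations at the published dinucleosome parameters
(K_D 5.29 nM, H 1.43, noise SD 0.03, 3 replicates, a 12-point two-fold
dilution series 0–60 nM).

Numerical conventions worth knowing: greedy ties break to the smaller
coordinate; matching ties break to the smaller dyad pair; track normalization
asserts unit mean to 1e−9; the hypergeometric pmf normalizes to 1 within
1e−12; Hill-fit scale equivariance holds to 1e−6 on noiseless data; zero
dyads, empty gene sets, flat titrations and infeasible gene packings are
explicit errors, not silent empties.

## A worked run

```{r pipeline, eval = FALSE}
res <- run_pipeline(list(
  n_genes = 200L, chromosome_length = 500000L, n_per_gene = 5L,
  shift_spec = c("2" = 10, "3" = 10, "4" = 10), seed = 101L
))
median_shift_by_position(res$shifts, genes = res$shifted_genes)
autoplot(res$profile)
```

## Limitations

* Occupancy-as-n significance is sequencing-depth dependent (see above).
* No deconvolution of overlapping/fuzzy nucleosomes; one call per 147 bp.
* The +1 anchor comes from the wild-type call set; a joint-calling anchor
  would differ slightly for strongly shifted +1 nucleosomes.
* Hill K_D values are apparent constants (no depletion correction).
* The generator's regular arrays and i.i.d. Gaussian fuzziness are idealized;
  conclusions about real chromatin require real data.
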