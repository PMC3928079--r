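---
title: "Methods: competitive CAP occupancy, spacing and the synthetic generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: competitive CAP occupancy, spacing and the synthetic generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `capra`, the
assumptions each estimator makes, every tunable parameter of the
synthetic-data generator, and the numerical choices where a published
method description leaves room for interpretation. It states no
empirical result beyond what the package's test suite and
`scripts/acceptance.R` themselves compute.

## 1. The scientific model

Two chromatin architectural proteins — HMGD1 and linker histone H1 —
bind the linker/entry-exit DNA of nucleosomes competitively: each
nucleosome carries at most one of the two labels. Binding is coupled to
gene activity (HMGD1 on active chromatin, H1 on silent chromatin), so
three genome-wide signatures follow:

* per-gene promoter occupancy rates correlate with expression, with the
  log-ratio `log2(HMGD1/H1)` the strongest single predictor;
* HMGD1 density falls with distance from open chromatin (DHSs), H1
  density does not;
* nucleosome spacing (NRL) lengthens as H1 dominance grows.

All statistics operate on **nucleosome midpoints (dyads)**, and all
coordinates are 0-based half-open (BED convention) internally; GFF3 is
converted at the I/O boundary.

## 2. Midpoint inference

**Paired-end.** Fragment lengths are filtered to the central 95% of
their empirical distribution: nearest-rank quantiles at 2.5% and 97.5%,
rounded outward to integers, boundaries kept. The midpoint of
`[start, end)` is `floor((start + end − 1) / 2)`. Assumption: fragment
ends are symmetric around the dyad, so length outliers (sub-nucleosomal
or di-nucleosomal fragments) are noise, not signal.

**Single-end.** The mean fragment length is estimated as `best_lag + 1`,
where `best_lag` maximizes the Pearson correlation between per-base
forward 5′-end depth at `x` and reverse 5′-end depth at `x + lag`,
pooled across chromosomes over lags `0..max_lag` (default 400 bp —
safely above any MNase fragment). Reads are then shifted towards the
dyad by `round(length/2)`. Assumptions: both strands sample the same
fragment population, and nucleosome positioning is not perfectly
periodic. The second matters: on an exactly periodic array the
covariation peak is ambiguous between the fragment length and the
fragment length ± one repeat length; spacing jitter of a few bp (always
present in real digests, and in the generator) removes the ambiguity.

## 3. Occupancy and expression statistics

* `RPKM = (count + 1) / ((exonic_length/1000) · (mapped/10^6))`; the
  pseudocount keeps `log2 RPKM` finite for silent genes. Expression
  tertiles are ranked thirds (ties broken by gene id; remainder genes to
  the lower groups, so 7 genes split 3/2/2).
* Feature classification precedence is promoter > exon > intron >
  intergenic, with "promoter" defined as absolute oriented distance ≤
  1 kb from the *nearest* TSS.
* TSS metagene profiles are strand-oriented (positive = downstream),
  per-group gene-count-normalized, divided by the track's genome-wide
  mean per-bp midpoint density (so a uniform track is ≈1 everywhere),
  and smoothed with a 25-bp centred moving average.
* Promoter rates: `log2((n_chip + ψ)/(n_total + ψ))` with ψ = 1 over
  `[−100, +500)` for HMGD1 and `[−550, +50)` for H1 — asymmetric windows
  reflecting downstream-leaning HMGD1 and upstream-leaning H1
  occupancy. The per-segment variant uses 175-bp windows
  (−3..−1 nucleosomes, the NDR `[−150, 0)`, +1..+4 nucleosomes); these
  segment boundaries are this package's own positioned-nucleosome
  segmentation and are fully configurable.
* Inference: Pearson `R` with the Fisher-z interval
  `tanh(atanh(R) ± z* /√(n − 3))` and a t-distributed p-value
  (`n − 2` df); the competitive-binding claim uses the nested
  extra-sum-of-squares F-test with 1 and `n − 3` df. A collinear second
  predictor reports `F = 0`; a perfectly fitting full model reports
  `F = Inf, p = 0`.

## 4. DHS distance and PTM clustering

Per-base distance to the nearest DHS is 0 inside a DHS and the bp count
to the nearest covered base outside. 1-kb windows carry
`log2(mean distance + 1)` — the `+1` guards the log for in-DHS windows,
a guard the conventional formula omits — against `log2(mean midpoint
depth + ψ)`. `exclude_tss_proximal()` drops windows whose centre lies
within 2 kb of a TSS (boundary kept). Note that in the synthetic
generator the DHS–occupancy coupling is entirely TSS-mediated, so the
sign pattern is assessed genome-wide; after distal exclusion the
synthetic gradient vanishes by construction (see §6).

PTM clustering takes 2-kb TSS windows, the mean of each bedGraph track
and the pseudocounted log2 ChIP/total ratio per window, the pairwise
Pearson matrix across windows, and average-linkage hierarchical
clustering of the distance `1 − R`. Constant experiments are excluded
with a warning.

## 5. NRL estimation

Regions (2-kb tiles) are ranked into quintiles of the pseudocounted
HMGD1/H1 log-ratio (quintile 1 = lowest ratio; zero-read regions
excluded; remainder to the lower quintiles). Within each region, every
ordered midpoint pair at separation `1..1200` bp increments the
quintile's phasogram; pairs never cross region boundaries, which caps
the useful separation below the region size. Counts are smoothed with a
truncated (±3 sd), edge-renormalized Gaussian kernel (sd 5 bp); local
maxima in `[120, max_distance − 3·sd]` are kept greedily by height
subject to ≥120 bp mutual separation — 120 bp excludes the
sub-nucleosomal shoulder. The NRL is the OLS slope of peak position on
peak index. The intercept is kept free (default) because MNase trimming
shifts all peaks by a common offset; a through-origin variant is
provided.

The gel-ladder estimator regresses band size on band number per
digestion time point (slope = NRL at that time), then NRL on time; the
intercept extrapolates to digestion time zero. Single-band time points
are dropped with a warning.

## 6. The synthetic generator

`sim_config()` collects every tunable with the study conditions as
defaults:

| parameter | default | units | rationale |
|---|---|---|---|
| `genome` | 2 × 400 kb | bp | two chromosomes exercise cross-chromosome pooling |
| `n_genes` | 200 | — | enough genes for stable correlations |
| `region_size` | 2000 | bp | the ratio-stratification tile |
| `nrl_by_quintile` | 174, 177, 180, 184, 187 | bp | the observed quintile NRL range; element *i* applies to quintile 6 − *i* (highest ratio ↔ shortest spacing) |
| `spacing_jitter_sd` | 5 | bp | realistic positional disorder; also disambiguates the single-end covariation peak |
| `fraglen_mean`, `fraglen_sd` | 146, 23 | bp | puts the central 95% of paired MNase fragment lengths at 101–191 bp |
| `fraglen_sd_single` | 4 | bp | single-end libraries model gel size-selected ChIP material, much tighter than the bulk digest; a sd-23 single-end library cannot support few-bp dyad accuracy |
| `depth` | 20 | fragments/nucleosome | Poisson sequencing depth |
| `ratio_slope` | 1 | — | logistic coupling of HMGD1 labelling to standardized log-expression |
| `noise_sd` | 0.5 | — | additive PTM-track noise |
| `gene_length` | 2000 | bp | fixed-length genes, two exons flanking one intron |
| `read_length` | 35 | bp | single-end read length |
| `dhs_width` | 200 | bp | DHS centred on active TSSs |
| `midpoint_blur_sd` | 3 | bp | MNase trimming noise on fragment midpoints |
| `baseline_nrl` | 180 | bp | spacing when not ratio-coupled |
| `expr_mean`, `expr_sd` | 2, 2 | log2 RPKM | true expression distribution |
| `tss_coupling_bp` | 1000 | bp | distance within which labelling follows the nearest gene's expression |

**What it emulates.** Renewal-process nucleosome arrays (first midpoint
uniform within one repeat, spacings Normal truncated below 148 bp so
adjacent cores cannot overlap); mutually exclusive HMGD1/H1 labels with
`P(HMGD1) = plogis(slope · z)` where `z` is the nearest gene's
standardized log-expression within the coupling distance and −1
(intergenic baseline) beyond it; Poisson fragment sampling with length
clamping to [50, 400] bp and midpoint blur; DHSs at the top third of
promoters by expression; activating/repressive PTM families
`±a·z + noise`; Poisson exon tag counts proportional to
`2^log_expr · exonic_length`. Every read records its source nucleosome,
so each stage is checkable against truth.

**What it does not emulate.** Mappability and GC bias, duplicated
reads, chromatin domains or long-range contact structure, partial/dual
CAP occupancy, nucleosome-free promoter architecture beyond the
labelling gradient, replication or copy-number effects, distal
regulatory DHSs (all synthetic DHSs are promoter-proximal — which is
why DHS sign patterns are evaluated genome-wide rather than after
TSS-distal filtering), and transcript isoform diversity (one transcript
per gene).

## 7. Numerical choices

* Strand-offset scan: per-lag pooled sufficient statistics with cumsum
  prefix sums, `O(max_lag · genome_span)`; depth vectors padded by
  `max_lag` so no lag clips a read.
* Nearest-rank (type-1) quantiles for the fragment filter, bounds
  rounded outward — conservative and exactly reproducible from a sort.
* Phasograms by per-region outer differences; exact, and fast because
  regions are small.
* Gaussian smoothing renormalizes by the in-window kernel mass, so edge
  bins are means of what is observable rather than damped toward zero.
* OLS fits use `lm()`; tests verify them against explicit
  normal-equations solutions.
* Tiling drops trailing partial windows; densities and window
  statistics therefore always refer to full-width windows.

## 8. Problem sizes

Test and acceptance problem sizes are this package's own choices,
selected for statistical power: 500 regions per stratum for NRL
recovery, a 2000-region genome for quintile monotonicity (per-region
ratio estimates are noisy at ~20 nucleosomes per region, so strict
ordering of five estimates needs a few hundred regions per quintile),
100 000 fragments for filter bounds, and 100 seeds × 2000 genes for the
ratio-dominance study.

## 9. Limitations

* The generator's association structure is deliberately simple; effect
  sizes (correlation magnitudes) are properties of the chosen slopes
  and noise levels, not predictions about any real genome.
* The quintile NRL pipeline assumes enough phasing signal for ≥2 peaks
  per quintile; sparse or unphased data raise an "insufficient phasing"
  error rather than returning an estimate.
* Single-end offset estimation assumes one dominant fragment-length
  mode; mixed libraries would need per-mode deconvolution.
* qPCR arithmetic fixes amplification efficiency (default 2) rather
  than fitting primer-efficiency curves; the signal-over-background
  ChIP formula is the standard `eff^(Ct_IgG − Ct_ab)` reading.
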