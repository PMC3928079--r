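# capra

Analysis pipeline for competitive chromatin architectural protein (CAP)
occupancy: nucleosome-midpoint inference from MNase/ChIP sequencing,
HMGD1/H1 occupancy statistics around genes and DNase I hypersensitive
sites (DHSs), correlation and nested-model comparison against gene
expression, histone-PTM correlation clustering, and phasogram-based
nucleosome repeat length (NRL) estimation — together with a
ground-truthed synthetic-data generator so that every stage is testable
without external sequencing data.

## Scientific problem

Linker-binding architectural proteins compete for the nucleosome
entry/exit DNA. In *Drosophila* S2 cells, HMGD1 marks active, open
chromatin while histone H1 marks silent, compacted chromatin; where one
binds, the other tends not to. The package quantifies this reciprocity
from sequencing data at three levels:

1. **Occupancy vs activity.** Per-gene occupancy rates over oriented
   promoter windows,
   `rate_HMGD1 = log2((n_HMGD1 + ψ) / (n_total + ψ))` over
   `[−100, +500)` bp around the TSS (H1: `[−550, +50)`), correlated with
   log2 RPKM expression. The discriminating statistic is the log-ratio
   `log2(HMGD1/H1)`: the claim of *competitive* binding is that
   `|R(ratio, expr)| > max(|R(HMGD1, expr)|, |R(H1, expr)|)`, backed by
   the nested extra-sum-of-squares F-test
   `F = (SSE_reduced − SSE_full) / (SSE_full / (n − 3))` for adding the
   second protein to either univariate model.
2. **Occupancy vs accessibility.** 1-kb genomic windows carrying
   `DHS_dist = log2(mean per-base distance to the nearest DHS + 1)`
   against `log2(mean midpoint depth + ψ)`: HMGD1 anticorrelates with
   distance from open chromatin, H1 does not.
3. **Spacing vs occupancy.** Regions stratified into quintiles of the
   HMGD1/H1 log-ratio; within each quintile the phasogram (histogram of
   pairwise midpoint separations) has periodic peaks whose least-squares
   slope over peak index is the NRL. H1-dominated chromatin shows longer
   repeat lengths (≈187 bp) than HMGD1-dominated chromatin (≈174 bp).

Upstream of all three, midpoints (dyads) are inferred from reads:
paired-end fragments are filtered to the central 95% of the length
distribution and the midpoint taken between the pair ends; single-end
reads are shifted by half the fragment length estimated from the lag
maximizing the forward/reverse 5′-depth correlation.

## Worked example

Simulate a 4-Mb genome whose nucleosome spacing is coupled to the true
HMGD1/H1 ratio, then run the full read-level pipeline back to repeat
lengths:

```r
library(capra)

cfg <- sim_config(seed = 1, genome = c(chrA = 2000000L, chrB = 2000000L))
sim <- simulate_spaced_genome(cfg)

hmgd  <- midpoints_from_pairs(sim$reads$hmgd,  label = "HMGD1")
h1    <- midpoints_from_pairs(sim$reads$h1,    label = "H1")
total <- midpoints_from_pairs(sim$reads$total, label = "total")
total
#> <midpoint_track> label=total, 443724 midpoints on 2 chromosome(s)

fragment_size_filter(sim$reads$total)$bounds
#>  low high
#>  101  191

regions <- ratio_quintiles(hmgd, h1, cfg$genome, cfg$region_size)
estimate_nrl_by_quintile(total, regions)
#>   quintile      nrl n_peaks r_squared
#> 1        1 186.7429       6 0.9999973
#> 2        2 182.8286       6 0.9999849
#> 3        3 177.4286       6 0.9999934
#> 4        4 176.8857       6 0.9999980
#> 5        5 174.1429       6 0.9999991

pearson_with_ci(regions$log_ratio, sim$regions$true_log_ratio)
#> Pearson R = 0.704  95% CI [0.681, 0.725]  n = 2000  p = 1.09e-298
```

The estimated repeat length falls strictly from 186.7 bp in the
lowest-ratio (H1-dominated) quintile to 174.1 bp in the highest-ratio
(HMGD1-dominated) quintile, recovering the configured 187→174 bp truth,
and the fragment filter brackets the designed Normal(146, 23) length
distribution at [101, 191] bp.

`simulate_regulatory_genome()` drives the expression-side analyses the
same way: `promoter_rates()` + `expression_table()` for the occupancy
correlations, `dhs_window_stats()` for the accessibility gradient,
`ptm_cluster()` for the PTM dendrogram, and `nested_f_test()` /
`pearson_with_ci()` for inference. `nrl_from_ladder()` covers gel-based
NRL estimation and `chip_fold_enrichment()` /
`expression_fold_change()` the qPCR arithmetic.

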