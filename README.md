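# ChIPRx

Quantitative, spike-in-calibrated comparison of ChIP-seq experiments, built
around the analysis that exposes PRC2/Ezh2 redistribution and locus-specific
H3K27me3 retention in H3.3K27M mutant cells.

## The problem

ChIP-seq read counts are relative: every sample is sequenced to an arbitrary
depth, so a *global* loss of a histone mark — such as the genome-wide
collapse of H3K27me3 caused by H3.3K27M oncohistone expression — is invisible
after ordinary per-sample depth normalization. The remedy is spike-in
chromatin (ChIP-Rx): a fixed proportion (1–5%) of chromatin from a second
organism is added to every sample before immunoprecipitation, reads are
aligned to a combined two-genome reference, and the spike-in read count
serves as an absolute yardstick. For a sample with `n_spike` deduplicated
spike-in fragments the normalization factor is

    alpha = C / n_spike        (C = 1e6 by default)

and the calibrated signal of a peak is `alpha ×` (fragments overlapping the
peak). Densities are expressed as reads per kilobase per 10 million mapped
reads (RPK10M):

    rpk10m(count, width, total) = count / ((width/1e3) · (total/1e7))

On top of this calibration the package implements the comparative analyses
such a study needs: dual-genome fragment partitioning and deduplication;
coverage tracks and expression-stratified metagene profiles over a
flank–TSS→TES–flank grid (100 bins per segment); a Poisson sliding-window
enrichment-domain caller for synthetic end-to-end runs; peak classification
across a control and two mutant clones (common / unique / unreplicated);
promoter assignment, Venn counts and reference-anchored
("tumor-initiating") promoter-set construction; binary feature-occupancy
annotation with Jaccard/average-linkage clustering; and differential
retention statistics (per-peak condition/control ratios, most/least-reduced
median split, two-tailed Student's t tests, fraction of increased peaks).

A seeded synthetic-data generator produces complete toy datasets — a
two-organism genome, gene models with expression tiers, planted enrichment
domains per mark with a condition-level global reduction, fixed-depth
fragment resampling, and a planted co-localization structure (retained
"strong PRC2" promoters, poised enhancers carrying H3K4me1 plus low
H3K27me3, active gene bodies carrying H3.3K27M) — so every stage can be
validated against known truth.

## Worked example

Simulate the default study (control + two H3.3K27M clones for H3K27me3 and
Ezh2, one H3.3K27M sample per clone, input, 2% spike-in, 100,000 fragments
per sample) and run the H3K27me3 retention workflow:

```r
library(ChIPRx)

cfg <- simulationConfig(seed = 1)
ds  <- simulateDataset(cfg)
print(ds$genome$layout)
#> GenomeLayout
#>   hs (primary): 2 chromosome(s), 6e+06 bp, prefix 'hs_'
#>   dm (spikein): 1 chromosome(s), 5e+05 bp, prefix 'dm_'

spikeInFactors(ds$samples[c("H3K27me3_control", "H3K27me3_clone1",
                            "H3K27me3_clone2")], ds$genome$layout)
#> SpikeInFactors for 3 sample(s)
#>         sample_id n_primary n_spike     C    alpha
#>  H3K27me3_control     96853    1921 1e+06 520.5622
#>   H3K27me3_clone1     94066    4876 1e+06 205.0861
#>   H3K27me3_clone2     93912    5025 1e+06 199.0050

rep <- runPipeline(ds, "retention")
```

The factor table already tells the story: the mutant clones yield ~2.5× more
spike-in fragments per sequenced fragment than the control, because the
H3K27me3 they have left competes against the same amount of spike
chromatin. The workflow report quantifies it:

```r
#> peaks in replicated universe:  291
#> median spike-normalized ratio: 0.297
#> median depth-normalized ratio: 0.787
#> increased peaks (%):           0.69
#> H3.3K27M, most- vs least-reduced group means: 322285 210467   p = 3.9e-06
```

The spike-normalized median ratio recovers the planted global reduction
(f = 0.3) almost exactly, while depth normalization of the very same counts
reports 0.79 — the masking that makes the spike-in step necessary. The
median split shows the planted biology: peaks that retain H3K27me3 carry
significantly less H3.3K27M than the most-reduced peaks.

`runPipeline(ds, "redistribution")` runs the Ezh2 chain instead: peak
classification across conditions, binary annotation against promoters,
H3K4me1, H3K27me3 and H3.3K27M, clustering, and the
common-vs-condition-unique comparisons; on the default dataset 100% of the
condition-unique Ezh2 peaks fall on planted poised enhancers.

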