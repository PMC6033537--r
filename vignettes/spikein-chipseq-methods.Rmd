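---
title: "Spike-in calibrated comparative ChIP-seq: models, parameters and design choices"
author: "ChIPRx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spike-in calibrated comparative ChIP-seq: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope

ChIPRx implements the comparative, spike-in-normalized ChIP-seq analysis
used to dissect how the H3.3K27M oncohistone reshapes the H3K27me3
landscape: a global collapse of the mark with locus-specific retention at a
minority of promoters, accompanied by redistribution of PRC2/Ezh2 to
poised enhancers. This vignette documents the models behind each stage,
the parameters that matter, what the synthetic-data generator does and does
not emulate, and the numerical choices a maintainer would want stated.

## The calibration model

Let a sample contain primary-organism chromatin plus exogenous spike-in
chromatin at proportion $s$ of the pre-IP pool. After IP and sequencing to
an arbitrary depth, the expected number of fragments falling in any
primary-genome region is proportional to that region's share of the pooled
IP-able material, and the spike-in fragment count $n_\mathrm{spike}$ is
proportional to the (constant) spike chromatin mass divided by the same
pool size. The per-sample factor

$$\alpha = C / n_\mathrm{spike}, \qquad C = 10^6 \text{ by default}$$

therefore cancels the pool-size term: $\alpha \times$ (fragments in a
peak) is comparable across samples on an absolute scale. The package takes
this formula as its definition; $C$ only sets the display scale and is
configurable everywhere it appears. Counting uses deduplicated fragments
(one per chromosome/start/end/strand tuple) and a one-base overlap
criterion under half-open coordinates — the same criterion used by every
interval operation in the package, with strand ignored throughout the
interval algebra (ChIP fragments measure occupancy, not transcription
direction).

Densities are reported as reads per kilobase per 10 million mapped reads,
$\mathrm{rpk10m}(c, w, N) = c / ((w/10^3)(N/10^7))$.

## Metagene profiles

Genes are ranked by expression and split into three contiguous rank tiers
(high/medium/low) of near-equal size, larger tiers at the top, ties broken
by gene id so the stratification is deterministic. For each gene the body
(TSS to TES) is divided into $B = 100$ bins with boundaries
$\lfloor L\,i/B + 0.5\rfloor$ — half-up rounding keeps the boundaries
strictly increasing for every $L \ge B$, which plain round-half-to-even
does not guarantee — and each 10 kb flank into $B$ fixed-width bins.
Per-bin summed coverage is converted to rpk10m with the bin's covered
width; flank bins truncated by a chromosome edge contribute only their
covered width, fully truncated bins contribute zero. Minus-strand genes are
reversed so bin 1 is always 5′-most. Genes shorter than $B$ bp are
excluded: they cannot populate $B$ non-empty bins. Tier curves are
unweighted means over genes, not pooled per base, so a long gene does not
dominate its tier. Profiles are per-sample rpk10m by default; a
`scaleFactor` argument lets callers apply a spike-in-derived factor when
cross-sample calibrated profiles are wanted.

## The enrichment-domain caller

The caller exists so that synthetic end-to-end runs need no external peak
caller; it does not attempt to reproduce a production caller's model.
Fixed windows (default 200 bp, step 100 bp) slide along the genome; a
window is retained when its fragment-equivalent count (summed coverage
divided by the mean fragment length) exceeds the Poisson upper-tail
quantile at $p \le 10^{-5}$ for a null mean taken from the depth-scaled
control window (floored at the genome-wide uniform rate); retained windows
closer than 500 bp merge into domains. All parameters are arguments.

One subtlety is documented because it shaped a default: the
coverage-derived window statistic is a sum of fractional fragment overlaps,
whose tail is thinner than the Poisson tail assumed by the test. At window
widths comparable to the fragment length this costs real power against
broad, globally reduced domains. The two built-in workflows therefore call
with 1 kb windows at 500 bp steps — a window scale suited to the
domain-type marks they analyse — while the caller's own defaults remain at
the sharper 200/100 setting.

## Cross-condition peak classification

The classification universe is the union of (a) condition peaks present in
both clones — a clone-1 peak overlapping any clone-2 peak by one base, with
the clone-1 interval kept as the anchor — and (b) all control peaks.
Replicated condition peaks are `common` when they overlap a control peak
and `unique_condition` otherwise; control peaks are `unique_control` only
when they overlap *neither* clone; clone peaks without a mate in the other
clone are `unreplicated` and excluded downstream. Because anchors are
clone-1 intervals, swapping the clones preserves the replicated loci and
all control-side labels but reports different anchor coordinates; the test
suite checks exactly that correspondence.

## Binary co-localization clustering

Peaks are annotated against named feature sets as a 0/1 occupancy matrix.
Rows are clustered with agglomerative hierarchical clustering under the
Jaccard distance (two all-zero rows are at distance 0) with average
linkage, and the tree is cut into $k$ clusters ($k = 5$ by default, the
number of co-localization classes the analysis distinguishes). Binary data
produce many tied distances, and `hclust` resolves ties by input order; to
make the result well-defined the rows are put into canonical
(lexicographic) order before the tree is built and cluster labels are
renumbered by first appearance in the caller's order. Clustering is
consequently deterministic and invariant under row permutation, which the
tests verify as ARI = 1 between permuted runs.

Recovery of planted block structure is scored as the median adjusted Rand
index over ten generator replicates (1,000 rows × 8 features, five 3-hot
block prototypes with pairwise intersection ≤ 1, 5% independent bit
flips). A single replicate occasionally scores ~0.75 rather than ~0.95:
a rare heavily-flipped outlier row can sit far from every block, and
cutting the tree at $k$ then spends one cluster on that outlier while two
true blocks stay merged. This is a property of cut-at-$k$ hierarchical
clustering on noisy binary data, not of the implementation; the median
over replicates reports the method's typical behaviour.

## Differential retention statistics

Per-peak ratios are the mean over condition samples of (condition signal /
control signal), computed on spike-in-normalized signals over a shared peak
universe; peaks with zero control signal are excluded and reported. The
"average of per-clone ratios" convention (rather than ratio of means) is
used because the clones are biological replicates of the same
perturbation. The two-group split is at the median, ascending, ties broken
by peak id, the extra element of an odd universe going to the upper group.
Group comparisons use the pooled-variance two-sample Student's t with
$df = n_x + n_y - 2$ and two-tailed p values; a Welch option delegates to
`stats::t.test`. Degenerate inputs are defined rather than fatal: zero
pooled variance yields $t = 0,\ p = 1$ for equal means and a $p = 0$
underflow sentinel otherwise. No multiple-testing correction is applied:
the workflows run single grouped tests, not per-peak tests. The
fraction-increased summary counts ratios strictly greater than 1.0 on a
0–100 scale.

## The synthetic-data generator

The generator emulates the statistical structure every downstream stage
assumes, with defaults chosen once as the package's study conditions:

* **Genome.** Primary organism: two 3 Mb chromosomes; spike-in organism:
  one 0.5 Mb chromosome; combined namespace via per-organism prefixes.
  These sizes are roughly 1/1000 of the mammalian case and keep a full
  study (ten samples) in seconds of compute.
* **Genes and expression.** 200 non-overlapping genes of 2–8 kb placed
  with 12 kb chromosome margins; each gene is assigned an expression tier
  and log-normal expression (meanlog 5/3/1 for high/medium/low,
  sdlog 0.5).
* **Planted H3K27me3.** 200 domains: 75% are 10 kb "bulk" domains subject
  to the full condition-level reduction $f = 0.3$; 25% are retained
  "strong PRC2" promoter domains (2 kb upstream / 500 bp downstream of the
  TSS of isolated low-expression genes) at $f = 0.9$. Fold enrichment over
  background is 30. With these numbers the in-domain fragment mass
  dominates the library (FRiP ≈ 0.95, a very clean broad-mark IP): that
  dominance is what makes a global loss invisible to depth normalization
  — the closed-form expectation of the depth-normalized ratio is
  $f\,(B + D)/(B + fD) = 0.87$ for background mass $B$ and in-domain mass
  $D$ — and is the regime the method exists for.
* **Redistribution structure.** 100 enhancers of 2 kb, 60% poised
  (H3K4me1 plus low H3K27me3 at fold 5); Ezh2 sits on retained promoters
  in both conditions (reduced to $f = 0.5$ in the mutant), on bulk domains
  in the control only, and on poised enhancers in the condition only.
  H3.3K27M is condition-only: high-expression gene bodies (fold 10),
  poised enhancers (fold 10) and bulk H3K27me3 domains (fold 8), never the
  retained promoters.
* **Sampling.** Fragment starts are drawn from a multinomial over genome
  segments with per-base weight 1 (background) or fold × $f$ (inside a
  planted domain present in that condition); exactly `depth` = 100,000
  fragments per sample (fixed-depth resampling), fragment length 200 bp,
  random strand. Spike chromatin mass is held constant across conditions,
  anchored so the *control* sample's expected spike proportion equals
  `spikeFraction` = 0.02; the mutant's spike share then rises as the mark
  is lost, which is precisely the signal ChIP-Rx normalization reads out.
  Under this model the expected spike-normalized peak ratio equals the
  planted $f$ exactly.

Everything is deterministic given `seed`; sub-stages derive fixed offsets
from it, so `makeGenome`, `buildTruth` and `simulateSample` are
individually reproducible.

What the generator does **not** emulate: sequencing errors, mappability
and GC bias, fragment-length variation, MNase digestion artefacts (real
MNase ChIP inflates TSS/TES enrichment of H3.3K27M; no correction is
applied here or in the analysis), copy-number differences, and the
antibody cross-reactivity that produces false-positive peaks in real
control samples. Passing tests therefore demonstrate correctness of the
computations and recoverability of planted structure under an idealized
noise model — not performance on real libraries.

## Workflow problem sizes

The built-in workflows and the acceptance script run on the default study:
ten samples × 100,000 fragments on a 6.5 Mb combined genome, a ~300-peak
replicated universe, and 1,000 × 8 clustering problems. These sizes were
chosen so a complete reproduction (simulation, both workflows, brute-force
oracle verification and the calibration experiment) finishes in a few
minutes on one core while keeping every per-peak count in the hundreds,
large enough that medians over peaks estimate planted parameters to within
a few percent.

## Known limitations

* The caller's Poisson test on coverage-derived counts is conservative at
  small windows (thin-tailed statistic), and the caller makes no attempt
  at local background estimation, duplicate modelling or q-values.
* Spike-in factors assume the spike chromatin amount per sample is exactly
  proportional to primary chromatin input; pipetting variation between
  samples is not modelled and would propagate directly into ratios.
* `classifyPeaks` anchors replicated peaks on clone-1 intervals; peak
  counts (not loci) therefore depend on which clone is first, and
  one-to-many overlaps are counted once per clone-1 anchor.
* Promoter windows exist in two conventions (−2000/+500 used by the
  analyses; −2000/+1000 appears in enhancer-annotation contexts); the
  package defaults to the former and exposes both via arguments.
* With fewer than $k$ distinct annotation patterns, cutting at $k$ is
  impossible; `clusterBinary` raises an error and `runPipeline` caps $k$
  at the number of distinct rows, recording the value used.
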