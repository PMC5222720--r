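---
title: "Quantifying X-chromosome activity from allele counts and RNA-FISH images"
author: "XCIquant authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying X-chromosome activity from allele counts and RNA-FISH images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(XCIquant)
```

## The problem

Female mammalian cells silence one of their two X chromosomes (X-chromosome
inactivation, XCI). In human pre-implantation embryos and naive pluripotent
stem cells, two long noncoding RNAs mark the state of the X: XIST, which
initiates silencing, and XACT, which coats transcriptionally active X
chromosomes. Two kinds of measurements track the onset of XCI in this
system: allele-specific single-cell RNA-seq, where the loss of bi-allelic
expression of X-linked genes signals the emergence of an expression
imbalance between the two X copies, and two-colour RNA-FISH, where the
number, size, compactness and overlap of the XIST and XACT clouds describe
what each nucleus is doing.

XCIquant implements both quantification arms and, because the original
embryo datasets are external, ships seed-deterministic synthetic-data
generators with full ground truth, so that every statistic can be validated
by recovery tests.

## The bi-allelic position statistic

The substrate is an `AlleleCountTable`: per cell and heterozygous position,
reference and alternative read counts. The minor-allele ratio of a position
is

$$r = \frac{\min(n_\mathrm{ref}, n_\mathrm{alt})}{n_\mathrm{ref} + n_\mathrm{alt}} \in [0, 0.5],$$

a symmetric quantity that needs no phasing. `callBiallelic()` applies two
filters: a position is *covered* when its depth reaches `minTotalReads`
(default 5), and a covered position is *bi-allelic* when $r$ reaches
`ratioThreshold` (default 0.2, boundary inclusive). Per cell and chromosome
the score is

$$S = \frac{\#\{\text{bi-allelic positions}\}}{\#\{\text{covered positions}\}} \in [0,1],$$

a coverage-normalized proportion: two active X chromosomes give a high X
score, initiation of XCI erodes it, and autosomes provide a flat internal
control. The alternative normalization by total covered read depth is
available (`normalization = "reads"`); we default to the proportion because
it is scale-free across cells of very different depth. Cells with fewer
than `minPositions` covered positions (default 5) get a flagged missing
score rather than a silent zero. Because the published analyses flag the
sensitivity of the conclusion to the ratio threshold, `thresholdSweep()`
re-scores a table over a threshold ladder; coverage is threshold-free, so
covered counts are constant and bi-allelic counts non-increasing — a
property the test suite asserts unconditionally.

Group and stage comparisons use a two-sided Wilcoxon rank-sum test
(`compareScoreGroups()`, `stageTrend()`): exact by full enumeration of rank
assignments for combined $n \le 20$ (this stays exact under ties), and a
tie-corrected normal approximation with continuity correction otherwise.
P-values are reported raw, without multiple-testing correction, matching
how pairwise stage comparisons are conventionally displayed.

`correlationNull()` implements the gene-null logic for co-expression: the
Spearman correlation of a target gene (XIST) with one focal partner (XACT)
is located inside the distribution of the target's correlations with every
X-linked gene. The focal quantile — the fraction of partners with a
correlation at most the focal one — is uniform under independence, which
the acceptance suite verifies by simulation, so an extreme quantile is
evidence that the pair is specifically co-regulated rather than jointly
switched on by zygotic genome activation.

`geneAllelicCalls()` pools counts per position across the cells of a
condition, calls positions informative/bi-allelic with the same
`CallParams`, and classifies genes as mono-allelic, bi-allelic, or
uninformative; two conditions are compared by Fisher's exact test on the
mono/bi gene counts.

## The sequencing-arm generator

`simulateExpression()` draws an FPKM-scale cells-by-genes matrix over an
ordered stage series with one design choice per observed feature of the
embryo data:

* both focal genes are off strictly before the ZGA stage (`zgaStage`,
  default the 8-cell stage); the maternal contribution of the XACT-like
  gene is off by default and available as a configurable trace level
  (`maternalTrace`), since it is reported as a trace quantity, not a
  target;
* after ZGA, the two focal genes' log-expressions come from a Gaussian
  copula calibrated with $\rho_{\mathrm{Pearson}} = 2\sin(\pi\rho_S/6)$ so
  the Spearman correlation across cells hits `focalRho` (default 0.7);
  because Spearman is invariant under the monotone marginal transform, the
  target transfers exactly;
* trophectoderm cells silence the XACT-like gene with probability
  `teSilencingProb` while the XIST-like gene stays on;
* background genes are independent log-normal draws
  (`exprLogmean = 1`, `exprLogsd = 1` on the natural log, i.e. median
  FPKM ≈ 2.7 — a generic moderately-expressed gene).

`simulateAlleleCounts()` then draws, for every cell and heterozygous
position, a negative-binomial depth (`coverageMean = 20`,
`coverageDispersion = 2`, an overdispersed single-cell-like regime) and a
latent bi-allelic indicator: on the female X its probability is the
stage's entry of `biallelicFractionByStage` (defaults erode from 0.5 to
0.2 across the blastocyst stages); male X positions are always
mono-allelic; autosomes use a flat 0.5. Bi-allelic positions split reads
Binomial(depth, 1/2); mono-allelic positions put all reads on one allele.
The expressed allele of a mono-allelic position is fixed per position
rather than per cell, so pooled-condition gene calls behave like clonal or
XCI-skewed samples; per-cell statistics are unaffected by this choice. An
optional symmetric per-read flip (`errorRate`, default 0) lets
threshold-sweep tests probe false bi-allelic calls. Latent indicators are
retained in the table's `truth` slot for recovery tests. Positions are
1-based and chromosome labels plain strings, following VCF conventions;
read-level simulation, alignment and variant calling are deliberately out
of scope — the table is the interface to any upstream caller.

What the generator does *not* emulate: transcriptional burstiness shared
between expression level and allele sampling (depth is independent of the
gene's expression), embryo-level genealogy, fluctuating allele-specific
expression, or reference-mapping bias. Passing recovery tests therefore
show that the statistics recover the designed signal under idealized
sampling, not that any real dataset has that signal.

## RNA-FISH quantification

A `NucleusImage` is a pair of 3D intensity arrays with voxel dimensions in
micrometres; all geometry is computed in micrometres on the anisotropic
grid.

* `computeThreshold()` is Otsu's method on a 256-bin histogram spanning the
  channel's intensity range: the returned bin edge maximizes between-class
  variance, deterministically (ties to the smallest edge). A constant
  image raises an error rather than fabricating a threshold.
* `segmentClouds()` labels 26-connected components of the inclusive
  above-threshold voxel set, discards components below `minVoxels`
  (default 27 voxels, about a 3×3×3 speck), and measures volume (voxel
  count × voxel volume), intensity-weighted centroid, integrated
  intensity and dispersion, ordering clouds by integrated intensity.
* the dispersion of a voxel set with intensities $w_i$ at positions $x_i$
  is
  $$D = \frac{\sum_i w_i \lVert x_i - \bar{x}_w \rVert / \sum_i w_i}{r_{\mathrm{eq}}},
  \qquad r_{\mathrm{eq}} = \left(\frac{3V}{4\pi}\right)^{1/3},$$
  the mean intensity-weighted distance to the centroid in units of the
  equivalent-sphere radius. It is 0 for a single voxel, 3/4 for a uniform
  ball in the continuum limit (the analytic calibration point asserted at
  radius 20 voxels within ±0.02), translation-invariant exactly and
  scale-invariant up to discretization. The published dispersion metric is
  defined only schematically, so this concrete, scale-free stand-in is the
  package's own; published absolute dispersion values are consequently not
  comparison targets, while the qualitative contrast (dispersed naive
  signal > compact primed signal) maps onto the generator's `cloudSpread`
  knob. `signalDispersion()` evaluates $D$ over the union of all segmented
  clouds of a channel, so a signal that scatters into fragments scores
  high — the per-nucleus quantity used by the pipeline.
* `colocalize()` ranks paired intensities over the *union* of the two
  above-threshold sets. The union, not the intersection, is deliberate:
  with spatially separated signals each channel is bright where the other
  is background, which the intersection would delete, erasing exactly the
  anticorrelated regime of interest. Spearman is undefined (flagged) below
  3 usable voxels or zero variance. `colocalizeNuclei()` reports the
  per-nucleus scores and their median. 3D is used throughout; a 2D
  variant via max-projection can be had by passing projected arrays.
* `countCloudPatterns()` clips per-channel cloud counts to {0, 1, 2+} and
  tabulates them per group with positive fractions; `fractionTrend()`
  relates positive fractions to an ordered group ranking by Spearman
  correlation; `comparePatterns()` tests two groups' category counts by
  Fisher's exact test (exact r×c enumeration up to a grand total of 30,
  chi-square with a warning beyond). Categories never observed in either
  group are dropped before testing; a remaining zero margin yields p = 1
  with a warning.

One practical guard in `countCloudPatterns()`: when a channel's
above-threshold set covers more than a quarter of the image, the channel
is treated as signal-free. Otsu always returns some threshold; on a
pure-noise channel it splits the noise distribution itself, flooding half
the image, whereas a genuine cloud occupies a small fraction of the
nucleus volume. The guard converts that failure mode into the correct
"zero clouds" answer and is irrelevant whenever true signal is present.

## The imaging-arm generator

`simulateNucleus()` builds each cloud as a sum of `nPuncta` isotropic
Gaussian puncta (σ = `punctumSigma`) whose centres scatter about the cloud
centre with standard deviation `cloudSpread` — the single knob that maps
onto measured dispersion, and the reason a puncta-based model was chosen
over a filled ellipsoid: RNA-FISH clouds are particulate accumulations of
single transcripts. Cloud centres are uniform in the nucleus sphere
(rejection-sampled with a bounded attempt count), same-channel centres
keep a minimum separation so that two-cloud nuclei are resolvable, and
channel-2 clouds are paired to channel-1 clouds displaced by
`interChannelOffset`, making overlap controllable from complete (offset 0)
to none. Gaussian background noise is added and clipped at zero.

Default geometry is a confocal-like stack: 24 z-planes of 64×64 voxels at
0.25 × 0.1 × 0.1 µm, nucleus radius 2.2 µm, background 5 ± 2 versus
punctum peak 50. The default texture — 150 puncta of σ = 0.25 µm at
`cloudSpread` 0.5 µm — makes each channel's intensity track the cloud's
smooth radial density rather than punctum-level shot noise; this is the
co-accumulation regime the embryo images show, and it is what makes
co-localization positive at offset 0. With very few, very sharp puncta the
two channels sample the same territory but not the same voxels, and the
per-nucleus correlation honestly degrades toward zero — a texture regime,
not a bug. The generator does not model an optical PSF beyond the
Gaussian puncta, chromatic aberration, or nucleus segmentation from
multi-cell fields (one nucleus per image).

TIFF output is one file per nucleus, z-planes interleaved by channel as
32-bit float pages, with a plain-text JSON sidecar holding voxel size,
channel order, intensity scale and ground truth — bit-exact apart from the
float32 representation and readable by any TIFF stack reader.

## Workflows and reproducibility

`runScrnaPipeline()` and `runFishPipeline()` chain simulate → analyze →
report; `runPipeline()` drives both from a YAML run configuration with
per-arm `enabled` flags (the package functions are the primary interface;
`inst/scripts/run-pipeline.R` is a thin shell wrapper). Every output table
carries the seed and an MD5 hash of the configuration in a header comment;
run logs are step-numbered without wall-clock timestamps, a deliberate
choice so that two runs with the same configuration and seed are
byte-identical — asserted in the acceptance suite. Any pipeline failure
names its stage and the configuration fingerprint.

Problem sizes used by the validation suite and the acceptance script are
deliberately moderate — e.g. 4 stages × 40 female cells with 60 X-linked
and 60 autosomal positions for the stage-trend recovery, 30 cells per
group for the two-group comparison, 100 or 200 simulation seeds for
calibration checks, 15–20 nuclei per imaging condition — the scale at
which the designed effects are comfortably detectable and the whole suite
runs in minutes on one core.

## Known limitations

* The bi-allelic score treats positions as exchangeable; linked positions
  within one gene are not modelled, so effective degrees of freedom are
  optimistic when many positions tag few genes.
* The "normalized by coverage" formula of the original analysis is not
  printed; both candidate normalizations are implemented and the
  proportion is the documented default.
* The dispersion metric is a stand-in with the correct invariances and
  calibration, not the published (schematic) definition; only qualitative
  contrasts are comparable.
* Sex inference from expression is out of scope; metadata carry sex as
  given. Phasing, imprinting and eQTL analyses are likewise out of scope.
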