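# XCIquant

Quantitative analysis of the onset of X-chromosome inactivation (XCI) in
early human embryos and naive pluripotent stem cells, built around two
measurement arms:

* **Allele-specific single-cell RNA-seq.** Per cell and chromosome, the
  package scores X activity as the coverage-normalized fraction of
  heterozygous positions expressed from both alleles,

  *S* = #{covered positions with min(ref, alt)/(ref+alt) ≥ *t*} / #{covered positions},

  with a depth filter per position and the allelic-ratio threshold *t*
  (default 0.2) exposed to sensitivity sweeps. Two active X chromosomes
  give a high X score; initiation of XCI erodes it while autosomes stay
  flat. Around the score: Wilcoxon rank-sum comparisons (exact by
  enumeration for small samples), stage trends with Spearman rank
  correlation, per-gene mono-/bi-allelic classification with Fisher's
  exact test, XACT-positive/negative cell classification, and an
  empirical gene-null that places the XIST–XACT correlation inside the
  distribution of XIST correlations with all X-linked genes.

* **Two-colour 3D RNA-FISH.** Per-nucleus computed intensity thresholds
  (Otsu, 256 bins), 26-connected cloud segmentation with volume in µm³,
  a scale-free dispersion measure (mean intensity-weighted distance to
  the centroid over the equivalent-sphere radius: 0 for a point, 3/4 for
  a uniform ball), per-nucleus co-localization (Spearman over the union
  of above-threshold voxel sets), cloud-count patterns clipped to
  {0, 1, 2+} with positive-fraction trends, and contingency comparisons.

Because the original embryo datasets are external, both arms come with
seed-deterministic synthetic-data generators carrying full ground truth
(ZGA-timed focal-gene activation, copula-tuned XIST–XACT correlation,
stage-eroding bi-allelic fractions, lineage-specific silencing; Gaussian
punctum clouds with controllable spread and inter-channel offset), so
every statistic is validated by recovery tests. The methods vignette
(`vignettes/xci-quantification.Rmd`) documents the models, parameter
choices and limitations.

## Worked example

Simulate a four-stage, all-female series whose X bi-allelic fraction
erodes from 0.5 to 0.15, score it, and test the trend:

```r
library(XCIquant)

cfg <- ScrnaSimConfig(seed = 2L, nEmbryos = 4L, cellsPerEmbryo = 30L,
    stages = c("8cell", "morula", "earlyblast", "lateblast"),
    zgaStage = "8cell", sexRatio = 1,
    biallelicFractionByStage = c("8cell" = 0.5, morula = 0.4,
                                 earlyblast = 0.3, lateblast = 0.15),
    nPositionsPerChrom = c(X = 80L, "7" = 80L),
    nGenesPerChrom = c(X = 30L, "7" = 30L))
ds  <- simulateExpression(cfg)
tab <- simulateAlleleCounts(ds, cfg)
bs  <- callBiallelic(tab, CallParams())

s  <- biallelicScores(bs)
s  <- merge(s[s$chrom == "X", ],
            as.data.frame(SummarizedExperiment::colData(ds))[, c("cell_id", "stage")])
tr <- stageTrend(s$score, s$stage, stageLevels(ds))
tr$perStage
#>       stage  n    median         q1        q3
#>       8cell 30 0.4604555 0.44325397 0.4982877
#>      morula 30 0.3972603 0.35506281 0.4177606
#>  earlyblast 30 0.2907609 0.26426983 0.3309859
#>   lateblast 30 0.1276660 0.09459459 0.1572365
tr$trend_r
#> -0.91
```

The per-stage medians track the generated erosion (0.5 → 0.15) closely —
the score is a proportion on the same scale as the latent bi-allelic
fraction, shrunk slightly toward the mono-allelic side by finite depth —
and the first-versus-last-stage rank-sum test gives p = 3e-11. Placing
the XACT-like gene inside the XIST gene-null:

```r
fg <- focalGenes(ds)
correlationNull(ds, fg[["focal1"]],
    setdiff(rownames(ds)[SummarizedExperiment::rowData(ds)$chrom == "X"],
            fg[["focal1"]]),
    fg[["focal2"]])
#> CorrelationNull: focal1 vs 31 partners ( 120 cells )
#>   focal partner focal2: r = 0.631, quantile = 1.000 (median r = -0.023)
```

The focal pair (generated at Spearman 0.7) sits above every background
X-linked gene, whose correlations centre on zero. The imaging arm runs
the same way: `simulateNucleus()` / `simulatePopulation()` produce
nuclei, `computeThreshold()`, `segmentClouds()`, `signalDispersion()`,
`colocalizeNuclei()` and `countCloudPatterns()` measure them, and
`comparePatterns()` / `compareMeasurements()` test group contrasts.
End-to-end runs with TSV/JSON reports: `runScrnaPipeline()`,
`runFishPipeline()`, or `runPipeline()` driven by a YAML config
(`inst/scripts/run-pipeline.R` is a shell wrapper).

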