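# epiclock

Epigenetic age prediction from nanopore methylation frequencies.

`epiclock` is an R package for building a methylation clock from
long-read (nanopore) CpG methylation calls in livestock cohorts, where
birthdates are often unknown and sequencing coverage is modest. It is
aimed at quantitative geneticists and epigenomics analysts who have
per-sample methylation frequency tables (the nanopolish/f5c dialect), a
gene annotation, and sample metadata, and want a cross-validated age
predictor plus gene-level methylation–age association tests.

## The method

1. **Windows and binarization.** Per-site methylation frequencies are
   aggregated into 100 bp windows (unweighted mean over motif groups)
   and binarized: mean > 0.5 → 1, < 0.5 → 0, no coverage (or an exact
   tie) → NA. Columns called in fewer than 80% of samples or with
   standard deviation below 0.5 are removed.
2. **Methylation relationship matrix.** With the filtered,
   column-mean-imputed matrix X (n samples × m windows),

   MRM = X X′ / m

   — the methylation analogue of a genomic relationship matrix. MRM-1
   uses all filtered windows; MRM-2 only windows overlapping a supplied
   (e.g. cross-species conserved) gene set.
3. **MeBLUP.** Age is modelled as
   `age = µ + herd + animal + error`, with `animal ~ N(0, σ²ₐ · MRM)`.
   Variance components are estimated by REML (eigendecomposition of the
   MRM, profiled restricted likelihood over the variance ratio), and
   ages of held-out samples are predicted through their MRM covariances
   with the training samples. Cross-validation masks folds of 5 samples
   (samples of the same animal stay together); accuracy is the Pearson
   correlation of pooled predictions vs actual age, with mean absolute
   deviation reported for the <3, 3–10 and ≥10 year classes.
4. **Gene association.** Per gene, methylation is the read-level
   percentage 100·C_m/C over the gene body; each gene is tested with
   `age ~ percent + (1 | herd)` (Satterthwaite p-values,
   Nakagawa–Schielzeth marginal R²), a gene counts as significant only
   if its slope sign matches the expected direction, and enrichment of
   the significant set is an exact binomial upper tail.

A synthetic-data generator with known ground truth (age-dependent
"switching" clock sites, herd-by-site confounding, coverage-driven
missingness, binomial sampling noise) emulates the cohort structure the
analysis assumes and drives the validation suite.

## Worked example

Simulate a cohort with the default study conditions (66 animals in 5
herds, ages 0.35–15.7 years, 18 repeat samples → 84 samples), build the
clock and test the genes:

```r
library(epiclock)

cfg <- simConfig(seed = 42)
study <- simulateStudy(cfg, file.path(tempdir(), "demo"))

wcm <- windowCallMatrix(study$records, windowSize = 100,
  sampleOrder = study$metadata$sample_id)
wcm
#> WindowCallMatrix: 84 samples x 1570 windows (100 bp), 10.0% missing

filt <- filterVariability(filterCallRate(wcm, 0.8), 0.5)
mrm <- computeMRM(imputeMissing(filt))
mrm
#> MethylationRelationshipMatrix (as_stated): 84 samples, m = 41 sites
#>   mean diagonal 0.4695, mean off-diagonal 0.2451

cv <- crossValidate(study$metadata, mrm, foldSize = 5, seed = 1)
cv
#> CrossValidationResult: 17 folds, 84 samples
#>   accuracy (pooled r) = 0.943 +/- 0.038
#>   MAD by age class (years): <3: 2.22, 3-10: 1.32, >=10: 0.90
```

Only 41 of 1570 windows survive filtering: the SD ≥ 0.5 rule keeps just
the windows split nearly 50/50 across samples, i.e. the ones that
switch methylation state inside the cohort's age range — which is why
the clock built on them predicts age well (pooled correlation 0.94 on
this synthetic cohort). The MAD rows give the mean absolute prediction
error per age class in years.

```r
genes <- readGeneAnnotation(study$paths$gff3)
conserved <- readConservedGeneList(study$paths$geneList)
prof <- filterGeneCoverage(geneMethylationPercent(study$records, genes), 10)
scan <- classifySignificance(geneAssociationScan(prof, study$metadata),
  conserved)
sum(scan$significant_nominal)
#> [1] 10
enrichmentTest(sum(scan$significant_nominal), nrow(scan))
#> [1] 2.068331e-05
```

All 10 truly age-associated genes (and none of the 30 decoys) are
recovered; 10 significant genes of 40 tested at α = 0.05 gives an
exact binomial enrichment p of 2.1e-5.

The same analysis runs end to end, with a JSON manifest of parameters
and output checksums, via `runPipeline(list(seed = 42), "run_dir")`, or
from a shell through the thin wrapper `inst/cli/epiclock.R`.

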