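---
title: "Methods: methylation relationship matrices and MeBLUP age prediction"
author: "epiclock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: methylation relationship matrices and MeBLUP age prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiclock)
```

## The problem

Epigenetic clocks predict an individual's chronological age from DNA
methylation. In extensively grazed cattle, birthdates are often unknown,
and tail-hair samples sequenced on portable long-read devices yield
per-site CpG methylation frequencies at modest coverage. `epiclock`
implements the full analysis for such data: from per-sample methylation
frequency tables to a cross-validated age predictor and gene-level
methylation–age association tests.

Unlike array-based clocks fitted by penalised regression on individual
CpGs, the approach here is a *relationship-matrix* method borrowed from
genomic prediction: samples that share methylation state across many
genomic windows are treated as "related", and age is predicted by best
linear unbiased prediction (BLUP) through that similarity structure. It
is robust to the patchy, low-coverage site sets typical of nanopore
methylomes because no individual site needs to be observed in every
sample.

## From frequencies to the call matrix X

1. **Windowing.** Each CpG motif group with 0-based start $s$ is
   assigned to window $\lfloor s / w \rfloor$ of its chromosome, with
   $w = 100$ bp by default and windows anchored at coordinate 0 (the
   anchor is a convention; nothing downstream depends on it). The
   window value for a sample is the *unweighted* mean of the site
   frequencies in it — a mean over motif groups, not reads, so a deeply
   covered site does not dominate its window.
2. **Binarization.** A window is called methylated (1) when its mean
   frequency exceeds 0.5 and unmethylated (0) below 0.5. A mean of
   exactly 0.5 carries no directional evidence and is recorded as
   missing rather than forced to either state. Windows without coverage
   are missing.
3. **Filtering.** Columns of the sample × window matrix are removed
   when called in fewer than 80% of samples (boundary inclusive: exactly
   80% survives) or when their standard deviation falls below 0.5
   (boundary inclusive: exactly 0.5 survives).

The SD filter deserves a note, because on a 0/1 column the denominator
matters materially: the population SD (denominator $n$) of a binary
column never exceeds 0.5 and attains it only at an exact 50/50 split, so
that reading would discard essentially every window. With the sample SD
(denominator $n-1$, the default here) near-balanced columns clear the
threshold, which makes 0.5 a satisfiable — and in fact very stringent —
variability cut: the windows that survive are those split close to
evenly between methylated and unmethylated samples, i.e. exactly the
windows that switch state somewhere inside the cohort's age range. Both
the denominator and whether the SD is computed over observed entries
only or after imputation are exposed as options of
`filterVariability()`.

Coordinates follow Bioconductor conventions internally: gene and window
intervals are `GRanges` (1-based, closed). The frequency-file dialect's
0-based starts are converted at the read boundary, and all overlap
semantics (windows are half-open in 0-based terms; a gene starting at a
window's end does not overlap it) are preserved and tested.

## The methylation relationship matrix

With the filtered matrix $X$ ($n$ samples × $m$ windows, missing calls
imputed by their column mean), the methylation relationship matrix is

$$\mathrm{MRM} = \frac{X X'}{m}.$$

This is the literal construction (`variant = "as_stated"`): on 0/1
calls, entry $(i,k)$ is the fraction of windows at which samples $i$
and $k$ are *both* methylated, so all entries lie in $[0, 1]$ and the
diagonal is each sample's methylated fraction. GRM tools from genomic
prediction (e.g. GCTA) instead centre and standardise the columns
first; both constructions cannot be in force at once, so the literal
formula is the default and `variant = "centered_standardized"` is
provided for sensitivity analysis. Column-mean imputation is the
minimal-assumption completion and keeps the matrix a Gram matrix, hence
positive semidefinite, which the class validity enforces.

Two matrices are built in the pipeline: MRM-1 from all filtered windows
and MRM-2 from the windows overlapping a supplied gene set (the
conserved dog/human clock genes in the motivating application — taken
as an input list, deliberately *not* re-selected on the analysis data,
which would leak information into the cross-validation).

## MeBLUP: the mixed model

Age is modelled as

$$\text{age} = \mu + \text{herd} + \text{animal} + e,$$

with $\mu$ and herd fixed, $\text{animal} \sim N(0, \sigma^2_a\,
\mathrm{MRM})$ and $e \sim N(0, \sigma^2_e I)$. Herd is included to
separate environment-driven methylation differences from the
chronological signal; the largest herd is the reference level, and an
optional season effect is off by default. Variance components are
estimated by REML:

* the (ridge-stabilised) MRM is eigendecomposed once,
  $K = U D U'$, rotating the model so the covariance is diagonal;
* the total variance is profiled out analytically and the restricted
  likelihood is maximised over the single ratio
  $h = \sigma^2_a / (\sigma^2_a + \sigma^2_e)$ on a 201-point grid
  followed by golden-section polishing to $|\Delta h| < 10^{-6}$;
* fixed effects and BLUPs come from the mixed-model equations at the
  optimum, $\hat u = \hat\sigma^2_a K V^{-1}(y - X\hat\beta)$.

A ridge of $10^{-6} \times \overline{\mathrm{diag}(K)}$ is added to the
MRM diagonal at solve time only; it is part of the solver contract (the
test oracles use the same ridged matrix) and never stored on the MRM.
The implementation is checked against dense-matrix oracles — explicit
$V = \sigma^2_a K + \sigma^2_e I$, determinants and generalized least
squares — to $10^{-8}$ on small fixtures.

**Masked prediction.** Validation samples have their ages removed but
stay in the MRM: REML and fixed effects are re-estimated on the
training samples, and the masked samples' effects are predicted through
their covariances, $\hat u_m = \hat\sigma^2_a K_{mt} V_{tt}^{-1}
(y_t - X_t \hat\beta)$ — the conditional expectation of the unobserved
effects. Predicted age is the estimable fixed-effect part plus
$\hat u_m$; a masked sample from a herd unseen in training falls back
to the intercept with a warning.

**Cross-validation.** Samples are partitioned into
$\lceil n / 5 \rceil$ folds under a seed — taking the "until all
animals had been dropped" coverage requirement as binding and the
nominal repeat count as approximate — and all samples sharing an
`animal_id` are kept in one fold, since repeat samples of an animal
have near-duplicate methylation profiles and would otherwise leak
across the split. Variance components are re-estimated within every
training fold (the conservative choice). Accuracy is the Pearson
correlation of the *pooled* out-of-fold predictions against actual age
(the per-fold mean is also retained); its standard error is the SD of
per-fold correlations divided by $\sqrt{\text{folds}}$, one reasonable
definition among several since fold-level correlations on 5 samples are
noisy. Mean absolute deviation is summarised in the age classes
$<3$, $3\!-\!10$ and $\ge 10$ years.

## Gene-level association

For each gene, methylation is the read-level percentage
$100 \cdot C_m / C$, where $C_m$ and $C$ sum the methylated and total
CpG calls of every motif group overlapping the gene body (introns
included; a `flank` option, default 0, widens the span). Counting
read-level calls rather than distinct positions follows the definition
of the percentage as a coverage-weighted quantity. Genes covered in
fewer than 11 samples are excluded (strictly more than 10 required).

Each retained gene is tested with
`age ~ percent + (1 | herd)` fitted by REML via `lme4`/`lmerTest`,
with the slope tested on Satterthwaite degrees of freedom — the same
machinery the field's gene-level analyses use. (Note the deliberate
asymmetry with the clock model, where herd is *fixed*: the two analyses
follow their own conventions.) A likelihood-ratio fallback
(`dfMethod = "lrt"`) uses the plain $\chi^2_1$ tail for the slope — no
boundary halving, which applies to variance components, not fixed
effects. The marginal pseudo-$R^2$ is the Nakagawa–Schielzeth ratio
$\mathrm{var}(X\hat\beta) / (\mathrm{var}(X\hat\beta) + \sigma^2_{herd}
+ \sigma^2_{res})$. With a single herd the model degenerates to
ordinary regression with classical degrees of freedom.

A gene counts as significant only when $p < \alpha$ *and* its slope
sign matches the direction reported for that gene in the conserved-gene
list; Bonferroni significance additionally requires
$p < \alpha / n_{\text{tests}}$. Enrichment of the significant set is
the exact binomial upper tail $P(X \ge k)$, $X \sim
\mathrm{Bin}(n_{\text{tested}}, \alpha)$. Because the direction rule
halves the effective null rate, keeping $\alpha$ in the null makes the
reported enrichment conservative.

## The synthetic-data generator

No desk-scale dataset can reproduce a 66-animal nanopore methylome, so
the package ships a generator whose defaults encode the cohort the
analysis targets: 66 animals in 5 herds, ages uniform on 0.35–15.7
years, 18 animals resampled 0.5–2 years later, ~15× mean depth and 10%
missing site–sample pairs. Methylation is generated on the logit scale
so probabilities stay in $(0,1)$:

* **Clock sites** (10% of sites by default) are switching CpGs: site
  $j$ has a transition age $a_j$ uniform over the age range and
  methylation probability $\mathrm{logit}^{-1}(\beta_j (\text{age} -
  a_j))$ with $|\beta_j|$ = `clockSlope` (default 0.3/yr). Spreading
  $a_j$ over the lifespan gives the cohort informative sites at all
  ages; with the default slope a site's transition spans several years,
  so binarized calls change gradually across the cohort. Slope signs
  are positive with probability 0.9 — most conserved clock genes gain
  methylation with age, a few lose it.
* **Background sites** draw a static baseline from Beta(0.4, 0.4),
  bimodal as in real methylomes; after binarization they are almost
  always constant and are removed by the variability filter.
* **Herd effects** are drawn per herd × site (SD 0.5 logit units), so
  herd confounds the methylation *pattern*, which is what the herd
  fixed effect in the clock model is meant to absorb.
* **Coverage** is Poisson with zero-inflation; zero-depth site–sample
  pairs are absent from the sample's file, exactly as in real frequency
  output.
* **Genes** partition the site run into contiguous blocks; each gene
  body covers the central 60% of its block (the rest is intergenic, so
  the gene-restricted MRM-2 is a genuine subset). All clock sites lie
  inside age-associated genes; the conserved-gene list contains those
  genes with their true direction plus undirected decoys.

What the generator does *not* emulate: read-level correlation and
sequence-context effects, basecalling error, CpG-island spatial
structure, non-uniform age distributions across herds, and age-related
variance changes (real clocks degrade for old animals; here old and
young are symmetric). Passing the recovery tests therefore shows the
statistical machinery is correct under the assumed generative
structure, not that real cattle methylomes meet that structure.

## Validation choices and problem sizes

The test suite validates each stage against an independent oracle:
brute-force window aggregation and interval overlap, dense-matrix REML
and conditional-expectation formulas ($n \le 12$, agreement to
$10^{-8}$), closed-form regression for the single-herd gene model, and
exact binomial summation for enrichment. Monte-Carlo checks use sizes
chosen to make the checked quantity stable at desk scale: variance-ratio
recovery over 200 replicates at $n = 300$ (mean $\hat h$ within 0.05 of
0.3/0.5/0.8), cross-validated clock recovery at $n = 200$ samples and
2000 sites with `clockSlope` 0.5 (pooled $r \ge 0.85$; permuted labels
$|r| < 0.2$), and 1000 null replicates for the gene model's type-I rate
(within [0.03, 0.07] at $\alpha = 0.05$).

## A compact run

```{r, eval = FALSE}
cfg <- simConfig(seed = 42)
study <- simulateStudy(cfg, tempdir())
wcm <- windowCallMatrix(study$records, 100,
  sampleOrder = study$metadata$sample_id)
mrm <- computeMRM(imputeMissing(
  filterVariability(filterCallRate(wcm))))
cv <- crossValidate(study$metadata, mrm, foldSize = 5, seed = 1)
cv
```

Or, as one orchestrated run with a manifest:

```{r, eval = FALSE}
runPipeline(list(seed = 42), "run_directory")
```

## Known limitations

* The REML profile is over a single variance ratio; models with more
  than one random term (beyond the residual) are out of scope.
* Column-mean imputation shrinks relationships for poorly called
  windows toward the average; with the 80% call-rate filter in force
  the effect is small, but the MRM is not an unbiased estimate of the
  complete-data Gram matrix.
* The accuracy standard error is computed from per-fold correlations of
  ~5 predictions each, which are individually very noisy; treat it as
  an order-of-magnitude guide.
* `filterVariability()`'s default assumes the sample-SD reading of the
  0.5 threshold; the population-SD alternative removes nearly all
  windows and is provided only for comparison.
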