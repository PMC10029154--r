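---
title: "Breed identification from SNP panels: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breed identification from SNP panels: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breedid)
```

## The problem

Domestic pig breeds are genetically structured populations: centuries of
natural and artificial selection have left breed-specific allele-frequency
profiles across the genome. Given a labelled reference panel of biallelic
SNP genotypes, breed identification proceeds in two stages — select a
subset of markers whose allele frequencies differ strongly among breeds
(the *breed-informative* markers), then fit a multi-class classifier on
those markers and assign each test animal the breed with the best model
fit. This package implements both stages, together with the supporting
machinery (genotype I/O and harmonisation, QC, cross-validation, a
rejection rule for animals from breeds absent from the reference) and a
genotype simulator that makes every stage testable end to end.

## Marker selectors

All four selectors assign one statistic per SNP; panels are the
`density` top-ranked SNPs (ties broken by chromosome and position so
panels are reproducible).

**Average Euclidean distance (AED).** With breed allele frequencies
$f_1,\dots,f_T$,
$$\mathrm{AED} = \frac{1}{\binom{T}{2}}\sqrt{\sum_{i=1}^{T}\sum_{j>i}^{T}(f_i-f_j)^2}.$$
A marginal, frequency-only statistic: zero when all breeds agree, bounded
by $\sqrt{\binom{T}{2}}^{-1}\cdot\sqrt{\binom{T}{2}} \le 1$.

**Weir–Cockerham $F_{ST}$.** The per-SNP multi-population estimator
$\hat\theta = a/(a+b+c)$ built from the among-population ($a$),
among-individual-within-population ($b$) and within-individual ($c$)
variance components, computed from observed genotype and heterozygote
counts with the exact finite-sample corrections of the 1984 estimator.
$\hat\theta$ can be slightly negative when there is no differentiation;
ranking uses the signed value, so undifferentiated SNPs sort below zero
and monomorphic SNPs (undefined denominator) get a missing score and rank
last.

**PCA loadings.** PCA of the breeds × SNPs frequency matrix with SNP
columns mean-centred and unscaled (the default of `prcomp`). The score of
a SNP is the sum of its squared entries over the first
$\min(10, T-1)$ eigenvectors; by orthonormality the scores over all SNPs
sum to the number of components used, which the tests exploit as an exact
invariant. Breeds are rows so that SNP loadings live in the eigenvectors.

**PLSR coefficients.** Breed labels are one-hot coded into a $T$-column
response and regressed on the genotype dosage matrix by partial least
squares (SIMPLS; predictors and responses mean-centred, unscaled —
dosages all live on the same 0–2 scale, so variance scaling would only
amplify noise at rare alleles). The score of a SNP is the sum over breeds
of its squared regression coefficients. The component count defaults to
150, capped at $\min(150, n-1, p)$; 150 presumes reference panels of
thousands of animals, and the cap is what makes the method defined on
small panels.

A note on collinearity: a multivariate regression splits weight across
duplicated predictors, so two *identical* marker columns each receive
half the coefficient a lone copy would get. This matters for synthetic
benchmarks (see the simulator section) but rarely for real panels, where
exact genotype duplicates are uncommon; the three marginal selectors are
insensitive to it.

## Classifiers

Six classifiers share one train/predict contract (`fit_classifier` /
`predict`); all operate on mean-imputed genotype dosages restricted to a
marker panel.

| name  | method | defaults |
|-------|--------|----------|
| KNN   | k-nearest neighbours, Euclidean distance | $k = 5$ |
| NSC   | nearest shrunken centroids | shrinkage $\Delta = 30$ |
| PLSDA | PLS regression on one-hot labels + softmax | 150 components |
| RF    | random forest | 500 trees, $\mathrm{mtry} = \lfloor\sqrt{p}\rfloor$ |
| SVMp  | SVM, polynomial kernel, one-vs-one | degree 3, $\gamma = 1/p$, cost 1 |
| SVMr  | SVM, radial kernel, one-vs-one | $\gamma = 1/p$, cost 1 |

Choices worth stating:

- **KNN k.** Published descriptions of this family of pipelines disagree
  internally between $k=5$ and $k=3$; the package defaults to $k = 5$ and
  exposes `k`. Ties among equally frequent neighbour labels go to the
  label of the nearest neighbour among the tied classes — deterministic
  and distance-respecting, where off-the-shelf implementations randomise.
- **NSC.** Centroids are standardised by the pooled within-breed SD plus
  the usual positive offset $s_0$ (the median of the per-SNP SDs; when
  that is zero — perfectly separable toy data — a small positive fallback
  keeps the discriminant defined), then soft-thresholded toward the
  overall centroid. A shrinkage large enough to collapse all centroids
  triggers a warning and degenerate (constant) predictions rather than an
  error.
- **SVM scaling.** Features are standardised with training-set mean/SD
  and the identical transform is applied to test data; zero-variance
  features are left centred.
- **PLS-DA probabilities.** Raw per-breed PLSR predictions $s_b$ are
  mapped through the softmax $p_b = e^{s_b}/\sum_c e^{s_c}$ (computed
  with max-subtraction for numerical stability; invariant to adding a
  constant to all scores). Only PLS-DA yields probabilities; the other
  classifiers return hard labels and therefore cannot drive rejection.
- **Random forest** is the only stochastic classifier; `fit_classifier`
  seeds it explicitly so repeated fits are identical.

## Rejecting unknown breeds and crossbreds

An animal whose true breed is absent from the reference is still forced
into some reference breed by any closed-set classifier. The rejection
rule re-labels an animal `"unknown"` when its highest PLS-DA softmax
probability falls strictly below a threshold; `NA` disables the rule.

The threshold is *not* scale-free: over $T$ training breeds the softmax
maximum is bounded below by $1/T$, and a confidently assigned animal
(raw prediction $\approx 1$ for one breed, $0$ elsewhere) reaches about
$e/(e+T-1)$. The informative range of the threshold is therefore the
interval $(1/T,\ e/(e+T-1))$, which for $T \approx 90$–$125$ breeds is
roughly $(0.008, 0.03)$ — hence the conventional default of $0.02$ and
sweep grid $0.010$–$0.030$ used with reference panels of that size, both
kept as defaults here. With few reference breeds the same absolute
default is inert (nothing can fall below it): for, say, $T = 18$ the
attainable range is $(0.056, 0.137)$ and a sensible operating point is
its midpoint. `threshold_sweep` traces the pure/unknown/crossbred
trade-off over any grid; pure-breed accuracy is non-increasing and
unknown/crossbred detection non-decreasing in the threshold, by
construction.

## Cross-validation

`repeated_cv` runs stratified $k$-fold CV repeated $r$ times (defaults
$5\times 5$; repeat $i$ shuffles folds with `seed` $+ i$, so repeats are
distinct yet reproducible). Within every fold the selector statistic is
computed on the training portion *only*, the panel built, the classifier
trained, and the held-out animals predicted; test-fold missing genotypes
are completed with training-fold means. Nesting the selection inside the
folds costs accuracy relative to selecting once on all data, but
unnested selection leaks held-out information into the panel and inflates
CV estimates; the test suite verifies the nesting directly by planting a
SNP whose informativeness lives only in one fold and asserting it never
enters that fold's panel. Accuracy is reported per individual (micro);
per-breed (macro) accuracies and a pooled confusion table come along for
diagnostics. For PLS-DA inside CV the argmax label is used — rejection is
an identification-time concern, not a CV one.

## The identification workflow

`identify_breeds` chains the full pipeline: normalise SNP ids on both
sides to `Chr:Pos:allele1:allele2` (alleles in ascending byte order, so
ids are strand-naive but orientation-proof), intersect upload and
reference by id, recode upload genotypes $g \to 2-g$ wherever the upload
counted the other allele, then — if the intersection holds at least
`n_select` SNPs (default 5000) — run the selector (PLSR) on the
reference restricted to the common SNPs and keep the top `n_select`;
otherwise skip selection and use every common SNP. The skip rule is
strict: exactly `n_select` common SNPs still triggers selection. A
common-SNP count below 200 (the smallest panel density worth using)
warns prominently rather than refusing. PLS-DA is then trained on the
reference panel and the upload predicted with softmax probabilities and
the rejection threshold.

`design_panel` serves the inverse need: given target breeds and a
density it returns the most discriminating panel plus an automatic
five-fold CV report. Multiple targets restrict the reference to those
breeds; a single target poses a two-class problem (target versus all
other reference breeds pooled), which for PLSR means a single-response
regression.

`build_reference` merges several labelled datasets by normalised-id
intersection, harmonises allele orientation to the first dataset, stacks
individuals and applies QC.

## Quality control and imputation

QC applies, in order: removal of sex-chromosome SNPs (labels
`X, Y, 23, 24` by default, covering the common pig-data dialects), then
SNPs with overall MAF below 0.01, then breeds with fewer than 10
individuals. The report counts removals per step so the arithmetic is
auditable.

Missing genotypes are imputed as the per-SNP mean dosage of observed
genotypes. A haplotype-based imputation engine would use linkage
information the classifiers here do not need: classification operates on
marginal dosages, for which the mean is the deterministic, unbiased
completion. This is a deliberate simplification and is the one place the
package's preprocessing is weaker than a production imputation pipeline;
with the low missingness typical of chip data (~1%) the effect on
accuracy is negligible.

## The simulator

`simulate_breed_frequencies` implements the Balding–Nichols drift model:
per SNP an ancestral frequency $p$ is drawn uniformly from
$[0.05, 0.5]$ (assigned to either allele at random; the lower bound
keeps quasi-monomorphic SNPs from dominating) and each breed draws its
frequency from $\mathrm{Beta}\!\left(p\frac{1-F}{F},\,
(1-p)\frac{1-F}{F}\right)$ — mean $p$, variance $F\,p(1-p)$, so the
drift parameter $F$ is interpretable as the expected between-breed
$F_{ST}$. Genotypes are Binomial(2, breed frequency) (Hardy–Weinberg
within breeds), missingness is independent per entry (MCAR), F1
crossbreds draw one allele from each parental breed, and
`spike_informative_snps` plants ground-truth informative markers by
pushing chosen SNPs toward opposite fixation between target breeds and
the rest. Positions are laid out sequentially on autosomes 1–18 (pig
autosome count; sex chromosomes deliberately absent) so PLINK export is
valid. Everything is reproducible from a single seed.

What the simulator does *not* emulate: linkage disequilibrium, pedigree
structure beyond F1 crosses, genotyping error, selection signatures, and
strand ambiguity. Passing tests on simulated panels therefore
demonstrate the correctness of the statistics and the plumbing and the
qualitative behaviour of the pipeline (accuracy rising with density and
divergence, rejection separating out-of-reference animals), not the
absolute accuracies attainable on real chip data, where between-breed
structure is less clean than any exchangeable drift model.

When spiking markers for selector benchmarks, give each spiked SNP its
own target breed (breed-specific markers, the structure of real
ancestry-informative panels). Spiking many SNPs with the *same* breed
split at full fixation manufactures byte-identical genotype columns, and
a multivariate selector (PLSR) then divides the weight among the
duplicates — a property of degenerate collinearity, not of marker
informativeness.

## Numerical choices and degenerate inputs

- Softmax uses max-subtraction; SIMPLS deflates the cross-product matrix
  with re-orthogonalisation against all previous loadings and stops early
  (with the component count recorded) when the residual response variance
  is numerically zero.
- Panel ranking places missing scores last and breaks score ties by
  (chromosome, position); chromosome labels sort numerically when
  numeric, alphabetically after the numbered ones otherwise.
- Monomorphic variant records (`allele1 == allele2`) cannot be id-ordered
  and are flagged, never silently renamed; A/T and C/G markers are
  matched by id as-is and listed in the harmonisation report, never
  strand-flipped (the id scheme cannot distinguish strand, and a silent
  flip corrupts data).
- An all-missing SNP is an error naming the SNP (impute cannot proceed);
  an empty PLINK sample set is refused at write time; a `.bed` without
  the `6c 1b 01` magic/mode bytes is a format error, as is a payload size
  inconsistent with the `.bim`/`.fam` dimensions.
- `write_plink` refuses fractional (imputed) dosages, which the 2-bit
  format cannot carry.

## Problem sizes used in the checks

The test suite and the acceptance script exercise the pipeline at sizes
chosen to mirror a mid-sized breed study while staying desk-scale: 20
breeds × 30 individuals at 10,000 SNPs for cross-validation and rejection
(drift 0.15, a typical between-breed value for pigs), 5,000 SNPs with 50
spiked markers at background drift 0.02 for selector recovery, and 20,000
SNPs × 2 breeds × 300 individuals for drift calibration. Larger panels
change runtimes, not conclusions: every statistic is either exact per SNP
or stabilises by the law of large numbers well below these sizes.

## Known limitations

- Rejection probabilities come from softmax of PLSR scores and are not
  calibrated probabilities; the threshold is an operating point chosen on
  a sweep, and its meaningful range depends on the breed count (see
  above). With few reference breeds, absolute thresholds quoted for
  ~100-breed references do not transfer.
- Mean imputation ignores linkage; heavy missingness (tens of percent)
  would blur breed signal that haplotype imputation could recover.
- Only biallelic SNPs are modelled; indels and multiallelic records are
  skipped at VCF import.
- The package ships no reference panel; users supply their own labelled
  data or simulate one.
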