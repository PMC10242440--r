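---
title: "Cross-cohort meta-analysis of diet-associated gut microbiome SGBs"
author: "sgbMeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-cohort meta-analysis of diet-associated gut microbiome SGBs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgbMeta)
library(SummarizedExperiment)
```

## The problem

Single-cohort mouse microbiome studies of dietary fat disagree with each
other: cohorts differ in diet formulation (the high-fat arms in public
studies span roughly 40–60% of calories from fat, the low-fat arms 5–17%),
mouse strain, age, sampling body site and sequencing depth, and study
identity typically explains more of the community variance than the diet
itself. `sgbMeta` implements the statistical machinery for asking which
species-level genome bins (SGBs) — including uncharacterized ones known only
from metagenome-assembled genomes (uSGBs) — are *reproducibly* associated
with a high- versus low-fat diet across many independent cohorts, and
whether those associations support cross-cohort prediction.

The data model is a `SummarizedExperiment` subclass, `SGBProfiles`: one
assay of relative abundances on the percent scale, feature annotation
(taxonomy string, kSGB/uSGB flag) in `rowData`, and curated per-sample
covariates (dataset, diet class, fat percentage, diet duration, age, sex,
strain, body site, antibiotic use, mouse, timepoint) in `colData`.

## The model

### Per-dataset effect models

Abundances are variance-stabilized with the arcsine-square-root transform
$y = \arcsin\sqrt{x/100}$. Within each dataset, every feature is fit by
ordinary least squares

$$y \sim \mathrm{age} + \mathrm{body\ site} + \mathrm{strain} +
  \mathrm{antibiotics} + \mathrm{sex} + \mathrm{diet},$$

with the diet indicator coded high-fat = 1, so positive effects mean
higher abundance under high fat. Covariates that are constant within a
dataset (a single-sex cohort, one body site) are dropped before fitting;
features with zero residual variance return a missing record rather than a
spurious $t = 0$. Sex is included by default although formulations differ
in whether they list it; a reduced covariate vector reproduces the smaller
model. The Wald $t$ of the diet term is converted to a standardized mean
difference (a Cohen's-d-type quantity) via

$$d = \frac{t\,(n_1+n_2)}{\sqrt{n_1 n_2}\sqrt{df}}, \qquad
  se_d = \sqrt{\frac{n_1+n_2-1}{n_1+n_2-3}\cdot\frac{4}{n_1+n_2}
  \left(1+\frac{d^2}{8}\right)},$$

the adjusted-SE variant of the classic conversion; the formula is
centralized in `tToSMD()` so an alternative variant can be swapped in one
place.

### Random-effects pooling

Per-dataset SMDs are pooled with inverse-variance random-effects weights
$w_i = 1/(v_i + \tau^2)$, where $\tau^2$ is the Paule–Mandel moment
estimate: the solution of $\sum_i w_i(\tau^2)(y_i - \hat\mu(\tau^2))^2 =
k-1$, found by Newton-type iteration to a tolerance of $10^{-10}$ (at most
100 iterations, DerSimonian–Laird fallback with a warning). Confidence
intervals use the normal 1.96 multiplier. Two-sided normal p-values are
corrected with the Benjamini–Yekutieli procedure (valid under arbitrary
dependence) at an FDR level of 0.2, applied separately within each analysis
family (binary diet contrast, fat-percentage correlation, duration
correlation) and only across the features that survive the
prevalence/detection filters, so the correction family equals the reported
feature set.

Filters follow the cross-cohort reporting rules: features must exceed 20%
overall prevalence (strictly) and be detected in at least five datasets for
the binary analysis; the fat-percentage and duration correlation analyses
require detection in at least four and three datasets respectively.
Overall prevalence is the unweighted mean of per-dataset prevalences over a
fixed denominator — a dataset where the feature is never seen contributes
zero rather than being dropped.

### Fold changes, correlations

For interpretability, a fold-change meta-analysis accompanies each SMD:
zeros are replaced by $\epsilon = 10^{-4}$, values are log2-transformed,
group means differenced with the SMD-favored group first, per-dataset
variances taken as the sum of the two group-mean variances, and datasets
combined by fixed effect. The reported meta standard error is the standard
deviation of the per-dataset effects over $\sqrt{k}$ with a
$t_{k-1}$ interval — a deliberately conservative descriptive choice
retained as the primary output (`standardSE = TRUE` switches to the
conventional fixed-effect SE). Linear-scale values are $2^{x}$.

Continuous exposures (fat percentage, diet duration) use partial Spearman
correlations per dataset — Pearson correlation of rank residuals after
regressing out the ranked covariates plus the respective other exposure —
pooled on the Fisher-$z$ scale with sampling variance
$1/(n - n_{\mathrm{cov}} - 3)$ (the classic $1/(n-3)$ adjusted for the
covariates partialled out) and back-transformed.

### Diversity and variance partitioning

Alpha diversity (Shannon with natural log, Gini–Simpson, richness with a
detection threshold of abundance $> 0$) and Bray–Curtis dissimilarity are
delegated to vegan. PERMANOVA is implemented in the package because exact
small-sample inference matters here: when the number of distinct label
arrangements is at most the requested permutation count the permutation
distribution is enumerated exhaustively and the p-value is exact; otherwise
$p = (1 + \#\{F^* \ge F\})/(1 + n_{\mathrm{perm}})$ with a seeded RNG
(default 999 permutations). Multivariate structure is quantified by a
sequential (user-ordered) distance-based variance partition using the
Gower-centered trace formulation, with per-term Ezekiel-adjusted
$R^2 = 1-(1-R^2)(n-1)/(n-k-1)$, $k$ the cumulative model degrees of
freedom. A fixed, user-specified term order replaces automated stepwise
selection: it is deterministic, testable, and the quantity of interest is
the final ranking of variance fractions, with study identity entered first.
Sequential increments are exactly additive (term $R^2$ values sum to the
full-model $R^2$) and agree with `vegan::adonis2(by = "terms")` to
machine precision, which the test suite asserts.

### Classification harness

Cross-cohort predictability is benchmarked with random forests (ranger):
1000 trees, minimum leaf size 5, unlimited depth, $\sqrt{p}$ features per
split. The Gini impurity criterion is used — the package's split-criterion
choice; for these binary, probability-forest experiments it is
behaviourally interchangeable with entropy-based splitting. Three designs
fill the prediction matrix: stratified 10-fold cross-validation with 10
random repetitions (diagonal), single-cohort-to-single-cohort transfer with
10 repetitions (off-diagonal), and leave-one-dataset-out (LODO, bottom
row). Eligibility rules: baseline timepoint per mouse, antibiotic-treated
samples excluded, and at least 20 samples per diet class per dataset (a
per-class reading of the size rule; `perClass = FALSE` gives the
per-dataset-total reading). Transfers align feature spaces by ID union
with zero fill, since absence on the relative-abundance scale is a true
zero. AUC is the rank-sum (Mann–Whitney) statistic; per-cell confidence
intervals are t-based, by default with (number of AUC values − 1) degrees
of freedom (`ciDf` accepts the literal datasets × randomizations − 1
convention instead). Feature importance is rank-averaged across LODO
training runs only, so the held-out cohort never influences the ranking;
only the ensemble seed varies across repeats.

## The synthetic-data generator

`generateCohorts()` emulates the structure of the pooled public cohorts so
that every stage is testable without downloads. For feature $f$, dataset
$d$, sample $s$, a latent arcsine-scale value

$$\ell_{fds} = b_f + u_{fd} + \textstyle\sum_c \beta_{fc} x_{cs} +
  \delta_f\,\mathbb{1}[\text{high fat}] + \varepsilon_{fds}$$

is clamped to $[0, \pi/2]$, zeroed with one minus the feature's detection
probability, mapped back through $100\sin^2(\cdot)$ and renormalized to a
100% composition. Defaults (chosen once as the package's study
conditions): 6 cohorts of 20 + 20 samples, 200 features, two thirds
flagged uSGB, residual sd $\sigma = 0.03$, study-effect sd $0.05$ (study
identity dominates the variance partition, as in the real cohorts), 8
biomarkers with $\delta_f = \pm 1.0\,\sigma$ — i.e. true SMD 1.0 — three
quarters of them high-fat-associated, per-cohort fat percentages drawn
from U(40, 60) vs U(5, 17) per arm, and per-sample diet durations spread
±14 days around a per-cohort center so duration correlations are
estimable within cohorts.

Because effects are injected on the arcsine scale, the injected SMD is
exactly the estimand of the pipeline. Two deliberate simplifications:
biomarkers are fully prevalent, moderate-abundance features (baseline
0.5%), which keeps the compositional renormalization perturbation below a
few percent of the injected effect (it scales with the biomarker latent
squared times the panel size) and makes parameter recovery well defined;
and features are independent given the study effects — no phylogenetic or
ecological covariance. Real data have lower prevalence biomarkers,
correlated taxa and heavier-tailed noise, so passing recovery tests
demonstrates correctness of the estimators under the stated model, not
performance guarantees on arbitrary real cohorts.

`generateLongitudinal()` produces per-mouse trajectories across dietary
phases (N, LFD, HFD, LLFD): biomarkers approach the phase-appropriate mean
with a first-order lag (default 0.7 of the gap per timepoint), giving the
paired phase-shift tests of `evaluateTrajectories()` a known ground truth.

## Worked example

```{r example, eval = FALSE}
g <- generateCohorts(syntheticSpec(seed = 7))
res <- runBinaryMeta(g$profiles)
head(res$smd[, c("feature_id", "k", "pooled", "ci_low", "ci_high", "q")])
corr <- runCorrelationMeta(g$profiles, "fat_pct")
ml <- runML(g$profiles, rfConfig(nTrees = 200, seed = 7))
aucMatrix(ml$all$grid)
```

The README shows output from this exact sequence. At the default study
conditions the pooled biomarker SMDs centre slightly below the injected
1.0 (the compositional renormalization attenuates injected effects by a
few percent), all or nearly all of the 8 biomarkers reach $q < 0.2$, and
false positives are rare.

## Numerical choices and degenerate inputs

* Paule–Mandel: truncation at $\tau^2 = 0$ when the generalized $Q$ at zero
  does not exceed $k-1$; the solver drives $Q(\tau^2)$ onto $k-1$ to
  machine precision (tighter than some library defaults, which the
  cross-checks against metafor accommodate at $10^{-4}$).
* Bray–Curtis between two all-zero samples is 0/0; it is defined as 0 with
  a warning to avoid NaN propagation.
* Detection threshold for prevalence and richness is abundance $> 0$.
* An `UNCLASSIFIED` residual row is dropped on import and columns are
  *not* renormalized, keeping abundances comparable across samples;
  SGB-level tables are likewise not renormalized after removing
  non-terminal taxonomy rows.
* kSGB/uSGB status is inferred from the clade string (placeholder
  genus/species tokens built from GGB/SGB numeric identifiers mark
  uSGBs); a sidecar file can override the inference.
* Ties in ranks use average ranks throughout (partial Spearman, AUC,
  importance ranking).
* Degenerate designs fail loudly: rank-deficient models name the collinear
  terms, one-class datasets are skipped with a warning, constant features
  or exposures yield missing records.

## Problem sizes

The shipped tests exercise the estimators at deliberately modest sizes —
200 synthetic replicates of the 6 × 40 default conditions for recovery and
coverage, 40 global-null replicates for FDR behaviour, 200 permutation
nulls for PERMANOVA uniformity, and LODO experiments at 200 trees — chosen
so the whole suite completes in a few minutes on one core while keeping
every Monte-Carlo band wide enough for the replicate counts used.

## Limitations

* No mixed-effects or repeated-measures modelling; multiple timepoints are
  handled by baseline selection (mandatory for the ML harness, optional
  for the meta-analyses, where the default uses all timepoints).
* The fold-change meta SE convention above is descriptive rather than
  inferential; use `standardSE = TRUE` for conventional weighting.
* Whether all per-dataset p-value families should share one FDR correction
  is ambiguous in multi-analysis reporting; the package corrects per
  analysis family and flags this in the documentation.
* The variance partition reports fractions and permutation tests only — no
  constrained-ordination axes or biplots.
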