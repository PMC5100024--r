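---
title: "Models and methods for stem-carbohydrate phenotyping strategies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for stem-carbohydrate phenotyping strategies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nscpheno)
```

Stem non-structural carbohydrates (NSC — starch plus soluble sugars stored
transiently in grass stems) are a breeding target in rice because reserves
accumulated before heading can be remobilized to the filling grain. Deciding
*how* to phenotype them raises three quantitative questions that this package
addresses with one toolkit: how heritable the traits are and how correlated
genetically (a Bayesian hierarchical model with a genomic relationship
matrix), how many biological replicates a greenhouse evaluation actually
needs (a subsampling design study), and whether near-infrared spectroscopy
can replace wet chemistry at scale (a full PLS calibration workflow).

Because raw data of this kind are rarely shareable, every analysis here is
exercised end-to-end on synthetic data whose generators are first-class,
tested package code. This vignette documents the models, their assumptions,
the defaults and the numerical choices; the README shows the worked
examples.

## The hierarchical genetic model

For replicated observations $y_{ir}$ of line $i$, replicate $r$:

$$y_{ir} = \mu + a_i + d_i + \varepsilon_{ir}$$

* $a \sim \mathcal N(0, \sigma^2_a K)$ — additive genetic values structured
  by the genomic relationship matrix $K$;
* $d \sim \mathcal N(0, \sigma^2_d I)$ — i.i.d. non-additive line
  deviations (dominance/epistasis and any line-level non-genetic effect);
* $\varepsilon_{ir} \sim \mathcal N(0, \sigma^2_{e,i})$ or scaled
  Student-$t$, with line-specific variances
  $\sigma^2_{e,i} \sim \text{Scale-inv-}\chi^2(\nu_h, \sigma^2_e)$ shrunk
  towards a common scale. The hierarchy degrees of freedom `line_var_df`
  ($\nu_h$, default 4) control how much dispersion heterogeneity the model
  allows; each line's posterior error scale gives its coefficient of
  variation $CV_i = \sigma_{e,i} / |\mu + a_i + d_i|$, flagged undefined
  when the line mean is within $10^{-8}$ of zero.

Per posterior draw the package reports narrow-sense heritability
$h^2 = \sigma^2_a / (\sigma^2_a + \sigma^2_d + \bar\sigma^2_e)$ with
$\bar\sigma^2_e$ the mean line error variance, broad-sense
$H^2 = (\sigma^2_a + \sigma^2_d) / (\cdot)$, GEBVs (posterior draws of
$a_i$), line means and line CVs. The bivariate variant ties the per-line
additive pairs to $K$ through a free $2 \times 2$ genetic covariance and
gives replicate-level errors a $2 \times 2$ environmental covariance,
yielding genetic and environmental correlations as (lower, point, upper)
credible triplets. Trait pairs are fitted pairwise rather than as one joint
multi-trait model; that matches how pairwise correlation tables are
presented and keeps every fit small, at the cost of not borrowing strength
across pairs.

The GRM is the VanRaden form $K = ZZ^\top / (2\sum_j p_j(1-p_j))$ on
dosages centered at $2p_j$, with mean imputation of missing calls and
monomorphic SNPs excluded from the denominator.

### Priors

Standard deviations of the genetic components get half-$t(3, A)$ priors via
the Huang–Wand inverse-gamma mixture, with $A = 2 \times \mathrm{sd}(y)$ by
default so the prior adapts to the trait scale. The common error scale
$\sigma_e$ gets a half-Normal($A$) prior — the conjugate choice inside the
scaled-inverse-$\chi^2$ line-variance hierarchy, and practically
indistinguishable from a half-$t$ at these sample sizes. The grand mean has
a diffuse normal prior centred on the sample mean. Student-$t$ degrees of
freedom are estimated with an Exponential prior on $\nu - 2$, keeping the
error variance finite.

### Sampler

Inference is by a blocked Gibbs sampler written for this model's geometry:

* $(g, \mu)$ with $g = a + d$ are drawn jointly from their exact Gaussian
  conditional — updating the total line effect and the grand mean
  separately mixes poorly because only their sum is well determined;
* $g$ is then decomposed into $a$ and $d$ exactly in the eigenbasis of $K$
  (diagonal conditional precisions);
* $(\sigma^2_a, \sigma^2_d)$ are refreshed by a marginal Metropolis move
  with the split integrated out analytically — the one-at-a-time conjugate
  updates are valid but nearly reducible along the weakly identified
  additive/non-additive direction, which is exactly the direction a small
  diversity panel (36 lines) leaves uncertain;
* line variances, the common error scale, and the Student-$t$ auxiliary
  weights use standard conjugate updates.

Chains (default 4) are gated by split-$\hat R < 1.05$; exceeding the gate
raises a warning and flags the fit, never silently. Effective sample sizes
use a Geyer-style initial-positive-sequence truncation. Reported unit sizes
in the test suite and acceptance script (2 chains, 250–600 retained draws
per chain for the design study; 600 for recovery studies) were chosen as
the smallest runs whose Monte-Carlo error is negligible against the
tolerances being tested.

### What the phenotype generator emulates

`simulate_phenotypes()` mirrors the fitted model by construction: additive
values built from Binomial($2, p$) SNP dosages with infinitesimal scaling
$\beta_j \sim \mathcal N(0, \sigma^2_a / (2\sum_j p_j(1-p_j)))$, i.i.d.
non-additive deviations, log-normal line-specific error scales
(`line_cv_spread` is the log-SD), Gaussian or unit-variance-standardized
Student-$t$ replicate errors, and scalar (exchangeable) or matrix-valued
genetic and environmental trait correlations. Defaults target the
moderate-heritability regime reported for stem NSC traits
($h^2 = 0.6$ from components $0.6/0.1/0.3$), 20 replicates per accession,
and a heterogeneous pairwise genetic-correlation structure when several
traits are simulated.

Two things it deliberately does not emulate: linkage disequilibrium /
subpopulation structure (the simulated GRM's eigenvalue spread is
controlled instead by the marker count — 100 SNPs for 36 lines gives a
spread comparable to a structured panel, 500 SNPs for 200 lines a flatter
one), and any genotype-by-environment interaction. Passing tests therefore
show the *procedures* are correct and well calibrated under the stated
model, not that real stem-NSC data satisfy that model.

## The replicate-size design study

`run_design_study()` fits the full data once, then for each replicate size
RS $\in \{2, 5, 10, 15\}$ draws `n_draws = 20` within-line subsamples
without replacement (mimicking running a smaller experiment), refits, and
measures accuracy (Pearson correlation of per-line estimate vectors against
the full-data fit) for line means, GEBVs and CVs; accuracy of the pairwise
genetic-correlation vector; and relative deviation
$(\text{sub} - \text{full})/\text{full}$ for variance components and
$h^2$. Subsample fits failing the convergence gate are counted and
excluded. Everything is deterministic given the data, subsample and chain
seeds.

Two replicate-size criteria are built in. The accuracy-plateau criterion
picks the smallest RS whose median accuracy comes within 0.05 of the best
across the evaluated sizes. The dispersion (CV) criterion asks a
reliability question: a smaller experiment yields a single realization of
each line's CV estimate, so per line we compute the fraction of subsample
draws whose CV falls within $[\text{full}/1.5, \text{full} \times 1.5]$,
call the line reliable when that fraction is $\ge 0.9$, and pick the
smallest RS at which $\ge 90\%$ of lines are reliable. An alternative
aggregation — taking each line's *median* CV over draws and asking whether
that median sits in the band — turns out to be degenerate: medians over
many draws are stable even at RS = 2, so the criterion would always select
the smallest size and could never express the observed cost of estimating
dispersion. The reliability form is the package's definition for exactly
that reason.

On the default mirrored simulation (36 lines, 20 replicates, 3 traits) the
study reproduces the qualitative design findings this analysis is known
for: line-mean and GEBV accuracy plateau after about five replicates,
genetic-correlation accuracy distributions tighten sharply between RS 5 and
RS 10, error variances are overestimated and narrow-sense heritabilities
underestimated at RS 2, and the CV criterion demands roughly twice the
replicates of the line-mean criterion (10 vs 5).

## The NIR calibration workflow

`calibrate()` runs the complete chemometric pipeline in a fixed, recorded
order: restrict the spectra to 4000–9000 cm$^{-1}$; SNV scatter correction
(per-spectrum centering/scaling, $n-1$ denominator); first-derivative
Savitzky–Golay smoothing (window 25 points, polynomial order 2 — the order
is not fixed by convention in reports of this workflow, and 2 is the common
chemometric default; coefficients from `signal::sgolay`, derivative scaled
by the grid spacing, half-window edges dropped rather than extrapolated);
Kennard–Stone maximin partitioning into calibration and validation sets
(distances in the pretreated spectral space, ties broken by lowest sample
index); an initial PLS model with full (leave-one-out) cross-validation; a
single-pass outlier exclusion of calibration samples whose cross-validated
residual exceeds $2 \times$ RMSECV (for PLS-2, a sample is excluded when
*either* response exceeds twice its own RMSECV); a refit without outliers;
and only then evaluation on the untouched validation set — permuting the
validation responses provably changes no fitted parameter, which the test
suite asserts.

PLS-1 and PLS-2 are mean-centered NIPALS, exposing weights, loadings,
scores and the regression coefficients $B$ such that prediction is the
affine map $\hat Y = \bar Y + (x - \bar X)B$; predictions are
cross-checked against an independent implementation (mixOmics) in the test
suite. $R^2$ is defined as $1 - SSE/SST$ about the evaluated set's
reference mean (a squared-Pearson variant is available). Reference-method
uncertainty is twice the mean within-sample SD of technical replicates.
Component counts are user-set, as they are chosen by curve inspection in
practice; `suggest_components()` implements a first-local-minimum helper.
Serialized models round-trip through JSON at 17 significant digits, which
is bit-exact for IEEE doubles.

The spectra generator produces scatter- and baseline-corrupted linear
mixtures of Gaussian-band pure-component profiles on a 3300–12 000
cm$^{-1}$ grid (4 cm$^{-1}$ default spacing; the workflow's tests use 8–16
cm$^{-1}$ to keep matrices small), plus a constant matrix background shared
by all samples. The background is not cosmetic: dried ground stem tissue is
mostly cell wall, so real spectra are a large common absorbance envelope
with constituent signal as relative variation on top. Without it,
per-spectrum SNV scaling would remove precisely the amplitude information
that carries concentration, and no calibration could succeed — a useful
reminder of what SNV assumes about the data. Nuisance terms (log-normal
multiplicative scatter, per-sample linear baseline, detector noise,
wet-chemistry error with optional triplicates) can each be disabled, which
is how the exactness tests isolate single properties. Sucrose is simulated
on a narrower concentration range than starch, which reproduces the
familiar pattern that the narrow-range constituent has the weakest
validation $R^2$.

## Trait utilities

`tnc_remobilized()` computes the remobilization index
$100 \times (TNC_{hd} STM_{hd} - TNC_{mt} STM_{mt}) / (TNC_{hd} STM_{hd})$
— the percentage of heading-stage TNC mass no longer present at maturity;
negative values mean net re-accumulation. A widely printed form of this
equation uses the heading stem weight in both numerator terms; because the
quantity it then computes is no longer a mass balance, the package defaults
to the corrected form and exposes the printed one behind `as_printed =
TRUE` rather than choosing silently. Both coincide exactly when stem
weight is unchanged between stages.

`maturity_group()` splits growth duration at < 120 / 120–129 / ≥ 130 days.
`correlation_matrix()` gives pairwise-complete Pearson correlations with
two-sided $p$-values and `*`/`**`/`***` stars at 0.05/0.01/0.001.
`select_contrasting()` standardizes the trait table, runs a
correlation-based PCA (traits are on different scales, so covariance PCA
would let one trait dominate), cuts complete- and average-linkage trees,
and greedily selects lines that cover distinct joint cluster memberships
while maximizing pairwise spread in the PC1–PC2 plane, seeded with the most
distant pair and breaking ties towards lower row indices. The greedy
maximin is checked against exhaustive search over all subsets at small
sizes in the test suite; the published selections this mimics also used
visual inspection, so the procedure is a declared, deterministic reading of
an inherently under-specified step.

## Orchestration and reproducibility

`run_pipeline()` executes simulate → fit → design-study → calibrate stages
from a nested configuration list (YAML-loadable via `read_run_config()`),
rejects unknown keys, derives an explicit seed for every stochastic stage
from the single global seed, writes all outputs as CSV plus a JSON
manifest, and halts on a stage failure with the stage named and a partial
manifest on disk. Identical configurations produce byte-identical outputs;
the test suite asserts this at file level. The exported functions and this
configuration interface are the package's operational surface; no separate
shell executable is shipped.

## Known limitations

* The genetic model's additive/non-additive split is only as identified as
  the GRM's eigenvalue spread allows; on small panels with near-identity
  relatedness the split (and hence $h^2$ as opposed to $H^2$) is strongly
  prior-influenced. This is a property of the design, not the sampler, and
  it is the regime the design study deliberately probes.
* Bivariate fits use a fixed $\nu = 4$ for the Student-$t$ option and do
  not model line-specific dispersion; dispersion analysis is the
  single-trait model's job.
* The spectra generator is a linear-mixture instrument model; it does not
  simulate wavelength-dependent scattering physics, water bands, or
  instrument drift, so transfer-of-calibration questions are out of reach
  of these synthetics.
* Subsampling mimics a smaller experiment drawn from the same season and
  greenhouse; it cannot speak to season-to-season variance.
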