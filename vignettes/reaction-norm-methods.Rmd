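---
title: "Modeling genotype-specific reaction norms in a poplar hybrid zone"
author: "hybridnorm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling genotype-specific reaction norms in a poplar hybrid zone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridnorm)
```

## The problem

*Populus trichocarpa* (a fast-growing Pacific-coast species) and
*P. balsamifera* (a cold-hardy boreal species) meet in a broad North
American hybrid zone. Clonally replicated genotypes spanning the
ancestry gradient, planted in many common gardens across a wide
winter-temperature range, let us ask how growth and survival respond to
climate, whether that response differs among genotypes (G&times;E), and
where on the landscape each ancestry should be favored as winters warm.

`hybridnorm` implements the full chain: data preparation, a
zero-inflated Gaussian mixed model fitted by maximizing a
Laplace-approximated marginal likelihood, model evaluation by
leave-one-garden-out cross-validation and transfer to novel genotypes
and sites, genotype-specific reaction norms over a continuous
temperature grid, and per-grid-cell projection of the best-performing
ancestry.

## The model

One record is one tree in one year. The response is the yearly height
increment $Y$ (cm), with trees recorded dead at the end of the season
coded $Y = 0$. Two linked components describe the data:

* a **zero-inflation (mortality) component**: the probability $p$ that a
  record is a structural zero, on the logit scale;
* a **conditional (growth) component**: for non-zero records, the
  transformed increment $\log(1 + Y)$ is Gaussian with mean $\mu$ and
  residual SD $\sigma$.

Both linear predictors share the same fixed-effect structure. With $G$
the garden mean coldest month temperature (MCMT) in the measurement
year, $H$ the genotype's home MCMT (30-year provenance average), and
$A, B, C$ the genotype's genomic PC1-3 scores (all scaled, see below):

$$
\eta = \mu_0 + G + G^2 + H + H^2 + G^2H^2 + G^2H + GH^2 + GH
     + A + B + C + AG + AG^2 + BG + BG^2 + CG + CG^2,
$$

plus random intercepts for block-nested-in-garden, genotype, year, and
individual tree (repeated measures across years). The quadratic in $G$
encodes the concave response with an intermediate temperature optimum;
the $G\times H$ products let the response depend on home climate (the
classical transfer-function view); the $PC \times G$ products let it
depend on genome-wide structure instead. The zero-inflation part uses
the same formula with its own coefficients and its own random-intercept
variances. The combined prediction $(1 - p)\,\mathrm{E}[Y \mid
\text{alive}]$ serves as the fitness proxy.

Reduced forms drop the home-climate terms (`genetics_only`) or the PC
terms (`climate_only`); all three keep the quadratic garden-MCMT
response and are built by `make_model()`.

### Two conventions for zeros

An observed zero can be treated two ways, and the package implements
both (`zero_density` in `fit_zigmm()`):

* `"point_mass"` (default): zeros are structural, contribution
  $\log p$. This matches the coding rule (dead &rArr; 0 by
  construction) and makes the likelihood separable: the conditional part
  is a plain Gaussian mixed model on survivors, the zero part a logistic
  mixed model on the zero indicator.
* `"mixture"`: contribution $\log\{p + (1 - p)\,\phi(0;\mu,\sigma)\}$,
  the convention of general-purpose mixed-model software for
  zero-inflated continuous families. It lets a survivor with (exactly)
  zero measured growth be explained by the conditional density as well.
  The two conventions are numerically distinguishable; tests pin each
  against its own oracle.

### Transform and scaling

Growth is transformed with $\log(1 + x)$, the only log-family monotone
transform that maps the structural zeros to exact zeros; predictions are
back-transformed with $e^{\eta} - 1$, floored at 0. Numeric covariates
are scaled **without centering**: each is divided by its
root-mean-square $\sqrt{\sum x_i^2/(n-1)}$ (the no-centering behavior of
the standard `scale()`), and the divisors are stored so new data are
scaled identically at prediction time. Quadratics and interactions are
products of the *scaled* columns. Not centering preserves the meaning of
zero and makes a unit change of a raw covariate provably irrelevant to
standardized effects.

## Estimation

The marginal likelihood integrates the random effects $b$ out of the
joint likelihood; the package maximizes its Laplace approximation

$$
-\log L(\theta) \approx f(\hat b;\theta)
 + \tfrac12 \log\det H(\hat b;\theta) - \tfrac q2 \log 2\pi,
$$

where $f$ is the joint negative log-likelihood (including the Gaussian
prior of $b$), $\hat b$ its minimizer, and $H$ its Hessian in $b$.
$\hat b$ is found by a sparse Newton iteration (Cholesky with a cached
symbolic factorization); the objective is convex in $b$ under the
point-mass convention.

Under the default convention the fit splits into two exact pieces:

* **Conditional part**: a Gaussian mixed model on survivors, for which
  the Laplace expression is the exact marginal. Fixed effects and
  $\sigma$ are profiled out in closed form, leaving a box-constrained
  optimization over one relative SD per random factor (the approach of
  the standard profiled ML deviance in mixed-model software).
* **Zero-inflation part**: a logistic mixed model over all records. The
  outer optimization runs over the fixed coefficients and the
  per-factor SDs jointly, with an analytic gradient of the Laplace
  objective (envelope term plus the log-determinant derivative via the
  implicit mode shift, computed from sparse triangular solves), warm
  starts of the inner mode across evaluations, and a penalized-IRLS
  refinement of the starting coefficients. SDs are optimized on their
  natural scale with a lower bound at zero so boundary (zero-variance)
  estimates are representable; a smooth $10^{-8}$ variance floor keeps
  the objective differentiable through the boundary.

Under the mixture convention the components couple at zeros and a
generic quasi-Newton optimization of the full Laplace objective is used
(slower; intended for comparisons on moderate problems). Deterministic
starting values (logistic GLM coefficients, relative SDs of 1, zi SDs of
0.5) make fits reproducible without seeds, and records are canonically
ordered during preparation so results do not depend on input order.

Wald covariance of the fixed effects comes from the exact
generalized-least-squares expression in the conditional part and the
Schur complement of the joint Hessian at the mode in the zero part; both
condition on the estimated variance components, the standard convention.
`wald_type2()` forms type II chi-squared tests respecting marginality
(a term is adjusted for everything except its higher-order relatives),
implemented as the difference of joint Wald statistics, which makes
order-invariance structural. `standardized_estimates()` reports
$\hat\beta \cdot \mathrm{SD}(x)/\mathrm{SD}(y)$ by default (response SD
taken over survivors' transformed growth); because the literature's
one-line descriptions of "standardized by dividing by its SD" are
ambiguous, the predictor-SD-only variant is selectable
(`method = "sd_x"`), and zero-inflation coefficients — which act on a
latent logit with no observable SD — always use the predictor-SD
convention.

## Evaluation conventions

*Leave-one-garden-out*: one refit per garden; predictions for the
held-out garden reuse the genotype and year modes (every genotype occurs
in training by design) but population-level garden and block effects —
the only interpretation under which predicting an unseen garden is
defined. Scaling divisors are recomputed from each training subset so a
fold is fully self-contained. Non-converged folds are flagged and
excluded from yearly means with a warning rather than aborting the
whole procedure.

*Transfer to the evaluation ("maxi") gardens*: predictions for novel
genotypes use their covariates only (no genotype or garden modes; year
modes when the year was seen). The conditional component is scored on
survivors only; the overall component on everyone.

*Model comparison*: per-fold Pearson correlations feed a one-way ANOVA
with folds as replicates, plus pairwise paired Wilcoxon signed-rank
tests. The signed-rank null is enumerated exactly (dynamic programming
over sign assignments with midranks) up to 25 folds, so the smallest
attainable p-value at 17 folds is $2/2^{17}$; beyond 25 folds a
tie-corrected normal approximation is used.

*Mortality calibration*: logistic regression of observed death on the
predicted probability; a significantly positive slope indicates the
predicted risk tracks realized mortality.

## Reaction norms and landscape projection

Reaction norms evaluate the fitted model, population-level, for one
genotype's covariates across an MCMT grid (default 100 points from
-23.9 to 9.8 &deg;C, covering home climates and garden climates). Grid
points outside the garden-observed MCMT window are computed but flagged
`extrapolated`: the gardens only support the warmer part of the range,
so cold-side predictions lean on the quadratic form. The fitness
optimum is the grid argmax of $(1-p)\cdot$growth, ties broken at the
first (coldest) index; a tenfold-refined grid is used as the refinement
oracle in tests.

The landscape module evaluates every genotype's fitness at each climate
cell's MCMT and keeps the winner's ancestry proportion. Cells outside
the mask window are excluded; the default mask (-13.05 to 10.85 &deg;C)
follows the published map convention even though the gardens' yearly
MCMT values span -16.5 to 9.8 &deg;C — the two windows disagree in the
source material, so both are plain arguments. Ties are broken by
genotype id order and logged. The ancestry shift map is future winner
ancestry minus historic winner ancestry, masked wherever either
scenario is.

## The synthetic study

`simulate_study()` generates data with the structure the analysis
assumes and known truth, at the field design's scale: 44 genotypes
&times; 17 gardens &times; 2 blocks &times; 2 years, garden MCMT spread
over -16.5 to 9.8 &deg;C with yearly jitter, home MCMT over -23.9 to
-3.8 &deg;C. Genomic PC1 is constructed to correlate with home MCMT at
exactly -0.69 in-sample (PC2, PC3 at the weaker -0.22 and -0.40);
ancestry follows a logistic gradient along PC1. Mortality is drawn from
the logit-linear zero model (rising at both temperature extremes, about
a quarter of records zero overall), survivor growth from the Gaussian
log1p model, and about 8% of surviving records are then corrupted to
negative increments to exercise the filtering stage. A deterministic
stream-splitting scheme derives every stage's seed from one master
seed.

Default truth coefficients were fixed once to make the curves
qualitatively realistic — a concave growth response peaking a few
degrees above freezing, optima shifting warmer with *trichocarpa*-like
PC1 scores, growth of one-to-tens of centimeters, cold-extreme growth
around 1-2 cm rather than essentially zero (so that structural zeros
come from the mortality process the generator documents, not from
flooring the back-transform) — and are not estimates from any dataset.

What the generator does **not** emulate: spatial structure and
dispersal, linkage and recombination (SNPs are independent
binomial draws from ancestry-mixed frequencies), garden loss in later
years, death persisting across years (mortality is drawn per record),
multivariate climate (one axis only), and herbivory that is anything
but random. Passing tests therefore certify the estimation and
prediction machinery under the model's assumptions plus mild
misspecification — not the field realism of any particular estimate.

## Numerical choices and problem sizes

* Outer optimizations use a relative tolerance of $10^{-8}$ by default
  (`control$rel_tol`); the study-scale analyses and simulations in the
  scripts use $10^{-7}$, which changes log-likelihoods by well under
  $10^{-3}$ while saving a third of the time.
* Inner Newton solves iterate to a gradient norm of $10^{-9}$ with step
  halving; a $10^{-8}$ ridge is added once, with a warning, if a
  Hessian factorization fails.
* The parameter-recovery (coverage) simulation runs 100 replicates at
  the full study size with a reduced but representative fixed-effect
  set (intercept, $G$, $G^2$, PC1, PC1$\times G$ in both components,
  all four random factors); Wald 95% intervals pool to roughly 0.89
  coverage, the deficit concentrated in the intercepts, whose intervals
  condition on a year variance estimated from only two year levels —
  a known small-level-count phenomenon, faithful to the two-year
  design.
* Cross-validation refits one model per garden (17 refits, a few
  seconds each at study scale).

## Known limitations

* Wald intervals ignore variance-parameter uncertainty; with two year
  levels the intercept intervals undercover (see above).
* The point-mass likelihood cannot attribute an exact-zero survivor to
  the growth component; the mixture convention can, at the cost of
  coupling the components.
* Laplace accuracy for the logistic part degrades when random-effect
  SDs are large and clusters are small; the quadrature cross-checks
  cover the regime the study design occupies.
* Landscape projections are single-axis (MCMT) and population-level;
  they rank the *measured* genotypes, not hypothetical recombinants,
  and inherit the extrapolation caveat outside the garden-supported
  window.
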