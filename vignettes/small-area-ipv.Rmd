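---
title: "Methods: area-level small-area estimation of IPV prevalence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: area-level small-area estimation of IPV prevalence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saeipv)
```

## Scope and estimand

The package estimates, for every district of a study area, the proportion
of ever-married women who experienced intimate partner violence (physical,
emotional, or sexual, each analysed as a separate binary outcome) in a
recall window. The data-generating situation it addresses is the standard
one for domestic-violence modules of large household surveys: a two-stage
cluster sample (PSUs within district, households within PSU), with the
module administered to one woman per household in a random ~15% household
subsample, under unequal design weights. District samples of ~150 women
make direct design-based estimates unstable; auxiliary covariates are only
available as district aggregates (census tables), which dictates an
*area-level* rather than unit-level small-area model.

## Direct estimation

For district $d$, the direct estimate is the weighted proportion
$\hat p_d = \sum_i w_i y_i / \sum_i w_i$. Its design variance uses
with-replacement first-stage Taylor linearisation over the $m_d$ PSUs,

$$\widehat{\mathrm{var}}(\hat p_d) = \frac{m_d}{m_d-1}
  \frac{\sum_j (z_{dj}-\bar z_d)^2}{(\sum_i w_i)^2},\qquad
  z_{dj} = \sum_{i \in \text{PSU } j} w_i (y_i - \hat p_d),$$

ignoring strata and finite-population corrections — the convention of
DHS-style analyses, and exact for the synthetic design, which has no
strata. The delta method carries the variance to the logit scale,
$\psi_d = \widehat{\mathrm{var}}(\hat p_d) / (\hat p_d(1-\hat p_d))^2$,
and 95% intervals are logit-scale Wald intervals back-transformed, which
keeps them inside $(0,1)$ and matches the model's scale. Districts with a
single PSU ($\psi_d$ inestimable) or $\hat p_d \in \{0,1\}$ (logit
undefined) are flagged unusable and treated by the model stage as
unsampled; they still receive synthetic predictions. This is the standard
practice for degenerate domains and avoids ad-hoc continuity corrections
that would distort $\psi_d$.

## The area-level model

Usable direct estimates enter the logit-scale area-level (Fay–Herriot)
model
$$\mathrm{logit}(\hat p_d) = x_d'\beta + u_d + e_d,\qquad
  u_d \sim N(0,\sigma^2_u),\quad e_d \sim N(0,\psi_d),$$
with $\psi_d$ treated as known. The default design matrix holds an
intercept, the census-style covariate proportions, the border proximity
factor, and state fixed effects (one-hot, reference = first state id in
sort order). Estimation:

* $\sigma^2_u$ by **profile maximum likelihood**: for fixed $\sigma^2_u$,
  $\beta$ has the closed-form GLS solution, so the likelihood is profiled
  to a scalar function maximised by Brent search on
  $[0,\,10\cdot\mathrm{var}(\mathrm{logit}\,\hat p_d)]$ with tolerance
  $10^{-10}$. The upper bracket is far above any plausible area variance;
  a fit at the ceiling is flagged. ML is the default because it is
  determinate and its small-sample difference from REML is immaterial at
  the design sizes used here; REML is available via `method = "REML"`.
* A likelihood maximised at $\sigma^2_u = 0$ is reported as a **boundary
  fit** with a flag, never jittered: a zero area variance is a legitimate
  answer (all between-district variation explained by covariates and
  sampling noise).
* Rank deficiency of the design matrix is an error naming the collinear
  columns; fits require at least $p+2$ usable districts.

The model-based estimate is the EBLUP
$\hat\eta_d = x_d'\hat\beta + \gamma_d(\mathrm{logit}(\hat p_d) - x_d'\hat\beta)$
with shrinkage $\gamma_d = \hat\sigma^2_u/(\hat\sigma^2_u+\psi_d)$, and
$\hat\theta_d = \mathrm{expit}(\hat\eta_d)$. The plain expit
back-transform is the default for transparency;
`backtransform = "bias_corrected"` integrates expit over
$N(\hat\eta_d, \mathrm{mse}_d)$ with 41-node Gauss–Hermite quadrature
(nodes by Golub–Welsch eigendecomposition), which matters only when MSEs
are large.

### MSE by parametric bootstrap

Uncertainty comes from a parametric bootstrap: each replicate draws
$u^*_d \sim N(0,\hat\sigma^2_u)$ for every district and
$e^*_d \sim N(0,\psi_d)$ for in-sample districts, rebuilds bootstrap
direct logits, refits, and predicts; the MSE is the mean squared
deviation of the bootstrap prediction from the bootstrap truth
$x_d'\hat\beta + u^*_d$. Out-of-sample districts thereby get the
synthetic-part uncertainty plus $\sigma^2_u$ automatically. The default
$B = 200$ (100 inside the replication experiment) keeps the Monte-Carlo
error of the MSE a few percent; the balanced intercept-only case
reproduces the analytic leading term $\gamma_d\psi_d$ within 15% at
$B = 500$, which the tests check. Refit failures above 10% of replicates
abort with an error. Intervals are
$\mathrm{expit}(\hat\eta_d \pm z_{0.975}\sqrt{\mathrm{mse}_d})$ and the
CV is the delta-method root-MSE on the proportion scale divided by
$\hat\theta_d$, i.e. $\sqrt{\mathrm{mse}_d}\,(1-\hat\theta_d)$.

## Diagnostics

**Residuals.** Standardised marginal residuals
$(\mathrm{logit}(\hat p_d) - x_d'\hat\beta)/\sqrt{\hat\sigma^2_u+\psi_d}$
are tested with Shapiro–Wilk (normality) and Breusch–Pagan against the
predicted values (homoskedasticity). "Randomly distributed residuals" is
thereby operationalised as two testable p-values rather than visual
judgement; interpretation is left to the caller.

**45°-line regression.** The consistency diagnostic regresses direct
estimates (y) on model predictions (x) on the proportion scale and tests
slope = 1 and intercept = 0. A genuinely open design choice here is *which*
model quantity to put on the x-axis. Regressing on the EBLUP itself is
common in applied reports but is not a calibrated test: the EBLUP contains
the same direct estimate it is compared against, which inflates the
expected slope to $(V+\sigma^2_u)/(V+\sigma^2_u-\gamma\psi) > 1$ even
under a correct model ($V$ = between-district variance of the covariate
predictions); at this package's reference design that expected slope is
about 1.2 and the test would reject essentially always. The package
therefore regresses on the **synthetic prediction**
$\mathrm{expit}(x_d'\hat\beta)$ by default — under a correct model the
direct estimate is that prediction plus zero-mean noise, so the test has
its nominal level (the tests verify ≥90% non-rejection over 50
replicates). The EBLUP orientation remains available via
`predictor = "eblup"` as a descriptive measure of agreement. With a
perfect fit (zero residual SE) the t statistics are defined as 0 with
p = 1 by convention.

**Precision.** Per-district CVs and 95% CI widths of both methods, the
share of districts whose model CV improves on the direct CV, and the
median CV ratio. Per-state variation of the model estimates is the
population-SD (divisor $n$) coefficient of variation — a descriptive, not
inferential, quantity; single-district states report CV 0 with a flag.

## Geometry: contiguity and the border proximity factor

Spatial weights use **queen contiguity, order 1, row-standardised** — the
default of the LISA literature and desktop tooling. Two districts are
neighbours if their polygon boundaries come within $10^{-9}$ of the map
diameter of touching (shared edges and corner touches both count).
Neighbourless districts (islands) are listed, carry zero weights, and are
excluded from standardisation.

The **border proximity factor** (BPF) of a district is the mean Euclidean
distance of the district from its own state's border — a covariate
capturing the idea that districts near interstate borders resemble their
cross-border neighbours. "Mean distance of a district" is ambiguous
(centroid? area average? boundary average?); the default takes the mean
over 256 points sampled uniformly by arc length along the district
boundary, the closest literal reading, with `method = "centroid"` as the
alternative. The study-area outer frame is **excluded** from state borders
by default (a coastal district far from any interstate border should have
a large BPF, since only interstate borders mediate cross-state
similarity); `include_outer_frame = TRUE` flips this, and is required for
single-state maps, where it is the generator's automatic fallback. State
borders are extracted as colinear overlaps of district edges between
districts of different states, which is exact for administrative tilings
whose shared borders coincide geometrically. BPF is translation invariant
and scale equivariant; distances are planar Euclidean (no geodesy), as the
synthetic maps live in arbitrary planar units.

## LISA

Local Moran's I uses $z$-scores standardised by the population SD over
districts with neighbours and non-missing values,
$I_i = z_i \sum_j w_{ij} z_j$. Inference is by conditional permutation:
$z_i$ stays fixed, the remaining $n-1$ values are assigned at random
without replacement to $i$'s neighbour slots, with pseudo p-value
$(\text{count}+1)/(n_{\mathrm{perm}}+1)$ on the one-sided tail matching
the sign of $I_i$. Defaults — 999 permutations, $\alpha = 0.05$, no
multiple-testing correction (a Benjamini–Hochberg option exists behind
`fdr = TRUE`) — reproduce the conventions of the standard desktop LISA
tool so that category maps are comparable with published ones. Significant
districts are classified by the signs of $z_i$ and the spatial lag into
high–high, low–low, high–low, low–high; neighbourless districts have
undefined $I_i$ and their own category. The mean of the local statistics
equals global Moran's I exactly (tested to $10^{-10}$), and the
permutation engine is validated against full enumeration on graphs with
$n \le 8$.

## The synthetic-data generator

The generator exists to give the pipeline data whose truth is known, with
the statistical structure the estimators assume:

* **Geography**: a rectangle tiled by rows of mildly jittered rectangular
  districts; states are contiguous blocks in snake order. This guarantees
  a connected contiguity graph, well-defined interstate borders for BPF,
  and exact tiling (union = bounding rectangle).
* **Covariates**: probability transforms of Gaussian random fields over
  district centroids with exponential correlation
  $\exp(-\mathrm{dist}/\texttt{spatial\_range})$, giving proportion-scaled
  covariates in $[0,1]$ with tunable spatial autocorrelation (so that
  prevalence clusters exist for LISA). A $10^{-6}$ nugget stabilises the
  Cholesky factor at long ranges. Default `spatial_range = 2` map units
  (about two district widths) — enough smoothness for visible clustering
  without degeneracy.
* **Truth**: $u_d \sim N(0, \sigma^2_{u,\text{true}})$ i.i.d. and
  $\mathrm{logit}(\theta_d) = x_d'\beta_{\text{true}} + u_d$ exactly —
  the same logit-Normal area-level model the estimation stage assumes,
  which is what a recovery experiment requires. Defaults
  $\beta_{\text{true}} = (-1.2, 0.8, -0.5)$ on two covariates and
  $\sigma_{u,\text{true}} = 0.3$ put district prevalence around 15–35%
  with realistic between-district spread. The three outcome columns share
  the sampling frame and differ by intercept shifts
  $(0, -0.9, -1.8)$, giving mean prevalences near 25%, 12% and 6% —
  the ordering and rough magnitudes typical of physical, emotional and
  sexual IPV reporting.
* **Sampling**: per district, `psus_per_district = 10` PSUs of
  `households_per_psu = 100` households; each household enters the module
  independently with probability `dv_subsample_fraction = 0.15` and
  contributes exactly one respondent, so ~150 respondents per district.
  The outcome probability is $\theta_d m_{\text{psu}}$ with
  $m_{\text{psu}} = \exp(N(0, 0.15^2))$, clipped into $(0,1)$ — a mild
  multiplicative PSU effect that induces design effects above 1 while
  leaving $\theta_d$ the exact district-level estimand (an additional
  logit-scale random effect would change the estimand itself). Design
  weights are log-normal with CV `weight_dispersion = 0.3`, rescaled to
  mean 1 within district — unequal weighting without replicating any
  specific survey's full weighting scheme. Weights are emitted already
  valid for the subsample (no renormalisation step is modelled).

What the generator does **not** emulate: stratification and its variance
components, non-response and its adjustments, state-level weight
normalisation, real administrative geography, spatially correlated area
effects, or covariate measurement error. Passing tests therefore show the
estimators are correct *under their own assumptions* plus mild PSU-level
misspecification — not that those assumptions hold in any particular real
survey.

## Reproducibility and problem sizes

Every stage seeds its RNG from a master seed via fixed integer offsets,
so stages are individually reproducible and a whole run is byte-identical
under the same configuration (`manifest.json` records file hashes). RNG
state is always restored after use.

The validation suite uses: a 100-district (5 states × 20) reference
design with ~150 expected respondents per district, 50 replicates and
$B = 100$ bootstrap draws for parameter recovery, interval coverage,
precision gain and 45°-line calibration; 500 districts for direct-interval
coverage; a 10×10 grid with 999 permutations × 20 seeds for the LISA null;
and exhaustive enumeration on $n \le 8$ graphs for the permutation engine.
These sizes put Monte-Carlo error comfortably inside the asserted bands
while keeping the full suite fast.

## Known limitations

* $\psi_d$ is treated as known although it is estimated from ~150
  respondents; the resulting extra variability is partly absorbed by the
  bootstrap but can bias $\hat\sigma^2_u$ slightly at small district
  sample sizes.
* The naive expit back-transform is not mean-unbiased for $\theta_d$;
  use the bias-corrected option when MSEs are large.
* Border extraction assumes shared district borders coincide exactly
  (colinear overlaps); maps digitised with slivers or gaps need cleaning
  first.
* No spatially correlated random effects: spatial structure enters only
  through covariates, so residual spatial correlation in real data would
  leave LISA clusters partly unexplained by the model.
* Raw-$\alpha$ LISA maps have a multiple-testing false-positive share
  near the null rate by design; enable `fdr = TRUE` for corrected maps.
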