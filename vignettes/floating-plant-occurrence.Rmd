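---
title: "Modelling the occurrence of an uncommon functional group across lakes and ponds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the occurrence of an uncommon functional group across lakes and ponds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(floatpool)
```

## The question

Free-floating plants (duckweeds such as *Lemna minor*, *Spirodela
polyrhiza* and *Wolffia* spp.) form a small functional group in temperate
lake floras — often fewer than ten species in a regional pool of a hundred
or more — yet where they establish they can blanket a water body and
restructure it. Across a regional survey of lakes and ponds, many sites
hold no member of the group at all. Two very different explanations are on
the table:

1. **Local conditions**: floating plants take their nutrients from the
   water column, so nutrient-rich, high-conductivity, low-clarity water
   bodies should favour them.
2. **Species-pool size**: a group with few member species will be missing
   from many sites by random sampling alone, regardless of conditions.

`floatpool` implements both analyses side by side: multimodel logistic
regression of occurrence on site covariates, and a species-pool
permutation null model for the prevalence of the whole group. A
synthetic-survey generator with known ground truth makes every stage
testable end to end.

## Occurrence models

Presence of the group (or of a single taxon) at site $i$ is modelled as
Bernoulli with

$$\operatorname{logit}(p_i) = \beta_0 + \sum_j \beta_j x_{ij},$$

where each predictor $x_j$ is first mapped affinely onto $[0,1]$
(`rescale_unit_interval()`), so coefficients are comparable across
predictors measured on wildly different scales (hectares, µS/cm, mg/L).
Fitting is ordinary iteratively reweighted least squares with a
convergence tolerance of $10^{-10}$ and at most 100 iterations; standard
errors come from the inverse observed information.

Because no single model is expected to dominate, `all_subsets()`
enumerates all $2^p$ predictor subsets (binary counting on the input
column order, intercept-only model included) and ranks them by the
small-sample Akaike criterion

$$\mathrm{AICc} = -2\ell + 2k + \frac{2k(k+1)}{n-k-1}.$$

Models within the band $\Delta\mathrm{AICc} < 2$ (strict inequality) form
the candidate set; their Akaike weights $w_i \propto e^{-\Delta_i/2}$ are
renormalised, and `model_average()` combines coefficients in both standard
variants:

* **full** average: a term absent from a model contributes 0 there,
  $\bar\beta = \sum_i w_i \hat\beta_i$;
* **conditional** average: weights renormalised over the models containing
  the term.

The unconditional standard error per term is
$\sum_i w_i \sqrt{\widehat{\mathrm{var}}_i + (\hat\beta_i - \bar\beta)^2}$,
with zero-variance, zero-estimate pseudo-entries included in the full
variant (for the conditional variant the sum runs over containing models
with renormalised weights — the formula is stated in the literature
without fixing the renormalisation; we renormalise so both variants
average to their own centre). A term is flagged significant when 0 lies
outside $\bar\beta \pm 1.96\,\mathrm{SE}$. The *full* variant is the
default headline, matching the default reporting of the widely used
multimodel-inference software; the conditional variant is always computed
alongside because the choice is genuinely open and shifts shrinkage
towards zero for rarely selected terms.

Predictions from the averaged model default to weight-averaged member
probabilities, $\sum_i w_i\,\mathrm{logit}^{-1}(X\hat\beta_i)$, which is
always well defined; applying the inverse link to the full-averaged
coefficients is available as an alternative mode since both conventions
circulate.

Models that fail to converge or show (quasi-)complete separation — the
usual pathology of small binary data sets with strong predictors — are
flagged and excluded from ranking rather than aborting the search.
AICc ties keep enumeration order, so results are deterministic.

Model fit is summarised by likelihood-ratio pseudo-$R^2$: Cox–Snell
$1 - e^{-\frac{2}{n}(\ell_1-\ell_0)}$ and its Nagelkerke rescaling. Both
are reported; neither is privileged, because the two common variants are
often cited interchangeably. Influence is screened by the standard
one-step Cook's distance
$D_i = r_i^2 h_i / (k (1-h_i)^2)$ with a default flag level of 0.9
("close to 1"); flagged observations are reported for analyst-confirmed
exclusion, never dropped automatically.

## Classification evaluation

Probabilities become presence/absence by the rule $p \ge t$.
`optimal_threshold()` scans $t \in \{0, 0.005, \dots, 1\}$ and maximises
sensitivity + specificity; tying grid points are averaged, which is how
three-decimal optima (e.g. 0.155) arise from a five-thousandths grid. The
step is configurable. Confusion matrices are oriented rows = predicted,
columns = observed, and summarised by the proportion correctly classified
and Cohen's kappa

$$\kappa = \frac{P_o - P_e}{1 - P_e},\qquad
P_e = \frac{(TN{+}FN)(TN{+}FP) + (FP{+}TP)(FN{+}TP)}{n^2}.$$

The kappa standard error uses the large-sample approximation
$\sqrt{P_o(1-P_o)/(n(1-P_e)^2)}$. It is reported as informative only:
several SE conventions for kappa circulate and they disagree at small
counts, so no automated check is keyed to it.

## The species-pool null model

`permutation_null()` asks what fraction of sites would lack the group if
communities assembled at random. Each iteration draws $S$ occupancy
frequencies **with replacement** from the occupancies of *all* taxa in the
regional flora (the focal group's own taxa included — they are part of the
pool being characterised), assigns each pseudo-species to that many
distinct sites uniformly at random, independently across species, and
records the fraction of sites with no pseudo-species. Summaries are the
mean, a percentile confidence interval (default 95%, interpolated order
statistics), and a two-sided add-one-corrected empirical p-value for an
observed proportion.

Conditional on drawn frequencies $k_1,\dots,k_S$, the expected empty
fraction is exactly

$$\prod_{i=1}^{S}\left(1 - \frac{k_i}{n}\right),$$

implemented as `expected_empty_exact()`. This analytic oracle is
independent of the Monte-Carlo machinery and anchors its tests; note that
with $S = 1$ the per-iteration statistic is deterministic
($1 - k/n$ exactly), since each species occupies exactly its drawn count
of sites.

The null deliberately assumes site interchangeability: no environmental
filtering, no interactions. That is its point — departures of the observed
prevalence from the null interval are evidence that more than pool size is
at work. Weighted frequency sampling and co-occurrence-constrained
assignment are left as hooks, not implemented.

## The synthetic survey generator

`simulate_survey()` produces data with the structure the analyses assume,
plus ground truth:

* **Occupancy frequencies** follow a log-normal distribution rounded to
  integers and truncated by rejection to $[1, n_{\text{sites}}]$ —
  strongly right-skewed, as regional occupancy-frequency distributions
  typically are. The defaults (`meanlog = 2.415`, `sdlog = 1.1`) give a
  mean occupancy of about 19 of 176 sites, so the single-species null
  expectation sits near 0.89 — the regime of a regional flora in which
  the typical taxon occupies roughly a tenth of the sites. The analytic
  moments of the rounded, truncated law
  (`occupancy_distribution_moments()`) serve as the sampling oracle.
* **Covariates** are Gaussian-process fields over between-site
  great-circle distances with exponential covariance
  $\exp(-d/\rho)$ (default range $\rho$ = 30 km over a roughly
  105 × 155 km box, i.e. clearly visible regional structure), mixed with
  a configurable fraction of independent noise (default 0.3) and mapped
  affinely to plausible limnological ranges with physical floors.
  Alkalinity shares latent structure with conductivity and pH, and
  maximum depth with area and Secchi depth, so the collinearity screen
  has realistic targets. A full Cholesky of the covariance is acceptable
  at the intended scales (hundreds of sites).
* **Group presences** follow the logistic model above with shared slopes
  (defaults: totalP $+4$, cond $+4$, secchi $-4$ on unit-scaled
  covariates, intercept $-2.5$) and per-member intercept offsets
  (0, −1, −1.6, −4, −4.5, −5) that create three common and three rare
  members, mimicking the common/rare composition of a small functional
  group; the defaults put group prevalence near 40–50%. True
  probabilities are returned for recovery tests.
* **Derived predictors** — neighbour counts within 1 and 10 km and
  distance to the nearest occupied water body for the three most common
  members — are computed from the generated coordinates and communities,
  not drawn.

What it does **not** emulate: detection error (a presence is a presence),
repeat-survey structure, river connectivity between water bodies, and
covariate measurement error. Tests passing on synthetic data therefore
validate the machinery and its statistical calibration, not the ecological
fidelity of any particular regional dataset.

## Numerical and design choices

* **Shoreline development index**: implemented as the standard
  dimensionless form $L / (2\sqrt{\pi A})$ (area converted ha → m²), which
  is 1 for a circle and scale-invariant. A formula without the square root
  sometimes appears in print but is not dimensionless and cannot satisfy
  the circle identity.
* **Distances** are great-circle (haversine, radius 6371.0088 km) on
  decimal degrees. Neighbour counting uses a closed ball
  ($d \le$ radius) and always excludes the focal site; distance to the
  nearest occupied site excludes the focal site even when itself occupied,
  and returns a flagged missing value (never zero) when no other occupied
  site exists.
* **Collinearity screening** reports Pearson correlations (point-biserial
  for 0/1 columns, numerically the same computation) for all predictor
  pairs and flags $|r| \ge 0.7$ by default. It is advisory: which member
  of a flagged pair to drop is an analyst decision recorded in the
  configuration (the default configuration drops alkalinity and maximum
  depth, the two classic redundancies noted above).
* **Missing covariates**: sites missing any model predictor are dropped
  from model fitting with a logged count; they remain in the occurrence
  matrix and the null model.
* **PCA** is on the correlation matrix (centred, scaled), all sites with
  complete values included; the Cook's-distance exclusion applies to the
  GLMs only. Component signs follow a fixed convention (largest-magnitude
  loading positive) since they are arbitrary up to reflection.
* **Seeds**: one root seed per pipeline run; the simulation, fitting and
  null-model stages draw deterministic child seeds, so outputs reproduce
  bit-identically.

## Problem sizes used by the test suite

The packaged tests exercise the generator at 25–176 sites, parameter
recovery at $n = 2000$ with 100–200 replicates, the null model at
$B$ = 400–10 000 iterations, and the calibration property (observed value
inside the null CI when assembly really is random) at 60 replicates —
sizes chosen so the full suite completes in well under a minute while
keeping Monte-Carlo standard errors small relative to the tested bands.

## Limitations

* Interactions between predictors and spatially autoregressive error
  structures are out of scope; latitude/longitude enter only as plain
  covariates.
* The averaged-model evaluation is in-sample, as is conventional for this
  design; no cross-validation is provided.
* Richness (count) models of the group, Poisson or quasi-Poisson, are a
  natural extension but not part of this version.
* The kappa SE and the choice between full and conditional averaging are
  conventions, not facts; both are surfaced rather than hidden.
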