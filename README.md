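# floatpool

Why is an uncommon functional group — free-floating plants such as
*Lemna*, *Spirodela* and *Wolffia* — present in some freshwater lakes and
ponds and absent from most? `floatpool` is an R package for analysts of
regional presence/absence surveys who want to weigh two complementary
explanations against each other:

* **Local abiotic control.** Occurrence of the group (or of a single
  taxon) is modelled by logistic regression on site covariates,
  `logit(p_i) = β₀ + Σ_j β_j x_ij`, with every predictor rescaled to
  [0, 1]. Because no single model dominates, all `2^p` predictor subsets
  are fitted and ranked by AICc
  (`−2ℓ + 2k + 2k(k+1)/(n−k−1)`); the models with ΔAICc < 2 are averaged
  with Akaike weights `w_i ∝ exp(−Δ_i/2)` (full and conditional
  variants, unconditional SEs). Averaged predictions are classified at
  the threshold maximising sensitivity + specificity and summarised by a
  confusion matrix, percent correctly classified, and Cohen's kappa
  `κ = (P_o − P_e)/(1 − P_e)`.
* **Species-pool size.** A permutation null model asks how many sites
  would lack the group under random assembly alone: draw `S` occupancy
  frequencies with replacement from the occupancies of the whole
  regional flora, scatter each pseudo-species over that many sites at
  random, and record the fraction of sites left empty. The exact
  conditional expectation `Π_i (1 − k_i/n)` is provided as an analytic
  oracle, and percentile intervals and empirical p-values compare the
  observed prevalence with the null.

Supporting tools: survey CSV input/output, derived spatial predictors
(great-circle distances, neighbour counts, distance to nearest occupied
water body, shoreline development index `L/(2√(πA))`), a collinearity
screen, correlation-matrix PCA of site conditions, Cook's-distance
diagnostics, likelihood-ratio pseudo-R², and a synthetic-survey generator
(spatially autocorrelated covariates, right-skewed occupancy frequencies,
known logistic effects) so the whole pipeline is testable with ground
truth. See the vignette `vignettes/floating-plant-occurrence.Rmd` for the
methods in full.

## Worked example

Simulate a survey at the default study conditions (176 water bodies, 124
taxa, a 6-member floating group driven by total phosphorus, conductivity
and Secchi depth), then run both analyses:

```r
library(floatpool)
sim <- simulate_survey(synth_config(), seed = 42)
obs <- observed_empty_proportion(sim$occ, "floating")   # 0.608

X <- as.data.frame(lapply(as.data.frame(sim$sites)[
  , c("totalP", "cond", "secchi", "pH", "lakes10km")], rescale_unit_interval))
y <- response_vector(response_spec("floating", group = "floating"), sim$occ)
avg <- model_average(candidate_set(all_subsets(X, y), delta_max = 2))
avg
#> averaged_model over 2 member model(s), headline = full
#>         term estimate_full   se_full  ... importance significant
#>  (Intercept)    -2.8981640 0.8192957        1.0000000        TRUE
#>       totalP     5.3017490 1.0194039        1.0000000        TRUE
#>         cond     5.5101615 1.2395169        1.0000000        TRUE
#>       secchi    -4.0784206 1.1535243        1.0000000        TRUE
#>    lakes10km     0.1032374 0.3772691        0.2695235       FALSE

evaluate_predictions(y, predict_average(avg, X))
#> threshold = 0.42
#>          observed
#> predicted absent present
#>   absent      87      15
#>   present     20      54
#> PCC = 80.1%  sens = 0.783  spec = 0.813  kappa = 0.588 (SE 0.062)

permutation_null(occupancy_frequencies(sim$occ), S = 6, n_sites = 176,
                 B = 2000, seed = 43, observed = obs)
#> null_model_result: S = 6, B = 2000
#> mean empty = 0.579  95% CI [0.159, 0.830]
#> observed = 0.608  two-sided p = 0.9645
```

Read together: the nutrient, conductivity and clarity coefficients are
strong and significant (local conditions matter — these are the true
generating effects), yet the observed 60.8% of sites without floating
plants sits well inside the random-assembly interval for a 6-species pool
(p = 0.96) — a pool this small is expected to be absent from most sites
by chance alone. Both things can be true at once, which is the point of
running both analyses.

The same workflow runs end to end from a YAML configuration with
`run_pipeline(read_pipeline_config("config.yml"), seed = 1, out_dir = "out")`,
which writes candidate-model, averaged-coefficient, evaluation,
null-model and PCA tables plus a JSON summary stamped with the seed and
config hash.

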