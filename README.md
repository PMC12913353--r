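# sifibci

Bayesian causal inference (BCI) modelling of the **sound-induced flash
illusion** across two stimulus dimensions: numerosity and time.

## The problem

When one flash is paired with two beeps, observers often report two flashes
(fission illusion); two flashes with one beep are often seen as one (fusion
illusion). The BCI account treats this as rational inference: the observer
weighs the hypothesis that flashes and beeps came from one audiovisual event
against the hypothesis of independent sources, and mixes the corresponding
estimates by their posterior probabilities. This package implements a
two-dimensional BCI observer in which *numerosity* evidence
(x_V, x_A) and *onset-time* evidence (t_V, t_A) are conditionally independent
channels that jointly drive the causal inference — so a large onset
asynchrony between streams weakens the illusions even when the counts
conflict in the usual way.

The observer receives Gaussian-noised evidence per present modality,

    x_A ~ N(s_A, sigma_A^2)    x_V ~ N(s_V, sigma_V^2)
    t_A ~ N(s_At, sigma_At^2)  t_V ~ N(s_Vt, sigma_Vt^2)

with Gaussian priors N(mu_p, sigma_p^2) over numerosity and
N(mu_tp, sigma_tp^2) over event time. Marginalizing the latent sources gives
closed-form likelihoods for the common-cause (C = 1) and independent-cause
(C = 2) structures; the posterior probability of a common cause is

    p(C=1 | x,t) = L1_num * L1_t * p_c / (L1_num * L1_t * p_c + L2_num * L2_t * (1 - p_c))

and each modality's continuous estimate is the model average
`p(C=1|.) * fused + p(C=2|.) * segregated` of precision-weighted estimates,
read out as the nearest response key in {0, 1, 2}. Fitting is by multinomial
maximum likelihood over the 3x3 joint response cells (marginal cells for
unisensory trials), with cell probabilities from common-random-number Monte
Carlo simulation, and four nested observer variants (2D BCI, numerosity-only
1D BCI, forced fusion, flat-prior cue combination) are compared by BIC. See
`vignettes/multidimensional-bci.Rmd` for the full model account.

Audience: computational cognitive scientists fitting trial-level
flash/beep report data (or simulating such experiments) who want a
reproducible reference implementation of the multidimensional BCI observer.

## Worked example

Simulate one observer from the default (group-mean) parameters over the
standard 20-condition design, fit the 2D model, and inspect the result:

```r
library(sifibci)

design <- build_design()          # 20 conditions x 10 reps = 200 trials
obs <- simulate_observer(design, bci_params(), seed = 7)
fit <- fit_bci(obs, variant = "bci2d",
               control = bci_control(n_mc = 6000, restarts = 10, seed = 1,
                                     refine_n_mc = 36000))
fit
```

```
Causal-inference observer fit, variant 'bci2d' (5 free parameters, 200 trials)
 sigma_v  sigma_a p_common  sigma_p     mu_p
  0.7029   0.3249   0.6366   0.9997   1.3546
logLik = -167.728, BIC = 361.948, R^2 = 0.9416, converged: TRUE
```

The recovered noise SDs, common-cause prior and numerosity prior sit near
the generating values (0.63, 0.33, 0.62, 1.33, 1.43) and the model
reproduces about 94% of the variance in this observer's response-category
proportions. (The prior parameters are weakly identified from a single
observer's 200 three-category reports and scatter across observers;
`recover_parameters()` runs the cohort-level recovery study where the means
behave.) The illusion's temporal signature is visible directly in the
simulator: the probability of reporting two flashes when one flash is paired
with two beeps falls as the streams are pulled apart in time:

```r
sapply(c(0, 150, 300, 500), function(soa)
  sum(response_distribution(1, 2, soa, n_mc = 1e5, seed = 1)$table["2", ]))
#> [1] 0.58531 0.40367 0.22296 0.20643
```

Model comparison across a small synthetic cohort ranks the generating 2D
model ahead of its nested alternatives by BIC:

```r
cohort <- simulate_cohort(4, design = design, seed = 9)
compare_bci_models(cohort, c("bci2d", "fusion", "mle"),
                   control = bci_control(n_mc = 3000, restarts = 3,
                                         maxit = 300, seed = 2))
```

Datasets round-trip through a flat CSV schema (`write_bci_data()` /
`read_bci_data()`), and `run_simulate()` / `run_fit()` / `run_compare()` /
`run_recover()` (plus the `inst/cli/bci-cli.R` wrapper) provide file-based
pipeline runs with reproducibility manifests.

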