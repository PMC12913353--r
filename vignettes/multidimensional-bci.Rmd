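---
title: "A numerosity-by-time Bayesian causal inference observer for the sound-induced flash illusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A numerosity-by-time Bayesian causal inference observer for the sound-induced flash illusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sifibci)
```

## The problem this package models

In the sound-induced flash illusion (SiFI), the number of flashes an observer
reports is pulled toward the number of concurrent beeps: one flash with two
beeps is often seen as two flashes (fission), two flashes with one beep as one
flash (fusion). Bayesian causal inference (BCI) explains this as a rational
decision: the observer weighs the hypothesis that flashes and beeps came from
a single audiovisual event (in which case the cues should be combined) against
the hypothesis of two independent sources (in which case each modality should
be judged on its own), and mixes the two answers by their posterior
probabilities.

`sifibci` implements a *two-dimensional* version of that observer. Evidence
about numerosity and evidence about stimulus timing are treated as separate,
conditionally independent channels that jointly drive the causal inference: a
large onset asynchrony between the streams is evidence for independent
sources even when the counts agree, and vice versa. The package provides the
closed-form probabilistic machinery, a trial-level Monte Carlo simulator, a
maximum-likelihood fitting routine for discrete 0/1/2 report data, BIC-based
comparison of four nested observer variants, and a synthetic-cohort generator
emulating the standard 20-condition flash/beep design.

## The generative model

A trial presents $s_V \in \{0,1,2\}$ flashes and $s_A \in \{0,1,2\}$ beeps
(at least one stream present), with the first onsets of the two streams
separated by an SOA of 0, 150, 300 or 500 ms. The observer receives four
noisy internal measurements, all Gaussian and mutually independent:

$$x_A \sim N(s_A, \sigma_A^2), \quad x_V \sim N(s_V, \sigma_V^2), \quad
  t_A \sim N(s_{At}, \sigma_{At}^2), \quad t_V \sim N(s_{Vt}, \sigma_{Vt}^2),$$

where $s_{Vt}, s_{At}$ are the true first-onset times measured from the
trial's temporal reference (the onset of the first stimulus in the sequence).
Numerosity has a Gaussian prior $N(\mu_p, \sigma_p^2)$ and event time a
Gaussian prior $N(\mu_{tp}, \sigma_{tp}^2)$.

Under a common cause ($C=1$) one latent source generates both modalities'
evidence in each dimension; under independent causes ($C=2$) each modality
has its own latent source. Marginalizing the latents gives closed Gaussian
forms, e.g. for numerosity

$$p(x_V, x_A \mid C=1) = \int N(x_V; s, \sigma_V^2)\, N(x_A; s, \sigma_A^2)\,
  N(s; \mu_p, \sigma_p^2)\, ds
  = N(x_V - x_A;\, 0,\, \sigma_V^2 + \sigma_A^2)\cdot
    N(w;\, \mu_p,\, \sigma_w^2 + \sigma_p^2),$$

with $w$ the precision-weighted mean of $x_V, x_A$ and $\sigma_w^2$ its
variance, and

$$p(x_V, x_A \mid C=2) = N(x_V; \mu_p, \sigma_V^2 + \sigma_p^2)\cdot
  N(x_A; \mu_p, \sigma_A^2 + \sigma_p^2).$$

The temporal factors have the identical structure with
$(\sigma_{Vt}, \sigma_{At}, \mu_{tp}, \sigma_{tp})$. Because the two
dimensions are conditionally independent given $C$, the posterior probability
of a common cause is

$$p(C=1 \mid x_V, x_A, t_V, t_A) =
  \frac{L^{num}_1 L^{t}_1\, p_c}
       {L^{num}_1 L^{t}_1\, p_c + L^{num}_2 L^{t}_2\, (1 - p_c)},$$

with $p_c$ the prior probability of a common cause. Conditional estimates are
precision-weighted means — the fused estimate combines $x_V$, $x_A$ and the
prior; each segregated estimate combines one cue with the prior — and the
final continuous estimate per modality is the **model average**
$\hat{s}_A = p(C{=}1|\cdot)\,\hat{s}_{fused} + p(C{=}2|\cdot)\,\hat{s}_{A,seg}$,
which minimizes expected squared error. The discrete report is the nearest
response key in $\{0,1,2\}$ (ties round up). All of this is exposed by
`numerosity_likelihoods()`, `temporal_likelihoods()`,
`posterior_common_cause()`, `estimate_*()` and `discretize_response()`, and is
verified in the test suite against brute-force quadrature oracles to
$|\Delta| < 10^{-8}$.

### A note on the normalizing constant

A plausible-looking alternative denominator for the posterior is the product
of the two per-dimension mixture marginals,
$\big(L^{num}_1 p_c + L^{num}_2 (1-p_c)\big)\big(L^{t}_1 p_c + L^{t}_2 (1-p_c)\big)$.
That expression does not normalize the joint posterior — the probabilities of
the two causal structures need not sum to one under it — so the package
defaults to the standard Bayes normalization above, which is a hard invariant
of a posterior distribution. The product-of-marginals form remains available
via `posterior_common_cause(..., denominator = "marginal")` for sensitivity
analyses.

## Parameters

| Parameter | Meaning | Units | Default |
|---|---|---|---|
| `sigma_v` | visual numerosity noise SD | numerosity | 0.63 |
| `sigma_a` | auditory numerosity noise SD | numerosity | 0.33 |
| `p_common` | prior probability of a common cause | — | 0.62 |
| `sigma_p` | numerosity prior SD | numerosity | 1.33 |
| `mu_p` | numerosity prior mean | numerosity | 1.43 |
| `sigma_vt` | visual onset noise SD | ms | 60 |
| `sigma_at` | auditory onset noise SD | ms | 40 |
| `mu_tp` | temporal prior mean | ms | 100 |
| `sigma_tp` | temporal prior SD | ms | 500 |

The five *free* parameters default to the group-mean estimates reported for
adult observers in this paradigm, so that `bci_params()` out of the box is a
realistic average observer — these are also the generating values used by the
package's own recovery studies. The four *temporal* parameters are fixed, not
fitted: observers report only numerosity, so onset noise is essentially
unconstrained by the data, and fitting it would only soak up degrees of
freedom. Their values follow earlier work with this paradigm. Auditory onset
noise is smaller than visual onset noise, which is what makes audition the
dominant modality at short SOAs.

## The four observer variants

* **`bci2d`** — full causal inference over numerosity and time (free:
  $\sigma_V, \sigma_A, p_c, \sigma_p, \mu_p$; k = 5).
* **`bci1d`** — temporal factors removed from the posterior; causal inference
  on numerosity alone (k = 5).
* **`fusion`** — forced fusion, $p(C{=}1|\cdot) \equiv 1$ (k = 4).
* **`mle`** — forced fusion with a flat numerosity prior: pure
  reliability-weighted averaging (k = 2).

The variants are nested: `fusion` is the $p_c = 1$ slice of `bci2d` (the test
suite checks the two produce bit-identical likelihoods there), and `mle` is
`fusion` with the prior precision sent to zero. Model comparison uses
$\mathrm{BIC} = k \ln n - 2\ell$ with $n$ the number of trials (the
likelihood is a product over trials), and paired t-tests on per-observer BIC
against the 2D model, Bonferroni-corrected.

## Likelihood of discrete reports and fitting

The data are 200 paired 0/1/2 reports. The package treats each trial as a
draw from a multinomial over *response cells*: the 3×3 joint
(flash report, beep report) cell for bimodal trials — the joint cell, rather
than independent per-modality margins, because causal inference predicts
correlated flash/beep errors within a trial — and the 3 marginal cells for
unisensory trials. Cell probabilities have no closed form under model
averaging, so they are estimated by forward Monte Carlo: `n_mc` simulated
trials per condition (default 10,000), with the standard-normal draws frozen
per seed and reused across parameter proposals (common random numbers). The
likelihood surface is therefore deterministic given the seed and safe to pass
to a derivative-free optimizer. Every cell probability is floored at
$\varepsilon = 10^{-4}$ and renormalized — a minimal lapse allowance that
guards $\log 0$ without introducing a free parameter.

`fit_bci()` maximizes this likelihood with Nelder–Mead in a transformed
space: each free parameter is mapped to an unconstrained axis as the log-odds
of its position inside its box (noise SDs in [0.05, 5], $\sigma_p$ in
[0.1, 10], $\mu_p$ in [0, 3], $p_c$ in [0.01, 0.99]). The search restarts
from Latin-hypercube starting points (default 10). A **refinement stage**
then carries the best few mutually distant coarse solutions (default 3 —
i.e. candidate *basins*, not just the single best restart) onto a finer
Monte Carlo surface (default $6 \times$ `n_mc` draws), polishes each with
one more simplex run, and keeps the best refined solution. This stage
matters: with three response categories the profile likelihood of the prior
SD is nearly flat, and at 10,000 draws the Monte Carlo noise floor (a
fraction of a log-likelihood unit, partly driven by floored tail cells) both
strands estimates on the flat ridge toward large $\sigma_p$ and can misrank
the competing basins, so refining only the coarse winner occasionally locks
in a spurious large-$\sigma_p$ corner. On the finer surface the genuine
curvature reappears and the correct basin wins; in the package's own
recovery runs this removed a cohort-level upward bias of about +2 numerosity
units in $\sigma_p$ while leaving the well-identified parameters unchanged.

Goodness of fit is summarized as $R^2 = 1 - SS_{res}/SS_{tot}$ over the
vector of observed response-category proportions (every condition ×
modality × response category, using per-modality marginals), with $SS_{tot}$
about the grand mean of the observed proportions. This is one reasonable
definition among several — a squared correlation over a different cell
vector would give different numbers — and its exact counterpart in earlier
reports of this paradigm is not documented, which should be kept in mind when
comparing absolute $R^2$ values across implementations.

## The synthetic-data generator

`build_design()` reproduces the 20-condition design: four bimodal flash/beep
pairings (1F1B, 1F2B, 2F1B, 2F2B) crossed with four SOAs, plus four
unisensory conditions, 10 repetitions each — 200 trials in pseudorandom
order. Two details are deliberately explicit rather than implicit:

* **Lead convention.** The design only specifies the onset *difference*
  between streams; which modality leads is an explicit `lead` flag (default
  `visual_first`) recorded in every dataset, because the modelled paradigm's
  description is ambiguous on this point.
* **Within-stream timing.** Double stimuli are separated by a 50-ms ISI, but
  only first onsets enter the model; the ISI is design metadata.

`simulate_cohort()` can either give every observer the same generating
parameters (the default, and the configuration used by the acceptance
recovery study) or draw each observer's free parameters around the group
means with SDs from `between_observer_sd()` (group-level SEs scaled by
$\sqrt{24}$), emulating between-subject variability.

What the generator does **not** emulate: attentional lapses and finger
errors beyond the $\varepsilon$ floor, fatigue or sequential effects, session
structure, reaction times, eye movements, or any departure of real observers
from the model family itself. Passing recovery and model-recovery tests
therefore demonstrates internal consistency of the estimation machinery —
that the code can find back what generated its input — not that real
observers obey the model.

## Numerical choices

* All density products are evaluated in log space; the posterior uses
  `plogis` of a log-odds difference, so extreme evidence cannot underflow.
* The discrete readout resolves half-integer ties upward
  (`discretize_response(1.5)` is 2).
* The optional **log-normal** numerosity family replaces Gaussian noise and
  prior with their log-scale counterparts (evidence
  $x = \exp(\log s + \sigma z)$, prior median `mu_p`). Because a log-normal
  likelihood and prior are Gaussian in log-numerosity, the same closed
  Gaussian marginalization applies on the log scale, and posterior-mean
  estimates are $\exp(m + v/2)$; no quadrature is needed at run time.
  Quadrature versions remain in the test suite as independent oracles. The
  temporal dimension stays Gaussian. This family is a robustness check for
  the Gaussian assumption on a strictly positive quantity, not the default.
* Unisensory trials bypass causal inference entirely (with one stream absent
  the causal structure is undefined) and use the single-cue shrinkage
  estimate of the present modality.
* The C++ Monte Carlo kernel and a vectorized R implementation of the same
  map are cross-checked for exact (integer count) equality in the tests.

### Problem sizes used by the tests and the acceptance study

The package's own validation uses sizes chosen to make the statistics
meaningful at interactive run times: oracle equivalence on 1,000 randomized
parameter/evidence draws; parameter recovery on 8 observers × 200 trials
fitted with 10 coarse restarts at 6,000 draws per condition and refinement at
36,000 (the standalone acceptance script uses the same search at the full
default 10,000/60,000 draws); model recovery on 12 + 12 observers with a
proportionally reduced fit budget; and 100,000-draw response distributions
for the SOA-monotonicity checks. Changing these sizes changes only the precision of
the checks, not the code paths exercised.

## Known limitations

* The temporal parameters are fixed by convention; datasets with explicit
  timing judgments would be needed to estimate them.
* Monte Carlo cell probabilities make the maximized log-likelihood an
  estimate; BIC differences well inside one log-likelihood unit should not be
  over-interpreted.
* The prior parameters $(\sigma_p, \mu_p)$ are weakly identified from 200
  trials of 3-category reports; single-observer estimates scatter widely even
  with refinement, and only cohort-level summaries are well behaved.
* Numerosities are capped at 2 by the paradigm; nothing in the code
  generalizes the readout beyond three response keys.
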