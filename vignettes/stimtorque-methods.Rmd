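---
title: "Methods: hierarchical Bayesian modelling of stimulus-evoked joint torque"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical Bayesian modelling of stimulus-evoked joint torque}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

When an insect leg muscle is driven with a burst of pulse-width-modulated
(PWM) electrical stimulation, the joint it actuates develops a torque that
grows with the burst duration. `stimtorque` models this stimulus-torque
relationship for a single muscle and a single PWM parameter set (voltage,
frequency, duty ratio held fixed) as a power law in the burst duration
$T$ (seconds):

$$\tau_i \sim N\!\left(\beta_{j(i)}\, T_i^{\gamma_{j(i)}},\ \sigma\right),$$

where $\tau_i$ is the measured joint torque in µNm of stimulation $i$,
$j(i)$ indexes the animal it came from, $\beta$ (µNm·s$^{-\gamma}$) is the
slope or base of the curve, $\gamma$ (dimensionless) its exponent, and
$\sigma$ (µNm) the observation noise, shared across animals within a fit.

Six variants of this one model are compared:

| id  | exponent        | slope level            | exponent level          |
|-----|-----------------|------------------------|-------------------------|
| 1-1 | $\gamma \equiv 1$ | shared $\beta$       | —                       |
| 1-2 | $\gamma \equiv 1$ | $\beta_j \sim N(\mu_\beta, \sigma_\beta)$ | — |
| 2-1 | free            | shared $\beta$         | shared $\gamma$         |
| 2-2 | free            | $\beta_j \sim N(\mu_\beta, \sigma_\beta)$ | shared $\gamma$ |
| 2-3 | free            | shared $\beta$         | $\gamma_j \sim N(\mu_\gamma, \sigma_\gamma)$ |
| 2-4 | free            | $\beta_j \sim N(\mu_\beta, \sigma_\beta)$ | $\gamma_j \sim N(\mu_\gamma, \sigma_\gamma)$ |

The hierarchical levels express inter-individual variation: each animal has
its own slope and/or exponent, drawn from a population normal whose mean
and SD are themselves estimated. The scientific question the comparison
answers is *which* parameters vary across individuals: a hierarchical level
pays a predictive price if the data do not support the extra spread.

All fits are per (muscle, voltage) condition; conditions are never pooled,
and there is no covariate for voltage, frequency or duty ratio inside a fit.
Durations are in seconds everywhere; consequently $\beta$ is µNm·s$^{-\gamma}$.
Fits use the full 0–1 s duration range by default; a burst-duration cutoff
(e.g. 0.5 s, the range over which the torque response is close to linear)
is available as the `cutoff_s` configuration key.

## Priors

Top-level parameters get independent non-informative uniform priors:
$\beta, \mu_\beta \in [0, 1000]$ µNm·s$^{-\gamma}$,
$\gamma, \mu_\gamma \in [0, 3]$, $\sigma, \sigma_\beta \in (0, 200]$ µNm,
$\sigma_\gamma \in (0, 3]$. These are generous relative to the torques the
experiment produces (of order 0–120 µNm over durations up to 1 s) and to the
exponents reported for insect muscle (near or below 1); all bounds are
configurable through `prior_spec()`. Per-animal parameters of hierarchical
variants are not additionally bounded: their prior is the population normal.

One consequence worth knowing: with only $J = 10$ animals informing
$(\mu_\beta, \sigma_\beta)$, the uniform prior on $\sigma_\beta$ leaves a
heavy right tail in its posterior. This widens the new-animal predictive
distribution and is part of why hierarchical and pooled models can be closer
in predictive score than a plug-in comparison would suggest (see the section
on model comparison below).

## Sampling

`sample_posterior()` is a self-contained adaptive random-walk
Metropolis-within-Gibbs sampler. Design choices:

* **Updates.** Each free parameter in turn gets a Gaussian proposal; scale
  parameters ($\sigma, \sigma_\beta, \sigma_\gamma$) are proposed on the log
  scale with the Jacobian correction and reported on the natural scale.
* **Adaptation.** Proposal scales adapt in batches of 25 warmup iterations
  toward a 0.44 acceptance rate with diminishing gains, then freeze; the
  kept draws come from a fixed kernel.
* **Joint moves.** Single-site samplers mix poorly across three known
  posterior ridges, so each iteration adds: (a) a translation of a
  hierarchical mean together with all its children ($\mu_\beta$ and every
  $\beta_j$); (b) a "funnel" move scaling a hierarchy SD and its children's
  deviations together, which is what makes $\sigma_\gamma \to 0$ posteriors
  (data without exponent spread) mix; and (c) a slope-exponent trade that
  shifts $\gamma$ while rescaling the whole $\beta$ block so the mean curve
  is preserved at the geometric-mean duration, with the exact Jacobian in
  the acceptance ratio.
* **Initialization.** Random draws from the priors (hierarchical children
  from their population normal given the drawn hyperparameters), retried up
  to 10 times if the log posterior is non-finite.
* **Determinism.** Every chain runs on an RNG stream derived from the
  configuration seed by a fixed splitting rule; identical configurations
  give bit-identical draws.
* **Defaults.** 4 chains × 1000 warmup × 1000 kept draws. The package's own
  simulation tests run 2 chains × 800 × 600, the shortest configuration at
  which every variant passes the convergence check on the reference
  conditions below.

Convergence is assessed with the split-chain Gelman-Rubin statistic
(`compute_rhat()`): each chain is halved and
$\hat R = \sqrt{((n-1)/n\,W + B/n)/W}$ is computed over the $2m$
half-chains, with a pass threshold of 1.10. The split form is used because
it also detects within-chain drift; it is strictly more conservative than
the unsplit statistic. Parameters with zero within-chain variance (e.g.
deliberately fixed ones) report `NaN` with a warning and are excluded from
the pass decision. Effective sample sizes use averaged within-chain
autocovariances with Geyer's initial positive-sequence truncation.

## New-animal WAIC

Models are compared by the widely applicable information criterion computed
for the *new-animal* predictive task: for each posterior draw, per-animal
parameters are integrated out over their population distribution, so
hierarchical and non-hierarchical variants are scored on the same question —
how well do they predict torques from an unseen individual. Per observation
$i$ with per-draw log marginal densities $\ell_{is}$:

$$\mathrm{lppd}_i = \operatorname{logsumexp}_s(\ell_{is}) - \log S, \qquad
  p_i = \operatorname{Var}_s(\ell_{is}),$$
$$\mathrm{WAIC} = \frac{1}{n}\sum_i (-\mathrm{lppd}_i + p_i).$$

This is the training-loss + functional-variance form (no ×2 deviance
factor); smaller (more negative) is better. Rankings are invariant to that
convention. All reductions over draws go through log-sum-exp; raw
exponentials of extreme values never occur.

**Marginalization.** The slope hierarchy has an exact Gaussian marginal,
because the mean is linear in $\beta$:
$\tau \mid T \sim N(\mu_\beta T^{\gamma}, \sqrt{\sigma_\beta^2 T^{2\gamma} + \sigma^2})$.
Both this closed form and a Simpson-quadrature path are implemented and
agree to better than $10^{-9}$ in log density; the quadrature path exists as
a cross-check and as the template for the exponent hierarchy, which has no
closed form. For model 2-3, Simpson quadrature runs over $\gamma$; for
model 2-4, $\beta$ is marginalized analytically *inside* the
$\gamma$-integrand, leaving a one-dimensional integral (a full 2-D Simpson
mode exists for cross-checking and agrees to $10^{-6}$).

**Quadrature settings.** 201 Simpson nodes over $\mu \pm 8$ population SDs.
The node count is far into the converged regime (doubling it changes WAIC
by less than $10^{-6}$); the range matters more, because the error is
dominated by the truncated tail rather than the Simpson $h^4$ term. At
$\pm 6$ SDs the worst-case log-density error against the closed form is
about $4 \times 10^{-6}$ (independent of node count); at $\pm 8$ SDs it
drops to about $2 \times 10^{-12}$. That truncation-dominance is why the
default range is wider than the conventional six sigmas.

**Ranking.** `compare_models()` sorts ascending by WAIC; exact ties break
toward fewer parameters, then lexicographic model id. Results computed on
different datasets refuse to compare.

## The synthetic experiment

`generate_dataset()` emulates the structure of the stimulation experiment
the package is designed around: $N = 10$ animals per muscle, each
stimulated tens of times per PWM voltage, burst durations varied at random
over (0, 1] s, torques of order 0–120 µNm, per-animal slope variation.
Defaults, chosen once as the reference study conditions:

* **Population truth**: $\mu_\beta = 100$ µNm/s, $\sigma_\beta = 30$,
  $\gamma = 1$, $\sigma = 10$ µNm (a linear slope hierarchy, generating
  model 1-2).
* **Counts**: per-animal stimulation counts drawn uniformly from 37–95, the
  range observed per animal and voltage in the emulated experiment, unless
  given explicitly.
* **Durations**: i.i.d. uniform on (0.02, 1.0] s. The lower edge is one PWM
  period at the standard 50 Hz carrier — a burst shorter than one period is
  not physically meaningful. The empirical duration distribution of the
  real experiment is not documented beyond "random in 0–1 s"; uniform is an
  assumption, and any operator bias toward particular durations is one
  feature of real data this generator does not reproduce.
* **Noise**: Gaussian on the torque; negative simulated torques are allowed,
  as negative measured values occur in practice near zero duration.
* **RNG**: one root seed; each animal consumes its own derived stream, so
  extending an experiment with more animals never perturbs the data of
  earlier animals.

`generate_force_trace()` additionally synthesizes raw force-sensor traces
(flat zero-mean baseline, half-sine deflection inside the stimulus window)
whose noiseless peak-to-peak amplitude encodes a requested torque exactly,
as a fixture for the torque-extraction pipeline. It is a unit-faithful
stand-in, not a biomechanical simulation: real sensor transients (muscle
activation dynamics, low-pass behaviour, drift) are out of scope.

What passing the simulation tests shows, therefore, is that the inference
machinery recovers the parameters of data that *match the model's
assumptions* at realistic sizes and noise levels — not that the model is
adequate for any particular real dataset. Fatigue, warm-up, operator
duration bias and non-Gaussian sensor noise are all absent from the
generator on purpose.

## Torque extraction

The calibration-and-extraction pipeline converts raw sensor voltages to
torques in three steps: (1) peak-to-peak sensor value within the stimulus
window, after subtracting the pre-stimulus baseline mean (so a constant
offset on the whole trace changes nothing); (2) conversion to force via a
calibration factor (mN/V) fitted by least squares *through the origin* on
known masses — after baseline subtraction, zero deflection means zero force
for a strain gauge, so the intercept is physical, with $g = 9.81$ m/s²
converting grams to mN; (3) multiplication by the moment arm (mm), the
distance from the joint axis to the transducer attachment point. The unit
chain V × mN/V × mm = µNm is exact, with no hidden factors. Whether the
original pipeline referenced the peak-to-peak value to a baseline is not
documented; baseline-referencing is this package's choice, and it is the
choice that makes the zero-torque trace read exactly zero.

## Numerical conventions and degenerate cases

* Uniform priors evaluate to their normalized density, so `log_prior()` is
  comparable across prior boxes; outside any bound it is $-\infty$.
* `waic()` with a single draw sets the functional variance to 0 and warns
  (the variance of one value is undefined; the degenerate case exists for
  tests).
* Zero within-chain variance yields `NaN` Rhat with a warning rather than
  an error, so fixed-parameter runs remain diagnosable.
* `logsumexp([a, a]) = a + log 2` exactly even at $a = -1000$.
* Exponent exactly 1 takes the linear code path, so the nesting identity
  between models 2-1 and 1-1 holds bit-exactly.
* Predictive surfaces are normalized in the sense that each
  duration-column integrates to 1 within $10^{-3}$ when the torque grid
  spans ±8 predictive SDs; `cmd_predict()` builds such a grid
  automatically.

## What the model comparison can and cannot show at these sizes

The package's repeated-simulation tests document two facts worth keeping
apart. Parameter recovery is reliable: fitting model 1-2 to data from the
reference truth recovers $\mu_\beta, \sigma_\beta, \sigma$ within 3
posterior SDs in ≥ 90% of seeded replicates. Model *identification* through
new-animal WAIC, however, is genuinely weak at the reference conditions.
With 10 animals, the hierarchical model's predictive advantage over the
pooled one (~0.08 per observation in log score at $\sigma_\beta = 30$,
$\sigma = 10$, and proportional to the *realized* squared animal spread,
which varies a lot across draws of 10 animals) is largely offset by the
extra functional-variance penalty its hyperparameter uncertainty incurs
(~0.06 per observation). The winner among the slope-hierarchy and pooled
variants is then close to a coin flip, and the package's tests assert only
the selection properties that are actually stable: the mismatched
exponent-only hierarchy (2-3) ranks reliably last, and the doubly
hierarchical model is not reliably worst when the data truly contain both
hierarchies. Decisive selection of the slope hierarchy requires either more
animals, a larger population spread relative to $\sigma$, or scoring whole
animals (a per-group joint marginal) rather than single observations — the
per-observation form is the one implemented, matching the convention of the
analysis this package reproduces.

## Problem sizes used by the test-suite and acceptance script

Simulation-heavy checks run on the reference conditions (10 animals × 60
stimulations) with 2 chains × 800 warmup × 600 kept draws: 20 replicates
for recovery, 10 for model selection, with all six variants fitted per
replicate in the selection runs. These sizes were chosen as the smallest at
which every variant passes the split-Rhat check on the reference
conditions; estimates at the package defaults (4 × 1000 × 1000) agree to
well within Monte-Carlo error.

## Known limitations

* The built-in sampler is a random-walk method; posteriors with much higher
  dimension (many more animals) or stronger ridges than the six variants
  produce here would be better served by a gradient-based backend behind
  the same `sample_posterior()` contract.
* The new-animal WAIC is per-observation; per-animal (joint) predictive
  scoring is not implemented.
* No PSIS/LOO-CV, DIC or BIC — WAIC is the only comparison implemented.
* The torque-extraction step does no filtering beyond baseline subtraction
  and no automatic stimulus-window detection; windows are supplied by the
  caller.
* Voltage enters only as a grouping label; no joint model across voltages
  is fitted, so cross-voltage summaries are tabulations of per-condition
  posteriors.
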