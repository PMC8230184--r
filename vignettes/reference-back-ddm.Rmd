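---
title: "Modeling reference-back working-memory control with the diffusion decision model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling reference-back working-memory control with the diffusion decision model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refbackddm)
```

## The task and the scientific question

In the reference-back task a probe (an `X` or an `O`) appears inside a red or
blue frame. The subject holds a *referent* in working memory (WM) — the
stimulus of the most recent red-framed trial — and answers on every trial
whether the probe is the *same* as or *different* from that referent. Red
frames additionally instruct the subject to *update* the referent with the
current probe (reference trials); blue frames instruct *maintenance*
(comparison trials). Crossing the updating factor with whether the updating
mode switched relative to the previous trial, and with probe–referent match,
yields a 2×2×2 design of eight cells. Contrasts between cells define six
canonical control costs — updating, comparison, switching, gate opening,
gate closing, and substitution — each usually observed as slower and/or less
accurate responding.

These costs are aggregate behavioral signatures; they do not by themselves
say *where* in the decision architecture the cost arises. This package casts
the question in terms of the diffusion decision model (DDM): noisy evidence
about probe–referent match accumulates at drift rate $v$ from relative start
point $z$ between two absorbing boundaries separated by $a$, and observed
response time adds a non-decision component $t_0$. Costs can then be
attributed to slower accumulation (lower $v$, e.g. reactive inhibition of a
prepotent response), extra processes outside the decision stage (higher
$t_0$, e.g. the WM update itself), or strategic caution shifts (higher $a$
when cued to update). The package provides everything needed to run the full
analysis on trial-level choice–RT data: the DDM likelihood, the task
annotation, synthetic data generation, per-subject and hierarchical Bayesian
estimation, DIC model selection, posterior contrasts, predictive checks, and
a parameter-recovery study.

Because the empirical dataset this analysis pipeline targets is not publicly
archived, every study in the package runs on synthetic data whose design
(512 trials in 4 blocks per subject; first trial of each block red-framed
and unanswered; frames and probes otherwise i.i.d. equiprobable) mirrors the
task as administered.

## The likelihood

The first-passage-time density of the Wiener process with absorbing
boundaries is evaluated by the standard pair of series expansions
(a small-time and a large-time representation), switching to whichever needs
fewer terms under an adaptive truncation bound targeting absolute error
$10^{-8}$. Conventions, fixed once and used everywhere:

* diffusion coefficient $s = 1$ (the modern scaling); $v$, $a$, $sv$ are on
  that scale;
* $z$ and $sz$ are *relative* (fractions of $a$), so a single start-point
  parameter is meaningful when thresholds differ between updating modes;
* the upper boundary codes the "same" response. Each design cell carries a
  drift *magnitude* toward the correct response; the signed drift passed to
  the density is $+v$ in "same" cells and $-v$ in "different" cells, so $z$
  expresses response bias toward "same";
* across-trial Gaussian drift variability ($sv$) is marginalized
  analytically; uniform start-point variability ($sz$) by fixed-order
  Gauss–Legendre quadrature (order 11);
* drift criterion and non-decision-time variability are fixed at zero
  (scaling constraint); densities are floored at $10^{-10}$ before logs so
  stray outlier RTs cannot destabilize sampling.

The companion simulator draws exact Gaussian increments on a 1 ms grid with
a Brownian-bridge correction for within-step boundary crossings and a
half-step continuity correction of the recorded RT. It shares no code with
the density series, which makes simulator-versus-density agreement
(Kolmogorov–Smirnov distance below 0.01 at $n = 10^5$) a genuine two-route
consistency check; a third, plain-R Euler simulator serves as a brute-force
oracle in the unit tests.

## Model variants

Four factorial variants formalize the competing explanations:

| variant | drift | non-decision | threshold | free parameters |
|---|---|---|---|---|
| top | 8 cells | 8 cells | reference/comparison | 21 |
| threshold-fixed | 8 cells | 8 cells | 1 | 20 |
| drift-fixed | 1 | 8 cells | reference/comparison | 14 |
| ndt-fixed | 8 cells | 1 | reference/comparison | 14 |

Every variant has exactly one $z$, one $sz$ and one $sv$. Because switch
status is undefined across block boundaries, the first trial of a block is
excluded; trial 2 is annotatable, with its switch status defined against the
forced red first trial (a choice this package declares, since either
convention is defensible).

## Estimation

Sampling is differential-evolution MCMC: each of $k$ interacting chains
proposes its current state plus $\gamma\,(x_{r_1} - x_{r_2})$ from two other
randomly chosen chains, with $\gamma = 2.38/\sqrt{2d}$ and small uniform
jitter; during burn-in a 5% migration probability lets a random ring of
chains exchange states. The default chain count is $3d$. Chains start
scattered around a posterior mode located by Nelder–Mead, so burn-in only
has to adapt the proposal geometry rather than find the high-density region;
prior-draw initialization remains available (`init = "prior"`) and requires
substantially longer burn-in.

Priors are independent truncated normals at each parameter's support —
drift magnitudes $N(2,3)$ on $(0,10)$, thresholds $N(1.5,1)$ on $(0.1,5)$,
$z$ $N(0.5,0.2)$ on $(0.05,0.95)$, $t_0$ $N(0.3,0.2)$ on $(0.05,1)$ s, $sv$
$N(1,1)$ on $(0,5)$, $sz$ $N(0.2,0.2)$ on $(0,0.9)$ — all configurable. The
hierarchical model places truncated-normal population distributions over
each free parameter (hyper-mean priors as above; half-normal scale-1 priors
on hyper-SDs). Because the hyper-parameter conditionals factorize per
parameter given the subject-level draws, the group level is updated by
componentwise DE-Metropolis on each (hyper-mean, hyper-SD) pair — a
deliberate choice that mixes far better than joint proposals over the full
group block — while each subject's block is updated jointly against its
likelihood and the current population distribution.

Convergence is summarized by split-chain R-hat; downstream analyses
(`effect_posterior()`, `posterior_predictive()`) refuse draws whose R-hat
exceeds 1.1 unless explicitly overridden. Everything is reproducible from
the seed in `sampler_config()`.

Model selection uses DIC with $p_D = \bar D - D(\bar\theta)$ (Spiegelhalter
form). If the posterior-mean vector falls outside the joint support (possible
with the $z \pm sz/2$ constraint), $D$ is evaluated at the
highest-posterior draw instead and the fallback is recorded.

## Cost contrasts and posterior inference

A single 6×8 weight matrix (`cost_weights()`) defines the contrast algebra
once, and is used verbatim for (i) empirical RT/accuracy costs, (ii)
posterior contrasts of hyper-mean parameters, and (iii) costs computed on
posterior predictions — one source of truth for all three. Updating and
comparison contrasts use no-switch cells only; the substitution contrast is
the updating-by-match double difference, averaged over switch levels (its
textbook derivation collapses the switching factor). RT costs are signed
costly-minus-baseline differences of mean correct RT; accuracy costs are
baseline-minus-costly, so "worse when costly" is positive for both. Cell
summaries and costs are computed per subject, then averaged (subjects as the
random effect); error-trial RTs enter only the error quantile summaries.

For each contrast the posterior distribution over hyper-means yields the
mean $M$, SD, standardized magnitude $Z = M/SD$, an equal-tailed 95%
credible interval, and a one-tailed Bayesian $p$ — the posterior probability
that the effect does not run in its most-sampled direction,
$p = \min\{P(D<0), P(D>0)\}$ with ties at zero split evenly (a degenerate
all-zero contrast reports $p = 0.5$, $Z = 0$ by convention).

## Synthetic data: what it emulates and what it does not

`simulate_dataset()` reproduces the session structure, the annotation rules,
and choice–RT generation from subject parameters drawn from truncated-normal
populations. The default generating group (`default_group_model()`) encodes
the qualitative pattern reference-back studies report — lower drift and
longer non-decision time on reference, switch, and mismatch trials, and a
higher threshold in updating mode — at magnitudes in the mid-range of the
DDM literature ($v$ between 1.6 and 3.5 across cells, $t_0$ 0.30–0.41 s,
$a$ 1.2/1.35, $z = 0.5$, $sv = 0.8$, $sz = 0.15$; hyper-SDs 0.35, 0.035,
0.12 for $v$, $t_0$, $a$). These are fixture values, not estimates.
`flat_group_model()` provides null groups and explicit planting of updating
effects for calibration studies. An optional contamination mode injects
uniform fast guesses and slow stragglers (default 1% when enabled) to
exercise the outlier filter, which removes responses faster than 150 ms or
slower than 3 s (strict inequalities) along with the unanswered first trial
of each block.

What the generator deliberately does not emulate: sequential carry-over
effects (priming, task-set inertia, Gratton-type adjustments), trial-to-trial
learning of control settings, the two-session structure of multi-session
samples (beyond a trial-count option), and any non-DDM contamination beyond
the uniform outliers. Passing recovery and calibration tests on these data
therefore demonstrates the estimation machinery is correct and calibrated
*under the model*, not that real reference-back data are free of such
effects.

## Study designs used by the checks

The packaged studies are sized to run on a single CPU in minutes while
retaining diagnostic power; all sizes are stated where they are used:

* *Recovery*: 20 subjects × 512 trials from the default group; hierarchical
  refit (36 chains, 350 burn-in + 300 retained). The hierarchical estimator
  is the package default for recovery because it is the same estimator used
  for group-level inference; its shrinkage is part of the procedure being
  validated. Per-subject refits (no shrinkage) are available and are
  calibrated but attenuated — with ~64 trials per design cell a drift
  magnitude has posterior SD around 0.3–0.4, which caps the attainable
  true-versus-recovered correlation.
* *Planted effects*: 12 subjects × 512 trials with a drift deficit of 1.0
  and a non-decision increase of 0.10 s in reference cells.
* *Null calibration*: three replicate groups of 10 subjects × 256 trials
  with no planted effects; the Bayesian $p$ of the twelve drift and
  non-decision contrasts should exceed 0.05 in at least ~90% of cases.
* *DIC*: 20 subjects × 256 trials generated from the drift-fixed model; the
  median DIC difference should not favor the top model.
* *Predictive coverage*: 100 posterior predictive replicates per fit; at
  least ~90% of observed per-cell accuracies and RT quantiles should fall in
  the 95% predictive intervals.

## Numerical choices and degenerate inputs

* Series truncation targets $10^{-8}$ absolute error; the truncation bound
  is computed once per evaluation at the largest quadrature-node leading
  factor (plus one safety term).
* The defective CDF integrates the density on a grid with spacing at most
  0.5 ms (trapezoid rule) and interpolates linearly; `Inf` maps to the
  absorption probability.
* Invalid parameter regions (including $z \pm sz/2$ outside $(0,1)$) have
  log-posterior $-\infty$; proposals there are rejected.
* Empty design cells are flagged in summaries and excluded from group
  averages; a subject with an empty cell can still be fit (the cell's
  parameters then follow the prior, with a warning).
* Boundary RTs exactly at 0.150 or 3.000 s are retained by the filter
  (strict inequalities).

## Known limitations

The sampler is a general-purpose DE-MCMC; very small trial counts per cell
leave $sv$ and $sz$ weakly identified, and their chains mix slowly (this is
visible in R-hat and does not silently corrupt the better-identified $v$,
$t_0$, $a$). The hierarchical model assumes independent truncated-normal
populations per parameter — no population-level correlations. Non-decision
time variability and drift criterion are fixed at zero by design; race
architectures are out of scope.

## A short worked example

```{r example, eval = FALSE}
spec <- model_spec("top")
group <- default_group_model(spec)
simd <- simulate_dataset(group, spec, n_subjects = 8, seed = 1)

cl <- clean_trials(simd$trials)
costs <- canonical_costs(cell_summary(cl$trials))
costs[, c("measure", "rt_cost", "acc_cost")]

cfg <- sampler_config(n_chains = 36, n_iter = 300, n_burn = 350, seed = 1)
hfit <- fit_hierarchical(cl$trials, spec, config = cfg)
effect_posterior(hfit, "updating", "v", check_convergence = FALSE)
effect_posterior(hfit, "updating", "a", check_convergence = FALSE)
```
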