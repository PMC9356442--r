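---
title: "Simulating response-adaptive randomisation: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating response-adaptive randomisation: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rarsim)
```

## The question and the data-generating model

This package asks how a large fixed-randomisation mortality trial would
have behaved under response-adaptive randomisation (RAR). The simulated
trial recruits patients in daily blocks — 100 blocks of 80 patients in
the two-arm setting (standard care vs dexamethasone, 8000 patients) or
120 in the four-arm setting (adding hydroxychloroquine and
lopinavir-ritonavir, 12 000 patients). Each patient belongs to one of
three respiratory-support subgroups (no oxygen, oxygen only, invasive
ventilation) with mix 24/60/16%, and dies by day 28 with probability
$P_{k,l}$ depending on subgroup $k$ and arm $l$:

$$Y_{i,j,k,l} \sim \mathrm{bern}(P_{k,l}).$$

The default $P_{k,l}$ are the stratified 28-day mortality rates observed
in the real trial (e.g. 41.4% for ventilated patients on standard care
vs 29.3% on dexamethasone; `recovery_two_arm()$mortality` prints the
full matrix). Because 24/60/16% of a block of 80 is non-integer, subgroup
membership is sampled per patient rather than fixed per block; this
matches the marginal mix and contributes the realistic sampling
variation of daily cohorts. Allocation probabilities are likewise
realised by a binomial draw (two arms) or a single multinomial draw
(four arms) per subgroup-block rather than deterministic rounding.

Single-point operating characteristics are taken where the simulated
sample size matches the real trial: at 80% completion, i.e. 6400 or
9600 patients (`metric_cut_fraction`, a scenario field so that the same
machinery yields per-block trajectory metrics).

## Allocation strategies

Writing $\theta(l)$ for the posterior probability that arm $l$ has the
lowest mortality and $s = j/J$ for the fraction of the trial completed
at an adaptation in block $j$, the two-arm dexamethasone probability is

* `FeR` $1/2$, `FuR` $1/3$ (the design used in practice);
* tuning rule `T`: $\theta(1)^s / (\theta(1)^s + (1-\theta(1))^s)$;
* REMAP-CAP rule `RMC`:
  $\sqrt{\theta(1)/(n_1+1)} \big/ \left(\sqrt{\theta(1)/(n_1+1)} +
  \sqrt{\theta(0)/(n_0+1)}\right)$,

with $n_l$ the number of patients on arm $l$ in the outcome-matured
window. The `_f` variants compute one $\theta$ from the whole cohort;
the `_s` variants run an independent copy of the rule inside each
subgroup. Adaptive two-arm probabilities are clipped to $[0.1, 0.9]$.

In the four-arm trial the control arm is fixed at 40% and the same two
rules, normalised over the three experimental arms, share a 0.6 budget.
Experimental probabilities below 0.05 are raised to the floor, the
deficit coming off the single largest arm (ties broken toward the lowest
index — the rule as stated does not fix a tie-break, and a deterministic
choice keeps replicates reproducible).

The exponent $s$ makes the tuning rule nearly indifferent early
($\theta^0$ flattens everything to 1:1) and maximally exploitative at
the end ($\theta^1 = \theta$); the $1/(n+1)$ discount makes the
REMAP-CAP rule self-limiting as one arm accumulates patients. Both
behaviours are visible in the allocation trajectories the engine
records per adaptation.

### Scheduling

Adaptation starts after a 34-block burn-in at the fixed symmetric
allocation (1:1; in the four-arm trial 0.4/0.2/0.2/0.2, keeping the
stated 40% control protection during burn-in as well) and repeats every
7 blocks: blocks 35, 42, …, 98. At block $j$ only blocks $1..j-28$ have
matured 28-day outcomes, so the first adaptation sees exactly the first
week of patients. The observed window is additionally capped at $j-1$,
which is inert for the default lag but makes lag-free configurations
(burn-in 0, cadence 1, lag 0) collapse to a standard bandit loop — a
useful sanity harness that the tests exercise with a stubbed
probability-of-best.

Deaths are *generated* at allocation time but only *revealed* to the
posterior per the lag. Since no metric distinguishes the two, this
choice is unobservable; metrics over the first $n$ patients count their
eventual outcomes (the lag constrains adaptation, not accounting). An
optional `mature_only` flag restricts the power calculation to matured
blocks instead.

## The posterior

The source design's posterior is specified only through its role — the
probability that an arm is optimal. We reconstruct it as independent
beta-binomial models per arm: a uniform Beta(1, 1) prior on each arm's
mortality updated by the windowed deaths/survivors, with "optimal"
meaning lowest mortality. This is the standard construction behind
Thompson-sampling-type rules and matches every qualitative behaviour the
design describes (symmetry during burn-in, the direction and speed of
ramp-up). If the original used a different vague prior (e.g. Jeffreys),
absolute allocation trajectories would shift slightly; the acceptance
tolerances on adaptive quantities are set accordingly.

Two arms: $P(p_1 < p_0)$ is computed by deterministic quadrature of one
beta density against the other's survival function (`integrate`, on the
union of the posteriors' effective supports, absolute tolerance 1e-8;
tested against closed forms and a Monte-Carlo oracle). Four arms:
$\theta$ is Monte Carlo with 10 000 joint draws (SE at most 0.005 per
component; the vector sums to 1 exactly; ties are broken uniformly at
random, though they have measure zero here). In the four-arm trial
$\theta$ compares all four arms including control — "optimal" is defined
against every treatment even though control's allocation is fixed.

Each replicate draws subgroups, allocations, outcomes and posterior
Monte Carlo from four named streams derived from `(seed, label)`, so
changing the posterior draw count cannot perturb patient outcomes, and
replicate seeds derive from `(base_seed, index)`, making batches
order-independent and extendable.

## Metrics

At the cut $n$: deaths among the first $n$ patients; allocation
proportions (cohort and per subgroup). Hypothesis tests fit the
binomial log-odds model of death on an arm indicator vs standard care
by maximum likelihood — for a single binary covariate this is the
saturated 2×2 fit, so the Wald statistic uses the sample log odds ratio
and $\mathrm{SE} = \sqrt{1/a + 1/b + 1/c + 1/d}$ (verified against
`glm` in the tests); a zero cell degenerates the Wald test and the
two-proportion score test is used instead, flagged in the output.
Two-arm tests run at 5%; the four-arm trial tests dexamethasone and
lopinavir at Bonferroni $0.05/3$, and the familywise error is the rate
of any false rejection across the three comparisons. For
subgroup-scoped policies power is reported for the oxygen-only and
ventilated subgroups, where the treatment truly helps.

Treatment effects enter bias and MSE as raw risk differences
$\hat P_{k,0} - \hat P_{k,1}$ from cell proportions at the cut (not
model coefficients — the defining formulas are in terms of estimated
rates):

$$\mathrm{bias}_k = E\!\left[\frac{(\hat P_{k,0}-\hat P_{k,1}) -
(P_{k,0}-P_{k,1})}{P_{k,0}-P_{k,1}}\right],\qquad
\mathrm{MSE} = \frac1N \sum_n \left((\hat P_{k,0}-\hat P_{k,1}) -
(P_{k,0}-P_{k,1})\right)^2.$$

Relative bias is undefined (and skipped) when the true difference is
zero, as in null variants. Although only RAR can induce allocation-
correlation bias, we compute bias for fixed policies too — its being
statistically zero there is itself a property worth asserting. Neyman's
power-optimal allocation $\sqrt{p_0q_0}/(\sqrt{p_0q_0}+\sqrt{p_1q_1})$
on the cohort-weighted rates (0.2570 vs 0.2294) gives the 51/49 split
that explains why 1:1 is nearly power-optimal here.

Cut points in the default designs fall exactly on block boundaries; a
cut inside a block takes that block's cells pro rata, which preserves
expectations for trajectory metrics (tests requiring integer cells
demand block-aligned cuts).

## Problem sizes and what the tests show

The study design uses 1000 replicates, and `scripts/acceptance.R`
reproduces the headline mortality quantities at exactly that size (about
two and a half minutes on one core). The packaged test suite checks the
same quantities with batch sizes fixed in advance by standard-error
arithmetic: 1000 replicates where batches are cheap and the tolerance is
tight in absolute terms (fixed and null designs), 500 for two-arm
adaptive policies, and 300–400 where each replicate carries 10 000-draw
posterior Monte Carlo steps. At those sizes every asserted tolerance is
at least three Monte-Carlo standard errors wide.

Passing tests show that the *generator's* operating characteristics
match the published ones under the stated mortality matrix. They do not
show anything about features the generator deliberately lacks: patient
drift (temporal change in case mix, the key confounder of real RAR),
arm dropping or addition, varying recruitment rates, censoring or
non-binary endpoints. Two published quantities are documented as not
reproduced and are not gated: the printed two-arm 1:1 power (67.7%)
sits below the asymptotic two-proportion value (≈73%) that our
all-outcomes test reproduces — restricting to lag-matured outcomes
lowers power below both, so the original may have used an intermediate
accounting — and the printed absolute four-arm mortality sits about 1%
below the closed-form mixture expectation, so four-arm mortality is
compared as deaths averted versus the 2:1:1:1 reference, which is robust
to that level shift.

## Numerical and degenerate-input choices

* Beta quadrature: `integrate` with tolerance 1e-10 on the union of
  central 1−2e−12 quantile ranges; result clamped to [0, 1].
* Both probabilities-of-best zero in the REMAP-CAP ratio: an error (the
  ratio is undefined), as is an all-zero weight vector in the four-arm
  rules and a floor that the largest arm cannot fund.
* `which.max` tie-break (lowest index) in the floor rule; uniform
  random tie-break in the Monte-Carlo argmin.
* Seeds: a modular hash over `(seed, label)` exact in double
  arithmetic, always below $2^{31}$.
* Empty subgroup in a block: no allocation draw; a subgroup with no
  patients at a cut yields `NaN` proportions rather than a fabricated 0.

## Limitations

Calibration is to one trial's printed mortality table; the scenarios
are a faithful test bed for that trial, not a general epidemic model.
The posterior is a reconstruction (above). Blocks are uniform in size
and composition over time by design — the conclusions therefore speak
to the allocation rules, not to operational feasibility, data-lag
logistics or drift robustness, which the source design itself lists as
open extensions.
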