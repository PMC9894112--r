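---
title: "Models and methods for social-aging analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for social-aging analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Cross-sectional comparisons in group-living animals often show that older
individuals have smaller social networks than younger ones. Two very
different processes can produce that pattern:

* **within-individual change** — individuals prune their own networks as
  they age (social selectivity), or
* **selective disappearance** — mortality is non-random with respect to
  sociality, so the survivors observed at old ages are a biased sample
  and no individual ever changed its behavior.

`socage` implements the full analysis chain used to separate these
processes in longitudinal focal-observation data on adult female
primates: event-level records are reduced to annual social-network
metrics, age is decomposed into within- and between-individual
components, generalized linear mixed models are fitted per prediction,
and an interval-based decision rule tests for selective disappearance.
Because the real long-term field data cannot be redistributed, the
package ships a synthetic-cohort generator with fully known ground
truth, and validates the whole chain against it.

# From events to metrics

The observation model is classic primate field protocol: fixed-duration
focal animal samples (default 600 s) on every adult female, continuous
recording of grooming bouts with direction and duration, instantaneous
proximity scans at evenly spaced points within each focal (default 3),
approach events, and decided agonistic interactions.

Per female and group-year the package computes:

* **degree metrics** — unique grooming partners (given or received),
  unique proximity partners, and directed approach out-/in-degree;
* **strength metrics** — dyadic interaction amounts divided by the
  combined observation effort of the two members (focal seconds for
  grooming, scan counts for proximity), summed over partners;
* **rank** — percent of other females dominated (majority of decided
  dyadic outcomes), binned as high (≥ 80%), medium (50–79%), low
  (≤ 49%). Values in the open interval (79%, 80%), unreachable in small
  groups but possible in general, fall in medium: the bins are read as
  [50%, 80%) and [80%, 100%];
* **kin measures** — pedigree relatedness r = 2φ from the standard
  recursive kinship algorithm, a boundary-inclusive kin cutoff at
  r ≥ 0.125, the proportion of kin among partners (partners are dyads
  with DSI > 0), and kin availability (proportion of kin among the other
  females in the group-year), which enters the kin-proportion model as
  an offset. Missing fathers contribute zero kinship, so purely
  matrilineal pedigrees are supported at the cost of invisible paternal
  kin.

The **dyadic sociality index** (DSI) for a pair is the mean of its
grooming and proximity rates, each standardized by the mean rate over
*all* pairs of subjects co-resident in the group-year, zeros included.
By construction the mean DSI in a group-year with any interaction is
exactly 1, a dyad that never interacts scores 0, and the index is
invariant to rescaling observation effort by a common factor. If one
behavior was never observed in a group-year its standardized term is
defined as 0 for all dyads (logged), rather than 0/0.

For the partner-choice analyses the package builds a "last-year"
dataset: each subject's final observed group-year, paired with every
potential partner present there, with the mean DSI over prior
co-resident years (0 when there are none — including partners first
observed in the final year, whose zeros may understate a relationship
formed before adulthood), a stable-partner flag (DSI > 0 in at least two
consecutive prior years), and whether the dyad was "chosen" (DSI > 0 in
the final year). Subjects need ≥ 2 years of data for the mean-DSI
analysis and ≥ 3 for the stability analysis; dropped subjects remain
available as partners.

# Age decomposition and the Model A / Model B contrast

Chronological age `x_ij` for female `j` in year `i` is split as

```
avg_age_j    = mean of x_ij over the years j was observed
within_age_ij = x_ij - avg_age_j
```

Model A regresses a metric on `within_age + avg_age + rank` (plus a
rank × within-age interaction, retained only when its 95% interval
excludes zero), with random intercepts for individual, group, and year,
and a random slope of within-age over individual. Model B replaces
`within_age` with raw `age`, keeping `avg_age` and dropping the random
slope. The two fixed-effect parameterizations are linear transforms of
one another: the age coefficient in B equals the within-age coefficient
in A, and the avg-age coefficient in B equals the *difference* between
the between- and within-individual slopes. A Model B avg-age interval
that excludes zero therefore flags selective disappearance, with the
sign telling whether low- (positive) or high- (negative) sociality
individuals disappear.

Families per prediction: Poisson (log link) for the degree counts;
zero-inflated beta (logit link) for the strengths; binomial (logit) with
the kin-availability offset for the kin proportion; Bernoulli (logit)
for the dyadic partner-choice models, with subject and partner random
intercepts plus group and year. The kin-availability offset defaults to
`qlogis(kin_available)` — the null model is partners drawn at random
with respect to kinship — with the raw proportion available as an
option. Degree models take no effort offset by default (an optional
log-effort offset exists), since the annual design equalizes effort
across subjects.

Effect sizes for log-link models are reported as the expected percent
change over 8 years for a mid-ranking female at the mean average age:
`100 * (exp(8 * beta) - 1)`, e.g. −38.1% for beta = −0.06.

# Estimation backend

Models are estimated by Laplace-approximate marginal likelihood via
glmmTMB, and 95% Wald intervals supply the interval-based significance
rule (an interval excluding zero). The estimation backend is a
contract, not a mandate: any estimator that passes the package's
parameter-recovery and reparameterization identities is conformant, and
the tests exercise exactly those properties. Two numerical choices
matter in practice:

* **Boundary degeneracies.** When a variance component collapses toward
  zero, or a random-slope correlation is estimated at ±1, the curvature
  matrix can lose positive definiteness and Wald intervals become
  undefined. `fit_glmm()` then applies an explicit simplification
  ladder — correlated slope → uncorrelated (`diag()`) slope →
  intercept only → drop the term — refitting until the fit is regular.
  Every simplification is recorded in the fit's diagnostics; nothing is
  silent.
* **Variance partitioning** is done on the linear-predictor scale:
  fixed-effect variance is the variance of the fixed linear predictor,
  each random term contributes the average of `z' Σ z` over the data
  (so random slopes are weighted by the observed slope covariate), and
  the residual variance is the lognormal approximation
  `ln(1 + 1/λ̄)` for log-link Poisson models and `π²/3` for logit-link
  models. Shares are these components over their total, × 100.

The dyadic partner-choice models approximate the multimembership
random-effect structure (one shared effect pool contributing through
both members of a dyad) with two crossed random intercepts, one for
subjects and one for partners. This estimates separate variances for
the two roles rather than a shared one; with the generator's symmetric
bonds the approximation is benign, but it is an approximation.

# What the synthetic cohort emulates

`sim_params()` defaults describe the study conditions the pipeline is
meant for: about 30 founding matrilines in 6 groups, a 20-year
demographic burn-in so matrilines carry mothers, sisters, aunts and
cousins, 6 study years, roughly 150–200 adult females aged 10+ entering
the models, 20 focal samples of 600 s per female-year with 3 scans per
focal, a median adult lifespan near 18 years from a Gompertz-like
hazard (base 0.02 at maturity, log-slope 0.15/yr), and mean subject age
near 14 years.

Each female carries a latent sociability (SD 0.4 on the log scale) and
a small slope deviation (SD 0.02); groups and years carry small
log-scale effects (SD 0.1 and 0.05) so the model's random-effect
structure is identifiable in fitted data. Expected partner count is

```
lambda = exp(alpha + (beta_within + rank term + slope_dev) * (age - 14.3)
             + sociability + group effect + year effect)
```

with `alpha = log(5)` partners at the reference age. Bonds are realized
as a symmetric dyadic Bernoulli graph with probabilities proportional to
`lambda_i * lambda_j * w_ij / sum(lambda)`, where the dyadic weight
`w_ij` is multiplicative in kin preference (rising with mean dyad age),
the previous year's bond intensity, and two-year stability. The
probability matrix is recalibrated by symmetric iterative proportional
scaling under a cap, so each female's expected bond count equals her
`lambda` — a direct "each female samples her partners" scheme was
rejected because incoming edges would attenuate the realized
within-individual age slope away from `beta_within`. Each female's
annual grooming budget (mean 3000 s, CV 0.2) is age-invariant and split
across her bonds; bouts are exponential (mean 120 s) and packed into
focals without exceeding focal duration. Proximity holds the expected
number of neighbors per scan constant (default 0.6), allocated across a
female's bonds with dyad probability `c0 / max(deg_i, deg_j)`: time in
proximity is then age-invariant (paralleling the constant grooming
budget) and effort-normalized proximity strength stays below 1, while
every bond is still scanned often enough that proximity degree tracks
the bond count. Approach events are Poisson per ordered bonded pair.
Both are thinned observations of the same bonds, preserving the
log-linear age structure in all degree metrics.
Mortality optionally depends on sociability through
`exp(-delta_select * sociability)`: negative `delta_select` makes
more-social females die sooner, the selective-disappearance mechanism.

Dominance is matrilineal with youngest ascendancy (daughters directly
below their mother, younger sisters above older), and agonistic records
are generated for every dyad with the higher-ranking female winning, so
the rank module recovers the true hierarchy exactly. Bout durations are
exponential by default because the field literature rarely reports bout
distributions; this is configurable. Time is discretized to whole
years — the analysis unit is the group-year — so events carry a year,
not a date.

What the generator does *not* emulate: male and juvenile behavior,
within-year seasonality, group fission/fusion or migration, unequal
observation effort across individuals, observer error in identities,
and paternal kinship in partner choice (the default pedigree is
matrilineal). Passing tests therefore show the pipeline recovers truth
under a faithful, simplified field design — not that any real
population satisfies these assumptions.

# Validation experiments

`recovery_experiment()` runs three replicated scenarios, each fitting
the naive (age-only), Model A and Model B grooming-degree models:

* **decline** — `beta_within = -0.06`, no selection: the within-age
  estimate should center on −0.06 with nominal interval coverage and a
  "none" selective-disappearance decision;
* **selective** — `beta_within = 0`, `delta_select = -2` with
  sociability SD 0.8 and 45 matrilines: the naive model is misled, Model
  A's within-age interval covers zero, and the Model B contrast flags a
  negative avg-age term. The scenario's strength was designed (not
  fitted to data) so that the selection-induced between-individual
  gradient is comparable in magnitude to the within-individual declines
  under study; far stronger selection is self-defeating, because it
  depletes sociability variance before females reach the study ages,
  and the wider sociability distribution gives selection material
  variance to act on;
* **null** — neither process: within-age significance should occur at
  roughly the nominal 5% rate.

The test suite runs these at 20 replicates (decline/selective) on the
default cohort sizes; the acceptance script uses 5 replicates per
scenario to stay light. These sizes are the package's chosen
validation design and are stated here so reruns are comparable.

# Known limitations

* Wald intervals from a Laplace approximation are not posterior credible
  intervals; for the effect sizes and data volumes simulated here the
  two agree closely, but small-sample or boundary cases may differ.
* The zero-inflation component for strengths is a single shared
  intercept; structured zero-inflation is out of scope.
* Dominance uses raw win proportions rather than a ratings algorithm
  (Elo, David's score); with sparse or intransitive agonism data the
  percent-dominated estimate is noisy, though the generator's complete
  decided matrices make it exact in simulation.
* `partner_deaths` counts a partner's death in year t−1 regardless of
  whether the dyad's interactions that year preceded the death;
  within-year ordering is not modeled.
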