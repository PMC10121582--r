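---
title: "The 2-HT eyewitness identification model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The 2-HT eyewitness identification model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lineup2ht)
```

## The measurement problem

An eyewitness shown a lineup produces one of three responses: identify the
suspect, identify a filler, or reject the lineup.  Crossed with whether the
lineup actually contains the culprit (culprit-present, CP) or an innocent
suspect in his place (culprit-absent, CA), this yields a 2 × 3 contingency
table per experimental condition.  Raw response rates conflate distinct
cognitive processes — a higher rejection rate can reflect better detection of
culprit absence or merely a reluctance to choose anyone.  The
two-high-threshold (2-HT) eyewitness identification model resolves the table
into four latent process probabilities:

* `dP` — detection of the culprit's presence (leads directly to a culprit
  identification),
* `dA` — detection of the culprit's absence (leads directly to a correct
  rejection),
* `b` — biased selection of a suspect who stands out from the fillers
  (non-zero only in unfair lineups),
* `g` — guessing-based selection among the lineup members when no
  detection or biased selection occurs.

A guessing-based selection lands on the suspect with a known sampling
constant: 1 divided by the lineup size (1/6 in a six-person lineup), a fact
of randomisation rather than cognition.  The category probabilities are sums
of products of these probabilities along the branches of two processing
trees (one per lineup type):

| outcome | culprit-present | culprit-absent |
|---|---|---|
| suspect ID | `dP + (1−dP)[b + (1−b)gc]` | `(1−dA)[b + (1−b)gc]` |
| filler ID | `(1−dP)(1−b)g(1−c)` | `(1−dA)(1−b)g(1−c)` |
| rejection | `(1−dP)(1−b)(1−g)` | `dA + (1−dA)(1−b)(1−g)` |

with `c` the suspect constant.  `category_probabilities()` implements
exactly this map; each tree's three probabilities sum to one for any
parameter values in the unit cube.

Two conventions for `c` are supported (`lineup_design()`): the default
"paper" mode uses the 5-decimal rounding (0.16667 for six-person lineups),
matching the convention of the multiTree family of MPT tools so that fitted
statistics agree with published analyses to the last printed digit; "exact"
mode uses 1/6.  The difference in any category probability is bounded by the
perturbation of the constant times a factor at most one, i.e. below 4e-5,
and never moves the headline statistics at two decimals.

## Joint model, restrictions, degrees of freedom

Conditions are modelled jointly as independent multinomials per condition
and lineup type (a product-multinomial likelihood).  With `K` conditions the
saturated parameterisation has `4K` free parameters against `4K` data
degrees of freedom, so the unrestricted model is not testable.  Restrictions
(`restriction_map()`) equate a parameter across conditions (`eq_constraint`)
or pin it to a constant (`fix_constraint`); each parameter instance may be
touched by at most one constraint, and the free-parameter count and
goodness-of-fit df (`K × 4 − n_free`) are exposed on the spec.

The *base model* for two-condition instruction experiments
(`base_model_spec()`) equates `b` and `dA` across conditions — both
justified by design when the same well-constructed lineups are used in both
conditions — leaving 6 free parameters and a 2-df fit test.  The free vector
is ordered canonically (`dP` per condition, `g` per condition, then the
remaining `b`, `dA` instances) so that seeds, serialised fits and restart
draws are reproducible across runs.

## Estimation

`fit_2ht()` maximises the likelihood under box constraints `[0, 1]`.  The
primary optimiser is the EM algorithm for multinomial processing tree
models: the E-step distributes each observed category count over the latent
branches consistent with it in proportion to the current branch
probabilities, and the M-step sets each free parameter to the ratio of
expected "success" traversals over expected visits to its node, pooled
across the conditions an equality class spans.  Plain EM approaches
boundary solutions (such as `b = 0`) only linearly, so each iteration tries
doubling the step along the EM direction, projected into the unit cube, for
as long as the likelihood improves — a monotone acceleration that preserves
EM's ascent property.  Convergence is declared when the absolute
log-likelihood change drops below 1e-10 (cap: 10,000 iterations).

Ten uniform random restarts (deterministic given `seed`) guard against
local maxima; the best restart by log-likelihood wins, ties going to the
lowest index.  A box-constrained quasi-Newton route
(`method = "lbfgsb"`, with a tight convergence factor and 1e-6 finite
difference steps) serves as an independent cross-check — the test suite
verifies agreement of the two routes within 1e-6 in log-likelihood on 100
simulated datasets — and as the faster option inside large Monte-Carlo
loops, where 2 restarts suffice for these well-behaved likelihoods.

Boundary values are legal parameter values: the likelihood uses the
convention `0 · log 0 = 0`, so a category with probability zero and count
zero contributes nothing, while a zero-probability category with a positive
count makes the data impossible (`-Inf`, flagged).  Estimates within 1e-4
of 0 or 1 are reported in the fit's `boundary` field.  This matters in
practice: in fair lineups `b` is routinely estimated at 0.

Goodness of fit is the likelihood-ratio statistic
`G² = 2 Σ obs · ln(obs / expected)`, identical (to 1e-8, tested) to twice
the log-likelihood gap to the saturated model, referred to the central
upper chi-square tail.  Standard errors are square roots of the diagonal of
the inverse *expected* Fisher information — the convention of standard MPT
tools — computed from central finite differences of the tree polynomials
(which stay valid at the boundary).  For boundary estimates the reported SE
comes from the same unconstrained information matrix; standard asymptotics
are distorted there, and no boundary-corrected (mixture) null is used for
p-values either, matching common practice in this literature.  Whether
published MPT software applies any further treatment at the boundary is not
documented; SEs at the boundary should therefore be read as descriptive.

## Nested tests and sensitivity

`compare_2ht()` tests a restriction by `ΔG² = G²(restricted) − G²(base)`
with `Δdf` the difference in free parameters, constructed so the restricted
model is nested by definition.  Numerical noise can make `ΔG²` minutely
negative; values above −1e-6 are clamped to zero silently, larger ones with
a warning.  The two scientific tests this package was built around — does
culprit-presence detection `dP` differ between instruction conditions, and
does guessing-based selection `g`? — are both single-parameter equality
restrictions run at α = 0.05 with no multiplicity correction, two planned
tests of distinct hypotheses.

`sensitivity_w()` solves the noncentral chi-square power equation: the
noncentrality `λ*` at which the `df`-df test at level α attains the target
power, converted to Cohen's effect size `w = sqrt(λ*/N)` where `N` counts
identification decisions (participants × lineups per participant; the
replication-style design contributes 4 decisions per participant).  The df
of a sensitivity analysis is taken as 1 by default — the single-parameter
restriction actually tested; at α = β = 0.05 and N = 1420 both df = 1 and
df = 2 round to w = 0.10, so the choice is documented but not
result-critical.  `power_of_test()` is the inverse;
`implied_effect_size()` converts a hypothetical parameter difference into
`w` by fitting the restricted model to the alternative's expected counts,
so that `N·w²` is the noncentrality of the ΔG² test at those cell sizes.

## The synthetic-data generator

`generating_scenario()` + `simulate_responses()` draw one multinomial
sample per condition and lineup type from the model's category
probabilities — exactly the statistical structure the likelihood assumes.
The default scenario (`replication_scenario()`) mirrors the
conceptual-replication design: two conditions, six-person lineups, equal CP
and CA decision counts per condition (366/344), and generating parameters
taken from the full-precision fit of the bundled replication table at call
time (the published figures display `dP` and `g` only graphically, so
refitting is the only faithful source; nothing is hard-coded).  Simulation
is at the decision level: within-participant dependence across a
participant's four lineups is not modelled, matching the aggregation
assumption of the analysis itself.  The generator also does not emulate the
sequential photo-by-photo decision process, suspect-position effects, or
confidence ratings — passing recovery and calibration checks therefore
validates the estimation pipeline under the model's own assumptions, not
the model's adequacy for any particular real dataset.

`recovery_experiment()` wraps the simulate–refit–summarise loop: bias,
RMSE and Monte-Carlo SE per free parameter, the fraction of replicates with
boundary estimates, and rejection rates of nominated ΔG² tests.  Replicate
`i` uses seed `seed + i`, keeping seed blocks disjoint and runs exactly
reproducible.

## Numerical choices and problem sizes

* EM tolerance 1e-10 (absolute log-likelihood change), 10,000 iteration
  cap, 10 restarts drawn uniformly from [0.02, 0.98].
* Quasi-Newton bounds [1e-9, 1 − 1e-9] with probabilities floored at
  1e-300 inside the objective, so the optimiser never sees `-Inf`.
* Fisher information: finite-difference step 1e-6; cells with probability
  below 1e-10 and vanishing derivatives are skipped; a singular matrix
  falls back to a pseudo-inverse with `NA` for undefined entries.
* Estimates are reported at full precision and rounded to two decimals
  only at the presentation layer.

The test suite sizes its Monte-Carlo checks to be decisive yet quick: the
type-I calibration of the equal-`dP` test uses 2,000 null datasets at the
replication's cell sizes (rejection rate required within 0.05 ± 0.02, about
four Monte-Carlo standard errors); route agreement uses 100 datasets;
recovery at n = 1e5 decisions per tree uses 30 replicates against a
|bias| < 0.005 bar; the root-n RMSE check uses 25 replicates at each of
n = 1e4, 1e5, 1e6; seed-block stability uses three disjoint blocks of 250.
These loops use the quasi-Newton route with 2 restarts, whose agreement
with EM is itself under test.

## Limitations

* Only the 2-HT lineup topology is implemented — conditions and
  restrictions are configurable, arbitrary MPT tree structures are not.
* Aggregated multinomial likelihood: no hierarchical (participant-level)
  extension, no Bayesian posterior.
* Unfair-lineup designs can be expressed (condition-specific `b`) but no
  dedicated fairness inference is provided.
* SEs for boundary estimates are reported but not boundary-corrected; the
  same applies to p-values of fits with boundary estimates.
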