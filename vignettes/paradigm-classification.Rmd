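---
title: "Classifying tipping-element policies as optimal, sustainable and safe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying tipping-element policies as optimal, sustainable and safe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tipmdp)
```

## The model and its assumptions

`tipmdp` studies the smallest Markov decision process that can express a
human-environment tipping element: two states (*prosperous*, *degraded*),
two actions (*high*, *low* pressure), one agent. The prosperous state is the
only reward source; the degraded state pays nothing regardless of action.
High pressure at the prosperous state earns `r_h` but triggers a collapse
with probability `delta` per step; low pressure earns `r_l` and is
guaranteed to stay. From the degraded state only low pressure opens
recovery, with probability `rho` per step. One model time step is one year,
which is what makes residence timescales of real systems translatable into
the transition probabilities.

Deliberate simplifications, and hence limits of interpretation:

* a single aggregated tipping element — interacting tipping cascades,
  multiple agents, and state spaces richer than binary are out of scope;
* rewards are stationary and scalar, so "welfare" is one-dimensional;
  classification depends on them only through `r_l/r_h` and `r_min/r_h`
  (a tested invariant), and `r_h = 1` is used as normalization in sweeps;
* policies are deterministic. There are only four; the two that apply high
  pressure at the degraded state trap the agent there forever and are
  weakly dominated (a tested property), which licenses deciding optimality
  between the *risky* (high at p) and *cautious* (low everywhere) policies
  only.

## Values and the two computation routes

Values are *normalized* discounted sums (prefactor `1 - gamma`), so a
value is a reward-scale quantity directly comparable with the
acceptability threshold `r_min`, and `gamma -> 1` connects continuously to
the long-run average reward. For `gamma < 1` the Bellman fixed point is a
2×2 linear system, solved exactly by `evaluate_policy_linear()`; the
closed forms in `value_risky()` and `value_cautious()` are the package's
analytical core and are continuously checked against that independent
route (to 1e-10 relative tolerance in the test suite). At `gamma = 1`,
`value_gamma1()` multiplies the stationary distribution of the
policy-induced chain with the expected one-step rewards; the closed forms
evaluated at `gamma = 1` agree with it wherever they are defined.

Two conventions fixed here:

* **Matrix orientation.** `effective_chain()` returns the transition
  matrix with *from*-states in rows, so rows sum to one (the transposed,
  column-oriented convention is equivalent; tests assert
  row-stochasticity and the invariance `sigma P = sigma`).
* **Reducible chains.** Under the cautious policy (or `rho = 0`, or a trap
  policy) the chain is reducible and the stationary distribution is not
  unique; the package uses the recurrent class reachable from the
  prosperous state — the state real systems are assumed to start in — and
  flags `reducible = TRUE`.

### Degenerate denominators

The closed forms have vanishing denominators at measure-zero corners:
`gamma = 1` with `delta + rho = 0` (risky) and `gamma = 1` with `rho = 0`
(cautious `v_d`). These resolve to their one-sided limits
(`(r_h, 0)` and `0` respectively) and the returned object carries a
`degenerate` flag rather than raising an error — parameter-space sampling
must be able to cross these corners (grid sampling with endpoints does)
without aborting.

## The three paradigms

* **Optimal**: value at least that of any other policy, in every state.
  The verdict is state-independent, so the vectorized sweep path compares
  prosperous-state values only; the scalar `is_optimal()` compares both
  states.
* **Acceptable / sustainable**: a state is acceptable under a policy iff
  its value is `>= r_min` (non-strict, so boundary surfaces belong to both
  sides; ties classify as acceptable/optimal for both policies by design).
  The risky policy visits both states recurrently and is sustainable only
  if both are acceptable; the cautious policy eventually settles at the
  prosperous state, so its sustainability reduces to `r_l >= r_min`.
* **Safe**: the safe operating space is the prosperous state alone, with
  no risk tolerance. The cautious policy never leaves it; the risky policy
  is never safe. At `delta = 0` the risky policy happens never to collapse,
  yet the blanket rule still labels it unsafe; `reachability_safe()`
  exposes the reachability-based alternative, which agrees everywhere
  except on that measure-zero boundary. The package keeps the blanket rule
  as the default semantics and surfaces the discrepancy through the
  cross-check rather than resolving it.

Each regime boundary is available in implicit form via
`boundary_residual()` (sign = predicate, zero = surface) and located by
`boundary_root()`, plain bisection with interval tolerance `1e-12` —
adequate because each residual is continuous and monotone in any single
parameter over `[0, 1]`.

```{r boundary}
m <- tipping_model(0, rho = 0.2, gamma = 0.9, r_l = 0.5, r_min = 0.3)
boundary_root("optimality", m, "delta")
```

## Volume of the paradigm combinations

`category_volumes()` classifies *both* policies at every sampled point of
the unit cube of `(delta, rho, gamma, r_l/r_h, r_min/r_h)` and gives each
policy half a unit of mass. This weighting is a modelling choice the
package makes explicitly: the safe categories then carry exactly the
cautious-policy mass and the unsafe ones the risky-policy mass, and the
safe-and-sustainable (SAJOS) fraction has the sharp closed form
`P(r_l >= r_min) / 2 = 1/4`, which doubles as a calibration check of the
sampler.

Two samplers are provided:

* **Grid** (`n` points per axis, endpoints 0 and 1 included). Endpoint
  slices bias fractions by `O(1/n)`; e.g. the grid SAJOS mass is exactly
  `(n + 1) / (4n)`. The test suite includes a refinement check (halving
  the spacing shrinks the change in every run from 6 to 11 to 21 points
  per axis). The acceptance test suite evaluates the full `n = 51` lattice
  (51^5 ≈ 345M point–policy classifications, about a minute on one core);
  interactive exploration is comfortable at `n = 21`.
* **Monte Carlo** (`n` uniform draws, seed mandatory and echoed in the
  report). Standard errors use the exact per-point contribution variance
  `f/2 - f^2`. `n = 10^6` resolves every category to ±0.1% in a fraction
  of a second and is the default route of `scripts/acceptance.R`.

```{r volumes}
category_volumes(sampling_spec("monte_carlo", 1e5, seed = 7))
```

## Case studies under parameter uncertainty

`timescale_to_probability()` maps a mean residence time of `N` years to a
per-year transition probability `1/(N + 1)` (the mean of the geometric
occupation time inverted). The shipped presets encode: climate — collapse
triggering within 30–50 years under business-as-usual (kept as a range),
recovery so slow it is "close to never" on policy timescales, encoded as a
5000-year timescale (the literature says only multi-millennial; the value
is configurable and results are insensitive to it once `rho` is near
zero); fisheries — collapse ≈ 20 y, recovery ≈ 50 y; farming — collapse
≈ 100 y, recovery ≈ 300 y.

`regime_probabilities()` samples the remaining parameters uniformly and
independently from an `uncertainty_box()` (defaults: `gamma` in
[0.95, 0.99], `r_l/r_h` in [0.3, 0.7], `r_min/r_h` in [0.1, 0.5]), jointly
marginalizing over the box at the case's fixed (or range-sampled)
`(delta, rho)`. Under the default box the cautious policy is sustainable
with the geometric probability `P(r_l >= r_min) = 0.875`, another closed
form the Monte Carlo is tested against.

```{r farming}
rp <- regime_probabilities(case_study("farming"), n = 2e4, seed = 11)
subset(rp, probability > 0.01)
```

## What the tests do and do not establish

The synthetic sampling emulates *ignorance*: uniform, independent
parameters over the unit cube (or a box). It does not emulate real-world
parameter correlations (e.g. farsightedness and acceptability norms likely
co-vary), non-stationary rewards, or estimation noise in timescales, so
the volume fractions are statements about the model's parameter space, not
empirical frequencies. The case studies are qualitative placements of
three systems in that space, faithful to the quoted timescales but not a
calibrated assessment.

Numerical conventions collected in one place: non-strict (`>=`)
comparisons everywhere; exact closed forms rather than iteration wherever
available; degenerate corners resolved by limits and flagged; bisection to
`1e-12`; file output at 12 significant digits with tolerance-based (never
string) comparisons in tests; every stochastic routine takes a mandatory
seed and records it in its output.
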