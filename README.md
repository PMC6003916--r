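# tipmdp

Governance of environmental tipping elements is commonly guided by one of
three policy paradigms: **economic welfare optimization** (maximize the
present value of discounted rewards), **sustainability** (every state the
system will visit must remain acceptable), and the **safe operating space**
(never leave the favorable region of state space). These paradigms can
disagree, and `tipmdp` is a small analytical toolkit for mapping out exactly
where they do, aimed at researchers in social-ecological modelling and
environmental decision theory.

## The model

The human-environment system is a two-state, two-action Markov decision
process. The environment is *prosperous* (p) or *degraded* (d); each yearly
time step the agent exerts *high* or *low* pressure:

* (p, high): stay at p with probability 1 − δ, reward r_h; collapse to d
  with probability δ, reward 0.
* (p, low): stay at p with certainty, reward r_l (typically r_l < r_h).
* (d, low): recover to p with probability ρ; reward 0 either way.
* (d, high): stay at d with certainty, reward 0.

The value of a state under a policy π is the expected *normalized*
discounted reward, v_π(s) = E[ lim_T Σ γ^t r_t / Σ γ^t ], with discount
factor (farsightedness) γ ∈ [0, 1], so values live on the reward scale.
Of the four deterministic policies the two non-trivial ones are the
**risky** policy (high at p, low at d) and the **cautious** policy (low
everywhere); the other two trap the agent in the degraded state. The
risky-policy values have the closed form

    v(p) = r_h (1 − δ)(1 − (1 − ρ)γ) / (1 − (1 − δ − ρ)γ)
    v(d) = r_h (1 − δ) ρ γ / (1 − (1 − δ − ρ)γ)

while the cautious policy has v(p) = r_l and
v(d) = ρ γ r_l / (1 − (1 − ρ)γ). At γ = 1 the value is the long-run average
reward, the stationary distribution of the policy's Markov chain dotted
with the expected one-step rewards.

A policy is **optimal** if its value is at least that of every other policy
in every state; a state is **acceptable** if its value meets a normative
threshold r_min, and a policy is **sustainable** if every state it
eventually visits is acceptable; the safe operating space is the prosperous
state alone (no risk tolerance), so only the cautious policy is **safe**.
Classification depends on the five ratios (δ, ρ, γ, r_l/r_h, r_min/r_h),
and every one of the eight (optimal, sustainable, safe) combinations is
realized somewhere in that unit cube — there is no master paradigm. A safe
*and* just operating space (SAJOS) exists exactly when r_l ≥ r_min.

## Worked example

```r
library(tipmdp)
m <- tipping_model(delta = 0.05, rho = 0.2, gamma = 0.9,
                   r_l = 0.5, r_min = 0.3)
value_risky(m)
#> State values under the risky policy (closed):
#>   v(prosperous) = 0.8184615385
#>   v(degraded)   = 0.5261538462
classify_policy("risky", m)
#> risky policy: OS-  (optimal: TRUE, sustainable: TRUE, safe: FALSE)
classify_policy("cautious", m)
#> cautious policy: -SF  (optimal: FALSE, sustainable: TRUE, safe: TRUE)
```

With a collapse probability of only 5% per year and a moderately farsighted
agent, high pressure is economically optimal and even the degraded state is
still acceptable (v(d) ≈ 0.53 ≥ r_min), so the risky policy is sustainable
— but it is not safe, since it gambles on collapse. The cautious policy is
safe and sustainable but forgoes optimality. The two policies trade places
at the critical collapse probability:

```r
boundary_root("optimality", m, "delta")
#> [1] 0.1917808
```

Integrating over the whole parameter cube (each policy counted with half
weight per sampled point) gives the volume of each paradigm combination —
codes are `O`ptimal / `S`ustainable / sa`F`e, with `-` for "not":

```r
category_volumes(sampling_spec("monte_carlo", 1e6, seed = 1))
#> Paradigm-combination volumes (monte_carlo, 1,000,000 points, seed 1)
#>   ---   26.80%  (se 0.0002)
#>   OSF   18.75%  (se 0.0002)
#>   O--   16.50%  (se 0.0002)
#>   --F   14.20%  (se 0.0002)
#>   O-F   10.82%  (se 0.0002)
#>   -SF    6.24%  (se 0.0002)
#>   OS-    3.93%  (se 0.0001)
#>   -S-    2.77%  (se 0.0001)
```

The regime where no paradigm holds is the single most likely one, followed
by the sweet spot where all three agree (together ≈ 45% of parameter
space), and the third-largest regime — optimal but neither sustainable nor
safe — is the biggest one in which the paradigms conflict. The safe and
sustainable categories (`OSF` + `-SF`) sum to 1/4: one in four random
agent–environment pairs lands in the SAJOS.

Case studies convert residence timescales to transition probabilities
(p = 1/(⟨N⟩ + 1) per year) and propagate box uncertainty in γ, r_l/r_h,
r_min/r_h:

```r
rp <- regime_probabilities(case_study("farming"), n = 1e5, seed = 1)
subset(rp, policy == "risky" & probability > 0.01)
#>   policy code optimal sustainable  safe probability       se
#> 2  risky  O--    TRUE       FALSE FALSE      0.9549 0.000657
#> 4  risky  ---   FALSE       FALSE FALSE      0.0345 0.000578
```

For farming (collapse ≈ 100 y, recovery ≈ 300 y), welfare optimization
almost surely selects the risky policy even though it is neither
sustainable nor safe.

## Command line

A thin wrapper is installed with the package:

```sh
$(Rscript -e 'cat(system.file("cli", "tipmdp", package = "tipmdp"))') \
    volumes --mode mc --n 1000000 --seed 7 --out volumes.json
```

Subcommands: `evaluate`, `classify`, `sweep`, `volumes`, `case`,
`fixtures`. Every output embeds its configuration (JSON `config` element,
or a leading `# config:` comment in CSV) and the seed of any stochastic
run, so outputs are byte-reproducible.

## Package tour

| Area | Functions |
| --- | --- |
| Model and chain | `tipping_model()`, `policy()`, `transition_model()`, `effective_chain()` |
| Values | `value_risky()`, `value_cautious()`, `evaluate_policy_linear()`, `value_gamma1()`, `policy_value()` |
| Paradigms | `is_optimal()`, `is_acceptable()`, `is_sustainable()`, `is_safe()`, `classify_policy()`, `boundary_residual()`, `boundary_root()`, `sweep_classification()` |
| Volumes | `sampling_spec()`, `category_volumes()`, `rank_categories()` |
| Case studies | `timescale_to_probability()`, `case_study()`, `uncertainty_box()`, `regime_probabilities()` |
| I/O | `run_cli()`, `read_cli_csv()`, `make_fixtures()`, `witness_points()` |

The methods vignette (`vignettes/paradigm-classification.Rmd`) documents
the model assumptions, the numerical choices, and the limitations in
detail.
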