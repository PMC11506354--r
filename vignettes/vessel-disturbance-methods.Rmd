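---
title: "Methods: activity budgets, reaction models and transition chains under vessel traffic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: activity budgets, reaction models and transition chains under vessel traffic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselwatch)
```

`vesselwatch` implements the standard control/impact analysis of
shore-based scan-sampling surveys of dolphin groups under vessel
traffic. This vignette explains the models and procedures, the
parameters that matter and their defaults, what the synthetic-data
generator does and does not emulate, and the numerical and design
choices made where the field's conventions leave room.

## The observation model

The raw unit is a per-minute *tick*: one row per observed minute of one
group in one session, carrying the behavioral state (`FEE` feeding,
`TRA` traveling, `SOC` socializing, `RES` resting), a boolean flag for a
vessel within the proximity radius (~200 m; the package never computes
distances — presence is a field judgment recorded upstream), and the
group's reaction (`POS`, `NEU`, `NEG`, or `NONE` exactly when no vessel
is present). Timestamps are integer minutes from session start; no
calendar arithmetic is needed for any statistic. The canonical CSV
dialect is comma-separated UTF-8 with columns `session_id`,
`timestamp_min`, `group_id`, `state`, `vessel_present` (0/1),
`reaction`, and `read_records()`/`write_records()` are exact inverses on
it.

### Blocks and events

Ticks are reduced to 5-minute sampling blocks (`make_blocks()`). Each
continuous run of ticks is tiled from its first tick; the final block
may be truncated, and a block's time contribution is its *actual*
duration, so a 2-minute sighting contributes 2 minutes, not 5. A block's
state is the **dominant state**: the modal state of its ticks, with ties
broken in favor of the tied state occupying the latest tick. This rule
is deterministic and independent of the label alphabet; a
latest-tick tie-break slightly favors the state the group is moving
*into*, which is the natural reading of a dominant activity at the end
of a sampling period. A block is vessel-present if **any** tick in it
is (the conservative exposure definition; a majority rule is available
via `vessel_rule = "majority"`), and its reaction is the modal non-`NONE`
reaction with ties resolved toward the more negative category
(`NEG` > `NEU` > `POS`) — conservative for impact detection, since the
analysis asks whether vessels disrupt behavior.

Blocks are grouped into **events** (`segment_events()`): runs of the
same (session, group) stream separated by less than 15 minutes are
merged; a gap of 15 minutes or more starts a new event. The interval
itself counts as sufficient separation — the independence rule
prescribes a 15-minute buffer, so exactly 15 minutes satisfies it.
Events never span sessions. Segmentation is idempotent and conserves
observed minutes exactly (tick minutes = block minutes = event minutes),
and both properties are asserted on every test run.

## Activity budgets and nonparametric comparison

`activity_budget()` sums block durations per state, per event and per
vessel scenario (`ABSENT`/`PRESENT`/`ALL`); percentages are over the
scenario's total time and always sum to 100 when any time was observed.
The absent/present partition is exact: absent plus present minutes equal
the overall total.

States seen in fewer than `min_samples` blocks (default 12) are excluded
from hypothesis testing but never from descriptive budgets
(`exclude_rare_states()`); the default threshold is the smallest integer
that excludes a state observed 11 times, the kind of sample size at
which a scan-sampling rate comparison has essentially no power.

Per-event scenario sums are compared with a two-sided Mann–Whitney *U*
test (`compare_budgets()`). Normality and homoscedasticity are checked
first (Shapiro–Wilk per group; Brown–Forsythe/Levene across groups,
via `car::leveneTest`) but are diagnostics only: the comparison is
nonparametric regardless, because per-event time sums are
short-right-tailed, tied and small-sample almost by construction. For
*n*₁+*n*₂ ≤ 12 the p-value is computed by exhaustive enumeration of all
`choose(n, n1)` group assignments — exact even under heavy ties, where
the classical exact distribution of *U* does not apply — and agreement
with an independently coded enumeration is part of the acceptance
suite. Larger samples use the normal approximation with tie-corrected
variance and continuity correction. Outlying events are retained: with
skewed, tied data the rank test is already robust, and dropping extreme
events would discard exactly the long encounters of greatest interest.

## Reaction-time models (gamma GEE)

For vessel-present blocks, time is summed per (event, behavior,
reaction) triple (`reaction_time_table()`). Zero-time combinations are
simply absent rather than imputed: the gamma family has no mass at zero,
and an unobserved combination carries no information about the *duration*
of a reaction that did not occur. The consequence is that the models
describe time spent *given that* a combination occurred.

The model suite is the conventional nested triple on the summed times,
clustered by event with reference levels reaction = `NEU`,
behavior = `TRA`:

* M1: `time ~ reaction`
* M2: `time ~ reaction + behavior`
* M3: `time ~ reaction * behavior`

(`M0`, intercept-only, exists for null-model checks.) Fitting is by
generalized estimating equations with gamma variance *V(μ) = μ²* and an
exchangeable working correlation: Fisher scoring on
Σᵢ Dᵢᵀ Vᵢ⁻¹ (yᵢ − μᵢ) = 0, with the dispersion φ and the working
correlation α re-estimated at each step from Pearson residuals (the
classical moment estimators). α may be negative — events in which one
reaction soaks up time at the expense of the others push it below
zero — and is clamped only at the positive-definiteness bound
−1/(n₍max₎−1). Inference uses the robust sandwich covariance; each
coefficient gets a Wald χ²(1), and nested pairs are compared with a
joint Wald χ² on the extra coefficients using the larger model's robust
covariance, with degrees of freedom equal to the number of extra
coefficients (`compare_models()`). No small-sample correction is
applied to the χ² reference distribution.

No GEE solver is a dependency: the scoring loop, moment estimators and
sandwich are implemented in the package and are verified against their
analytic limit — with an independence working structure and singleton
clusters the fit must match `stats::glm(family = Gamma)` to 10⁻⁶ — and
by parameter recovery on `generate_gee_dataset()` output.

The link is selectable. The default is the gamma-canonical inverse
link, the conventional default of gamma GEE/GLM software; the log link
is available (`link = "log"`) and is often preferable for simulation
work because any coefficient vector keeps the mean positive. Results
always carry the link they were fitted with.

## Control/impact transition chains

Within each event, every ordered pair of consecutive blocks is one
transition; transitions never cross event boundaries, and
single-block events contribute nothing. Counts *a₍ᵢⱼ₎* are split into a
CONTROL and an IMPACT scenario by an **exposure rule**, because the
analysis protocol does not itself say which scenario owns a transition
that spans a vessel arrival or departure. The default, `preceding`,
assigns the transition to the earlier block's exposure — the behavioral
response follows the stimulus — with `succeeding` and `both` (drop mixed
pairs) selectable; outputs are always labeled with the rule used.
Self-transitions are counted.

Probabilities are row-normalized maximum-likelihood estimates
*p₍ᵢⱼ₎ = a₍ᵢⱼ₎ / Σⱼ a₍ᵢⱼ₎* over the four-state space. A state with no
outgoing transitions (resting, in surveys where it never occurs) is
reported as *no data*, never as a zero row or an absorbing state —
normalizing an empty row would fabricate dynamics. `compare_chains()`
reports per-cell impact−control differences and, optionally, two-sided
permutation p-values under the exchangeable null obtained by shuffling
scenario labels among transitions within each event; the permutation
stream is seed-deterministic. Chains export to Graphviz DOT with edge
probabilities printed to two decimals (`export_chain_diagram()`).

## The synthetic survey generator

`generate_survey()` emulates the observation protocol so that every
downstream stage can be scored against known truth:

* **Sessions**: `n_sessions` (default 38 — observation days on which
  groups were actually sighted in a year-round every-other-day survey)
  of `session_length` 480 min (an 08:00–16:00 shift).
* **Sightings**: while no group is in view, each 5-minute scan sights a
  new group with probability `sighting_hazard` (default 0.025, giving
  on the order of two sightings per day). Event length in blocks is
  drawn from `duration_blocks` (default 1 + negative binomial, mean
  ≈ 8.5 blocks, truncated at 27), and the final block is truncated to
  2–5 minutes, so event durations span 2–135 min. Consecutive events in
  a session are separated by at least the 15-minute independence
  interval *by construction*, so segmentation must recover the
  generator's event labels exactly — and is tested to.
* **Interruptions**: with probability `p_interrupt` (default 0.15) per
  within-event block boundary the group is momentarily lost, leaving a
  5–14 min hole in the record stream. These exercise the merge half of
  the independence rule.
* **Dynamics**: the block-level state sequence is a first-order Markov
  chain whose transition matrix is `P_impact` when the earlier block is
  vessel-present and `P_control` otherwise, matching the `preceding`
  exposure rule, so scenario-split estimation is consistent for the two
  configured matrices. Vessel presence follows a two-state persistence
  chain (`p_gain` 0.16, `p_keep` 0.80; stationary share ≈ 0.44 of
  blocks vessel-present). Reactions are drawn per vessel-present block
  from `reaction_probs` conditionally on the state.
* **Defaults**: the default matrices encode strong traveling persistence
  (0.73 control, 0.79 impact), feeding persistence near 0.6 in both
  scenarios, a feeding-to-traveling shift under vessels (0.38 → 0.41),
  a suppressed traveling-to-feeding return (0.26 → 0.18), loss of the
  feeding-to-socializing transition under vessels, and socializing that
  mostly resolves into traveling (0.6). Under these dynamics the
  occupancy works out to roughly 60% traveling / 36% feeding / 2%
  socializing and the reaction mixture to roughly 80% neutral / 16%
  negative / 4% positive of vessel-present time — a realistic
  mildly-disturbed estuarine scenario. Resting is configured
  unreachable; its matrix rows exist but are never visited.
* **Determinism**: one private random stream per survey, seeded
  explicitly; the caller's RNG state is untouched, and identical seeds
  give identical records on any platform.

Within a block, all ticks share the latent state by default;
`tick_noise` injects minority-tick noise to exercise the dominant-state
rule without ever displacing the latent mode. What the generator does
**not** emulate: observer error and misclassification, detection that
varies with sea state or distance, group fission/fusion and group-size
effects, vessel type or count, diel or seasonal structure. Passing
recovery tests therefore show that the *estimators* are correct for
data satisfying the protocol's assumptions — not that real field data
satisfy them.

`generate_gee_dataset()` draws clustered gamma times whose marginal
means follow a stated coefficient vector exactly and whose within-event
correlation is an exact target α: times are μ · G₍event₎ · E₍row₎ with
independent mean-1 gamma multipliers whose variances solve
var(G) = α·φ and (1+var(G))(1+var(E)) = 1+φ for target dispersion φ.
This construction covers α ∈ [0, 1); negative-α data (not producible by
a shared multiplier) are exercised in tests by competitive
splitting of a fixed event total.

## Numerical choices and degenerate inputs

* GEE convergence: relative coefficient change below 10⁻¹⁰, cap 100
  iterations; non-convergence and means leaving the gamma support are
  errors that carry the step-size trace. Rank-deficient designs are
  rejected with the aliased term named.
* Mann–Whitney: `U` is computed by pairwise counting with ½ for ties;
  the exact/approximate switch is at *n*₁+*n*₂ = 12 (924 assignments at
  the boundary — exact enumeration is instantaneous there, and beyond it
  the normal approximation with tie correction is accurate). All values
  tied across both groups give p = 1 with a warning.
* Permutation p-values use the add-one estimator (1+#{|d*| ≥ |d|})/(B+1),
  which is valid (never anti-conservative) and never zero; comparisons
  at cells with an unsupported row are `NA`.
* Empty selections (a scenario with no blocks, a survey with no
  vessel-present time) yield empty, *flagged* outputs — zero totals with
  a warning, "no exposure data" report sections — rather than errors, so
  single-scenario surveys run end to end.
* Budget percentages over an empty scenario are reported as 0 rather
  than NaN, with the empty flag set.

## Problem sizes used in the validation suite

The test and acceptance suites size their simulations to what the
estimators need rather than to survey realism: oracle-equivalence
checks run on 1,000 small randomized surveys; transition recovery uses
a survey large enough for ≥10,000 transitions per scenario (all
supported cells within 3 binomial standard errors of the configured
matrices); GEE recovery uses 100 replicates of 200 events (each
coefficient within 3 robust SEs of truth in ≥95); Wald-comparison
type-I error uses 500 null replicates (5% ± 2%); and the chain
permutation null uses 250 replicates at 199 permutations, with its
calibration band set a priori to 5% ± 2.5% because permutation tests on
discrete transition counts are conservative-leaning.

## Known limitations

* One group per record stream: simultaneous multi-group sightings must
  arrive as separate streams, and groups are not re-identified across
  sessions.
* The GEE χ² reference is asymptotic in the number of events; with few
  dozen clusters the robust Wald tests run slightly liberal, which the
  calibration tests quantify.
* The exposure rule for mixed transitions is a documented convention,
  not a fact of the data; results should be reported with the rule, and
  `compare_chains()` re-run under alternatives when it matters.
* Reaction is modeled as a per-block category; reaction *durations*
  within a block are not resolved.
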