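---
title: "Methods: a two-component decision model for post-PCI outcome projection"
author: "acsmarkov"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a two-component decision model for post-PCI outcome projection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acsmarkov)
```

## The decision problem

Patients with acute coronary syndrome (ACS) who undergo percutaneous
coronary intervention (PCI) remain at substantial risk of recurrent major
adverse cardiovascular events (MACE): reinfarction, stroke, unstable
angina (UA), and death. Trials of adjunctive therapies typically follow
patients for a year, while the clinically relevant question is the
long-term balance of survival and quality of life. This package projects
ten-year outcomes for two strategies — six months of adjunctive Chinese
herbal medicine (CHM) on top of conventional secondary prevention versus
conventional treatment alone — from one-year trial event probabilities and
literature-based long-term transition probabilities.

The model has the classic two-component structure used throughout
trial-based decision-analytic modelling:

1. **A one-year decision tree.** Each arm's cohort is split over five
   mutually exclusive outcomes: event-free, nonfatal myocardial
   infarction (MI), nonfatal stroke, nonfatal UA, and all-cause death.
   The branch probabilities are the arm-specific annual event
   probabilities; the event-free fraction is the residual
   $1 - (p_\mathrm{MI} + p_\mathrm{stroke} + p_\mathrm{UA} + p_\mathrm{death})$.
   Treating the five branches as a single chance node (rather than
   competing hazards) matches how per-branch probabilities are reported
   for a fixed one-year window.

2. **An eight-state Markov cohort model** with annual cycles for years 2
   to 10. States: `event_free`, `new_mi`, `post_mi`, `new_stroke`,
   `post_stroke`, `new_ua`, `post_ua`, and absorbing `dead`. The `new_*`
   states are one-cycle *tunnel* states: post-event risks differ between
   the first year after an event and later years, and the tunnel encodes
   that tenure dependence structurally, so the transition matrix itself
   is time-homogeneous. Survivors of a `new_*` cycle who have no further
   event move to the matching `post_*` state; a recurrent event re-enters
   the corresponding `new_*` state (tenure resets — the chain has no
   memory beyond the current state). Two structural exclusions reflect
   the available evidence base: neither `post_mi` nor `post_stroke` can
   transition into `new_ua`, and UA does not recur from `post_ua`.

Both arms share the long-term transition probabilities; the treatment
effect enters the model only through the year-1 distribution with which
each arm enters the Markov stage. This is the conservative "no benefit
beyond the trial horizon" assumption.

## Parameters

All inputs are `(base, low, high)` triples; `(low, high)` is the
univariate sensitivity range. The packaged base case
(`default_parameters()`, also shipped as
`inst/extdata/acs-pci-parameters.yaml` with a JSON-Schema in the same
directory) carries the published trial and literature values. Rates
reported per unit time are converted to per-cycle probabilities under a
constant-hazard assumption, $p = 1 - e^{-rt}$
(`rate_to_probability()`).

Three parameter-level choices deserve note:

* **One base value lies outside its own printed range** (the late
  post-MI reinfarction probability, 0.018 against a range of
  0.001–0.008). We store the values verbatim and make
  `validate_parameters()` warn rather than error: fidelity to the
  published inputs outweighs internal consistency, and the sweep still
  varies the parameter over its printed range.
* **The age-related MACE odds ratio per decade (0.5, range 0.33–0.87)**
  is stored but disabled by default (`apply_age_or = FALSE`). Its
  application point in the transition structure is not defined by the
  source material, and the base-case results are reproducible without it
  (the year-1 closed form below is independent of it, and the ten-year
  survival check passes with it off). When enabled, it scales all
  outgoing event and death probabilities of living states on the hazard
  scale by $\mathrm{OR}^{(t-1)/10}$.
* **Post-event mortality is treated as all-cause**, not added on top of
  the event-free background mortality; the published post-event rows are
  read as totals. This is exposed structurally (the rows are used as
  given) rather than behind a switch, and it is corroborated by the
  survival reproduction below.

A quirk of the published table worth knowing: later-year post-UA
mortality (0.020) is *below* event-free mortality (0.027), so surviving a
UA episode is marginally protective for long-term survival in this
parameterisation. This is why elementwise-better year-1 risks guarantee a
QALY gain but not, in full generality, a survival gain; the test suite
states the survival dominance property on its actual domain (no
post-event mortality below event-free mortality).

## Rewards, half-cycle correction, and discounting

Each state earns an annual utility: the arm's event-free utility $u$ for
`event_free`, $u$ minus the event's disutility for event and post-event
states (MI 0.127, stroke 0.139, UA 0.117), and 0 for `dead`. The default
`disutility_mode = "persistent"` subtracts the disutility in every year
spent in an event or post-event state; a `"one-off"` mode (event year
only) is available. Persistent subtraction is the default because the
closed-form year-1 anchor (below) and the ten-year totals are reproduced
with it.

With per-cycle rewards $R_t$ (utility-weighted end-of-cycle occupancy)
and discount factor $\delta_t = (1+r)^{-(t-1)}$, total QALYs are
$\sum_t w_t R_t \delta_t$ where the weights $w_t$ implement the
half-cycle convention:

* `"standard"` (default): $w_1 = w_H = \tfrac12$, all other $w_t = 1$ —
  the classic half-cycle correction crediting half a cycle at entry and
  at the horizon;
* `"entry-half"`: $\tfrac12 R_1$ for cycle 1, then the mean of
  adjacent-cycle rewards (trapezoidal continuation);
* `"none"`: full end-of-cycle rewards.

**Calibration.** The year-1 QALY value admits a closed form that bypasses
the Markov engine entirely: half the utility-weighted end-of-year-1
occupancy, computable by hand from the year-1 probabilities and the
utilities. Both `"standard"` and `"entry-half"` share this cycle-1 term,
and it reproduces the reference year-1 values (0.405 and 0.396 per arm)
to three decimals — this anchors the disutility application and the
half-cycle handling independently of everything else. The ten-year
totals then discriminate between the conventions and the candidate
discount rates $\{0, 0.03, 0.035, 0.05\}$ (no rate is stated with the
reference results): only the `"standard"` convention at $r = 0.03$
reproduces the reference totals (5.52 and 5.41 against 5.519 and 5.408),
while the trapezoidal variant overshoots at every candidate rate. The
package therefore defaults to `half_cycle = "standard"`,
`discount_rate = 0.03` — also the conventional annual discount rate for
health outcomes — and records both choices in every run manifest.
Discounting starts at cycle 2 ($\delta_1 = 1$), consistent with the
undiscounted year-1 anchor. Survival is reported undiscounted.

## Event accounting per cohort

`events_per_cohort()` reports, per 1000 patients: patients gaining
event-free status and deaths avoided from *terminal* occupancy
differences, and incident MIs, strokes, and UA episodes prevented from
*cumulative inflow* into the tunnel states (by the tunnel property,
the summed `new_*` occupancy). The terminal occupancy differences of the
event-state pairs are also exposed (`terminal_state_diff`), since
"patients prevented from suffering an event" can defensibly mean either
reading; the two differ because patients die out of, and recur within,
the event states. Counts are rounded half-away-from-zero to whole
patients. Note an arithmetic identity worth keeping in mind when reading
per-1000 summaries: deaths avoided per 1000 is exactly ten times the
terminal survival difference in percentage points, so a 0.20-point
survival gain corresponds to 2 deaths avoided, and the terminal
state-pair differences balance the event-free gain.

## One-way sensitivity analysis

`one_way_sensitivity()` varies each of the 37 ranged parameters to its
low and high endpoint, one at a time, holding everything else at base.
Long-term probabilities, utilities, and disutilities are shared inputs
and therefore move in both arms simultaneously; the year-1 probabilities
are arm-specific and move only in their own arm. Ranking defaults to the
spread in CHM-arm total QALYs (the quantity for which reference ranges
are quoted); incremental-QALY ranking is available. Ties are broken by
parameter name for reproducibility.

Two structural observations, both verified by the test suite:

* Among the shared risk parameters, the five most influential are the
  event-free mortality, UA, stroke, and MI risks, then the UA
  disutility — in that order. The full ranking, however, is led by the
  baseline event-free utilities, whose printed ranges are an order of
  magnitude wider (e.g. 0.418–0.848) than any probability range.
* Dominance of the CHM arm (positive incremental QALYs at every one-way
  endpoint) holds for every probability and disutility parameter, but
  *cannot* hold across the printed baseline-utility ranges: the
  conventional arm's utility at its high endpoint (0.848) exceeds the
  CHM arm's base value (0.818), which reverses the QALY ordering by
  construction. `dominance_check()` reports the strict full-sweep
  property and is therefore `FALSE` on the base case; restricted to the
  35 other parameters it is `TRUE`.

## The scenario and generator layer

The study's inputs are point probabilities with ranges, not patient-level
data, so the synthetic layer samples parameter space rather than
simulating patients. `random_parameter_set(seed)` draws every value
uniformly within its range (structurally valid by construction under the
packaged ranges); `perturb(params, scale, seed)` moves each value a
fraction `scale` of the way toward a randomly chosen range endpoint; and
`scenario(name)` provides degenerate closed-form cases
(`zero_mortality`, `immediate_absorption`, `two_state_geometric`,
`reversed_dominance`, `equal_arms`) whose exact behaviour is asserted in
the tests — e.g. the two-state scenario must match the geometric
survival curve $(1 - 0.027)^{t-1}$ to $10^{-12}$.

What passing these tests shows is that the *model machinery* is correct
under the stated conditions; none of it validates the clinical inputs
themselves, which come from one trial year and a heterogeneous
literature, nor does it test patient-level heterogeneity, adherence, or
treatment-effect waning, all of which are outside a cohort model's
scope.

## Numerical choices and degenerate inputs

* Occupancy conservation is enforced to $10^{-10}$ per trace row in the
  property tests; matrix rows are constructed to sum to 1 exactly
  (residual bookkeeping, no renormalisation).
* Outgoing probabilities of a state are applied additively; a row whose
  specified probabilities sum beyond 1 is an infeasibility error naming
  the state. Sums of exactly 1 (no residual) are legal, which keeps the
  absorbing scenarios expressible.
* Entry distributions must sum to 1 within $10^{-9}$.
* Horizon 1 is legal: the single cycle is both first and last, and the
  standard convention credits it half a cycle, so the total equals the
  year-1 term.
* YAML serialisation uses 20 significant digits so parameter sets
  round-trip bit-exactly; the packaged fixture is written with short
  literals that parse to exactly the in-code constants.
* Per-1000 counts round half-away-from-zero (whole patients).

## Problem sizes used by the checks

The test suite exercises 100-seed sweeps for validation and QALY
monotonicity, 50-seed sweeps for conservation/monotone-mortality and the
perturbation-dominance record, and full 37-parameter tornado sweeps
(75 model runs each); a complete base case plus tornado takes well under
a second. These sizes are the package's own choice: the model is an
8-state, 10-cycle matrix recursion, so every quantity of interest is
exactly computable at negligible cost.

## Known limitations

* No costs, cost-effectiveness ratios, or probabilistic sensitivity
  analysis: the model projects effectiveness only, and parameter
  uncertainty is explored one-way over printed ranges.
* Transition probabilities are constant beyond the first post-event
  year; there is no parametric survival extrapolation and no age or sex
  structure (the age odds ratio is available but off by default, see
  above).
* The cohort is homogeneous and memoryless: event history beyond the
  current state is forgotten, so compounding risks in multi-event
  patients are understated.
* The published parameter set itself contains tensions the package
  preserves rather than repairs: one base value outside its printed
  range, post-UA mortality below event-free mortality, and baseline
  utility ranges wide enough to reverse any between-arm ordering.
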