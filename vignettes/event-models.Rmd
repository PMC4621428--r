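---
title: "From change detection to temporal inference: the eventmodels engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From change detection to temporal inference: the eventmodels engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eventmodels)
```

## The model

`eventmodels` implements a process model of event cognition with three
committed claims:

* **Discrete episodes.** Continuous experience is carved at instants of
  change. Each such instant yields one episodic marker — a punctate
  chunk recording *all* changes detected at that instant (channel,
  entity, polarity, and what was replaced), linked to the previous
  marker and tagged with the goal context. Durational events are not
  stored as such: a remembered event is a *pair* of markers, one for its
  start and one for its end.
* **Prioritized reconstruction.** Event models are built only
  retrospectively, from retrieved markers. Changes are ranked
  goal > location > person > object: goals impose top-down structure
  (while a goal is active, perceptual changes begin subevents *within*
  it, and the goal's satisfaction bounds those subevents), and the
  default reconstruction keeps only the superordinate events.
* **Iconic, ordinal models.** An event model is a spatial arrangement of
  events on a timeline that preserves order and containment but no
  metric information: boundaries occupy consecutive ordinals `1..k`,
  simultaneous boundaries share an ordinal, and inference is scanning —
  left of means before, containment means during. Modal verdicts come
  from enumerating the distinct arrangements a description admits:
  `necessary` holds in all, `possible` in some, `impossible` in none.

The input is already symbolic: a stream of timestamped change reports
(`{"t": 3, "ch": "location", "entity": "location-b", "pol": "onset"}`).
Perceptual front-ends (vision, speech, face recognition) are out of
scope by design — the theory's algorithms begin where "a change in
content is detected". The location channel is single-valued (entering a
location implicitly supplies leaving the previous one, so one marker can
end one location event and begin the next); goal, person, and object
channels are multi-valued, and goals nest by stack discipline.

## Worked partonomy

```{r office}
m <- construct_model(segment_stream(office_day_fixture()))
cat(render(m), sep = "\n")
positions_of(m)
query(m, "dinner during day")
```

A punctate event (the dinner) sits at one ordinal inside a durational
event (the evening), which nests in the day; the meeting's end marker is
ordinal `r boundary_ordinal(m, "meeting", "end")` of
`r nrow(positions_of(m))`. Scanning yields that the dinner did not occur
during the meeting, the meeting preceded the evening, and the dinner
occurred during the day.

## Parameters that matter

| parameter | default | units / range | role |
|---|---|---|---|
| `decay_d` | 0.5 | dimensionless | base-level decay exponent; larger = faster forgetting |
| `beta` | 1.0 | activation per change | initial strength gain per encoded change |
| `spread_fraction` | 0.5 | fraction of a spike | one-step spreading to associates on retrieval |
| `epsilon` | 1e-3 | time units | floor on `now − t_j`, avoids the singularity at access time |
| `retrieval_threshold` | `-Inf` | activation | markers below it are unavailable to reconstruction |
| `temporal_limit` | `Inf` | time units | lookback horizon of retrieval |
| `priority_order` | goal, location, person, object | — | channel ranking for prioritized reconstruction and nesting |
| `max_depth` | 4 | levels | partonomy bound; deeper nesting is flattened to this depth |
| `max_models` | 8 | models | enumeration bound; a `necessary` verdict at the bound is flagged `bounded` |

The defaults for `retrieval_threshold` and `temporal_limit` make
retrieval lossless, so veridical reconstruction is exact unless the user
opts into forgetting. `max_depth = 4` reflects only that the partonomy
must be bounded; the value is arbitrary and configurable. `max_models`
encodes bounded cognition: beyond it, necessity claims are only
"necessary up to the bound".

## Numerical and design choices

* **Activation equation.** The theory's commitments are qualitative
  (initial strength grows with the number of encoded changes; memory
  fades; retrieval spikes and spreads). We adopt the standard ACT-R
  base-level form `A = β·|changes| + ln Σ_j w_j (now − t_j)^(−d)`
  because the qualitative claims all hold under it; the exact form, the
  one-step spreading topology (markers sharing a goal context or a
  change channel), and the fractional-pseudo-access implementation of
  spreading are engineering choices, parameterized rather than asserted
  as theory.
* **Compatibility and goal closure.** A provisional event closes on a
  marker with the same channel and entity (a goal completes only on its
  own satisfaction). In addition, a goal's offset closes the
  lower-priority provisional events opened within that goal's context:
  in the two-location example the goal's satisfaction marker is also the
  end of the visit to location 2, which is what makes the three-row
  model (goal containing location-1 then location-2) come out. Events
  still open when the markers run out are committed open and behave as
  right-unbounded intervals.
* **Prioritized mode.** The default prioritized model contains only the
  events of the highest-priority channel present (the superordinate
  structure); `flesh_out = TRUE` additionally commits lower-priority
  events that fall within the bounds of an already committed
  higher-priority event. Person/object episodes (Bob's visit) are
  therefore absent from the default prioritized model and appear only on
  request.
* **Relation semantics.** `before` is strict precedence (`end <
  start`) — two events sharing a boundary are *not* ordered by
  `before`; `when` is punctate co-position; `while` places a punctate
  operand strictly inside a durational one (with two durational
  operands it degrades to overlap — an extension beyond the
  punctate-in-durational case the theory illustrates); `during` is
  proper containment. Coincidence between events arises only where a
  `when` premise forces it: enumeration is over strict orders of
  boundary tokens, which is why "A before B, A before C" admits exactly
  two models, not a third with B and C tied.
* **Ties and determinism.** Simultaneous changes collapse into one
  marker; simultaneous boundaries share an ordinal; when an event fits
  in two same-priority containers the earliest-starting container is its
  parent; the initial model of a premise set is the first-fit insertion
  in premise order, and enumeration order is fixed, so all outputs are
  deterministic given inputs and configuration.
* **Goal-offset context.** A marker that ends a goal carries the ending
  (innermost) goal as its context — the figures do not disambiguate
  this; the alternative (the parent goal) would only relabel boundary
  markers.
* **Degenerate inputs.** Empty streams yield empty marker lists and
  models; dangling offsets (an offset for an inactive entity, as when a
  robot drops observations) warn and record a contentless change in
  tolerant mode or error in strict mode; contradictory premise sets
  yield zero models and an `inconsistent-premises` verdict rather than
  vacuous necessity.

## What the synthetic generator emulates — and what it does not

`random_scenario()` places Poisson change points independently per
channel: one recurring goal with alternating onset/offset, a location
channel that switches labels, and two alternating person/object entities
each. Its ground truth replicates the closure semantics above, including
goal-bounding of subevents. This emulates the *structure* of activity
traces (nested, alternating, open-ended events) with realistic sparsity
(default 0.1 change points per unit time and channel over 100 units,
roughly the density of the worked patrol trace), but not: noisy or
missed change detection, simultaneous multi-cue boundaries (which real
event boundaries often are), nested goals, or any human timing
statistics. A green ground-truth-recovery suite therefore establishes
that segmentation and reconstruction are exact inverses of the
generative process under lossless retrieval — not that the model fits
human segmentation behaviour.

Likewise, the premise-set generator draws relations uniformly-ish over
five events; the oracle-equivalence suite establishes that the model
enumerator and an independent exhaustive permutation oracle agree on
verdicts and model counts, not that verdict difficulty tracks human
error rates (the one-model/multi-model difficulty asymmetry is exposed
only as the `model_count` statistic).

## Known limitations

* Boundary strength is all-or-none; fine vs coarse grain is not modeled.
* No metric duration: models cannot answer "how long"; that is a
  deliberate representational claim, not an omission.
* Spreading activation is one-step and untyped; no partial matching or
  noisy retrieval.
* The brute-force verdict oracle refuses more than six events
  (factorial growth); the production enumerator handles larger sets but
  under the `max_models` bound.
* Aspect (punctate vs durational) is inferred from relations and hints,
  not from world knowledge; background-belief effects on initial models
  are out of scope.
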