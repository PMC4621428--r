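# eventmodels

People experience the world as a continuous stream of sensation, yet
remember and reason about it as discrete *events* — "the meeting", "the
patrol", "dinner" — nested inside one another and ordered on a mental
timeline. `eventmodels` is an R implementation of a unified computational
account of how that happens, aimed at researchers in event cognition,
episodic memory, and cognitive robotics who want a runnable, testable
engine rather than a verbal theory. It connects three stages:

1. **Online event segmentation.** A symbolic observation stream over four
   channels (goal, location, person, object) is segmented automatically:
   every instant at which content changes yields one *episodic marker*
   `Ep-n`, a punctate memory chunk recording all changes detected at that
   instant, linked to its predecessor and tagged with the active goal.
2. **Episodic memory.** Markers live in a store with ACT-R-style
   base-level activation: a marker accessed at times `t_j` (weights
   `w_j`) has activation `A(t) = β·|changes| + ln Σ_j w_j (t − t_j)^(−d)`
   — markers encoding more changes start stronger, all markers fade,
   retrieval spikes a marker and spreads a fraction of the spike to its
   associates.
3. **Event models and temporal inference.** On demand (never online),
   retrieved markers are swept to build an *event model*: durational
   events span a start and an end marker, punctate events occupy one
   instant, and events nest into a bounded partonomy placed at ordinal
   positions `1..k` with no metric content. Models may be *veridical*
   (every marker pair becomes an event) or *prioritized*
   (goal > location > person > object; only the superordinate events are
   kept by default). Temporal relations (`before`, `after`, `while`,
   `when`, `during`) are read off by scanning a model; verdicts over a
   premise set (`necessary` / `possible` / `impossible`) come from
   enumerating the distinct models the premises admit; counterfactuals
   come from revising a model and re-scanning it.

## Worked example

The patrol trace: an agent is told to patrol an area, passes through
three locations, meets Bob, completes the goal, and moves on.

```r
library(eventmodels)
rep <- run_pipeline(patrol_fixture(),
                    queries = c("Bob during patrol",
                                "location-a before location-c"))
print(rep)
#> <pipeline report: 8 markers, 6 events>
#> [                                      patrol                                       ]
#>               [ location-a  ]
#>                             [ location-b  ]
#>                                           [               location-c                ]
#>                                                         [     Bob     ]
#>                                                                                                   [ location-d ...
#>   Bob during patrol                        necessary
#>   location-a before location-c             necessary
```

The eight observations yield eight markers (`Ep-1` goal onset … `Ep-8`
post-goal location change). Veridical reconstruction recovers six
events; the diagram is the model itself — one line per event, bracketed
extents, column position = ordinal position, `...` marking the
still-open post-goal location event. Both queries are `necessary`
because they hold in the (single) model: Bob's interval is properly
contained in the patrol's, and location-a's end ordinal precedes
location-c's start ordinal. With `mode = "prioritized"` the model
contains only the superordinate `patrol` event.

Premise-based reasoning works without any observation stream:

```r
query(build_models("shower before coffee\ncoffee before breakfast"),
      "shower before breakfast")
#> <verdict: necessary (1/1 models)>
query(build_models("shower before coffee\nshower before breakfast"),
      "coffee before breakfast")
#> <verdict: possible (1/2 models)>
```

The first description admits one model, so the inference is immediate;
the second admits two, and no coffee/breakfast relation is necessary.

## Command line

An installed `exec/eventmodels` script exposes the pipeline as
subcommands over JSONL/JSON files:

```sh
eventmodels simulate --seed 7 --channels 2 --duration 50 --rate 0.1 --out obs.jsonl
eventmodels segment --stream obs.jsonl --out markers.jsonl
eventmodels reconstruct --markers markers.jsonl --mode veridical --out model.json
eventmodels query --model model.json --assert "location-2 during goal-1"
eventmodels run --stream obs.jsonl --query "goal-1 before location-4" --out report.json
```

## Documentation

See the methods vignette (`vignettes/event-models.Rmd`) for the model,
its assumptions, parameter semantics, and known limitations.
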