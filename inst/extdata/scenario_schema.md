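# Scenario file schema

Scenario files describe sequential binary decision tasks from the point of
view of the focal (last) decision maker. Two equivalent serialisations are
supported: CSV and JSON.

## CSV

One row per scenario, header required, columns in this order:

| column           | type      | meaning                                                      |
|------------------|-----------|--------------------------------------------------------------|
| `scenario_id`    | character | unique label                                                 |
| `study`          | character | free-form grouping tag (e.g. `study1`, `study2`)             |
| `predecessors`   | character | semicolon-separated `RANK:DECISION` tokens, in decision order; empty string for no predecessors |
| `private_signal` | character | `a` or `b`, the focal actor's private signal                 |
| `reliability`    | numeric   | `p(signal | matching state)`, in (0, 1), not 0.5             |
| `prior_A`        | numeric   | prior probability of option A, in (0, 1)                     |

Rank tokens: `EQ` (equally ranked source) or `HR` (higher ranked source).
Decision tokens: `A` or `B`. The two options are always coded `A`/`B`
internally; domain labels (e.g. appendicitis vs. sigmoid diverticulitis,
where the second option and its signal map to `B`/`b`) belong to the
presentation layer.

Example token string for "authority decided A, then a peer decided B":
`HR:A;EQ:B`.

## JSON

A top-level array of objects with keys `scenario_id`, `study`,
`predecessors` (array of `{"rank": ..., "decision": ...}` objects, in
order), `private_signal`, `reliability`, `prior_A`. Keys are emitted in
sorted order by the writer; floats are written with 6 significant digits.

## Packaged fixtures

* `scenarios_study1.csv` — the 12 urn-task designs (canonical orientation;
  mirrored presentations are generated by the loader's `mirrored` flag).
* `scenarios_study2.csv` — the 40 clinical-framing designs with mixed
  source ranks.
* `observed_study1.csv`, `observed_study2.csv` — published per-scenario
  response summaries: `pct_choice` is the percentage of choices for the
  Bayesian-favoured option (for the option favoured by the private signal
  in indifference scenarios), `judgment` the mean probability judgment.
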