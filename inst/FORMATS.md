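# File formats

All files are plain text, UTF-8, "." decimal separator, `NA` for missing
values. Angles are degrees everywhere; positive means rightward of the
task reference.

## Trials CSV

Headered, comma-separated, one row per trial:

| column         | type            | meaning                                        |
|----------------|-----------------|------------------------------------------------|
| `session_id`   | string          | session identifier (may be `NA` for single-session files) |
| `t`            | integer >= 1    | trial index, strictly increasing within a session |
| `condition`    | `L`/`N`/`R`     | leftward-context, neutral, rightward-context   |
| `omega_deg`    | float           | stimulus direction relative to the reference   |
| `choice`       | `left`/`right`  | the subject's report                           |
| `reward`       | 0/1/`NA`        | reward delivered (NA if not recorded)          |
| `boundary_deg` | float/`NA`      | reward boundary used on that trial             |

Read/write/validate with `read_trials()`, `write_trials()`,
`validate_trials()`.

## Prior specification YAML

One explicit key per hyperparameter of `prior_spec()`:
`P_L_mean`, `P_L_sd`, `P_R_mean`, `P_R_sd`, `D_mean`, `D_sd`,
`S_shape`, `S_rate` (length 3, ordered L/N/R), `lapse_shape1`,
`lapse_shape2`, `flat`.

## Posterior JSON

`write_posterior_json()` emits posterior means, SDs, central 68% and 95%
intervals, effective sample sizes, the split-chain convergence statistic,
a `converged` flag, and the trial count; raw draws go to a CSV on
request.

## Multi-session inputs

`perceptbias hyper` takes a session summary CSV (`P_L_mean`, `P_L_sd`,
`P_R_mean`, `P_R_sd`, `D_mean`, `D_sd`; one row per session, chronological)
plus a covariates CSV with one row per session (e.g. `heading_deg`,
`eccentricity_deg`). Experiment runners also write a JSON manifest
(config, seeds, package version) alongside every output so results can be
regenerated from the manifest alone.
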