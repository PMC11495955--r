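# File formats

All tables are comma-separated UTF-8 text with a header row and `.` decimal
separator. Writers emit full precision; readers validate strictly (missing
column: error; unknown column: warning; malformed cell: error with row
context).

## Track (`write_track` / `read_track`)

| column   | type    | meaning                                   |
|----------|---------|-------------------------------------------|
| `time_s` | numeric | seconds from CEE start, strictly increasing |
| `x_m`    | numeric | easting, local planar frame, metres        |
| `y_m`    | numeric | northing, local planar frame, metres       |

## Block series (`write_blocks` / `read_blocks`)

One row per 5 s analysis block on the phase-schedule grid.

| column     | type    | meaning                                         |
|------------|---------|--------------------------------------------------|
| `block`    | integer | 1-based block index                              |
| `phase`    | factor  | `pre`, `exposure` or `post`                      |
| `value`    | numeric | response value; empty iff `observed` is 0        |
| `observed` | 0/1     | whether the block was observed                   |

## Ping log (`write_pings` / `read_pings`)

| column        | type    | meaning                                        |
|---------------|---------|-------------------------------------------------|
| `time_s`      | numeric | ping start time, strictly increasing            |
| `range_m`     | numeric | source-to-focal-group range at the ping         |
| `spl_db`      | numeric | received RMS SPL, dB re 1 uPa                   |
| `sel_db`      | numeric | per-ping SEL, dB re 1 uPa^2 s                   |
| `transmitted` | 0/1     | 0 marks mock pings of a no-sonar control CEE    |

## Detection-flag fixture (`table_detections.csv`)

Per-CEE detection flags (response/persistence probability > 0.9) for the 34
common-dolphin CEEs by subspecies, metric (`whistle`, `subgroup`,
`movement`) and phase comparison (`exposure_vs_pre`, `post_vs_pre`), with
`available` marking whether the metric had sufficient data for that CEE
(unavailable CEEs are excluded from summary denominators). Lines starting
with `#` are comments.

## Per-CEE results (`write_cee_result`)

JSON object with `cee_id`, a `metrics` array (per-metric phase means and
sds, response/persistence probabilities, directions, detection flags,
maximum PSRF), `rl_max_db`, `csel_db`, `v1_kmh` and the MCMC configuration.
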