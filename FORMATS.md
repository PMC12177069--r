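# File formats

All times are seconds from trial start; intervals are half-open
`[start, end)`; samples are 0-based. Numeric CSV payloads are written at
15 significant digits.

## Kinematics CSV (per trial)

One row per sample at the wearable rate (default 100 Hz).

| column | unit | description |
|---|---|---|
| `time_s` | s | sample time |
| `fsr_heel_l`, `fsr_met1_l`, `fsr_met5_l`, `fsr_toe_l` | a.u. | left footswitch channels (heel, 1st/5th metatarsal, hallux) |
| `fsr_heel_r`, `fsr_met1_r`, `fsr_met5_r`, `fsr_toe_r` | a.u. | right footswitch channels |
| `gonio_l`, `gonio_r` | deg | ankle dorsiflexion angle |
| `wrist_l`, `wrist_r` | m | anteroposterior wrist position |
| `pelvis_pos` | m | cumulative pelvis anteroposterior position |
| `pelvis_heading` | deg | pelvis heading (turns ramp by 180°) |
| `chest_accel` | g | chest-worn accelerometer magnitude |

## Neural signals

Float32 column binary (`write_signals()`): channels concatenated
column-wise, NaN marks blanked/missing samples. JSON sidecar
(`<file>.json`): `channels` (e.g. `GP`, `ctxA`, `ctxB`), `rate_Hz`
(500), `n_samples`, `dtype`. The device accelerometer (64 Hz) uses the
same container. Neural and device-accelerometer streams live on the
device clock; `estimate_sync()` returns the device-minus-wearable
offset.

## Events CSV

`time_s,label` with labels `LHS`, `RTO`, `RHS`, `LTO`.

## Trial/stride metrics CSV

Stride level: `stride_index`, `stride_time_s`, `stride_length_m`,
`stride_velocity`, `step_time_s`, `step_length_m`,
`arm_swing_amplitude`, `is_turn`. Trial level: `stride_velocity`,
`arm_swing_amplitude`, `step_length_cv`, `step_time_cv` (coefficients of
variation, sample SD / mean), `n_valid_strides`, `usable`.

## WPI CSV

`trial_id`, `visit_id`, `subject_id`, `raw` (in [0, 1]),
`baseline_normalized` (clinical trial = 1), `rank` (1 = best).

## Artifact mask CSV

`start_s,end_s,provenance` with provenance `gamma_outlier` or
`packet_loss`.

## Feature table CSV

Long format, one row per phase-band feature per trial: `subject_id`,
`hemisphere` (`left`/`right`), `site_or_pair` (`GP`, `ctxA`, `ctxB`,
`GP-ctxA`, `GP-ctxB`, `ctxA-ctxB`), `kind` (`power`/`coherence`),
`band` (`delta`/`theta`/`alpha`/`beta`), `phase`
(`DS1`/`CLS`/`DS2`/`ILS`), `trial_id`, `visit_id`, `value` (z units),
`wpi`, `amplitude_mA`, `frequency_Hz`, `pulse_width_us`, `clinical`.

## Cohort manifest CSV

`trial_id`, `subject_id`, `visit_id`, `amplitude_mA`, `frequency_Hz`,
`pulse_width_us`, `clinical` (logical), `order_in_visit`.

## Pipeline configuration JSON

Schema: `inst/extdata/pipeline-config-schema.json` (validated by
`load_config()`). The run directory's `manifest.json` records the
package version, master seed, stage list and an MD5 per output file.
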