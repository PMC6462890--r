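# hearscale

Simulation and evaluation toolkit for **stratified-scale smartphone hearing
screening** of school-age children.

Conventional pure-tone screening (PTS) presents a few fixed-level tones and
returns only a dichotomous *pass*/*fail* per ear. The Hearing Scale Test (HST)
instead stratifies the level range into hearing scales S_1, S_2, …, each a set
of four per-frequency levels 5 dB apart from its neighbours:

```
level(f, s) = 5 · (s − 1) + offset(f),   offset(500 Hz) = 5, otherwise 0
```

so S_1 presents 0/0/0 dB HL at 1/2/4 kHz and 5 dB HL at 500 Hz, up to S_10 at
45/45/45/50 dB HL (extensible to S_20). An adaptive engine starts at S_5 and
presents the four tones in fixed order (1000, 2000, 4000, 500 Hz); if all are
heard it descends one scale, otherwise it ascends, until it finds the
**minimum audible hearing scale** — the lowest scale at which all four tones
are heard — or declares *no response* (NR) past S_10. Scales S_1–S_5 classify
as *pass*; S_6–S_10 and NR as *fail*. Screening performance is judged against
a sound-treated-booth reference where impairment is a pure-tone average (PTA)
above 25 dB.

The package provides, with no hardware or human subjects required:

- `scale_table()`, `scale_level()`, `classify_scale()` — the scale
  stratification and pass rule;
- `run_hst()` — the adaptive screening state machine, plus an independent
  brute-force check `minimum_audible_scale_oracle()` and `test_retest()`;
- `protocol_preset()` / `fixed_level_screen()` — fixed-level presets (AAP at
  20 dB × 4 frequencies; two ASHA variants) with the two-procedure fail rule;
- `simulated_listener()` / `respond()` — psychometric listeners (logistic
  function with guess/lapse rates; slope 0 = deterministic step), and cohort
  generators `cohort_from_table3()` (the 170-ear validation cohort) and
  `sample_cohort()`;
- `run_staircase()` — the 2-down-1-up, 1 dB-step calibration staircase with
  ascending pre-scan, terminating after a set number of reversals;
- `hl_to_spl()`, `spl_to_amplitude()`, `synthesize_tone()`, `write_wav()` —
  the RETSPL calibration chain and amplitude-modulated tone synthesis;
- `contingency()`, `screen_metrics()`, `scale_group_summary()`,
  `scale_pta_correlation()`, `compare_protocols()` — screening-test
  evaluation;
- a CLI (`hst_main()`, wrapped by `inst/cli/hearscale.R`) with `screen`,
  `cohort`, `evaluate` and `stimuli` subcommands.

## Worked example

Reconstruct the 170-ear validation cohort from its per-scale group counts and
booth PTA labels, screen every ear with the adaptive engine, and evaluate
against the PTA > 25 dB reference:

```r
library(hearscale)
set.seed(1)

cohort <- cohort_from_table3()      # 170 deterministic listeners
run    <- run_protocol(cohort, "HST")

table(run$classifications)
#> fail pass
#>    2  168

ct <- contingency(run$classifications, reference_impaired(cohort))
print(screen_metrics(ct))
#> sensitivity:        100.0%
#> specificity:        100.0%
#> PPV:                100.0%
#> NPV:                100.0%
#> false-positive rate:0.0%
#> false-negative rate:0.0%

pta <- vapply(cohort, function(l) l$booth_pta_db, numeric(1))
scale_group_summary(run$assigned_scales, pta)
#>   scale  n mean_pta_db sd_pta_db
#> 1     1 16           5         0
#> 2     2 58           7         0
#> 3     3 59           9         0
#> 4     4 27          11         0
#> 5     5  8          12         0
#> 6     7  1          31       NaN
#> 7     8  1          36       NaN
```

168 ears pass (scales S_1–S_5) and 2 fail (S_7, S_8); both failing ears are
exactly the two with booth PTA above 25 dB, so sensitivity and specificity are
both 100%. The per-scale rows recover the fixture's group counts
(16/58/59/27/8/1/1) and booth PTA labels; the SD column is 0 within the
deterministic groups and undefined (`NaN`) for single-ear groups.

Or from a shell:

```sh
Rscript inst/cli/hearscale.R evaluate --protocol HST,AAP,ASHA_as_tested --seed 1
Rscript inst/cli/hearscale.R stimuli --frequency 1000 --level-hl 20 \
    --profile inst/extdata/synthetic_calibration_profile.json --out tone.wav
```

(The shipped calibration profile contains synthetic placeholder values, not
measured hardware; supply your own measured RETSPL/max-output JSON for real
devices.)

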