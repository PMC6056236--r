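# vestcoh

Time-frequency coherence analysis of stochastic electrical vestibular
stimulation (EVS) and ground reaction forces (GRF), for studying how the
vestibular control of balance is modulated — and transiently suspended —
around transitions between motor states (quiet standing ↔ locomotion,
posture ↔ posture).

The package is aimed at sensorimotor neurophysiologists and biomechanists
who work with forceplate recordings under stochastic vestibular
stimulation. Because raw recordings of this kind are rarely shared, the
package includes a first-class trial simulator with controllable
vestibulo-motor coupling, so every stage of the analysis chain can be
exercised, calibrated and tested end to end without any external data.

## What it computes

For a stimulus `x(t)` (EVS current, mA) and a shear-force channel `y(t)`
(N), each trial is decomposed with a continuous complex Morlet wavelet
(centre parameter ω₀ = 6) on a 1–20 Hz grid, with the force record advanced
by the 200 ms latency of the vestibular balance-correcting response. Auto-
and cross-spectra are averaged over L trials and the time-frequency
coherence is

    C(τ, f) = |P̄xy(τ, f)|² / ( P̄xx(τ, f) · P̄yy(τ, f) ),

a 0–1 measure of linear vestibulo-motor coupling at time τ and frequency f.
Estimated coherence is significant at level α when it exceeds the
closed-form confidence limit

    CL(L, α) = 1 − α^(1/(L−1)),

which at the 99% level gives 0.045 for L = 100 trials, 0.005 for 1000
pooled segments and 0.008 for 600 pooled segments.

Around each transition the package derives:

* gait events (toe-off / heel-strike at 5% of body weight) and transition
  markers (centre-of-pressure speed above baseline mean + 3 SD),
* movement-time-normalized and marker-centred trial-averaged coherence maps,
* the band-averaged (1–10 Hz) coherence time course and the **null period**
  — the stretch around the transition where coherence falls below the
  confidence limit,
* per-phase peak coherence magnitude and frequency, compared across phases
  with a repeated-measures multivariate test, paired Hotelling T² post hocs
  and Bonferroni-corrected paired t-tests.

## Worked example

```r
library(vestcoh)

cfg  <- run_config(protocol = "locomotor_initiation", n_trials = 100, seed = 1)
summ <- run_pipeline(cfg, "out")

np <- summ$per_subject[[1]]$null_period
cat(sprintf("null period: lead %.3f s, duration %.3f s (cl = %.3f)\n",
            np$onset_lead, np$duration, summ$per_subject[[1]]$cl))
```

```
null period: lead 0.420 s, duration 0.852 s (cl = 0.045)
```

With the default simulator settings, the coupling gain is zeroed for 0.8 s
starting 0.4 s before the transition onset; the recovered lead (0.420 s)
and duration (0.852 s) show the analysis locating that suspension from the
coherence alone — the small excess over the injected 0.4/0.8 s reflects the
temporal smearing of the low-frequency wavelets. `out/` additionally holds
the per-subject and pooled coherence matrices (`coherence_*.tsv`), the
detected events (`events.json`) and the full summary (`summary.json`),
every file stamped with a hash of the configuration.

Single steps are available as plain functions (`generate_evs`,
`simulate_trial`, `detect_gait_events`, `morlet_spectra`,
`average_and_cohere`, `detect_null_period`, `hotelling_paired`, ...), and a
thin command-line front end with `simulate` / `events` / `coherence` /
`analyze` / `stats` / `all` subcommands is installed at
`inst/cli/vestcoh.R`.

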