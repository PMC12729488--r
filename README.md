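# koalawalk

Koalas spend almost all of their time in trees, but the few minutes a day
they spend walking on the ground account for most of their mortality —
vehicle strikes and dog attacks happen during brief tree-to-tree
transits. Quantifying *when*, *how often* and *for how long* koalas are on
the ground therefore matters directly for conservation scheduling (speed
limits, crossings, dog curfews). `koalawalk` is an R implementation of the
full collar-accelerometry pipeline used to answer those questions: from raw
50 Hz tri-axial signal to behaviour labels, energetics, ground-visit
statistics and diel activity curves. It is aimed at movement ecologists
working with collar accelerometers on arboreal mammals.

## What the pipeline computes

1. **Synthetic collar streams** (`sim_config()`, `simulate_stream()`):
   behaviour-annotated 50 Hz heave/surge/sway streams with semi-Markov bout
   structure, a diel ground-visit process concentrated in the pre-dawn
   window, optional canopy-sway contamination, and collar-tap calibration
   events. Every downstream stage is testable against known ground truth.
2. **Stream I/O** (`read_stream()`, `downsample()`, `detect_taps()`):
   delimited-text streams with JSON sidecars, g → m·s⁻² conversion, gap
   flagging, boxcar-mean decimation (100 → 50 Hz), and tap-event detection
   for video/collar clock alignment.
3. **Features and energetics** (`extract_feature_table()`,
   `vedba_seconds()`): 1 s windows with 50 % overlap; per-axis statistics,
   spectral features and cross-axis correlations; the static (gravity)
   component is a 2 s rolling mean and the dynamic residual gives
   VeDBA = √(d²ₓ+d²ᵧ+d²_z) and ODBA = |dₓ|+|dᵧ|+|d_z| per sample, with
   per-second maxima/minima.
4. **Classification** (`chronological_split()`, `tune_forest()`,
   `train_forest()`, `predict_seconds()`): chronological 60/20/20 split per
   behaviour per individual (no sequence leakage), Random-Forest
   hyperparameter search maximising macro-F1 on the validation set, and
   per-second behaviour prediction.
5. **Post-processing** (`modal_filter()`, `collapse_blips()`, `regroup()`,
   `bin_20s()`): centred 5 s modal filter (ties keep the centre label),
   collapse of runs shorter than 3 s into the surrounding state, regrouping
   of the seven classifier classes into four final categories plus Other,
   and non-overlapping 20 s majority bins with VeDBA summaries.
6. **Ground visits and budgets** (`detect_visits()`, `daily_budget()`,
   `peak_hour()`): clusters of Walking bins separated by ≤ 60 s form Ground
   Visits; daily budgets are rescaled to 1440 min, averaged within
   individuals across days and then across animals.
7. **Diel models and comparisons** (`fit_cyclic_activity()`,
   `fit_walking_curve()`, `compare_vedba()`, `walking_covariate_test()`):
   GAMMs with cyclic cubic splines over hour-of-day and individual random
   intercepts; Kruskal–Wallis plus pairwise Wilcoxon (Benjamini–Hochberg)
   on log VeDBA across behaviours; a linear mixed model for sex/habitat
   effects on daily walking.
8. **Orchestration** (`run_pipeline()`, `validate_report()`): one call from
   simulation to report bundle, with a config hash on every output, plus
   arithmetic validation of metrics/budget reports. A thin CLI lives at
   `inst/scripts/run_pipeline.R`.

## Worked example

Simulate a nine-animal, eight-day deployment, push the ground-truth labels
through the post-processing chain, and summarise ground use:

```r
library(koalawalk)

config  <- sim_config(seed = 1)          # 9 koalas x 8 days, 50 Hz
profile <- individual_profile(config)

bins <- dplyr::bind_rows(lapply(1:9, function(i) {
  secs <- sequence_to_seconds(simulate_behaviour_sequence(config, i))
  postprocess_labels(secs$label, NULL, individual = profile$individual[i])
}))
bins <- exclude_other(bins)

visits <- detect_visits(bins)
summarise_visits(visits, n_days = 8)$population$visits_per_day_mean
#> [1] 2.472222
budget <- summarise_budget(daily_budget(bins))
budget$minutes_mean[budget$category == "Walking"]
#> [1] 2.731714
peak_hour(bins, "Walking")
#> [1] 2
```

Read: the detection pipeline recovers about 2.5 ground visits per day and
2.7 min of daily walking from a population simulated at 2.95 visits/day and
3.0 min/day (short sub-bin visits are invisible at 20 s resolution), and
walking peaks in the 02:00–03:00 clock hour — the pre-dawn window in which
the simulated visit intensity is concentrated.

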