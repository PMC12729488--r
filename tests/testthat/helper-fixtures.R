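# Shared fixtures. The end-to-end classifier fixture and the multi-day
# ground-truth label-path fixture are expensive, so they are built lazily
# once per test run and reused across files.

.kw_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .kw_cache)) {
    assign(name, builder(), envir = .kw_cache)
  }
  get(name, envir = .kw_cache)
}

# captive training deployment -> forest -> scored wild day for 2 animals
classifier_fixture <- function() {
  cached("classifier", function() {
    cfg <- captive_sim_config(seed = 3, hours = 2)
    feats <- dplyr::bind_rows(lapply(
      seq_len(cfg$n_individuals),
      function(i) extract_feature_table(simulate_stream(cfg, i))
    ))
    sp <- suppressWarnings(chronological_split(feats))
    tr <- sp[sp$split == "train", ]
    va <- sp[sp$split == "validation", ]
    te <- sp[sp$split == "test", ]
    rf_cfg <- list(number_trees = 300, mtry = 7, max_depth = 16, seed = 1)
    model <- train_forest(tr, rf_cfg)
    test_metrics <- classification_metrics(
      confusion_matrix(te$label, predict_windows(model, te))
    )
    # deployment model: refit on all labelled data once assessed
    model_full <- train_forest(sp, rf_cfg)

    wcfg <- sim_config(seed = 9, days_per_individual = 1)
    prof <- individual_profile(wcfg)
    wild <- lapply(c(6L, 9L), function(i) {
      stream <- simulate_stream(wcfg, i)
      feats <- extract_feature_table(stream, overlap = 0)
      secs <- predict_seconds(model_full, feats)
      vs <- vedba_seconds(stream)
      truth <- sequence_to_seconds(simulate_behaviour_sequence(wcfg, i))
      list(
        individual = prof$individual[i],
        secs = secs, truth = truth,
        pred_bins = postprocess_labels(
          secs$label, vs, individual = prof$individual[i],
          sex = prof$sex[i], habitat = prof$habitat[i],
          mass_kg = prof$mass_kg[i]
        ),
        true_bins = postprocess_labels(
          truth$label, vs, individual = prof$individual[i]
        )
      )
    })
    list(cfg = cfg, train = tr, validation = va, test = te, model = model,
         model_full = model_full, test_metrics = test_metrics, wild = wild)
  })
}

# ground-truth labels for the full wild deployment (9 animals x 8 days)
# pushed through smoothing, binning, visit detection and budgets
labelpath_fixture <- function() {
  cached("labelpath", function() {
    cfg <- sim_config(seed = 101)
    prof <- individual_profile(cfg)
    bins <- dplyr::bind_rows(lapply(seq_len(cfg$n_individuals), function(i) {
      secs <- sequence_to_seconds(simulate_behaviour_sequence(cfg, i))
      postprocess_labels(
        secs$label, NULL, individual = prof$individual[i],
        sex = prof$sex[i], habitat = prof$habitat[i],
        mass_kg = prof$mass_kg[i]
      )
    }))
    bins <- exclude_other(bins)
    visits <- detect_visits(bins)
    list(
      cfg = cfg, profile = prof, bins = bins, visits = visits,
      visit_summary = summarise_visits(visits, cfg$days_per_individual),
      budget = daily_budget(bins)
    )
  })
}

# tiny labelled stream for cheap unit tests
tiny_stream <- function(seed = 5, hours = 0.25) {
  simulate_stream(captive_sim_config(seed = seed, hours = hours), 1)
}

constant_stream <- function(label = "Still", secs = 60, fs = 50,
                            value = c(0, 0, 9.81)) {
  n <- secs * fs
  labelled_stream(
    tibble::tibble(t = (seq_len(n) - 1) / fs,
                   ax = value[1], ay = value[2], az = value[3],
                   label = label),
    sample_rate = fs, individual_id = "const"
  )
}

# noisy sinusoidal diel-activity bins with a planted peak
sin_bins <- function(peak_hour, n_days = 3, inds = c("a", "b"),
                     noise = 0.05, seed = 5) {
  set.seed(seed)
  dplyr::bind_rows(lapply(inds, function(id) {
    start_s <- seq(0, n_days * 86400 - 1, by = 20)
    h <- hour_of_day(start_s)
    tibble::tibble(
      start_s = start_s,
      label = "General Movement in Tree",
      vedba_max_mean = 1 + 0.5 * cos(2 * pi * (h - peak_hour) / 24) +
        stats::rnorm(length(start_s), 0, noise) +
        ifelse(id == "a", 0.2, -0.2),
      vedba_min_mean = 0,
      individual = id, gap = FALSE
    )
  }))
}

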