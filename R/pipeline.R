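# End-to-end pipeline orchestration and report validation.

#' Reference classifier metrics from the original koala deployment
#'
#' Published per-class and macro performance of the tuned Random-Forest
#' behaviour classifier, bundled to validate reporting arithmetic
#' (macro-averaging, harmonic-mean F1).
#'
#' @return tibble mirroring the metrics report layout
#' @export
reference_class_metrics <- function() {
  readr::read_csv(
    system.file("extdata", "reference_classifier_metrics.csv",
                package = "koalawalk"),
    show_col_types = FALSE, progress = FALSE
  )
}

#' Reference daily behavioural budget from the original koala deployment
#'
#' Published population means: minutes and percent of day per category,
#' diel peak hours, and the ground-visit rate and per-visit walking
#' duration. Used to parameterise the default simulation and to validate
#' budget arithmetic.
#'
#' @return tibble with one row per behaviour category
#' @export
reference_daily_budget <- function() {
  readr::read_csv(
    system.file("extdata", "reference_daily_budget.csv",
                package = "koalawalk"),
    show_col_types = FALSE, progress = FALSE
  )
}

#' Run the full analysis pipeline on synthetic data
#'
#' Simulates a captive training deployment and a wild scoring deployment,
#' extracts features, performs the chronological split, tunes and trains
#' the Random Forest, predicts per-second labels for the wild animals,
#' post-processes them into 20 s bins, detects ground visits, computes
#' daily budgets, and fits the diel models. Identical config + seed give an
#' identical bundle.
#'
#' @param train_config `sim_config` for the captive training animals
#'   (balanced behaviour shares help rare-class recall)
#' @param wild_config `sim_config` for the wild animals to score
#' @param tune_budget hyperparameter search budget (1 skips searching
#'   beyond a single configuration)
#' @param seed integer seed
#' @param out_dir optional directory for CSV/JSON outputs
#' @return list: model, split counts, test metrics table, wild bins, ground
#'   visits, budget summary, diel fits, config hash
#' @export
run_pipeline <- function(train_config, wild_config, tune_budget = 3,
                         seed = 1L, out_dir = NULL) {
  hash <- rlang::hash(list(train_config, wild_config, tune_budget, seed))
  log_lines <- c(sprintf("run %s seed %d", hash, seed))

  # 1. training data: captive streams -> features -> chronological split
  train_feats <- dplyr::bind_rows(lapply(
    seq_len(train_config$n_individuals), function(i) {
      extract_feature_table(simulate_stream(train_config, i))
    }
  ))
  split_tab <- chronological_split(train_feats)
  tr <- split_tab[split_tab$split == "train", ]
  va <- split_tab[split_tab$split == "validation", ]
  te <- split_tab[split_tab$split == "test", ]
  log_lines <- c(log_lines, sprintf(
    "windows: %d train / %d validation / %d test", nrow(tr), nrow(va),
    nrow(te)
  ))

  # 2. tune + final fit on train+validation, assess on test
  cfg <- tune_forest(tr, va, budget = tune_budget, seed = seed)
  model <- train_forest(dplyr::bind_rows(tr, va), cfg)
  test_pred <- predict_windows(model, te)
  test_metrics <- classification_metrics(
    confusion_matrix(te$label, test_pred)
  )
  log_lines <- c(log_lines,
                 sprintf("test macro-F1 %.3f", test_metrics$macro$f1))

  # 3. score wild animals second by second and post-process
  wild <- lapply(seq_len(wild_config$n_individuals), function(i) {
    stream <- simulate_stream(wild_config, i)
    feats <- extract_feature_table(stream)
    secs <- predict_seconds(model, feats)
    vs <- vedba_seconds(stream)
    postprocess_labels(
      secs$label, vs,
      individual = stream$meta$individual_id, sex = stream$meta$sex,
      habitat = stream$meta$habitat, mass_kg = stream$meta$mass_kg
    )
  })
  bins <- exclude_other(dplyr::bind_rows(wild))

  # 4. visits, budgets, models
  visits <- detect_visits(bins)
  vis_sum <- if (nrow(visits) > 0) {
    summarise_visits(visits, wild_config$days_per_individual)
  } else NULL
  budget <- daily_budget(bins)
  budget_sum <- summarise_budget(budget)
  act_fit <- fit_cyclic_activity(bins)
  walk_fit <- if ("Walking" %in% bins$label) fit_walking_curve(bins) else NULL
  vedba_cmp <- compare_vedba(bins)

  report <- list(
    config_hash = hash, seed = seed,
    model_config = cfg,
    test_metrics = metrics_table(test_metrics),
    bins = bins, visits = visits, visit_summary = vis_sum,
    budget = budget, budget_summary = budget_sum,
    activity_fit = act_fit, walking_fit = walk_fit,
    vedba_comparison = vedba_cmp,
    log = log_lines
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# write the CSV/JSON bundle; every file carries the config hash
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- function(df) {
    df$config_hash <- report$config_hash
    df
  }
  readr::write_csv(stamp(report$test_metrics),
                   file.path(out_dir, "metrics.csv"), progress = FALSE)
  readr::write_csv(stamp(report$budget_summary),
                   file.path(out_dir, "budget.csv"), progress = FALSE)
  readr::write_csv(stamp(report$visits),
                   file.path(out_dir, "visits.csv"), progress = FALSE)
  readr::write_csv(stamp(report$activity_fit$predictions),
                   file.path(out_dir, "activity_curve.csv"), progress = FALSE)
  if (!is.null(report$walking_fit)) {
    readr::write_csv(stamp(report$walking_fit$predictions),
                     file.path(out_dir, "walking_curve.csv"),
                     progress = FALSE)
  }
  jsonlite::write_json(
    list(config_hash = report$config_hash, seed = report$seed,
         model_config = report$model_config,
         visit_summary = report$visit_summary,
         log = report$log),
    file.path(out_dir, "run.json"), auto_unbox = TRUE, digits = NA
  )
  writeLines(report$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' Check the internal arithmetic of a metrics + budget report
#'
#' Recomputes the arithmetic relationships any correct report must satisfy:
#' the macro row equals the unweighted mean of the per-class rows, each F1
#' equals the harmonic mean of its precision and recall, and percent-of-day
#' follows from minutes per day under 1440-min rescaling.
#'
#' @param metrics metrics table (per-class rows + macro row) or NULL
#' @param budget budget table with MinutesPerDay and PercentOfDay or NULL
#' @param tol_metrics absolute tolerance on metric arithmetic
#' @param tol_percent absolute tolerance on percent arithmetic (0.05 covers
#'   1-decimal rounding of the printed values)
#' @return tibble of checks: check, value, expected, pass; errors when both
#'   inputs are NULL
#' @export
validate_report <- function(metrics = NULL, budget = NULL,
                            tol_metrics = 5e-7, tol_percent = 0.055) {
  if (is.null(metrics) && is.null(budget)) {
    stop("empty report: nothing to validate")
  }
  checks <- list()
  if (!is.null(metrics)) {
    pc <- metrics[metrics$Behaviour != "Macro-average", ]
    mac <- metrics[metrics$Behaviour == "Macro-average", ]
    stopifnot(nrow(mac) == 1)
    for (col in c("Precision", "Recall", "F1")) {
      checks[[paste0("macro_", tolower(col))]] <- tibble::tibble(
        check = paste("macro", col, "is unweighted class mean"),
        value = mean(pc[[col]]),
        expected = mac[[col]],
        pass = abs(mean(pc[[col]]) - mac[[col]]) <= tol_metrics
      )
    }
    hm <- 2 * pc$Precision * pc$Recall / (pc$Precision + pc$Recall)
    checks[["f1_harmonic"]] <- tibble::tibble(
      check = "per-class F1 is harmonic mean of precision and recall",
      value = max(abs(hm - pc$F1)),
      expected = 0,
      pass = max(abs(hm - pc$F1)) <= tol_metrics
    )
  }
  if (!is.null(budget)) {
    b <- budget[!is.na(budget$PercentOfDay), ]
    implied <- b$MinutesPerDay / 14.4
    checks[["budget_percent"]] <- tibble::tibble(
      check = "percent of day follows from minutes under 1440-min rescaling",
      value = max(abs(implied - b$PercentOfDay)),
      expected = 0,
      pass = max(abs(implied - b$PercentOfDay)) <= tol_percent
    )
  }
  dplyr::bind_rows(checks)
}
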