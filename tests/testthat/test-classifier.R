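make_windows <- function(n, label = "A", individual = "k1", start = 0) {
  tibble::tibble(
    window = seq_len(n), start_s = start + (seq_len(n) - 1) * 0.5,
    label = label, purity = 1, individual = individual,
    f1 = stats::rnorm(n), f2 = stats::rnorm(n)
  )
}

test_that("chronological split cuts 60/20/20 in time order per stratum", {
  w <- make_windows(10)
  s <- chronological_split(w)
  expect_equal(as.integer(table(s$split)[c("train", "validation", "test")]),
               c(6L, 2L, 2L))
  expect_lt(max(s$start_s[s$split == "train"]),
            min(s$start_s[s$split == "validation"]))
  expect_lt(max(s$start_s[s$split == "validation"]),
            min(s$start_s[s$split == "test"]))
})

test_that("split is invariant to input order and strata stay separate", {
  set.seed(2)
  w <- dplyr::bind_rows(
    make_windows(20, "A", "k1"), make_windows(15, "B", "k1"),
    make_windows(12, "A", "k2")
  )
  shuffled <- w[sample(nrow(w)), ]
  s1 <- chronological_split(w)
  s2 <- chronological_split(shuffled)
  expect_equal(dplyr::arrange(s1, individual, label, start_s),
               dplyr::arrange(s2, individual, label, start_s))
  for (grp in split(s1, list(s1$individual, s1$label), drop = TRUE)) {
    expect_lt(max(grp$start_s[grp$split == "train"]),
              min(grp$start_s[grp$split == "validation"]))
  }
})

test_that("tiny strata go wholly to training with a warning", {
  w <- dplyr::bind_rows(make_windows(10, "A"), make_windows(3, "B"))
  expect_warning(s <- chronological_split(w), "wholly in training")
  expect_true(all(s$split[s$label == "B"] == "train"))
})

test_that("unlabelled windows are dropped before splitting", {
  w <- make_windows(10)
  w$label[3] <- NA
  s <- suppressWarnings(chronological_split(w))
  expect_equal(nrow(s), 9)
})

test_that("tuning is seed-deterministic and returns the dominant config", {
  fx <- classifier_fixture()
  tr <- fx$train[seq_len(800), ]
  va <- fx$validation[seq_len(300), ]
  ranges <- list(number_trees = c(50L, 150L), mtry = c(4L, 8L),
                 max_depth = c(6L, 12L))
  c1 <- tune_forest(tr, va, budget = 3, seed = 5, ranges = ranges)
  c2 <- tune_forest(tr, va, budget = 3, seed = 5, ranges = ranges)
  expect_equal(c1[c("number_trees", "mtry", "max_depth")],
               c2[c("number_trees", "mtry", "max_depth")])
  ev <- attr(c1, "evaluated")
  best <- ev[which.max(ev$macro_f1), ]
  expect_equal(c1$number_trees, best$number_trees)
  expect_equal(attr(c1, "macro_f1"), max(ev$macro_f1))

  # budget 1 returns the single evaluated configuration
  c3 <- tune_forest(tr, va, budget = 1, seed = 5, ranges = ranges)
  expect_equal(nrow(attr(c3, "evaluated")), 1)

  expect_error(tune_forest(tr, va[0, ], budget = 1, seed = 5), "validation")
})

test_that("training error is below validation error", {
  fx <- classifier_fixture()
  err <- function(w) {
    mean(predict_windows(fx$model, w) != w$label)
  }
  expect_lt(err(fx$train), err(fx$validation) + 1e-12)
})

test_that("prediction rejects mismatched feature names", {
  fx <- classifier_fixture()
  bad <- fx$test
  names(bad)[names(bad) == "ax_mean"] <- "ax_average"
  expect_error(predict_windows(fx$model, bad), "feature names")
})

test_that("per-second prediction uses exactly the on-grid windows", {
  fx <- classifier_fixture()
  te <- fx$test[1:200, ]
  secs <- predict_seconds(fx$model, te)
  on_grid <- te[abs(te$start_s - round(te$start_s)) < 1e-9, ]
  expect_equal(nrow(secs), nrow(on_grid))
  expect_equal(secs$second, as.integer(round(on_grid$start_s)))
  expect_false(any(duplicated(secs$second)))
})

test_that("an all-still stream is predicted almost entirely Still", {
  cfg <- sim_config(seed = 44, sway_noise_sd = 0.05)
  seq <- tibble::tibble(behaviour = "Still", start_s = 0, duration_s = 600)
  attr(seq, "total_s") <- 600
  st <- synthesize_axes(seq, cfg, 1)
  fx <- classifier_fixture()
  secs <- predict_seconds(fx$model, extract_feature_table(st, overlap = 0))
  expect_gte(mean(secs$label == "Still"), 0.95)
})

test_that("metric arithmetic satisfies the defining identities", {
  # precision = recall = p gives F1 = p (harmonic-mean identity)
  cm <- matrix(c(8, 2, 2, 8), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  m <- classification_metrics(cm)
  expect_equal(m$per_class$precision, m$per_class$recall)
  expect_equal(m$per_class$f1, m$per_class$precision)
  # per-class F1 is always the harmonic mean of precision and recall
  cm2 <- matrix(c(30, 5, 1, 2, 40, 3, 4, 6, 50), 3, 3,
                dimnames = list(letters[1:3], letters[1:3]))
  m2 <- classification_metrics(cm2)
  expect_equal(m2$per_class$f1,
               2 * m2$per_class$precision * m2$per_class$recall /
                 (m2$per_class$precision + m2$per_class$recall))
  expect_equal(m2$macro$f1, mean(m2$per_class$f1))
  expect_equal(m2$per_class$prevalence, unname(rowSums(cm2)))
})

test_that("metrics are equivariant under class permutation", {
  cm <- matrix(c(30, 5, 1, 2, 40, 3, 4, 6, 50), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  perm <- c(3, 1, 2)
  m1 <- classification_metrics(cm)
  m2 <- classification_metrics(cm[perm, perm])
  expect_equal(m2$per_class$f1[order(m2$per_class$class)],
               m1$per_class$f1[order(m1$per_class$class)])
  expect_equal(m2$macro$f1, m1$macro$f1)
})

test_that("a class absent from the truth is flagged with zero recall", {
  cm <- matrix(c(10, 0, 3, 0), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  m <- classification_metrics(cm)
  expect_true(m$per_class$undefined_recall[m$per_class$class == "b"])
  expect_equal(m$per_class$recall[m$per_class$class == "b"], 0)
  expect_error(classification_metrics(matrix(0, 2, 2)), "empty")
})
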