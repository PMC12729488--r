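# Chronological splitting, Random-Forest training/tuning, per-second
# prediction and multiclass evaluation.

#' Chronologically stratified train/validation/test split
#'
#' Within each (behaviour, individual) stratum, windows are ordered by time
#' and cut into the first `fractions[1]`, middle `fractions[2]` and
#' remaining `fractions[3]`, so no behavioural sequence spans two sets.
#' Strata with fewer than 5 labelled windows go wholly to training with a
#' warning. Unlabelled (impure) windows are dropped.
#'
#' @param windows feature table with columns label, individual, start_s
#' @param fractions train/validation/test fractions summing to 1
#' @return the table with an added `split` column
#'   ("train"/"validation"/"test"), unlabelled windows removed
#' @export
chronological_split <- function(windows, fractions = c(0.6, 0.2, 0.2)) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9)
  w <- windows[!is.na(windows$label), ]
  w <- w[order(w$individual, w$label, w$start_s), ]
  sp <- character(nrow(w))
  n_small <- 0L
  for (idx in split(seq_len(nrow(w)), list(w$individual, w$label),
                    drop = TRUE)) {
    n <- length(idx)
    if (n < 5) {
      sp[idx] <- "train"
      n_small <- n_small + 1L
      next
    }
    n_tr <- floor(fractions[1] * n)
    n_va <- floor(fractions[2] * n)
    sp[idx] <- rep(c("train", "validation", "test"),
                   c(n_tr, n_va, n - n_tr - n_va))
  }
  w$split <- sp
  if (n_small > 0) {
    warning(n_small,
            " stratum/strata with < 5 windows placed wholly in training")
  }
  w
}

feature_matrix <- function(windows) {
  as.matrix(windows[, setdiff(names(windows),
                              c(feature_id_cols(), "split"))])
}

#' Train a Random Forest on labelled feature windows
#'
#' @param train feature table of training windows (labelled)
#' @param config list with number_trees, mtry, max_depth, seed
#' @return object of class `koala_forest`
#' @export
train_forest <- function(train, config) {
  x <- feature_matrix(train)
  stopifnot(config$mtry <= ncol(x))
  fit <- ranger::ranger(
    x = x, y = factor(train$label),
    num.trees = config$number_trees,
    mtry = config$mtry,
    max.depth = config$max_depth,
    seed = config$seed %||% 1L,
    num.threads = 1
  )
  structure(
    list(fit = fit, feature_names = colnames(x),
         classes = levels(factor(train$label)), config = config),
    class = "koala_forest"
  )
}

#' Predict behaviour labels for feature windows
#'
#' @param model a `koala_forest`
#' @param windows feature table
#' @return character vector of predicted labels, one per window
#' @export
predict_windows <- function(model, windows) {
  x <- feature_matrix(windows)
  missing <- setdiff(model$feature_names, colnames(x))
  extra <- setdiff(colnames(x), model$feature_names)
  if (length(missing) > 0 || length(extra) > 0) {
    stop("feature names do not match training: missing [",
         paste(missing, collapse = ","), "] unseen [",
         paste(extra, collapse = ","), "]")
  }
  x <- x[, model$feature_names, drop = FALSE]
  as.character(predict(model$fit, data = x, num.threads = 1)$predictions)
}

#' Predict one behaviour label per clock second
#'
#' With 50%-overlap windows, each second's label is the prediction of the
#' window starting at that second; off-grid windows are used for training
#' only.
#'
#' @param model a `koala_forest`
#' @param windows feature table covering the stream to score
#' @return tibble with columns second, label
#' @export
predict_seconds <- function(model, windows) {
  on_grid <- abs(windows$start_s - round(windows$start_s)) < 1e-9
  w <- windows[on_grid, ]
  tibble::tibble(
    second = as.integer(round(w$start_s)),
    label = predict_windows(model, w)
  )
}

#' Default hyperparameter search ranges
#'
#' @param p number of features
#' @return list of ranges: number_trees, mtry, max_depth
#' @export
default_search_ranges <- function(p) {
  list(
    number_trees = c(100L, 1000L),
    mtry = c(max(1L, ceiling(sqrt(p) / 2)), max(1L, floor(p / 2))),
    max_depth = c(4L, 32L)
  )
}

#' Tune Random-Forest hyperparameters on validation macro-F1
#'
#' Seed-deterministic search over number_trees, mtry and max_depth,
#' maximising the macro-averaged F1 score on the validation set. Search
#' method is pluggable: "random" draws `budget` uniform configurations,
#' "grid" evaluates a regular grid of about `budget` points.
#'
#' @param train,validation disjoint labelled feature tables
#' @param budget number of configurations to evaluate
#' @param seed integer seed for the search and forest fits
#' @param ranges list of ranges as in [default_search_ranges()]
#' @param method "random" or "grid"
#' @return the best configuration, with `macro_f1` attached
#' @export
tune_forest <- function(train, validation, budget = 10, seed = 1L,
                        ranges = NULL, method = c("random", "grid")) {
  method <- match.arg(method)
  if (nrow(validation) == 0) stop("empty validation set")
  p <- ncol(feature_matrix(train))
  ranges <- ranges %||% default_search_ranges(p)
  set.seed(seed)
  grid_axis <- function(r, k) unique(round(seq(r[1], r[2], length.out = k)))
  configs <- if (method == "grid") {
    k <- max(2L, ceiling(budget^(1 / 3)))
    g <- expand.grid(
      number_trees = grid_axis(ranges$number_trees, k),
      mtry = grid_axis(ranges$mtry, k),
      max_depth = grid_axis(ranges$max_depth, k)
    )
    g[seq_len(min(nrow(g), max(budget, 1L))), , drop = FALSE]
  } else {
    data.frame(
      number_trees = round(runif(budget, ranges$number_trees[1],
                                 ranges$number_trees[2])),
      mtry = round(runif(budget, ranges$mtry[1], ranges$mtry[2])),
      max_depth = round(runif(budget, ranges$max_depth[1],
                              ranges$max_depth[2]))
    )
  }
  scores <- numeric(nrow(configs))
  for (i in seq_len(nrow(configs))) {
    cfg <- list(number_trees = configs$number_trees[i],
                mtry = min(configs$mtry[i], p),
                max_depth = configs$max_depth[i],
                seed = seed)
    model <- train_forest(train, cfg)
    pred <- predict_windows(model, validation)
    cm <- confusion_matrix(validation$label, pred)
    scores[i] <- classification_metrics(cm)$macro$f1
  }
  best <- which.max(scores)
  out <- list(number_trees = configs$number_trees[best],
              mtry = min(configs$mtry[best], p),
              max_depth = configs$max_depth[best],
              seed = seed)
  attr(out, "macro_f1") <- scores[best]
  attr(out, "evaluated") <- cbind(configs, macro_f1 = scores)
  out
}

#' Confusion matrix (rows = truth, columns = predicted)
#'
#' @param truth,pred character vectors of equal length
#' @param classes optional ordered label set; defaults to the union
#' @return square matrix of counts
#' @export
confusion_matrix <- function(truth, pred, classes = NULL) {
  classes <- classes %||% sort(unique(c(truth, pred)))
  table(factor(truth, classes), factor(pred, classes))
}

#' Per-class and macro classification metrics from a confusion matrix
#'
#' Precision = TP/(TP+FP), recall = TP/(TP+FN), F1 = harmonic mean of the
#' two (0 when both are 0), balanced accuracy = (recall + specificity)/2.
#' Macro values are unweighted means over classes. A class absent from the
#' truth has undefined recall, reported as 0 and flagged.
#'
#' @param cm confusion matrix from [confusion_matrix()]
#' @return list with `per_class` (tibble: class, precision, recall, f1,
#'   balanced_accuracy, prevalence, undefined_recall) and `macro` (named
#'   list of the four macro metrics)
#' @export
classification_metrics <- function(cm) {
  cm <- as.matrix(cm)
  if (sum(cm) == 0) stop("empty confusion matrix")
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- sum(cm) - tp - fp - fn
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  specificity <- ifelse(tn + fp > 0, tn / (tn + fp), 0)
  bal_acc <- (recall + specificity) / 2
  per_class <- tibble::tibble(
    class = rownames(cm),
    precision = unname(precision),
    recall = unname(recall),
    f1 = unname(f1),
    balanced_accuracy = unname(bal_acc),
    prevalence = unname(rowSums(cm)),
    undefined_recall = unname(rowSums(cm) == 0)
  )
  list(
    per_class = per_class,
    macro = list(
      precision = mean(precision),
      recall = mean(recall),
      f1 = mean(f1),
      balanced_accuracy = mean(bal_acc)
    )
  )
}

#' Render metrics as a report table (per-class rows + macro row)
#'
#' @param metrics output of [classification_metrics()]
#' @return tibble with columns Behaviour, Precision, Recall, F1, Accuracy,
#'   Prevalence
#' @export
metrics_table <- function(metrics) {
  pc <- metrics$per_class
  dplyr::bind_rows(
    tibble::tibble(
      Behaviour = paste("Class:", pc$class),
      Precision = pc$precision, Recall = pc$recall, F1 = pc$f1,
      Accuracy = pc$balanced_accuracy, Prevalence = pc$prevalence
    ),
    tibble::tibble(
      Behaviour = "Macro-average",
      Precision = metrics$macro$precision, Recall = metrics$macro$recall,
      F1 = metrics$macro$f1, Accuracy = metrics$macro$balanced_accuracy,
      Prevalence = NA_real_
    )
  )
}
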