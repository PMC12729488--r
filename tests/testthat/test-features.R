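test_that("window counts follow the 50%-overlap arithmetic", {
  expect_equal(nrow(segment(constant_stream(secs = 10))), 19)  # (10-1)/0.5+1
  expect_equal(nrow(segment(constant_stream(secs = 1))), 1)
  st <- constant_stream(secs = 1)
  st$data <- st$data[1:25, ]  # half a second
  expect_warning(w <- segment(st), "shorter")
  expect_equal(nrow(w), 0)
})

test_that("mixed-behaviour windows below the purity threshold are dropped", {
  st <- constant_stream(secs = 2)
  st$data$label <- rep(c("A", "B"), c(60, 40))
  w <- segment(st, purity = 0.7)
  # window 2 spans samples 26..75: 35 A + 15 B = 70% A, kept at threshold
  expect_identical(w$label[1], "A")
  expect_identical(w$label[2], "A")
  # window at 0.5 s with purity below 0.7 is unlabelled
  st$data$label <- rep(c("A", "B"), c(55, 45))
  w2 <- segment(st, purity = 0.7)
  expect_true(is.na(w2$label[2]))
})

test_that("static + dynamic reconstructs the raw signal exactly", {
  st <- tiny_stream(seed = 6, hours = 0.01)
  sd_ <- static_dynamic_split(st)
  raw <- as.matrix(st$data[, c("ax", "ay", "az")])
  expect_equal(sd_$static + sd_$dynamic, raw, ignore_attr = TRUE)
  # constant stream: dynamic identically zero
  cs <- constant_stream(secs = 10)
  expect_equal(max(abs(static_dynamic_split(cs)$dynamic)), 0)
})

test_that("2 s boxcar smoothing passes a 2 Hz sinusoid almost untouched", {
  fs <- 50
  t <- (0:(20 * fs - 1)) / fs
  a <- 1.7
  st <- labelled_stream(
    tibble::tibble(t = t, ax = a * sin(2 * pi * 2 * t), ay = 0, az = 9.81),
    sample_rate = fs
  )
  dyn <- static_dynamic_split(st, smooth_s = 2)$dynamic[, "ax"]
  mid <- dyn[(2 * fs):(18 * fs)]  # ignore shrunken-window edges
  expect_lt(abs(max(mid) - a) / a, 0.05)
})

test_that("vedba computes the Euclidean norm with guarded inputs", {
  expect_equal(vedba(c(0, 0, 0)), 0)
  expect_equal(vedba(c(3, 4, 0)), 5)
  expect_error(vedba(c(1, NA, 0)), "non-finite")
  m <- matrix(c(1, 2, 2, 0, 3, 4), ncol = 3, byrow = TRUE)
  expect_equal(vedba(m), c(3, 5))
})

test_that("ODBA dominates VeDBA at every sample and both are non-negative", {
  st <- tiny_stream(seed = 9, hours = 0.02)
  d <- static_dynamic_split(st)$dynamic
  v <- vedba(d)
  o <- odba(d)
  expect_true(all(v >= 0))
  expect_true(all(o >= v - 1e-12))
})

test_that("per-second VeDBA summaries satisfy min <= max and ordering", {
  st <- tiny_stream(seed = 10, hours = 0.05)
  vs <- vedba_seconds(st)
  expect_true(all(vs$vedba_min <= vs$vedba_max))
  expect_true(all(vs$vedba_min >= 0))

  # still seconds nearly always fall below walking seconds
  cfg <- sim_config(seed = 15, sway_noise_sd = 0)
  mk <- function(behaviour) {
    seq <- tibble::tibble(behaviour = behaviour, start_s = 0,
                          duration_s = 100)
    attr(seq, "total_s") <- 100
    vedba_seconds(synthesize_axes(seq, cfg, 1))$vedba_max
  }
  still <- mk("Still")
  walking <- mk("Walking")
  expect_gte(mean(walking > still), 0.99)
})

test_that("VeDBA is invariant to a static re-orientation of the collar", {
  st <- tiny_stream(seed = 12, hours = 0.02)
  theta <- 0.7
  R <- matrix(c(cos(theta), -sin(theta), 0,
                sin(theta), cos(theta), 0,
                0, 0, 1), 3, 3, byrow = TRUE)
  rot <- st
  acc <- as.matrix(st$data[, c("ax", "ay", "az")]) %*% t(R)
  rot$data$ax <- acc[, 1]; rot$data$ay <- acc[, 2]; rot$data$az <- acc[, 3]
  expect_equal(vedba_seconds(rot)$vedba_max, vedba_seconds(st)$vedba_max,
               tolerance = 1e-10)
})

test_that("degenerate constant windows map to the defined sentinels", {
  v <- extract_features(matrix(5, nrow = 50, ncol = 3,
                               dimnames = list(NULL, c("ax", "ay", "az"))))
  expect_equal(v[["ax_sd"]], 0)
  expect_equal(v[["ax_skew"]], 0)
  expect_equal(v[["ax_kurt"]], 0)
  expect_equal(v[["ax_spec_entropy"]], 0)
  expect_equal(v[["corr_ax_ay"]], 0)
  expect_true(all(is.finite(v)))
})

test_that("dominant frequency recovers a planted 5 Hz sine", {
  t <- (0:49) / 50
  m <- cbind(ax = sin(2 * pi * 5 * t), ay = 0, az = 0)
  v <- extract_features(m, sample_rate = 50)
  expect_equal(v[["ax_dom_freq"]], 5)
})

test_that("feature extraction is pure and order-independent", {
  st <- tiny_stream(seed = 14, hours = 0.01)
  a <- extract_feature_table(st)
  b <- extract_feature_table(st)
  expect_identical(a, b)
  # the same window through the single-window path gives the same vector
  w <- as.matrix(st$data[1:50, c("ax", "ay", "az")])
  v1 <- extract_features(w)
  v2 <- extract_features(w)
  expect_identical(v1, v2)
})

test_that("feature tables are finite with stable names across streams", {
  f1 <- extract_feature_table(tiny_stream(seed = 16, hours = 0.01))
  f2 <- extract_feature_table(tiny_stream(seed = 17, hours = 0.01))
  expect_identical(names(f1), names(f2))
  feat_cols <- setdiff(names(f1), c("window", "start_s", "label", "purity",
                                    "individual"))
  expect_true(all(vapply(f1[feat_cols], function(x) all(is.finite(x)),
                         logical(1))))
  expect_gte(length(feat_cols), 40)
})
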