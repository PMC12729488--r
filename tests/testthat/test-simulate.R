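test_that("fixed seed reproduces sequences and streams bit-identically", {
  cfg <- sim_config(seed = 42, days_per_individual = 0.5, n_individuals = 2)
  s1 <- simulate_behaviour_sequence(cfg, 1)
  s2 <- simulate_behaviour_sequence(cfg, 1)
  expect_identical(s1, s2)
  st1 <- synthesize_axes(s1, cfg, 1)
  st2 <- synthesize_axes(s2, cfg, 1)
  expect_identical(st1$data, st2$data)
  # different individuals get different realisations
  expect_false(identical(
    s1$behaviour, simulate_behaviour_sequence(cfg, 2)$behaviour
  ))
})

test_that("sequences are contiguous, non-overlapping and cover the period", {
  cfg <- sim_config(seed = 7, days_per_individual = 1)
  s <- simulate_behaviour_sequence(cfg, 3)
  expect_equal(s$start_s[1], 0)
  expect_equal(s$start_s[-1], (s$start_s + s$duration_s)[-nrow(s)])
  expect_equal(sum(s$duration_s), 86400)
  expect_true(all(s$duration_s > 0))
})

test_that("zero-duration simulation and zero visit rate degenerate cleanly", {
  cfg0 <- sim_config(seed = 1, days_per_individual = 0)
  expect_warning(s <- simulate_behaviour_sequence(cfg0, 1), "zero-duration")
  expect_equal(nrow(s), 0)

  cfg_nv <- sim_config(seed = 1, days_per_individual = 2, visit_rate = 0,
                       daily_walk_minutes = NULL)
  s <- simulate_behaviour_sequence(cfg_nv, 1)
  expect_false("Walking" %in% s$behaviour)
})

test_that("empirical visit rate matches the configured rate (Monte Carlo)", {
  cfg <- sim_config(seed = 77, visit_rate = 2.95,
                    visit_walk_minutes = 1.59, daily_walk_minutes = NULL,
                    n_individuals = 1)
  prof <- individual_profile(cfg)
  n_days <- 10000
  set.seed(1234)
  v <- koalawalk:::simulate_visits(cfg, prof[1, ], n_days * 86400)
  rate <- nrow(v) / n_days
  se <- sqrt(2.95 / n_days)
  expect_lt(abs(rate - 2.95), 2 * se + 0.01)
  # mean walking duration near the configured per-visit mean
  expect_lt(abs(mean(v$duration_s) / 60 - 1.59), 0.1)
})

test_that("long-run behaviour time shares converge to configured budgets", {
  cfg <- sim_config(seed = 13, days_per_individual = 100, n_individuals = 1,
                    visit_rate = 0, daily_walk_minutes = NULL)
  s <- simulate_behaviour_sequence(cfg, 1)
  shares <- tapply(s$duration_s, s$behaviour, sum) / sum(s$duration_s)
  targets <- vapply(cfg$behaviour_specs, `[[`, numeric(1), "share")
  for (b in c("Still", "In-tree Movement", "Climbing", "Feeding",
              "Grooming")) {
    expect_lt(abs(shares[[b]] - targets[[b]]) / targets[[b]], 0.05,
              label = paste("relative share error for", b))
  }
  # the trace behaviour is present at roughly its configured order of
  # magnitude
  expect_lt(abs(shares[["Bellowing"]] / targets[["Bellowing"]] - 1), 1)
})

test_that("walking concentrates inside the configured diel window", {
  cfg <- sim_config(seed = 21, days_per_individual = 20, n_individuals = 1,
                    visit_rate = 5, visit_walk_minutes = 1.5,
                    daily_walk_minutes = NULL)
  s <- simulate_behaviour_sequence(cfg, 1)
  walk <- s[s$behaviour == "Walking", ]
  hr <- hour_of_day(walk$start_s + walk$duration_s / 2)
  in_window <- hr >= 2 & hr < 5
  frac <- sum(walk$duration_s[in_window]) / sum(walk$duration_s)
  expect_gt(frac, 3 / 24)   # far above the window's share of the day
  expect_gt(frac, 0.5)
})

test_that("individual profile reconciles rate, duration and daily minutes", {
  prof <- individual_profile(sim_config(seed = 1))
  expect_equal(mean(prof$visit_rate), 2.95, tolerance = 1e-6)
  expect_equal(mean(prof$visit_minutes), 1.59, tolerance = 1e-6)
  expect_equal(prof$visit_rate * prof$visit_minutes, rep(3, 9),
               tolerance = 1e-6)
  # homogeneous when daily minutes equal rate x duration
  prof0 <- individual_profile(sim_config(seed = 1, visit_rate = 2,
                                         visit_walk_minutes = 1.5,
                                         daily_walk_minutes = NULL))
  expect_equal(prof0$visit_rate, rep(2, 9))
})

test_that("still behaviour without sway gives near-zero VeDBA", {
  specs <- default_behaviour_specs()
  seq <- tibble::tibble(behaviour = "Still", start_s = 0, duration_s = 120)
  attr(seq, "total_s") <- 120
  cfg <- sim_config(seed = 2, sway_noise_sd = 0)
  st <- synthesize_axes(seq, cfg, 1)
  v <- vedba_seconds(st)
  expect_lt(mean(c(v$vedba_max, v$vedba_min)), 0.05)
})

test_that("walking heave axis peaks at the configured dominant frequency", {
  cfg <- sim_config(seed = 8)
  seq <- tibble::tibble(behaviour = "Walking", start_s = 0, duration_s = 40)
  attr(seq, "total_s") <- 40
  st <- synthesize_axes(seq, cfg, 1)
  x <- st$data$ax - mean(st$data$ax)
  spec_est <- Mod(stats::fft(x))[2:(length(x) %/% 2)]
  f_peak <- which.max(spec_est) / (length(x) / 50)
  expect_lt(abs(f_peak - cfg$behaviour_specs$Walking$dom_freq), 0.2 + 1e-9)
})

test_that("mean VeDBA orders walking > feeding > still under defaults", {
  cfg <- sim_config(seed = 31, sway_noise_sd = 0.05)
  mean_vedba <- function(behaviour) {
    seq <- tibble::tibble(behaviour = behaviour, start_s = 0,
                          duration_s = 300)
    attr(seq, "total_s") <- 300
    st <- synthesize_axes(seq, cfg, 1)
    mean(vedba(static_dynamic_split(st)$dynamic))
  }
  v <- vapply(c("Walking", "Feeding", "Still"), mean_vedba, numeric(1))
  expect_gt(v[["Walking"]], v[["Feeding"]])
  expect_gt(v[["Feeding"]], v[["Still"]])
})

test_that("unknown behaviour names are rejected at synthesis", {
  cfg <- sim_config(seed = 1)
  seq <- tibble::tibble(behaviour = "Flying", start_s = 0, duration_s = 10)
  attr(seq, "total_s") <- 10
  expect_error(synthesize_axes(seq, cfg, 1), "unknown behaviour")
})

test_that("injected taps round-trip through detection within 0.2 s", {
  st <- constant_stream(secs = 60)
  events <- c(12.5, 43)
  tapped <- inject_taps(st, events)
  found <- detect_taps(tapped)
  expect_length(found, 2)
  expect_lt(max(abs(sort(found) - sort(events))), 0.2)
  # labels untouched and empty event list is the identity
  expect_identical(tapped$data$label, st$data$label)
  expect_identical(inject_taps(st, numeric(0)), st)
})

test_that("taps too close to the stream edge are rejected", {
  st <- constant_stream(secs = 10)
  expect_error(inject_taps(st, 0.1), "edge")
  expect_error(inject_taps(st, 9.95), "edge")
})
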