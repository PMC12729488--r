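# Synthetic collar-stream generator.
#
# Behaviour sequences are semi-Markov: bouts have explicit gamma dwell-time
# distributions and the probability of entering a behaviour is modulated
# over the 24 h cycle, so diel peaks and bout-length structure are both
# controllable. Ground visits (Walking) are overlaid as a time-inhomogeneous
# visit process concentrated in the configured pre-dawn window.

DAY_S <- 86400

# Entry weights u_b such that the realised time share of each behaviour,
# averaged over the day, matches its configured share despite diel
# modulation. Fixed-point iteration on u_b <- u_b * target_b / achieved_b.
calibrated_weights <- function(specs) {
  specs <- specs[vapply(specs, function(s) s$name != "Walking", logical(1))]
  share <- vapply(specs, `[[`, numeric(1), "share")
  share <- share / sum(share)
  peak <- vapply(specs, `[[`, numeric(1), "diel_peak")
  amp <- vapply(specs, `[[`, numeric(1), "diel_amp")
  h <- seq(0, 23.75, by = 0.25)
  m <- sapply(seq_along(specs), function(j) {
    if (is.na(peak[j]) || amp[j] == 0) rep(1, length(h))
    else 1 + amp[j] * cos(2 * pi * (h - peak[j]) / 24)
  })
  u <- share
  for (it in 1:300) {
    w <- sweep(m, 2, u, `*`)
    achieved <- colMeans(w / rowSums(w))
    u <- u * share / pmax(achieved, 1e-12)
    u <- u / sum(u)
  }
  list(u = u, m = m, h = h, specs = specs)
}

# entry probabilities at hour `hr` (time share ~ p * dwell mean)
entry_probs <- function(cal, hr) {
  mu <- vapply(cal$specs, `[[`, numeric(1), "dwell_mean_s")
  j <- findInterval(hr %% 24, cal$h)
  mod <- cal$m[j, ]
  p <- cal$u * mod / mu
  p / sum(p)
}

#' Simulate a behaviour bout sequence for one individual
#'
#' Generates contiguous non-overlapping behaviour intervals covering
#' `days_per_individual` days. In-tree behaviours follow the semi-Markov
#' process defined by the behaviour specifications; Walking is then overlaid
#' as ground visits drawn from an inhomogeneous daily visit process with the
#' individual's visit rate and mean per-visit duration (see
#' [individual_profile()]).
#'
#' @param config a [sim_config()]
#' @param individual integer index of the individual (1-based)
#' @return tibble with columns behaviour, start_s, duration_s; attributes
#'   `individual`, `profile` (the animal's profile row), `total_s`
#' @export
simulate_behaviour_sequence <- function(config, individual = 1L) {
  stopifnot(inherits(config, "sim_config"))
  total_s <- config$days_per_individual * DAY_S
  profile <- individual_profile(config)[individual, ]
  if (total_s <= 0) {
    warning("zero-duration simulation; returning empty sequence")
    out <- tibble::tibble(behaviour = character(), start_s = numeric(),
                          duration_s = numeric())
    attr(out, "individual") <- profile$individual
    attr(out, "profile") <- profile
    attr(out, "total_s") <- 0
    return(out)
  }
  set.seed(child_seed(config$seed, 1000L + individual))

  cal <- calibrated_weights(config$behaviour_specs)
  mu <- vapply(cal$specs, `[[`, numeric(1), "dwell_mean_s")
  shp <- vapply(cal$specs, `[[`, numeric(1), "dwell_shape")
  nm <- unname(vapply(cal$specs, `[[`, character(1), "name"))

  # base in-tree sequence
  t <- 0
  beh <- character(0); st <- numeric(0); dur <- numeric(0)
  while (t < total_s) {
    p <- entry_probs(cal, hour_of_day(t))
    j <- sample.int(length(p), 1L, prob = p)
    d <- rgamma(1, shape = shp[j], scale = mu[j] / shp[j])
    d <- max(d, 1)
    d <- min(d, total_s - t)
    beh <- c(beh, nm[j]); st <- c(st, t); dur <- c(dur, d)
    t <- t + d
  }

  # ground-visit overlay
  visits <- simulate_visits(config, profile, total_s)
  out <- overlay_walking(
    tibble::tibble(behaviour = beh, start_s = st, duration_s = dur),
    visits, total_s
  )
  attr(out, "individual") <- profile$individual
  attr(out, "profile") <- profile
  attr(out, "total_s") <- total_s
  out
}

# Draw ground visits (start_s, duration_s) for one individual.
# Daily counts are Poisson at the individual's rate; start hours follow the
# configured hourly intensity; durations are lognormal with the individual's
# mean and the configured CV. Visits are kept >= 61 s apart so the visit
# count survives downstream gap clustering.
simulate_visits <- function(config, profile, total_s) {
  v_rate <- profile$visit_rate
  if (v_rate <= 0 || total_s <= 0) {
    return(tibble::tibble(start_s = numeric(), duration_s = numeric()))
  }
  n_days <- ceiling(total_s / DAY_S)
  wt <- config$walk_intensity / sum(config$walk_intensity)
  cv <- config$visit_duration_cv
  # visit walking duration = observational floor + lognormal excess, with
  # the individual's configured mean preserved
  floor_s <- config$visit_min_s
  excess_mean <- max(profile$visit_minutes * 60 - floor_s, 5)
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(excess_mean) - sdlog^2 / 2

  starts <- numeric(0); durs <- numeric(0)
  for (day in seq_len(n_days) - 1L) {
    n <- rpois(1, v_rate)
    if (n == 0) next
    hr <- sample.int(24, n, replace = TRUE, prob = wt) - 1L
    s <- day * DAY_S + hr * 3600 + runif(n) * 3600
    d <- floor_s + rlnorm(n, meanlog, sdlog)
    starts <- c(starts, s); durs <- c(durs, d)
  }
  if (length(starts) == 0) {
    return(tibble::tibble(start_s = numeric(), duration_s = numeric()))
  }
  o <- order(starts); starts <- starts[o]; durs <- durs[o]
  # enforce separation: shift a visit that would begin within 61 s of the
  # previous visit's end
  for (i in seq_along(starts)[-1]) {
    min_start <- starts[i - 1] + durs[i - 1] + 61
    if (starts[i] < min_start) starts[i] <- min_start
  }
  keep <- starts + durs <= total_s
  tibble::tibble(start_s = starts[keep], duration_s = durs[keep])
}

# Paint walking visits over a base sequence, splitting base bouts at visit
# boundaries and merging adjacent identical labels.
overlay_walking <- function(base, visits, total_s) {
  if (nrow(visits) == 0) return(base)
  cuts <- sort(unique(c(
    base$start_s, visits$start_s, visits$start_s + visits$duration_s, total_s
  )))
  cuts <- cuts[cuts >= 0 & cuts <= total_s]
  seg_start <- cuts[-length(cuts)]
  seg_end <- cuts[-1]
  keep <- seg_end > seg_start
  seg_start <- seg_start[keep]; seg_end <- seg_end[keep]
  mid <- (seg_start + seg_end) / 2
  base_lab <- base$behaviour[findInterval(mid, base$start_s)]
  in_visit <- findInterval(mid, visits$start_s)
  walking <- in_visit >= 1 &
    mid < (visits$start_s + visits$duration_s)[pmax(in_visit, 1L)]
  lab <- ifelse(walking, "Walking", base_lab)
  # merge runs of identical labels
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts_idx <- c(1L, utils::head(ends, -1L) + 1L)
  tibble::tibble(
    behaviour = r$values,
    start_s = seg_start[starts_idx],
    duration_s = seg_end[ends] - seg_start[starts_idx]
  )
}

#' Per-second ground-truth labels from a bout sequence
#'
#' @param sequence output of [simulate_behaviour_sequence()]
#' @return tibble with columns second (0-based integer) and label (label at
#'   the centre of each second)
#' @export
sequence_to_seconds <- function(sequence) {
  total_s <- attr(sequence, "total_s")
  if (is.null(total_s)) {
    total_s <- max(sequence$start_s + sequence$duration_s)
  }
  sec <- seq_len(floor(total_s)) - 1L
  lab <- sequence$behaviour[findInterval(sec + 0.5, sequence$start_s)]
  tibble::tibble(second = sec, label = lab)
}

#' Synthesize tri-axial acceleration for a behaviour sequence
#'
#' Each sample is the gravity projection of the behaviour's static
#' orientation plus a behaviour-specific dynamic component: periodic
#' oscillation at the dominant frequency for walking, near-zero noise when
#' still, intermittent one-second bursts for feeding/grooming, and large
#' low-frequency excursions for climbing. Optional slow (< 0.5 Hz) canopy
#' sway is added to all non-walking samples. Values are clipped to the
#' +/- 4 g logger range.
#'
#' @param sequence output of [simulate_behaviour_sequence()]
#' @param config a [sim_config()]
#' @param individual integer index (seeds the signal noise independently of
#'   the sequence)
#' @return a `labelled_stream`
#' @export
synthesize_axes <- function(sequence, config, individual = 1L) {
  stopifnot(inherits(config, "sim_config"))
  unknown <- setdiff(unique(sequence$behaviour),
                     names(config$behaviour_specs))
  if (length(unknown) > 0) {
    stop("unknown behaviour name(s) in sequence: ",
         paste(unknown, collapse = ", "))
  }
  fs <- config$sample_rate
  total_s <- attr(sequence, "total_s") %||%
    max(sequence$start_s + sequence$duration_s)
  n <- round(total_s * fs)
  t <- (seq_len(n) - 1L) / fs
  set.seed(child_seed(config$seed, 2000L + individual))

  ax <- numeric(n); ay <- numeric(n); az <- numeric(n)
  lab <- sequence$behaviour[findInterval(t + 1e-9, sequence$start_s)]

  for (i in seq_len(nrow(sequence))) {
    spec <- config$behaviour_specs[[sequence$behaviour[i]]]
    i0 <- floor(sequence$start_s[i] * fs) + 1L
    i1 <- min(n, ceiling((sequence$start_s[i] + sequence$duration_s[i]) * fs))
    if (i1 < i0) next
    idx <- i0:i1
    m <- length(idx)
    tt <- t[idx]
    phase <- runif(1) * 2 * pi
    # bout-to-bout variation in posture, vigour and tempo
    ori <- spec$orientation + rnorm(3, 0, 0.08)
    ori <- ori / sqrt(sum(ori^2))
    A <- spec$dyn_amp * exp(rnorm(1, 0, 0.25))
    freq <- spec$dom_freq * runif(1, 0.9, 1.1)
    # one-second burst gating
    nblock <- ceiling(m / fs)
    active <- rep(runif(nblock) < spec$burstiness, each = fs)[seq_len(m)]
    gate <- ifelse(active, 1, 0.08)
    carrier <- sin(2 * pi * freq * tt + phase)
    noise_sd <- 0.15 * A + 0.01
    ax[idx] <- GRAVITY * ori[1] +
      gate * (A * carrier + rnorm(m, 0, noise_sd))
    ay[idx] <- GRAVITY * ori[2] +
      gate * (0.6 * A * sin(2 * pi * freq * tt + phase + 1.3) +
                rnorm(m, 0, noise_sd))
    az[idx] <- GRAVITY * ori[3] +
      gate * (0.4 * A * sin(2 * pi * freq * tt + phase + 2.1) +
                rnorm(m, 0, noise_sd))
  }

  if (config$sway_noise_sd > 0) {
    sway_phase <- runif(1) * 2 * pi
    sway <- config$sway_noise_sd * sin(2 * pi * 0.2 * t + sway_phase)
    tree <- lab != "Walking"
    ay[tree] <- ay[tree] + sway[tree]
    az[tree] <- az[tree] + 0.7 * sway[tree]
  }

  lim <- 4 * GRAVITY
  profile <- attr(sequence, "profile")
  labelled_stream(
    tibble::tibble(
      t = t,
      ax = pmin(pmax(ax, -lim), lim),
      ay = pmin(pmax(ay, -lim), lim),
      az = pmin(pmax(az, -lim), lim),
      label = lab
    ),
    sample_rate = fs,
    individual_id = if (!is.null(profile)) profile$individual
                    else sprintf("koala%02d", individual),
    sex = if (!is.null(profile)) profile$sex else NA_character_,
    habitat = if (!is.null(profile)) profile$habitat else NA_character_,
    mass_kg = if (!is.null(profile)) profile$mass_kg else NA_real_
  )
}

#' Simulate one individual's labelled stream (sequence + signal)
#'
#' @inheritParams simulate_behaviour_sequence
#' @return a `labelled_stream`
#' @export
simulate_stream <- function(config, individual = 1L) {
  seq <- simulate_behaviour_sequence(config, individual)
  synthesize_axes(seq, config, individual)
}

#' Superimpose collar-tap calibration events on a stream
#'
#' Each event adds five high-amplitude (>= 3 g) spikes 0.1 s apart to the
#' heave axis, emulating the collar taps used to align video and collar
#' clocks. Labels are unchanged.
#'
#' @param stream a `labelled_stream`
#' @param event_times numeric vector of event centre times (s)
#' @param n_spikes spikes per event
#' @param spacing_s spacing between spikes
#' @param amplitude_g spike amplitude in g added to the heave axis
#' @return the modified `labelled_stream`
#' @export
inject_taps <- function(stream, event_times, n_spikes = 5,
                        spacing_s = 0.1, amplitude_g = 3.6) {
  stopifnot(inherits(stream, "labelled_stream"))
  if (length(event_times) == 0) return(stream)
  fs <- stream$meta$sample_rate
  n <- nrow(stream$data)
  span <- (n_spikes - 1) * spacing_s
  edge <- span / 2 + 0.5
  if (any(event_times < edge | event_times > n / fs - edge)) {
    stop("tap event too close to stream edge")
  }
  lim <- 4 * GRAVITY
  for (e in event_times) {
    times <- e - span / 2 + (seq_len(n_spikes) - 1) * spacing_s
    idx <- round(times * fs) + 1L
    stream$data$ax[idx] <- pmin(
      stream$data$ax[idx] + amplitude_g * GRAVITY, lim
    )
  }
  stream
}
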