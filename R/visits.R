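# Ground-visit detection, daily behavioural budgets and peak hours.

#' Cluster Walking bins into Ground Visits
#'
#' Consecutive Walking-labelled 20 s bins whose inter-bin gaps are at most
#' `max_gap_s` form one Ground Visit; a larger gap starts a new visit.
#' Visit start/end are the first/last Walking bin boundaries.
#'
#' @param bins behaviour-bin tibble (one or more individuals)
#' @param max_gap_s maximum within-visit gap between Walking bins, seconds
#' @param bin_s bin length, seconds
#' @return tibble: individual, start_s, end_s, n_bins, walking_minutes
#' @export
detect_visits <- function(bins, max_gap_s = 60, bin_s = 20) {
  walk <- bins[!is.na(bins$label) & bins$label == "Walking", ]
  if (nrow(walk) == 0) {
    return(tibble::tibble(individual = character(), start_s = numeric(),
                          end_s = numeric(), n_bins = integer(),
                          walking_minutes = numeric()))
  }
  dplyr::bind_rows(lapply(split(walk, walk$individual), function(w) {
    w <- w[order(w$start_s), ]
    gap <- c(Inf, w$start_s[-1] - (w$start_s[-nrow(w)] + bin_s))
    w$visit <- cumsum(gap > max_gap_s)
    out <- dplyr::summarise(
      dplyr::group_by(w, .data$visit),
      individual = .data$individual[1],
      visit_start = min(.data$start_s),
      visit_end = max(.data$start_s) + bin_s,
      n_bins = dplyr::n(),
      walking_minutes = dplyr::n() * bin_s / 60,
      .groups = "drop"
    )
    dplyr::select(
      dplyr::rename(out, start_s = "visit_start", end_s = "visit_end"),
      -"visit"
    )
  }))
}

#' Per-visit and per-day ground-visit summaries
#'
#' @param visits output of [detect_visits()]
#' @param n_days recording days per individual (scalar or named vector by
#'   individual) used as the visits-per-day denominator
#' @return list with `per_individual` (tibble: individual, visits_per_day,
#'   mean_visit_minutes) and `population` (named list of means and SDs
#'   across individuals)
#' @export
summarise_visits <- function(visits, n_days) {
  per <- dplyr::summarise(
    dplyr::group_by(visits, .data$individual),
    n_visits = dplyr::n(),
    mean_visit_minutes = mean(.data$walking_minutes),
    .groups = "drop"
  )
  days <- if (length(n_days) == 1) rep(n_days, nrow(per)) else
    n_days[per$individual]
  per$visits_per_day <- per$n_visits / days
  list(
    per_individual = per,
    population = list(
      visits_per_day_mean = mean(per$visits_per_day),
      visits_per_day_sd = sd(per$visits_per_day),
      visit_minutes_mean = mean(per$mean_visit_minutes),
      visit_minutes_sd = sd(per$mean_visit_minutes)
    )
  )
}

#' Daily behavioural budgets rescaled to 1440 minutes
#'
#' Per (individual, day): minutes per category from 20 s bin counts,
#' proportions over recorded (non-gap) time, and minutes rescaled so each
#' day totals 1440 min. Days with less than `min_recorded_min` of recording
#' are excluded with a warning.
#'
#' @param bins behaviour-bin tibble (Other normally excluded beforehand)
#' @param bin_s bin length, seconds
#' @param min_recorded_min minimum recorded minutes for a day to count
#' @return tibble: individual, day, category, recorded_minutes, percent,
#'   minutes_1440 (percent * 14.4)
#' @export
daily_budget <- function(bins, bin_s = 20, min_recorded_min = 60) {
  b <- bins[!is.na(bins$label), ]
  b$day <- b$start_s %/% DAY_S
  rec <- dplyr::summarise(
    dplyr::group_by(b, .data$individual, .data$day),
    recorded_minutes = dplyr::n() * bin_s / 60,
    .groups = "drop"
  )
  drop <- rec[rec$recorded_minutes < min_recorded_min, ]
  if (nrow(drop) > 0) {
    warning(nrow(drop), " individual-day(s) with < ", min_recorded_min,
            " recorded min excluded")
    rec <- rec[rec$recorded_minutes >= min_recorded_min, ]
  }
  cats <- sort(unique(b$label))
  counts <- dplyr::summarise(
    dplyr::group_by(b, .data$individual, .data$day, .data$label),
    minutes = dplyr::n() * bin_s / 60,
    .groups = "drop"
  )
  out <- tidyr::complete(
    dplyr::inner_join(rec, counts, by = c("individual", "day")),
    tidyr::nesting(!!rlang::sym("individual"), !!rlang::sym("day"),
                   !!rlang::sym("recorded_minutes")),
    label = cats,
    fill = list(minutes = 0)
  )
  out$percent <- 100 * out$minutes / out$recorded_minutes
  out$minutes_1440 <- out$percent * 14.4
  dplyr::select(
    dplyr::rename(out, category = "label"),
    "individual", "day", "category", "recorded_minutes", "percent",
    "minutes_1440"
  )
}

#' Study-level budget summary (mean +/- SD across individuals)
#'
#' Percentages and rescaled minutes are first averaged within individuals
#' across days, then summarised across individuals.
#'
#' @param budget output of [daily_budget()]
#' @return tibble: category, minutes_mean, minutes_sd, percent_mean,
#'   percent_sd
#' @export
summarise_budget <- function(budget) {
  per_ind <- dplyr::summarise(
    dplyr::group_by(budget, .data$individual, .data$category),
    minutes = mean(.data$minutes_1440),
    percent = mean(.data$percent),
    .groups = "drop"
  )
  dplyr::summarise(
    dplyr::group_by(per_ind, .data$category),
    minutes_mean = mean(.data$minutes),
    minutes_sd = sd(.data$minutes),
    percent_mean = mean(.data$percent),
    percent_sd = sd(.data$percent),
    .groups = "drop"
  )
}

#' Clock hour with the maximum mean share of a behaviour category
#'
#' For each individual and clock hour, the share is the fraction of that
#' hour's labelled bins in the category; shares are averaged across
#' individuals and the hour with the maximum mean share is returned (ties
#' go to the earlier hour).
#'
#' @param bins behaviour-bin tibble covering at least 24 h
#' @param category final behaviour category
#' @return integer hour in 0..23 (start of the peak hour), or `NA` with a
#'   warning when the category is absent
#' @export
peak_hour <- function(bins, category) {
  b <- bins[!is.na(bins$label), ]
  if (!category %in% b$label) {
    warning("category absent from bins: ", category)
    return(NA_integer_)
  }
  b$hour <- floor(hour_of_day(b$start_s))
  shares <- dplyr::summarise(
    dplyr::group_by(b, .data$individual, .data$hour),
    share = mean(.data$label == category),
    .groups = "drop"
  )
  hourly <- dplyr::summarise(
    dplyr::group_by(shares, .data$hour),
    share = mean(.data$share),
    .groups = "drop"
  )
  hourly$hour[which.max(hourly$share)]
}
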