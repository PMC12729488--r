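# Reading, writing, validating and resampling collar streams.

#' Construct a labelled accelerometer stream
#'
#' @param data tibble with columns `t` (seconds, uniform spacing), `ax`,
#'   `ay`, `az` (m/s^2), optional `gx`, `gy`, `gz` (deg/s) and `label`
#' @param sample_rate sampling rate, Hz
#' @param units acceleration units of `data` ("ms2" internally)
#' @param individual_id,sex,habitat,mass_kg animal metadata
#' @param start_time ISO-8601 start timestamp of sample 0 (local clock)
#' @param gaps tibble of recording gaps (start_s, duration_s)
#' @return object of class `labelled_stream`
#' @export
labelled_stream <- function(data, sample_rate, units = "ms2",
                            individual_id = NA_character_,
                            sex = NA_character_, habitat = NA_character_,
                            mass_kg = NA_real_,
                            start_time = "2023-05-15T00:00:00+10:00",
                            gaps = NULL) {
  stopifnot(all(c("t", "ax", "ay", "az") %in% names(data)))
  if (!"label" %in% names(data)) data$label <- NA_character_
  structure(
    list(
      data = tibble::as_tibble(data),
      meta = list(
        sample_rate = sample_rate,
        units = units,
        axes = intersect(c("ax", "ay", "az", "gx", "gy", "gz"), names(data)),
        individual_id = individual_id,
        sex = sex, habitat = habitat, mass_kg = mass_kg,
        start_time = start_time,
        gaps = gaps %||% tibble::tibble(start_s = numeric(),
                                        duration_s = numeric())
      )
    ),
    class = "labelled_stream"
  )
}

#' @export
print.labelled_stream <- function(x, ...) {
  m <- x$meta
  cat(sprintf(
    "<labelled_stream> %s: %d samples @ %g Hz (%.1f h), %d gap(s)\n",
    m$individual_id, nrow(x$data), m$sample_rate,
    nrow(x$data) / m$sample_rate / 3600, nrow(m$gaps)
  ))
  invisible(x)
}

#' Duration of a stream in seconds
#' @param stream a `labelled_stream`
#' @export
stream_duration <- function(stream) {
  nrow(stream$data) / stream$meta$sample_rate
}

#' Write a labelled stream as delimited text with a JSON metadata sidecar
#'
#' @param stream a `labelled_stream`
#' @param path CSV output path; metadata goes to `<path>.json`
#' @param units output units: "ms2" or "g"
#' @return `path`, invisibly
#' @export
write_stream <- function(stream, path, units = c("ms2", "g")) {
  units <- match.arg(units)
  d <- stream$data
  if (units == "g") {
    for (a in stream$meta$axes[1:3]) d[[a]] <- d[[a]] / GRAVITY
  }
  readr::write_csv(d, path, progress = FALSE)
  meta <- stream$meta
  meta$units <- units
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' Read a collar stream from delimited text
#'
#' Validates monotone timestamps, flags (but does not fill) recording gaps,
#' converts g to m/s^2 when the declared units require it, and rejects files
#' with more than 5% missing samples over their span.
#'
#' @param path CSV file with a `t` column plus at least three numeric axis
#'   columns; a `<path>.json` sidecar supplies metadata when present
#' @param meta_overrides named list overriding sidecar/default metadata
#'   (e.g. `list(units = "g", sample_rate = 50)`)
#' @param max_missing maximum tolerated fraction of missing samples
#' @return a `labelled_stream` (units always m/s^2)
#' @export
read_stream <- function(path, meta_overrides = list(), max_missing = 0.05) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  meta <- list(sample_rate = 50, units = "ms2")
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- utils::modifyList(meta, jsonlite::read_json(sidecar,
                                                        simplifyVector = TRUE))
  }
  meta <- utils::modifyList(meta, meta_overrides)
  if (!meta$sample_rate %in% c(25, 50, 100)) {
    stop("sample_rate must be one of 25, 50, 100 Hz")
  }
  axes <- intersect(c("ax", "ay", "az", "gx", "gy", "gz"), names(d))
  if (!"t" %in% names(d) || length(axes) < 3) {
    stop("file must contain a 't' column and at least 3 axis columns")
  }
  if (any(diff(d$t) <= 0)) stop("non-monotone timestamps")

  fs <- meta$sample_rate
  dt <- diff(d$t)
  gap_idx <- which(dt > 1.5 / fs)
  gaps <- tibble::tibble(
    start_s = d$t[gap_idx],
    duration_s = dt[gap_idx] - 1 / fs
  )
  span <- d$t[nrow(d)] - d$t[1] + 1 / fs
  expected <- round(span * fs)
  missing_frac <- max(0, (expected - nrow(d)) / expected)
  if (missing_frac > max_missing) {
    stop(sprintf(
      "rejected: %.1f%% of samples missing over the file span (%d gaps)",
      100 * missing_frac, nrow(gaps)
    ))
  }
  if (identical(meta$units, "g")) {
    for (a in axes[axes %in% c("ax", "ay", "az")]) d[[a]] <- d[[a]] * GRAVITY
    meta$units <- "ms2"
  }
  gaps_tbl <- if (!is.null(meta$gaps) && length(meta$gaps) &&
                  NROW(meta$gaps$start_s)) {
    tibble::as_tibble(meta$gaps)
  } else gaps
  labelled_stream(
    d,
    sample_rate = fs, units = "ms2",
    individual_id = meta$individual_id %||% NA_character_,
    sex = meta$sex %||% NA_character_,
    habitat = meta$habitat %||% NA_character_,
    mass_kg = meta$mass_kg %||% NA_real_,
    start_time = meta$start_time %||% NA_character_,
    gaps = gaps_tbl
  )
}

#' Down-sample a stream by boxcar-mean decimation
#'
#' Anti-aliases by averaging each group of `factor` consecutive samples
#' (where `factor = source_rate / target_rate`) before decimating. Labels
#' are taken from the first sample of each group.
#'
#' @param stream a `labelled_stream`
#' @param target_rate target sampling rate, Hz; must divide the source rate
#' @return a `labelled_stream` at `target_rate`
#' @export
downsample <- function(stream, target_rate) {
  fs <- stream$meta$sample_rate
  if (target_rate > fs) stop("target rate exceeds source rate")
  factor <- fs / target_rate
  if (abs(factor - round(factor)) > 1e-9) {
    stop("target rate must divide the source rate")
  }
  factor <- as.integer(round(factor))
  if (factor == 1L) return(stream)
  n <- nrow(stream$data)
  ngroup <- n %/% factor
  idx <- seq_len(ngroup * factor)
  grp <- rep(seq_len(ngroup), each = factor)
  first <- (seq_len(ngroup) - 1L) * factor + 1L
  d <- tibble::tibble(t = stream$data$t[first])
  for (a in stream$meta$axes) {
    d[[a]] <- as.numeric(rowsum(stream$data[[a]][idx], grp)) / factor
  }
  d$label <- stream$data$label[first]
  out <- stream
  out$data <- d
  out$meta$sample_rate <- target_rate
  out
}

#' Detect collar-tap calibration events
#'
#' Finds groups of at least `min_spikes` super-threshold spikes on the
#' dynamic acceleration norm within `max_span_s`, as produced when a collar
#' is tapped repeatedly to create a clock-alignment timestamp.
#'
#' @param stream a `labelled_stream`
#' @param min_spikes minimum spikes per reported event
#' @param max_span_s maximum span of one spike group, seconds
#' @param amp_threshold_g spike threshold on the dynamic norm, in g
#' @return numeric vector of event centre times (s); empty when none
#' @export
detect_taps <- function(stream, min_spikes = 5, max_span_s = 3,
                        amp_threshold_g = 3) {
  fs <- stream$meta$sample_rate
  if (stream_duration(stream) < max_span_s) {
    stop("stream shorter than max_span_s")
  }
  sd_ <- static_dynamic_split(stream)
  vn <- sqrt(rowSums(sd_$dynamic[, c("ax", "ay", "az")]^2))
  above <- vn > amp_threshold_g * GRAVITY
  if (!any(above)) return(numeric(0))
  # one spike = one contiguous super-threshold run
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  spike_t <- (starts[r$values] + ends[r$values]) / 2 / fs
  # group spikes separated by <= 1 s
  grp <- cumsum(c(TRUE, diff(spike_t) > 1))
  events <- vapply(split(spike_t, grp), function(ts) {
    if (length(ts) >= min_spikes && diff(range(ts)) <= max_span_s) mean(ts)
    else NA_real_
  }, numeric(1))
  as.numeric(events[!is.na(events)])
}
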