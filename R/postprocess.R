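# Label smoothing, blip collapse, regrouping and 20 s binning.
#
# Converts raw per-second behaviour predictions into the smoothed,
# regrouped, binned series on which budgets, ground visits and diel models
# are computed.

#' Centred modal filter over per-second labels
#'
#' Each second is reassigned to the most frequent label of its
#' `+/- half_width` window. When two or more labels tie for the maximum
#' count, the original centre label is retained. Stream edges use shrunken
#' windows. `NA` seconds neither vote nor change.
#'
#' @param labels character vector of per-second labels (contiguous seconds)
#' @param half_width window half width, seconds (2 gives the 5 s filter)
#' @return character vector of smoothed labels
#' @export
modal_filter <- function(labels, half_width = 2) {
  n <- length(labels)
  if (n == 0) return(labels)
  f <- factor(labels)
  lv <- levels(f)
  if (length(lv) <= 1) return(labels)
  code <- as.integer(f)
  i <- seq_len(n)
  lo <- pmax(i - half_width, 1L)
  hi <- pmin(i + half_width, n)
  counts <- vapply(seq_along(lv), function(c) {
    cs <- cumsum(c(0L, !is.na(code) & code == c))
    cs[hi + 1L] - cs[lo]
  }, integer(n))
  best <- as.vector(do.call(pmax, asplit(counts, 2)))
  n_best <- rowSums(counts == best)
  winner <- lv[max.col(counts, ties.method = "first")]
  out <- ifelse(n_best > 1L, labels, winner)
  out[is.na(labels)] <- NA_character_
  out
}

#' Collapse sub-threshold label runs into their surrounding state
#'
#' Missing labels are first filled by last-observation-carried-forward
#' (leading gaps by next-observation-carried-backward). Then every maximal
#' interior run shorter than `min_run` seconds is absorbed: if the two
#' flanking states agree the run takes that state; if they disagree it takes
#' the longer flank (ties go to the preceding state). Interior runs are
#' absorbed from the left first; a short run touching a stream edge has a
#' single neighbour and is absorbed into it once no interior run remains.
#' This repeats until no run is shorter than `min_run` (a stream consisting
#' of a single short run is returned unchanged).
#'
#' @param labels character vector of per-second labels
#' @param min_run minimum surviving run length, seconds
#' @return character vector with no interior run shorter than `min_run`
#' @export
collapse_blips <- function(labels, min_run = 3) {
  if (all(is.na(labels))) stop("all labels missing")
  lab <- zoo::na.locf(labels, na.rm = FALSE)
  lab <- zoo::na.locf(lab, fromLast = TRUE, na.rm = FALSE)
  r <- rle(lab)
  vals <- r$values
  lens <- r$lengths
  repeat {
    k <- length(vals)
    if (k < 2) break
    short <- which(lens < min_run)
    if (length(short) == 0) break
    interior <- short[short > 1 & short < k]
    i <- if (length(interior) > 0) interior[1] else short[1]
    vals[i] <- if (i == 1) vals[2]
      else if (i == k) vals[k - 1]
      else if (vals[i - 1] == vals[i + 1]) vals[i - 1]
      else if (lens[i + 1] > lens[i - 1]) vals[i + 1]
      else vals[i - 1]
    if (i < k && vals[i + 1] == vals[i]) {
      lens[i] <- lens[i] + lens[i + 1]
      vals <- vals[-(i + 1)]; lens <- lens[-(i + 1)]
    }
    if (i > 1 && vals[i - 1] == vals[i]) {
      lens[i - 1] <- lens[i - 1] + lens[i]
      vals <- vals[-i]; lens <- lens[-i]
    }
  }
  inverse.rle(list(values = vals, lengths = lens))
}

#' Regroup classifier labels into final behaviour categories
#'
#' @param labels character vector of seven-class labels
#' @param scheme named map from class to category (see [regroup_scheme()])
#' @return character vector of final-category labels (`NA` passed through)
#' @export
regroup <- function(labels, scheme = regroup_scheme()) {
  known <- !is.na(labels)
  unknown <- setdiff(unique(labels[known]), names(scheme))
  if (length(unknown) > 0) {
    stop("unknown label(s): ", paste(unknown, collapse = ", "))
  }
  out <- unname(scheme[labels])
  out[!known] <- NA_character_
  out
}

#' Aggregate per-second labels and VeDBA into 20 s behaviour bins
#'
#' Each non-overlapping bin takes the majority label over its seconds (ties
#' go to the label of the bin's central second); VeDBA summaries are the
#' means of the within-second maxima and minima. Bins with more than 50%
#' missing seconds are flagged as gaps and left unlabelled.
#'
#' @param labels character vector of per-second labels, second 0 aligned to
#'   the individual's local midnight
#' @param vedba per-second VeDBA tibble from [vedba_seconds()], or NULL
#' @param bin_s bin length, seconds
#' @param individual,sex,habitat,mass_kg metadata carried onto each bin
#' @return tibble of behaviour bins: start_s, label, vedba_max_mean,
#'   vedba_min_mean, n_seconds, gap, individual, sex, habitat, mass_kg
#' @export
bin_20s <- function(labels, vedba = NULL, bin_s = 20,
                    individual = NA_character_, sex = NA_character_,
                    habitat = NA_character_, mass_kg = NA_real_) {
  n <- length(labels)
  stopifnot(n > 0)
  bin <- (seq_len(n) - 1L) %/% bin_s
  n_bins <- max(bin) + 1L
  f <- factor(labels)
  lv <- levels(f)
  code <- as.integer(f)
  ok <- !is.na(code)
  if (length(lv) == 0) {
    win_lab <- rep(NA_character_, n_bins)
    n_obs <- rep(0L, n_bins)
  } else {
    counts <- vapply(seq_along(lv), function(c) {
      as.integer(rowsum((ok & code == c) + 0L, bin))
    }, integer(n_bins))
    if (is.null(dim(counts))) counts <- matrix(counts, nrow = n_bins)
    best <- as.vector(do.call(pmax, asplit(counts, 2)))
    winner <- lv[max.col(counts, ties.method = "first")]
    ties <- rowSums(counts == best) > 1L & best > 0L
    if (any(ties)) {
      central <- labels[pmin((which(ties) - 1L) * bin_s + bin_s %/% 2 + 1L, n)]
      winner[ties] <- ifelse(is.na(central), winner[ties], central)
    }
    win_lab <- ifelse(best > 0L, winner, NA_character_)
    n_obs <- as.integer(rowsum(ok + 0L, bin))
  }
  gap <- n_obs <= bin_s / 2
  win_lab[gap] <- NA_character_

  vmax <- vmin <- rep(NA_real_, n_bins)
  if (!is.null(vedba)) {
    vsec <- vedba[vedba$second >= 0 & vedba$second < n, ]
    vbin <- vsec$second %/% bin_s
    cnt <- as.integer(table(factor(vbin, levels = seq_len(n_bins) - 1L)))
    sums_max <- rowsum(vsec$vedba_max, factor(vbin, seq_len(n_bins) - 1L))
    sums_min <- rowsum(vsec$vedba_min, factor(vbin, seq_len(n_bins) - 1L))
    vmax <- ifelse(cnt > 0, as.numeric(sums_max) / cnt, NA_real_)
    vmin <- ifelse(cnt > 0, as.numeric(sums_min) / cnt, NA_real_)
  }
  tibble::tibble(
    start_s = (seq_len(n_bins) - 1L) * bin_s,
    label = win_lab,
    vedba_max_mean = vmax,
    vedba_min_mean = vmin,
    n_seconds = n_obs,
    gap = gap,
    individual = individual, sex = sex, habitat = habitat, mass_kg = mass_kg
  )
}

#' Remove Other bins before modelling and budgets
#'
#' @param bins behaviour-bin tibble
#' @return bins without Other; the removed fraction is attached as
#'   attribute `other_fraction`, with a warning above 5% (a model-drift
#'   signal)
#' @export
exclude_other <- function(bins) {
  labelled <- !is.na(bins$label)
  frac <- if (any(labelled)) mean(bins$label[labelled] == "Other") else 0
  if (frac > 0.05) {
    warning(sprintf("Other category is %.1f%% of labelled bins (> 5%%)",
                    100 * frac))
  }
  out <- bins[is.na(bins$label) | bins$label != "Other", ]
  attr(out, "other_fraction") <- frac
  out
}

#' Full post-processing chain: smooth, collapse, regroup, bin
#'
#' @param labels per-second seven-class labels
#' @param vedba per-second VeDBA tibble or NULL
#' @param half_width modal-filter half width, seconds
#' @param min_run blip-collapse threshold, seconds
#' @param bin_s bin length, seconds
#' @inheritParams bin_20s
#' @return behaviour-bin tibble (Other retained; see [exclude_other()])
#' @export
postprocess_labels <- function(labels, vedba = NULL, half_width = 2,
                               min_run = 3, bin_s = 20,
                               individual = NA_character_,
                               sex = NA_character_, habitat = NA_character_,
                               mass_kg = NA_real_) {
  smoothed <- modal_filter(labels, half_width)
  collapsed <- collapse_blips(smoothed, min_run)
  final <- regroup(collapsed)
  bin_20s(final, vedba, bin_s, individual, sex, habitat, mass_kg)
}
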