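# Windowed feature extraction and dynamic body acceleration.
#
# The static (gravity) component of each axis is a centred rolling mean; the
# dynamic component is the residual. VeDBA is the Euclidean norm of the
# dynamic 3-vector, ODBA its 1-norm analogue. Features are computed over
# 1 s windows with 50% overlap.

#' Split a stream into static (gravity) and dynamic components
#'
#' Static = centred rolling mean over `smooth_s` seconds per axis (edges use
#' shrunken windows); dynamic = raw - static, so the decomposition is exact
#' at every sample.
#'
#' @param stream a `labelled_stream`
#' @param smooth_s smoothing window, seconds
#' @return list with matrices `static` and `dynamic` (columns = axes)
#' @export
static_dynamic_split <- function(stream, smooth_s = 2) {
  fs <- stream$meta$sample_rate
  width <- round(smooth_s * fs) + 1L  # odd width, exactly centred
  acc_axes <- intersect(c("ax", "ay", "az"), stream$meta$axes)
  raw <- as.matrix(stream$data[, acc_axes])
  stat <- apply(raw, 2, rolling_mean, width = width)
  if (is.null(dim(stat))) stat <- matrix(stat, ncol = length(acc_axes),
                                         dimnames = list(NULL, acc_axes))
  list(static = stat, dynamic = raw - stat)
}

#' Vectorial dynamic body acceleration of dynamic samples
#'
#' Euclidean norm sqrt(dx^2 + dy^2 + dz^2) per sample.
#'
#' @param dynamic numeric 3-vector or matrix with 3 columns
#' @return numeric vector of VeDBA values, m/s^2
#' @export
vedba <- function(dynamic) {
  if (is.null(dim(dynamic))) dynamic <- matrix(dynamic, nrow = 1)
  if (any(!is.finite(dynamic))) stop("non-finite dynamic acceleration")
  sqrt(rowSums(dynamic^2))
}

#' Overall dynamic body acceleration (1-norm) of dynamic samples
#' @inheritParams vedba
#' @export
odba <- function(dynamic) {
  if (is.null(dim(dynamic))) dynamic <- matrix(dynamic, nrow = 1)
  rowSums(abs(dynamic))
}

#' Per-second VeDBA summaries
#'
#' The maximum and minimum of the per-sample VeDBA norm over the samples of
#' each whole second.
#'
#' @param stream a `labelled_stream`
#' @param smooth_s static-component smoothing window, seconds
#' @return tibble with columns second (0-based), vedba_max, vedba_min
#' @export
vedba_seconds <- function(stream, smooth_s = 2) {
  fs <- stream$meta$sample_rate
  v <- vedba(static_dynamic_split(stream, smooth_s)$dynamic)
  n_sec <- floor(length(v) / fs)
  v <- v[seq_len(n_sec * fs)]
  m <- matrix(v, nrow = fs)
  tibble::tibble(
    second = seq_len(n_sec) - 1L,
    vedba_max = do.call(pmax, asplit(m, 1)),
    vedba_min = do.call(pmin, asplit(m, 1))
  )
}

#' Segment a stream into overlapping window shells
#'
#' Windows of `window_s` seconds start every `window_s * (1 - overlap)`
#' seconds. A window's label is the majority per-sample label over its span;
#' windows whose majority label covers less than `purity` of the span get
#' `NA` (they are dropped from training).
#'
#' @param stream a `labelled_stream`
#' @param window_s window length, seconds
#' @param overlap fractional overlap between consecutive windows
#' @param purity minimum fraction of the window occupied by the majority
#'   label for the window to keep a training label
#' @return tibble with columns window, start_s, label, purity
#' @export
segment <- function(stream, window_s = 1, overlap = 0.5, purity = 0.7) {
  fs <- stream$meta$sample_rate
  dur <- stream_duration(stream)
  if (dur < window_s) {
    warning("stream shorter than one window; returning no windows")
    return(tibble::tibble(window = integer(), start_s = numeric(),
                          label = character(), purity = numeric()))
  }
  step <- window_s * (1 - overlap)
  starts <- seq(0, dur - window_s + 1e-9, by = step)
  wlen <- round(window_s * fs)
  f <- factor(stream$data$label)
  lv <- levels(f)
  if (length(lv) == 0) {
    out_lab <- rep(NA_character_, length(starts))
    out_pur <- rep(0, length(starts))
  } else {
    idx <- outer(seq_len(wlen), round(starts * fs), `+`)
    codes <- matrix(as.integer(f)[idx], nrow = wlen)
    counts <- vapply(seq_along(lv),
                     function(c) colSums(codes == c, na.rm = TRUE),
                     numeric(length(starts)))
    if (is.null(dim(counts))) counts <- matrix(counts, nrow = length(starts))
    out_lab <- lv[max.col(counts, ties.method = "first")]
    out_pur <- do.call(pmax, asplit(counts, 2)) / wlen
  }
  tibble::tibble(
    window = seq_along(starts),
    start_s = starts,
    label = ifelse(out_pur >= purity, out_lab, NA_character_),
    purity = out_pur
  )
}

# per-axis feature block over a samples-by-windows matrix, vectorised
axis_features <- function(M, D, fs) {
  n <- nrow(M)
  mu <- colMeans(M)
  C <- sweep(M, 2, mu)
  ss <- colSums(C^2)
  sdv <- sqrt(ss / (n - 1))
  mn <- do.call(pmin, asplit(M, 1))
  mx <- do.call(pmax, asplit(M, 1))
  m3 <- colSums(C^3) / n
  m4 <- colSums(C^4) / n
  varp <- ss / n
  skew <- ifelse(varp > 0, m3 / varp^1.5, 0)
  kurt <- ifelse(varp > 0, m4 / varp^2 - 3, 0)
  rms <- sqrt(colMeans(M^2))
  zc <- colSums(D[-1, , drop = FALSE] * D[-n, , drop = FALSE] < 0)
  # spectrum of the dynamic component; bins 2..floor(n/2)+1
  sp <- Mod(stats::mvfft(D))[2:(floor(n / 2) + 1L), , drop = FALSE]
  pow <- sp^2
  tot <- colSums(pow)
  domf <- ifelse(tot > 0, (max.col(t(pow), ties.method = "first")) * fs / n, 0)
  p <- sweep(pow, 2, pmax(tot, 1e-300), `/`)
  ent <- ifelse(tot > 0,
                -colSums(ifelse(p > 0, p * log(p), 0)) / log(nrow(pow)), 0)
  Dc <- sweep(D, 2, colMeans(D))
  den <- colSums(Dc^2)
  ac1 <- ifelse(den > 0,
                colSums(Dc[-1, , drop = FALSE] * Dc[-n, , drop = FALSE]) / den,
                0)
  rbind(mean = mu, sd = sdv, min = mn, max = mx, range = mx - mn,
        skew = skew, kurt = kurt, rms = rms, zero_cross = zc,
        dom_freq = domf, spec_entropy = ent, acf1 = ac1)
}

#' Extract the feature table for all windows of a stream
#'
#' Per axis: mean, SD, min, max, range, skewness, excess kurtosis, RMS,
#' zero-crossing count (dynamic), dominant frequency (dynamic), normalised
#' spectral entropy (dynamic) and lag-1 autocorrelation (dynamic). Cross
#' axis: the three pairwise correlations. Whole window: mean ODBA, mean and
#' max VeDBA, and the linear trend slope of the per-sample VeDBA. Degenerate
#' zero-variance windows map to defined sentinels (correlation, skewness,
#' kurtosis, entropy and autocorrelation all 0).
#'
#' @param stream a `labelled_stream`
#' @param window_s,overlap,purity see [segment()]
#' @param smooth_s static-component smoothing window, seconds
#' @return tibble: window, start_s, label, purity, individual, then one
#'   column per feature (stable order)
#' @export
extract_feature_table <- function(stream, window_s = 1, overlap = 0.5,
                                  purity = 0.7, smooth_s = 2) {
  fs <- stream$meta$sample_rate
  shells <- segment(stream, window_s, overlap, purity)
  if (nrow(shells) == 0) return(shells)
  wlen <- round(window_s * fs)
  sd_ <- static_dynamic_split(stream, smooth_s)
  idx <- outer(seq_len(wlen), round(shells$start_s * fs), `+`)

  acc_axes <- intersect(c("ax", "ay", "az"), stream$meta$axes)
  gyro_axes <- intersect(c("gx", "gy", "gz"), stream$meta$axes)
  feats <- list()
  Dlist <- list()
  for (a in acc_axes) {
    M <- matrix(stream$data[[a]][idx], nrow = wlen)
    D <- matrix(sd_$dynamic[, a][idx], nrow = wlen)
    Dlist[[a]] <- D
    fb <- axis_features(M, D, fs)
    rownames(fb) <- paste(a, rownames(fb), sep = "_")
    feats[[a]] <- fb
  }
  for (a in gyro_axes) {
    M <- matrix(stream$data[[a]][idx], nrow = wlen)
    fb <- axis_features(M, sweep(M, 2, colMeans(M)), fs)
    rownames(fb) <- paste(a, rownames(fb), sep = "_")
    feats[[a]] <- fb
  }
  # pairwise correlations of the raw acceleration axes
  pairs <- utils::combn(acc_axes, 2)
  corr <- sapply(seq_len(ncol(pairs)), function(j) {
    X <- matrix(stream$data[[pairs[1, j]]][idx], nrow = wlen)
    Y <- matrix(stream$data[[pairs[2, j]]][idx], nrow = wlen)
    Xc <- sweep(X, 2, colMeans(X)); Yc <- sweep(Y, 2, colMeans(Y))
    den <- sqrt(colSums(Xc^2) * colSums(Yc^2))
    ifelse(den > 0, colSums(Xc * Yc) / den, 0)
  })
  if (is.null(dim(corr))) corr <- matrix(corr, nrow = 1)
  colnames(corr) <- paste0("corr_", pairs[1, ], "_", pairs[2, ])

  V <- sqrt(Dlist$ax^2 + Dlist$ay^2 + Dlist$az^2)
  O <- abs(Dlist$ax) + abs(Dlist$ay) + abs(Dlist$az)
  tt <- (seq_len(wlen) - (wlen + 1) / 2) / fs
  slope <- colSums(V * tt) / sum(tt^2)
  win_feats <- cbind(
    odba_mean = colMeans(O),
    vedba_mean = colMeans(V),
    vedba_max = do.call(pmax, asplit(V, 1)),
    vedba_trend = slope
  )

  fm <- cbind(t(do.call(rbind, feats)), corr, win_feats)
  stopifnot(all(is.finite(fm)))
  out <- dplyr::bind_cols(
    shells,
    tibble::tibble(individual = stream$meta$individual_id),
    tibble::as_tibble(fm)
  )
  out
}

#' Extract the feature vector for a single window of samples
#'
#' @param samples numeric matrix (samples x axes) covering exactly one
#'   window; columns named ax, ay, az (optionally gx, gy, gz)
#' @param sample_rate sampling rate, Hz
#' @param smooth_s static smoothing window, seconds
#' @return named numeric feature vector (same order as
#'   [extract_feature_table()])
#' @export
extract_features <- function(samples, sample_rate = 50, smooth_s = 2) {
  samples <- as.matrix(samples)
  if (nrow(samples) < 2) stop("wrong sample count for a feature window")
  stream <- labelled_stream(
    tibble::as_tibble(cbind(t = (seq_len(nrow(samples)) - 1) / sample_rate,
                            samples)),
    sample_rate = sample_rate
  )
  tab <- extract_feature_table(stream, window_s = nrow(samples) / sample_rate,
                               overlap = 0, smooth_s = smooth_s)
  v <- as.numeric(tab[1, -(1:5)])
  names(v) <- names(tab)[-(1:5)]
  v
}

#' Names of the non-feature leading columns of a feature table
#' @keywords internal
feature_id_cols <- function() c("window", "start_s", "label", "purity",
                                "individual")
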