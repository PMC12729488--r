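# Independent brute-force reference implementations used to cross-check the
# production smoothing, blip-collapse and visit-clustering code. These are
# written position-by-position from the rules, with no shared code.

oracle_modal <- function(labels, half_width = 2) {
  n <- length(labels)
  out <- labels
  for (i in seq_len(n)) {
    if (is.na(labels[i])) next
    win <- labels[max(1, i - half_width):min(n, i + half_width)]
    win <- win[!is.na(win)]
    tab <- table(win)
    top <- names(tab)[tab == max(tab)]
    out[i] <- if (length(top) == 1) top else labels[i]
  }
  out
}

oracle_collapse <- function(labels, min_run = 3) {
  # LOCF then NOCB
  lab <- labels
  for (i in seq_along(lab)) {
    if (is.na(lab[i]) && i > 1) lab[i] <- lab[i - 1]
  }
  for (i in rev(seq_along(lab))) {
    if (is.na(lab[i]) && i < length(lab)) lab[i] <- lab[i + 1]
  }
  repeat {
    r <- rle(lab)
    k <- length(r$lengths)
    if (k < 2) return(lab)
    idx <- which(r$lengths < min_run)
    if (length(idx) == 0) return(lab)
    interior <- idx[idx > 1 & idx < k]
    i <- if (length(interior) > 0) interior[1] else idx[1]
    new <- if (i == 1) r$values[2]
      else if (i == k) r$values[k - 1]
      else if (r$values[i - 1] == r$values[i + 1]) r$values[i - 1]
      else if (r$lengths[i + 1] > r$lengths[i - 1]) r$values[i + 1]
      else r$values[i - 1]
    # rewrite that run sample-by-sample and rebuild
    pos <- (cumsum(r$lengths)[i] - r$lengths[i] + 1):cumsum(r$lengths)[i]
    lab[pos] <- new
  }
}

# O(n^2) pairwise clustering: two Walking bins belong to the same visit iff
# they are connected by a chain of bins with successive gaps <= max_gap_s
oracle_visit_count <- function(start_s, max_gap_s = 60, bin_s = 20) {
  n <- length(start_s)
  if (n == 0) return(0L)
  s <- sort(start_s)
  same <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      same[i, j] <- abs(s[i] - s[j]) <= bin_s + max_gap_s
    }
  }
  # transitive closure
  repeat {
    nxt <- same | (same %*% same > 0)
    if (all(nxt == same)) break
    same <- nxt
  }
  length(unique(apply(same, 1, function(r) min(which(r)))))
}

# exhaustive Benjamini-Hochberg from the definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  for (i in seq_len(n)) {
    rank_i <- which(o == i)
    adj[i] <- min(1, min(p[o][rank_i:n] * n / (rank_i:n)))
  }
  adj
}

random_label_seq <- function(n, k = 3, p_na = 0) {
  lab <- sample(LETTERS[seq_len(k)], n, replace = TRUE)
  if (p_na > 0) lab[runif(n) < p_na] <- NA_character_
  lab
}
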