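# Independent oracles used across the suite. These are deliberately
# naive (sample-by-sample loops, explicit tallies) and share no code with
# the implementation paths they check.

# Exhaustive threshold-scan spike detector: walks the trace one sample at
# a time, thresholds at median + k * raw MAD of the polarity signal,
# takes the first sample of every suprathreshold excursion and enforces
# the refractory period greedily.
oracle_detect <- function(x, fs_hz, mad_k = 3, refractory_ms = 1,
                          polarity = "absolute") {
  s <- switch(polarity, absolute = abs(x), positive = x, negative = -x)
  m <- median(s)
  madv <- median(abs(s - m))
  if (madv == 0) return(numeric(0))
  thr <- m + mad_k * madv
  out <- numeric(0)
  last <- -Inf
  in_excursion <- FALSE
  for (i in seq_along(s)) {
    if (s[i] > thr) {
      if (!in_excursion) {
        t <- (i - 1) / fs_hz * 1000
        if (t - last >= refractory_ms) {
          out <- c(out, t)
          last <- t
        }
        in_excursion <- TRUE
      }
    } else in_excursion <- FALSE
  }
  out
}

# brute-force window tally
oracle_count <- function(times, lo, hi) {
  n <- 0L
  for (t in times) if (t >= lo && t < hi) n <- n + 1L
  n
}

# precision/recall of detected vs ground-truth spike times
score_detection <- function(detected, truth, tol_ms = 0.3) {
  tp <- 0L
  used <- rep(FALSE, length(detected))
  for (t in truth) {
    d <- abs(detected - t)
    i <- which(!used & d <= tol_ms)
    if (length(i) > 0) {
      used[i[1]] <- TRUE
      tp <- tp + 1L
    }
  }
  fp <- length(detected) - tp
  fn <- length(truth) - tp
  f1 <- if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
  list(tp = tp, fp = fp, fn = fn, f1 = f1)
}

# hand-built frequency response area object
make_fra <- function(rate, freqs, levels, spont_mean = 5, spont_sd = 1) {
  structure(list(rate_hz = rate, n = matrix(10L, nrow(rate), ncol(rate)),
                 spont_mean_hz = spont_mean, spont_sd_hz = spont_sd,
                 freqs_khz = freqs, levels_db = levels, incomplete = FALSE),
            class = "fra")
}

# response matrix from per-cell generators: f(electrode, intensity_index)
# returning n_trials counts
make_counts <- function(n_trials, n_el, intensities, gen) {
  counts <- array(0, dim = c(n_trials, n_el, length(intensities)))
  for (e in seq_len(n_el))
    for (k in seq_along(intensities))
      counts[, e, k] <- gen(e, k)
  counts
}
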