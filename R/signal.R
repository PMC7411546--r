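#' Raw extracellular voltage trace
#'
#' @param samples numeric vector of voltages.
#' @param fs_hz sampling rate (32 kHz for ICC multi-unit recordings,
#'   50 kHz for evoked brainstem potentials).
#' @param t0_ms time of stimulus onset within the trace (ms from the
#'   first sample); spike times are reported relative to it.
#' @return an object of class `raw_trace`.
#' @export
raw_trace <- function(samples, fs_hz, t0_ms = 0) {
  stopifnot(is.numeric(samples), all(is.finite(samples)), fs_hz > 0)
  structure(list(samples = as.numeric(samples), fs_hz = fs_hz,
                 t0_ms = t0_ms),
            class = "raw_trace")
}

#' Multi-unit spike detection configuration
#'
#' Defaults follow the standard multi-unit extraction recipe: 0.6-6 kHz
#' 4th-order Butterworth band-pass, threshold at the median plus three
#' *raw* median absolute deviations (no normal-consistency factor), and a
#' 1 ms artificial refractory period.
#'
#' @param band_hz length-2 band edges in Hz.
#' @param filter_order Butterworth order (of the analog prototype; the
#'   band-pass has twice this order).
#' @param mad_k threshold multiplier on the MAD.
#' @param refractory_ms artificial refractory period.
#' @param polarity which signal is thresholded: `"absolute"` (default;
#'   the original analysis states only "peaks exceeding a threshold"),
#'   `"positive"` or `"negative"` (negated trace).
#' @return an object of class `detection_config`.
#' @export
detection_config <- function(band_hz = c(600, 6000), filter_order = 4,
                             mad_k = 3, refractory_ms = 1,
                             polarity = c("absolute", "positive",
                                          "negative")) {
  polarity <- match.arg(polarity)
  stopifnot(length(band_hz) == 2, band_hz[1] > 0, band_hz[1] < band_hz[2],
            filter_order >= 1, mad_k > 0, refractory_ms > 0)
  structure(list(band_hz = band_hz, filter_order = filter_order,
                 mad_k = mad_k, refractory_ms = refractory_ms,
                 polarity = polarity),
            class = "detection_config")
}

# ---- Butterworth band-pass design (zpk + bilinear transform) ----------
# No DSP package is available in this environment, so the classic design
# is carried out here: analog low-pass prototype poles, low-pass ->
# band-pass transform, bilinear transform with frequency pre-warping,
# polynomial coefficients from the (complex) roots.

.poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rt in r) p <- c(p, 0) - c(0, p * rt)
  p
}

.butter_bandpass <- function(order, lo_hz, hi_hz, fs_hz) {
  nyq <- fs_hz / 2
  if (hi_hz >= nyq) stop("upper band edge must be below the Nyquist rate")
  if (lo_hz <= 0 || lo_hz >= hi_hz) stop("invalid band edges")
  # analog prototype poles on the unit circle, left half-plane
  k <- seq_len(order)
  p <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  # pre-warped analog band edges
  w1 <- 2 * fs_hz * tan(pi * lo_hz / fs_hz)
  w2 <- 2 * fs_hz * tan(pi * hi_hz / fs_hz)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  # low-pass -> band-pass: each prototype pole maps to a conjugate pair
  pl <- p * bw / 2
  bp <- c(pl + sqrt(pl^2 - w0^2), pl - sqrt(pl^2 - w0^2))
  zeros <- rep(0 + 0i, order)          # order zeros at s = 0
  gain <- bw^order
  # bilinear transform s = 2 fs (z - 1)/(z + 1)
  fs2 <- 2 * fs_hz
  zd <- (fs2 + bp) / (fs2 - bp)
  zz <- c((fs2 + zeros) / (fs2 - zeros), rep(-1 + 0i, order))
  gd <- gain * Re(prod(fs2 - zeros) / prod(fs2 - bp))
  b <- Re(.poly_from_roots(zz)) * gd
  a <- Re(.poly_from_roots(zd))
  list(b = b, a = a)
}

# direct-form IIR application via stats::filter (FIR part by convolution,
# AR part recursively); zero initial conditions
.iir_apply <- function(b, a, x) {
  nb <- length(b)
  xx <- c(rep(0, nb - 1), x)
  v <- stats::filter(xx, b, method = "convolution", sides = 1)
  v <- as.numeric(v)[-seq_len(nb - 1)]
  if (length(a) > 1) {
    y <- stats::filter(v / a[1], -a[-1] / a[1], method = "recursive")
    as.numeric(y)
  } else v / a[1]
}

# zero-phase forward-backward filtering with odd-reflection edge padding
.filtfilt <- function(b, a, x) {
  n <- length(x)
  pad <- min(3 * (max(length(a), length(b)) - 1), n - 1)
  if (pad > 0) {
    pre <- 2 * x[1] - x[seq(pad + 1, 2)]
    post <- 2 * x[n] - x[seq(n - 1, n - pad)]
    xe <- c(pre, x, post)
  } else xe <- x
  y <- .iir_apply(b, a, xe)
  y <- rev(.iir_apply(b, a, rev(y)))
  if (pad > 0) y <- y[seq(pad + 1, pad + n)]
  y
}

#' Zero-phase Butterworth band-pass filter
#'
#' Filters a raw trace with the configured band-pass, applied forward and
#' backward (zero phase) so that spike timing is preserved. Output has
#' the same length and sampling rate as the input.
#'
#' @param trace a [raw_trace()].
#' @param cfg a [detection_config()] supplying band edges and order.
#' @return the filtered [raw_trace()].
#' @export
bandpass_filter <- function(trace, cfg = detection_config()) {
  stopifnot(inherits(trace, "raw_trace"), inherits(cfg, "detection_config"))
  ba <- .butter_bandpass(cfg$filter_order, cfg$band_hz[1], cfg$band_hz[2],
                         trace$fs_hz)
  if (length(trace$samples) < 3 * (length(ba$a) - 1))
    stop("trace shorter than the filter transient")
  raw_trace(.filtfilt(ba$b, ba$a, trace$samples), trace$fs_hz, trace$t0_ms)
}

#' Detect multi-unit spike times
#'
#' Thresholds the (optionally band-pass filtered) trace at
#' `median + mad_k * MAD` of the polarity signal, where MAD is the raw
#' median absolute deviation. Each suprathreshold excursion contributes
#' one event at its first suprathreshold sample; events closer than the
#' refractory period to the previously accepted event are dropped
#' greedily in time order.
#'
#' @param trace a [raw_trace()].
#' @param cfg a [detection_config()].
#' @param filter if `TRUE` (default) the trace is band-pass filtered
#'   first; set `FALSE` when a filtered trace is supplied.
#' @return numeric vector of spike times in ms relative to `t0_ms`.
#' @export
detect_spikes <- function(trace, cfg = detection_config(), filter = TRUE) {
  stopifnot(inherits(trace, "raw_trace"), inherits(cfg, "detection_config"))
  if (filter) trace <- bandpass_filter(trace, cfg)
  s <- switch(cfg$polarity,
              absolute = abs(trace$samples),
              positive = trace$samples,
              negative = -trace$samples)
  madv <- stats::mad(s, constant = 1)
  if (madv == 0) {
    warning("MAD of the trace is zero; no spikes detected")
    return(numeric(0))
  }
  thr <- stats::median(s) + cfg$mad_k * madv
  supra <- s > thr
  if (!any(supra)) return(numeric(0))
  # first sample of each suprathreshold excursion
  starts <- which(supra & !c(FALSE, supra[-length(supra)]))
  t_ms <- (starts - 1) / trace$fs_hz * 1000 - trace$t0_ms
  keep <- rep(FALSE, length(t_ms))
  last <- -Inf
  for (i in seq_along(t_ms)) {
    if (t_ms[i] - last >= cfg$refractory_ms) {
      keep[i] <- TRUE
      last <- t_ms[i]
    }
  }
  t_ms[keep]
}

#' Analysis window for optically evoked responses
#'
#' The default 3-20 ms window skips the stimulus-onset artifact while
#' retaining the evoked response. The window is half-open: `[start, end)`.
#'
#' @param start_ms,end_ms window bounds in ms after stimulus onset.
#' @return an object of class `response_window`.
#' @export
response_window <- function(start_ms = 3, end_ms = 20) {
  stopifnot(start_ms >= 0, start_ms < end_ms)
  structure(list(start_ms = start_ms, end_ms = end_ms),
            class = "response_window")
}

#' Count spikes in the response window
#'
#' Half-open convention: a spike at exactly `start_ms` is counted, one at
#' exactly `end_ms` is not.
#'
#' @param spikes numeric vector of spike times (ms relative to stimulus
#'   onset).
#' @param win a [response_window()].
#' @return integer count.
#' @export
count_in_window <- function(spikes, win = response_window()) {
  stopifnot(inherits(win, "response_window"))
  sum(spikes >= win$start_ms & spikes < win$end_ms)
}

#' Peri-stimulus time histogram
#'
#' @param spikes either a numeric vector of spike times pooled across
#'   trials (ms relative to onset) or a list of per-trial time vectors.
#' @param bin_ms bin width (0.25 ms by default).
#' @param span length-2 analysis span `[from, to)` in ms relative to
#'   onset; may start before 0 to include a baseline.
#' @param n_trials number of trials (required when `spikes` is a plain
#'   vector).
#' @return an object of class `psth` with bin edges, per-bin counts and
#'   rates in spikes/s.
#' @export
build_psth <- function(spikes, bin_ms = 0.25, span = c(-50, 50),
                       n_trials = NULL) {
  if (bin_ms <= 0) stop("bin_ms must be positive")
  stopifnot(length(span) == 2, span[1] < span[2])
  if (is.list(spikes)) {
    n_trials <- length(spikes)
    spikes <- unlist(spikes, use.names = FALSE)
  }
  if (is.null(n_trials) || n_trials < 1)
    stop("n_trials is required (>= 1)")
  edges <- seq(span[1], span[2], by = bin_ms)
  if (edges[length(edges)] < span[2]) edges <- c(edges, span[2])
  spikes <- spikes[spikes >= span[1] & spikes < span[2]]
  idx <- findInterval(spikes, edges, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = length(edges) - 1)
  structure(
    list(bin_ms = bin_ms, edges = edges, counts = counts,
         rate_hz = counts / (n_trials * bin_ms / 1000),
         n_trials = n_trials, span = span),
    class = "psth"
  )
}

#' Detect an evoked response window in a PSTH
#'
#' Criterion: the pre-stimulus baseline mean rate plus 3 baseline SD.
#' Latency is the start of the first post-onset bin whose rate exceeds
#' the criterion for at least two consecutive bins; the response ends at
#' the first subsequent position where the rate stays below the
#' criterion for at least two consecutive bins. With a zero-variance
#' baseline the criterion degenerates to `mean + 3` spikes/s
#' (documented fallback).
#'
#' @param psth a [build_psth()] result whose span includes pre-stimulus
#'   time.
#' @param baseline_span length-2 span (ms, before onset) used as the
#'   baseline; must cover at least 20 bins.
#' @return a list `(latency_ms, duration_ms, criterion_hz)` or `NULL`
#'   when the criterion is never exceeded.
#' @export
detect_response_window <- function(psth, baseline_span = c(-50, 0)) {
  stopifnot(inherits(psth, "psth"), length(baseline_span) == 2,
            baseline_span[1] < baseline_span[2], baseline_span[2] <= 0)
  starts <- psth$edges[-length(psth$edges)]
  base <- starts >= baseline_span[1] & starts < baseline_span[2]
  if (sum(base) < 20)
    stop("baseline span must cover at least 20 bins")
  mu <- mean(psth$rate_hz[base])
  sdv <- stats::sd(psth$rate_hz[base])
  crit <- if (sdv == 0) mu + 3 else mu + 3 * sdv
  post <- which(starts >= 0)
  above <- psth$rate_hz[post] > crit
  if (length(above) < 2) return(NULL)
  onset_rel <- which(above & c(above[-1], FALSE))
  if (length(onset_rel) == 0) return(NULL)
  i0 <- onset_rel[1]
  below <- !above
  off_rel <- which(below & c(below[-1], FALSE))
  off_rel <- off_rel[off_rel > i0]
  latency <- starts[post[i0]]
  end_t <- if (length(off_rel) == 0) psth$span[2] else starts[post[off_rel[1]]]
  list(latency_ms = latency, duration_ms = end_t - latency,
       criterion_hz = crit)
}

#' Average evoked far-field potentials
#'
#' Band-pass filters (default 300-3000 Hz, the standard auditory
#' brainstem response band) and averages equal-length trials aligned to
#' stimulus onset.
#'
#' @param traces numeric matrix (trials in rows) or list of equal-length
#'   numeric vectors.
#' @param fs_hz sampling rate in Hz.
#' @param band_hz band edges in Hz.
#' @param filter_order Butterworth prototype order.
#' @return numeric vector: the filtered trial average.
#' @export
average_evoked_response <- function(traces, fs_hz, band_hz = c(300, 3000),
                                    filter_order = 4) {
  if (is.list(traces)) {
    len <- vapply(traces, length, integer(1))
    if (length(unique(len)) != 1)
      stop("all trials must have the same length")
    traces <- do.call(rbind, traces)
  }
  stopifnot(is.matrix(traces), nrow(traces) >= 1)
  avg <- colMeans(traces)
  ba <- .butter_bandpass(filter_order, band_hz[1], band_hz[2], fs_hz)
  .filtfilt(ba$b, ba$a, avg)
}
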