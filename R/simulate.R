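#' Default acoustic stimulation grid
#'
#' Pure tones between 0.5 and 32 kHz in quarter-octave steps, levels from
#' 0 dB SPL upwards.
#'
#' @param f_lo_khz,f_hi_khz frequency range in kHz.
#' @param step_oct frequency step in octaves.
#' @param levels_db sound levels in dB SPL.
#' @return list with `freqs_khz` and `levels_db`.
#' @export
default_fra_grid <- function(f_lo_khz = 0.5, f_hi_khz = 32,
                             step_oct = 0.25,
                             levels_db = seq(0, 60, by = 10)) {
  list(freqs_khz = 2^seq(log2(f_lo_khz), log2(f_hi_khz), by = step_oct),
       levels_db = levels_db)
}

# canonical SpikeTable column order
.spike_cols <- c("animal_id", "condition", "emitter_set", "intensity",
                 "trial", "electrode", "t_ms")

.empty_spike_table <- function(extra = character(0)) {
  df <- data.frame(animal_id = character(0), condition = character(0),
                   emitter_set = character(0), intensity = numeric(0),
                   trial = integer(0), electrode = integer(0),
                   t_ms = numeric(0), stringsAsFactors = FALSE)
  for (e in extra) df[[e]] <- numeric(0)
  df
}

.sort_spike_table <- function(df) {
  o <- order(df$animal_id, df$condition, df$emitter_set, df$intensity,
             df$trial, df$electrode, df$t_ms, method = "radix")
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Expand per-row Poisson counts into uniformly placed event times.
# grid: data.frame of trial metadata; n: counts; lo/hi: vectors (recycled)
# of the uniform time support per row.
.spread_counts <- function(grid, n, lo, hi) {
  tot <- sum(n)
  if (tot == 0) return(cbind(grid[0, , drop = FALSE], t_ms = numeric(0)))
  idx <- rep.int(seq_len(nrow(grid)), n)
  lo <- rep_len(lo, nrow(grid))[idx]
  hi <- rep_len(hi, nrow(grid))[idx]
  out <- grid[idx, , drop = FALSE]
  out$t_ms <- stats::runif(tot, lo, hi)
  rownames(out) <- NULL
  out
}

#' Simulate an acoustic frequency-tuning dataset
#'
#' Generates a spike-time table for a full pseudo-random tone grid
#' (frequency x level, `n_trials` repetitions each) on all electrodes of
#' a linear ICC probe. Each electrode has a generative best frequency set
#' by its depth through the tonotopic gradient; the tuning is V-shaped
#' (threshold grows linearly, in dB per octave, with distance from the
#' best frequency) and counts are Poisson. Trials span
#' `[-pre_ms, tone_ms + pad_ms)` ms around tone onset: baseline activity
#' everywhere, evoked activity uniform in `[latency, latency + tone_ms)`.
#' Deaf and wild-type-deaf animals produce spontaneous activity only.
#'
#' @param model a [cochlear_model()] (part of the stated world; acoustic
#'   tuning itself is parameterised on the ICC side).
#' @param probe a [recording_geometry()].
#' @param act an [activation_model()] carrying the tonotopic gradient and
#'   the acoustic V-tuning parameters.
#' @param grid a [default_fra_grid()]-style list.
#' @param n_trials repetitions of each frequency-level pair (20-30 is
#'   typical; default 25).
#' @param seed mandatory RNG seed.
#' @param animal_id identifier written into the table.
#' @param status hearing status; `"deaf"` and `"wildtype_deaf"` silence
#'   evoked acoustic responses.
#' @param tone_ms tone duration.
#' @param pre_ms pre-stimulus baseline span included in every trial.
#' @param latency_ms acoustic response latency.
#' @return a SpikeTable `data.frame` with the canonical columns plus
#'   `freq_khz` and `level_db` (`intensity` mirrors `level_db`).
#' @export
simulate_fra_dataset <- function(model = cochlear_model(),
                                 probe = recording_geometry(),
                                 act = activation_model(),
                                 grid = default_fra_grid(),
                                 n_trials = 25, seed,
                                 animal_id = "a01", status = "hearing",
                                 tone_ms = 100, pre_ms = 50,
                                 latency_ms = 5) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(n_trials >= 1, tone_ms > 0, pre_ms > 0)
  freqs <- grid$freqs_khz
  levels <- grid$levels_db
  if (any(diff(levels) <= 0)) stop("level grid must be strictly increasing")
  if (log2(max(freqs) / min(freqs)) < 2)
    stop("acoustic grid must cover at least 2 octaves")
  set.seed(seed)
  deaf <- status %in% c("deaf", "wildtype_deaf")

  bf <- electrode_cf(act, probe)
  cells <- expand.grid(electrode = seq_len(probe$n_electrodes),
                       freq_khz = freqs, level_db = levels,
                       KEEP.OUT.ATTRS = FALSE)
  doct <- abs(log2(cells$freq_khz / bf[cells$electrode]))
  thr <- act$fra_tip_threshold_db + act$fra_slope_db_per_oct * doct
  frac <- pmin(pmax((cells$level_db - thr) / act$fra_dynamic_range_db, 0), 1)
  evoked_hz <- if (deaf) rep(0, nrow(cells)) else act$fra_rate_max_hz * frac

  span_ms <- pre_ms + tone_ms + latency_ms
  grid_trials <- cells[rep(seq_len(nrow(cells)), each = n_trials), ,
                       drop = FALSE]
  grid_trials$trial <- rep(seq_len(n_trials), nrow(cells))
  lam_base <- act$baseline_rate_hz * span_ms / 1000
  lam_ev <- rep(evoked_hz, each = n_trials) * tone_ms / 1000
  nb <- stats::rpois(nrow(grid_trials), lam_base)
  ne <- stats::rpois(nrow(grid_trials), lam_ev)
  base_ev <- .spread_counts(grid_trials, nb, -pre_ms, tone_ms + latency_ms)
  ev <- .spread_counts(grid_trials, ne, latency_ms, tone_ms + latency_ms)
  out <- rbind(base_ev, ev)
  out$animal_id <- animal_id
  out$condition <- "acoustic"
  out$emitter_set <- NA_character_
  out$intensity <- out$level_db
  .sort_spike_table(out[, c(.spike_cols, "freq_khz", "level_db")])
}

# per-emitter driving currents for one ladder step
.per_emitter_current <- function(kind, total, n_active) {
  switch(kind,
         single_led = total,
         block4 = total / n_active,
         all_leds = total / n_active,
         stop("not an emitter-driven ladder kind: ", kind))
}

# effective irradiance profile along the cochlea for one intensity step
.irradiance_profile <- function(xs, ladder, layout, act, active_set,
                                intensity) {
  if (ladder$kind == "fiber") {
    # broad illumination: flat effective irradiance
    return(rep(intensity * act$fiber_coupling_per_mw, length(xs)))
  }
  pos <- emitter_positions(layout)
  cur <- .per_emitter_current(ladder$kind, intensity, length(active_set))
  E <- rep(0, length(xs))
  for (e in active_set) {
    if (!layout$functional_mask[e]) next  # dead emitters draw current only
    fl <- flux_from_current(ladder, cur)
    E <- E + fl * exp(-(xs - pos[e])^2 / (2 * act$light_sigma_mm^2))
  }
  E
}

# multi-unit firing rates (Hz) on all electrodes for one intensity step.
# Electrode places use the *unclamped* inverse place-frequency map: a unit
# whose CF lies beyond the modelled range maps to a virtual place outside
# [0, length_mm] and is correspondingly weakly driven, instead of piling
# up at the cochlear base.
.optical_rates <- function(model, layout, probe, act, ladder, active_set,
                           intensity, status) {
  cf <- electrode_cf(act, probe)
  x_el <- log2(model$base_freq_khz / cf) / model$slope_oct_per_mm
  xs <- seq(0, model$length_mm, by = 0.02)
  E <- .irradiance_profile(xs, ladder, layout, act, active_set, intensity)
  recr <- act$transduction_profile(xs) *
    E^act$hill_slope / (E^act$hill_slope + act$i50^act$hill_slope)
  recr[E == 0] <- 0
  dx <- xs[2] - xs[1]
  drive <- vapply(x_el, function(x0) {
    sum(recr * exp(-(xs - x0)^2 / (2 * act$pool_sigma_mm^2))) * dx
  }, numeric(1))
  evoked <- act$rate_max_hz * drive / (drive + act$drive50)
  if (grepl("^wildtype", status)) evoked <- 0 * evoked  # no opsin

  oa <- rep(0, probe$n_electrodes)
  if (status == "wildtype_hearing" && intensity > 0) {
    # opto-acoustic effect: weak, dorsally biased, near-max flux only
    total_mw <- if (ladder$kind == "fiber") intensity else {
      cur <- .per_emitter_current(ladder$kind, intensity, length(active_set))
      sum(layout$functional_mask[active_set]) * flux_from_current(ladder, cur)
    }
    s <- total_mw^4 / (total_mw^4 + act$oa_i50_mw^4)
    depth_rel <- (seq_len(probe$n_electrodes) - 1) * probe$pitch_mm
    oa <- act$oa_rate_hz * s * exp(-depth_rel / act$oa_dorsal_tau_mm)
  }
  list(evoked = evoked, oa = oa)
}

#' Simulate optically evoked multi-unit trials
#'
#' For every intensity step of the ladder (including the mandatory zero
#' baseline) and every trial, generates spike times on all probe
#' electrodes. Effective irradiance along the cochlear place axis is the
#' sum over active emitters of flux(current) with 1-D Gaussian spatial
#' decay; SGN recruitment is a Hill sigmoid scaled by the opsin
#' transduction profile; multi-unit drive pools recruitment over a
#' Gaussian receptive field and saturates into a firing rate. Evoked
#' spikes are uniform in `[latency, latency + duration)`; baseline
#' activity covers the whole trial. For `block4` and `all_leds` the total
#' driving current is split equally across the addressed emitters.
#'
#' @param model a [cochlear_model()].
#' @param layout an [emitter_layout()] (ignored for `fiber` ladders).
#' @param act an [activation_model()].
#' @param ladder a [stimulus_ladder()].
#' @param active_set indices of the addressed emitters (non-empty subset;
#'   ignored for `fiber`).
#' @param seed mandatory RNG seed.
#' @param probe a [recording_geometry()].
#' @param animal_id,condition identifiers written to the table; the
#'   condition defaults to the ladder kind plus the active set.
#' @param status one of the cohort hearing statuses; wild-type animals
#'   have no opsin response (hearing wild-types show a weak, dorsally
#'   biased opto-acoustic response with longer latency and shorter
#'   duration).
#' @param trial_ms trial duration in ms.
#' @return a SpikeTable `data.frame` (canonical columns).
#' @export
simulate_optical_trials <- function(model = cochlear_model(),
                                    layout = emitter_layout(),
                                    act = activation_model(),
                                    ladder, active_set = 1L, seed,
                                    probe = recording_geometry(),
                                    animal_id = "a01", condition = NULL,
                                    status = "hearing", trial_ms = 50) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(inherits(ladder, "stimulus_ladder"))
  if (ladder$kind != "fiber") {
    if (length(active_set) == 0) stop("active_set must be non-empty")
    if (any(active_set < 1 | active_set > layout$n_emitters))
      stop("active_set outside the emitter layout")
    emitter_positions(layout, model)  # validates placement in the cochlea
  }
  set.seed(seed)
  if (is.null(condition))
    condition <- paste0(ladder$kind, "_",
                        paste(range(active_set), collapse = "-"))
  wt <- grepl("^wildtype", status)
  lat <- if (wt) act$wt_latency_ms else act$latency_ms
  dur <- if (wt) act$wt_duration_ms else act$duration_ms
  n_tr <- ladder$n_trials_per_step
  n_el <- probe$n_electrodes

  pieces <- vector("list", length(ladder$intensities))
  for (k in seq_along(ladder$intensities)) {
    I <- ladder$intensities[k]
    r <- .optical_rates(model, layout, probe, act, ladder, active_set, I,
                        status)
    evoked_hz <- r$evoked + r$oa
    g <- expand.grid(electrode = seq_len(n_el), trial = seq_len(n_tr),
                     KEEP.OUT.ATTRS = FALSE)
    g$intensity <- I
    nb <- stats::rpois(nrow(g), act$baseline_rate_hz * trial_ms / 1000)
    lam_e <- if (I == 0) rep(0, nrow(g)) else
      evoked_hz[g$electrode] * dur / 1000
    ne <- stats::rpois(nrow(g), lam_e)
    pieces[[k]] <- rbind(
      .spread_counts(g, nb, 0, trial_ms),
      .spread_counts(g, ne, lat, min(lat + dur, trial_ms))
    )
  }
  out <- do.call(rbind, pieces)
  out$animal_id <- animal_id
  out$condition <- condition
  out$emitter_set <- if (ladder$kind == "fiber") "fiber" else
    paste(active_set, collapse = "+")
  .sort_spike_table(out[, .spike_cols])
}

#' Default biphasic spike waveform kernel
#'
#' A short biphasic (negative-then-positive) waveform spanning about
#' 0.6 ms, well inside the 1 ms refractory period.
#'
#' @param fs_hz sampling rate.
#' @param amp peak (absolute) amplitude.
#' @return numeric vector.
#' @export
spike_kernel <- function(fs_hz = 32000, amp = 1) {
  t <- seq(0, 0.6e-3, by = 1 / fs_hz)
  w <- -sin(2 * pi * t / 0.6e-3) * exp(-t / 0.4e-3)
  amp * w / max(abs(w))
}

#' Synthesize a raw trace from ground-truth spike times
#'
#' Background noise plus a waveform kernel inserted at every spike time;
#' the ground truth is retained so spike-detector performance can be
#' scored. Spikes closer together than the kernel support trigger an
#' overlap warning.
#'
#' The default noise is *bounded* (uniform, matched to `noise_sd`): a
#' median-plus-k-MAD threshold then sits above the noise ceiling and
#' detection can be exact. With unbounded Gaussian noise any such
#' relative threshold (about 2 noise SD for k = 3 and raw MAD) admits a
#' constant false-positive rate, so Gaussian noise is available but
#' exact-recall scoring is only meaningful with the bounded kind.
#'
#' @param spike_times_ms ground-truth spike times (ms from trace start).
#' @param duration_ms trace duration.
#' @param fs_hz sampling rate (must be at least 20 kHz).
#' @param kernel waveform kernel (numeric vector at `fs_hz`).
#' @param noise_sd noise standard deviation.
#' @param noise one of `"uniform"` (bounded, default) or `"gaussian"`.
#' @param seed mandatory RNG seed.
#' @return a [raw_trace()] with attribute `ground_truth_ms`.
#' @export
simulate_raw_trace <- function(spike_times_ms, duration_ms, fs_hz = 32000,
                               kernel = spike_kernel(fs_hz),
                               noise_sd = 1,
                               noise = c("uniform", "gaussian"), seed) {
  if (missing(seed)) stop("a seed is mandatory")
  if (fs_hz < 20000) stop("fs_hz must be at least 20 kHz")
  noise <- match.arg(noise)
  n <- round(duration_ms / 1000 * fs_hz)
  support_ms <- length(kernel) / fs_hz * 1000
  st <- sort(spike_times_ms)
  if (length(st) > 1 && any(diff(st) < support_ms))
    warning("spikes closer than the kernel support: overlapping waveforms")
  set.seed(seed)
  half <- noise_sd * sqrt(3)  # uniform half-range with SD = noise_sd
  x <- if (noise_sd == 0) rep(0, n)
       else if (noise == "uniform") stats::runif(n, -half, half)
       else stats::rnorm(n, 0, noise_sd)
  for (t in st) {
    i0 <- round(t / 1000 * fs_hz) + 1
    idx <- i0:(i0 + length(kernel) - 1)
    ok <- idx >= 1 & idx <= n
    x[idx[ok]] <- x[idx[ok]] + kernel[ok]
  }
  tr <- raw_trace(x, fs_hz)
  attr(tr, "ground_truth_ms") <- st
  tr
}
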