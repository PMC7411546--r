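#' Cochlear place-frequency model
#'
#' A straightened model of the gerbil scala tympani with a log-linear
#' place-frequency map. Place is measured in mm from the round window
#' (0 = base); frequency decreases monotonically from base to apex.
#' The gerbil scala tympani is approximately 11 mm long; the log-linear
#' map between 32 kHz (base) and 0.5 kHz (apex) is a configurable
#' modelling default, not a measured map.
#'
#' @param length_mm cochlear (scala tympani) length in mm.
#' @param base_freq_khz frequency mapped to place 0 (the base).
#' @param apex_freq_khz frequency mapped to place `length_mm` (the apex).
#' @return an object of class `cochlear_model`.
#' @export
cochlear_model <- function(length_mm = 11, base_freq_khz = 32,
                           apex_freq_khz = 0.5) {
  stopifnot(length_mm > 0, base_freq_khz > apex_freq_khz, apex_freq_khz > 0)
  structure(
    list(
      length_mm = length_mm,
      base_freq_khz = base_freq_khz,
      apex_freq_khz = apex_freq_khz,
      # octaves lost per mm travelled towards the apex
      slope_oct_per_mm = log2(base_freq_khz / apex_freq_khz) / length_mm
    ),
    class = "cochlear_model"
  )
}

#' Map cochlear place to frequency
#'
#' @param model a [cochlear_model()].
#' @param place_mm place(s) in mm from the round window.
#' @return frequency in kHz.
#' @export
place_to_freq <- function(model, place_mm) {
  stopifnot(inherits(model, "cochlear_model"))
  model$base_freq_khz * 2^(-model$slope_oct_per_mm * place_mm)
}

#' Map frequency to cochlear place
#'
#' Inverse of [place_to_freq()]. Frequencies outside the modelled range
#' are clamped to the cochlear extent.
#'
#' @inheritParams place_to_freq
#' @param freq_khz frequency in kHz.
#' @return place in mm from the round window.
#' @export
freq_to_place <- function(model, freq_khz) {
  stopifnot(inherits(model, "cochlear_model"), all(freq_khz > 0))
  x <- log2(model$base_freq_khz / freq_khz) / model$slope_oct_per_mm
  pmin(pmax(x, 0), model$length_mm)
}

#' Micro-LED emitter layout of an optical cochlear implant
#'
#' 16 individually addressable emitters (60 x 60 um) at a pitch of 100,
#' 150 or 250 um. `insertion_depth_mm` is the cochlear place of the most
#' basal emitter; emitters extend apically from it.
#'
#' @param n_emitters number of emitters on the implant.
#' @param pitch_mm center-to-center spacing in mm.
#' @param insertion_depth_mm place (mm from round window) of the most
#'   basal emitter.
#' @param emitter_size_um emitter edge length in um.
#' @param functional_mask logical vector; `FALSE` marks dead emitters
#'   (which draw current but emit no light).
#' @return an object of class `emitter_layout`.
#' @export
emitter_layout <- function(n_emitters = 16, pitch_mm = 0.25,
                           insertion_depth_mm = 0.5, emitter_size_um = 60,
                           functional_mask = rep(TRUE, n_emitters)) {
  stopifnot(n_emitters >= 1, pitch_mm > 0, insertion_depth_mm >= 0,
            length(functional_mask) == n_emitters)
  structure(
    list(
      n_emitters = n_emitters,
      pitch_mm = pitch_mm,
      insertion_depth_mm = insertion_depth_mm,
      emitter_size_um = emitter_size_um,
      functional_mask = as.logical(functional_mask)
    ),
    class = "emitter_layout"
  )
}

#' Cochlear places of the emitters
#'
#' Emitter 1 is the most basal; places increase apically. When `model` is
#' supplied, emitters outside `[0, length_mm]` raise an error.
#'
#' @param layout an [emitter_layout()].
#' @param model optionally, a [cochlear_model()] used to validate that all
#'   emitters lie within the cochlea.
#' @return numeric vector of places in mm.
#' @export
emitter_positions <- function(layout, model = NULL) {
  stopifnot(inherits(layout, "emitter_layout"))
  pos <- layout$insertion_depth_mm +
    (seq_len(layout$n_emitters) - 1) * layout$pitch_mm
  if (!is.null(model)) {
    stopifnot(inherits(model, "cochlear_model"))
    if (any(pos < 0 | pos > model$length_mm))
      stop("emitter placed outside the cochlea ([0, ", model$length_mm,
           "] mm)")
  }
  pos
}

# Saturating flux-current calibration F(I) = a I / (1 + I / b), solved from
# two anchors: 0.76 mW at 10 mA for a single uLED and 3.15 mW total at
# 40 mA across 16 uLEDs (2.5 mA each).
.default_flux_calibration <- function() {
  i1 <- 2.5;  f1 <- 3.15 / 16
  i2 <- 10;   f2 <- 0.76
  b <- i1 * i2 * (f1 - f2) / (f2 * i1 - f1 * i2)
  a <- f2 * (1 + i2 / b) / i2
  c(a = a, b = b)
}

#' Stimulus intensity ladder
#'
#' An ordered set of stimulus intensities starting at exactly 0 (the
#' baseline, no-stimulation condition), with the per-step trial count and
#' the flux-current calibration for optical ladders. Intensities are total
#' driving current (mA) for `single_led`, `block4` and `all_leds`, radiant
#' flux (mW) for `fiber`, and dB SPL for `acoustic`.
#'
#' @param kind one of `"single_led"`, `"block4"`, `"all_leds"`, `"fiber"`,
#'   `"acoustic"`.
#' @param intensities strictly increasing numeric vector whose first
#'   element is 0.
#' @param pulse_ms optical pulse duration in ms.
#' @param n_trials_per_step repetitions of every intensity step.
#' @param flux_calibration named vector `c(a, b)` of the saturating
#'   calibration `flux = a * I / (1 + I / b)` (mW per mA); the default is
#'   anchored at 0.76 mW per emitter at 10 mA and 3.15 mW total for 16
#'   emitters at 2.5 mA each.
#' @return an object of class `stimulus_ladder`.
#' @export
stimulus_ladder <- function(kind = c("single_led", "block4", "all_leds",
                                     "fiber", "acoustic"),
                            intensities, pulse_ms = 1,
                            n_trials_per_step = 20,
                            flux_calibration = .default_flux_calibration()) {
  kind <- match.arg(kind)
  stopifnot(length(intensities) >= 2, pulse_ms > 0, n_trials_per_step >= 1)
  if (intensities[1] != 0)
    stop("the first intensity must be exactly 0 (baseline condition)")
  if (any(diff(intensities) <= 0))
    stop("intensities must be strictly increasing")
  structure(
    list(kind = kind, intensities = intensities, pulse_ms = pulse_ms,
         n_trials_per_step = n_trials_per_step,
         flux_calibration = flux_calibration),
    class = "stimulus_ladder"
  )
}

#' Radiant flux of one emitter as a function of driving current
#'
#' Saturating calibration curve `a * I / (1 + I / b)`.
#'
#' @param ladder a [stimulus_ladder()] carrying the calibration.
#' @param current_ma per-emitter driving current in mA.
#' @return radiant flux in mW.
#' @export
flux_from_current <- function(ladder, current_ma) {
  stopifnot(inherits(ladder, "stimulus_ladder"), all(current_ma >= 0))
  cal <- ladder$flux_calibration
  cal[["a"]] * current_ma / (1 + current_ma / cal[["b"]])
}

#' Optogenetic activation model
#'
#' Parameters governing how light at the cochlea turns into multi-unit
#' firing in the central nucleus of the inferior colliculus (ICC).
#' Effective irradiance at cochlear place x is the sum over active
#' emitters of flux(current) decayed by a 1-D Gaussian of width
#' `light_sigma_mm`. Recruitment at x is a Hill sigmoid of irradiance
#' scaled by the local opsin `transduction_profile`; a multi-unit pools
#' recruitment over a Gaussian receptive field (`pool_sigma_mm`) and
#' fires at `baseline_rate_hz + rate_max_hz * drive / (drive + drive50)`.
#' Evoked spikes fall uniformly in `[latency_ms, latency_ms + duration_ms)`
#' (3.25 / 14 ms for opsin-transduced responses; wild-type opto-acoustic
#' responses use 5.0 / 5.5 ms and a dorsal bias).
#'
#' @param light_sigma_mm Gaussian decay width of effective irradiance
#'   along the place axis, mm.
#' @param rate_max_hz maximal evoked multi-unit rate above baseline, Hz.
#' @param i50 irradiance (mW) of half-maximal SGN recruitment.
#' @param hill_slope Hill coefficient of the recruitment sigmoid.
#' @param baseline_rate_hz spontaneous multi-unit rate, Hz.
#' @param latency_ms,duration_ms evoked-response timing for transduced
#'   animals.
#' @param wt_latency_ms,wt_duration_ms timing of the opto-acoustic
#'   response in non-injected hearing animals.
#' @param tonotopic_slope_oct_per_mm ICC tonotopic gradient along the
#'   probe (octaves of characteristic frequency per mm of depth).
#' @param cf_dorsal_khz characteristic frequency at the most dorsal
#'   electrode (electrode 1).
#' @param transduction_profile function of cochlear place returning the
#'   opsin expression factor in `[0, 1]`.
#' @param pool_sigma_mm width of the multi-unit spatial pooling kernel on
#'   the cochlear place axis, mm.
#' @param drive50 pooled drive of half-maximal firing (mm of fully
#'   recruited cochlea).
#' @param fiber_coupling_per_mw effective irradiance per mW of fiber
#'   output under broad (flat) illumination.
#' @param oa_rate_hz,oa_i50_mw,oa_dorsal_tau_mm amplitude, flux of
#'   half-activation, and dorsal decay length of the wild-type
#'   opto-acoustic response.
#' @param fra_tip_threshold_db,fra_slope_db_per_oct,fra_rate_max_hz,fra_dynamic_range_db
#'   acoustic V-tuning: threshold at the tip, threshold growth away from
#'   the best frequency, maximal evoked rate, and the level range over
#'   which the rate grows from 0 to maximal.
#' @return an object of class `activation_model`.
#' @export
activation_model <- function(light_sigma_mm = 0.15,
                             rate_max_hz = 800,
                             i50 = 0.3,
                             hill_slope = 1,
                             baseline_rate_hz = 20,
                             latency_ms = 3.25,
                             duration_ms = 14,
                             wt_latency_ms = 5.0,
                             wt_duration_ms = 5.5,
                             tonotopic_slope_oct_per_mm = 4.34,
                             cf_dorsal_khz = 0.5,
                             transduction_profile = function(x) rep(1, length(x)),
                             pool_sigma_mm = 1.0,
                             drive50 = 1.5,
                             fiber_coupling_per_mw = 0.05,
                             oa_rate_hz = 60,
                             oa_i50_mw = 2,
                             oa_dorsal_tau_mm = 0.4,
                             fra_tip_threshold_db = 20,
                             fra_slope_db_per_oct = 50,
                             fra_rate_max_hz = 80,
                             fra_dynamic_range_db = 30) {
  stopifnot(light_sigma_mm > 0, rate_max_hz >= 0, i50 > 0, hill_slope > 0,
            baseline_rate_hz >= 0, latency_ms >= 0, duration_ms > 0,
            tonotopic_slope_oct_per_mm > 0, is.function(transduction_profile),
            pool_sigma_mm > 0, drive50 > 0)
  structure(
    list(light_sigma_mm = light_sigma_mm, rate_max_hz = rate_max_hz,
         i50 = i50, hill_slope = hill_slope,
         baseline_rate_hz = baseline_rate_hz,
         latency_ms = latency_ms, duration_ms = duration_ms,
         wt_latency_ms = wt_latency_ms, wt_duration_ms = wt_duration_ms,
         tonotopic_slope_oct_per_mm = tonotopic_slope_oct_per_mm,
         cf_dorsal_khz = cf_dorsal_khz,
         transduction_profile = transduction_profile,
         pool_sigma_mm = pool_sigma_mm, drive50 = drive50,
         fiber_coupling_per_mw = fiber_coupling_per_mw,
         oa_rate_hz = oa_rate_hz, oa_i50_mw = oa_i50_mw,
         oa_dorsal_tau_mm = oa_dorsal_tau_mm,
         fra_tip_threshold_db = fra_tip_threshold_db,
         fra_slope_db_per_oct = fra_slope_db_per_oct,
         fra_rate_max_hz = fra_rate_max_hz,
         fra_dynamic_range_db = fra_dynamic_range_db),
    class = "activation_model"
  )
}

#' Linear recording-probe geometry
#'
#' 32-channel silicon probe, 50 um pitch; electrode 1 is the most dorsal,
#' depth increases ventrally, and characteristic frequencies are expected
#' to increase with depth.
#'
#' @param n_electrodes number of recording sites.
#' @param pitch_mm electrode pitch in mm.
#' @param depth_of_first_electrode_mm depth of electrode 1 in mm (only an
#'   offset; slopes are invariant to it).
#' @return an object of class `recording_geometry`.
#' @export
recording_geometry <- function(n_electrodes = 32, pitch_mm = 0.05,
                               depth_of_first_electrode_mm = 2.0) {
  stopifnot(n_electrodes >= 1, pitch_mm > 0)
  structure(
    list(n_electrodes = n_electrodes, pitch_mm = pitch_mm,
         depth_of_first_electrode_mm = depth_of_first_electrode_mm),
    class = "recording_geometry"
  )
}

#' Electrode depths along the probe
#'
#' @param geometry a [recording_geometry()].
#' @return numeric vector of depths in mm (electrode 1 first).
#' @export
electrode_depths <- function(geometry) {
  stopifnot(inherits(geometry, "recording_geometry"))
  geometry$depth_of_first_electrode_mm +
    (seq_len(geometry$n_electrodes) - 1) * geometry$pitch_mm
}

#' Generative characteristic frequencies of the electrodes
#'
#' CF of electrode k follows the ICC tonotopic gradient:
#' `log2(cf_k) = log2(cf_dorsal) + slope * (depth_k - depth_1)`.
#'
#' @param act an [activation_model()].
#' @param geometry a [recording_geometry()].
#' @return numeric vector of CFs in kHz.
#' @export
electrode_cf <- function(act, geometry) {
  stopifnot(inherits(act, "activation_model"),
            inherits(geometry, "recording_geometry"))
  d <- electrode_depths(geometry)
  act$cf_dorsal_khz *
    2^(act$tonotopic_slope_oct_per_mm * (d - d[1]))
}

#' Cohort specification for synthetic experiments
#'
#' @param n_animals number of animals.
#' @param hearing_status character vector (recycled) with entries from
#'   `"hearing"`, `"deaf"`, `"wildtype_hearing"`, `"wildtype_deaf"`.
#'   Deaf animals give no acoustic responses; wild-type animals carry no
#'   opsin (`transduction_profile` identically 0).
#' @param seed mandatory master seed; per-animal substreams are derived
#'   deterministically from it.
#' @param jitter_sd standard deviation of the multiplicative log-normal
#'   per-animal jitter applied to `rate_max_hz` and `i50`.
#' @param cf_jitter_oct SD (octaves) of the per-animal shift of
#'   `cf_dorsal_khz`, emulating variable probe placement.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_animals, hearing_status = "hearing", seed,
                        jitter_sd = 0.1, cf_jitter_oct = 0.2) {
  if (missing(seed)) stop("a seed is mandatory for a cohort_spec")
  stopifnot(n_animals >= 1, jitter_sd >= 0)
  status <- rep_len(hearing_status, n_animals)
  ok <- c("hearing", "deaf", "wildtype_hearing", "wildtype_deaf")
  if (!all(status %in% ok))
    stop("hearing_status entries must be one of: ", paste(ok, collapse = ", "))
  structure(
    list(n_animals = n_animals, hearing_status = status,
         seed = as.integer(seed), jitter_sd = jitter_sd,
         cf_jitter_oct = cf_jitter_oct),
    class = "cohort_spec"
  )
}

#' Per-animal parameter draws for a cohort
#'
#' Applies the cohort's multiplicative log-normal jitter to `rate_max_hz`
#' and `i50` and a normal octave shift to `cf_dorsal_khz`; wild-type
#' animals get a transduction profile that is identically zero. Each
#' animal also receives its own derived seed (kept below 2^31).
#'
#' @param spec a [cohort_spec()].
#' @param act the baseline [activation_model()] shared by the cohort.
#' @return a list with one entry per animal: `animal_id`, `status`,
#'   `seed` and the jittered `act`.
#' @export
simulate_animal_params <- function(spec, act = activation_model()) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(act, "activation_model"))
  set.seed(spec$seed)
  out <- vector("list", spec$n_animals)
  for (i in seq_len(spec$n_animals)) {
    a <- act
    a$rate_max_hz <- act$rate_max_hz * exp(stats::rnorm(1, 0, spec$jitter_sd))
    a$i50 <- act$i50 * exp(stats::rnorm(1, 0, spec$jitter_sd))
    a$cf_dorsal_khz <- act$cf_dorsal_khz *
      2^stats::rnorm(1, 0, spec$cf_jitter_oct)
    if (grepl("^wildtype", spec$hearing_status[i]))
      a$transduction_profile <- function(x) rep(0, length(x))
    out[[i]] <- list(
      animal_id = sprintf("a%02d", i),
      status = spec$hearing_status[i],
      seed = (spec$seed + 7919L * i) %% .Machine$integer.max,
      act = a
    )
  }
  out
}
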