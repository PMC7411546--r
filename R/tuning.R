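#' Build a frequency response area for one electrode
#'
#' Mean firing rate per (frequency, level) cell over the trial
#' repetitions, plus a spontaneous-rate estimate (mean and SD of the
#' per-trial rate) from the pre-stimulus spans of all trials. Missing
#' cells are tolerated up to 20 % of the grid (flagged); beyond that the
#' FRA is rejected.
#'
#' @param spikes SpikeTable slice for a single animal and electrode, as
#'   produced by [simulate_fra_dataset()] (columns `freq_khz`, `level_db`,
#'   `trial`, `t_ms`).
#' @param freqs_khz,levels_db the stimulus grid. Defaults are taken from
#'   the values present in `spikes`.
#' @param n_trials repetitions per cell.
#' @param tone_ms analysis window `[0, tone_ms)` for evoked rates.
#' @param pre_ms pre-stimulus span `[-pre_ms, 0)` for the spontaneous
#'   estimate.
#' @return an object of class `fra`: `rate_hz` (frequency x level
#'   matrix), `n` (trial counts per cell), `spont_mean_hz`,
#'   `spont_sd_hz`, `freqs_khz`, `levels_db`, `incomplete` flag.
#' @export
build_fra <- function(spikes, freqs_khz = NULL, levels_db = NULL,
                      n_trials = NULL, tone_ms = 100, pre_ms = 50) {
  need <- c("freq_khz", "level_db", "trial", "t_ms")
  if (!all(need %in% names(spikes)))
    stop("spikes must carry columns: ", paste(need, collapse = ", "))
  if (is.null(freqs_khz)) freqs_khz <- sort(unique(spikes$freq_khz))
  if (is.null(levels_db)) levels_db <- sort(unique(spikes$level_db))
  if (is.null(n_trials)) n_trials <- max(spikes$trial)
  dt <- data.table::as.data.table(spikes)
  lvl <- NULL; t_ms <- NULL; freq_khz <- NULL; level_db <- NULL # NSE notes

  evoked <- dt[t_ms >= 0 & t_ms < tone_ms,
               .N, by = list(freq_khz, level_db, trial)]
  full <- data.table::CJ(freq_khz = freqs_khz, level_db = levels_db,
                         trial = seq_len(n_trials))
  evoked <- evoked[full, on = c("freq_khz", "level_db", "trial")]
  evoked[is.na(evoked$N), "N"] <- 0L
  cell <- evoked[, list(rate = mean(N) / (tone_ms / 1000), n = .N),
                 by = list(freq_khz, level_db)]

  rate <- matrix(NA_real_, length(freqs_khz), length(levels_db),
                 dimnames = list(signif(freqs_khz, 6), levels_db))
  nmat <- matrix(0L, length(freqs_khz), length(levels_db))
  fi <- match(cell$freq_khz, freqs_khz)
  li <- match(cell$level_db, levels_db)
  rate[cbind(fi, li)] <- cell$rate
  nmat[cbind(fi, li)] <- cell$n

  # spontaneous: per-trial rate in the pre-stimulus span, pooled over cells
  spont <- dt[t_ms >= -pre_ms & t_ms < 0,
              .N, by = list(freq_khz, level_db, trial)]
  spont <- spont[full, on = c("freq_khz", "level_db", "trial")]
  spont[is.na(spont$N), "N"] <- 0L
  sp_rates <- spont$N / (pre_ms / 1000)

  missing_frac <- mean(is.na(rate))
  if (missing_frac > 0.2)
    stop("more than 20% of FRA cells are missing")
  structure(
    list(rate_hz = rate, n = nmat,
         spont_mean_hz = mean(sp_rates), spont_sd_hz = stats::sd(sp_rates),
         freqs_khz = freqs_khz, levels_db = levels_db,
         incomplete = missing_frac > 0),
    class = "fra"
  )
}

#' Characteristic frequency from a frequency response area
#'
#' A cell is responsive when its mean rate exceeds the spontaneous mean
#' plus `criterion_k` spontaneous SD. The characteristic frequency (CF)
#' is the frequency responsive at the lowest level; when several
#' frequencies are responsive at that level the one with the highest rate
#' wins (deterministic tie-break). A CF falling on the first or last grid
#' frequency is indeterminate (the tuning tip may lie outside the tested
#' range) and is flagged non-responsive under the default
#' `edge_policy = "exclude"`.
#'
#' @param fra a [build_fra()] result.
#' @param criterion_k SD multiplier of the responsiveness criterion.
#' @param edge_policy `"exclude"` (default) or `"keep"` grid-edge CFs.
#' @return a list (`tuning_result`): `cf_khz`, `threshold_db`,
#'   `responsive`.
#' @export
characteristic_frequency <- function(fra, criterion_k = 3,
                                     edge_policy = c("exclude", "keep")) {
  stopifnot(inherits(fra, "fra"))
  edge_policy <- match.arg(edge_policy)
  sdv <- fra$spont_sd_hz
  if (!is.finite(sdv) || sdv == 0) sdv <- 1e-9
  crit <- fra$spont_mean_hz + criterion_k * sdv
  resp <- !is.na(fra$rate_hz) & fra$rate_hz > crit
  none <- list(cf_khz = NA_real_, threshold_db = NA_real_,
               responsive = FALSE)
  if (!any(resp)) return(structure(none, class = "tuning_result"))
  li <- which(colSums(resp) > 0)[1]
  fi_cand <- which(resp[, li])
  fi <- fi_cand[which.max(fra$rate_hz[fi_cand, li])]
  if (edge_policy == "exclude" &&
      (fi == 1 || fi == length(fra$freqs_khz)))
    return(structure(none, class = "tuning_result"))
  structure(list(cf_khz = fra$freqs_khz[fi],
                 threshold_db = fra$levels_db[li], responsive = TRUE),
            class = "tuning_result")
}

#' Per-electrode tuning table for one animal
#'
#' Convenience wrapper running [build_fra()] and
#' [characteristic_frequency()] on every electrode of a simulated or
#' recorded acoustic dataset.
#'
#' @param spikes SpikeTable for one animal ([simulate_fra_dataset()]
#'   output).
#' @param geometry a [recording_geometry()].
#' @inheritParams build_fra
#' @inheritParams characteristic_frequency
#' @return `data.frame` with `electrode`, `depth_mm`, `cf_khz`,
#'   `threshold_db`, `responsive`.
#' @export
animal_tuning_table <- function(spikes, geometry = recording_geometry(),
                                n_trials = NULL, tone_ms = 100,
                                pre_ms = 50, criterion_k = 3,
                                edge_policy = "exclude") {
  depths <- electrode_depths(geometry)
  freqs <- sort(unique(spikes$freq_khz))
  levels <- sort(unique(spikes$level_db))
  if (is.null(n_trials)) n_trials <- max(spikes$trial)
  rows <- lapply(seq_len(geometry$n_electrodes), function(e) {
    sl <- spikes[spikes$electrode == e, , drop = FALSE]
    fra <- build_fra(sl, freqs, levels, n_trials, tone_ms, pre_ms)
    tr <- characteristic_frequency(fra, criterion_k, edge_policy)
    data.frame(electrode = e, depth_mm = depths[e], cf_khz = tr$cf_khz,
               threshold_db = tr$threshold_db, responsive = tr$responsive)
  })
  do.call(rbind, rows)
}

#' Fit the tonotopic slope of one animal
#'
#' Least-squares fit of `log2(cf)` on recording depth (mm) over the
#' responsive electrodes; the slope is reported in octaves/mm and is
#' positive when CF increases with depth. At least 3 responsive
#' electrodes are required for a valid fit.
#'
#' @param tuning a `data.frame` with columns `depth_mm`, `cf_khz` and
#'   `responsive` (see [animal_tuning_table()]).
#' @param animal_id identifier carried into the result.
#' @return a list (`tonotopic_fit`): `slope_oct_per_mm`, `intercept_oct`,
#'   `pearson_r`, `n_points`, `valid`, `animal_id`.
#' @export
fit_tonotopic_slope <- function(tuning, animal_id = NA_character_) {
  ok <- tuning$responsive & !is.na(tuning$cf_khz)
  n <- sum(ok)
  if (n < 3) {
    return(structure(list(slope_oct_per_mm = NA_real_,
                          intercept_oct = NA_real_, pearson_r = NA_real_,
                          n_points = n, valid = FALSE,
                          animal_id = animal_id),
                     class = "tonotopic_fit"))
  }
  x <- tuning$depth_mm[ok]
  y <- log2(tuning$cf_khz[ok])
  fit <- stats::lm.fit(cbind(1, x), y)
  r <- if (stats::sd(y) == 0 || stats::sd(x) == 0) 0 else
    stats::cor(x, y)
  structure(list(slope_oct_per_mm = unname(fit$coefficients[2]),
                 intercept_oct = unname(fit$coefficients[1]),
                 pearson_r = r, n_points = n, valid = TRUE,
                 animal_id = animal_id),
            class = "tonotopic_fit")
}

#' Cohort summary of tonotopic slopes
#'
#' Median and raw median absolute deviation over the valid per-animal
#' fits. Deaf animals cannot be mapped acoustically: they are excluded
#' from fitting and are later assigned the hearing-cohort median slope
#' for spatial-to-spectral conversion.
#'
#' @param fits list of [fit_tonotopic_slope()] results.
#' @return list with `median_oct_per_mm`, `mad_oct_per_mm`, `n`,
#'   `slopes`.
#' @export
cohort_slope_summary <- function(fits) {
  slopes <- vapply(fits, function(f) {
    stopifnot(inherits(f, "tonotopic_fit"))
    if (isTRUE(f$valid)) f$slope_oct_per_mm else NA_real_
  }, numeric(1))
  slopes <- slopes[!is.na(slopes)]
  if (length(slopes) == 0) stop("no valid tonotopic fits")
  list(median_oct_per_mm = stats::median(slopes),
       mad_oct_per_mm = stats::mad(slopes, constant = 1),
       n = length(slopes), slopes = slopes)
}
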