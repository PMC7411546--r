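#' Response matrix from explicit counts
#'
#' Constructs the trials x electrodes x intensities count container
#' directly; used for hand-built cases and by
#' [build_response_matrix()]. Means and SDs (n-1 denominator) per
#' (electrode, intensity) cell are precomputed.
#'
#' @param counts 3-D array `[trial, electrode, intensity]` of
#'   response-window spike counts.
#' @param intensities intensity axis; the first entry must be 0 (the
#'   baseline condition).
#' @return an object of class `response_matrix`.
#' @export
response_matrix <- function(counts, intensities) {
  stopifnot(is.array(counts), length(dim(counts)) == 3,
            dim(counts)[3] == length(intensities))
  if (intensities[1] != 0)
    stop("the intensity axis must start at 0 (baseline)")
  if (any(counts < 0)) stop("counts must be non-negative")
  structure(
    list(counts = counts, intensities = intensities,
         n_trials = dim(counts)[1], n_electrodes = dim(counts)[2],
         mean = apply(counts, c(2, 3), mean),
         sd = apply(counts, c(2, 3), stats::sd)),
    class = "response_matrix"
  )
}

#' Build a response matrix from a spike table
#'
#' Sorts multi-unit activity in the response window into the
#' two-dimensional (recording site x stimulus intensity) matrix of
#' trial-wise counts.
#'
#' @param spikes SpikeTable for one stimulation condition (columns
#'   `intensity`, `trial`, `electrode`, `t_ms`).
#' @param ladder the [stimulus_ladder()] that produced the trials (its
#'   intensity axis and trial count define the matrix even for
#'   electrode/intensity cells without spikes).
#' @param win a [response_window()].
#' @param n_electrodes number of recording sites.
#' @return a [response_matrix()].
#' @export
build_response_matrix <- function(spikes, ladder, win = response_window(),
                                  n_electrodes = 32) {
  stopifnot(inherits(ladder, "stimulus_ladder"),
            inherits(win, "response_window"))
  if (!any(spikes$intensity == 0) && !0 %in% ladder$intensities)
    stop("zero-intensity baseline trials are required")
  n_tr <- ladder$n_trials_per_step
  ints <- ladder$intensities
  dt <- data.table::as.data.table(spikes)
  t_ms <- NULL; intensity <- NULL # NSE notes
  cnt <- dt[t_ms >= win$start_ms & t_ms < win$end_ms,
            .N, by = list(intensity, trial, electrode)]
  counts <- array(0L, dim = c(n_tr, n_electrodes, length(ints)))
  if (nrow(cnt) > 0) {
    ii <- match(cnt$intensity, ints)
    if (anyNA(ii)) stop("spike table contains intensities not on the ladder")
    counts[cbind(cnt$trial, cnt$electrode, ii)] <- cnt$N
  }
  response_matrix(counts, ints)
}

#' Cumulative d-prime matrix
#'
#' Per electrode, the step increment from intensity i-1 to i is
#' `(mu_i - mu_{i-1}) / max(sqrt((sd_i^2 + sd_{i-1}^2) / 2), var_floor)`,
#' capped at `|increment| <= cap`, and the cumulative d' is the running
#' sum starting from 0 at zero intensity. The pooled-SD convention makes
#' a rise of one SD over baseline a d' of exactly 1 when the two cells
#' share the same SD. Negative increments (suppression) are retained in
#' the raw cumulative trace; a copy floored at 0 is kept for contouring
#' and thresholds, which are excitation-defined.
#'
#' @param rm a [response_matrix()].
#' @param var_floor lower bound on the pooled SD (spikes/window);
#'   prevents unbounded d' from zero-variance cells.
#' @param cap bound on any single increment's magnitude.
#' @return an object of class `dprime_matrix` with `dprime` (floored,
#'   electrodes x intensities), `dprime_raw`, `increments`,
#'   `intensities`.
#' @export
cumulative_dprime <- function(rm, var_floor = 0.5, cap = 5) {
  stopifnot(inherits(rm, "response_matrix"))
  if (length(rm$intensities) < 2)
    stop("at least 2 intensity steps are required")
  mu <- rm$mean
  sd <- rm$sd
  n_int <- ncol(mu)
  pooled <- sqrt((sd[, -1, drop = FALSE]^2 +
                  sd[, -n_int, drop = FALSE]^2) / 2)
  pooled <- pmax(pooled, var_floor)
  inc <- (mu[, -1, drop = FALSE] - mu[, -n_int, drop = FALSE]) / pooled
  inc <- pmin(pmax(inc, -cap), cap)
  cum <- cbind(0, t(apply(inc, 1, cumsum)))
  dimnames(cum) <- list(NULL, rm$intensities)
  structure(
    list(dprime = pmax(cum, 0), dprime_raw = cum, increments = inc,
         intensities = rm$intensities, n_electrodes = nrow(cum)),
    class = "dprime_matrix"
  )
}

#' Construct a d-prime matrix from explicit values
#'
#' For hand-built spatial tuning curves (e.g. worked examples); the usual
#' entry point is [cumulative_dprime()].
#'
#' @param dprime electrodes x intensities matrix of cumulative d' values
#'   (first column must be 0: the zero-intensity baseline).
#' @param intensities intensity axis starting at 0.
#' @return an object of class `dprime_matrix`.
#' @export
dprime_matrix <- function(dprime, intensities) {
  dprime <- as.matrix(dprime)
  stopifnot(ncol(dprime) == length(intensities), intensities[1] == 0)
  if (any(dprime[, 1] != 0))
    stop("cumulative d' must be 0 at zero intensity")
  structure(
    list(dprime = pmax(dprime, 0), dprime_raw = dprime,
         increments = t(apply(dprime, 1, diff)),
         intensities = intensities, n_electrodes = nrow(dprime)),
    class = "dprime_matrix"
  )
}

# first upward crossing of `level` along (x, y); linear interpolation
.first_crossing <- function(x, y, level) {
  if (y[1] >= level) return(x[1])
  for (i in seq_len(length(y) - 1)) {
    if (y[i] < level && y[i + 1] >= level) {
      return(x[i] + (level - y[i]) / (y[i + 1] - y[i]) *
               (x[i + 1] - x[i]))
    }
  }
  NA_real_
}

# d-prime of every electrode at an arbitrary intensity (linear interp)
.dprime_at_intensity <- function(dp, intensity) {
  apply(dp$dprime, 1, function(y)
    stats::approx(dp$intensities, y, xout = intensity, rule = 2)$y)
}

#' Spatial tuning curve
#'
#' Per-electrode activation thresholds (interpolated intensity at which
#' the cumulative d' first crosses 1), the best electrode (BE; lowest
#' threshold, ties broken by higher maximal d', then by the more dorsal
#' index), the maximal d', the active-electrode count, and iso-contour
#' polylines at d' levels 1, 1.5, 2, ... computed on the (electrode x
#' intensity) grid with the electrode axis linearly interpolated at
#' half-electrode resolution.
#'
#' @param dp a [cumulative_dprime()] result.
#' @param contour_levels d' levels for the iso-contours.
#' @return an object of class `stc`: `thresholds` (per electrode, NA if
#'   never crossing 1), `best_electrode` (NA when no electrode crosses),
#'   `be_threshold`, `max_dprime`, `n_active`, `contours` (`data.frame`
#'   of `level`, `electrode`, `intensity`), `dp`.
#' @export
build_stc <- function(dp, contour_levels = NULL) {
  stopifnot(inherits(dp, "dprime_matrix"))
  maxd <- max(dp$dprime)
  if (is.null(contour_levels)) {
    contour_levels <- if (maxd >= 1) seq(1, floor(maxd * 2) / 2, by = 0.5)
                      else numeric(0)
  }
  thr <- apply(dp$dprime, 1, function(y)
    .first_crossing(dp$intensities, y, 1))
  n_active <- sum(apply(dp$dprime, 1, max) >= 1)
  be <- NA_integer_
  if (any(!is.na(thr))) {
    cand <- which(thr == min(thr, na.rm = TRUE))
    if (length(cand) > 1) {
      mx <- apply(dp$dprime[cand, , drop = FALSE], 1, max)
      cand <- cand[mx == max(mx)]
    }
    be <- cand[1]  # most dorsal among remaining ties
  }
  # contours on the half-electrode grid
  el_fine <- seq(1, dp$n_electrodes, by = 0.5)
  contours <- NULL
  if (length(contour_levels) > 0 && dp$n_electrodes >= 2) {
    surf <- apply(dp$dprime, 2, function(col)
      stats::approx(seq_len(dp$n_electrodes), col, xout = el_fine)$y)
    rows <- lapply(contour_levels, function(lv) {
      ints <- apply(surf, 1, function(y)
        .first_crossing(dp$intensities, y, lv))
      data.frame(level = lv, electrode = el_fine, intensity = ints)
    })
    contours <- do.call(rbind, rows)
    contours <- contours[!is.na(contours$intensity), , drop = FALSE]
    rownames(contours) <- NULL
  }
  structure(
    list(thresholds = thr, best_electrode = be,
         be_threshold = if (is.na(be)) NA_real_ else thr[be],
         max_dprime = maxd, n_active = n_active,
         contours = contours, dp = dp),
    class = "stc"
  )
}

#' Spread of excitation
#'
#' For each criterion d', finds the interpolated intensity at which the
#' best electrode's cumulative d' reaches the criterion, takes the set of
#' electrodes whose d' at that intensity is at least 1, and reports the
#' span between the dorsal-most and ventral-most member (outermost-bound
#' rule: sub-threshold electrodes inside the span are bridged to avoid
#' underestimating multi-peaked tuning curves).
#'
#' @param stc a [build_stc()] result.
#' @param criteria criterion d' values at the best electrode.
#' @param pitch_mm electrode pitch used to convert the electrode span to
#'   mm.
#' @return `data.frame` with one row per criterion: `criterion`,
#'   `achieved`, `intensity`, `dorsal`, `ventral`, `span_mm`.
#' @export
spread_of_excitation <- function(stc, criteria = c(1.5, 2, 2.5, 3),
                                 pitch_mm = 0.05) {
  stopifnot(inherits(stc, "stc"))
  dp <- stc$dp
  be <- stc$best_electrode
  if (is.na(be)) stop("spread of excitation requires a defined best electrode")
  be_curve <- dp$dprime[be, ]
  rows <- lapply(criteria, function(cr) {
    none <- data.frame(criterion = cr, achieved = FALSE,
                       intensity = NA_real_, dorsal = NA_integer_,
                       ventral = NA_integer_, span_mm = NA_real_)
    icr <- .first_crossing(dp$intensities, be_curve, cr)
    if (is.na(icr)) return(none)
    d_at <- .dprime_at_intensity(dp, icr)
    resp <- which(d_at >= 1)
    if (length(resp) == 0) return(none)
    data.frame(criterion = cr, achieved = TRUE, intensity = icr,
               dorsal = min(resp), ventral = max(resp),
               span_mm = (max(resp) - min(resp)) * pitch_mm)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count active electrodes
#'
#' Electrodes whose maximal cumulative d' reaches at least 1 anywhere on
#' the intensity ladder.
#'
#' @param dp a [cumulative_dprime()] result.
#' @return integer count.
#' @export
count_active_electrodes <- function(dp) {
  stopifnot(inherits(dp, "dprime_matrix"))
  sum(apply(dp$dprime, 1, max) >= 1)
}

#' Qualify an implant's tuning curves for tonotopy analysis
#'
#' An implant enters the place-code analysis only when spatial tuning
#' curves from at least two different emitters each reach threshold at a
#' minimum of 3 electrodes and attain a maximal d' of 1.5 or more.
#'
#' @param stcs list of per-emitter [build_stc()] results.
#' @param min_emitters,min_electrodes,min_dprime the qualification rule.
#' @return logical inclusion flag (attribute `n_qualifying` carries the
#'   qualifying-emitter count).
#' @export
qualify_stc <- function(stcs, min_emitters = 2, min_electrodes = 3,
                        min_dprime = 1.5) {
  ok <- vapply(stcs, function(s) {
    stopifnot(inherits(s, "stc"))
    sum(!is.na(s$thresholds)) >= min_electrodes &&
      s$max_dprime >= min_dprime
  }, logical(1))
  structure(sum(ok) >= min_emitters, n_qualifying = sum(ok))
}
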