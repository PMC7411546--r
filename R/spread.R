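#' Normalize best-electrode positions across emitters
#'
#' Expresses each responsive emitter's cochlear place relative to the
#' apical-most responsive emitter on the implant, and its best electrode
#' relative to that reference emitter's best electrode. The reference
#' maps to the point (0, 0); positions grow towards the base and
#' best-electrode shifts grow ventrally, so a basal emitter exciting a
#' more ventral (higher-frequency) ICC region gives positive
#' coordinates. Negative shifts can appear when a more basal emitter has
#' a more dorsal best electrode.
#'
#' @param be_table `data.frame` with columns `emitter` (index),
#'   `position_mm` (cochlear place of the emitter) and `best_electrode`
#'   (NA when the emitter evoked no thresholded response); optional
#'   columns `animal_id` and `emitter_mode` are carried through.
#' @return `data.frame` of place-code points: `emitter_position_mm`
#'   (relative, >= 0 towards the base), `relative_be_electrodes`, plus
#'   any carried columns; zero rows when fewer than one emitter is
#'   responsive.
#' @export
normalize_be_positions <- function(be_table) {
  need <- c("emitter", "position_mm", "best_electrode")
  if (!all(need %in% names(be_table)))
    stop("be_table must carry columns: ", paste(need, collapse = ", "))
  ok <- !is.na(be_table$best_electrode)
  tb <- be_table[ok, , drop = FALSE]
  if (nrow(tb) == 0) return(tb[0, , drop = FALSE])
  ref <- which.max(tb$position_mm)  # apical-most responsive emitter
  tb$emitter_position_mm <- tb$position_mm[ref] - tb$position_mm
  tb$relative_be_electrodes <- tb$best_electrode - tb$best_electrode[ref]
  rownames(tb) <- NULL
  tb
}

#' Fit the tonotopic place code
#'
#' Least-squares regression of the relative best-electrode shift on the
#' relative stimulus place, with Pearson correlation and two-sided
#' p-value. The slope is in electrodes per millimetre of cochlear place.
#'
#' @param points `data.frame` from [normalize_be_positions()] (possibly
#'   pooled over animals), with columns `emitter_position_mm` and
#'   `relative_be_electrodes`.
#' @return a list (`place_code_fit`): `slope_electrodes_per_mm`,
#'   `intercept`, `pearson_r`, `p_value`, `n_points`.
#' @export
fit_place_code <- function(points) {
  need <- c("emitter_position_mm", "relative_be_electrodes")
  if (!all(need %in% names(points)))
    stop("points must carry columns: ", paste(need, collapse = ", "))
  x <- points$emitter_position_mm
  y <- points$relative_be_electrodes
  if (length(x) < 3) stop("at least 3 place-code points are required")
  if (stats::sd(x) == 0)
    stop("degenerate stimulus places: all emitters at one location")
  fit <- stats::lm.fit(cbind(1, x), y)
  ct <- stats::cor.test(x, y)
  structure(list(slope_electrodes_per_mm = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1]),
                 pearson_r = unname(ct$estimate),
                 p_value = ct$p.value, n_points = length(x)),
            class = "place_code_fit")
}

#' Convert a spatial span to spectral spread
#'
#' Octaves spanned = span in mm along the probe times the animal's
#' tonotopic slope (octaves/mm). Deaf animals cannot be mapped
#' acoustically and use the hearing-cohort median slope.
#'
#' @param span_mm spatial span along the recording probe in mm.
#' @param slope_oct_per_mm a positive tonotopic slope, either a number or
#'   a [fit_tonotopic_slope()] result.
#' @return spread in octaves.
#' @export
spatial_to_spectral <- function(span_mm, slope_oct_per_mm) {
  if (inherits(slope_oct_per_mm, "tonotopic_fit"))
    slope_oct_per_mm <- slope_oct_per_mm$slope_oct_per_mm
  if (is.null(slope_oct_per_mm) || length(slope_oct_per_mm) != 1 ||
      is.na(slope_oct_per_mm))
    stop("a tonotopic slope is required (deaf animals use the ",
         "hearing-cohort median)")
  if (slope_oct_per_mm <= 0) stop("the tonotopic slope must be positive")
  span_mm * slope_oct_per_mm
}

#' Convert a best-electrode shift to micrometres
#'
#' @param shift_electrodes shift in electrode indices.
#' @param geometry a [recording_geometry()].
#' @return shift in um.
#' @export
electrodes_to_um <- function(shift_electrodes,
                             geometry = recording_geometry()) {
  stopifnot(inherits(geometry, "recording_geometry"))
  shift_electrodes * geometry$pitch_mm * 1000
}

#' Implant coverage of the cochlea
#'
#' Span = (n_emitters - 1) x pitch; coverage is the percentage of the
#' scala tympani length, reported to one decimal.
#'
#' @param layout an [emitter_layout()].
#' @param model a [cochlear_model()].
#' @return list with `span_mm` and `percent_of_cochlea`.
#' @export
coverage_stats <- function(layout = emitter_layout(),
                           model = cochlear_model()) {
  stopifnot(inherits(layout, "emitter_layout"),
            inherits(model, "cochlear_model"))
  span <- (layout$n_emitters - 1) * layout$pitch_mm
  list(span_mm = span,
       percent_of_cochlea = round(100 * span / model$length_mm, 1))
}

#' Optical pulse energy
#'
#' @param power_mw radiant flux in mW.
#' @param duration_ms pulse duration in ms.
#' @return energy in uJ (`mW x ms`).
#' @export
pulse_energy <- function(power_mw, duration_ms) {
  stopifnot(all(power_mw >= 0), all(duration_ms >= 0))
  power_mw * duration_ms
}

#' Published electrical-CI spread-of-excitation reference values
#'
#' Spectral spread (octaves) at criterion d' 1.5/2/2.5/3 for monopolar
#' and bipolar electrical stimulation with a clinical-style implant, and
#' for acoustic and fiber-based optical stimulation, reprinted from a
#' prior published study for comparison plots only. These are published
#' constants, not quantities recomputed by this package.
#'
#' @return `data.frame` with `mode`, `criterion`, `spread_octaves`.
#' @export
eci_reference_spread <- function() {
  data.frame(
    mode = rep(c("monopolar_eci", "bipolar_eci", "acoustic", "fiber"),
               each = 4),
    criterion = rep(c(1.5, 2, 2.5, 3), 4),
    spread_octaves = c(2.06, 4.92, 6.91, 7.29,
                       0.67, 3.90, 5.89, 6.96,
                       0.89, 1.42, 1.73, 2.23,
                       1.07, 1.89, 2.96, 3.57)
  )
}
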