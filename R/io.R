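#' Read a spike table from CSV
#'
#' The on-disk schema is `animal_id, condition, emitter_set, intensity,
#' trial, electrode, t_ms` (times in ms relative to stimulus onset,
#' electrode index 1-based with 1 = most dorsal). Extra columns (e.g.
#' `freq_khz`, `level_db` for acoustic data) are preserved. Rows may
#' arrive in any order and are canonically sorted.
#'
#' @param path CSV file path.
#' @return a SpikeTable `data.frame`.
#' @export
read_spike_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.spike_cols, names(df))
  if (length(missing_cols) > 0)
    stop("spike table ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!is.numeric(df$t_ms) || !is.numeric(df$intensity))
    stop("columns t_ms and intensity must be numeric in ", path)
  df$trial <- as.integer(df$trial)
  df$electrode <- as.integer(df$electrode)
  df$emitter_set <- as.character(df$emitter_set)
  df$intensity <- as.numeric(df$intensity)
  df$t_ms <- as.numeric(df$t_ms)
  .sort_spike_table(df)
}

#' Write a spike table to CSV
#'
#' @param table a SpikeTable `data.frame`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_spike_table <- function(table, path) {
  missing_cols <- setdiff(.spike_cols, names(table))
  if (length(missing_cols) > 0)
    stop("spike table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  utils::write.csv(.sort_spike_table(table), path, row.names = FALSE)
  invisible(path)
}

#' Read a run configuration
#'
#' Configurations are JSON (keys mirror the constructor arguments of the
#' domain types); a plain R list is accepted as-is. Unset keys fall back
#' to the defaults below.
#'
#' @param config path to a JSON file or a named list.
#' @return a complete configuration list.
#' @export
read_run_config <- function(config = list()) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  stopifnot(is.list(config))
  defaults <- list(
    seed = 1L,
    n_animals = 3L,
    hearing_status = "hearing",
    pitch_mm = 0.25,
    insertion_depth_mm = 0.5,
    n_emitters = 16L,
    single_emitters = c(2L, 6L, 10L, 14L),
    optical_intensities = c(0, 0.5, 1, 2, 4, 7, 10),
    all_intensities = c(0, 2, 4, 8, 16, 28, 40),
    n_trials_optical = 20L,
    n_trials_acoustic = 25L,
    window = c(3, 20),
    criteria = c(1.5, 2, 2.5, 3),
    mad_k = 3,
    band_hz = c(600, 6000)
  )
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  config
}

#' Run the full synthetic-experiment pipeline
#'
#' Chains simulate -> tonotopic calibration -> response matrices ->
#' cumulative d-prime / spatial tuning curves -> spread of excitation ->
#' place-code regression, and writes a report bundle (CSV tables, the
#' effective configuration and a checksum manifest) to `out_dir`.
#' Deterministic for a fixed seed: re-running with the same configuration
#' produces byte-identical files. Deaf animals skip the acoustic stage
#' and are assigned the hearing-cohort median tonotopic slope (or the
#' default gradient when no hearing animal is present).
#'
#' @param config configuration list or JSON path, see
#'   [read_run_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the main results (`slopes`, `summary`,
#'   `stc_summary`, `spread`, `place_fit`, `manifest`).
#' @export
run_pipeline <- function(config = list(), out_dir) {
  cfg <- read_run_config(config)
  if (missing(out_dir)) stop("out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (cfg$n_animals < 1) stop("empty cohort: n_animals must be >= 1")

  model <- cochlear_model()
  probe <- recording_geometry()
  layout <- emitter_layout(n_emitters = cfg$n_emitters,
                           pitch_mm = cfg$pitch_mm,
                           insertion_depth_mm = cfg$insertion_depth_mm)
  win <- response_window(cfg$window[1], cfg$window[2])
  spec <- cohort_spec(cfg$n_animals, cfg$hearing_status, seed = cfg$seed)
  animals <- simulate_animal_params(spec)

  # --- stage 1: acoustic calibration (hearing animals only) -----------
  tuning_rows <- list(); fits <- list()
  for (an in animals) {
    if (an$status %in% c("hearing", "wildtype_hearing")) {
      fra_tab <- simulate_fra_dataset(model, probe, an$act,
                                      n_trials = cfg$n_trials_acoustic,
                                      seed = an$seed,
                                      animal_id = an$animal_id,
                                      status = an$status)
      tuning <- animal_tuning_table(fra_tab, probe,
                                    n_trials = cfg$n_trials_acoustic)
      tuning$animal_id <- an$animal_id
      tuning_rows[[an$animal_id]] <- tuning
      fits[[an$animal_id]] <- fit_tonotopic_slope(tuning, an$animal_id)
    }
  }
  valid_fits <- Filter(function(f) isTRUE(f$valid), fits)
  summary <- if (length(valid_fits) > 0) cohort_slope_summary(valid_fits)
             else list(median_oct_per_mm = activation_model()$
                         tonotopic_slope_oct_per_mm,
                       mad_oct_per_mm = NA_real_, n = 0L,
                       slopes = numeric(0))
  slope_for <- function(id) {
    f <- fits[[id]]
    if (!is.null(f) && isTRUE(f$valid)) f$slope_oct_per_mm
    else summary$median_oct_per_mm  # deaf animals: hearing-cohort median
  }

  # --- stage 2: optical stimulation, STCs, spread, place code ---------
  stc_rows <- list(); spread_rows <- list(); pc_points <- list()
  pos <- emitter_positions(layout, model)
  for (an in animals) {
    conds <- c(
      lapply(cfg$single_emitters, function(e)
        list(kind = "single_led", set = as.integer(e),
             ints = cfg$optical_intensities,
             label = sprintf("single_%02d", e))),
      list(list(kind = "all_leds", set = seq_len(cfg$n_emitters),
                ints = cfg$all_intensities, label = "all_leds"))
    )
    be_tab <- NULL
    for (i in seq_along(conds)) {
      cd <- conds[[i]]
      ladder <- stimulus_ladder(cd$kind, cd$ints,
                                n_trials_per_step = cfg$n_trials_optical)
      tab <- simulate_optical_trials(model, layout, an$act, ladder,
                                     active_set = cd$set,
                                     seed = (an$seed + 131L * i) %%
                                       .Machine$integer.max,
                                     probe = probe,
                                     animal_id = an$animal_id,
                                     condition = cd$label,
                                     status = an$status)
      rmx <- build_response_matrix(tab, ladder, win, probe$n_electrodes)
      dp <- cumulative_dprime(rmx)
      stc <- build_stc(dp)
      stc_rows[[paste(an$animal_id, cd$label)]] <- data.frame(
        animal_id = an$animal_id, condition = cd$label,
        status = an$status, max_dprime = stc$max_dprime,
        n_active = stc$n_active, best_electrode = stc$best_electrode,
        be_threshold = stc$be_threshold)
      if (!is.na(stc$best_electrode)) {
        soe <- spread_of_excitation(stc, cfg$criteria, probe$pitch_mm)
        soe$span_octaves <- ifelse(
          soe$achieved,
          spatial_to_spectral(ifelse(is.na(soe$span_mm), 0, soe$span_mm),
                              slope_for(an$animal_id)), NA_real_)
        soe$animal_id <- an$animal_id
        soe$condition <- cd$label
        spread_rows[[paste(an$animal_id, cd$label)]] <- soe
      }
      if (cd$kind == "single_led") {
        be_tab <- rbind(be_tab, data.frame(
          emitter = cd$set, position_mm = pos[cd$set],
          best_electrode = stc$best_electrode,
          animal_id = an$animal_id, emitter_mode = "single"))
      }
    }
    if (!is.null(be_tab))
      pc_points[[an$animal_id]] <- normalize_be_positions(be_tab)
  }
  points <- do.call(rbind, pc_points)
  place_fit <- if (!is.null(points) && nrow(points) >= 3 &&
                   stats::sd(points$emitter_position_mm) > 0)
    fit_place_code(points) else NULL

  # --- stage 3: report bundle -----------------------------------------
  w <- function(x, f) {
    p <- file.path(out_dir, f)
    utils::write.csv(x, p, row.names = FALSE)
    p
  }
  files <- character(0)
  if (length(tuning_rows) > 0)
    files <- c(files, w(do.call(rbind, tuning_rows), "tuning.csv"))
  slopes_df <- do.call(rbind, lapply(fits, function(f)
    data.frame(animal_id = f$animal_id, slope = f$slope_oct_per_mm,
               intercept = f$intercept_oct, r = f$pearson_r,
               n = f$n_points)))
  if (!is.null(slopes_df)) files <- c(files, w(slopes_df, "slopes.csv"))
  files <- c(files, w(do.call(rbind, stc_rows), "stc_summary.csv"))
  if (length(spread_rows) > 0)
    files <- c(files, w(do.call(rbind, spread_rows), "spread.csv"))
  if (!is.null(points)) files <- c(files, w(points, "place_code_points.csv"))
  if (!is.null(place_fit))
    files <- c(files, w(data.frame(
      slope_electrodes_per_mm = place_fit$slope_electrodes_per_mm,
      pearson_r = place_fit$pearson_r, p_value = place_fit$p_value,
      n_points = place_fit$n_points), "place_code_fit.csv"))
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, cfg_path)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  manifest <- manifest[order(manifest$file), , drop = FALSE]
  rownames(manifest) <- NULL
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(list(slopes = slopes_df, summary = summary,
                 stc_summary = do.call(rbind, stc_rows),
                 spread = if (length(spread_rows) > 0)
                   do.call(rbind, spread_rows) else NULL,
                 place_fit = place_fit, manifest = manifest))
}
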