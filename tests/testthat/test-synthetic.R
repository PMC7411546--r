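small_grid <- default_fra_grid(f_lo_khz = 1, f_hi_khz = 16, step_oct = 0.5,
                               levels_db = c(0, 20, 40, 60))

test_that("generators are fully reproducible under a fixed seed", {
  a <- simulate_fra_dataset(grid = small_grid, n_trials = 5, seed = 17)
  b <- simulate_fra_dataset(grid = small_grid, n_trials = 5, seed = 17)
  expect_identical(a, b)

  lad <- stimulus_ladder("single_led", c(0, 5, 10), n_trials_per_step = 5)
  x <- simulate_optical_trials(ladder = lad, active_set = 8L, seed = 23)
  y <- simulate_optical_trials(ladder = lad, active_set = 8L, seed = 23)
  expect_identical(x, y)

  t1 <- simulate_raw_trace(c(5, 10), 20, seed = 4)
  t2 <- simulate_raw_trace(c(5, 10), 20, seed = 4)
  expect_identical(t1$samples, t2$samples)
})

test_that("generative tonotopy follows the configured gradient exactly", {
  act <- activation_model()
  probe <- recording_geometry()
  cf <- electrode_cf(act, probe)
  d <- electrode_depths(probe)
  fit <- stats::lm(log2(cf) ~ d)
  expect_equal(unname(coef(fit)[2]), act$tonotopic_slope_oct_per_mm,
               tolerance = 1e-12)
  # electrodes 0.1 mm apart differ by exactly slope * 0.1 octaves
  expect_equal(log2(cf[3] / cf[1]),
               act$tonotopic_slope_oct_per_mm * (d[3] - d[1]),
               tolerance = 1e-12)
})

test_that("evoked FRA counts match the analytic Poisson mean within 3 SE", {
  act <- activation_model(fra_rate_max_hz = 80)
  probe <- recording_geometry(n_electrodes = 1)
  # tone at the electrode's best frequency, top level: full evoked rate
  bf <- electrode_cf(act, probe)[1]
  grid <- list(freqs_khz = bf * 2^seq(-1, 1, by = 0.5),
               levels_db = c(0, 30, 60))
  n_trials <- 200
  tab <- simulate_fra_dataset(probe = probe, act = act, grid = grid,
                              n_trials = n_trials, seed = 6)
  tip <- tab[abs(tab$freq_khz - bf) < 1e-9 & tab$level_db == 60 &
               tab$t_ms >= 0 & tab$t_ms < 100, ]
  counts <- tabulate(tip$trial, n_trials)
  # analytic mean in [0, 100): baseline everywhere + evoked from 5 ms on
  lam <- act$baseline_rate_hz * 0.1 + 80 * 0.095
  expect_lt(abs(mean(counts) - lam), 3 * sqrt(lam / n_trials))
})

test_that("deaf and wild-type-deaf animals give spontaneous acoustic activity only", {
  for (status in c("deaf", "wildtype_deaf")) {
    tab <- simulate_fra_dataset(grid = small_grid, n_trials = 30, seed = 8,
                                status = status)
    in_tone <- tab[tab$t_ms >= 0 & tab$t_ms < 100, ]
    hi <- in_tone[in_tone$level_db == 60, ]
    lo <- in_tone[in_tone$level_db == 0, ]
    n_cells <- 32 * length(small_grid$freqs_khz) * 30
    # evoked rate at the top level equals the baseline rate
    expect_equal(nrow(hi) / n_cells, nrow(lo) / n_cells, tolerance = 0.1)
  }
})

test_that("zero-intensity optical steps emit baseline activity only", {
  act <- activation_model()
  lad <- stimulus_ladder("single_led", c(0, 10), n_trials_per_step = 100)
  tab <- simulate_optical_trials(act = act, ladder = lad, active_set = 8L,
                                 seed = 12)
  base <- tab[tab$intensity == 0, ]
  rate <- nrow(base) / (100 * 32 * 0.05)  # trials x electrodes x 50 ms
  se <- sqrt(act$baseline_rate_hz / (100 * 32 * 0.05))
  expect_lt(abs(rate - act$baseline_rate_hz), 3 * se)
})

test_that("recruiting all emitters evokes more spikes than a single one", {
  win <- response_window()
  tally <- function(kind, set, top) {
    lad <- stimulus_ladder(kind, c(0, top), n_trials_per_step = 200)
    tab <- simulate_optical_trials(ladder = lad, active_set = set,
                                   seed = 33)
    hi <- tab[tab$intensity == top, ]
    sum(hi$t_ms >= win$start_ms & hi$t_ms < win$end_ms)
  }
  expect_gt(tally("all_leds", 1:16, 40), tally("single_led", 8L, 10))
})

test_that("broad fiber illumination drives nearly all recording sites", {
  lad <- stimulus_ladder("fiber", c(0, 1, 2, 5, 10, 20, 35),
                         n_trials_per_step = 20)
  tab <- simulate_optical_trials(ladder = lad, active_set = 1L, seed = 44)
  dp <- cumulative_dprime(build_response_matrix(tab, lad))
  expect_gte(count_active_electrodes(dp), 30)
})

test_that("optical responses match between hearing and deafened transduced animals", {
  lad <- stimulus_ladder("all_leds", c(0, 40), n_trials_per_step = 150)
  h <- simulate_optical_trials(ladder = lad, active_set = 1:16, seed = 51,
                               status = "hearing")
  d <- simulate_optical_trials(ladder = lad, active_set = 1:16, seed = 52,
                               status = "deaf")
  win <- response_window()
  counts <- function(tab) {
    hi <- tab[tab$intensity == 40 & tab$t_ms >= win$start_ms &
                tab$t_ms < win$end_ms, ]
    as.vector(table(factor(hi$electrode, 1:32), factor(hi$trial, 1:150)))
  }
  ks <- suppressWarnings(stats::ks.test(counts(h), counts(d)))
  expect_gt(ks$p.value, 0.01)
})

test_that("wild-type animals lack opsin responses; hearing ones show weak opto-acoustic effects", {
  lad <- stimulus_ladder("all_leds", c(0, 40), n_trials_per_step = 60)
  win <- response_window()
  rate_at_max <- function(status) {
    tab <- simulate_optical_trials(ladder = lad, active_set = 1:16,
                                   seed = 61, status = status)
    hi <- tab[tab$intensity == 40, ]
    sum(hi$t_ms >= win$start_ms & hi$t_ms < win$end_ms)
  }
  transduced <- rate_at_max("hearing")
  wt_hear <- rate_at_max("wildtype_hearing")
  wt_deaf <- rate_at_max("wildtype_deaf")
  expect_gt(transduced, 2 * wt_hear)  # opto-acoustic is much weaker
  expect_gt(wt_hear, wt_deaf)         # and requires intact hair cells
  # wild-type opto-acoustic responses are dorsally biased
  tab <- simulate_optical_trials(ladder = lad, active_set = 1:16,
                                 seed = 62, status = "wildtype_hearing")
  hi <- tab[tab$intensity == 40 & tab$t_ms >= win$start_ms &
              tab$t_ms < win$end_ms, ]
  expect_lt(mean(hi$electrode), 16)
})

test_that("generator preconditions are enforced", {
  expect_error(simulate_fra_dataset(grid = small_grid, n_trials = 5),
               "seed")
  bad_grid <- small_grid
  bad_grid$levels_db <- c(0, 40, 20)
  expect_error(simulate_fra_dataset(grid = bad_grid, n_trials = 5,
                                    seed = 1), "increasing")
  narrow <- list(freqs_khz = c(4, 5), levels_db = c(0, 30))
  expect_error(simulate_fra_dataset(grid = narrow, n_trials = 5, seed = 1),
               "2 octaves")
  lad <- stimulus_ladder("single_led", c(0, 10), n_trials_per_step = 2)
  deep <- emitter_layout(insertion_depth_mm = 10.9)
  expect_error(simulate_optical_trials(layout = deep, ladder = lad,
                                       active_set = 16L, seed = 1),
               "outside the cochlea")
  expect_error(stimulus_ladder("single_led", c(1, 2)), "exactly 0")
  expect_error(stimulus_ladder("single_led", c(0, 2, 2)), "increasing")
})

test_that("raw-trace synthesis honours its contract", {
  tr <- simulate_raw_trace(numeric(0), 10, noise_sd = 0, seed = 1)
  expect_true(all(tr$samples == 0))
  expect_warning(simulate_raw_trace(c(5, 5.1), 10, seed = 1), "overlap")

  truth <- seq(10, 55, by = 5)
  tr2 <- simulate_raw_trace(truth, 60, kernel = spike_kernel(amp = 10),
                            noise_sd = 1, seed = 2)
  st <- detect_spikes(tr2, filter = FALSE)
  sc <- score_detection(st, truth)
  expect_equal(sc$tp, 10)
  expect_equal(sc$fp, 0)
})

test_that("cohort parameter draws are seeded and respect hearing status", {
  spec <- cohort_spec(4, c("hearing", "deaf", "wildtype_hearing",
                           "wildtype_deaf"), seed = 5)
  a1 <- simulate_animal_params(spec)
  a2 <- simulate_animal_params(spec)
  expect_equal(vapply(a1, function(x) x$act$rate_max_hz, 1),
               vapply(a2, function(x) x$act$rate_max_hz, 1))
  expect_true(all(vapply(a1, function(x) x$seed, 1) < 2^31))
  expect_equal(a1[[3]]$act$transduction_profile(c(1, 5)), c(0, 0))
  expect_gt(a1[[1]]$act$transduction_profile(1), 0)
  expect_error(cohort_spec(3, "hearing"), "seed")
  expect_error(cohort_spec(2, "hard-of-hearing", seed = 1), "status")
})
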