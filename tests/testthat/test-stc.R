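test_that("response matrices record counts, means and SDs faithfully", {
  ints <- c(0, 2, 4)
  counts <- make_counts(5, 3, ints, function(e, k) rep(e + k, 5))
  rm <- response_matrix(counts, ints)
  expect_true(all(rm$sd == 0))           # all-equal counts
  expect_equal(rm$mean[2, 3], 2 + 3)
  expect_error(response_matrix(counts, c(1, 2, 4)), "start at 0")
  expect_error(response_matrix(-counts, ints), "non-negative")
})

test_that("matrix cells match a brute-force tally and ignore row order", {
  lad <- stimulus_ladder("single_led", c(0, 5, 10), n_trials_per_step = 6)
  tab <- simulate_optical_trials(ladder = lad, active_set = 8L, seed = 70)
  win <- response_window()
  rm <- build_response_matrix(tab, lad, win)
  for (e in c(1, 17, 32)) {
    for (k in 1:3) {
      for (tr in 1:6) {
        sel <- tab$electrode == e & tab$intensity == lad$intensities[k] &
          tab$trial == tr
        expect_equal(rm$counts[tr, e, k],
                     oracle_count(tab$t_ms[sel], 3, 20))
      }
    }
  }
  shuffled <- tab[sample(nrow(tab)), ]
  rm2 <- build_response_matrix(shuffled, lad, win)
  expect_equal(rm2$counts, rm$counts)
})

test_that("cumulative d-prime reproduces hand-computed values", {
  ints <- c(0, 2)
  # baseline mean 10, step mean 12, common SD 2 -> d' = 1 exactly
  base <- c(8, 8, 12, 12, 10)     # mean 10, sd exactly 2
  counts <- array(c(base, base + 2), dim = c(5, 1, 2))
  dp <- cumulative_dprime(response_matrix(counts, ints))
  expect_equal(unname(dp$dprime[1, ]), c(0, 1))

  # means (10, 12, 14), equal SDs -> cumulative (0, 1, 2)
  counts3 <- array(c(base, base + 2, base + 4), dim = c(5, 1, 3))
  dp3 <- cumulative_dprime(response_matrix(counts3, c(0, 1, 2)))
  expect_equal(unname(dp3$dprime[1, ]), c(0, 1, 2))

  # equal means everywhere -> identically 0
  flat <- array(rep(base, 3), dim = c(5, 1, 3))
  expect_true(all(cumulative_dprime(response_matrix(flat, c(0, 1, 2)))$
                    dprime == 0))

  expect_error(cumulative_dprime(response_matrix(
    array(base, dim = c(5, 1, 1)), 0)), "2 intensity steps")
})

test_that("d-prime is location-free and scales with the mean separation", {
  set.seed(80)
  ints <- c(0, 1, 2, 3)
  counts <- make_counts(10, 4, ints, function(e, k)
    rpois(10, 2 + e * k))
  rm1 <- response_matrix(counts, ints)
  rm2 <- response_matrix(counts + 7, ints)     # constant added everywhere
  expect_equal(cumulative_dprime(rm1)$dprime_raw,
               cumulative_dprime(rm2)$dprime_raw)

  # scaling the mean separation by c at fixed SD scales increments by c
  base <- c(8, 8, 12, 12, 10)
  mk <- function(step) response_matrix(
    array(c(base, base + step), dim = c(5, 1, 2)), c(0, 1))
  i1 <- cumulative_dprime(mk(1))$increments[1, 1]
  i3 <- cumulative_dprime(mk(3))$increments[1, 1]
  expect_equal(i3, 3 * i1)
})

test_that("zero-variance cells hit the variance floor and the increment cap", {
  ints <- c(0, 1)
  counts <- array(c(rep(0, 5), rep(9, 5)), dim = c(5, 1, 2))
  dp <- cumulative_dprime(response_matrix(counts, ints))
  expect_equal(unname(dp$dprime[1, 2]), 5)  # capped: 9 / 0.5 -> 18 -> 5
})

test_that("STC thresholds interpolate linearly and find the best electrode", {
  # d' rising 0 -> 2 between intensities 2 and 4: crossing 1 at exactly 3
  dp <- dprime_matrix(rbind(c(0, 0, 2), c(0, 0.5, 1.5), c(0, 0, 0.5)),
                      c(0, 2, 4))
  stc <- build_stc(dp)
  expect_equal(stc$thresholds[1], 3)
  expect_equal(stc$thresholds[2], 3)        # 0.5 -> 1.5 crosses 1 at 3
  expect_true(is.na(stc$thresholds[3]))
  expect_equal(stc$n_active, 2)
  expect_equal(stc$best_electrode, 1L)       # tie on threshold: higher max d'
  expect_equal(stc$be_threshold, 3)

  # no electrode crossing 1: STC valid but thresholdless
  dp0 <- dprime_matrix(rbind(c(0, 0.2), c(0, 0.6)), c(0, 1))
  stc0 <- build_stc(dp0)
  expect_equal(stc0$n_active, 0)
  expect_true(is.na(stc0$best_electrode))

  # full tie: most dorsal electrode wins
  dpt <- dprime_matrix(rbind(c(0, 2), c(0, 2)), c(0, 1))
  expect_equal(build_stc(dpt)$best_electrode, 1L)
})

test_that("thresholds agree with a dense brute-force evaluation", {
  set.seed(81)
  for (rep in 1:5) {
    ints <- c(0, cumsum(runif(3, 0.5, 2)))
    d <- cbind(0, matrix(runif(4 * 3, 0, 3), 4, 3))
    d <- t(apply(d, 1, cummax))  # monotone surfaces for a clean oracle
    dp <- dprime_matrix(d, ints)
    stc <- build_stc(dp)
    fine <- seq(0, max(ints), length.out = 20001)
    for (e in 1:4) {
      y <- approx(ints, d[e, ], xout = fine)$y
      brute <- if (any(y >= 1)) fine[which(y >= 1)[1]] else NA_real_
      if (is.na(brute)) expect_true(is.na(stc$thresholds[e]))
      else expect_equal(stc$thresholds[e], brute, tolerance = 1e-3)
    }
    if (!is.na(stc$best_electrode))
      expect_equal(stc$be_threshold, min(stc$thresholds, na.rm = TRUE))
  }
})

test_that("spread of excitation spans the outermost responsive electrodes", {
  n_el <- 32
  mk <- function(responsive, be = 8) {
    # BE reaches d' 3 at the top intensity; responsive set holds d' >= 1
    d <- matrix(0, n_el, 3)
    d[responsive, 2] <- 1.4   # responsive from low intensities on
    d[responsive, 3] <- 1.6
    d[be, 2] <- 2             # lowest threshold, reaches d' 3.5
    d[be, 3] <- 3.5
    dprime_matrix(d, c(0, 5, 10))
  }
  # contiguous electrodes 5..12 -> (12 - 5) x 0.050 mm
  stc <- build_stc(mk(5:12))
  soe <- spread_of_excitation(stc, criteria = c(1.5, 2, 2.5, 3))
  expect_true(all(soe$achieved))
  expect_equal(soe$span_mm, rep(0.35, 4))
  # gap at electrode 9: outermost rule bridges it
  stc_gap <- build_stc(mk(c(5:8, 10:12)))
  soe_gap <- spread_of_excitation(stc_gap, criteria = 2)
  expect_equal(soe_gap$span_mm, 0.35)
  # single responsive electrode: zero span
  stc1 <- build_stc(mk(8))
  expect_equal(spread_of_excitation(stc1, criteria = 2)$span_mm, 0)
  # criterion never reached at the BE
  soe_na <- spread_of_excitation(stc1, criteria = 4)
  expect_false(soe_na$achieved)
  expect_true(is.na(soe_na$span_mm))
})

test_that("spread grows with the criterion on simulated tuning curves", {
  lad <- stimulus_ladder("all_leds", c(0, 2, 4, 8, 16, 28, 40),
                         n_trials_per_step = 20)
  ok <- 0
  for (seed in c(207, 211, 223)) {
    tab <- simulate_optical_trials(ladder = lad, active_set = 1:16,
                                   seed = seed)
    stc <- build_stc(cumulative_dprime(build_response_matrix(tab, lad)))
    if (is.na(stc$best_electrode)) next
    soe <- spread_of_excitation(stc, criteria = c(1.5, 3))
    if (all(soe$achieved)) {
      ok <- ok + 1
      expect_gte(soe$span_mm[2], soe$span_mm[1])
    }
  }
  expect_gte(ok, 1)  # at least one replicate exercises the comparison
})

test_that("the best electrode has the minimal threshold on simulator output", {
  lad <- stimulus_ladder("single_led", c(0, 0.5, 1, 2, 4, 7, 10),
                         n_trials_per_step = 20)
  tab <- simulate_optical_trials(ladder = lad, active_set = 8L, seed = 301)
  stc <- build_stc(cumulative_dprime(build_response_matrix(tab, lad)))
  expect_false(is.na(stc$best_electrode))
  expect_true(all(stc$be_threshold <= stc$thresholds, na.rm = TRUE))
})

test_that("single-emitter tuning curves center near the emitter's mapped place", {
  model <- cochlear_model(); probe <- recording_geometry()
  layout <- emitter_layout(pitch_mm = 0.25)
  act <- activation_model()
  lad <- stimulus_ladder("single_led", c(0, 0.5, 1, 2, 4, 7, 10),
                         n_trials_per_step = 40)
  devs <- vapply(c(4L, 6L, 8L, 10L, 12L), function(e) {
    tab <- simulate_optical_trials(model, layout, act, lad, active_set = e,
                                   seed = 310 + e, probe = probe)
    stc <- build_stc(cumulative_dprime(build_response_matrix(tab, lad)))
    x_e <- emitter_positions(layout)[e]
    cf_e <- place_to_freq(model, x_e)
    depth_expect <- 1 + log2(cf_e / act$cf_dorsal_khz) /
      act$tonotopic_slope_oct_per_mm / probe$pitch_mm
    abs(stc$best_electrode - depth_expect)
  }, numeric(1))
  # unbiased placement: centered within 2 electrodes on average, and no
  # single emitter lands far off the broad pooled-activation plateau
  expect_lte(mean(devs), 2)
  expect_lte(max(devs), 4)
})

test_that("active-electrode counts are exact and bounded", {
  d <- matrix(0, 32, 2)
  d[sample(32, 13), 2] <- 1.4
  dp <- dprime_matrix(d, c(0, 1))
  expect_equal(count_active_electrodes(dp), 13)
  expect_lte(count_active_electrodes(dp), 32)
  expect_equal(count_active_electrodes(dprime_matrix(matrix(0, 32, 2),
                                                     c(0, 1))), 0)
})

test_that("the STC qualification rule gates implants correctly", {
  mk_stc <- function(n_thr, maxd) {
    d <- matrix(0, 8, 3)
    if (n_thr > 0) {
      d[seq_len(n_thr), 2] <- 1.1
      d[seq_len(n_thr), 3] <- 1.2
    }
    d[1, 3] <- maxd
    build_stc(dprime_matrix(d, c(0, 1, 2)))
  }
  good <- mk_stc(3, 1.5)
  weak <- mk_stc(2, 3)
  expect_false(qualify_stc(list(good)))                   # one emitter
  expect_true(qualify_stc(list(good, good)))              # rule boundary
  expect_false(qualify_stc(list(weak, weak)))             # 2 electrodes each
  expect_false(qualify_stc(list(good, mk_stc(3, 1.4))))   # d' below 1.5
  expect_equal(attr(qualify_stc(list(good, good, weak)), "n_qualifying"), 2)
})
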