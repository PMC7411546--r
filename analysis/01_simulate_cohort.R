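#!/usr/bin/env Rscript
# Simulate the synthetic cohort this workflow analyses: 11 hearing and 5
# deafened opsin-transduced animals (plus 2 wild-type hearing controls),
# mirroring the group sizes of the in vivo study the generator emulates.
# Writes one acoustic and one optical example spike table (full tables
# are regenerated on the fly by the later stages; they are deterministic
# in the seed) plus the cohort roster.

library(ocistc)

seed <- 20260918 %% 2^31
dir.create("results", showWarnings = FALSE)

spec <- cohort_spec(18, c(rep("hearing", 11), rep("deaf", 5),
                          rep("wildtype_hearing", 2)), seed = seed)
animals <- simulate_animal_params(spec)
roster <- data.frame(
  animal_id = vapply(animals, `[[`, "", "animal_id"),
  status = vapply(animals, `[[`, "", "status"),
  seed = vapply(animals, `[[`, 1, "seed"),
  rate_max_hz = vapply(animals, function(a) a$act$rate_max_hz, 1),
  i50_mw = vapply(animals, function(a) a$act$i50, 1),
  cf_dorsal_khz = vapply(animals, function(a) a$act$cf_dorsal_khz, 1))
write.csv(roster, "results/cohort_roster.csv", row.names = FALSE)

# example tables for inspection (one animal each)
an <- animals[[1]]
fra_tab <- simulate_fra_dataset(act = an$act, seed = an$seed, n_trials = 25,
                                animal_id = an$animal_id)
lad <- stimulus_ladder("all_leds", c(0, 2, 4, 8, 16, 28, 40),
                       n_trials_per_step = 20)
opt_tab <- simulate_optical_trials(act = an$act, ladder = lad,
                                   active_set = 1:16, seed = an$seed + 1,
                                   animal_id = an$animal_id)
write_spike_table(opt_tab, "results/example_optical_spikes.csv")

cat("Cohort of", spec$n_animals, "animals written to results/cohort_roster.csv\n")
cat("Acoustic example:", nrow(fra_tab), "spikes across",
    length(unique(fra_tab$electrode)), "electrodes\n")
cat("Optical example:", nrow(opt_tab), "spikes,",
    length(unique(opt_tab$intensity)), "intensity steps ->",
    "results/example_optical_spikes.csv\n")
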