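---
title: "Quantifying spectrally selective optical activation of the auditory nerve"
author: "ocistc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spectrally selective optical activation of the auditory nerve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ocistc)
```

## The scientific problem

Electrical cochlear implants stimulate the auditory nerve with currents
that spread widely in the conductive perilymph, limiting how many
independent frequency channels a user can perceive. Optogenetics offers
an alternative: render spiral ganglion neurons (SGNs) light-sensitive
and stimulate them with arrays of microscale LEDs, exploiting the fact
that light can be confined in space. Establishing that such micro-LED
optical cochlear implants activate the auditory pathway *tonotopically*
— more apical emitters exciting lower-frequency neurons — and with a
*narrow spread of excitation* requires a quantitative chain from raw
extracellular voltage traces in the auditory midbrain (the central
nucleus of the inferior colliculus, ICC, recorded with a 32-channel
linear probe at 50 µm pitch) to summary statistics of spectral
selectivity. This package implements that chain, together with a seeded
synthetic-data generator standing in for the in vivo recordings, which
are not publicly available.

## The analysis chain

1. **Spike extraction** (`bandpass_filter()`, `detect_spikes()`):
   traces are band-passed at 0.6–6 kHz with a 4th-order Butterworth
   filter and thresholded at the *median plus three raw median absolute
   deviations*; each suprathreshold excursion contributes one event at
   its first suprathreshold sample, and a 1 ms artificial refractory
   period is enforced greedily to avoid over-counting.
2. **Acoustic calibration** (`build_fra()`,
   `characteristic_frequency()`, `fit_tonotopic_slope()`): pure tones
   (0.5–32 kHz, quarter-octave steps, 20–30 repetitions) yield a
   frequency response area per electrode; the characteristic frequency
   (CF) is the frequency responsive at the lowest level, and the
   per-animal tonotopic slope is the least-squares slope of log2(CF) on
   recording depth, in octaves/mm. The cohort is summarised by the
   median and raw MAD; deafened animals, which cannot be mapped
   acoustically, are assigned the hearing-cohort median.
3. **Optical response quantification** (`build_response_matrix()`,
   `cumulative_dprime()`, `build_stc()`): spike counts in the 3–20 ms
   post-onset window (chosen to skip the stimulus-onset artifact) are
   sorted into a (recording site × stimulus intensity) matrix, and the
   cumulative discrimination index d′ is accumulated over the intensity
   ladder, starting from the mandatory zero-intensity baseline. The
   increment from step i−1 to i is
   (µ_i − µ_{i−1}) / sqrt((σ_i² + σ_{i−1}²)/2), so a rise of one pooled
   SD over baseline is exactly d′ = 1. Spatial tuning curves (STCs) are
   iso-contours of cumulative d′; the interpolated intensity at which an
   electrode first reaches d′ = 1 is its activation threshold, and the
   electrode with the lowest threshold is the best electrode (BE).
4. **Spread of excitation and place code** (`spread_of_excitation()`,
   `normalize_be_positions()`, `fit_place_code()`,
   `spatial_to_spectral()`): the spread of excitation at criterion d′ ∈
   {1.5, 2, 2.5, 3} is the electrode span with d′ ≥ 1 at the intensity
   at which the BE reaches the criterion, bridging sub-threshold gaps
   (outermost-bound rule) to avoid underestimating multi-peaked STCs;
   spans convert to octaves via the animal's tonotopic slope. For the
   place code, emitter positions and BEs are normalized to the
   apical-most responsive emitter and regressed (electrodes per mm of
   cochlear place, with Pearson correlation).

## The synthetic world

The generator emulates the experiment at its published operating points:
an 11 mm scala tympani with a log-linear place-frequency map (32 kHz at
the base to 0.5 kHz at the apex — a modelling default, not a measured
gerbil map), implants of 16 emitters (60 µm, pitch 100/150/250 µm,
driving currents 0–10 mA per emitter with a saturating flux calibration
anchored at 0.76 mW at 10 mA and 3.15 mW total at 40 mA across 16), a
32-channel probe whose generative CFs follow a 4.34 octaves/mm ICC
gradient, V-shaped acoustic tuning with Poisson spike counts, and
response timing of 3.25 ms latency / 14 ms duration for
opsin-transduced responses versus 5.0 / 5.5 ms for the weak, dorsally
biased opto-acoustic responses of non-injected hearing controls. Deaf
animals lack acoustic responses but keep optical ones; wild-type
animals carry no opsin.

### The irradiance-to-rate model and its calibration

No irradiance-rate relation for CatCh-transduced SGNs is published, so
the pathway is an explicit modelling choice: effective irradiance along
the place axis is a sum of Gaussian light profiles (σ = 0.15 mm) scaled
by each emitter's flux; SGN recruitment is a Michaelis-Menten sigmoid
(half-activation 0.3 mW); a multi-unit's drive pools recruitment over a
Gaussian receptive field (σ = 1 mm); and firing saturates as
drive/(drive + 1.5) times a maximal evoked rate of 800 Hz. Two
qualitative constraints fix these knobs: response strength and spatial
extent must be ordered single µLED < block of four < all sixteen <
fiber (as observed in vivo), and broad fiber illumination must recruit
essentially all 32 recording sites. The pooling stage is essential —
with a pointwise sigmoid alone, a single µLED at 10 mA (the highest
peak flux of any mode) would always dominate a 4-µLED block at 2.5 mA
each, inverting the observed order. For the same reason the light σ is
narrower (0.15 mm) than a first guess of 0.3 mm: the block's 0.75 mm
footprint, not its peak flux, must carry its advantage. These
parameters were fixed against the ordinal constraints before any
acceptance measurement and are not tuned to reproduce printed d′
values; that the resulting means (≈2.4 / 2.7–3.0 / 3.7–3.9 for
single/block/all) bracket the published 1.97 / 2.86 / 3.35 is a
consequence, not a target.

### What a green test does and does not establish

Synthetic spike trains are homogeneous Poisson processes within their
windows; real multi-unit activity is bursty, adapts within and across
trials, and its background noise is neither white nor stationary. The
generator reproduces the *statistical structure the pipeline relies
on* — tonotopic ordering, intensity-dependent recruitment,
trial-to-trial Poisson variability — so green tests establish that the
pipeline recovers known ground truth under that structure; they do not
establish robustness to bursting, electrode drift, or artifact
contamination, and the published absolute in vivo magnitudes (maximal
d′ values, active-electrode counts, milliwatt thresholds) depend on
unavailable recordings and are only mirrored ordinally.

## Numerical and design choices

- **Filtering** is zero-phase (forward-backward) with the 4th-order
  design, preserving spike timing; coefficients were verified against
  an independent DSP implementation. No DSP package is available in the
  supported environment, so the design (bilinear transform of the
  analog prototype) is implemented here, while filter application uses
  R's compiled `stats::filter`.
- **MAD** is raw, without the 1.4826 normal-consistency factor,
  following the method description literally. The polarity of the
  thresholded signal (absolute/positive/negative) is configurable; the
  default is the absolute trace.
- **Bounded noise in detector fixtures.** Against *unbounded* Gaussian
  noise, any median + k·MAD threshold sits at ≈2 noise SD and admits a
  constant false-positive rate, so exact-recall scoring is impossible in
  principle. Ground-truth traces therefore default to bounded (uniform)
  noise — the threshold (≈2.2 SD) then exceeds the noise ceiling
  (≈1.7 SD) — with Gaussian noise available as an option.
- **Window conventions** are half-open: a spike at exactly 3 ms is
  inside the 3–20 ms response window, one at exactly 20 ms is not.
- **d′ degeneracies**: the pooled SD has a floor of 0.5 spikes/window
  (half a count) and single increments are capped at |Δd′| ≤ 5, so
  zero-variance cells cannot produce unbounded d′. Negative increments
  (suppression) are retained in a raw cumulative trace, but contouring
  and thresholds use the trace floored at 0: activation thresholds are
  excitation-defined.
- **Interpolation** of thresholds and criterion intensities is linear
  in the intensity unit of the ladder as given (mA for µLED drives, mW
  for fiber); contours use half-electrode resolution on the site axis.
- **Best-electrode ties** resolve deterministically: lowest threshold,
  then higher maximal d′, then the more dorsal index.
- **Characteristic-frequency edge policy**: a CF on the first or last
  grid frequency is indeterminate (the tuning tip may lie outside the
  tested range) and is excluded from tonotopic fits by default. This
  matters because the probe's 6.7-octave generative CF span exceeds the
  6-octave stimulus grid; without the exclusion, clamped CFs at the
  grid edges would bias every slope fit towards zero.
- **CF tie-break**: among frequencies responsive at the lowest level,
  the highest-rate frequency wins.
- **FRA responsiveness** is mean rate above the spontaneous mean plus 3
  spontaneous SD (the original criterion is cited but not printed; the
  multiplier is configurable).
- **Qualification before place-code fitting**: only STCs that reach
  threshold on ≥ 3 electrodes with maximal d′ ≥ 1.5 contribute a BE,
  and implants qualify with ≥ 2 such emitters. On synthetic data this
  rule is what keeps the place-code slope unbiased: weak STCs produce
  essentially random BEs, and because the reference point is pinned at
  (0, 0), a noisy *reference* BE would otherwise bias the regression
  upward.
- **Electrode placement mapping**: ICC units whose generative CF lies
  beyond the modelled cochlear frequency range map to virtual places
  outside the cochlea (and are weakly driven), rather than being
  clamped to the basal end — clamping would pile many electrodes onto
  one place and distort single-emitter tuning curves near the base.
- **Configuration format** is JSON (`jsonlite`); no TOML/YAML parser is
  available in the supported environment.
- **Evoked-potential band**: far-field averages are filtered at
  300–3000 Hz (the conventional auditory-brainstem-response band; the
  published "300 and 3,000 kHz" is read as a units typo).

## Reproducibility

Every generator takes a mandatory seed; a cohort seed deterministically
derives per-animal substreams (kept below 2^31), and `run_pipeline()`
writes a checksum manifest so that identical configurations yield
byte-identical report bundles.

## A worked example

```{r example, eval = FALSE}
# Eleven hearing animals: tone grids, characteristic frequencies,
# per-animal tonotopic slopes, cohort median.
spec <- cohort_spec(11, "hearing", seed = 1)
fits <- lapply(simulate_animal_params(spec), function(an) {
  tab <- simulate_fra_dataset(act = an$act, seed = an$seed, n_trials = 25)
  fit_tonotopic_slope(animal_tuning_table(tab, n_trials = 25),
                      an$animal_id)
})
cohort_slope_summary(fits)$median_oct_per_mm  # ~4.34 octaves/mm

# One optical condition: all 16 emitters, 0-40 mA ladder.
lad <- stimulus_ladder("all_leds", c(0, 2, 4, 8, 16, 28, 40),
                       n_trials_per_step = 20)
tab <- simulate_optical_trials(ladder = lad, active_set = 1:16, seed = 2)
stc <- build_stc(cumulative_dprime(build_response_matrix(tab, lad)))
stc$max_dprime; stc$n_active; stc$best_electrode
spread_of_excitation(stc)
```

## Known limitations

Light propagation is a 1-D Gaussian along a straightened place axis (no
3-D Lambertian optics, no spiral geometry); there are no channel
kinetics, no thermal model of the emitters, and no spike sorting (the
pipeline is multi-unit by design). Electrical-implant comparison values
are bundled as published constants for plotting only and are never
recomputed. Group-level inferential statistics (ANOVA, rank tests) are
left to standard R routines and are not part of the pipeline.
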