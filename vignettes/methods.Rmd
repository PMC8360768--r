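---
title: "Models and methods behind lgnchrom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lgnchrom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`lgnchrom` implements the analysis machinery used to study cone-driven
color opponency in the mouse lateral geniculate nucleus (LGN): the
design of photoreceptor-isolating ("silent substitution") stimuli, a
generative model of trial-structured LGN spike trains, the statistics
that classify units as responsive, color-opponent or
melanopsin-responsive, spike-triggered averaging, receptive-field
mapping, and a "random wiring" retinal model. Every analysis stage is
exercised end-to-end on synthetic data with ground-truth labels; no
recordings are required. This vignette explains the models, the
defaults, and the choices made where the design was genuinely open.

## Opsin-effective flux and silent substitution

The mouse retina studied here carries four relevant photopigments, all
modeled as vitamin-A1 pigments with the Govardovskii alpha+beta template:
S-cone opsin (peak 365 nm), the red-shifted human L-cone opsin knocked
into the `Opn1mw^R` line (556 nm), rhodopsin (498 nm) and melanopsin
(480 nm). Prereceptoral filtering is a smooth logistic stand-in for the
mouse lens (half transmission at 325 nm, i.e. UV-transmitting); a
measured transmission table can be substituted anywhere a lens curve is
accepted. The opsin-effective photon flux of a spectrum is the
trapezoid integral of `spectrum x sensitivity x transmission` on a 1 nm
grid, and Michelson contrast is `(bright - dim) / (bright + dim)` of
those effective fluxes. A 75% contrast therefore corresponds to a
7-fold bright:dim flux ratio.

Stimuli come from three Gaussian LED primaries (405, 460, 620 nm; FWHM
20 nm by default — peaks are known, spectral widths are a modeling
choice). Because the bright and dim phases of a modulation are
`d * (1 ± m)` around the background drives `d`, each opsin's Michelson
contrast is exactly linear in the per-primary modulation fractions `m`,
and stimulus design reduces to a small linear system. Targeted opsins
contribute equality constraints; any remaining degree of freedom
minimizes the maximum absolute contrast over the "minimize" opsins
(bounded 1-D search on a convex piecewise-linear objective). Achieved
contrasts are always *recomputed from the emitted spectra* rather than
read off the linear solve, so the validation path is independent of the
solver path.

**The background matters more than the solver.** The background is
calibrated so that a *wild-type* opsin complement (S 365, native M 508,
rod 498) experiences the same effective fluxes as under a daylight
spectrum (a 5500 K blackbody photon spectrum by default). Matching the
native M-opsin — not the knock-in L-opsin — forces most of the
long-wavelength flux onto the 620 nm primary (which carries ~94% of the
L-effective background flux). That headroom is what makes 75% L-opsin
contrast achievable while holding rod and melanopsin residuals to 3.7%
(the design bound is 6%) and silenced-cone residuals to numerical zero.
Matching the knock-in L-opsin instead leaves ~39% rod residual, far
outside the stated bounds — an instructive failure mode. A `reduced_s`
background variant attenuates the S-opsin flux target 10-fold; it is
the background under which ±65% independent rod/L/S white-noise
contrast is within gamut. Neutral-density filters are exact spectrally
neutral `10^-nd` scalings and leave every contrast invariant.

The melanopsin-probing step pair consists of a 460 nm step ("Mel High")
and a 405+620 mixture ("Mel Low") matched exactly for L- and S-opsin
flux; with the default spectra the pair differs 877-fold in melanopsin
and 188-fold in rod flux (the design class is "hundreds-fold"; the
exact value depends on the assumed LED spectra).

## The generative spike model

Each model neuron is a rectified-linear LN cascade driven by the
stimulus contrast traces:

```
rate(t) = max(0, baseline
              + gain * [wL*cL + wS*cS + wrod*crod](t - latency)
              + wmel * (cmel ⊛ k_slow)(t))
```

with a single cone latency (50 ms default), an exponential low-pass
`k_slow` with 2 s time constant for melanopsin (its sluggish
phototransduction), and inhomogeneous-Poisson spiking. Spatial stimuli
drive the same cascade through a difference-of-Gaussians overlap
(surround sigma fixed at 3x the center sigma), normalized so a
perfectly centered square yields unit drive and a full-field stimulus
yields `1 - surround_weight`; a cell with surround weight 1 therefore
loses its full-field response while remaining responsive to local
stimuli — the surround-suppressed phenotype.

Population defaults are the observed class frequencies (252:31:72:78:282
for non-opponent ON/OFF, L-ON/S-OFF, S-ON/L-OFF and non-responsive out
of 715, i.e. opponent cells are ~35% of responsive cells), with
per-class melanopsin-input probabilities from the observed
cross-tabulation. Weights are `(1±p)/2` with the preference index `p`
linearly coupled to RF elevation (slope −0.012 per degree, noise SD
0.12), so the S-bias of responses grows with elevation as the
dorsoventral opsin gradient predicts; azimuth carries no coupling.
Baselines (3–8 spikes/s) and gains (15–25 spikes/s per unit weighted
contrast) are drawn once per unit; these are "high-SNR" values typical
of well-isolated LGN units, chosen a priori and not revisited. Opponent
cells cluster medially in a 1000x1000 um anatomical template
(means 320 vs 650 um mediolateral, SD 120 um).

What a green test establishes: that the analysis pipeline recovers the
labels and parameters of *this* generative world at its stated noise
level. What it does not establish: robustness to burst firing,
adaptation, eye movements, correlated noise across units, or
electrode-sorting artifacts — none of which the generator emulates.

## Response detection and classification

Full-field responses are quantified on 100-bin cycle histograms
smoothed with a circular 5-bin boxcar; the response statistic is the
smoothed peak-trough amplitude. The null distribution comes from 100
shuffles in which each repeat's spikes are circularly time-shifted by
an independent uniform offset. Two decisions here deserve note:

* **The shuffle repeat unit is one stimulus cycle.** The protocol
  delivers 5 blocks of 6 cycles ("30 repeats"); shifting whole 6-cycle
  blocks leaves most stimulus locking intact (only 5 random phases) and
  the null tracks the signal, costing ~20% sensitivity. Shifting each
  cycle independently matches the repeat count the protocol describes.
  A full permutation alternative was considered and rejected because a
  circular shift preserves ISI structure.
* **Significance is `raw > 95th percentile` of the null,** with the
  null mean subtracted to give the corrected amplitude. With 100
  shuffle samples the empirical false-positive rate is ~6% rather than
  the nominal 5% (the quantile of 100 draws is itself noisy); measured
  specificity on 1,000 null Poisson units is 93–94%.

Polarity is read from the histogram bin with the largest absolute
deviation from the mean: positive deviations in the bright half-cycle
(or negative in the dim half) are ON.

Opponency follows the two evidence paths: opposite-sign significant
responses to L-only and S-only stimulation; or exactly one detectable
opsin plus significantly larger per-block amplitudes for the antiphase
(L−S) than the in-phase (L+S) stimulus (Welch t-test on the 5 block
amplitudes, p < 0.05, with the mean difference in the right direction).
Units with no significant single-opsin response are non-responsive. In
the end-to-end pipeline the *responsiveness* decision uses a
family-wise 95% limit over the paired L/S shuffle draws (the 95th
percentile of the per-shuffle max), keeping the per-unit false-positive
rate at ~5% across the two tests — without it, ~10% of truly
non-responsive units acquire labels and the zero-gain control would sit
at twice its nominal false-positive rate. `classify_opponency` itself
is agnostic: it consumes whatever significance flags it is given.

Melanopsin responsiveness compares 10 s Mel High vs Low steps (10 s
darkness baseline): a unit is MR when the late change (last 5 s,
baseline-subtracted) is significantly greater for High while the early
change (first 250 ms) does not differ, Welch t-tests at p < 0.05. The
early-window criterion is evaluated at the same intensity that passes
the late criterion (the protocol wording is ambiguous between
per-intensity and pooled; per-intensity is the stricter reading). The
simulator has no light adaptation, so intensities are replicates; the
pipeline defaults to one intensity and 10 repeats. Zero-variance
windows (a rectified-silent unit) are handled by a degenerate-t
convention: equal means give p = 1, unequal give p = 0.

The periodogram statistic is the percentage of total variance captured
by the cycle-mean waveform at the stimulus period (the cited method is
not restated in detail anywhere accessible; this is the stated quantity
"percentage variance accounted for by a rhythmic process at the
stimulus period"). Its small-sample null expectation is
`(k-1)/(nk-1)` for `k` bins and `n` cycles, which the tests verify
against simulation.

## STA and receptive-field mapping

Spike-triggered averages are computed at the 10 Hz frame resolution
over a 1 s window (the window length is a choice; the kernel mass of
the generative model sits in the first frame). Polarity uses the lag of
largest absolute deviation within 0–300 ms of the spike. The shuffled
floor is the 95th percentile of amplitudes from spike-time
randomization.

Bar/square responses are the mean rate in the best 50 ms epoch (5 ms
steps, ties to the earliest) within 35–125 ms after onset, minus the
100 ms pre-onset baseline, averaged over repeats. Light and dark maps
combine by subtraction (ON or OFF) or addition (ON-OFF); when the cell
type is not declared it is inferred from the dominant response sign
(comparable light and dark maxima, ratio > 0.5, infer ON-OFF). RF
centers come from least-squares Gaussian-plus-offset fits (isotropic in
2-D; elliptical fits were not needed for the synthetic world and are
out of scope), run from multiple starts (both map extremes, four seed
widths) under box constraints; a fit is "mappable" when variance
explained reaches 0.4 (a chosen threshold, configurable) and the center
lies within the tested extent plus a quarter-span margin. Negative
amplitudes are legitimate (OFF-center maps under an ON-combination
convention) and carry the center polarity used by RF-opponency typing.

The cone-preference-versus-elevation trend bins preference in 10-degree
elevation bins, fits ordinary least squares to the bin means, and tests
the slope with an extra sum-of-squares F-test against the constant
model. Elevations are snout-axis-relative; the projected dorsoventral
retinal midpoint sits at +22 degrees (stored once as
`RETINAL_MIDPOINT_ELEVATION`).

## The random-wiring retinal model

The model asks whether non-selective ("random") cone sampling by a
difference-of-Gaussians RF over the dorsoventral opsin gradient can
produce the observed opponency. A 1-D strip of cones (default 500 over
100 degrees) is drawn from a parametric gradient standing in for the
reported cone-type distributions: 5% genuine S-cones throughout, a
dorsal pole with 70% L(M)-only cones, a sharp logistic transition at
the meridian (slope 0.05 in normalized position), and co-expressing
cones whose S-opsin fraction runs 10% to 90% dorsal-to-ventral. The
exact digitized distributions are out of scope; every shape parameter
is exposed.

Each model RF (center diameter 6–20 degrees, surround fixed at 3x,
surround weight 0.5–1, sampling fraction 1–100%) weights its sampled
cones by Gaussian center and surround profiles (sigma = diameter/4).
One normalization decision is load-bearing: kernels are normalized by
their *expected* mosaic weight (cone density x sampling fraction x
Gaussian mass), not by the realized draw. Renormalizing over the
realized cones makes the L and S responses sum to exactly zero at
surround weight 1 (each cone's opsin fractions sum to 1), so every RF
would be trivially "opponent" with identically zero bias — a degenerate
artifact. Keeping the expected-weight scale preserves exactly the
sampling imbalance that the random-wiring hypothesis is about. On this
scale a full-field unit-contrast stimulus drives `1 - surround_weight`
in expectation.

A cell is opponent when its L and S responses (to the 75% L-only and
S-only stimuli) have opposite signs, both exceeding 1e-6 of the larger
magnitude (the conversion from model response to an "opponent" call is
not otherwise specified; the tolerance is a decision). The bias index
is computed from the per-opsin cone *input weights* — the wiring, not
the response — because the claim under test concerns the relative
weighting of cone inputs to opponent cells. With these choices the
sweep (100 strips per parameter cell) shows: prevalence ~0 without
surround antagonism, rising steeply with surround weight to ~0.45–0.55
at weight 1 (the experimental proportion among responsive cells is
~0.35); more opponency dorsal than ventral of the midpoint; and
opponent cells more strongly cone-biased than non-opponent cells — the
qualitative structure that makes the random-wiring account sit poorly
with the experimentally balanced, elevation-independent opponency.

## Numerical and reproducibility notes

* Solver tolerance: achieved-vs-target contrast mismatch ≤ 1e-6
  absolute (observed: ~1e-16 for fully-determined solves).
* Square waves: bright phase first, linear 40 ms ramps centered on the
  transitions; contrast traces are instantaneous fractional flux
  deviations from the background, so plateaus sit at the Michelson
  contrast.
* White-noise marginals are uniform over ±amplitude ("pseudorandom" is
  all that is specified); a truncated-Gaussian option exists behind a
  flag. Frames are solved exactly; an out-of-gamut frame raises an
  error naming the frame.
* Every stochastic stage takes an explicit seed and restores the
  caller's RNG state; unit-level streams are derived as
  `(seed, unit_id)` so populations and simulations are reproducible
  element-wise, and all derived seeds stay below 2^31.
* Anatomical maps use a 150 um moving circular window on a 25 um grid
  (grid step is a choice), masking nodes with fewer than 10 cells.
* Scale choices for the test suite: the acceptance-style checks run at
  the stated sizes (1,000 null units, 400-unit population, 100-strip
  sweeps); everything completes in a few minutes on one CPU.

## Known limitations

* LED spectra are idealized Gaussians and the daylight reference is a
  blackbody; printed values that depend on the authors' measured
  calibration (absolute log-flux levels, the exact melanopsin contrast
  of the rod stimulus) are reproduced in class but not to the digit.
* The generative model is phenomenological: no adaptation, no bursting,
  no correlated variability, delta-function temporal kernels at the
  noise frame rate.
* The retinal model is 1-D and linear; bipolar/amacrine circuitry and
  fitting the model to recorded data are out of scope.
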