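# lgnchrom

Silent-substitution stimulus design and cone-opponency analysis for
mouse LGN electrophysiology — exercised end-to-end on synthetic data.

## The problem

Mice carry two cone opsins (S, UV-peaked at 365 nm; M at 508 nm,
replaced by the human L-opsin at 556 nm in the `Opn1mw^R` line), plus
rhodopsin (498 nm) and melanopsin (480 nm). Because every one of these
pigments has appreciable UV sensitivity behind the mouse's
UV-transmitting lens, a "UV versus green" stimulus does not isolate a
photoreceptor class. The clean way to ask which pigment drives a neuron
is **silent substitution**: modulate several spectral primaries jointly
so that the opsin-effective photon flux

&nbsp;&nbsp;&nbsp;&nbsp;*F* = ∫ *E*(λ) · *S*(λ) · *T*(λ) dλ

(spectrum x Govardovskii A1 sensitivity template x prereceptoral
transmission) changes for one pigment while staying constant for the
others, with contrast quantified as Michelson contrast
(*F*<sub>bright</sub> − *F*<sub>dim</sub>)/(*F*<sub>bright</sub> +
*F*<sub>dim</sub>) of effective flux. A unit is **color opponent** when
it responds with opposite sign to selective L- and S-opsin modulation
(or responds more to antiphase L−S than to in-phase L+S stimulation),
and **melanopsin responsive** when its sustained — but not initial —
firing distinguishes cone-matched stimuli differing several-hundred-fold
in melanopsin flux.

The package provides, as testable modules:

* opsin nomograms, effective-flux arithmetic, spectra I/O
  (`nomogram_sensitivity`, `effective_flux`, `michelson_contrast`);
* a three-primary silent-substitution solver with first-principles
  residual validation and square-wave / step / white-noise waveform
  builders (`solve_silent_substitution`, `validate_solution`,
  `build_square_wave`, `build_step_pair`, `build_white_noise`);
* a ground-truth LN-Poisson spike simulator for full-field, spatial and
  white-noise protocols (`make_population`, `simulate_full_field`,
  `simulate_spatial`, `simulate_white_noise`);
* shuffle-null response detection on 100-bin cycle histograms,
  opponency / cone-preference / melanopsin classification and a
  periodicity statistic (`response_amplitude`, `classify_opponency`,
  `classify_mr`, `cone_preference`, `chi2_periodogram`);
* spike-triggered averaging (`compute_sta`), receptive-field mapping and
  the preference-vs-elevation trend (`location_response_map`,
  `fit_rf_center`, `classify_rf_opponency`, `elevation_trend`);
* a "random wiring" center–surround retinal model over the dorsoventral
  cone-opsin gradient (`cone_gradient`, `sample_strip`, `rf_response`,
  `sweep_random_wiring`);
* an end-to-end pipeline with anatomical moving-window maps and a CLI
  (`run_pipeline`, `moving_window_map`, `lgnchrom_cli`).

## Worked example

Design a 75% L-opsin-isolating stimulus on the daylight-matched
background and validate it from the emitted spectra:

```r
library(lgnchrom)
bg  <- make_background()   # wild-type daylight match, 405/460/620 nm LEDs
sol <- solve_silent_substitution(
  bg, contrast_spec(target = c(L = 0.75), silence = "S",
                    minimize = c("rod", "mel")))
round(sol$achieved, 5)
#>        S        L      rod      mel
#>  0.00000  0.75000  0.03726 -0.03726
validate_solution(sol, bg)
#>   opsin     role achieved    error bound pass
#> 1     S silenced   0.0000 0.00e+00 2e-03 TRUE
#> 2     L   target   0.7500 1.11e-16 1e-06 TRUE
#> 3   rod minimize   0.0373 3.73e-02 6e-02 TRUE
#> 4   mel minimize  -0.0373 3.73e-02 6e-02 TRUE
```

The targeted opsin sits exactly at 75% contrast (a 7-fold change in
effective flux), the silenced cone at numerical zero, and the free
degree of freedom balances rod and melanopsin residuals at 3.7%, inside
the 6% design bound. The melanopsin-probing step pair is matched for
both cones while differing ~877-fold in melanopsin flux:

```r
sp <- build_step_pair(bg)
sprintf("mel ratio High/Low: %.1f, rod ratio: %.1f", sp$mel_ratio, sp$rod_ratio)
#> "mel ratio High/Low: 877.1, rod ratio: 188.2"
```

Simulate and classify a 100-unit synthetic session end to end:

```r
rep <- run_pipeline(pipeline_config(
  n_units = 100, seeds = list(population = 1, simulation = 2, analysis = 3)))
rep
#> <session_report> 100 units; opponency accuracy 1.000; MR accuracy 0.980
rep$confusion$table
#>                  L_ON_S_OFF non_opponent non_responsive S_ON_L_OFF
#>   L_ON_S_OFF             11            0              0          0
#>   non_opponent            0           38              0          0
#>   non_responsive          0            0             37          0
#>   S_ON_L_OFF              0            0              0         14
```

Rows are ground-truth labels, columns the pipeline's calls: every
opponent and non-opponent unit is recovered, and 98% of
melanopsin-responsive flags agree with the generative truth.

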