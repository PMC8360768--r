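# Ground-truth populations and the LN-Poisson spike generator.

test_that("populations are reproducible and respect prevalences", {
  p1 <- make_population(200, seed = 5)
  p2 <- make_population(200, seed = 5)
  expect_identical(population_truth(p1), population_truth(p2))
  # degenerate prevalence
  p3 <- make_population(50, prevalences = c(nonresponsive = 1), seed = 1)
  expect_true(all(population_truth(p3)$class_label == "nonresponsive"))
  expect_error(make_population(10, prevalences = c(nonopp_ON = 0.5)),
               "sum to 1")
})

test_that("the opponent fraction of responsive cells is ~35%", {
  tr <- population_truth(make_population(4000, seed = 2))
  resp <- tr$class_label != "nonresponsive"
  frac <- mean(tr$class_label[resp] %in% c("L_ON_S_OFF", "S_ON_L_OFF"))
  expect_equal(frac, 150 / 433, tolerance = 0.1)
})

test_that("generative weights are consistent with every class label", {
  units <- make_population(500, seed = 3)$units
  for (u in units) {
    switch(u$class_label,
      L_ON_S_OFF = expect_true(u$w_L > 0 && u$w_S < 0),
      S_ON_L_OFF = expect_true(u$w_S > 0 && u$w_L < 0),
      nonopp_ON = expect_true(u$w_L >= 0 && u$w_S >= 0 && u$w_L + u$w_S > 0),
      nonopp_OFF = expect_true(u$w_L <= 0 && u$w_S <= 0 && u$w_L + u$w_S < 0),
      nonresponsive = expect_true(u$w_L == 0 && u$w_S == 0 && u$gain == 0))
    if (u$mr_flag) expect_gt(u$w_mel, 0)
  }
})

test_that("neuron_spec rejects inconsistent weights", {
  expect_error(neuron_spec(1, "L_ON_S_OFF", w_L = 1, w_S = 0.5),
               "opposite-sign")
  expect_error(neuron_spec(1, "nonopp_ON", w_L = 1, w_S = -0.5), "same-sign")
  expect_error(neuron_spec(1, "nonopp_ON", w_L = 1, w_S = 0, mr_flag = TRUE),
               "w_mel")
})

test_that("a null neuron fires at its baseline (Poisson sanity)", {
  wf <- fixture_flat_waveform(n_cycles = 2)   # 8 s of constant background
  u <- neuron_spec(1, "nonresponsive", gain = 0, baseline_rate = 6)
  spk <- simulate_full_field(one_unit(u), wf, n_trials = 500, seed = 11)
  counts <- tabulate(spk$trial, 500)
  expected <- 6 * 8
  se <- sqrt(expected / 500)
  expect_lt(abs(mean(counts) - expected), 3 * se)
  # count variance/mean within [0.8, 1.2] over 500 trials
  expect_gt(var(counts) / mean(counts), 0.8)
  expect_lt(var(counts) / mean(counts), 1.2)
})

test_that("simulations are reproducible from their seeds", {
  wf <- fixture_battery()$L_only$waveform
  pop <- make_population(5, seed = 9)
  s1 <- simulate_full_field(pop, wf, n_trials = 2, seed = 4)
  s2 <- simulate_full_field(pop, wf, n_trials = 2, seed = 4)
  expect_identical(s1, s2)
})

test_that("an opponent neuron is driven harder by antiphase stimuli", {
  bat <- fixture_battery()
  u <- neuron_spec(1, "L_ON_S_OFF", w_L = 0.5, w_S = -0.5, gain = 20,
                   baseline_rate = 5)
  amp <- function(wf, seed) {
    spk <- simulate_full_field(one_unit(u), wf, n_trials = 5, seed = seed)
    h <- cycle_histogram(spk, period = 4, trial_duration = 24)
    max(h$smoothed) - min(h$smoothed)
  }
  expect_gt(amp(bat$LmS$waveform, 21), amp(bat$LpS$waveform, 22))
})

test_that("melanopsin step responses match the convolution oracle", {
  steps <- build_step_pair(fixture_background())
  u <- neuron_spec(1, "nonresponsive", gain = 0, baseline_rate = 5,
                   w_mel = 10, tau_mel = 2, mr_flag = TRUE)
  late_rate <- function(wf, seed) {
    spk <- simulate_full_field(one_unit(u), wf, n_trials = 300, seed = seed)
    sum(spk$time_s >= 15 & spk$time_s < 20) / (300 * 5)
  }
  d_obs <- late_rate(steps$high, 31) - late_rate(steps$low, 32)
  # oracle (scratch/oracle_spectral.py): mean of the exponential low-pass
  # (tau = 2 s) of a unit step over the last 5 s of a 10 s step is
  # 0.9698612; the Mel Low trace is 1/877.09 of the High trace
  d_exp <- 10 * 0.9698612 * (1 - 1 / 877.0898)
  se <- sqrt(2 * 15 / 5 / 300)   # Poisson SE of the rate difference
  expect_lt(abs(d_obs - d_exp), 3 * se + 0.05)
})

test_that("spatial responses follow the center-surround geometry", {
  ev <- data.frame(trial = rep(1:20, each = 3),
                   onset_s = rep(c(0.5, 1.5, 2.5), 20),
                   azimuth_deg = rep(c(20, 60, 20), 20),
                   elevation_deg = rep(c(25, 55, 25), 20),
                   size_deg = 6, polarity = 1,
                   full_field = rep(c(FALSE, FALSE, TRUE), 20))
  ev$contrast_L <- 0.72; ev$contrast_S <- 0.72
  count_in <- function(spk, onsets) {
    sum(vapply(seq_len(nrow(spk)), function(i) {
      any(spk$time_s[i] - onsets >= 0.035 & spk$time_s[i] - onsets < 0.135)
    }, logical(1)))
  }
  # surround_weight 1: full-field drive ~0, centered local stimulus drives
  u <- neuron_spec(1, "nonopp_ON", w_L = 0.5, w_S = 0.5, gain = 60,
                   baseline_rate = 4, rf_center = c(20, 25),
                   rf_center_diameter = 12, surround_weight = 1)
  spk <- simulate_spatial(one_unit(u), ev, trial_duration = 3, seed = 8)
  n_center <- count_in(spk, 0.5)
  n_far <- count_in(spk, 1.5)
  n_full <- count_in(spk, 2.5)
  base <- 4 * 0.1 * 20   # expected baseline count in 20 windows of 100 ms
  expect_gt(n_center, base + 4 * sqrt(base))
  expect_lt(abs(n_far - base), 4 * sqrt(base))
  expect_lt(abs(n_full - base), 4 * sqrt(base))
})

test_that("white-noise simulation recovers the generative kernel", {
  bg <- make_background(variant = "reduced_s")
  wn <- build_white_noise(bg, duration = 600, seed = 12)
  u <- neuron_spec(1, "L_ON_S_OFF", w_L = 0.7, w_S = -0.3, gain = 25,
                   baseline_rate = 20)
  s1 <- simulate_white_noise(one_unit(u), wn, seed = 13)
  s2 <- simulate_white_noise(one_unit(u), wn, seed = 13)
  expect_identical(s1, s2)
  sta <- compute_sta(s1$time_s, wn$meta$sequences[, c("L", "S", "rod")],
                     seed = 14)
  k <- true_kernel(u)
  expect_gt(cor(sta$sta[, "L"], k[, "L"]), 0.9)
  expect_gt(cor(sta$sta[, "S"], k[, "S"]), 0.9)
  # absent rod input: rod STA sits at the shuffled floor
  expect_lt(sta$amplitude[["rod"]], 1.5 * sta$shuffle_floor[["rod"]])
})
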