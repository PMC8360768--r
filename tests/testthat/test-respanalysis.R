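# Cycle histograms, shuffle-null detection, classification rules and the
# periodogram.

make_measure <- function(significant, polarity, corrected = 10) {
  structure(list(significant = significant, polarity = polarity,
                 corrected = corrected, raw = corrected,
                 signed = if (polarity == "ON") corrected else -corrected),
            class = "response_measure")
}

test_that("cycle histograms fold, scale and smooth correctly", {
  empty <- cycle_histogram(numeric(0), period = 4, n_cycles = 10)
  expect_equal(empty$rate, rep(0, 100))
  # constant-rate Poisson at 10 spikes/s over 30 cycles: bins ~10
  spk <- with(list(), {
    set.seed(1)
    data.frame(trial = 1, time_s = sort(runif(rpois(1, 10 * 120), 0, 120)))
  })
  h <- cycle_histogram(spk, period = 4, n_cycles = 30)
  expect_equal(mean(h$rate), 10, tolerance = 0.1)
  expect_lt(max(abs(h$smoothed - 10)), 5 * sqrt(10 / (30 * 0.04 * 5)))
})

test_that("smoothing matches an independent boxcar convolution", {
  # deterministic half-cycle burst: one spike per 40 ms bin in each 2 s
  # bright phase of a 4 s cycle, over 30 cycles (rate 25 in-phase, 0 out)
  t1 <- as.vector(outer(seq(0.02, 1.98, by = 0.04), (0:29) * 4, `+`))
  h <- cycle_histogram(data.frame(trial = 1, time_s = t1), period = 4,
                       n_cycles = 30)
  profile <- c(rep(25, 50), rep(0, 50))   # exact unsmoothed rate profile
  expect_equal(h$rate, profile)
  # independent circular 5-bin boxcar (window b-2..b+2)
  wrap <- c(profile[99:100], profile, profile[1:2])
  sm_oracle <- vapply(1:100, function(b) mean(wrap[b:(b + 4)]), numeric(1))
  expect_equal(h$smoothed, sm_oracle)
  expect_equal(max(h$smoothed) - min(h$smoothed), 25)
})

test_that("stimulus-locked units are detected with the right polarity", {
  bat <- fixture_battery()
  on_u <- neuron_spec(1, "nonopp_ON", w_L = 0.8, w_S = 0.2, gain = 20,
                      baseline_rate = 5)
  off_u <- neuron_spec(2, "nonopp_OFF", w_L = -0.8, w_S = -0.2, gain = 20,
                       baseline_rate = 8)
  spk <- simulate_full_field(list(on_u, off_u), bat$L_only$waveform,
                             n_trials = 5, seed = 6)
  mon <- response_amplitude(unit_spikes(spk, 1), 4, 24, seed = 7)
  moff <- response_amplitude(unit_spikes(spk, 2), 4, 24, seed = 8)
  expect_true(mon$significant); expect_identical(mon$polarity, "ON")
  expect_true(moff$significant); expect_identical(moff$polarity, "OFF")
  expect_gt(mon$corrected, 0)
})

test_that("a shuffle-invariant uniform train has ~zero corrected amplitude", {
  # one spike per histogram bin, every cycle: invariant under circular
  # shifts that are multiples of a bin; nearly invariant in general
  t1 <- as.vector(outer(seq(0.02, 3.98, by = 0.04), (0:29) * 4, `+`))
  m <- response_amplitude(data.frame(trial = 1, time_s = t1), 4, 120,
                          seed = 3)
  expect_false(m$significant)
  expect_lt(abs(m$corrected), 1)
})

test_that("shuffle-test specificity is ~5% on null units", {
  wf <- fixture_flat_waveform()
  pop <- make_population(200, prevalences = c(nonresponsive = 1), seed = 15,
                         baseline_range = c(5, 5))
  spk <- simulate_full_field(pop, wf, n_trials = 30, seed = 16)
  flagged <- vapply(population_truth(pop)$unit_id, function(uid) {
    response_amplitude(unit_spikes(spk, uid), 4, 4, seed = uid)$significant
  }, logical(1))
  # binomial(200, 0.05): mean 10, sd 3.1
  expect_gt(mean(flagged), 0.0)
  expect_lt(mean(flagged), 0.125)
})

test_that("corrected amplitude grows with generative gain", {
  bat <- fixture_battery()
  amps <- vapply(c(5, 15, 30), function(g) {
    u <- neuron_spec(1, "nonopp_ON", w_L = 0.6, w_S = 0.4, gain = g,
                     baseline_rate = 5)
    spk <- simulate_full_field(one_unit(u), bat$L_only$waveform,
                               n_trials = 5, seed = 40 + g)
    response_amplitude(spk, 4, 24, seed = 50 + g)$corrected
  }, numeric(1))
  expect_true(all(diff(amps) > 0))
})

test_that("opponency rules produce the stated labels", {
  on <- make_measure(TRUE, "ON"); off <- make_measure(TRUE, "OFF")
  ns <- make_measure(FALSE, "ON", corrected = 1)
  big <- c(20, 22, 19, 21, 20); small <- c(10, 11, 9, 10, 12)
  expect_identical(classify_opponency(on, off, big, small)$label, "L_ON_S_OFF")
  expect_identical(classify_opponency(off, on, big, small)$label, "S_ON_L_OFF")
  expect_identical(classify_opponency(on, on, small, big)$label, "non_opponent")
  expect_identical(classify_opponency(ns, ns, big, small)$label,
                   "non_responsive")
  # one detectable + L-S dominance: opponent oriented by the detected opsin
  c1 <- classify_opponency(on, ns, big, small)
  expect_identical(c1$label, "L_ON_S_OFF")
  expect_identical(c1$evidence, "LminusS_dominance")
  c2 <- classify_opponency(ns, on, big, small)
  expect_identical(c2$label, "S_ON_L_OFF")
  # one detectable but no dominance: non-opponent
  expect_identical(classify_opponency(on, ns, small, big)$label,
                   "non_opponent")
})

test_that("opponency calls are invariant to trial order and rate scaling", {
  bat <- fixture_battery()
  u <- neuron_spec(1, "L_ON_S_OFF", w_L = 0.6, w_S = -0.4, gain = 20,
                   baseline_rate = 5)
  spkL <- simulate_full_field(one_unit(u), bat$L_only$waveform, 5, seed = 61)
  spkS <- simulate_full_field(one_unit(u), bat$S_only$waveform, 5, seed = 62)
  mL <- response_amplitude(spkL, 4, 24, seed = 63)
  mS <- response_amplitude(spkS, 4, 24, seed = 64)
  base <- classify_opponency(mL, mS, c(20, 21, 19, 22, 20),
                             c(10, 9, 11, 10, 12))$label
  # relabeled trials
  perm <- spkL; perm$trial <- 6 - perm$trial
  mLp <- response_amplitude(perm, 4, 24, seed = 63)
  expect_identical(classify_opponency(mLp, mS, c(20, 21, 19, 22, 20),
                                      c(10, 9, 11, 10, 12))$label, base)
  expect_identical(base, "L_ON_S_OFF")
})

test_that("cone preference index behaves", {
  expect_equal(cone_preference(1, 1), 0)
  expect_equal(cone_preference(1, 0), 1)
  expect_equal(cone_preference(3, 1), 0.5)
  expect_error(cone_preference(0, 0), "undefined")
})

test_that("periodogram: sinusoid limit, noise bias and mixtures", {
  k <- 20; n <- 30
  t_idx <- seq_len(k * n)
  pure <- sin(2 * pi * t_idx / k)
  expect_equal(chi2_periodogram(pure, k)$percent_variance, 100,
               tolerance = 1e-9)
  # white-noise expectation equals the permutation-oracle small-sample
  # bias: E[R^2] = (k - 1) / (n k - 1)
  set.seed(77)
  pcts <- replicate(400, chi2_periodogram(rnorm(k * n), k)$percent_variance)
  bias <- 100 * (k - 1) / (n * k - 1)
  expect_equal(mean(pcts), bias, tolerance = 0.15)
  # sinusoid + equal-variance noise: ~50% plus the noise bias share
  set.seed(78)
  mixed <- replicate(100, {
    x <- sqrt(2) * sin(2 * pi * t_idx / k) + rnorm(k * n)
    chi2_periodogram(x, k)$percent_variance
  })
  expect_equal(mean(mixed), 50, tolerance = 0.1 * 50)
  expect_warning(chi2_periodogram(rnorm(k * n + 3), k), "truncated")
})

test_that("MR classification separates melanopsin input", {
  steps <- build_step_pair(fixture_background())
  mr_u <- neuron_spec(1, "nonopp_ON", w_L = 0.5, w_S = 0.5, gain = 15,
                      baseline_rate = 5, w_mel = 10, mr_flag = TRUE)
  cone_u <- neuron_spec(2, "nonopp_ON", w_L = 0.5, w_S = 0.5, gain = 15,
                        baseline_rate = 5)
  hi <- simulate_full_field(list(mr_u, cone_u), steps$high, 10, seed = 71)
  lo <- simulate_full_field(list(mr_u, cone_u), steps$low, 10, seed = 72)
  per_unit <- function(uid) list(list(high = unit_spikes(hi, uid),
                                      low = unit_spikes(lo, uid)))
  expect_identical(classify_mr(per_unit(1))$label, "MR")
  expect_identical(classify_mr(per_unit(2))$label, "non_MR")
  # identical responses -> non-MR by construction
  same <- list(list(high = unit_spikes(hi, 2), low = unit_spikes(hi, 2)))
  expect_identical(classify_mr(same)$label, "non_MR")
  expect_error(classify_mr(per_unit(1), pre_s = 0), "baseline")
})
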