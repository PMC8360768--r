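# Receptive-field mapping, Gaussian fits, RF opponency typing and the
# cone-preference-vs-elevation trend.

make_fit <- function(az, el, sigma, amplitude, mappable = TRUE) {
  structure(list(center = c(azimuth = az, elevation = el), sigma = sigma,
                 amplitude = amplitude, mappable = mappable,
                 variance_explained = 0.9, converged = TRUE),
            class = "rf_estimate")
}

test_that("location maps are flat for null units, peaked for ON cells", {
  ev <- square_mapping_events(n_repeats = 8, seed = 201)
  null_u <- neuron_spec(1, "nonresponsive", gain = 0, baseline_rate = 5)
  on_u <- neuron_spec(2, "nonopp_ON", w_L = 0.5, w_S = 0.5, gain = 60,
                      baseline_rate = 5, rf_center = c(20, 22),
                      rf_center_diameter = 10, surround_weight = 0.2)
  spk <- simulate_spatial(list(null_u, on_u), ev, seed = 202)
  m0 <- location_response_map(unit_spikes(spk, 1), ev)
  expect_lt(max(abs(m0$map$combined)), 25)   # pure windowing noise
  m1 <- location_response_map(unit_spikes(spk, 2), ev, cell_type = "ON")
  best <- m1$map[which.max(m1$map$combined), ]
  expect_lt(abs(best$azimuth_deg - 20), 3)
  expect_lt(abs(best$elevation_deg - 22), 3)
})

test_that("ON-OFF combination adds what subtraction cancels", {
  ev <- square_mapping_events(n_repeats = 8, seed = 203)
  onoff <- neuron_spec(1, "nonopp_ON", w_L = 0.5, w_S = 0.5, gain = 60,
                       baseline_rate = 5, rf_center = c(20, 22),
                       rf_center_diameter = 10, surround_weight = 0,
                       rf_type = "ON_OFF")
  spk <- simulate_spatial(one_unit(onoff), ev, seed = 204)
  sub <- location_response_map(spk, ev, cell_type = "ON")
  add <- location_response_map(spk, ev, cell_type = "ON_OFF")
  at_center <- function(m) {
    d2 <- (m$map$azimuth_deg - 20)^2 + (m$map$elevation_deg - 22)^2
    mean(m$map$combined[d2 < 16])
  }
  expect_gt(at_center(add), 3 * abs(at_center(sub)))
  # auto-typing recognizes the equal light/dark responses
  auto <- location_response_map(spk, ev)
  expect_identical(auto$cell_type, "ON_OFF")
})

test_that("Gaussian fits recover noise-free and simulated centers", {
  grid <- expand.grid(azimuth_deg = seq(2, 38, by = 3),
                      elevation_deg = seq(8, 36, by = 3))
  grid$response <- 12 * exp(-((grid$azimuth_deg - 20)^2 +
                                (grid$elevation_deg - 25)^2) / (2 * 8^2)) + 1
  fit <- fit_rf_center(grid)
  expect_true(fit$mappable)
  expect_lt(abs(fit$center[["azimuth"]] - 20), 0.1)
  expect_lt(abs(fit$center[["elevation"]] - 25), 0.1)
  expect_lt(abs(fit$sigma - 8), 0.2)
  # flat map is rejected by the variance-explained threshold
  flat <- grid; flat$response <- 1
  expect_false(fit_rf_center(flat)$mappable)
  # simulated neuron with 8 repeats: center within 2 degrees
  ev <- square_mapping_events(n_repeats = 8, seed = 205)
  u <- neuron_spec(1, "nonopp_ON", w_L = 0.5, w_S = 0.5, gain = 60,
                   baseline_rate = 5, rf_center = c(24, 20),
                   rf_center_diameter = 12, surround_weight = 0.2)
  spk <- simulate_spatial(one_unit(u), ev, seed = 206)
  f <- fit_rf_center(location_response_map(spk, ev, cell_type = "ON"))
  expect_true(f$mappable)
  expect_lt(abs(f$center[["azimuth"]] - 24), 2)
  expect_lt(abs(f$center[["elevation"]] - 20), 2)
})

test_that("1D fits work on bar-style profiles", {
  prof <- data.frame(azimuth_deg = seq(0, 60, by = 1.5), elevation_deg = 0)
  prof$response <- 8 * exp(-(prof$azimuth_deg - 33)^2 / (2 * 5^2)) + 0.5
  f <- fit_rf_center(prof, kind = "1D_azimuth")
  expect_true(f$mappable)
  expect_lt(abs(f$center[["azimuth"]] - 33), 0.1)
  expect_true(is.na(f$center[["elevation"]]))
})

test_that("RF opponency typing follows the rules", {
  L_on <- make_fit(20, 22, 5, 10)
  S_off <- make_fit(21, 23, 5, -8)
  S_on <- make_fit(21, 23, 5, 8)
  none <- structure(list(mappable = FALSE), class = "rf_estimate")
  ff_opp <- structure(list(label = "L_ON_S_OFF"), class = "opponency_call")
  ff_non <- structure(list(label = "non_opponent"), class = "opponency_call")
  r1 <- classify_rf_opponency(L_on, S_off, ff_non)
  expect_identical(r1$label, "opponent_RF_L_ON_S_OFF")
  expect_lt(r1$overlap, 1)
  expect_identical(classify_rf_opponency(L_on, S_on, ff_opp)$label,
                   "fullfield_only_opponent")
  expect_identical(classify_rf_opponency(L_on, none, ff_non)$label,
                   "single_opsin_only")
  expect_identical(classify_rf_opponency(none, none, ff_opp)$label,
                   "fullfield_only_opponent")
  expect_error(classify_rf_opponency(none, none, ff_non), "unclassifiable")
})

test_that("maps are equivariant to grid translation", {
  base <- expand.grid(azimuth_deg = seq(2, 38, by = 3),
                      elevation_deg = seq(8, 36, by = 3))
  base$response <- 10 * exp(-((base$azimuth_deg - 18)^2 +
                                (base$elevation_deg - 20)^2) / (2 * 6^2))
  shifted <- base
  shifted$azimuth_deg <- shifted$azimuth_deg + 7
  f0 <- fit_rf_center(base); f1 <- fit_rf_center(shifted)
  expect_equal(f1$center[["azimuth"]] - f0$center[["azimuth"]], 7,
               tolerance = 1e-3)
  expect_equal(f1$center[["elevation"]], f0$center[["elevation"]],
               tolerance = 1e-3)
})

test_that("elevation trend recovers a known preference gradient", {
  tr <- population_truth(make_population(600, seed = 210))
  cells <- tr[!is.na(tr$preference),
              c("preference", "elevation", "azimuth")]
  trend <- elevation_trend(cells)
  # generator slope is -0.012 per degree of elevation
  expect_lt(abs(trend$elevation$slope - (-0.012)) / 0.012, 0.10)
  expect_lt(trend$elevation$p, 0.01)
  expect_gt(trend$azimuth$p, 0.05)
  # degenerate cases
  const <- data.frame(preference = 0.2,
                      elevation = rep(seq(5, 55, by = 10), each = 4),
                      azimuth = rep(seq(5, 35, by = 10), 6))
  t0 <- elevation_trend(const)
  expect_equal(t0$elevation$slope, 0, tolerance = 1e-12)
  lin <- const
  lin$preference <- 0.5 - 0.01 * lin$elevation
  t1 <- elevation_trend(lin)
  expect_identical(t1$elevation$F, .Machine$double.xmax)
  expect_error(elevation_trend(data.frame(preference = 1:2,
                                          elevation = c(1, 2),
                                          azimuth = c(1, 2))), "3 populated")
})
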