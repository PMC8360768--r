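# Ground-truth model neurons and trial-structured spike-train generation.
# The rate model is a rectified-linear LN cascade: cone/rod contrast acts
# with a fixed latency, melanopsin contrast through an exponential
# low-pass (sluggish phototransduction), and spikes are drawn as an
# inhomogeneous Poisson process.

.neuron_classes <- c("nonopp_ON", "nonopp_OFF", "L_ON_S_OFF", "S_ON_L_OFF",
                     "nonresponsive")

# class prevalences observed across the LGN complex: 715 recorded units of
# which 433 responded (283 non-opponent, split ~89/11 ON/OFF; 72 L-ON/S-OFF;
# 78 S-ON/L-OFF), so opponent cells are ~35% of responsive cells.
.default_prevalences <- c(nonopp_ON = 252 / 715, nonopp_OFF = 31 / 715,
                          L_ON_S_OFF = 72 / 715, S_ON_L_OFF = 78 / 715,
                          nonresponsive = 282 / 715)

# probability a cell of each class is melanopsin-responsive (MR), from the
# observed cross-tabulation (19/72, 34/78, 113/283, 29/282).
.default_mr_prob <- c(nonopp_ON = 113 / 283, nonopp_OFF = 113 / 283,
                      L_ON_S_OFF = 19 / 72, S_ON_L_OFF = 34 / 78,
                      nonresponsive = 29 / 282)

#' Ground-truth parameters of one model neuron
#'
#' Weights are signed contributions (spikes/s at unit contrast, before the
#' shared `gain`); opponent classes have `sign(w_L) != sign(w_S)` with both
#' nonzero, non-opponent classes share one sign.
#'
#' @param unit_id Integer id.
#' @param class_label One of `nonopp_ON`, `nonopp_OFF`, `L_ON_S_OFF`,
#'   `S_ON_L_OFF`, `nonresponsive`.
#' @param w_L,w_S,w_rod Signed cone/rod weights.
#' @param w_mel Nonnegative melanopsin weight (spikes/s at full sustained
#'   mel drive); must be > 0 iff `mr_flag`.
#' @param baseline_rate Spontaneous rate, spikes/s, >= 0.
#' @param gain Multiplier on the cone/rod drive (spikes/s per unit
#'   weighted contrast).
#' @param latency Cone/rod response latency, s.
#' @param tau_mel Melanopsin low-pass time constant, s.
#' @param rf_center `c(azimuth_deg, elevation_deg)`.
#' @param rf_center_diameter RF center diameter, degrees; the surround
#'   diameter is fixed at 3x the center.
#' @param surround_weight Relative surround strength in `[0, 1]`.
#' @param anatomy `c(x_ml_um, y_dv_um)` within the LGN template.
#' @param mr_flag Logical, melanopsin-responsive ground truth.
#' @param rf_type `"ON"`, `"OFF"` or `"ON_OFF"` spatial response type.
#' @return Object of class `neuron_spec`.
#' @export
neuron_spec <- function(unit_id, class_label, w_L = 0, w_S = 0, w_rod = 0,
                        w_mel = 0, baseline_rate = 5, gain = 20,
                        latency = 0.05, tau_mel = 2,
                        rf_center = c(20, 25), rf_center_diameter = 12,
                        surround_weight = 0.25, anatomy = c(500, 500),
                        mr_flag = FALSE, rf_type = NULL) {
  class_label <- match.arg(class_label, .neuron_classes)
  stopifnot(baseline_rate >= 0, gain >= 0, rf_center_diameter > 0,
            surround_weight >= 0, surround_weight <= 1, tau_mel > 0)
  if (class_label %in% c("L_ON_S_OFF", "S_ON_L_OFF")) {
    if (w_L == 0 || w_S == 0 || sign(w_L) == sign(w_S)) {
      stop("opponent classes need nonzero opposite-sign w_L and w_S")
    }
    ok <- if (class_label == "L_ON_S_OFF") w_L > 0 else w_S > 0
    if (!ok) stop("weight signs inconsistent with ", class_label)
  }
  if (class_label %in% c("nonopp_ON", "nonopp_OFF")) {
    if (w_L * w_S < 0) stop("non-opponent classes need same-sign weights")
    sgn <- if (class_label == "nonopp_ON") 1 else -1
    if (sgn * (w_L + w_S) <= 0) stop("weight signs inconsistent with ", class_label)
  }
  if (mr_flag && w_mel <= 0) stop("mr_flag requires w_mel > 0")
  if (is.null(rf_type)) {
    rf_type <- switch(class_label, nonopp_OFF = "OFF", "ON")
  }
  structure(list(unit_id = as.integer(unit_id), class_label = class_label,
                 w_L = w_L, w_S = w_S, w_rod = w_rod, w_mel = w_mel,
                 baseline_rate = baseline_rate, gain = gain,
                 latency = latency, tau_mel = tau_mel,
                 rf_center = rf_center,
                 rf_center_diameter = rf_center_diameter,
                 surround_weight = surround_weight,
                 surround_diameter = 3 * rf_center_diameter,
                 anatomy = anatomy, mr_flag = mr_flag, rf_type = rf_type),
            class = "neuron_spec")
}

#' Sample a ground-truth population of model neurons
#'
#' Class labels follow `prevalences`; weights are drawn so the cone
#' preference index `(|w_L| - |w_S|)/(|w_L| + |w_S|)` of responsive cells
#' is linearly coupled to RF elevation (S-bias increasing with elevation,
#' mirroring the dorsoventral opsin gradient) with slope
#' `elevation_slope`, plus noise. Opponent cells cluster medially in the
#' anatomical template, non-opponent cells laterally.
#'
#' @param n Population size.
#' @param prevalences Named class probabilities summing to 1.
#' @param seed Integer seed.
#' @param baseline_range,gain_range,mel_weight_range Uniform sampling
#'   ranges.
#' @param elevation_range RF elevation span (degrees, snout-relative).
#' @param azimuth_range RF azimuth span (degrees).
#' @param elevation_slope Change in cone preference index per degree of
#'   elevation (negative: more S-biased higher up).
#' @param preference_sd SD of preference noise around the elevation trend.
#' @param mr_prob Named per-class probability of melanopsin input.
#' @param medial_sd,x_opponent,x_other,template_um Anatomical layout
#'   parameters (micrometres).
#' @return Object of class `population`: list of [neuron_spec()] plus the
#'   seed and prevalence table used.
#' @export
make_population <- function(n, prevalences = .default_prevalences, seed = 1,
                            baseline_range = c(3, 8),
                            gain_range = c(15, 25),
                            mel_weight_range = c(6, 14),
                            elevation_range = c(-10, 60),
                            azimuth_range = c(0, 40),
                            elevation_slope = -0.012,
                            preference_sd = 0.12,
                            mr_prob = .default_mr_prob,
                            medial_sd = 120, x_opponent = 320,
                            x_other = 650, template_um = c(1000, 1000)) {
  stopifnot(n >= 1, all(prevalences >= 0))
  if (abs(sum(prevalences) - 1) > 1e-8) stop("prevalences must sum to 1")
  if (!all(names(prevalences) %in% .neuron_classes)) {
    stop("unknown class in prevalences")
  }
  units <- with_seed(seed, {
    labels <- sample(names(prevalences), n, replace = TRUE, prob = prevalences)
    lapply(seq_len(n), function(i) {
      cls <- labels[i]
      el <- stats::runif(1, elevation_range[1], elevation_range[2])
      az <- stats::runif(1, azimuth_range[1], azimuth_range[2])
      # preference index tied to elevation (midpoint of the modeled span
      # pins the intercept), then perturbed and kept away from +/-1 so
      # both weights stay nonzero for opponent cells
      mid <- mean(elevation_range)
      pref <- elevation_slope * (el - mid) + stats::rnorm(1, 0, preference_sd)
      pref <- max(-0.85, min(0.85, pref))
      aL <- (1 + pref) / 2
      aS <- (1 - pref) / 2
      w <- switch(cls,
        nonopp_ON = c(aL, aS),
        nonopp_OFF = c(-aL, -aS),
        L_ON_S_OFF = c(aL, -aS),
        S_ON_L_OFF = c(-aL, aS),
        nonresponsive = c(0, 0))
      mr <- stats::runif(1) < mr_prob[[cls]]
      opp <- cls %in% c("L_ON_S_OFF", "S_ON_L_OFF")
      x0 <- if (opp) x_opponent else x_other
      xy <- c(min(max(stats::rnorm(1, x0, medial_sd), 0), template_um[1]),
              min(max(stats::rnorm(1, 500, 200), 0), template_um[2]))
      neuron_spec(
        unit_id = i, class_label = cls, w_L = w[1], w_S = w[2], w_rod = 0,
        w_mel = if (mr) stats::runif(1, mel_weight_range[1], mel_weight_range[2]) else 0,
        baseline_rate = stats::runif(1, baseline_range[1], baseline_range[2]),
        gain = if (cls == "nonresponsive") 0 else stats::runif(1, gain_range[1], gain_range[2]),
        rf_center = c(az, el),
        rf_center_diameter = stats::runif(1, 6, 20),
        surround_weight = stats::runif(1, 0, 0.5),
        anatomy = xy, mr_flag = mr)
    })
  })
  structure(list(units = units, seed = seed, prevalences = prevalences),
            class = "population")
}

#' @export
print.population <- function(x, ...) {
  tab <- table(vapply(x$units, `[[`, character(1), "class_label"))
  cat("<population>", length(x$units), "units:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Ground-truth label table of a population
#'
#' @param population A [make_population()] object.
#' @return data.frame: unit_id, class_label, mr_flag, preference
#'   (`(|w_L|-|w_S|)/(|w_L|+|w_S|)`), rf azimuth/elevation, anatomy.
#' @export
population_truth <- function(population) {
  u <- population$units
  data.frame(
    unit_id = vapply(u, `[[`, integer(1), "unit_id"),
    class_label = vapply(u, `[[`, character(1), "class_label"),
    mr_flag = vapply(u, `[[`, logical(1), "mr_flag"),
    preference = vapply(u, function(s) {
      if (abs(s$w_L) + abs(s$w_S) == 0) NA_real_
      else (abs(s$w_L) - abs(s$w_S)) / (abs(s$w_L) + abs(s$w_S))
    }, numeric(1)),
    azimuth = vapply(u, function(s) s$rf_center[1], numeric(1)),
    elevation = vapply(u, function(s) s$rf_center[2], numeric(1)),
    x_ml = vapply(u, function(s) s$anatomy[1], numeric(1)),
    y_dv = vapply(u, function(s) s$anatomy[2], numeric(1)))
}

# exponential low-pass with time constant tau on a uniformly sampled trace
lowpass_exp <- function(x, dt, tau) {
  a <- exp(-dt / tau)
  drop(stats::filter(x * (1 - a), a, method = "recursive"))
}

# shift a trace later in time by `lat` seconds (edge-padded)
shift_trace <- function(x, tt, lat) {
  if (lat == 0) return(x)
  stats::approx(tt, x, xout = tt - lat, rule = 2)$y
}

# deterministic firing-rate trace of one unit for a full-field waveform
unit_rate_trace <- function(unit, waveform) {
  tt <- waveform$time
  cx <- waveform$contrasts
  dt <- diff(tt[1:2])
  need <- c("L", "S", "rod", "mel")
  miss <- setdiff(need, colnames(cx))
  if (length(miss)) stop("waveform lacks contrast traces: ",
                         paste(miss, collapse = ", "))
  cone <- unit$w_L * shift_trace(cx[, "L"], tt, unit$latency) +
    unit$w_S * shift_trace(cx[, "S"], tt, unit$latency) +
    unit$w_rod * shift_trace(cx[, "rod"], tt, unit$latency)
  mel <- if (unit$w_mel > 0) {
    unit$w_mel * lowpass_exp(cx[, "mel"], dt, unit$tau_mel)
  } else 0
  pmax(0, unit$baseline_rate + unit$gain * cone + mel)
}

# draw one Poisson spike train (times) from a rate trace on grid tt
poisson_spikes <- function(rate, tt) {
  dt <- diff(tt)
  lam <- (rate[-length(rate)] + rate[-1]) / 2 * dt
  k <- stats::rpois(length(lam), lam)
  if (sum(k) == 0) return(numeric(0))
  idx <- rep.int(seq_along(k), k)
  sort(tt[idx] + stats::runif(sum(k)) * dt[idx])
}

#' Simulate trial-structured responses to a full-field waveform
#'
#' `rate(t) = max(0, baseline + gain*(w_L c_L + w_S c_S + w_rod c_rod)(t -
#' latency) + w_mel * lowpass(c_mel))`, spikes drawn as an inhomogeneous
#' Poisson process, independently per trial.
#'
#' @param population A [make_population()] object (or list of
#'   [neuron_spec()]).
#' @param waveform A stimulus `waveform` carrying per-opsin contrast
#'   traces.
#' @param n_trials Trials (repeats of the whole waveform) per unit.
#' @param seed Integer seed; every unit/trial gets a derived substream.
#' @return data.frame: `unit_id`, `trial`, `time_s` (sorted within trial).
#' @export
simulate_full_field <- function(population, waveform, n_trials = 5, seed = 1) {
  units <- if (inherits(population, "population")) population$units else population
  stopifnot(inherits(waveform, "waveform"), n_trials >= 1)
  out <- vector("list", length(units))
  for (i in seq_along(units)) {
    u <- units[[i]]
    rate <- unit_rate_trace(u, waveform)
    trials <- with_seed(derive_seed(seed, u$unit_id), {
      lapply(seq_len(n_trials), function(tr) poisson_spikes(rate, waveform$time))
    })
    ns <- vapply(trials, length, integer(1))
    out[[i]] <- data.frame(unit_id = u$unit_id,
                           trial = rep.int(seq_len(n_trials), ns),
                           time_s = unlist(trials))
  }
  do.call(rbind, out)
}

# Gaussian-overlap drive of a localized square/bar on a center-surround
# RF. Center and surround kernels have unit integral (so a full-field
# stimulus yields 1 - surround_weight per unit contrast); local drives
# are expressed relative to the center overlap of a perfectly centered
# stimulus, so the peak response amplitude is set by the cell's gain, not
# by the stimulus/RF area ratio.
spatial_drive <- function(unit, az, el, stim_size, full_field = FALSE) {
  sc <- unit$rf_center_diameter / 4
  ss <- unit$surround_diameter / 4
  if (full_field) return(1 - unit$surround_weight)
  sg <- stim_size / 4
  d2 <- (az - unit$rf_center[1])^2 + (el - unit$rf_center[2])^2
  f <- function(sig) exp(-d2 / (2 * (sig^2 + sg^2))) / (2 * pi * (sig^2 + sg^2))
  f0 <- 1 / (2 * pi * (sc^2 + sg^2))
  (f(sc) - unit$surround_weight * f(ss)) / f0
}

#' Simulate responses to spatially localized stimuli
#'
#' Each event (a light or dark bar/square) drives the unit through the
#' overlap of the stimulus with its Gaussian center minus
#' `surround_weight` times the overlap with its Gaussian surround
#' (surround sigma fixed at 3x center). The drive gates a transient rate
#' pulse of `pulse_ms` starting `latency` after onset; OFF cells invert
#' the sign, ON-OFF cells take the absolute value.
#'
#' @param population A [make_population()] object or list of specs.
#' @param events data.frame with columns `trial`, `onset_s`,
#'   `azimuth_deg`, `elevation_deg`, `size_deg`, and per-opsin contrasts
#'   `contrast_L`, `contrast_S` (signed; a dark stimulus has negative
#'   contrast). An optional logical `full_field` column marks full-field
#'   events.
#' @param trial_duration Duration of each trial (s); defaults to last
#'   onset + 0.5 s.
#' @param pulse_ms Transient response duration (default 80 ms).
#' @param seed Integer seed.
#' @return data.frame `unit_id`, `trial`, `time_s`.
#' @export
simulate_spatial <- function(population, events, trial_duration = NULL,
                             pulse_ms = 80, seed = 1) {
  units <- if (inherits(population, "population")) population$units else population
  need <- c("trial", "onset_s", "azimuth_deg", "elevation_deg", "size_deg",
            "contrast_L", "contrast_S")
  miss <- setdiff(need, names(events))
  if (length(miss)) stop("events lack columns: ", paste(miss, collapse = ", "))
  if (is.null(events$full_field)) events$full_field <- FALSE
  if (is.null(trial_duration)) trial_duration <- max(events$onset_s) + 0.5
  dt <- 0.005
  tt <- seq(0, trial_duration, by = dt)
  trials <- sort(unique(events$trial))
  out <- vector("list", length(units))
  for (i in seq_along(units)) {
    u <- units[[i]]
    geom <- vapply(seq_len(nrow(events)), function(e) {
      spatial_drive(u, events$azimuth_deg[e], events$elevation_deg[e],
                    events$size_deg[e], events$full_field[e])
    }, numeric(1))
    chrom <- u$w_L * events$contrast_L + u$w_S * events$contrast_S
    drive <- geom * chrom
    # signed weights already encode ON/OFF polarity; ON-OFF cells respond
    # to both polarities
    if (u$rf_type == "ON_OFF") drive <- abs(drive)
    amp <- u$gain * drive
    res <- with_seed(derive_seed(seed, u$unit_id), {
      lapply(trials, function(tr) {
        idx <- which(events$trial == tr)
        rate <- rep(u$baseline_rate, length(tt))
        for (e in idx) {
          w0 <- events$onset_s[e] + u$latency
          sel <- tt >= w0 & tt < w0 + pulse_ms / 1000
          rate[sel] <- rate[sel] + amp[e]
        }
        poisson_spikes(pmax(0, rate), tt)
      })
    })
    ns <- vapply(res, length, integer(1))
    out[[i]] <- data.frame(unit_id = u$unit_id,
                           trial = rep.int(trials, ns), time_s = unlist(res))
  }
  do.call(rbind, out)
}

#' Simulate responses to a white-noise contrast waveform
#'
#' The LN rate model evaluated frame-by-frame on the noise contrast
#' sequences (rates constant within a frame), Poisson spikes per frame.
#'
#' @param population A [make_population()] object or list of specs.
#' @param noise_waveform A waveform from [build_white_noise()].
#' @param seed Integer seed.
#' @return data.frame `unit_id`, `trial` (always 1), `time_s`.
#' @export
simulate_white_noise <- function(population, noise_waveform, seed = 1) {
  units <- if (inherits(population, "population")) population$units else population
  stopifnot(inherits(noise_waveform, "waveform"),
            noise_waveform$meta$kind == "noise")
  cx <- noise_waveform$contrasts
  rate_hz <- noise_waveform$meta$rate
  dt <- 1 / rate_hz
  tt <- noise_waveform$time
  out <- vector("list", length(units))
  for (i in seq_along(units)) {
    u <- units[[i]]
    lag <- round(u$latency * rate_hz)
    sh <- function(x) if (lag == 0) x else c(rep(0, lag), x[seq_len(length(x) - lag)])
    drive <- u$gain * (u$w_L * sh(cx[, "L"]) + u$w_S * sh(cx[, "S"]) +
                         u$w_rod * sh(cx[, "rod"]))
    rate <- pmax(0, u$baseline_rate + drive)
    times <- with_seed(derive_seed(seed, u$unit_id), {
      k <- stats::rpois(length(rate), rate * dt)
      idx <- rep.int(seq_along(k), k)
      sort(tt[idx] + stats::runif(sum(k)) * dt)
    })
    out[[i]] <- data.frame(unit_id = u$unit_id, trial = 1L, time_s = times)
  }
  do.call(rbind, out)
}

#' Ground-truth linear kernel of a unit at the noise frame rate
#'
#' @param unit A [neuron_spec()].
#' @param frame_rate Noise frame rate, Hz.
#' @param window Kernel window, s.
#' @return Matrix lags x opsins (L, S, rod): `gain * w` at the latency
#'   frame, 0 elsewhere.
#' @export
true_kernel <- function(unit, frame_rate = 10, window = 1) {
  n_lag <- round(window * frame_rate)
  k <- matrix(0, n_lag, 3, dimnames = list(NULL, c("L", "S", "rod")))
  lag <- round(unit$latency * frame_rate) + 1
  if (lag <= n_lag) {
    k[lag, ] <- unit$gain * c(unit$w_L, unit$w_S, unit$w_rod)
  }
  k
}

#' Write / read spike tables as CSV
#'
#' Columns `unit_id, trial, time_s`.
#'
#' @param spikes data.frame.
#' @param path File path.
#' @export
write_spikes_csv <- function(spikes, path) {
  utils::write.csv(spikes[c("unit_id", "trial", "time_s")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_spikes_csv
#' @export
read_spikes_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("unit_id", "trial", "time_s")
  if (!all(need %in% names(df))) stop("spike CSV needs columns ",
                                      paste(need, collapse = ", "))
  df[need]
}

#' Write population ground truth as JSON
#'
#' @param population A `population`.
#' @param path Output path.
#' @export
write_population_json <- function(population, path) {
  jsonlite::write_json(list(
    seed = population$seed,
    prevalences = as.list(population$prevalences),
    units = lapply(population$units, function(u) u[!vapply(u, is.null, TRUE)])
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
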