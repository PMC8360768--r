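# Receptive-field estimation from sparse bar/square stimuli, RF-based
# opponency typing, and the cone-preference-versus-elevation trend.
# Coordinate convention: elevations are relative to the snout axis; the
# projected dorsal-ventral retinal midpoint sits at +22 degrees.

#' Elevation (degrees, snout-relative) of the projected dorsoventral
#' retinal midpoint
#' @export
RETINAL_MIDPOINT_ELEVATION <- 22

#' Map responses across stimulus locations
#'
#' For each (location, polarity) condition: the response is the mean rate
#' in the best 50 ms window (5 ms steps) within 35--125 ms after stimulus
#' onset, minus the mean rate in the 100 ms before onset, averaged over
#' repeats. Light and dark responses are combined by subtraction (ON or
#' OFF cells) or addition (ON-OFF cells); with `cell_type = "auto"` the
#' type is inferred from the dominant response sign (light-driven
#' positive peak: ON; dark-driven: OFF; both comparable: ON-OFF) and
#' recorded in the result.
#'
#' @param spikes data.frame `trial`, `time_s` for one unit.
#' @param events data.frame: `trial`, `onset_s`, `azimuth_deg`,
#'   `elevation_deg`, `polarity` (+1 light / -1 dark).
#' @param cell_type `"auto"`, `"ON"`, `"OFF"` or `"ON_OFF"`.
#' @param win Response search window after onset, s (default `c(0.035,
#'   0.125)`), scanned with 50 ms epochs at 5 ms steps.
#' @param baseline_s Pre-onset baseline duration (default 0.1 s).
#' @return Object of class `location_response_map`: data.frame `map`
#'   (`azimuth_deg`, `elevation_deg`, `light`, `dark`, `combined`),
#'   `cell_type`, `cell_type_inferred`.
#' @export
location_response_map <- function(spikes, events,
                                  cell_type = c("auto", "ON", "OFF", "ON_OFF"),
                                  win = c(0.035, 0.125), baseline_s = 0.1) {
  cell_type <- match.arg(cell_type)
  need <- c("trial", "onset_s", "azimuth_deg", "elevation_deg", "polarity")
  miss <- setdiff(need, names(events))
  if (length(miss)) stop("events lack columns: ", paste(miss, collapse = ", "))
  starts <- seq(win[1], win[2] - 0.05, by = 0.005)
  # per event: best 50 ms epoch rate minus pre-onset baseline rate
  resp <- vapply(seq_len(nrow(events)), function(e) {
    tr <- events$trial[e]; on <- events$onset_s[e]
    tm <- spikes$time_s[spikes$trial == tr]
    rel <- tm - on
    base <- sum(rel >= -baseline_s & rel < 0) / baseline_s
    peak <- max(vapply(starts, function(s) {
      sum(rel >= s & rel < s + 0.05) / 0.05
    }, numeric(1)))
    peak - base
  }, numeric(1))
  agg <- stats::aggregate(
    resp,
    by = list(azimuth_deg = events$azimuth_deg,
              elevation_deg = events$elevation_deg,
              polarity = events$polarity),
    FUN = mean)
  light <- agg[agg$polarity == 1, c("azimuth_deg", "elevation_deg", "x")]
  dark <- agg[agg$polarity == -1, c("azimuth_deg", "elevation_deg", "x")]
  names(light)[3] <- "light"; names(dark)[3] <- "dark"
  map <- merge(light, dark, by = c("azimuth_deg", "elevation_deg"),
               all = TRUE)
  map$light[is.na(map$light)] <- 0; map$dark[is.na(map$dark)] <- 0
  inferred <- FALSE
  if (cell_type == "auto") {
    inferred <- TRUE
    ml <- max(map$light); md <- max(map$dark)
    cell_type <- if (ml > 0 && md > 0 && min(ml, md) / max(ml, md) > 0.5) {
      "ON_OFF"
    } else if (md > ml) "OFF" else "ON"
  }
  map$combined <- switch(cell_type,
                         ON = map$light - map$dark,
                         OFF = map$dark - map$light,
                         ON_OFF = map$light + map$dark)
  structure(list(map = map, cell_type = cell_type,
                 cell_type_inferred = inferred),
            class = "location_response_map")
}

#' Fit a Gaussian to a location response map
#'
#' Least-squares Gaussian plus constant offset: 1-D (bar stimuli; fit
#' along one axis) or isotropic 2-D (square stimuli). The fit is
#' "mappable" when the variance explained reaches `min_ve`.
#'
#' @param map A [location_response_map()] (its `combined` column is fit)
#'   or a data.frame with `azimuth_deg`, `elevation_deg`, `response`.
#' @param kind `"2D"` (default), `"1D_azimuth"` or `"1D_elevation"`.
#' @param min_ve Variance-explained acceptance threshold (default 0.4).
#' @return Object of class `rf_estimate`: `center` (az, el; `NA` on the
#'   unfit axis for 1-D), `sigma` (degrees), `amplitude`, `offset`,
#'   `variance_explained`, `mappable`, `converged`.
#' @export
fit_rf_center <- function(map, kind = c("2D", "1D_azimuth", "1D_elevation"),
                          min_ve = 0.4) {
  kind <- match.arg(kind)
  df <- if (inherits(map, "location_response_map")) {
    data.frame(azimuth_deg = map$map$azimuth_deg,
               elevation_deg = map$map$elevation_deg,
               response = map$map$combined)
  } else map
  if (kind != "2D") {
    axis <- if (kind == "1D_azimuth") "azimuth_deg" else "elevation_deg"
    prof <- stats::aggregate(list(resp = df$response),
                             by = list(pos = df[[axis]]), FUN = mean)
    xm <- matrix(prof$pos, ncol = 1)
    y <- prof$resp
  } else {
    xm <- as.matrix(df[c("azimuth_deg", "elevation_deg")])
    y <- df$response
  }
  n_loc <- nrow(unique(xm))
  if (n_loc < 5) stop("need >= 5 locations on each fitted axis")
  nd <- ncol(xm)
  span <- max(apply(xm, 2, function(v) diff(range(v))))
  peak <- xm[which.max(y), ]
  model <- function(p) {
    d2 <- rowSums(sweep(xm, 2, p[seq_len(nd)])^2)
    p[nd + 2] * exp(-d2 / (2 * p[nd + 1]^2)) + p[nd + 3]
  }
  lo <- c(apply(xm, 2, min) - span / 4, span / 50, -Inf, -Inf)
  hi <- c(apply(xm, 2, max) + span / 4, 2 * span, Inf, Inf)
  # multi-start over sigma, centered on the map extremes (an OFF-center
  # map is an inverted Gaussian with negative amplitude)
  starts <- list(c(peak, max(y) - stats::median(y)),
                 c(xm[which.min(y), ], min(y) - stats::median(y)))
  best <- NULL
  for (st in starts) {
    for (sig0 in span * c(0.05, 0.1, 0.2, 0.4)) {
      p0 <- c(st[seq_len(nd)], sig0, st[nd + 1], stats::median(y))
      fit <- try(stats::optim(p0, function(p) sum((y - model(p))^2),
                              method = "L-BFGS-B", lower = lo, upper = hi,
                              control = list(maxit = 500, factr = 1e3)),
                 silent = TRUE)
      if (!inherits(fit, "try-error") && is.finite(fit$value) &&
          (is.null(best) || fit$value < best$value)) best <- fit
    }
  }
  if (is.null(best)) {
    return(structure(list(converged = FALSE, mappable = FALSE),
                     class = "rf_estimate"))
  }
  p <- best$par
  ss_res <- best$value
  ss_tot <- sum((y - mean(y))^2)
  ve <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  ctr <- p[seq_len(nd)]
  center <- c(azimuth = NA_real_, elevation = NA_real_)
  if (kind == "2D") center[] <- ctr
  else if (kind == "1D_azimuth") center["azimuth"] <- ctr
  else center["elevation"] <- ctr
  # reject centers far outside the tested extent
  extent_ok <- all(vapply(seq_len(ncol(xm)), function(j) {
    r <- range(xm[, j]); ctr[j] >= r[1] - span / 4 && ctr[j] <= r[2] + span / 4
  }, logical(1)))
  structure(list(center = center, sigma = p[nd + 1],
                 amplitude = p[nd + 2], offset = p[nd + 3],
                 variance_explained = ve, converged = TRUE,
                 mappable = ve >= min_ve && extent_ok && p[nd + 2] != 0,
                 kind = kind),
            class = "rf_estimate")
}

#' Classify RF-level opponency
#'
#' Combines per-opsin RF maps/fits with the full-field opponency call:
#' both RFs mappable with opposite center polarity gives an opponent RF;
#' same-polarity or single-opsin RFs on a full-field-opponent cell give
#' `fullfield_only_opponent`; otherwise `non_opponent` or
#' `single_opsin_only`. The overlap metric is center distance over the
#' mean sigma of the two fits.
#'
#' @param L_fit,S_fit [fit_rf_center()] results (either may be
#'   unmappable); their `amplitude` sign after polarity combination
#'   determines center polarity, so pass fits of maps combined with
#'   `cell_type = "ON"` so that positive amplitude = ON center.
#' @param fullfield_call An [classify_opponency()] result, or `NULL`.
#' @return Object of class `rf_opponency_call`: `label`, `overlap`
#'   (center distance / mean sigma, `NA` unless both RFs mapped).
#' @export
classify_rf_opponency <- function(L_fit, S_fit, fullfield_call = NULL) {
  mappable <- function(f) !is.null(f) && isTRUE(f$mappable)
  pol <- function(f) if (f$amplitude >= 0) "ON" else "OFF"
  ff_opp <- !is.null(fullfield_call) &&
    fullfield_call$label %in% c("L_ON_S_OFF", "S_ON_L_OFF")
  lm <- mappable(L_fit); sm <- mappable(S_fit)
  overlap <- NA_real_
  if (lm && sm) {
    d <- sqrt(sum((L_fit$center - S_fit$center)^2, na.rm = TRUE))
    overlap <- d / mean(c(L_fit$sigma, S_fit$sigma))
    if (pol(L_fit) != pol(S_fit)) {
      lab <- if (pol(L_fit) == "ON") "opponent_RF_L_ON_S_OFF"
             else "opponent_RF_S_ON_L_OFF"
      return(structure(list(label = lab, overlap = overlap),
                       class = "rf_opponency_call"))
    }
    lab <- if (ff_opp) "fullfield_only_opponent" else "non_opponent"
    return(structure(list(label = lab, overlap = overlap),
                     class = "rf_opponency_call"))
  }
  if (lm || sm) {
    lab <- if (ff_opp) "fullfield_only_opponent" else "single_opsin_only"
    return(structure(list(label = lab, overlap = overlap),
                     class = "rf_opponency_call"))
  }
  if (ff_opp) {
    return(structure(list(label = "fullfield_only_opponent", overlap = overlap),
                     class = "rf_opponency_call"))
  }
  stop("nothing mappable and no full-field opponency: unclassifiable")
}

#' Cone preference versus RF position trends
#'
#' Bins cone preference by RF elevation (and azimuth), fits ordinary
#' least squares to the bin means, and tests for a non-zero slope with an
#' extra sum-of-squares F-test against the constant model:
#' `F = (SS_const - SS_line) / (SS_line / (k - 2))`.
#'
#' @param cells data.frame: `preference`, `elevation`, `azimuth`.
#' @param bin_deg Bin width in degrees (default 10).
#' @return List with `elevation` and `azimuth` components, each of class
#'   `elevation_trend`: `bins` (center, mean, n), `slope`, `intercept`,
#'   `F`, `p`, `df`.
#' @export
elevation_trend <- function(cells, bin_deg = 10) {
  stopifnot(all(c("preference", "elevation", "azimuth") %in% names(cells)))
  one_axis <- function(x, pref) {
    ctr <- floor(x / bin_deg) * bin_deg + bin_deg / 2
    agg <- stats::aggregate(pref, by = list(center = ctr),
                            FUN = function(v) c(mean(v), length(v)))
    bins <- data.frame(center = agg$center, mean = agg$x[, 1], n = agg$x[, 2])
    k <- nrow(bins)
    if (k < 3) stop("need >= 3 populated bins")
    fit <- stats::lm(mean ~ center, data = bins)
    ss_line <- sum(stats::residuals(fit)^2)
    ss_const <- sum((bins$mean - mean(bins$mean))^2)
    Fv <- if (ss_line <= 1e-10 * max(ss_const, .Machine$double.eps)) {
      .Machine$double.xmax   # numerically exact linear fit
    } else (ss_const - ss_line) / (ss_line / (k - 2))
    p <- stats::pf(Fv, 1, k - 2, lower.tail = FALSE)
    structure(list(bins = bins, slope = unname(stats::coef(fit)[2]),
                   intercept = unname(stats::coef(fit)[1]),
                   F = Fv, p = p, df = c(1, k - 2)),
              class = "elevation_trend")
  }
  cells <- cells[is.finite(cells$preference), , drop = FALSE]
  list(elevation = one_axis(cells$elevation, cells$preference),
       azimuth = one_axis(cells$azimuth, cells$preference))
}

#' Build a sparse-square mapping event table
#'
#' Squares on an 11 x 14 grid of overlapping locations, light and dark,
#' presented in random order with 250 ms on / 250 ms off, `n_repeats`
#' per condition, optionally per opsin channel (cone-isolating squares).
#'
#' @param n_az,n_el Grid size (default 14 x 11 to cover a 40 x 30 degree
#'   display).
#' @param extent_az,extent_el Display extent, degrees.
#' @param origin_az,origin_el Display lower-left corner, degrees.
#' @param size_deg Square size (default 6).
#' @param contrast Michelson contrast magnitude (default 0.72).
#' @param opsin `"both"` (achromatic), `"L"` or `"S"`.
#' @param n_repeats Repeats per location/polarity (default 8).
#' @param seed Order-shuffling seed.
#' @return Events data.frame suitable for [simulate_spatial()] and
#'   [location_response_map()]; one trial per repeat.
#' @export
square_mapping_events <- function(n_az = 14, n_el = 11, extent_az = 40,
                                  extent_el = 30, origin_az = 0,
                                  origin_el = 7, size_deg = 6,
                                  contrast = 0.72,
                                  opsin = c("both", "L", "S"),
                                  n_repeats = 8, seed = 1) {
  opsin <- match.arg(opsin)
  az <- origin_az + (seq_len(n_az) - 0.5) * extent_az / n_az
  el <- origin_el + (seq_len(n_el) - 0.5) * extent_el / n_el
  conds <- expand.grid(azimuth_deg = az, elevation_deg = el,
                       polarity = c(1, -1))
  with_seed(seed, {
    out <- lapply(seq_len(n_repeats), function(rep_i) {
      ord <- sample.int(nrow(conds))
      df <- conds[ord, , drop = FALSE]
      df$trial <- rep_i
      df$onset_s <- (seq_len(nrow(df)) - 1) * 0.5
      df
    })
    ev <- do.call(rbind, out)
    ev$size_deg <- size_deg
    ev$contrast_L <- if (opsin %in% c("both", "L")) ev$polarity * contrast else 0
    ev$contrast_S <- if (opsin %in% c("both", "S")) ev$polarity * contrast else 0
    rownames(ev) <- NULL
    ev
  })
}
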