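# "Random wiring" retinal model: does a center-surround RF sampling
# non-selectively from a graded S/L(M)-opsin cone mosaic produce color
# opponency, as a function of surround weight, RF size, sampling fraction
# and dorsoventral position?

#' Parametric dorsoventral cone opsin gradient
#'
#' A smooth stand-in for reported mouse cone-type distributions:
#' genuine S-cones are sparse everywhere; L(M)-opsin-only cones dominate
#' dorsally and give way to co-expressing cones around the dorsoventral
#' midpoint; the S-opsin fraction of co-expressers rises from 10% dorsal
#' to 90% ventral along a logistic.
#'
#' Coordinate: `v` in `[0, 1]`, 0 = dorsal pole, 0.5 = midpoint.
#'
#' @param s_only_density Fraction of genuine S-cones (default 0.05).
#' @param l_only_max Dorsal plateau fraction of L-only cones (default
#'   0.7: most dorsal cones express predominantly L(M)-opsin).
#' @param l_only_mid,l_only_slope Logistic midpoint and slope of the
#'   L-only decline (defaults 0.5, 0.05: a sharp transition at the
#'   horizontal meridian).
#' @param s_frac_range S-opsin fraction range for co-expressers (default
#'   `c(0.1, 0.9)`).
#' @param s_frac_mid,s_frac_slope Logistic midpoint and slope of the
#'   co-expresser S fraction (defaults 0.5, 0.05).
#' @return Object of class `cone_gradient` with functions
#'   `type_probs(v)` (matrix v x {s_only, l_only, coexp}) and
#'   `s_fraction(v)`.
#' @export
cone_gradient <- function(s_only_density = 0.05, l_only_max = 0.7,
                          l_only_mid = 0.5, l_only_slope = 0.05,
                          s_frac_range = c(0.1, 0.9), s_frac_mid = 0.5,
                          s_frac_slope = 0.05) {
  stopifnot(s_only_density >= 0, l_only_max >= 0,
            s_only_density + l_only_max <= 1,
            s_frac_range[1] >= 0.1 - 1e-9, s_frac_range[2] <= 0.9 + 1e-9)
  type_probs <- function(v) {
    l_only <- l_only_max * stats::plogis((l_only_mid - v) / l_only_slope)
    s_only <- rep(s_only_density, length(v))
    cbind(s_only = s_only, l_only = l_only, coexp = 1 - s_only - l_only)
  }
  s_fraction <- function(v) {
    s_frac_range[1] + diff(s_frac_range) *
      stats::plogis((v - s_frac_mid) / s_frac_slope)
  }
  structure(list(type_probs = type_probs, s_fraction = s_fraction,
                 params = list(s_only_density = s_only_density,
                               l_only_max = l_only_max,
                               l_only_mid = l_only_mid,
                               l_only_slope = l_only_slope,
                               s_frac_range = s_frac_range,
                               s_frac_mid = s_frac_mid,
                               s_frac_slope = s_frac_slope)),
            class = "cone_gradient")
}

#' Sample a 1-D strip of cones from the gradient
#'
#' Cone positions are uniform along the strip; types follow the
#' gradient's categorical distribution at each position; co-expressers
#' get their deterministic position-dependent S fraction.
#'
#' @param gradient A [cone_gradient()].
#' @param n_cones Number of cones (>= 1; default 500).
#' @param extent_deg Strip length in visual degrees (default 100,
#'   roughly the dorsoventral span of the mouse retina).
#' @param seed Integer seed.
#' @return Object of class `retinal_strip`: data.frame `cones`
#'   (`position_deg`, `v`, `type`, `s_fraction`, `l_fraction`, sorted by
#'   position), `extent_deg`, `seed`.
#' @export
sample_strip <- function(gradient, n_cones = 500, extent_deg = 100, seed = 1) {
  stopifnot(inherits(gradient, "cone_gradient"), n_cones >= 1)
  probe <- gradient$type_probs(c(0.1, 0.5, 0.9))
  if (all(rowSums(probe) == 0)) stop("degenerate gradient: all densities zero")
  cones <- with_seed(seed, {
    v <- sort(stats::runif(n_cones))
    pr <- gradient$type_probs(v)
    u <- stats::runif(n_cones)
    type <- ifelse(u < pr[, "s_only"], "s_only",
                   ifelse(u < pr[, "s_only"] + pr[, "l_only"], "l_only",
                          "coexp"))
    sf <- ifelse(type == "s_only", 1,
                 ifelse(type == "l_only", 0, gradient$s_fraction(v)))
    data.frame(position_deg = v * extent_deg, v = v, type = type,
               s_fraction = sf, l_fraction = 1 - sf)
  })
  structure(list(cones = cones, extent_deg = extent_deg, seed = seed),
            class = "retinal_strip")
}

#' Model-RF parameters for the random-wiring simulation
#'
#' @param center_deg RF center position along the strip (degrees).
#' @param center_diameter Center diameter, 6--20 degrees.
#' @param surround_weight Relative surround strength, 0.5--1 in the
#'   standard sweep (any value in `[0, 1]` accepted).
#' @param sampling_fraction Fraction of cones within the RF actually
#'   wired, in `(0, 1]`.
#' @return Object of class `model_rf_spec`; surround diameter is fixed
#'   at 3x center.
#' @export
model_rf_spec <- function(center_deg, center_diameter = 12,
                          surround_weight = 1, sampling_fraction = 1) {
  stopifnot(center_diameter > 0, surround_weight >= 0, surround_weight <= 1,
            sampling_fraction > 0, sampling_fraction <= 1)
  structure(list(center_deg = center_deg,
                 center_diameter = center_diameter,
                 surround_diameter = 3 * center_diameter,
                 surround_weight = surround_weight,
                 sampling_fraction = sampling_fraction),
            class = "model_rf_spec")
}

#' Effective per-opsin contrast response of a model RF
#'
#' Each sampled cone contributes its opsin fraction weighted by Gaussian
#' center and surround profiles (sigma = diameter / 4). Kernels are
#' normalized by their *expected* total weight over the cone mosaic
#' (density x sampling fraction x Gaussian mass), not by the realized
#' draw: random wiring means a neuron does not renormalize away its
#' sampling imbalance, and it is exactly this imbalance, riding on the
#' opsin gradient, that can produce opponency. On this scale a full-field
#' unit-contrast stimulus drives `1 - surround_weight` in expectation.
#' The per-opsin response is
#' `stimulus_contrast * (center_sum - surround_weight * surround_sum)`;
#' opponency requires opposite-sign L and S responses, both exceeding
#' `tol` times the larger magnitude. The bias index is computed from the
#' summed cone *input weights* per opsin (the model's wiring, not the
#' response): `(W_L - W_S) / (W_L + W_S)`.
#'
#' @param strip A [sample_strip()] result.
#' @param rf A [model_rf_spec()].
#' @param stimulus Named contrasts, default `c(L = 0.75, S = 0.75)` (the
#'   L-only and S-only stimuli applied at 75%, each read out on its own
#'   opsin channel).
#' @param tol Relative zero threshold (default 1e-6).
#' @param seed Seed for the sampling-fraction subset.
#' @return Object of class `model_result`: `response` (L, S), `opponent`,
#'   `bias` (cone input-weight preference index), `n_cones_used`,
#'   `dv_position` (v of the center), `empty`.
#' @export
rf_response <- function(strip, rf, stimulus = c(L = 0.75, S = 0.75),
                        tol = 1e-6, seed = 1) {
  stopifnot(inherits(strip, "retinal_strip"), inherits(rf, "model_rf_spec"))
  cones <- strip$cones
  if (rf$center_deg < 0 || rf$center_deg > strip$extent_deg) {
    stop("RF center outside the strip extent")
  }
  sig_c <- rf$center_diameter / 4
  sig_s <- rf$surround_diameter / 4
  d <- cones$position_deg - rf$center_deg
  use <- which(abs(d) <= 3 * sig_s)
  if (rf$sampling_fraction < 1 && length(use) > 0) {
    keep <- with_seed(seed, {
      stats::runif(length(use)) < rf$sampling_fraction
    })
    use <- use[keep]
  }
  if (length(use) == 0) {
    return(structure(list(empty = TRUE, n_cones_used = 0L),
                     class = "model_result"))
  }
  density <- nrow(cones) / strip$extent_deg
  norm_c <- rf$sampling_fraction * density * sqrt(2 * pi) * sig_c
  norm_s <- rf$sampling_fraction * density * sqrt(2 * pi) * sig_s
  wc <- exp(-d[use]^2 / (2 * sig_c^2)) / norm_c
  ws <- exp(-d[use]^2 / (2 * sig_s^2)) / norm_s
  resp <- vapply(c(L = "l_fraction", S = "s_fraction"), function(col) {
    sum(wc * cones[[col]][use]) -
      rf$surround_weight * sum(ws * cones[[col]][use])
  }, numeric(1))
  resp <- resp * stimulus[c("L", "S")]
  mx <- max(abs(resp))
  nonzero <- mx > 0 & abs(resp) > tol * mx
  opponent <- all(nonzero) && sign(resp[["L"]]) != sign(resp[["S"]])
  w_in <- vapply(c(L = "l_fraction", S = "s_fraction"), function(col) {
    sum((wc + rf$surround_weight * ws) * cones[[col]][use])
  }, numeric(1))
  bias <- if (sum(w_in) == 0) NA_real_ else {
    (w_in[["L"]] - w_in[["S"]]) / sum(w_in)
  }
  structure(list(empty = FALSE, response = resp, opponent = opponent,
                 bias = bias, input_weights = w_in,
                 n_cones_used = length(use),
                 dv_position = rf$center_deg / strip$extent_deg),
            class = "model_result")
}

#' Parameter sweep of the random-wiring model
#'
#' For every cell of the parameter grid, `n_strips` independent strips
#' are sampled, each probed by one RF at a random position; the summary
#' reports opponency prevalence (overall and split dorsal/ventral of the
#' midpoint) and the mean absolute cone-weight bias of opponent versus
#' non-opponent cells.
#'
#' @param gradient A [cone_gradient()].
#' @param center_diameters,surround_weights,sampling_fractions Grid
#'   values (defaults span the standard ranges 6--20 deg, 0.5--1,
#'   0.01--1).
#' @param n_strips Strips per parameter cell (default 100).
#' @param n_cones Cones per strip.
#' @param extent_deg Strip extent.
#' @param seed Master seed.
#' @return List: `cells` (tidy data.frame, one row per parameter cell x
#'   strip) and `summary` (one row per parameter cell).
#' @export
sweep_random_wiring <- function(gradient,
                                center_diameters = c(6, 13, 20),
                                surround_weights = c(0.5, 0.75, 1),
                                sampling_fractions = c(0.1, 0.5, 1),
                                n_strips = 100, n_cones = 500,
                                extent_deg = 100, seed = 1) {
  grid <- expand.grid(center_diameter = center_diameters,
                      surround_weight = surround_weights,
                      sampling_fraction = sampling_fractions)
  rows <- vector("list", nrow(grid) * n_strips)
  k <- 0
  for (s in seq_len(n_strips)) {
    strip <- sample_strip(gradient, n_cones = n_cones,
                          extent_deg = extent_deg,
                          seed = derive_seed(seed, s))
    centers <- with_seed(derive_seed(seed, 100000 + s), {
      stats::runif(nrow(grid), 0.15, 0.85) * extent_deg
    })
    for (g in seq_len(nrow(grid))) {
      rf <- model_rf_spec(centers[g], grid$center_diameter[g],
                          grid$surround_weight[g],
                          grid$sampling_fraction[g])
      res <- rf_response(strip, rf, seed = derive_seed(seed, 200000 + s * 100 + g))
      k <- k + 1
      rows[[k]] <- data.frame(
        strip = s, center_diameter = grid$center_diameter[g],
        surround_weight = grid$surround_weight[g],
        sampling_fraction = grid$sampling_fraction[g],
        dv_position = if (res$empty) NA_real_ else res$dv_position,
        response_L = if (res$empty) NA_real_ else res$response[["L"]],
        response_S = if (res$empty) NA_real_ else res$response[["S"]],
        opponent = if (res$empty) NA else res$opponent,
        bias = if (res$empty) NA_real_ else res$bias)
    }
  }
  cells <- do.call(rbind, rows)
  ok <- !is.na(cells$opponent)
  summary <- do.call(rbind, lapply(seq_len(nrow(grid)), function(g) {
    sel <- ok & cells$center_diameter == grid$center_diameter[g] &
      cells$surround_weight == grid$surround_weight[g] &
      cells$sampling_fraction == grid$sampling_fraction[g]
    cc <- cells[sel, , drop = FALSE]
    dorsal <- cc$dv_position < 0.5
    data.frame(
      center_diameter = grid$center_diameter[g],
      surround_weight = grid$surround_weight[g],
      sampling_fraction = grid$sampling_fraction[g],
      n = nrow(cc),
      prevalence = mean(cc$opponent),
      prevalence_dorsal = if (any(dorsal)) mean(cc$opponent[dorsal]) else NA_real_,
      prevalence_ventral = if (any(!dorsal)) mean(cc$opponent[!dorsal]) else NA_real_,
      mean_abs_bias_opponent = if (any(cc$opponent)) {
        mean(abs(cc$bias[cc$opponent])) } else NA_real_,
      mean_abs_bias_nonopponent = if (any(!cc$opponent)) {
        mean(abs(cc$bias[!cc$opponent])) } else NA_real_)
  }))
  list(cells = cells, summary = summary)
}
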