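# Multiprimary silent-substitution design: solve per-primary modulations
# hitting target opsin Michelson contrasts, validate residuals from first
# principles, and build stimulus waveforms (square waves, Mel High/Low
# steps, white noise).

#' LED primary with a Gaussian spectral model
#'
#' The spectrum at unit drive is a Gaussian in wavelength with the stated
#' peak and FWHM; drive scales the spectrum linearly (no saturation model).
#'
#' @param label Short name, e.g. `"405"`.
#' @param peak_nm Peak wavelength (nm).
#' @param fwhm_nm Full width at half maximum (nm), default 20.
#' @param max_drive Upper drive bound (same units as background drives).
#' @param grid Wavelength grid for the spectrum.
#' @return Object of class `primary` with a unit-drive [spectral_curve()].
#' @export
led_primary <- function(label, peak_nm, fwhm_nm = 20, max_drive = Inf,
                        grid = wavelength_grid()) {
  stopifnot(peak_nm > 0, fwhm_nm > 0, max_drive > 0)
  wl <- as.numeric(grid)
  sigma <- fwhm_nm / (2 * sqrt(2 * log(2)))
  vals <- exp(-(wl - peak_nm)^2 / (2 * sigma^2))
  structure(list(label = label, peak_nm = peak_nm, fwhm_nm = fwhm_nm,
                 max_drive = max_drive,
                 spectrum = spectral_curve(wl, vals)),
            class = "primary")
}

#' The default three-LED primary set (405, 460, 620 nm)
#'
#' @param fwhm_nm Shared FWHM (nm).
#' @param grid Wavelength grid.
#' @return Named list of [led_primary()] objects.
#' @export
default_primaries <- function(fwhm_nm = 20, grid = wavelength_grid()) {
  peaks <- c(`405` = 405, `460` = 460, `620` = 620)
  lapply(stats::setNames(nm = names(peaks)), function(nm) {
    led_primary(nm, peaks[[nm]], fwhm_nm = fwhm_nm, grid = grid)
  })
}

#' Daylight-like photon flux spectrum
#'
#' Blackbody photon spectral radiance at the given color temperature,
#' normalized to a total photon flux over the grid. Serves as the "natural
#' daylight" reference that backgrounds are matched to.
#'
#' @param grid Wavelength grid.
#' @param temp_K Color temperature (K), default 5500.
#' @param total_flux Total photon flux over the grid (photons/cm^2/s).
#' @return [spectral_curve()] of photon flux density.
#' @export
daylight_spectrum <- function(grid = wavelength_grid(), temp_K = 5500,
                              total_flux = 1e15) {
  wl_m <- as.numeric(grid) * 1e-9
  h <- 6.62607015e-34; c0 <- 299792458; kB <- 1.380649e-23
  # photon spectral density ~ lambda^-4 / (exp(hc/lambda kT) - 1)
  q <- wl_m^-4 / (exp(h * c0 / (wl_m * kB * temp_K)) - 1)
  sc <- spectral_curve(as.numeric(grid), q)
  scale <- total_flux / trapz(sc$wavelengths, sc$values)
  spectral_curve(sc$wavelengths, sc$values * scale)
}

# P[i, j]: opsin-effective flux of primary j at unit drive, for opsin i.
opsin_flux_matrix <- function(primaries, opsins = default_opsins(),
                              lens = default_lens()) {
  P <- vapply(primaries, function(pr) {
    vapply(opsins, function(op) {
      effective_flux(pr$spectrum, nomogram_sensitivity(op, pr$spectrum$wavelengths),
                     lens)
    }, numeric(1))
  }, numeric(length(opsins)))
  dimnames(P) <- list(names(opsins), names(primaries))
  P
}

#' Background settings for a primary set
#'
#' Solves primary drive levels so the background recreates a wild-type
#' mouse's experience of natural daylight: the opsin-effective photon
#' fluxes of the *wild-type* opsin complement (S-cone 365 nm, native
#' M-cone 508 nm, rod 498 nm) match those of a daylight reference
#' spectrum. Contrasts for the recorded animals are then computed against
#' the red-shifted L-opsin (and mel) sensitivities in `opsins`. Matching
#' the native M-opsin is what forces most of the long-wavelength flux
#' onto the red primary, which in turn makes high-contrast L-opsin
#' isolation possible with small rod/mel residuals. The `reduced_s`
#' variant attenuates the S-opsin flux target (used for white-noise
#' experiments needing independent rod/cone contrast), and `nd` applies a
#' spectrally neutral `10^-nd` scaling.
#'
#' @param primaries Named list of [led_primary()] objects (>= 3).
#' @param opsins Named list of [opsin()] objects used for contrast
#'   arithmetic; must include S, L, rod, mel.
#' @param lens Prereceptoral transmission curve.
#' @param variant `"daylight"` or `"reduced_s"`.
#' @param s_scale Multiplier on the daylight S flux for `reduced_s`.
#' @param nd Neutral-density level (0--4).
#' @param daylight Reference [spectral_curve()]; default [daylight_spectrum()].
#' @param match_lambda_max Peak sensitivities (nm) of the opsin set whose
#'   daylight fluxes the background reproduces (default wild-type
#'   S/M/rod).
#' @return Object of class `background`: drives, per-opsin fluxes, the
#'   unit-drive flux matrix and bookkeeping.
#' @export
make_background <- function(primaries = default_primaries(),
                            opsins = default_opsins(),
                            lens = default_lens(),
                            variant = c("daylight", "reduced_s"),
                            s_scale = 0.1, nd = 0,
                            daylight = NULL,
                            match_lambda_max = c(S = 365, M = 508, rod = 498)) {
  variant <- match.arg(variant)
  stopifnot(length(primaries) >= 3, nd >= 0, nd <= 4,
            length(match_lambda_max) == 3)
  if (is.null(daylight)) {
    daylight <- daylight_spectrum(primaries[[1]]$spectrum$wavelengths)
  }
  P <- opsin_flux_matrix(primaries, opsins, lens)
  match_ops <- mapply(opsin, names(match_lambda_max), match_lambda_max,
                      SIMPLIFY = FALSE)
  P_match <- opsin_flux_matrix(primaries, match_ops, lens)
  f_day <- vapply(match_ops, function(op) {
    effective_flux(daylight, nomogram_sensitivity(op, daylight$wavelengths), lens)
  }, numeric(1))
  if (variant == "reduced_s") f_day["S"] <- f_day["S"] * s_scale
  # use the first three primaries to hit the three matched fluxes exactly
  d3 <- solve(P_match[, 1:3, drop = FALSE], f_day)
  if (any(d3 < 0)) {
    stop("daylight-matched background infeasible: negative drive for primary ",
         paste(names(primaries)[1:3][d3 < 0], collapse = ", "))
  }
  drives <- stats::setNames(rep(0, length(primaries)), names(primaries))
  drives[1:3] <- d3
  drives <- drives * 10^(-nd)
  fluxes <- drop(P %*% drives)
  structure(list(drives = drives, fluxes = fluxes, P = P,
                 primaries = primaries, opsins = opsins, lens = lens,
                 variant = variant, nd = nd),
            class = "background")
}

#' Rescale a background by a neutral-density filter
#'
#' @param background A [make_background()] object.
#' @param nd New ND level (total, not incremental).
#' @return New `background` with drives scaled by `10^(nd_old - nd)`.
#' @export
with_nd <- function(background, nd) {
  stopifnot(inherits(background, "background"), nd >= 0, nd <= 4)
  background$drives <- background$drives * 10^(background$nd - nd)
  background$fluxes <- drop(background$P %*% background$drives)
  background$nd <- nd
  background
}

#' Specification of per-opsin contrast constraints
#'
#' @param target Named numeric of signed Michelson fractions to hit
#'   exactly (e.g. `c(L = 0.75)`), each `|value| < 1`.
#' @param silence Character vector of opsins whose contrast is constrained
#'   to exactly zero.
#' @param minimize Character vector of opsins whose maximum absolute
#'   contrast is minimized with any remaining degrees of freedom.
#' @return Object of class `contrast_spec`.
#' @export
contrast_spec <- function(target = numeric(), silence = character(),
                          minimize = character()) {
  stopifnot(all(abs(target) < 1))
  if (length(intersect(names(target), silence)) > 0) {
    stop("an opsin cannot be both targeted and silenced")
  }
  structure(list(target = target, silence = silence, minimize = minimize),
            class = "contrast_spec")
}

# Weight matrix W[i, j] = d_j P[i, j] / F_i: Michelson contrast per unit
# modulation fraction (the bright/dim phases are d * (1 +/- m), so the
# contrast of opsin i is sum_j W[i, j] m_j exactly).
contrast_weight_matrix <- function(background) {
  sweep(background$P, 2, background$drives, `*`) / background$fluxes
}

#' Solve a silent-substitution modulation
#'
#' Finds per-primary modulation fractions `m` (drive `d*(1+m)` in the
#' bright phase, `d*(1-m)` in the dim phase) such that targeted opsins see
#' their requested Michelson contrast and silenced opsins see zero. Any
#' remaining degrees of freedom minimize the maximum absolute contrast
#' over the `minimize` opsins (bounded search). Achieved contrasts are
#' recomputed from the full bright/dim spectra, not from the linear system.
#'
#' @param background A [make_background()] object.
#' @param spec A [contrast_spec()].
#' @return Object of class `substitution_solution` with fields
#'   `modulation` (per primary), `achieved` (per opsin, from spectra),
#'   `feasible`, `spec`, `condition`.
#' @export
solve_silent_substitution <- function(background, spec) {
  stopifnot(inherits(background, "background"), inherits(spec, "contrast_spec"))
  W <- contrast_weight_matrix(background)
  npr <- ncol(W)
  constrained <- c(names(spec$target), spec$silence)
  if (length(constrained) > npr) {
    stop("more constrained opsins (", length(constrained),
         ") than primaries (", npr, ")")
  }
  bad <- setdiff(c(constrained, spec$minimize), rownames(W))
  if (length(bad)) stop("unknown opsin(s): ", paste(bad, collapse = ", "))
  rhs <- c(spec$target, stats::setNames(rep(0, length(spec$silence)), spec$silence))
  if (length(constrained) == 0) {
    m <- rep(0, npr)
    cond <- 1
  } else {
    Wc <- W[constrained, , drop = FALSE]
    sv <- svd(Wc)
    cond <- sv$d[1] / sv$d[length(sv$d)]
    if (!is.finite(cond) || cond > 1e10) {
      stop("silent-substitution system is numerically singular (condition ",
           format(cond), ")")
    }
    if (length(constrained) == npr) {
      m <- solve(Wc, rhs)
    } else {
      # minimum-norm particular solution + null-space search
      m0 <- drop(sv$v %*% ((t(sv$u) %*% rhs) / sv$d))
      Nmat <- svd(Wc, nu = 0, nv = npr)$v[, (length(constrained) + 1):npr,
                                          drop = FALSE]
      m <- m0 + drop(Nmat %*% optimize_null_space(W, m0, Nmat, spec$minimize))
    }
  }
  m <- stats::setNames(as.numeric(m), colnames(W))
  achieved <- achieved_contrasts(background, m)
  feas <- all(abs(m) <= 1 + 1e-12) &&
    all(vapply(seq_along(m), function(j) {
      mx <- background$primaries[[j]]$max_drive
      background$drives[j] * (1 + abs(m[j])) <= mx ||
        background$drives[j] == 0
    }, logical(1)))
  structure(list(modulation = m, achieved = achieved, spec = spec,
                 feasible = feas, condition = cond),
            class = "substitution_solution")
}

# Minimize max |contrast| over `minimize` opsins along the null space.
# For the common 1-D case the objective is a convex piecewise-linear
# function of t; a coarse grid plus local refinement finds the minimum.
optimize_null_space <- function(W, m0, Nmat, minimize) {
  kdim <- ncol(Nmat)
  if (length(minimize) == 0) return(rep(0, kdim))
  Wm <- W[minimize, , drop = FALSE]
  base <- drop(Wm %*% m0)
  slope <- Wm %*% Nmat
  obj <- function(t) max(abs(base + drop(slope %*% t)))
  if (kdim == 1) {
    # t range keeping |m| <= 1 componentwise
    lo <- -Inf; hi <- Inf
    for (j in seq_along(m0)) {
      n <- Nmat[j, 1]
      if (abs(n) < 1e-14) next
      r <- sort(c((-1 - m0[j]) / n, (1 - m0[j]) / n))
      lo <- max(lo, r[1]); hi <- min(hi, r[2])
    }
    if (!is.finite(lo)) { lo <- -1e3 }
    if (!is.finite(hi)) { hi <- 1e3 }
    if (lo > hi) return(matrix(0, 1))
    ts <- seq(lo, hi, length.out = 2001)
    vals <- vapply(ts, function(t) obj(t), numeric(1))
    i <- which.min(vals)
    lo2 <- ts[max(1, i - 1)]; hi2 <- ts[min(length(ts), i + 1)]
    matrix(stats::optimize(function(t) obj(t), c(lo2, hi2),
                           tol = 1e-12)$minimum, 1)
  } else {
    fit <- stats::optim(rep(0, kdim), function(t) obj(t),
                        method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 5000))
    matrix(fit$par, kdim)
  }
}

# Recompute per-opsin Michelson contrasts from the full bright/dim spectra
# (sum of primary spectra at modulated drives), the first-principles path.
achieved_contrasts <- function(background, modulation) {
  wl <- background$primaries[[1]]$spectrum$wavelengths
  spec_mat <- vapply(background$primaries, function(p) {
    resample_curve(p$spectrum, wl)$values
  }, numeric(length(wl)))
  bright <- spectral_curve(wl, pmax(drop(
    spec_mat %*% (background$drives * (1 + modulation))), 0))
  dim_ <- spectral_curve(wl, pmax(drop(
    spec_mat %*% (background$drives * (1 - modulation))), 0))
  vapply(background$opsins, function(op) {
    sens <- nomogram_sensitivity(op, wl)
    michelson_contrast(effective_flux(bright, sens, background$lens),
                       effective_flux(dim_, sens, background$lens))
  }, numeric(1))
}

#' Validate a substitution solution against contrast bounds
#'
#' Recomputes all opsin contrasts from first principles (spectra to fluxes
#' to Michelson contrast) and checks: targets within `target_tol` of their
#' requested value, silenced opsins within `silence_bound`, minimized
#' opsins within `residual_bound`.
#'
#' @param solution A [solve_silent_substitution()] result.
#' @param background The background it was solved against.
#' @param target_tol Absolute tolerance on targeted contrasts.
#' @param silence_bound Bound on silenced-opsin |contrast| (default 0.002,
#'   i.e. 0.2% Michelson).
#' @param residual_bound Bound on minimized-opsin |contrast| (default
#'   0.06, i.e. 6%).
#' @return data.frame: opsin, role, achieved, bound, pass; attribute
#'   `all_pass`.
#' @export
validate_solution <- function(solution, background, target_tol = 1e-6,
                              silence_bound = 0.002, residual_bound = 0.06) {
  stopifnot(inherits(solution, "substitution_solution"))
  ach <- achieved_contrasts(background, solution$modulation)
  spec <- solution$spec
  role <- stats::setNames(rep("free", length(ach)), names(ach))
  role[spec$silence] <- "silenced"
  role[spec$minimize] <- "minimize"
  role[names(spec$target)] <- "target"
  err <- abs(ach)
  err[names(spec$target)] <- abs(ach[names(spec$target)] - spec$target)
  bound <- stats::setNames(rep(NA_real_, length(ach)), names(ach))
  bound[role == "target"] <- target_tol
  bound[role == "silenced"] <- silence_bound
  bound[role == "minimize"] <- residual_bound
  pass <- ifelse(is.na(bound), TRUE, err <= bound)
  out <- data.frame(opsin = names(ach), role = unname(role),
                    achieved = unname(ach), error = unname(err),
                    bound = unname(bound), pass = unname(pass))
  attr(out, "all_pass") <- all(pass)
  out
}

new_waveform <- function(time, drives, contrasts, meta) {
  structure(list(time = time, drives = drives, contrasts = contrasts,
                 meta = meta), class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform:%s> %.3g s, %d samples, %d primaries, %d opsin traces\n",
              x$meta$kind, max(x$time), length(x$time), ncol(x$drives),
              ncol(x$contrasts)))
  invisible(x)
}

#' Square-wave modulation waveform
#'
#' Periodic bright/dim alternation of a substitution solution, bright
#' phase first, with linear ramps at each transition. Per-opsin contrast
#' traces are attached as instantaneous fractional flux deviation from the
#' background, so the bright plateau of a targeted opsin sits at its
#' Michelson contrast.
#'
#' @param solution Feasible [solve_silent_substitution()] result.
#' @param background Matching background.
#' @param frequency Modulation frequency in Hz (default 0.25).
#' @param ramp_ms Linear transition duration (default 40 ms).
#' @param n_cycles Number of cycles (default 6).
#' @param sample_rate Samples per second (default 200).
#' @return A `waveform` (kind `"square"`).
#' @export
build_square_wave <- function(solution, background, frequency = 0.25,
                              ramp_ms = 40, n_cycles = 6, sample_rate = 200) {
  stopifnot(inherits(solution, "substitution_solution"), frequency > 0)
  period <- 1 / frequency
  ramp <- ramp_ms / 1000
  if (ramp > period / 2) stop("ramp longer than half the stimulus period")
  dur <- n_cycles * period
  tt <- seq(0, dur, by = 1 / sample_rate)
  ph <- (tt %% period) / period
  # square profile in [-1, 1], bright first, linear ramps centred on the
  # phase transitions at 0 and 0.5
  sq <- ifelse(ph < 0.5, 1, -1)
  for (edge in c(0, 0.5, 1)) {
    idx <- abs(ph - edge) < (ramp / 2) / period
    sgn <- if (edge == 0.5) -1 else 1
    sq[idx] <- sgn * (ph[idx] - edge) * period / (ramp / 2)
  }
  drives <- outer(sq, solution$modulation) + 1
  drives <- sweep(drives, 2, background$drives, `*`)
  F_t <- drives %*% t(background$P)
  contrasts <- sweep(sweep(F_t, 2, background$fluxes, `/`), 2, 1, `-`)
  new_waveform(tt, drives, contrasts,
               list(kind = "square", frequency = frequency, period = period,
                    ramp_ms = ramp_ms, n_cycles = n_cycles,
                    sample_rate = sample_rate,
                    michelson = solution$achieved))
}

#' Melanopsin High / Low step pair
#'
#' Builds the two 10-s light steps from darkness used to detect melanopsin
#' input: "Mel High" drives the mid-wavelength primary alone; "Mel Low"
#' mixes the short- and long-wavelength primaries to match the L- and
#' S-opsin effective fluxes of Mel High while delivering far less
#' melanopsin (and rod) flux. Traces attach per-opsin normalized flux
#' (flux / max flux across the pair), suitable for driving the simulator.
#'
#' @param background A [make_background()] object (supplies primaries and
#'   calibration; the steps themselves start from darkness).
#' @param step_s Step duration (s), default 10.
#' @param pre_s Pre-stimulus darkness (s), default 10.
#' @param post_s Post-stimulus darkness (s), default 5.
#' @param sample_rate Samples per second.
#' @return List: `high`, `low` (waveforms, kind `"step"`), `mel_ratio`,
#'   `rod_ratio` (High/Low effective-flux ratios), `l_match`, `s_match`
#'   (relative mismatch of the matched fluxes).
#' @export
build_step_pair <- function(background, step_s = 10, pre_s = 10, post_s = 5,
                            sample_rate = 100) {
  stopifnot(inherits(background, "background"))
  P <- background$P
  prim <- background$primaries
  if (length(prim) < 3) stop("step pair requires >= 3 primaries")
  peaks <- vapply(prim, `[[`, numeric(1), "peak_nm")
  i_mid <- which.min(abs(peaks - 460))
  i_short <- which.min(peaks); i_long <- which.max(peaks)
  if (i_mid %in% c(i_short, i_long)) stop("primaries do not span short/mid/long")
  # Mel High: mid primary at the drive reproducing the background L flux
  a <- background$fluxes[["L"]] / P["L", i_mid]
  f_high <- P[, i_mid] * a
  # Mel Low: short+long mixture matching L and S of Mel High
  d2 <- solve(P[c("L", "S"), c(i_short, i_long)], f_high[c("L", "S")])
  if (any(d2 < 0)) stop("Mel Low mixture infeasible (negative drive)")
  d_high <- d_low <- stats::setNames(rep(0, length(prim)), names(prim))
  d_high[i_mid] <- a
  d_low[c(i_short, i_long)] <- d2
  f_low <- drop(P %*% d_low)
  f_scale <- pmax(f_high, f_low)
  dur <- pre_s + step_s + post_s
  tt <- seq(0, dur, by = 1 / sample_rate)
  on <- as.numeric(tt >= pre_s & tt < pre_s + step_s)
  mk <- function(d, f, label) {
    drives <- outer(on, d)
    contrasts <- outer(on, f / f_scale)
    colnames(contrasts) <- names(f)
    new_waveform(tt, drives, contrasts,
                 list(kind = "step", label = label, pre_s = pre_s,
                      step_s = step_s, sample_rate = sample_rate,
                      fluxes = f,
                      step_window = c(pre_s, pre_s + step_s)))
  }
  list(high = mk(d_high, f_high, "mel_high"),
       low = mk(d_low, f_low, "mel_low"),
       mel_ratio = f_high[["mel"]] / f_low[["mel"]],
       rod_ratio = f_high[["rod"]] / f_low[["rod"]],
       l_match = abs(f_high[["L"]] - f_low[["L"]]) / f_high[["L"]],
       s_match = abs(f_high[["S"]] - f_low[["S"]]) / f_high[["S"]])
}

#' White-noise contrast waveform
#'
#' Frame-by-frame independent pseudorandom contrasts (uniform over
#' `+/- contrast_amp` by default, Gaussian optional) for rod, L and S
#' opsin, each frame solved exactly through the three-primary system.
#' Requires a background under which every frame is within gamut (the
#' `reduced_s` background variant is designed for this).
#'
#' @param background A [make_background()] object with >= 3 primaries.
#' @param contrast_amp Contrast amplitude (default 0.65).
#' @param rate Frame rate in Hz (default 10).
#' @param duration Total duration (s).
#' @param seed Integer seed; sequences are reproducible bit-for-bit.
#' @param marginal `"uniform"` or `"gaussian"` (sd = amp/2, truncated at
#'   `+/- amp`).
#' @param opsins_modulated Three opsins receiving independent contrast.
#' @return A `waveform` (kind `"noise"`): frame times, per-frame drives,
#'   achieved contrasts for all opsins; `meta$sequences` holds the
#'   requested per-frame contrasts.
#' @export
build_white_noise <- function(background, contrast_amp = 0.65, rate = 10,
                              duration = 600, seed = 1,
                              marginal = c("uniform", "gaussian"),
                              opsins_modulated = c("rod", "L", "S")) {
  marginal <- match.arg(marginal)
  stopifnot(inherits(background, "background"), contrast_amp > 0,
            contrast_amp < 1, length(opsins_modulated) == 3)
  W <- contrast_weight_matrix(background)
  W3 <- W[opsins_modulated, 1:3, drop = FALSE]
  n_frames <- floor(duration * rate)
  C <- with_seed(seed, {
    if (marginal == "uniform") {
      matrix(stats::runif(3 * n_frames, -contrast_amp, contrast_amp), nrow = 3)
    } else {
      z <- matrix(stats::rnorm(3 * n_frames, 0, contrast_amp / 2), nrow = 3)
      pmin(pmax(z, -contrast_amp), contrast_amp)
    }
  })
  rownames(C) <- opsins_modulated
  M <- solve(W3, C)                           # 3 x n_frames modulations
  bad <- which(apply(abs(M) > 1 + 1e-12, 2, any))
  if (length(bad)) {
    j <- bad[1]
    stop(sprintf(
      "white-noise frame %d out of gamut: |modulation| = %.3f > 1 (background variant '%s')",
      j, max(abs(M[, j])), background$variant))
  }
  drives <- t(M * background$drives[1:3] + background$drives[1:3])
  colnames(drives) <- names(background$drives)[1:3]
  achieved <- t(W[, 1:3, drop = FALSE] %*% M)
  colnames(achieved) <- rownames(W)
  tt <- (seq_len(n_frames) - 1) / rate
  new_waveform(tt, drives, achieved,
               list(kind = "noise", rate = rate, seed = seed,
                    contrast_amp = contrast_amp, marginal = marginal,
                    sequences = t(C), duration = n_frames / rate))
}

#' Serialize a substitution solution to JSON
#'
#' @param solution A `substitution_solution`.
#' @param path Output path.
#' @export
write_solution_json <- function(solution, path) {
  jsonlite::write_json(list(
    modulation = as.list(solution$modulation),
    achieved = as.list(solution$achieved),
    target = as.list(solution$spec$target),
    silence = solution$spec$silence,
    minimize = solution$spec$minimize,
    feasible = solution$feasible,
    condition = solution$condition
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export a waveform as CSV
#'
#' Columns: `time_s`, one `drive_<primary>` per primary, one
#' `contrast_<opsin>` per opsin trace.
#'
#' @param waveform A `waveform`.
#' @param path Output path.
#' @export
write_waveform_csv <- function(waveform, path) {
  df <- data.frame(time_s = waveform$time)
  dn <- colnames(waveform$drives)
  if (is.null(dn)) dn <- paste0("p", seq_len(ncol(waveform$drives)))
  for (j in seq_len(ncol(waveform$drives))) {
    df[[paste0("drive_", dn[j])]] <- waveform$drives[, j]
  }
  cn <- colnames(waveform$contrasts)
  for (j in seq_len(ncol(waveform$contrasts))) {
    df[[paste0("contrast_", cn[j])]] <- waveform$contrasts[, j]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
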