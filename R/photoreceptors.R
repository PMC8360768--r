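# Opsin spectral templates, prereceptoral filtering and opsin-effective
# photon-flux arithmetic. All flux quantities are photons/cm^2/s (/nm for
# spectral densities); sensitivities are unitless, peak-normalized.

#' Construct a wavelength grid
#'
#' A strictly increasing vector of wavelengths (nm) used as the common
#' abscissa for spectra and sensitivity templates.
#'
#' @param from,to Range in nm. Must lie within 200--1000 nm and cover the
#'   opsins being modeled (default 330--700 nm).
#' @param by Step in nm (<= 1 nm recommended).
#' @return Numeric vector of class `wavelength_grid`.
#' @export
wavelength_grid <- function(from = 330, to = 700, by = 1) {
  stopifnot(is.numeric(from), is.numeric(to), from < to, by > 0)
  if (from < 200 || to > 1000) {
    stop("wavelength grid must lie within 200-1000 nm")
  }
  wl <- seq(from, to, by = by)
  structure(wl, class = "wavelength_grid")
}

#' Spectral curve: values on a wavelength grid
#'
#' Pairs a wavelength grid with nonnegative values: photon flux density
#' (photons/cm^2/s/nm) or unitless relative sensitivity/transmission.
#'
#' @param wavelengths Numeric, strictly increasing (nm).
#' @param values Numeric, same length, all finite and >= 0.
#' @return Object of class `spectral_curve` with fields `wavelengths`, `values`.
#' @export
spectral_curve <- function(wavelengths, values) {
  wavelengths <- as.numeric(wavelengths)
  values <- as.numeric(values)
  if (length(wavelengths) != length(values)) {
    stop("wavelengths and values must have the same length")
  }
  if (any(!is.finite(wavelengths)) || any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be finite and strictly increasing")
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("spectral values must be finite and nonnegative")
  }
  structure(list(wavelengths = wavelengths, values = values),
            class = "spectral_curve")
}

#' @export
print.spectral_curve <- function(x, ...) {
  cat(sprintf("<spectral_curve> %d points, %.0f-%.0f nm, peak %.4g at %.0f nm\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              max(x$values), x$wavelengths[which.max(x$values)]))
  invisible(x)
}

# default peak sensitivities (nm) for the four mouse opsin classes modeled;
# L is the human L-cone opsin knocked into Opn1mw^R mice.
.opsin_lambda_max <- c(S = 365, L = 556, rod = 498, mel = 480)

#' Opsin descriptor
#'
#' @param name One of `"S"`, `"L"`, `"rod"`, `"mel"`, or a custom label if
#'   `lambda_max` is supplied.
#' @param lambda_max Peak sensitivity in nm; defaults per class
#'   (S = 365, L = 556, rod = 498, mel = 480), all treated as vitamin-A1
#'   pigments.
#' @return Object of class `opsin`.
#' @export
opsin <- function(name, lambda_max = NULL) {
  if (is.null(lambda_max)) {
    if (!name %in% names(.opsin_lambda_max)) {
      stop("unknown opsin '", name, "'; supply lambda_max explicitly")
    }
    lambda_max <- .opsin_lambda_max[[name]]
  }
  stopifnot(is.numeric(lambda_max), lambda_max > 200, lambda_max < 1000)
  structure(list(name = name, lambda_max = lambda_max, template = "A1"),
            class = "opsin")
}

#' The default opsin set
#'
#' @return Named list of [opsin()] objects for S, L, rod and mel.
#' @export
default_opsins <- function() {
  lapply(stats::setNames(nm = names(.opsin_lambda_max)), opsin)
}

# Govardovskii et al. A1 visual pigment template (alpha + beta band),
# evaluated at wavelength lambda (nm) for a pigment peaking at lambda_max.
govardovskii_a1 <- function(lambda, lambda_max) {
  x <- lambda_max / lambda
  A <- 69.7; B <- 28; C <- -14.9; D <- 0.674
  b <- 0.922; cc <- 1.104
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  alpha <- 1 / (exp(A * (a - x)) + exp(B * (b - x)) + exp(C * (cc - x)) + D)
  lam_b <- 189 + 0.315 * lambda_max
  bw <- -40.5 + 0.195 * lambda_max
  beta <- 0.26 * exp(-((lambda - lam_b) / bw)^2)
  alpha + beta
}

#' Opsin spectral sensitivity from the A1 nomogram
#'
#' Evaluates the Govardovskii A1 visual-pigment template (alpha plus beta
#' band) on a wavelength grid and normalizes the result to peak 1.
#'
#' @param ops An [opsin()].
#' @param grid A [wavelength_grid()] (or numeric vector of wavelengths).
#' @return [spectral_curve()] of relative sensitivity in `[0, 1]`.
#' @export
nomogram_sensitivity <- function(ops, grid = wavelength_grid()) {
  stopifnot(inherits(ops, "opsin"))
  wl <- as.numeric(grid)
  if (ops$lambda_max < min(wl) || ops$lambda_max > max(wl)) {
    stop("lambda_max (", ops$lambda_max, " nm) outside wavelength grid")
  }
  s <- govardovskii_a1(wl, ops$lambda_max)
  spectral_curve(wl, s / max(s))
}

#' Default mouse prereceptoral (lens) transmission
#'
#' A smooth parametric stand-in for mouse lens/ocular-media transmission:
#' mice have UV-transmitting lenses, so transmission is high by the
#' near-UV and saturates at 1 in the visible. User-measured tables can be
#' supplied anywhere a lens filter is accepted.
#'
#' @param grid Wavelength grid.
#' @param lambda_half Wavelength of half transmission (nm).
#' @param slope Logistic slope (nm).
#' @return [spectral_curve()] of transmission fractions in `[0, 1]`.
#' @export
default_lens <- function(grid = wavelength_grid(), lambda_half = 325,
                         slope = 12) {
  wl <- as.numeric(grid)
  tr <- stats::plogis((wl - lambda_half) / slope)
  spectral_curve(wl, tr)
}

# Linearly resample a spectral curve onto a target grid. Values outside the
# source support are taken as 0 (a spectrum/template has no mass there);
# a curve with no overlap with the target grid is rejected.
resample_curve <- function(curve, wl_out) {
  stopifnot(inherits(curve, "spectral_curve"))
  wl_out <- as.numeric(wl_out)
  if (max(curve$wavelengths) < min(wl_out) ||
      min(curve$wavelengths) > max(wl_out)) {
    stop("spectral curve does not overlap the target wavelength grid")
  }
  v <- stats::approx(curve$wavelengths, curve$values, xout = wl_out,
                     rule = 1)$y
  v[is.na(v)] <- 0
  spectral_curve(wl_out, v)
}

# trapezoid integral of y over x
trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)])) / 2

#' Opsin-effective photon flux
#'
#' Integrates `spectrum x sensitivity x transmission` over wavelength
#' (trapezoid rule) on the spectrum's grid, resampling the sensitivity and
#' lens curves by linear interpolation where needed.
#'
#' @param spectrum [spectral_curve()] of photon flux density
#'   (photons/cm^2/s/nm).
#' @param sensitivity [spectral_curve()] of relative sensitivity.
#' @param lens Optional [spectral_curve()] of transmission; `NULL` means
#'   unit transmission.
#' @return Scalar effective flux (photons/cm^2/s), >= 0.
#' @export
effective_flux <- function(spectrum, sensitivity, lens = NULL) {
  stopifnot(inherits(spectrum, "spectral_curve"))
  wl <- spectrum$wavelengths
  sens <- resample_curve(sensitivity, wl)$values
  tr <- if (is.null(lens)) 1 else resample_curve(lens, wl)$values
  trapz(wl, spectrum$values * sens * tr)
}

#' Michelson contrast of two flux levels
#'
#' `(bright - dim) / (bright + dim)`; negative when `dim > bright`.
#'
#' @param bright,dim Nonnegative fluxes, not both zero.
#' @return Signed fraction in `(-1, 1)`.
#' @export
michelson_contrast <- function(bright, dim) {
  stopifnot(all(bright >= 0), all(dim >= 0))
  if (any(bright + dim == 0)) stop("contrast undefined for two zero fluxes")
  (bright - dim) / (bright + dim)
}

#' Read a spectrum from a two-column text file
#'
#' Whitespace- or comma-delimited `wavelength_nm, value` pairs; `#`
#' comments ignored, one optional header line allowed.
#'
#' @param path File path.
#' @return [spectral_curve()].
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  parse_one <- function(ln) {
    parts <- strsplit(ln, "[,[:space:]]+")[[1]]
    suppressWarnings(as.numeric(parts[1:2]))
  }
  rows <- t(vapply(lines, parse_one, numeric(2), USE.NAMES = FALSE))
  if (anyNA(rows[1, ])) rows <- rows[-1, , drop = FALSE]  # header line
  if (anyNA(rows)) stop("unparseable spectrum file: ", path)
  ord <- order(rows[, 1])
  spectral_curve(rows[ord, 1], rows[ord, 2])
}

#' Write a spectrum as two-column text
#'
#' @param curve [spectral_curve()].
#' @param path Output path.
#' @export
write_spectrum <- function(curve, path) {
  stopifnot(inherits(curve, "spectral_curve"))
  writeLines(c("wavelength_nm value",
               sprintf("%.6g %.10g", curve$wavelengths, curve$values)), path)
  invisible(path)
}
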