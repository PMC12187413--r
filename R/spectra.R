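#' Construct a wavelength-indexed spectrum
#'
#' A `spectrum` holds a nonnegative function of wavelength sampled on a
#' strictly increasing grid: a reflectance, an illuminant spectral power
#' distribution, or a receptor sensitivity. Values between grid points are
#' interpreted by linear interpolation throughout the package.
#'
#' @param wavelengths Numeric vector of wavelengths in nm, strictly
#'   increasing, length >= 2.
#' @param values Nonnegative numeric vector, same length as `wavelengths`.
#'   Reflectances are expected in roughly \[0, 1\]; illuminants and
#'   sensitivities are in arbitrary units (only relative shape matters for
#'   chromatic contrast).
#' @param label Optional character label carried through for reporting.
#' @return An object of class `spectrum`: a list with elements
#'   `wavelengths`, `values`, `label`.
#' @examples
#' s <- spectrum(400:700, rep(0.4, 301), label = "grey40")
#' range(s$wavelengths)
#' @export
spectrum <- function(wavelengths, values, label = NULL) {
  wavelengths <- as.numeric(wavelengths)
  values <- as.numeric(values)
  if (length(wavelengths) != length(values)) {
    stop("`wavelengths` and `values` must have equal length", call. = FALSE)
  }
  if (length(wavelengths) < 2L) {
    stop("a spectrum needs at least 2 grid points", call. = FALSE)
  }
  if (anyNA(wavelengths) || anyNA(values)) {
    stop("spectra must not contain missing values", call. = FALSE)
  }
  if (any(diff(wavelengths) <= 0)) {
    stop("`wavelengths` must be strictly increasing", call. = FALSE)
  }
  if (any(values < 0)) {
    stop("spectral values must be nonnegative", call. = FALSE)
  }
  structure(list(wavelengths = wavelengths, values = values,
                 label = label), class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum%s: %d points, %.0f-%.0f nm, values [%.3g, %.3g]>\n",
              if (is.null(x$label)) "" else paste0(" '", x$label, "'"),
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Flat (spectrally neutral) reflectance
#'
#' Convenience constructor for an achromatic reflectance such as the 40%
#' grey reference against which chromatic contrasts are computed.
#'
#' @param level Reflectance level in \[0, 1\]; default 0.40.
#' @param wavelengths Wavelength grid in nm; default `300:750`.
#' @return A `spectrum`.
#' @export
flat_reflectance <- function(level = 0.40, wavelengths = 300:750) {
  stopifnot(is.numeric(level), length(level) == 1L, level >= 0)
  spectrum(wavelengths, rep(level, length(wavelengths)),
           label = sprintf("flat %.0f%% grey", 100 * level))
}

#' Daylight-like blackbody illuminant
#'
#' Analytic stand-in for broadband daylight: Planck's law at the given
#' colour temperature, normalised to peak 1 on the supplied grid. Used as
#' the package default illuminant; any measured illuminant can be supplied
#' instead as a `spectrum`.
#'
#' @param wavelengths Wavelength grid in nm; default `300:750`.
#' @param temp Blackbody temperature in kelvin; default 6500.
#' @return A `spectrum`.
#' @export
daylight_illuminant <- function(wavelengths = 300:750, temp = 6500) {
  stopifnot(temp > 0)
  lam <- wavelengths * 1e-9
  # Planck spectral radiance, constants folded into the normalisation
  hc_k <- 6.62607015e-34 * 2.99792458e8 / 1.380649e-23
  v <- lam^-5 / (exp(hc_k / (lam * temp)) - 1)
  spectrum(wavelengths, v / max(v), label = sprintf("%gK blackbody", temp))
}

#' Gaussian receptor sensitivities
#'
#' Simple unimodal receptor templates: unit-height Gaussians centred on the
#' given peak wavelengths. Adequate for simulation and testing; measured
#' sensitivities can be passed anywhere these are accepted.
#'
#' @param peaks Peak wavelengths in nm, one per receptor channel. Default
#'   `c(lw = 560, mw = 530, sw = 440)`.
#' @param sigma Common standard deviation in nm; default 40.
#' @param wavelengths Wavelength grid in nm; default `300:750`.
#' @return Named list of `spectrum` objects, one per channel.
#' @export
gaussian_sensitivities <- function(peaks = c(lw = 560, mw = 530, sw = 440),
                                   sigma = 40, wavelengths = 300:750) {
  stopifnot(length(peaks) >= 1L, sigma > 0)
  if (is.null(names(peaks))) names(peaks) <- paste0("ch", seq_along(peaks))
  out <- lapply(seq_along(peaks), function(i) {
    spectrum(wavelengths, exp(-((wavelengths - peaks[i])^2) / (2 * sigma^2)),
             label = names(peaks)[i])
  })
  names(out) <- names(peaks)
  out
}

# Linear interpolation of a spectrum onto a new grid (no extrapolation:
# callers must stay inside the spectrum's support).
interp_spectrum <- function(s, grid) {
  stats::approx(s$wavelengths, s$values, xout = grid, method = "linear",
                rule = 1)$y
}

#' Read spectra from delimited text
#'
#' Expects a wide table whose first column is wavelength (nm) and whose
#' remaining columns are named series; returns a named list of `spectrum`
#' objects.
#'
#' @param file Path to a delimited text file.
#' @param sep Field separator, default ",".
#' @return Named list of `spectrum` objects.
#' @export
read_spectra <- function(file, sep = ",") {
  d <- utils::read.table(file, header = TRUE, sep = sep,
                         check.names = FALSE)
  if (ncol(d) < 2L) stop("spectra file needs wavelength + >=1 series",
                         call. = FALSE)
  wl <- d[[1L]]
  out <- lapply(names(d)[-1L], function(nm) spectrum(wl, d[[nm]], label = nm))
  names(out) <- names(d)[-1L]
  out
}
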