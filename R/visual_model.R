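#' Receptor quantum catches
#'
#' Computes the quantum catch of each receptor class for a stimulus:
#' \deqn{q_i = \int R(\lambda)\, I(\lambda)\, S_i(\lambda)\, d\lambda}
#' over the wavelength range shared by reflectance, illuminant and all
#' sensitivities. All three inputs are treated as piecewise-linear in
#' wavelength; the integral is evaluated exactly for that model by
#' two-point Gauss-Legendre quadrature on each segment of the union grid
#' (the integrand is a cubic per segment, which two-point Gauss integrates
#' exactly).
#'
#' @param reflectance A `spectrum` (values nominally in \[0, 1\]).
#' @param illuminant A `spectrum` (arbitrary units).
#' @param sensitivities A nonempty list of `spectrum` objects, one per
#'   receptor channel; names become channel labels.
#' @param max_step Optional maximum grid spacing in nm; the union grid is
#'   refined to at most this spacing before integration. The integral is
#'   already exact for piecewise-linear inputs, so refinement only matters
#'   if callers want denser sampling for other reasons. Default 1.
#' @return A `cone_catch` object (see [cone_catch()]).
#' @seealso [chromatic_contrast()], [grey_reference()]
#' @examples
#' sens <- gaussian_sensitivities()
#' illum <- daylight_illuminant()
#' q <- quantum_catches(flat_reflectance(0.4), illum, sens)
#' q
#' @export
quantum_catches <- function(reflectance, illuminant, sensitivities,
                            max_step = 1) {
  stopifnot(inherits(reflectance, "spectrum"), inherits(illuminant, "spectrum"))
  if (!is.list(sensitivities) || length(sensitivities) == 0L) {
    stop("`sensitivities` must be a nonempty list of spectra", call. = FALSE)
  }
  if (!all(vapply(sensitivities, inherits, logical(1), "spectrum"))) {
    stop("all sensitivities must be `spectrum` objects", call. = FALSE)
  }
  lo <- max(c(min(reflectance$wavelengths), min(illuminant$wavelengths),
              vapply(sensitivities, function(s) min(s$wavelengths), 0)))
  hi <- min(c(max(reflectance$wavelengths), max(illuminant$wavelengths),
              vapply(sensitivities, function(s) max(s$wavelengths), 0)))
  if (lo >= hi) {
    stop("spectra have disjoint wavelength ranges (no common support)",
         call. = FALSE)
  }
  grid <- union_grid(list(reflectance, illuminant), sensitivities, lo, hi,
                     max_step)
  r <- interp_spectrum(reflectance, grid)
  i <- interp_spectrum(illuminant, grid)
  q <- vapply(sensitivities, function(s) {
    gauss2_product_integral(grid, r, i, interp_spectrum(s, grid))
  }, numeric(1))
  if (any(q <= 0)) {
    stop("degenerate stimulus: zero quantum catch in channel(s) ",
         paste(names(sensitivities)[q <= 0], collapse = ", "), call. = FALSE)
  }
  labels <- names(sensitivities)
  if (is.null(labels)) labels <- paste0("ch", seq_along(q))
  cone_catch(q, labels)
}

# Union of all grids clipped to [lo, hi], refined so no segment exceeds
# max_step.
union_grid <- function(spectra, sensitivities, lo, hi, max_step) {
  pts <- sort(unique(c(lo, hi, unlist(
    lapply(c(spectra, sensitivities), function(s) s$wavelengths)))))
  pts <- pts[pts >= lo & pts <= hi]
  if (is.finite(max_step) && max_step > 0) {
    seg <- diff(pts)
    extra <- unlist(lapply(which(seg > max_step), function(k) {
      n <- ceiling(seg[k] / max_step)
      pts[k] + seg[k] * seq_len(n - 1L) / n
    }))
    pts <- sort(c(pts, extra))
  }
  pts
}

# Exact integral of the product of three piecewise-linear functions
# sampled on a common grid: two-point Gauss-Legendre per segment
# (exact for cubics).
gauss2_product_integral <- function(x, a, b, c) {
  h <- diff(x)
  n <- length(x)
  # Gauss nodes at t = 1/2 +- 1/(2*sqrt(3)) on each unit segment
  t1 <- 0.5 - 0.5 / sqrt(3)
  t2 <- 0.5 + 0.5 / sqrt(3)
  lin <- function(v, t) v[-n] * (1 - t) + v[-1L] * t
  f1 <- lin(a, t1) * lin(b, t1) * lin(c, t1)
  f2 <- lin(a, t2) * lin(b, t2) * lin(c, t2)
  sum(h * (f1 + f2) / 2)
}

#' Construct a cone-catch vector
#'
#' @param q Positive numeric vector of quantum catches, one per receptor
#'   channel (length >= 2; the JND maths takes logs, so zeros are invalid).
#' @param labels Channel labels; defaults to names of `q` or `ch1..chn`.
#' @return An object of class `cone_catch`: a named numeric vector.
#' @export
cone_catch <- function(q, labels = names(q)) {
  q <- as.numeric(q)
  if (length(q) < 2L) stop("need at least 2 receptor channels", call. = FALSE)
  if (anyNA(q) || any(q <= 0)) {
    stop("all quantum catches must be positive and non-missing",
         call. = FALSE)
  }
  if (is.null(labels)) labels <- paste0("ch", seq_along(q))
  if (length(labels) != length(q)) {
    stop("`labels` must match the number of channels", call. = FALSE)
  }
  structure(stats::setNames(q, labels), class = "cone_catch")
}

#' @export
print.cone_catch <- function(x, ...) {
  cat("<cone_catch>\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Receptor noise from relative cone abundances
#'
#' Per-channel noise standard deviations for the receptor-noise-limited
#' model: \eqn{e_i = \nu / \sqrt{\eta_i / \max(\eta)}}, so the most
#' abundant channel carries exactly the Weber fraction \eqn{\nu} and rarer
#' channels are noisier in proportion to \eqn{1/\sqrt{\eta}}. This scaling
#' keeps \eqn{\nu} interpretable whether or not the abundances are
#' normalised.
#'
#' @param abundances Positive numeric vector of relative cone abundances
#'   (e.g. `c(lw = 0.06, mw = 0.08, sw = 0.15)`).
#' @param weber Weber fraction of the most abundant channel, in (0, 1);
#'   default 0.05.
#' @return An object of class `receptor_noise`: list with `abundances`,
#'   `weber`, `e` (per-channel noise sd), `labels`.
#' @examples
#' receptor_noise(c(lw = 0.06, mw = 0.08, sw = 0.15), weber = 0.05)
#' @export
receptor_noise <- function(abundances, weber = 0.05) {
  labels0 <- names(abundances)
  abundances <- as.numeric(abundances)
  names(abundances) <- labels0
  if (length(abundances) < 2L) {
    stop("need at least 2 receptor channels", call. = FALSE)
  }
  if (anyNA(abundances) || any(abundances <= 0)) {
    stop("all abundances must be positive", call. = FALSE)
  }
  if (!is.numeric(weber) || length(weber) != 1L || weber <= 0 || weber >= 1) {
    stop("`weber` must be a single number in (0, 1)", call. = FALSE)
  }
  labels <- names(abundances)
  if (is.null(labels)) labels <- paste0("ch", seq_along(abundances))
  e <- weber / sqrt(abundances / max(abundances))
  structure(list(abundances = stats::setNames(abundances, labels),
                 weber = weber, e = stats::setNames(e, labels),
                 labels = labels),
            class = "receptor_noise")
}

#' @export
print.receptor_noise <- function(x, ...) {
  cat(sprintf("<receptor_noise: %d channels, weber = %g>\n",
              length(x$e), x$weber))
  print(rbind(abundance = x$abundances, e = x$e), ...)
  invisible(x)
}

check_channels <- function(a, b, noise) {
  n <- length(noise$e)
  if (length(a) != n || (!is.null(b) && length(b) != n)) {
    stop("channel-count mismatch between catches and noise", call. = FALSE)
  }
  n
}

#' Receptor-noise-limited chromatic contrast (JND)
#'
#' Perceptual distance \eqn{\Delta S} between two stimuli in just-noticeable
#' differences under the log-linear receptor-noise-limited model. With
#' \eqn{\Delta f_i = \ln(q_i^a / q_i^b)} and channel noise \eqn{e_i}, the
#' trichromatic form is
#' \deqn{\Delta S^2 = \frac{e_1^2(\Delta f_3-\Delta f_2)^2 +
#'   e_2^2(\Delta f_3-\Delta f_1)^2 + e_3^2(\Delta f_1-\Delta f_2)^2}
#'   {(e_1 e_2)^2 + (e_1 e_3)^2 + (e_2 e_3)^2}}
#' and for two channels \eqn{\Delta S = |\Delta f_1-\Delta f_2| /
#' \sqrt{e_1^2+e_2^2}}. The implementation uses the general n-channel
#' quadratic form (pairwise opponent differences), which reduces to both.
#' \eqn{\Delta S = 1} is nominally the discrimination threshold.
#'
#' @param a,b `cone_catch` objects with matching channel count.
#' @param noise A `receptor_noise` object.
#' @return Nonnegative scalar \eqn{\Delta S} in JND units.
#' @examples
#' noise <- receptor_noise(c(0.06, 0.08, 0.15))
#' chromatic_contrast(cone_catch(c(2, 1, 1)), cone_catch(c(1, 1, 1)), noise)
#' @export
chromatic_contrast <- function(a, b, noise) {
  stopifnot(inherits(noise, "receptor_noise"))
  if (anyNA(a) || anyNA(b) || any(a <= 0) || any(b <= 0)) {
    stop("quantum catches must be positive (log-domain)", call. = FALSE)
  }
  n <- check_channels(a, b, noise)
  df <- log(as.numeric(a)) - log(as.numeric(b))
  e2 <- noise$e^2
  # general pairwise opponent form; products written as sums of logs would
  # lose nothing here (n is small), so take them directly
  prod_e2 <- prod(e2)
  num <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      num <- num + (prod_e2 / (e2[i] * e2[j])) * (df[i] - df[j])^2
    }
  }
  den <- sum(prod_e2 / e2)
  sqrt(max(num / den, 0))
}

#' RNL chromaticity coordinates
#'
#' Maps a cone catch to a point in an (n-1)-dimensional chromaticity space
#' in which Euclidean distance equals [chromatic_contrast()]. Construction:
#' log catches are noise-whitened (\eqn{f_i/e_i}) and projected onto a
#' fixed orthonormal basis of the subspace orthogonal to the achromatic
#' direction \eqn{(1/e_1, \dots, 1/e_n)}. The basis is deterministic for a
#' given `noise` object, so coordinates are comparable across stimuli.
#'
#' @param a A `cone_catch`.
#' @param noise A `receptor_noise`.
#' @return An object of class `rnl_point`: numeric vector of length
#'   n_channels - 1.
#' @export
rnl_coordinates <- function(a, noise) {
  stopifnot(inherits(noise, "receptor_noise"))
  if (anyNA(a) || any(a <= 0)) {
    stop("quantum catches must be positive (log-domain)", call. = FALSE)
  }
  n <- check_channels(a, NULL, noise)
  f <- log(as.numeric(a))
  B <- rnl_basis(noise)
  structure(as.numeric(crossprod(B, f / noise$e)), class = "rnl_point")
}

# Orthonormal basis of the orthogonal complement of the whitened
# achromatic axis u = (1/e_i)/||.||; deterministic via Householder QR of
# [u, I] with a fixed sign convention.
rnl_basis <- function(noise) {
  u <- (1 / noise$e) / sqrt(sum(1 / noise$e^2))
  n <- length(u)
  qd <- qr(cbind(u, diag(n)))
  B <- qr.Q(qd)[, 2:n, drop = FALSE]
  # fix signs: largest-magnitude entry of each column positive
  for (j in seq_len(ncol(B))) {
    k <- which.max(abs(B[, j]))
    if (B[k, j] < 0) B[, j] <- -B[, j]
  }
  B
}

#' @export
print.rnl_point <- function(x, ...) {
  cat("<rnl_point> ")
  print(as.numeric(x), ...)
  invisible(x)
}

#' Grey-reference cone catch
#'
#' Quantum catches of a spectrally flat grey (default 40% reflectance)
#' under a given illuminant: the reference stimulus against which
#' chromatic contrasts of displayed colours are computed.
#'
#' @param illuminant A `spectrum`.
#' @param sensitivities List of `spectrum` objects, one per channel.
#' @param reflectance Grey level in \[0, 1\]; default 0.40.
#' @return A `cone_catch`.
#' @export
grey_reference <- function(illuminant, sensitivities, reflectance = 0.40) {
  wl <- illuminant$wavelengths
  quantum_catches(flat_reflectance(reflectance, range(wl)), illuminant,
                  sensitivities)
}

#' Maximum chromatic contrast over an image series
#'
#' For one individual's sequence of colour measurements (one cone catch
#' per image), returns the maximum \eqn{\Delta S} against the grey
#' reference and the index at which it occurs. This is the per-trial trait
#' used downstream: the peak colour expression reached during a contest.
#' Ties are broken by the earliest index.
#'
#' @param series Nonempty list of `cone_catch` objects.
#' @param reference `cone_catch` of the grey reference under the same
#'   illuminant.
#' @param noise A `receptor_noise`.
#' @return List with `max_jnd`, `argmax` (1-based index), and `jnd`
#'   (the full \eqn{\Delta S} series).
#' @export
max_series_contrast <- function(series, reference, noise) {
  if (!is.list(series) || length(series) == 0L) {
    stop("`series` must be a nonempty list of cone catches", call. = FALSE)
  }
  ds <- vapply(series, chromatic_contrast, numeric(1), b = reference,
               noise = noise)
  k <- which.max(ds)  # which.max returns the earliest maximum
  list(max_jnd = ds[[k]], argmax = k, jnd = as.numeric(ds))
}

#' Per-individual maximum contrasts from a cone-catch table
#'
#' Applies [max_series_contrast()] to a long table of per-image cone
#' catches (columns `individual_id`, `image_index`, `region`, then one
#' `q_*` column per channel), returning one row per individual x region.
#'
#' @param catches Data frame in the long per-image layout.
#' @param reference `cone_catch` of the grey reference.
#' @param noise A `receptor_noise`.
#' @return Data frame with columns `individual_id`, `region`, `max_jnd`,
#'   `argmax_image`.
#' @export
max_contrast_table <- function(catches, reference, noise) {
  need <- c("individual_id", "image_index", "region")
  if (!all(need %in% names(catches))) {
    stop("`catches` needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  qcols <- grep("^q_", names(catches), value = TRUE)
  if (length(qcols) < 2L) stop("need at least two q_* columns", call. = FALSE)
  labels <- sub("^q_", "", qcols)
  out <- do.call(rbind, lapply(
    split(catches, catches[c("individual_id", "region")], drop = TRUE),
    function(d) {
      d <- d[order(d$image_index), , drop = FALSE]
      ser <- lapply(seq_len(nrow(d)),
                    function(i) cone_catch(as.numeric(d[i, qcols]), labels))
      m <- max_series_contrast(ser, reference, noise)
      data.frame(individual_id = d$individual_id[1L], region = d$region[1L],
                 max_jnd = m$max_jnd,
                 argmax_image = d$image_index[m$argmax])
    }))
  rownames(out) <- NULL
  out[order(out$individual_id, out$region), , drop = FALSE]
}
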