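# Point-spectroscopy emission spectra: container, smoothing, and detection
# of the PpIX 635 nm emission peak.

#' Emission spectrum container
#'
#' @param wavelength_nm strictly increasing wavelength grid (nm).
#' @param intensity non-negative intensities, arbitrary units.
#' @return object of class `emission_spectrum`.
#' @export
emission_spectrum <- function(wavelength_nm, intensity) {
  stopifnot(length(wavelength_nm) == length(intensity),
            length(wavelength_nm) >= 2)
  if (any(diff(wavelength_nm) <= 0)) {
    stop("wavelengths must be strictly increasing")
  }
  if (any(intensity < 0)) stop("intensities must be non-negative")
  structure(list(wavelength_nm = as.numeric(wavelength_nm),
                 intensity = as.numeric(intensity)),
            class = "emission_spectrum")
}

#' Savitzky-Golay smoothing of an emission spectrum
#'
#' Polynomial least-squares smoothing on the same wavelength grid; negative
#' filter outputs are clamped to zero. A plain moving average is available
#' via `method = "moving_average"`.
#'
#' @param s an [emission_spectrum].
#' @param window odd window length in samples (> `order`, <= spectrum
#'   length). Default 15.
#' @param order polynomial order (default 3; ignored for the moving
#'   average).
#' @param method `"savitzky_golay"` (default) or `"moving_average"`.
#' @return smoothed [emission_spectrum].
#' @export
smooth_spectrum <- function(s, window = 15L, order = 3L,
                            method = c("savitzky_golay", "moving_average")) {
  method <- match.arg(method)
  n <- length(s$intensity)
  if (window %% 2 == 0 || window <= order || window > n) {
    stop("parameter error: window must be odd, > order and <= length")
  }
  sm <- if (method == "savitzky_golay") {
    as.numeric(signal::sgolayfilt(s$intensity, p = order, n = window))
  } else {
    as.numeric(stats::filter(s$intensity, rep(1 / window, window),
                             sides = 2))
  }
  sm[is.na(sm)] <- s$intensity[is.na(sm)]
  emission_spectrum(s$wavelength_nm, pmax(sm, 0))
}

# Local maxima and their topographic prominences. A prominence of a peak is
# its height above the higher of the two minima separating it from higher
# terrain (or from the spectrum ends).
.find_peaks <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  i <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
  i
}

.peak_prominence <- function(v, i) {
  n <- length(v)
  left <- if (i == 1) v[1] else {
    higher <- which(v[1:(i - 1)] > v[i])
    lo <- if (length(higher)) max(higher) else 1L
    min(v[lo:i])
  }
  right <- if (i == n) v[n] else {
    higher <- which(v[(i + 1):n] > v[i])
    hi <- if (length(higher)) i + min(higher) else n
    min(v[i:hi])
  }
  v[i] - max(left, right)
}

#' Detect the PpIX emission peak near 635 nm
#'
#' Searches the (optionally pre-smoothed) spectrum for a local maximum
#' inside the search window with topographic prominence at least
#' `min_prominence`. The most prominent qualifying maximum is reported.
#'
#' @param s an [emission_spectrum].
#' @param window_nm numeric length-2 search window; default `c(625, 645)`.
#' @param min_prominence minimum prominence in intensity units
#'   (default 0.05).
#' @param smooth apply [smooth_spectrum()] first (default TRUE).
#' @return list of class `peak_result`: `present` (logical),
#'   `wavelength_nm` (NA when absent), `prominence`.
#' @export
detect_ppix_peak <- function(s, window_nm = c(625, 645),
                             min_prominence = 0.05, smooth = TRUE) {
  stopifnot(length(window_nm) == 2, window_nm[1] < window_nm[2])
  if (window_nm[1] < min(s$wavelength_nm) ||
        window_nm[2] > max(s$wavelength_nm)) {
    stop("parameter error: search window outside spectrum support")
  }
  if (smooth) s <- smooth_spectrum(s)
  v <- s$intensity
  peaks <- .find_peaks(v)
  w <- s$wavelength_nm[peaks]
  peaks <- peaks[w >= window_nm[1] & w <= window_nm[2]]
  if (length(peaks)) {
    prom <- vapply(peaks, function(i) .peak_prominence(v, i), 1)
    best <- which.max(prom)
    if (prom[best] >= min_prominence) {
      return(structure(list(present = TRUE,
                            wavelength_nm = s$wavelength_nm[peaks[best]],
                            prominence = prom[best]),
                       class = "peak_result"))
    }
  }
  structure(list(present = FALSE, wavelength_nm = NA_real_, prominence = 0),
            class = "peak_result")
}
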