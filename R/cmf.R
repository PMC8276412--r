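# CIE 1931 colorimetry primitives: color-matching functions, spectral
# integration, spectral locus, dominant wavelength and excitation purity.

#' CIE 1931 2-degree color-matching functions
#'
#' Evaluates the CIE 1931 2-degree standard observer color-matching functions
#' \eqn{\bar{x}, \bar{y}, \bar{z}} at arbitrary wavelengths using the
#' piecewise-Gaussian analytic fit of Wyman, Sloan and Shirley (2013), which
#' reproduces the tabulated observer to within about 1 percent. Values are
#' clamped to be non-negative.
#'
#' @param wavelength_nm numeric vector of wavelengths in nanometres.
#' @return numeric matrix with one row per wavelength and columns
#'   `xbar`, `ybar`, `zbar`.
#' @export
#' @examples
#' cie_cmf(c(520, 555, 635))
cie_cmf <- function(wavelength_nm) {
  stopifnot(is.numeric(wavelength_nm), all(is.finite(wavelength_nm)))
  lobe <- function(l, mu, t1, t2) {
    tau <- ifelse(l < mu, t1, t2)
    exp(-0.5 * ((l - mu) * tau)^2)
  }
  l <- wavelength_nm
  xbar <- 0.362 * lobe(l, 442.0, 0.0624, 0.0374) +
    1.056 * lobe(l, 599.8, 0.0264, 0.0323) -
    0.065 * lobe(l, 501.1, 0.0490, 0.0382)
  ybar <- 0.821 * lobe(l, 568.8, 0.0213, 0.0247) +
    0.286 * lobe(l, 530.9, 0.0613, 0.0322)
  zbar <- 1.217 * lobe(l, 437.0, 0.0845, 0.0278) +
    0.681 * lobe(l, 459.0, 0.0385, 0.0725)
  cbind(xbar = pmax(xbar, 0), ybar = pmax(ybar, 0), zbar = pmax(zbar, 0))
}

#' Integrate an emission spectrum to CIE XYZ tristimulus values
#'
#' Trapezoidal integration of spectral intensity against the CIE 1931
#' 2-degree color-matching functions. The result is linear in the spectrum,
#' so mixtures of spectra map to the same mixtures of XYZ.
#'
#' @param spectrum an [emission_spectrum] (or any list with `wavelength_nm`
#'   and `intensity` fields).
#' @return named numeric vector `c(X, Y, Z)` (arbitrary units).
#' @export
spectrum_to_xyz <- function(spectrum) {
  w <- spectrum$wavelength_nm
  v <- spectrum$intensity
  stopifnot(length(w) == length(v), length(w) >= 2)
  cmf <- cie_cmf(w)
  dw <- diff(w)
  trap <- function(f) sum(dw * (f[-1] + f[-length(f)]) / 2)
  c(X = trap(v * cmf[, "xbar"]),
    Y = trap(v * cmf[, "ybar"]),
    Z = trap(v * cmf[, "zbar"]))
}

#' Chromaticity coordinates from XYZ
#'
#' @param xyz numeric vector `c(X, Y, Z)` or a 3-column matrix.
#' @return numeric vector `c(x, y)` (or 2-column matrix).
#' @export
xyz_to_xy <- function(xyz) {
  if (is.matrix(xyz)) {
    s <- rowSums(xyz)
    cbind(x = xyz[, 1] / s, y = xyz[, 2] / s)
  } else {
    s <- sum(xyz)
    if (s <= 0) stop("undefined chromaticity: X + Y + Z is zero")
    c(x = xyz[[1]] / s, y = xyz[[2]] / s)
  }
}

# D65 white point chromaticity (sRGB reference white).
.d65_xy <- c(x = 0.312727, y = 0.329023)

# Spectral locus cache: chromaticities of monochromatic stimuli.
.locus_env <- new.env(parent = emptyenv())

.spectral_locus <- function() {
  if (is.null(.locus_env$xy)) {
    lam <- seq(420, 700, by = 1)
    cmf <- cie_cmf(lam)
    s <- rowSums(cmf)
    .locus_env$lambda <- lam
    .locus_env$xy <- cbind(cmf[, 1] / s, cmf[, 2] / s)
  }
  list(lambda = .locus_env$lambda, xy = .locus_env$xy)
}

#' Dominant wavelength and excitation purity of a chromaticity
#'
#' Intersects the ray from the D65 white point through the sample
#' chromaticity with the spectral locus (monochromatic chromaticities,
#' 420-700 nm). Samples whose ray exits through the purple line (the segment
#' joining the locus extremes) have no dominant wavelength; they are flagged
#' and their purity is measured against the purple-line intersection.
#'
#' @param xy numeric `c(x, y)` chromaticity.
#' @param white reference white chromaticity (default D65).
#' @return list with `dominant_wavelength_nm` (NA for purples or for the
#'   white point itself), `purity` in \[0, 1\], and logical `purple`.
#' @export
dominant_wavelength <- function(xy, white = .d65_xy) {
  stopifnot(is.numeric(xy), length(xy) == 2, all(is.finite(xy)))
  d <- c(xy[[1]] - white[[1]], xy[[2]] - white[[2]])
  dn <- sqrt(sum(d^2))
  if (dn < 1e-12) {
    return(list(dominant_wavelength_nm = NA_real_, purity = 0, purple = FALSE))
  }
  loc <- .spectral_locus()
  hit <- .ray_polyline_hit(white, d, loc$xy)
  if (!is.null(hit)) {
    lam <- loc$lambda[hit$i] +
      hit$s * (loc$lambda[hit$i + 1] - loc$lambda[hit$i])
    return(list(dominant_wavelength_nm = lam,
                purity = min(dn / hit$t_dist, 1), purple = FALSE))
  }
  # purple line
  n <- nrow(loc$xy)
  hit <- .ray_polyline_hit(white, d, loc$xy[c(n, 1), , drop = FALSE])
  purity <- if (is.null(hit)) 1 else min(dn / hit$t_dist, 1)
  list(dominant_wavelength_nm = NA_real_, purity = purity, purple = TRUE)
}

# Intersect ray origin + t*dir (t > 0) with a polyline; returns the segment
# index, the within-segment parameter s, and the distance from origin to the
# intersection, or NULL when there is no forward crossing.
.ray_polyline_hit <- function(origin, dir, poly) {
  a <- poly[-nrow(poly), , drop = FALSE]
  b <- poly[-1, , drop = FALSE]
  ex <- b[, 1] - a[, 1]
  ey <- b[, 2] - a[, 2]
  fx <- a[, 1] - origin[[1]]
  fy <- a[, 2] - origin[[2]]
  denom <- dir[[1]] * ey - dir[[2]] * ex
  ok <- abs(denom) > 1e-14
  t <- (fx * ey - fy * ex) / denom
  s <- (fx * dir[[2]] - fy * dir[[1]]) / denom
  ok <- ok & t > 1e-9 & s >= -1e-9 & s <= 1 + 1e-9
  if (!any(ok, na.rm = TRUE)) return(NULL)
  i <- which(ok)[which.min(t[ok])]
  dn <- sqrt(sum(dir^2))
  list(i = i, s = min(max(s[i], 0), 1), t_dist = t[i] * dn)
}
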