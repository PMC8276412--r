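# Synthetic specimen generator: tissue label maps, spectrally rendered
# fluorescence images, punch-biopsy sampling and point spectra with the
# statistical structure the downstream analysis assumes.

#' Tissue class codes
#'
#' Integer codes used in tissue label maps. `tumor` is the demarcated
#' primary carcinoma, `occult_cancer` are grossly occult foci outside the
#' demarcated border, `benign_proliferative` are non-malignant proliferative
#' foci that can express PpIX (the false-positive substrate), `connective`
#' is green-autofluorescent stroma and `adipose` dull pink/brown fat.
#'
#' @format named integer vector.
#' @export
TISSUE_CLASSES <- c(background = 0L, scale_marker = 1L, tumor = 2L,
                    occult_cancer = 3L, benign_proliferative = 4L,
                    connective = 5L, adipose = 6L)

.CANCER_CLASSES <- c("tumor", "occult_cancer", "benign_proliferative")

#' Simulation configuration
#'
#' Defines the study conditions for one simulated dose group. Defaults model
#' the trial arms this package is built around: three oral 5-ALA dose groups
#' (none / 15 mg/kg / 30 mg/kg), 15 specimens per group, punch biopsies of
#' 2 or 4 mm, and an occult-cancer prevalence outside the demarcated tumor
#' border of about 0.2.
#'
#' @param dose_group one of `"control"`, `"low"`, `"high"`; maps to relative
#'   PpIX gain 0, `g_low`, `g_high`.
#' @param n_specimens specimens per group.
#' @param occult_focus_rate expected number of grossly occult cancer foci
#'   per specimen (Poisson).
#' @param occult_site_prob probability that an outside-border biopsy site
#'   targets an occult focus, given at least one exists. The effective
#'   cancer prevalence among outside sites is
#'   `occult_site_prob * (1 - exp(-occult_focus_rate))`
#'   (see [expected_occult_prevalence()]).
#' @param benign_positive_rate probability that a non-cancer outside-border
#'   site targets a PpIX-expressing benign proliferative focus.
#' @param masking_ratio_threshold carcinoma-to-connective area ratio below
#'   which connective-tissue green autofluorescence masks PpIX (its
#'   amplitude is attenuated); set to 0 to disable masking.
#' @param noise_sd additive Gaussian sensor/detector noise sd, in normalized
#'   linear units (images) and arbitrary intensity units (spectra).
#' @param seed integer master seed; each specimen derives its own stream
#'   from `(seed, specimen_index)`.
#' @param g_low,g_high relative PpIX gain of the two dose arms. The trial
#'   found no significant dose effect, so both default to 1.
#' @param border_defined_prob probability that the gross tumor border is
#'   clinically demarcatable (ill-defined borders occur at rate
#'   `1 - border_defined_prob`).
#' @param masking_prone_prob probability that a cancer focus is stroma-rich
#'   (low per-pixel carcinoma fraction), the substrate for masking false
#'   negatives.
#' @param pixel_size_mm physical size of one pixel.
#' @param grid `c(rows, cols)` of the simulated specimen slice raster.
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(dose_group = c("high", "low", "control"),
                              n_specimens = 15L,
                              occult_focus_rate = 1.5,
                              occult_site_prob = 0.26,
                              benign_positive_rate = 0.18,
                              masking_ratio_threshold = 0.20,
                              noise_sd = 0.01,
                              seed = 1L,
                              g_low = 1,
                              g_high = 1,
                              border_defined_prob = 0.8,
                              masking_prone_prob = 0.35,
                              pixel_size_mm = 0.5,
                              grid = c(110L, 140L)) {
  dose_group <- match.arg(dose_group)
  cfg <- list(dose_group = dose_group,
              n_specimens = as.integer(n_specimens),
              occult_focus_rate = occult_focus_rate,
              occult_site_prob = occult_site_prob,
              benign_positive_rate = benign_positive_rate,
              masking_ratio_threshold = masking_ratio_threshold,
              noise_sd = noise_sd,
              seed = as.integer(seed),
              g_low = g_low, g_high = g_high,
              border_defined_prob = border_defined_prob,
              masking_prone_prob = masking_prone_prob,
              pixel_size_mm = pixel_size_mm,
              grid = as.integer(grid))
  validate_simulation_config(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

validate_simulation_config <- function(cfg) {
  ok <- function(cond, msg) if (!cond) stop("parameter error: ", msg)
  ok(cfg$n_specimens >= 1, "n_specimens must be positive")
  ok(cfg$g_high >= cfg$g_low && cfg$g_low > 0, "need g_high >= g_low > 0")
  rates <- c(cfg$occult_site_prob, cfg$benign_positive_rate,
             cfg$border_defined_prob, cfg$masking_prone_prob)
  ok(all(rates >= 0 & rates <= 1), "rates must lie in [0, 1]")
  ok(cfg$occult_focus_rate >= 0, "occult_focus_rate must be >= 0")
  ok(cfg$masking_ratio_threshold >= 0,
     "masking_ratio_threshold must be >= 0")
  ok(cfg$noise_sd >= 0, "noise_sd must be non-negative")
  ok(cfg$pixel_size_mm > 0, "pixel_size_mm must be positive")
  ok(length(cfg$grid) == 2 && all(cfg$grid >= 40),
     "grid must be c(rows, cols), each >= 40")
  invisible(cfg)
}

#' Expected cancer prevalence among outside-border biopsy sites
#'
#' Each outside-border site independently attempts to target an occult
#' focus with probability `occult_site_prob`; each focus hosts at most one
#' punch, so with `T` targeting attempts among `N` outside sites and `F`
#' available foci (Poisson), the number of cancer-positive outside sites is
#' `min(T, F)`. The expected prevalence is `E[min(T, F)] / E[N]` under the
#' sampler's fixed site-count distribution (1, 2 or 3 outside sites with
#' probabilities 0.25, 0.40, 0.35).
#'
#' @param config a [simulation_config].
#' @return scalar prevalence in \[0, 1\].
#' @export
expected_occult_prevalence <- function(config) {
  n_probs <- c(`1` = 0.25, `2` = 0.40, `3` = 0.35)
  q <- config$occult_site_prob
  fmax <- 50
  pf <- stats::dpois(0:fmax, config$occult_focus_rate)
  e_min <- 0
  for (n in 1:3) {
    pt <- stats::dbinom(0:n, n, q)
    for (t in 0:n) {
      e_min <- e_min + n_probs[[n]] * pt[t + 1] *
        sum(pf * pmin(t, 0:fmax))
    }
  }
  e_min / sum(n_probs * (1:3))
}

.dose_gain <- function(config) {
  switch(config$dose_group, control = 0,
         low = config$g_low, high = config$g_high)
}

# Derive a per-specimen seed below 2^31 from the master seed.
.specimen_seed <- function(seed, specimen_index) {
  as.integer((as.double(seed) + 7919 * (specimen_index + 1)) %% 2147483647)
}

#' Tissue label map constructor
#'
#' @param labels integer matrix of [TISSUE_CLASSES] codes.
#' @param pixel_size_mm positive pixel size.
#' @param cancer_cell_fraction matrix in \[0, 1\], non-zero only on cancer
#'   classes; interpreted as the sub-pixel area fraction occupied by
#'   carcinoma cells (the remainder of a cancer pixel is stromal).
#' @return object of class `tissue_label_map`.
#' @export
tissue_label_map <- function(labels, pixel_size_mm, cancer_cell_fraction) {
  stopifnot(is.matrix(labels), length(labels) > 0, pixel_size_mm > 0,
            identical(dim(labels), dim(cancer_cell_fraction)))
  if (!all(labels %in% TISSUE_CLASSES)) stop("unknown tissue class code")
  noncancer <- !(labels %in% TISSUE_CLASSES[.CANCER_CLASSES])
  if (any(cancer_cell_fraction[noncancer] != 0)) {
    stop("cancer_cell_fraction must be 0 on non-cancer classes")
  }
  if (any(cancer_cell_fraction < 0 | cancer_cell_fraction > 1)) {
    stop("cancer_cell_fraction must lie in [0, 1]")
  }
  structure(list(labels = labels, pixel_size_mm = pixel_size_mm,
                 cancer_cell_fraction = cancer_cell_fraction),
            class = "tissue_label_map")
}

#' Tumor border polygon
#'
#' @param polygon numeric matrix of `(row, col)` vertices (closed implicitly;
#'   0-based pixel frame is not assumed, vertices are in matrix coordinates).
#' @param defined logical; ill-defined gross borders carry an empty polygon.
#' @return object of class `tumor_border`.
#' @export
tumor_border <- function(polygon, defined = TRUE) {
  if (!defined) polygon <- matrix(numeric(0), ncol = 2)
  stopifnot(is.matrix(polygon), ncol(polygon) == 2)
  if (defined && nrow(polygon) < 3) stop("defined border needs >= 3 vertices")
  structure(list(polygon = polygon, defined = defined),
            class = "tumor_border")
}

# --- low-level field helpers -----------------------------------------------

# Box-filtered mean of a matrix (k x k window, edge-clamped), via cumsums.
.box_mean <- function(m, k) {
  h <- (k - 1L) %/% 2L
  one_dim <- function(mm) {
    n <- nrow(mm)
    cs <- rbind(0, apply(mm, 2, cumsum))
    hi <- pmin(seq_len(n) + h, n)
    lo <- pmax(seq_len(n) - h - 1L, 0L)
    (cs[hi + 1L, , drop = FALSE] - cs[lo + 1L, , drop = FALSE]) / (hi - lo)
  }
  t(one_dim(t(one_dim(m))))
}

# Smooth standardized Gaussian random field.
.smooth_field <- function(nr, nc, k = 11L) {
  f <- .box_mean(.box_mean(matrix(stats::rnorm(nr * nc), nr, nc), k), k)
  (f - mean(f)) / stats::sd(f)
}

# Even-odd point-in-polygon for a pixel grid; polygon rows are (row, col).
.polygon_mask <- function(polygon, nr, nc) {
  px <- matrix(FALSE, nr, nc)
  if (nrow(polygon) < 3) return(px)
  rr <- rep(seq_len(nr), nc)
  cc <- rep(seq_len(nc), each = nr)
  inside <- in_polygon(rr, cc, polygon)
  matrix(inside, nr, nc)
}

#' Even-odd point-in-polygon test
#'
#' Crossing-number (even-odd) rule; points exactly on a horizontal-crossing
#' edge resolve by the half-open vertex convention, which counts boundary
#' pixels of simulated borders as inside in practice.
#'
#' @param r,c numeric vectors of point coordinates (rows, cols).
#' @param polygon two-column matrix of `(row, col)` vertices.
#' @return logical vector.
#' @export
in_polygon <- function(r, c, polygon) {
  n <- nrow(polygon)
  inside <- logical(length(r))
  j <- n
  for (i in seq_len(n)) {
    ri <- polygon[i, 1]; ci <- polygon[i, 2]
    rj <- polygon[j, 1]; cj <- polygon[j, 2]
    cross <- ((ri > r) != (rj > r)) &
      (c < (cj - ci) * (r - ri) / (rj - ri) + ci)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# --- label-map generation --------------------------------------------------

#' Generate a synthetic tissue label map and tumor border
#'
#' Builds one specimen slice: a tissue region of connective and adipose
#' tissue containing a lobulated primary tumor blob, Poisson-distributed
#' grossly occult cancer foci strictly outside the demarcated border,
#' PpIX-expressing benign proliferative foci, and a scale-marker sticker
#' patch in one corner. Deterministic for fixed `(config$seed,
#' specimen_index)`.
#'
#' Cancer pixels carry a `cancer_cell_fraction` in (0, 1\]: the sub-pixel
#' carcinoma area fraction, with the remainder modeled as stroma. A
#' configurable proportion of cancer foci (`masking_prone_prob`) is
#' stroma-rich (low fraction), which is the substrate for green-masking
#' false negatives.
#'
#' @param config a [simulation_config].
#' @param specimen_index non-negative integer.
#' @return list with elements `map` ([tissue_label_map]) and `border`
#'   ([tumor_border]).
#' @export
generate_label_map <- function(config, specimen_index = 0L) {
  validate_simulation_config(config)
  stopifnot(specimen_index >= 0)
  set.seed(.specimen_seed(config$seed, specimen_index))
  nr <- config$grid[1]; nc <- config$grid[2]
  r0 <- (nr + 1) / 2; c0 <- (nc + 1) / 2
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)

  # tissue outline: wobbled ellipse
  ph <- stats::runif(2, 0, 2 * pi)
  th <- atan2(rr - r0, cc - c0)
  rad <- sqrt(((rr - r0) / (0.42 * nr))^2 + ((cc - c0) / (0.44 * nc))^2)
  wob <- 1 + 0.06 * sin(2 * th + ph[1]) + 0.04 * sin(3 * th + ph[2])
  tissue <- rad < wob

  labels <- matrix(TISSUE_CLASSES[["background"]], nr, nc)
  f_conn <- .smooth_field(nr, nc, 9L)
  conn <- tissue & f_conn > stats::quantile(f_conn[tissue], 0.5)
  labels[tissue] <- TISSUE_CLASSES[["adipose"]]
  labels[conn] <- TISSUE_CLASSES[["connective"]]

  # lobulated primary tumor
  tc <- c(r0, c0) + stats::runif(2, -5, 5)
  rt <- stats::runif(1, 14, 20)
  amp <- stats::runif(4, 0, 0.12)
  phs <- stats::runif(4, 0, 2 * pi)
  tumor_radius <- function(theta) {
    r <- rep(rt, length(theta))
    for (k in 2:5) r <- r * (1 + amp[k - 1] * sin(k * theta + phs[k - 1]))
    r
  }
  th_t <- atan2(rr - tc[1], cc - tc[2])
  dist_t <- sqrt((rr - tc[1])^2 + (cc - tc[2])^2)
  tumor <- tissue & dist_t < tumor_radius(th_t)

  ccf <- matrix(0, nr, nc)
  f_ccf <- .smooth_field(nr, nc, 7L)
  draw_ccf_mean <- function() {
    if (stats::runif(1) < config$masking_prone_prob) {
      stats::runif(1, 0.10, 0.14)   # stroma-rich, masking-prone
    } else {
      stats::runif(1, 0.25, 0.90)   # carcinoma-dense
    }
  }
  ccf[tumor] <- pmin(pmax(draw_ccf_mean() + 0.04 * f_ccf[tumor], 0.10), 0.98)
  labels[tumor] <- TISSUE_CLASSES[["tumor"]]

  # demarcated border: tumor outline with a small clearance
  th_poly <- seq(0, 2 * pi, length.out = 73L)[-73L]
  poly <- cbind(tc[1] + 1.08 * tumor_radius(th_poly) * sin(th_poly),
                tc[2] + 1.08 * tumor_radius(th_poly) * cos(th_poly))
  defined <- stats::runif(1) < config$border_defined_prob
  border <- tumor_border(poly, defined = defined)

  place_focus <- function(radius, min_border_clear) {
    for (i in 1:200) {
      p <- c(stats::runif(1, 1 + radius, nr - radius),
             stats::runif(1, 1 + radius, nc - radius))
      thp <- atan2(p[1] - tc[1], p[2] - tc[2])
      dt <- sqrt(sum((p - tc)^2))
      if (dt < 1.08 * tumor_radius(thp) + radius + min_border_clear) next
      radp <- sqrt(((p[1] - r0) / (0.42 * nr))^2 +
                     ((p[2] - c0) / (0.44 * nc))^2)
      wobp <- 1 + 0.06 * sin(2 * atan2(p[1] - r0, p[2] - c0) + ph[1]) +
        0.04 * sin(3 * atan2(p[1] - r0, p[2] - c0) + ph[2])
      if (radp > wobp - radius / (0.42 * nr)) next
      occupied <- labels[round(p[1]), round(p[2])]
      if (occupied %in% TISSUE_CLASSES[.CANCER_CLASSES]) next
      return(p)
    }
    NULL
  }
  stamp_focus <- function(center, radius, class, focus_ccf) {
    d <- sqrt((rr - center[1])^2 + (cc - center[2])^2)
    px <- tissue & d <= radius &
      !(labels %in% TISSUE_CLASSES[.CANCER_CLASSES])
    labels[px] <<- TISSUE_CLASSES[[class]]
    ccf[px] <<- pmin(pmax(focus_ccf + 0.04 * f_ccf[px], 0.10), 0.98)
  }

  n_occ <- stats::rpois(1, config$occult_focus_rate)
  occult_centers <- matrix(numeric(0), ncol = 2)
  if (n_occ > 0) {
    for (i in seq_len(n_occ)) {
      p <- place_focus(radius = 5, min_border_clear = 4)
      if (is.null(p)) next
      stamp_focus(p, 5, "occult_cancer", draw_ccf_mean())
      occult_centers <- rbind(occult_centers, p)
    }
  }

  n_ben <- 1L + stats::rpois(1, 0.7)
  benign_centers <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n_ben)) {
    p <- place_focus(radius = 4, min_border_clear = 4)
    if (is.null(p)) next
    stamp_focus(p, 4, "benign_proliferative", stats::runif(1, 0.35, 0.6))
    benign_centers <- rbind(benign_centers, p)
  }

  # scale-marker sticker in the background corner
  labels[3:12, 3:16] <- TISSUE_CLASSES[["scale_marker"]]
  ccf[3:12, 3:16] <- 0

  map <- tissue_label_map(labels, config$pixel_size_mm, ccf)
  attr(map, "tumor_center") <- tc
  attr(map, "occult_centers") <- occult_centers
  attr(map, "benign_centers") <- benign_centers
  list(map = map, border = border)
}

# --- emission model --------------------------------------------------------

# Spectral basis (wavelength grid 500-800 nm, 1 nm steps):
#   ppix: PpIX doublet, Gaussians at 635 nm (major) and 705 nm (minor, 0.2x)
#   conn: connective-tissue green autofluorescence, Gaussian at 520 nm
#   adip: broad low-amplitude adipose autofluorescence spanning 500-700 nm
#   white: flat (scale sticker reflectance)
.SPEC_GRID <- seq(500, 800, by = 1)
.PPIX_SIGMA <- 12
.PPIX_MINOR_RATIO <- 0.2
.CONN_SIGMA <- 30
.K_PPIX <- 120          # PpIX brightness per unit carcinoma fraction,
                        # relative to unit autofluorescence: PpIX-laden
                        # cancer cells vastly outshine tissue AF at 405 nm
                        # excitation, so even carcinoma-sparse areas read red
                        # unless masked
.STROMA_SHARE <- 0.85   # share of the non-carcinoma part of a cancer pixel
                        # that is stromal connective tissue
.MASK_ATTEN_FLOOR <- 0.03

.basis_spectra <- function(wavelength = .SPEC_GRID) {
  g <- function(mu, sigma) exp(-0.5 * ((wavelength - mu) / sigma)^2)
  list(ppix = g(635, .PPIX_SIGMA) + .PPIX_MINOR_RATIO * g(705, .PPIX_SIGMA),
       conn = g(520, .CONN_SIGMA),
       adip = 0.55 * g(595, 95),
       white = rep(1, length(wavelength)))
}

.basis_env <- new.env(parent = emptyenv())
.basis_xyz <- function() {
  if (is.null(.basis_env$xyz)) {
    b <- .basis_spectra()
    .basis_env$xyz <- vapply(b, function(v) {
      spectrum_to_xyz(list(wavelength_nm = .SPEC_GRID, intensity = v))
    }, numeric(3))
  }
  .basis_env$xyz
}

# Per-class basis amplitudes for one pixel. Cancer-class pixels mix PpIX
# (proportional to dose gain and carcinoma fraction) with stromal green and
# broad cellular autofluorescence; pure connective is green-dominant; pure
# adipose is dim and broad.
.class_amplitudes <- function(class, ccf, dose_gain) {
  switch(class,
    tumor = ,
    occult_cancer = ,
    benign_proliferative = c(
      ppix = .K_PPIX * dose_gain * ccf,
      conn = 0.53 * (1 - ccf) + 0.45 * ccf,
      adip = 0.55 * (1 - ccf) + 0.50 * ccf,
      white = 0),
    connective = c(ppix = 0, conn = 1, adip = 0.10, white = 0),
    adipose = c(ppix = 0, conn = 0.06, adip = 1, white = 0),
    scale_marker = c(ppix = 0, conn = 0, adip = 0, white = 2.5),
    background = c(ppix = 0, conn = 0, adip = 0, white = 0.004),
    stop("parameter error: unknown tissue class '", class, "'"))
}

# Amplitude maps for a whole label map, including the masking attenuation of
# PpIX where the local (box-filtered) carcinoma-to-connective area ratio
# falls below the configured threshold.
.emission_coefficients <- function(map, config,
                                   dose_gain = .dose_gain(config)) {
  lb <- map$labels
  ccf <- map$cancer_cell_fraction
  nr <- nrow(lb); nc <- ncol(lb)
  amp <- list(ppix = matrix(0, nr, nc), conn = matrix(0, nr, nc),
              adip = matrix(0, nr, nc), white = matrix(0, nr, nc))
  for (class in names(TISSUE_CLASSES)) {
    px <- lb == TISSUE_CLASSES[[class]]
    if (!any(px)) next
    base <- .class_amplitudes(class, ccf = 1, dose_gain = 1)
    if (class %in% .CANCER_CLASSES) {
      amp$ppix[px] <- .K_PPIX * dose_gain * ccf[px]
      amp$conn[px] <- 0.53 * (1 - ccf[px]) + 0.45 * ccf[px]
      amp$adip[px] <- 0.55 * (1 - ccf[px]) + 0.50 * ccf[px]
    } else {
      amp$ppix[px] <- base[["ppix"]]
      amp$conn[px] <- base[["conn"]]
      amp$adip[px] <- base[["adip"]]
      amp$white[px] <- base[["white"]]
    }
  }
  amp$ppix <- amp$ppix * .masking_attenuation(map, config)
  amp
}

# Local carcinoma-to-connective area ratio and the resulting PpIX
# attenuation. Carcinoma area is the carcinoma cell fraction; connective
# area is pure connective pixels plus the stromal share of cancer pixels.
.masking_attenuation <- function(map, config) {
  lb <- map$labels
  ccf <- map$cancer_cell_fraction
  cancer <- lb %in% TISSUE_CLASSES[.CANCER_CLASSES]
  conn_area <- (lb == TISSUE_CLASSES[["connective"]]) * 1 +
    cancer * .STROMA_SHARE * (1 - ccf)
  ratio <- .box_mean(ccf, 9L) / (.box_mean(conn_area, 9L) + 1e-9)
  thr <- config$masking_ratio_threshold
  atten <- matrix(1, nrow(lb), ncol(lb))
  if (thr > 0) {
    masked <- cancer & ratio < thr
    atten[masked] <- .MASK_ATTEN_FLOOR +
      (1 - .MASK_ATTEN_FLOOR) * 0.1 * (ratio[masked] / thr)^4
  }
  atten
}

#' Emission spectrum of one tissue element
#'
#' Mixture of (i) the PpIX doublet (Gaussian peaks at 635 nm and, at fixed
#' 0.2 relative amplitude, 705 nm) scaled by `dose_gain` times
#' `cancer_cell_fraction`; (ii) connective-tissue green autofluorescence
#' (Gaussian at 520 nm); and (iii) broad low-amplitude adipose
#' autofluorescence spanning 500-700 nm. Component weights are set by the
#' tissue class.
#'
#' @param class tissue class name (see [TISSUE_CLASSES]).
#' @param cancer_cell_fraction carcinoma area fraction in \[0, 1\].
#' @param dose_gain relative PpIX gain (0 for the no-5-ALA control).
#' @param wavelength_nm wavelength grid (default 500-800 nm, 1 nm).
#' @return an [emission_spectrum].
#' @export
#' @examples
#' s <- tissue_emission_spectrum("tumor", 1, 1)
#' s$wavelength_nm[which.max(s$intensity)]  # 635
tissue_emission_spectrum <- function(class, cancer_cell_fraction, dose_gain,
                                     wavelength_nm = .SPEC_GRID) {
  stopifnot(cancer_cell_fraction >= 0, cancer_cell_fraction <= 1,
            dose_gain >= 0)
  a <- .class_amplitudes(class, cancer_cell_fraction, dose_gain)
  b <- .basis_spectra(wavelength_nm)
  intensity <- a[["ppix"]] * b$ppix + a[["conn"]] * b$conn +
    a[["adip"]] * b$adip + a[["white"]] * b$white
  emission_spectrum(wavelength_nm, intensity)
}

# --- rendering -------------------------------------------------------------

#' Specimen image constructor
#'
#' @param rgb integer array `rows x cols x 3` of 8-bit values.
#' @param pixel_size_mm pixel size.
#' @param dose_group dose group label.
#' @return object of class `specimen_image`.
#' @export
specimen_image <- function(rgb, pixel_size_mm, dose_group = NA_character_) {
  stopifnot(is.array(rgb), length(dim(rgb)) == 3, dim(rgb)[3] == 3)
  structure(list(rgb = rgb, pixel_size_mm = pixel_size_mm,
                 dose_group = dose_group), class = "specimen_image")
}

#' Render a fluorescence image from a tissue label map
#'
#' Per pixel: the emission spectrum (a mixture of PpIX and autofluorescence
#' basis spectra) is integrated against the CIE 1931 2-degree
#' color-matching functions to XYZ, converted to linear sRGB (D65), exposed
#' so that the 99th-percentile linear channel value encodes to 245,
#' perturbed with additive Gaussian sensor noise (`noise_sd`, linear
#' domain, skipped when 0), gamma-encoded per IEC 61966-2-1 and quantized
#' to 8 bits. Because XYZ is linear in the spectrum, rendering uses
#' precomputed basis tristimuli and is fully vectorized.
#'
#' Uses the current RNG stream (the label-map generator seeds it per
#' specimen); with `noise_sd = 0` the output is a deterministic function of
#' the map.
#'
#' @param map a [tissue_label_map].
#' @param config a [simulation_config].
#' @return a [specimen_image].
#' @export
render_fluorescence_image <- function(map, config) {
  stopifnot(inherits(map, "tissue_label_map"))
  amp <- .emission_coefficients(map, config)
  bx <- .basis_xyz()
  nr <- nrow(map$labels); nc <- ncol(map$labels)
  n <- nr * nc
  xyz <- cbind(X = as.vector(amp$ppix) * bx["X", "ppix"] +
                 as.vector(amp$conn) * bx["X", "conn"] +
                 as.vector(amp$adip) * bx["X", "adip"] +
                 as.vector(amp$white) * bx["X", "white"],
               Y = as.vector(amp$ppix) * bx["Y", "ppix"] +
                 as.vector(amp$conn) * bx["Y", "conn"] +
                 as.vector(amp$adip) * bx["Y", "adip"] +
                 as.vector(amp$white) * bx["Y", "white"],
               Z = as.vector(amp$ppix) * bx["Z", "ppix"] +
                 as.vector(amp$conn) * bx["Z", "conn"] +
                 as.vector(amp$adip) * bx["Z", "adip"] +
                 as.vector(amp$white) * bx["Z", "white"])
  lin <- xyz %*% t(.M_XYZ2RGB)
  lin[lin < 0] <- 0
  q99 <- stats::quantile(lin, 0.99, names = FALSE)
  if (q99 > 0) lin <- lin * (srgb_decode(245 / 255) / q99)
  if (config$noise_sd > 0) {
    lin <- lin + stats::rnorm(length(lin), sd = config$noise_sd)
  }
  lin[lin < 0] <- 0
  lin[lin > 1] <- 1
  rgb8 <- array(as.integer(round(255 * srgb_encode(lin))), dim = c(nr, nc, 3))
  specimen_image(rgb8, map$pixel_size_mm, config$dose_group)
}

# --- biopsy sampling -------------------------------------------------------

# Pixel offsets of a punch disc of the given radius (pixels).
.disc_offsets <- function(radius_px) {
  r <- ceiling(radius_px)
  dr <- rep(-r:r, times = 2 * r + 1)
  dc <- rep(-r:r, each = 2 * r + 1)
  keep <- dr^2 + dc^2 <= radius_px^2
  cbind(dr = dr[keep], dc = dc[keep])
}

.disc_index <- function(row, col, radius_px, nr, nc) {
  off <- .disc_offsets(radius_px)
  rr <- row + off[, 1]; cc <- col + off[, 2]
  if (any(rr < 1 | rr > nr | cc < 1 | cc > nc)) {
    stop("bounds error: punch disc extends outside the image")
  }
  cbind(rr, cc)
}

.punch_radius_px <- function(punch_mm, pixel_size_mm) {
  punch_mm / 2 / pixel_size_mm
}

#' Sample punch-biopsy sites from a specimen
#'
#' Emulates the trial's biopsy protocol: between 1 and 4 sites per
#' specimen, exactly one inside the demarcated tumor border (placed at the
#' densest carcinoma neighborhood) and 1-3 outside it, collected with 2- or
#' 4-mm punch devices and non-overlapping discs. Outside sites target a
#' grossly occult focus with probability `occult_site_prob` (when present),
#' otherwise a PpIX-expressing benign proliferative focus with probability
#' `benign_positive_rate` (when present), otherwise normal tissue clear of
#' cancer. Ground-truth histology is positive iff any tumor or occult-cancer
#' pixel lies within the punch disc; benign-proliferative content is
#' recorded as its own flag.
#'
#' Uses the current RNG stream (see [generate_label_map()]).
#'
#' @param map a [tissue_label_map].
#' @param border the matching [tumor_border].
#' @param config a [simulation_config].
#' @return data frame of biopsy records: `site_id`, `row`, `col`,
#'   `punch_mm`, `stratum` (`inside`/`outside`), `histology` (`pos`/`neg`),
#'   `proliferative` (0/1).
#' @export
sample_biopsies <- function(map, border, config) {
  stopifnot(inherits(map, "tissue_label_map"))
  lb <- map$labels
  nr <- nrow(lb); nc <- ncol(lb)
  psz <- map$pixel_size_mm
  max_r <- .punch_radius_px(4, psz)
  if (nr < 4 * max_r || nc < 4 * max_r) {
    stop("placement error: specimen too small for a punch biopsy")
  }
  cancer <- lb == TISSUE_CLASSES[["tumor"]] |
    lb == TISSUE_CLASSES[["occult_cancer"]]
  benign <- lb == TISSUE_CLASSES[["benign_proliferative"]]

  sites <- list()
  taken <- matrix(numeric(0), ncol = 3)  # row, col, radius_px
  fits <- function(row, col, rad) {
    if (row - rad < 1 || row + rad > nr || col - rad < 1 || col + rad > nc) {
      return(FALSE)
    }
    if (nrow(taken) == 0) return(TRUE)
    all(sqrt((taken[, 1] - row)^2 + (taken[, 2] - col)^2) >
          taken[, 3] + rad + 1)
  }
  push <- function(row, col, punch_mm, stratum) {
    idx <- .disc_index(row, col, .punch_radius_px(punch_mm, psz), nr, nc)
    hist_pos <- any(cancer[idx])
    prolif <- any(benign[idx])
    taken <<- rbind(taken, c(row, col, .punch_radius_px(punch_mm, psz)))
    sites[[length(sites) + 1]] <<- data.frame(
      row = row, col = col, punch_mm = punch_mm, stratum = stratum,
      histology = if (hist_pos) "pos" else "neg",
      proliferative = as.integer(prolif))
  }

  # inside-border site: densest tumor neighborhood (skipped when the map
  # carries no primary tumor, e.g. a tumor-free slice)
  tumor_ind <- (lb == TISSUE_CLASSES[["tumor"]]) * 1
  if (any(tumor_ind > 0)) {
    dens <- .box_mean(tumor_ind, 9L)
    dens[!(lb == TISSUE_CLASSES[["tumor"]])] <- -1
    best <- arrayInd(which.max(dens), dim(dens))
    push(best[1], best[2], punch_mm = 4, stratum = "inside")
  }

  inside_mask <- if (border$defined) {
    .polygon_mask(border$polygon, nr, nc)
  } else {
    # ill-defined border: keep outside sites clear of the tumor blob
    .box_mean(tumor_ind, 13L) > 0
  }

  occ_centers <- attr(map, "occult_centers")
  ben_centers <- attr(map, "benign_centers")
  tissue <- lb == TISSUE_CLASSES[["connective"]] |
    lb == TISSUE_CLASSES[["adipose"]]

  # each focus hosts at most one punch (punches remove tissue)
  occ_free <- seq_len(NROW(occ_centers))
  ben_free <- seq_len(NROW(ben_centers))
  target_focus <- function(centers, free, rad, jitter, ok_pixel) {
    for (k in sample(free)) {
      for (try in 1:25) {
        p <- round(centers[k, ] + stats::runif(2, -jitter, jitter))
        if (p[1] < 1 || p[1] > nr || p[2] < 1 || p[2] > nc) next
        if (fits(p[1], p[2], rad) && ok_pixel(p)) {
          return(list(p = p, k = k))
        }
      }
    }
    NULL
  }

  n_outside <- sample(1:3, 1, prob = c(0.25, 0.40, 0.35))
  for (i in seq_len(n_outside)) {
    punch_mm <- sample(c(2, 4), 1)
    rad <- .punch_radius_px(punch_mm, psz)
    u <- stats::runif(1)
    placed <- FALSE
    if (u < config$occult_site_prob && length(occ_free) > 0) {
      hit <- target_focus(occ_centers, occ_free, rad, jitter = 1.5,
                          ok_pixel = function(p) cancer[p[1], p[2]])
      if (!is.null(hit)) {
        push(hit$p[1], hit$p[2], punch_mm, "outside")
        occ_free <- setdiff(occ_free, hit$k)
        placed <- TRUE
      }
    } else if (u >= config$occult_site_prob &&
                 u < config$occult_site_prob + config$benign_positive_rate &&
                 length(ben_free) > 0) {
      hit <- target_focus(ben_centers, ben_free, rad, jitter = 1,
                          ok_pixel = function(p) {
                            benign[p[1], p[2]] &&
                              !any(cancer[.disc_index(p[1], p[2], rad,
                                                      nr, nc)])
                          })
      if (!is.null(hit)) {
        push(hit$p[1], hit$p[2], punch_mm, "outside")
        ben_free <- setdiff(ben_free, hit$k)
        placed <- TRUE
      }
    }
    if (!placed) {
      normal_ok <- function(p) {
        if (!tissue[p[1], p[2]] || inside_mask[p[1], p[2]]) return(FALSE)
        if (!fits(p[1], p[2], rad)) return(FALSE)
        idx <- .disc_index(p[1], p[2], rad, nr, nc)
        !(any(cancer[idx]) || any(benign[idx]) ||
            any(lb[idx] == TISSUE_CLASSES[["background"]]) ||
            any(lb[idx] == TISSUE_CLASSES[["scale_marker"]]) ||
            any(inside_mask[idx]))
      }
      for (try in 1:200) {
        p <- c(sample(seq_len(nr), 1), sample(seq_len(nc), 1))
        if (normal_ok(p)) {
          push(p[1], p[2], punch_mm, "outside"); placed <- TRUE; break
        }
      }
      if (!placed) {
        # exhaustive fallback over candidate tissue pixels, random order
        cand <- which(tissue & !inside_mask)
        for (j in sample(cand)) {
          p <- c((j - 1) %% nr + 1, (j - 1) %/% nr + 1)
          if (normal_ok(p)) {
            push(p[1], p[2], punch_mm, "outside"); placed <- TRUE; break
          }
        }
      }
    }
    # a site can still fail on a pathologically crowded specimen, in which
    # case fewer biopsies are collected
  }
  out <- do.call(rbind, sites)
  out <- cbind(site_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

# --- point spectroscopy ----------------------------------------------------

#' Simulate a fiberoptic point spectrum at a biopsy site
#'
#' Area-weighted mixture of the per-pixel emission spectra over the punch
#' disc (identical emission model to the image renderer, including masking
#' attenuation), plus additive Gaussian noise with sd `config$noise_sd`,
#' on a 500-800 nm grid with 1 nm steps.
#'
#' @param site one biopsy record (a row of [sample_biopsies()] output, or
#'   any list with `row`, `col`, `punch_mm`).
#' @param map the [tissue_label_map] the site was sampled from.
#' @param config a [simulation_config].
#' @return an [emission_spectrum].
#' @export
generate_point_spectrum <- function(site, map, config) {
  idx <- .disc_index(site$row, site$col,
                     .punch_radius_px(site$punch_mm, map$pixel_size_mm),
                     nrow(map$labels), ncol(map$labels))
  amp <- .emission_coefficients(map, config)
  b <- .basis_spectra()
  a <- c(ppix = mean(amp$ppix[idx]), conn = mean(amp$conn[idx]),
         adip = mean(amp$adip[idx]), white = mean(amp$white[idx]))
  intensity <- a[["ppix"]] * b$ppix + a[["conn"]] * b$conn +
    a[["adip"]] * b$adip + a[["white"]] * b$white
  if (config$noise_sd > 0) {
    intensity <- pmax(
      intensity + stats::rnorm(length(intensity), sd = config$noise_sd), 0)
  }
  emission_spectrum(.SPEC_GRID, intensity)
}
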