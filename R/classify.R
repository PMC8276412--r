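# Deterministic fluorescence color categorization of biopsy sites:
# red (PpIX) / green (connective) / dull pink-brown (adipose), and the
# binary +RedFL / -RedFL call used for diagnostic accuracy.

#' Median chromaticity of a punch-biopsy disc
#'
#' Decodes the image to XYZ and takes the median x and median y over the
#' disc's per-pixel chromaticities (median for robustness to speckle).
#' Pixels with zero tristimulus sum (pure black) are dropped.
#'
#' @param image a [specimen_image].
#' @param site a biopsy record (list/row with `row`, `col`, `punch_mm`).
#' @return named numeric `c(x, y)`.
#' @export
site_chromaticity <- function(image, site) {
  .site_chromaticity_raster(decode_srgb_to_xyz(image),
                            image$pixel_size_mm, site)
}

.site_chromaticity_raster <- function(raster, pixel_size_mm, site) {
  radius <- .punch_radius_px(site$punch_mm, pixel_size_mm)
  idx <- .disc_index(site$row, site$col, radius,
                     nrow(raster$X), ncol(raster$X))
  X <- raster$X[idx]; Y <- raster$Y[idx]; Z <- raster$Z[idx]
  s <- X + Y + Z
  keep <- s > 0
  if (!any(keep)) stop("undefined chromaticity: disc is black")
  c(x = stats::median(X[keep] / s[keep]),
    y = stats::median(Y[keep] / s[keep]))
}

#' Classify a chromaticity as red, green or dull pink/brown fluorescence
#'
#' Deterministic stand-in for the study team's visual call. The dominant
#' wavelength and excitation purity relative to D65 are computed by
#' spectral-locus intersection; the category is `red` when the dominant
#' wavelength is >= 600 nm with purity >= `p_min`, `green` when it lies in
#' \[490, 570) nm with purity >= `p_min`, and `pink_brown` otherwise
#' (including low-purity "dull" colors and, flagged, out-of-locus purples).
#' Band-edge ties resolve to the longer-wavelength band.
#'
#' @param xy numeric `c(x, y)` chromaticity.
#' @param p_min minimum excitation purity for a saturated (red/green) call;
#'   default 0.25.
#' @return object of class `color_call`: `category`, `red_positive`,
#'   `dominant_wavelength_nm`, `purity`, `out_of_gamut`.
#' @export
classify_color <- function(xy, p_min = 0.25) {
  dw <- dominant_wavelength(xy)
  category <- "pink_brown"
  if (!dw$purple && !is.na(dw$dominant_wavelength_nm) && dw$purity >= p_min) {
    lam <- dw$dominant_wavelength_nm
    if (lam >= 600) {
      category <- "red"
    } else if (lam >= 490 && lam < 570) {
      category <- "green"
    }
  }
  structure(list(category = category,
                 red_positive = category == "red",
                 dominant_wavelength_nm = dw$dominant_wavelength_nm,
                 purity = dw$purity,
                 out_of_gamut = dw$purple),
            class = "color_call")
}

#' Binary +RedFL / -RedFL call
#'
#' @param call a [classify_color()] result.
#' @return `TRUE` iff the category is `red` (positive for PpIX red
#'   fluorescence); green and dull pink/brown are both negative.
#' @export
binarize_call <- function(call) {
  stopifnot(inherits(call, "color_call"))
  identical(call$category, "red")
}

#' Classify all biopsy sites on a specimen image
#'
#' Applies [site_chromaticity()] and [classify_color()] to each record and
#' appends the call columns.
#'
#' @param image a [specimen_image].
#' @param records biopsy record data frame (`row`, `col`, `punch_mm`, ...).
#' @param p_min purity threshold passed to [classify_color()].
#' @return `records` with added columns `category`, `red_positive`,
#'   `dominant_wavelength_nm`, `purity`.
#' @export
classify_biopsies <- function(image, records, p_min = 0.25) {
  raster <- decode_srgb_to_xyz(image)
  calls <- lapply(seq_len(nrow(records)), function(i) {
    xy <- .site_chromaticity_raster(raster, image$pixel_size_mm,
                                    records[i, ])
    classify_color(xy, p_min = p_min)
  })
  records$category <- vapply(calls, `[[`, "", "category")
  records$red_positive <- vapply(calls, `[[`, TRUE, "red_positive")
  records$dominant_wavelength_nm <-
    vapply(calls, `[[`, 1, "dominant_wavelength_nm")
  records$purity <- vapply(calls, `[[`, 1, "purity")
  records
}
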