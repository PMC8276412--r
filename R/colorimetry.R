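# sRGB <-> XYZ conversion and the tumor-to-normal chromaticity contrast
# analysis applied to specimen fluorescence images.

# Linear sRGB -> XYZ (D65, IEC 61966-2-1); rows sum to the D65 white point.
.M_RGB2XYZ <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041), nrow = 3, byrow = TRUE)
.M_XYZ2RGB <- solve(.M_RGB2XYZ)

#' sRGB transfer functions
#'
#' Forward (`srgb_encode`) and inverse (`srgb_decode`) electro-optical
#' transfer functions of IEC 61966-2-1, operating on values in \[0, 1\].
#'
#' @param u encoded (gamma) values in \[0, 1\].
#' @param v linear values in \[0, 1\].
#' @return numeric vector of the same length.
#' @export
srgb_decode <- function(u) {
  ifelse(u <= 0.04045, u / 12.92, ((u + 0.055) / 1.055)^2.4)
}

#' @rdname srgb_decode
#' @export
srgb_encode <- function(v) {
  ifelse(v <= 0.0031308, 12.92 * v, 1.055 * v^(1 / 2.4) - 0.055)
}

#' Decode an 8-bit sRGB image to a CIE XYZ raster
#'
#' Per pixel: channel/255, sRGB linearization, then the linear-RGB-to-XYZ
#' matrix with sRGB primaries and D65 white. White (255,255,255) maps to
#' Y = 1 exactly.
#'
#' @param image a [specimen_image] or a numeric/integer array of dimension
#'   `c(rows, cols, 3)` holding 8-bit RGB values in 0..255.
#' @return object of class `xyz_raster`: list of matrices `X`, `Y`, `Z`.
#' @export
decode_srgb_to_xyz <- function(image) {
  rgb <- if (inherits(image, "specimen_image")) image$rgb else image
  if (!(is.array(rgb) && length(dim(rgb)) == 3 && dim(rgb)[3] == 3)) {
    stop("format error: expected an rows x cols x 3 RGB array")
  }
  if (min(rgb) < 0 || max(rgb) > 255) {
    stop("format error: 8-bit RGB values must lie in 0..255")
  }
  d <- dim(rgb)
  lin <- srgb_decode(rgb / 255)
  dim(lin) <- c(d[1] * d[2], 3)
  xyz <- lin %*% t(.M_RGB2XYZ)
  out <- list(X = matrix(xyz[, 1], d[1], d[2]),
              Y = matrix(xyz[, 2], d[1], d[2]),
              Z = matrix(xyz[, 3], d[1], d[2]))
  class(out) <- "xyz_raster"
  out
}

# XYZ (rows of a matrix, or 3-vector) -> gamma-encoded sRGB in [0,1];
# out-of-gamut channels are clamped.
.xyz_to_srgb <- function(xyz) {
  lin <- xyz %*% t(.M_XYZ2RGB)
  srgb_encode(pmin(pmax(lin, 0), 1))
}

#' Mean chromaticity of a region of interest
#'
#' Averages X, Y and Z over the effective ROI (`include & !exclude`) first,
#' then projects the mean tristimulus to chromaticity:
#' \eqn{x = \bar X/(\bar X+\bar Y+\bar Z)}, \eqn{y = \bar Y/(\ldots)}.
#' The averaging order (XYZ first, projection second) is a fixed contract:
#' it is a luminance-weighted chromaticity, not a mean of per-pixel
#' chromaticities.
#'
#' @param raster an `xyz_raster` from [decode_srgb_to_xyz()].
#' @param include logical matrix selecting candidate pixels.
#' @param exclude optional logical matrix of pixels to drop (background,
#'   scale sticker, confirmed cancer outside the tumor border).
#' @return named numeric `c(x, y)`.
#' @export
roi_mean_chromaticity <- function(raster, include, exclude = NULL) {
  stopifnot(inherits(raster, "xyz_raster"))
  eff <- include
  if (!is.null(exclude)) eff <- eff & !exclude
  if (!any(eff)) stop("analysis error: effective ROI is empty")
  m <- c(mean(raster$X[eff]), mean(raster$Y[eff]), mean(raster$Z[eff]))
  s <- sum(m)
  if (s <= 0) stop("undefined chromaticity: mean X + Y + Z is zero")
  c(x = m[1] / s, y = m[2] / s)
}

#' Euclidean distance between two chromaticities
#'
#' The tumor-to-normal color contrast measure: straight-line distance in the
#' CIE (x, y) plane, a proxy for perceived color difference.
#'
#' @param p,q numeric `c(x, y)` chromaticities.
#' @return non-negative scalar.
#' @export
chromatic_distance <- function(p, q) {
  stopifnot(length(p) == 2, length(q) == 2)
  sqrt((p[[1]] - q[[1]])^2 + (p[[2]] - q[[2]])^2)
}

#' Express a chromatic distance in just-noticeable-difference units
#'
#' Reporting aid only: divides the distance by a configurable MacAdam-style
#' just-noticeable-difference scalar.
#'
#' @param distance chromatic distance(s).
#' @param jnd just-noticeable difference in (x, y) units; default 0.004,
#'   a representative MacAdam ellipse semi-axis.
#' @return distance in JND units.
#' @export
macadam_units <- function(distance, jnd = 0.004) {
  stopifnot(jnd > 0)
  distance / jnd
}

#' Compare tumor-to-normal chromatic distances across dose groups
#'
#' One-way ANOVA with Tukey HSD multiple comparisons on per-specimen
#' Euclidean chromaticity distances, grouped by dose.
#'
#' When the between-group differences are non-zero but every group is
#' internally constant (zero residual variance), the F statistic is infinite
#' and pairwise p-values degenerate to 0 for unequal and 1 for equal group
#' means; this limit is handled explicitly.
#'
#' @param distances_by_group named list of numeric vectors (>= 2 groups,
#'   each with >= 2 values).
#' @return object of class `group_contrast`: list with `groups` (per-group
#'   n, mean, sd), `f_statistic`, `p_value`, and `tukey` (data frame of
#'   pairwise differences and adjusted p-values).
#' @export
group_contrast <- function(distances_by_group) {
  g <- distances_by_group
  if (!is.list(g) || length(g) < 2) {
    stop("analysis error: need at least 2 groups")
  }
  if (is.null(names(g)) || any(!nzchar(names(g)))) {
    names(g) <- paste0("group", seq_along(g))
  }
  if (any(vapply(g, length, 1L) < 2)) {
    stop("analysis error: each group needs at least 2 values")
  }
  value <- unlist(g, use.names = FALSE)
  group <- factor(rep(names(g), vapply(g, length, 1L)), levels = names(g))
  if (stats::var(value) < .Machine$double.eps) {
    stop("analysis error: all values identical; variance is degenerate")
  }
  stats_df <- data.frame(
    group = names(g),
    n = vapply(g, length, 1L),
    mean = vapply(g, mean, 1),
    sd = vapply(g, stats::sd, 1),
    row.names = NULL)
  within_ss <- sum(vapply(g, function(v) sum((v - mean(v))^2), 1))
  pairs <- utils::combn(names(g), 2)
  if (within_ss < 1e-12 * sum((value - mean(value))^2)) {
    diffs <- apply(pairs, 2, function(p) mean(g[[p[2]]]) - mean(g[[p[1]]]))
    tukey <- data.frame(
      pair = paste(pairs[2, ], pairs[1, ], sep = "-"),
      diff = diffs,
      p_adj = ifelse(abs(diffs) > 0, 0, 1))
    out <- list(groups = stats_df, f_statistic = Inf, p_value = 0,
                tukey = tukey)
  } else {
    fit <- stats::aov(value ~ group, data = data.frame(value, group))
    s <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit)$group
    out <- list(groups = stats_df,
                f_statistic = s[["F value"]][1],
                p_value = s[["Pr(>F)"]][1],
                tukey = data.frame(pair = rownames(tk),
                                   diff = tk[, "diff"],
                                   p_adj = tk[, "p adj"],
                                   row.names = NULL))
  }
  class(out) <- "group_contrast"
  out
}

#' @export
print.group_contrast <- function(x, ...) {
  cat("Tumor-to-normal chromatic contrast by group\n")
  print(x$groups, row.names = FALSE)
  cat(sprintf("one-way ANOVA: F = %.3g, p = %.3g\n",
              x$f_statistic, x$p_value))
  print(x$tukey, row.names = FALSE)
  invisible(x)
}

#' Tumor and normal ROI chromaticities for one specimen image
#'
#' Builds the tumor ROI (tissue inside the demarcated border) and normal ROI
#' (tissue outside the border) from a tissue label map and border polygon,
#' applies the standard exclusions (background, scale sticker, and
#' histologically confirmed cancer outside the border, i.e. occult foci),
#' and returns both mean chromaticities and their Euclidean distance.
#' Specimens without a defined border are excluded from contrast analysis;
#' for those this function returns `NULL`.
#'
#' @param image a [specimen_image].
#' @param map the matching [tissue_label_map].
#' @param border the matching [tumor_border].
#' @return `NULL` when `border$defined` is `FALSE`; otherwise a
#'   `chromaticity_pair`: list with `xy_tumor`, `xy_normal`, `distance`.
#' @export
specimen_contrast <- function(image, map, border) {
  stopifnot(inherits(map, "tissue_label_map"), inherits(border, "tumor_border"))
  if (!border$defined) return(NULL)
  raster <- decode_srgb_to_xyz(image)
  lb <- map$labels
  tissue <- lb != TISSUE_CLASSES[["background"]] &
    lb != TISSUE_CLASSES[["scale_marker"]]
  inside <- .polygon_mask(border$polygon, nrow(lb), ncol(lb))
  occult <- lb == TISSUE_CLASSES[["occult_cancer"]]
  xy_t <- roi_mean_chromaticity(raster, include = tissue & inside)
  xy_n <- roi_mean_chromaticity(raster, include = tissue & !inside,
                                exclude = occult)
  out <- list(xy_tumor = xy_t, xy_normal = xy_n,
              distance = chromatic_distance(xy_t, xy_n))
  class(out) <- "chromaticity_pair"
  out
}
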