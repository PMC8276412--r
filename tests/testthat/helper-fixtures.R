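# Fixture builders shared across test files; everything is generated in code.

# Uniform 8-bit RGB image of the given color.
uniform_image <- function(rgb, nr = 8, nc = 8, pixel_size_mm = 1) {
  arr <- array(0L, c(nr, nc, 3))
  for (k in 1:3) arr[, , k] <- rgb[k]
  specimen_image(arr, pixel_size_mm)
}

# Minimal xyz_raster from explicit per-pixel XYZ triples (list of rows).
raster_from_xyz <- function(xyz_rows) {
  n <- length(xyz_rows)
  structure(list(X = matrix(vapply(xyz_rows, `[[`, 1, 1), 1, n),
                 Y = matrix(vapply(xyz_rows, `[[`, 1, 2), 1, n),
                 Z = matrix(vapply(xyz_rows, `[[`, 1, 3), 1, n)),
            class = "xyz_raster")
}

# Small fast config for pipeline smoke tests.
fast_config <- function(...) {
  simulation_config(grid = c(80L, 100L), ...)
}

# A label map whose central disc holds prescribed class counts; the rest of
# the disc is background (excluded from tissue fractions).
counted_disc_map <- function(n_tumor, n_conn, n_adip, ccf = 1,
                             pixel_size_mm = 1) {
  nr <- nc <- 41L
  labels <- matrix(TISSUE_CLASSES[["background"]], nr, nc)
  idx <- fluormargin:::.disc_index(21, 21, 10 / pixel_size_mm, nr, nc)
  stopifnot(nrow(idx) >= n_tumor + n_conn + n_adip)
  codes <- rep(TISSUE_CLASSES[["background"]], nrow(idx))
  codes[seq_len(n_tumor)] <- TISSUE_CLASSES[["tumor"]]
  codes[seq_len(n_conn) + n_tumor] <- TISSUE_CLASSES[["connective"]]
  codes[seq_len(n_adip) + n_tumor + n_conn] <- TISSUE_CLASSES[["adipose"]]
  labels[idx] <- codes
  frac <- matrix(0, nr, nc)
  frac[idx[codes == TISSUE_CLASSES[["tumor"]], , drop = FALSE]] <- ccf
  tissue_label_map(labels, pixel_size_mm, frac)
}
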