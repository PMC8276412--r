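test_that("sRGB decoding reproduces the standard chromaticities", {
  white <- decode_srgb_to_xyz(uniform_image(c(255, 255, 255), 1, 1))
  xy <- roi_mean_chromaticity(white, matrix(TRUE, 1, 1))
  expect_equal(unname(xy), c(0.3127, 0.3290), tolerance = 1e-3)

  red <- decode_srgb_to_xyz(uniform_image(c(255, 0, 0), 1, 1))
  xy <- roi_mean_chromaticity(red, matrix(TRUE, 1, 1))
  expect_equal(unname(xy), c(0.640, 0.330), tolerance = 1e-3)

  black <- decode_srgb_to_xyz(uniform_image(c(0, 0, 0), 1, 1))
  expect_identical(c(black$X[1], black$Y[1], black$Z[1]), c(0, 0, 0))

  expect_error(decode_srgb_to_xyz(matrix(1, 3, 3)), "format error")
})

test_that("decoding agrees with grDevices::convertColor", {
  set.seed(11)
  cols <- matrix(sample(0:255, 60, replace = TRUE), ncol = 3)
  for (i in seq_len(nrow(cols))) {
    ours <- decode_srgb_to_xyz(uniform_image(cols[i, ], 1, 1))
    ref <- grDevices::convertColor(matrix(cols[i, ] / 255, 1),
                                   from = "sRGB", to = "XYZ")
    # convertColor's sRGB path differs in the last per-mille; this is a
    # sanity cross-check, the exact targets are the white point and
    # primaries asserted above
    expect_equal(c(ours$X[1], ours$Y[1], ours$Z[1]), as.numeric(ref),
                 tolerance = 0.01)
  }
})

test_that("ROI chromaticity averages XYZ first, then projects", {
  # two pixels (1,1,1) and (3,1,1): mean (2,1,1) -> (x,y) = (0.5, 0.25)
  r <- raster_from_xyz(list(c(1, 1, 1), c(3, 1, 1)))
  xy <- roi_mean_chromaticity(r, matrix(TRUE, 1, 2))
  expect_equal(unname(xy), c(0.5, 0.25), tolerance = 1e-12)

  # uniform ROI equals the single-pixel chromaticity
  r1 <- raster_from_xyz(list(c(2, 1, 1), c(2, 1, 1), c(2, 1, 1)))
  expect_equal(roi_mean_chromaticity(r1, matrix(TRUE, 1, 3)),
               roi_mean_chromaticity(r1, matrix(c(TRUE, FALSE, FALSE), 1)))

  # excluded pixels can hold arbitrary values without changing the result
  r2 <- raster_from_xyz(list(c(1, 1, 1), c(3, 1, 1), c(99, 0, 7)))
  include <- matrix(TRUE, 1, 3)
  exclude <- matrix(c(FALSE, FALSE, TRUE), 1)
  expect_equal(unname(roi_mean_chromaticity(r2, include, exclude)),
               c(0.5, 0.25), tolerance = 1e-12)

  expect_error(roi_mean_chromaticity(r2, matrix(FALSE, 1, 3)),
               "empty")
})

test_that("chromatic distance is a metric and scale invariant", {
  p <- c(0.640, 0.330); q <- c(0.300, 0.600)
  expect_equal(chromatic_distance(p, q), 0.4342, tolerance = 1e-4)
  expect_identical(chromatic_distance(p, p), 0)
  expect_equal(chromatic_distance(p, q), chromatic_distance(q, p))

  set.seed(7)
  for (i in 1:25) {
    a <- runif(2, 0, 0.8); b <- runif(2, 0, 0.8); c <- runif(2, 0, 0.8)
    expect_gte(chromatic_distance(a, b) + chromatic_distance(b, c),
               chromatic_distance(a, c) - 1e-12)
    expect_gte(chromatic_distance(a, b), 0)
  }

  # multiplying XYZ by a constant leaves chromaticity unchanged
  r <- raster_from_xyz(list(c(1, 2, 0.5), c(2, 1, 1)))
  rs <- raster_from_xyz(list(c(1, 2, 0.5) * 7.3, c(2, 1, 1) * 7.3))
  inc <- matrix(TRUE, 1, 2)
  expect_equal(roi_mean_chromaticity(r, inc),
               roi_mean_chromaticity(rs, inc), tolerance = 1e-12)
})

test_that("spectral rendering round-trips chromaticity through 8-bit sRGB", {
  # in-gamut spectra (with short-wavelength content) survive encode/decode
  lam <- seq(380, 780, by = 2)
  specs <- list(rep(1, length(lam)),                       # equal energy
                exp(-0.5 * ((lam - 550) / 120)^2) + 0.3,   # broad greenish
                0.6 + 0.4 * (lam - 380) / 400)             # warm ramp
  for (v in specs) {
    xyz <- spectrum_to_xyz(list(wavelength_nm = lam, intensity = v))
    xyz <- xyz / xyz[["Y"]] * 0.5                          # mid exposure
    rgb8 <- round(255 * fluormargin:::.xyz_to_srgb(matrix(xyz, 1)))
    expect_true(all(rgb8 >= 0 & rgb8 <= 255))              # in gamut
    img <- uniform_image(rgb8, 2, 2)
    xy_back <- roi_mean_chromaticity(decode_srgb_to_xyz(img),
                                     matrix(TRUE, 2, 2))
    expect_equal(unname(xy_back), unname(xyz_to_xy(xyz)), tolerance = 0.01)
  }
})

test_that("group contrast handles standard and degenerate ANOVA inputs", {
  # three identical groups: no between-group signal
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  res <- group_contrast(g)
  expect_equal(res$f_statistic, 0)
  expect_equal(res$p_value, 1)

  # zero within-group variance: only truly different pairs are flagged
  res <- group_contrast(list(a = c(0, 0, 0, 0), b = c(1, 1, 1, 1),
                             c = c(1, 1, 1, 1)))
  p <- setNames(res$tukey$p_adj, res$tukey$pair)
  expect_equal(unname(p[c("b-a", "c-a")]), c(0, 0))
  expect_equal(unname(p["c-b"]), 1)

  expect_error(group_contrast(list(a = 1:3)), "at least 2 groups")
  expect_error(group_contrast(list(a = c(2, 2), b = c(2, 2))),
               "degenerate")

  # agreement with stats::aov on a regular case
  set.seed(3)
  g <- list(a = rnorm(8), b = rnorm(8, 1), c = rnorm(8, 2))
  res <- group_contrast(g)
  df <- data.frame(v = unlist(g), grp = rep(names(g), each = 8))
  ref <- summary(stats::aov(v ~ grp, df))[[1]]
  expect_equal(res$f_statistic, ref[["F value"]][1])
  expect_equal(res$p_value, ref[["Pr(>F)"]][1])
})
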