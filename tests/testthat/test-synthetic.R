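test_that("label-map generation is deterministic and respects zero rates", {
  cfg <- fast_config(seed = 4)
  a <- generate_label_map(cfg, 3)
  b <- generate_label_map(cfg, 3)
  expect_identical(a$map$labels, b$map$labels)
  expect_identical(a$map$cancer_cell_fraction, b$map$cancer_cell_fraction)
  expect_identical(a$border$polygon, b$border$polygon)

  cfg0 <- fast_config(seed = 4, occult_focus_rate = 0)
  m <- generate_label_map(cfg0, 1)$map
  expect_false(any(m$labels == TISSUE_CLASSES[["occult_cancer"]]))

  expect_error(simulation_config(occult_site_prob = 1.4), "parameter error")
  expect_error(simulation_config(g_low = 0), "parameter error")
})

test_that("label maps satisfy their structural invariants", {
  cfg <- fast_config(seed = 9)
  for (i in 0:4) {
    lm <- generate_label_map(cfg, i)
    lb <- lm$map$labels
    frac <- lm$map$cancer_cell_fraction
    expect_true(all(lb %in% TISSUE_CLASSES))
    cancer <- lb %in% TISSUE_CLASSES[c("tumor", "occult_cancer",
                                       "benign_proliferative")]
    expect_true(all(frac[!cancer] == 0))
    expect_true(all(frac[cancer] > 0 & frac[cancer] <= 1))
    expect_true(any(lb == TISSUE_CLASSES[["scale_marker"]]))
    # the demarcated border encloses tumor pixels
    if (lm$border$defined) {
      inside <- fluormargin:::.polygon_mask(lm$border$polygon,
                                            nrow(lb), ncol(lb))
      expect_gt(sum(inside & lb == TISSUE_CLASSES[["tumor"]]), 0)
      # occult foci lie strictly outside the border
      expect_equal(sum(inside & lb == TISSUE_CLASSES[["occult_cancer"]]), 0)
    }
  }
})

test_that("occult focus counts follow the configured Poisson rate", {
  cfg <- fast_config(seed = 12)
  counts <- vapply(0:99, function(i) {
    NROW(attr(generate_label_map(cfg, i)$map, "occult_centers"))
  }, 1L)
  se <- sqrt(cfg$occult_focus_rate / 100)
  expect_lt(abs(mean(counts) - cfg$occult_focus_rate), 3 * se)
})

test_that("tissue emission spectra peak in the documented bands", {
  argmax <- function(s) s$wavelength_nm[which.max(s$intensity)]

  # no 5-ALA: autofluorescence only, greenish peak
  s <- tissue_emission_spectrum("tumor", 1, 0)
  expect_true(argmax(s) >= 500 && argmax(s) <= 570)

  # PpIX-dominated tumor: 635 nm
  s <- tissue_emission_spectrum("tumor", 1, 1)
  expect_equal(argmax(s), 635, tolerance = 2)

  # connective autofluorescence: 520 nm regardless of dose
  for (g in c(0, 1)) {
    s <- tissue_emission_spectrum("connective", 0, g)
    expect_equal(argmax(s), 520, tolerance = 2)
  }

  expect_error(tissue_emission_spectrum("bone", 0, 1), "unknown tissue")
})

test_that("rendering is deterministic and monotone in PpIX gain", {
  cfg0 <- fast_config(seed = 6, noise_sd = 0)
  lm <- generate_label_map(cfg0, 0)
  img1 <- render_fluorescence_image(lm$map, cfg0)
  img2 <- render_fluorescence_image(lm$map, cfg0)
  expect_identical(img1$rgb, img2$rgb)

  # red/green channel ratio in the tumor increases with PpIX gain
  cfg_hi <- fast_config(seed = 6, noise_sd = 0, dose_group = "high")
  cfg_ctl <- fast_config(seed = 6, noise_sd = 0, dose_group = "control")
  tum <- lm$map$labels == TISSUE_CLASSES[["tumor"]]
  rg <- function(img) {
    mean(img$rgb[, , 1][tum]) / mean(img$rgb[, , 2][tum])
  }
  expect_gt(rg(render_fluorescence_image(lm$map, cfg_hi)),
            rg(render_fluorescence_image(lm$map, cfg_ctl)))
})

test_that("rendered chromaticity separates tumor from connective tissue", {
  cfg <- fast_config(seed = 15, dose_group = "high")
  lm <- generate_label_map(cfg, 4)
  img <- render_fluorescence_image(lm$map, cfg)
  raster <- decode_srgb_to_xyz(img)
  med_xy <- function(mask) {
    s <- raster$X[mask] + raster$Y[mask] + raster$Z[mask]
    keep <- s > 0  # fully dark pixels carry no chromaticity
    c(median(raster$X[mask][keep] / s[keep]),
      median(raster$Y[mask][keep] / s[keep]))
  }
  tum <- lm$map$labels == TISSUE_CLASSES[["tumor"]] &
    lm$map$cancer_cell_fraction > 0.2
  conn <- lm$map$labels == TISSUE_CLASSES[["connective"]]
  dw_t <- dominant_wavelength(med_xy(tum))
  dw_c <- dominant_wavelength(med_xy(conn))
  expect_gte(dw_t$dominant_wavelength_nm, 600)  # red band
  expect_true(dw_c$dominant_wavelength_nm >= 490 &&
                dw_c$dominant_wavelength_nm < 570)  # green band
})

test_that("biopsy sampling respects the punch-biopsy protocol", {
  cfg <- fast_config(seed = 8)
  for (i in 0:9) {
    lm <- generate_label_map(cfg, i)
    b <- sample_biopsies(lm$map, lm$border, cfg)
    expect_gte(nrow(b), 1)
    expect_lte(nrow(b), 4)
    expect_equal(sum(b$stratum == "inside"), 1)
    expect_true(all(b$punch_mm %in% c(2, 4)))
    # discs do not overlap
    if (nrow(b) > 1) {
      d <- as.matrix(dist(b[, c("row", "col")]))
      rad <- b$punch_mm / 2 / lm$map$pixel_size_mm
      pairs <- which(upper.tri(d), arr.ind = TRUE)
      expect_true(all(d[pairs] > rad[pairs[, 1]] + rad[pairs[, 2]]))
    }
    # ground truth: positive iff cancer pixels inside the disc
    for (j in seq_len(nrow(b))) {
      idx <- fluormargin:::.disc_index(
        b$row[j], b$col[j], b$punch_mm[j] / 2 / lm$map$pixel_size_mm,
        nrow(lm$map$labels), ncol(lm$map$labels))
      has_cancer <- any(lm$map$labels[idx] %in%
                          TISSUE_CLASSES[c("tumor", "occult_cancer")])
      expect_identical(b$histology[j] == "pos", has_cancer)
    }
  }
})

test_that("a punch disc fully in adipose tissue is cancer-negative", {
  nr <- nc <- 60L
  labels <- matrix(TISSUE_CLASSES[["adipose"]], nr, nc)
  map <- tissue_label_map(labels, 0.5, matrix(0, nr, nc))
  cfg <- fast_config(seed = 2)
  set.seed(1)
  b <- sample_biopsies(map, tumor_border(matrix(numeric(0), ncol = 2),
                                         defined = FALSE), cfg)
  expect_true(all(b$histology == "neg"))
  expect_true(all(b$stratum == "outside"))

  tiny <- tissue_label_map(matrix(TISSUE_CLASSES[["adipose"]], 10, 10),
                           0.5, matrix(0, 10, 10))
  expect_error(sample_biopsies(tiny, tumor_border(matrix(numeric(0),
                                                         ncol = 2), FALSE),
                               cfg),
               "placement error")
})

test_that("outside-border cancer prevalence matches the configured level", {
  cfg <- fast_config(seed = 5)
  pos <- 0; tot <- 0
  for (i in 0:199) {
    lm <- generate_label_map(cfg, i)
    b <- sample_biopsies(lm$map, lm$border, cfg)
    o <- b[b$stratum == "outside", ]
    tot <- tot + nrow(o)
    pos <- pos + sum(o$histology == "pos")
  }
  ci <- clopper_pearson(pos, tot)
  expected <- expected_occult_prevalence(cfg)
  expect_gte(expected, ci$lower)
  expect_lte(expected, ci$upper)
})

test_that("point spectra mix disc tissue and honor the noise model", {
  cfg <- fast_config(seed = 10, noise_sd = 0, dose_group = "high")
  lm <- generate_label_map(cfg, 0)
  b <- sample_biopsies(lm$map, lm$border, cfg)
  site <- b[b$stratum == "inside", ][1, ]
  s1 <- generate_point_spectrum(site, lm$map, cfg)
  s2 <- generate_point_spectrum(site, lm$map, cfg)
  expect_identical(s1$intensity, s2$intensity)  # noiseless is exact

  # control dose: no PpIX peak at the same site
  cfg_ctl <- fast_config(seed = 10, noise_sd = 0, dose_group = "control")
  s0 <- generate_point_spectrum(site, lm$map, cfg_ctl)
  expect_false(detect_ppix_peak(s0)$present)
})
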