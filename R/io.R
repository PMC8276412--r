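# Plain-format I/O: biopsy tables (CSV), label maps (PNG + JSON legend),
# border polygons (JSON), spectra (CSV), simulation configs (YAML), and
# the pipeline JSON report.

#' Read and validate a biopsy record table
#'
#' Expects a CSV with header columns `specimen_id`, `site_id`, `row`,
#' `col`, `punch_mm`, `stratum`, `histology` (optional: `proliferative`,
#' `dose_group`, `red_positive`, `category`). Strata and histology codes
#' are case-insensitive and restricted to `inside`/`outside` and
#' `pos`/`neg`.
#'
#' @param path CSV path.
#' @return validated data frame of biopsy records.
#' @export
read_biopsy_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("specimen_id", "site_id", "row", "col", "punch_mm",
                "stratum", "histology")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("load error: missing column(s): ", paste(missing, collapse = ", "))
  }
  df$stratum <- tolower(trimws(df$stratum))
  df$histology <- tolower(trimws(df$histology))
  bad <- which(!df$stratum %in% c("inside", "outside"))
  if (length(bad)) {
    stop("load error: row ", bad[1], ": unknown stratum '",
         df$stratum[bad[1]], "'")
  }
  bad <- which(!df$histology %in% c("pos", "neg"))
  if (length(bad)) {
    stop("load error: row ", bad[1], ": unknown histology '",
         df$histology[bad[1]], "'")
  }
  key <- paste(df$specimen_id, df$site_id)
  if (anyDuplicated(key)) {
    stop("load error: duplicate (specimen_id, site_id) at row ",
         which(duplicated(key))[1])
  }
  if (!all(df$punch_mm %in% c(2, 4))) {
    stop("load error: punch_mm must be 2 or 4")
  }
  df
}

#' Write a specimen image as lossless 8-bit PNG
#'
#' @param image a [specimen_image].
#' @param path output path.
#' @export
write_specimen_image <- function(image, path) {
  png::writePNG(image$rgb / 255, path)
  invisible(path)
}

#' Read a specimen image from PNG/JPEG-decoded RGB array
#'
#' @param path PNG path.
#' @param pixel_size_mm pixel size metadata to attach.
#' @param dose_group dose group metadata to attach.
#' @return a [specimen_image].
#' @export
read_specimen_image <- function(path, pixel_size_mm, dose_group = NA) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 2) arr <- array(rep(arr, 3), c(dim(arr), 3))
  specimen_image(array(as.integer(round(255 * arr[, , 1:3])),
                       c(dim(arr)[1:2], 3)),
                 pixel_size_mm, dose_group)
}

#' Write a tissue label map (single-channel PNG plus JSON legend)
#'
#' @param map a [tissue_label_map].
#' @param png_path class-code raster output path.
#' @param legend_path JSON legend output path (class code -> name, plus
#'   pixel size).
#' @export
write_label_map <- function(map, png_path, legend_path) {
  png::writePNG(map$labels / 255, png_path)
  jsonlite::write_json(
    list(classes = as.list(TISSUE_CLASSES),
         pixel_size_mm = map$pixel_size_mm),
    legend_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(png_path)
}

#' Write a border polygon as a JSON list of (row, col) vertices
#'
#' @param border a [tumor_border].
#' @param path JSON path.
#' @export
write_border <- function(border, path) {
  jsonlite::write_json(
    list(defined = border$defined,
         polygon = unname(apply(border$polygon, 1, as.list))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write spectra to CSV (long format)
#'
#' @param spectra named list of [emission_spectrum] objects.
#' @param path CSV path with columns `site_id`, `wavelength_nm`,
#'   `intensity`.
#' @export
write_spectra_csv <- function(spectra, path) {
  rows <- lapply(names(spectra), function(id) {
    data.frame(site_id = id,
               wavelength_nm = spectra[[id]]$wavelength_nm,
               intensity = spectra[[id]]$intensity)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read spectra from a long-format CSV
#'
#' @param path CSV with `site_id`, `wavelength_nm`, `intensity`.
#' @return named list of [emission_spectrum] objects.
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("site_id", "wavelength_nm", "intensity") %in% names(df)))
  out <- lapply(split(df, df$site_id), function(d) {
    d <- d[order(d$wavelength_nm), ]
    emission_spectrum(d$wavelength_nm, pmax(d$intensity, 0))
  })
  out
}

#' Load a simulation configuration from YAML
#'
#' Unknown fields are rejected; missing fields fall back to the
#' [simulation_config()] defaults.
#'
#' @param path YAML file.
#' @return a [simulation_config].
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(simulation_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown)) {
    stop("load error: unknown config field(s): ",
         paste(unknown, collapse = ", "))
  }
  do.call(simulation_config, y)
}

#' Write the pipeline report as a single JSON document
#'
#' The report carries a schema version, the seed and a config echo plus all
#' stage results; writing the same inputs twice yields byte-identical
#' files.
#'
#' @param summaries a `study_summary` (or NULL).
#' @param contrasts group-contrast results (or NULL).
#' @param peaks per-site peak-detection results (or NULL).
#' @param compositions per-biopsy composition table (or NULL).
#' @param path output path.
#' @param config config echo (list), optional.
#' @param seed seed echo, optional.
#' @param log character vector of exclusion/log messages.
#' @return the report list, invisibly.
#' @export
write_report <- function(summaries = NULL, contrasts = NULL, peaks = NULL,
                         compositions = NULL, path, config = NULL,
                         seed = NULL, log = character(0)) {
  strip <- function(x) {
    if (inherits(x, "data.frame")) return(x)
    if (is.list(x)) {
      x <- unclass(x)
      return(lapply(x, strip))
    }
    x
  }
  report <- list(schema_version = "1.0",
                 seed = seed,
                 config = strip(config),
                 log = as.list(log),
                 diagnostics = strip(summaries),
                 contrasts = strip(contrasts),
                 peaks = strip(peaks),
                 compositions = compositions)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(report)
}
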