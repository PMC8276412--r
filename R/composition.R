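# Per-biopsy tissue-area fractions and the carcinoma-to-connective ratio,
# compared between red- and green-classified biopsies.

#' Tissue-area fractions within a punch-biopsy disc
#'
#' Percentages are computed over tissue pixels only (background and scale
#' marker excluded). Carcinoma area is the sum of the per-pixel carcinoma
#' cell fraction over cancer-class pixels; connective area is pure
#' connective pixels plus the stromal share of cancer pixels. For label
#' maps whose cancer pixels carry fraction 1 this reduces to plain pixel
#' counting.
#'
#' @param map a [tissue_label_map].
#' @param row,col disc center (pixels).
#' @param punch_mm punch diameter in mm.
#' @return object of class `composition_record`: `pct_cancer`,
#'   `pct_connective`, `pct_adipose`, `ratio_cancer_connective` (NA,
#'   flagged, when there is no connective area), `tissue_pixels`.
#' @export
area_fractions <- function(map, row, col, punch_mm) {
  stopifnot(inherits(map, "tissue_label_map"))
  idx <- .disc_index(row, col,
                     .punch_radius_px(punch_mm, map$pixel_size_mm),
                     nrow(map$labels), ncol(map$labels))
  lb <- map$labels[idx]
  ccf <- map$cancer_cell_fraction[idx]
  tissue <- lb != TISSUE_CLASSES[["background"]] &
    lb != TISSUE_CLASSES[["scale_marker"]]
  n_tissue <- sum(tissue)
  if (n_tissue == 0) stop("validation error: disc contains no tissue")
  cancer_px <- lb %in% TISSUE_CLASSES[.CANCER_CLASSES]
  carcinoma <- lb == TISSUE_CLASSES[["tumor"]] |
    lb == TISSUE_CLASSES[["occult_cancer"]]
  cancer_area <- sum(ccf[carcinoma])
  conn_area <- sum(lb == TISSUE_CLASSES[["connective"]]) +
    sum(.STROMA_SHARE * (1 - ccf[cancer_px]))
  adip_area <- sum(lb == TISSUE_CLASSES[["adipose"]])
  ratio <- if (conn_area == 0) {
    if (cancer_area == 0) 0 else NA_real_
  } else {
    cancer_area / conn_area
  }
  structure(list(pct_cancer = 100 * cancer_area / n_tissue,
                 pct_connective = 100 * conn_area / n_tissue,
                 pct_adipose = 100 * adip_area / n_tissue,
                 ratio_cancer_connective = ratio,
                 ratio_undefined = conn_area == 0 && cancer_area > 0,
                 tissue_pixels = n_tissue),
            class = "composition_record")
}

#' Composition of every biopsy in a record table
#'
#' @param map a [tissue_label_map].
#' @param records biopsy records with `row`, `col`, `punch_mm`.
#' @return `records` with appended composition columns.
#' @export
biopsy_composition <- function(map, records) {
  comp <- lapply(seq_len(nrow(records)), function(i) {
    area_fractions(map, records$row[i], records$col[i],
                   records$punch_mm[i])
  })
  records$pct_cancer <- vapply(comp, `[[`, 1, "pct_cancer")
  records$pct_connective <- vapply(comp, `[[`, 1, "pct_connective")
  records$pct_adipose <- vapply(comp, `[[`, 1, "pct_adipose")
  records$ratio_cancer_connective <-
    vapply(comp, `[[`, 1, "ratio_cancer_connective")
  records
}

#' Mann-Whitney comparison of composition measures between two groups
#'
#' Wilcoxon rank-sum (Mann-Whitney U) test, exact when the combined sample
#' size is at most 20 and there are no ties, otherwise the normal
#' approximation with tie correction (and continuity correction).
#'
#' @param group_a,group_b numeric vectors (each non-empty).
#' @return list with `U` (the U statistic of `group_a`), `p_value`, and
#'   `exact` (whether the exact null distribution was used).
#' @export
compare_composition <- function(group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop("validation error: both groups must be non-empty")
  }
  ties <- any(duplicated(c(group_a, group_b)))
  exact <- (length(group_a) + length(group_b) <= 20) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = exact, correct = !exact))
  list(U = unname(wt$statistic), p_value = wt$p.value, exact = exact)
}
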