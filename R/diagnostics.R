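# Stratified diagnostic accuracy: 2x2 tables from biopsy records, PPV /
# NPV / sensitivity / specificity with Clopper-Pearson exact confidence
# intervals, and the diagnostic odds ratio with a log-scale
# normal-approximation interval.

#' Contingency table constructor
#'
#' @param tp,fp,fn,tn non-negative integer cell counts. True positive =
#'   red-fluorescence biopsy, histology cancer-positive; false positive =
#'   red, cancer-negative; false negative = non-red, cancer-positive; true
#'   negative = non-red, cancer-negative.
#' @param stratum `"inside"`, `"outside"` or `"overall"` (biopsy location
#'   relative to the demarcated tumor border).
#' @param dose_group `"low"`, `"high"` or `"control"`.
#' @return object of class `contingency_table`.
#' @export
contingency_table <- function(tp, fp, fn, tn,
                              stratum = c("overall", "inside", "outside"),
                              dose_group = NA_character_) {
  stratum <- match.arg(stratum)
  counts <- c(tp, fp, fn, tn)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  structure(list(TP = as.integer(tp), FP = as.integer(fp),
                 FN = as.integer(fn), TN = as.integer(tn),
                 stratum = stratum, dose_group = dose_group),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("2x2 table (%s, %s): TP=%d FP=%d FN=%d TN=%d\n",
              x$dose_group, x$stratum, x$TP, x$FP, x$FN, x$TN))
  invisible(x)
}

#' Build a contingency table from classified biopsy records
#'
#' @param records data frame with a logical `red_positive` call and a
#'   `histology` label (`"pos"`/`"neg"`) per biopsy; an empty data frame
#'   yields an all-zero table.
#' @param stratum,dose_group labels attached to the table (counts are taken
#'   from `records` as given; subset before calling to stratify).
#' @return a [contingency_table].
#' @export
build_contingency <- function(records, stratum = "overall",
                              dose_group = NA_character_) {
  if (nrow(records) == 0) {
    return(contingency_table(0, 0, 0, 0, stratum, dose_group))
  }
  need <- c("red_positive", "histology")
  for (col in need) {
    bad <- which(is.na(records[[col]]))
    if (is.null(records[[col]]) || length(bad)) {
      stop("validation error: record ", if (length(bad)) bad[1] else "",
           " is missing '", col, "'")
    }
  }
  if (!all(records$histology %in% c("pos", "neg"))) {
    stop("validation error: histology must be 'pos' or 'neg'")
  }
  red <- as.logical(records$red_positive)
  pos <- records$histology == "pos"
  contingency_table(sum(red & pos), sum(red & !pos),
                    sum(!red & pos), sum(!red & !pos),
                    stratum, dose_group)
}

#' Pool contingency tables cellwise
#'
#' @param ... `contingency_table`s (e.g. inside + outside of one dose
#'   group).
#' @param stratum,dose_group labels of the pooled table.
#' @return a [contingency_table].
#' @export
pool_tables <- function(..., stratum = "overall",
                        dose_group = NA_character_) {
  ts <- list(...)
  stopifnot(all(vapply(ts, inherits, TRUE, "contingency_table")))
  contingency_table(sum(vapply(ts, `[[`, 1L, "TP")),
                    sum(vapply(ts, `[[`, 1L, "FP")),
                    sum(vapply(ts, `[[`, 1L, "FN")),
                    sum(vapply(ts, `[[`, 1L, "TN")),
                    stratum, dose_group)
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' The exact (Pearson-Clopper) interval from Beta-distribution quantiles:
#' lower = `qbeta(alpha/2, x, n - x + 1)` (0 when x = 0), upper =
#' `qbeta(1 - alpha/2, x + 1, n - x)` (1 when x = n). At the degenerate
#' corners this reduces to the closed forms `(alpha/2)^(1/n)` and
#' `1 - (alpha/2)^(1/n)`.
#'
#' @param x number of successes (0 <= x <= n).
#' @param n number of trials; `n = 0` yields an undefined estimate with
#'   bounds (0, 1) and `undefined = TRUE`.
#' @param level confidence level in (0, 1); default 0.95.
#' @return object of class `proportion_ci`: `estimate`, `lower`, `upper`,
#'   `x`, `n`, `level`, `undefined`.
#' @export
#' @examples
#' clopper_pearson(8, 8)   # lower bound 0.025^(1/8) = 0.631
clopper_pearson <- function(x, n, level = 0.95) {
  stopifnot(level > 0, level < 1, x >= 0, n >= 0, x <= n,
            x == round(x), n == round(n))
  if (n == 0) {
    out <- list(estimate = NA_real_, lower = 0, upper = 1,
                x = 0L, n = 0L, level = level, undefined = TRUE)
  } else {
    a <- 1 - level
    out <- list(
      estimate = x / n,
      lower = if (x == 0) 0 else stats::qbeta(a / 2, x, n - x + 1),
      upper = if (x == n) 1 else stats::qbeta(1 - a / 2, x + 1, n - x),
      x = as.integer(x), n = as.integer(n), level = level,
      undefined = FALSE)
  }
  class(out) <- "proportion_ci"
  out
}

#' @export
print.proportion_ci <- function(x, ...) {
  if (x$undefined) {
    cat("proportion: undefined (n = 0)\n")
  } else {
    cat(sprintf("%.1f%% (%.1f - %.1f), x/n = %d/%d, %g%% CI\n",
                100 * x$estimate, 100 * x$lower, 100 * x$upper,
                x$x, x$n, 100 * x$level))
  }
  invisible(x)
}

#' Predictive values with exact confidence intervals
#'
#' PPV = TP / (TP + FP): probability that cancer is present in a
#' red-fluorescent area. NPV = TN / (TN + FN): probability that cancer is
#' absent from a non-red area. Both are prevalence-dependent.
#'
#' @param t a [contingency_table].
#' @param level confidence level.
#' @return list with `ppv` and `npv`, each a [clopper_pearson()] result
#'   (undefined-flagged when the denominator is 0).
#' @export
predictive_values <- function(t, level = 0.95) {
  stopifnot(inherits(t, "contingency_table"))
  list(ppv = clopper_pearson(t$TP, t$TP + t$FP, level),
       npv = clopper_pearson(t$TN, t$TN + t$FN, level))
}

#' Sensitivity and specificity with exact confidence intervals
#'
#' @param t a [contingency_table].
#' @param level confidence level.
#' @return list with `sensitivity` (TP / (TP + FN)) and `specificity`
#'   (TN / (TN + FP)).
#' @export
sensitivity_specificity <- function(t, level = 0.95) {
  stopifnot(inherits(t, "contingency_table"))
  list(sensitivity = clopper_pearson(t$TP, t$TP + t$FN, level),
       specificity = clopper_pearson(t$TN, t$TN + t$FP, level))
}

#' Diagnostic odds ratio with log-scale normal-approximation interval
#'
#' DOR = (TP * TN) / (FP * FN): the odds of red PpIX fluorescence when
#' cancer is present relative to the odds when it is absent. The confidence
#' interval is `exp(log(DOR) +/- z * sqrt(1/TP + 1/FP + 1/FN + 1/TN))`. If
#' any cell is zero the DOR is reported not-applicable (matching the
#' published convention); an optional Haldane correction adds 0.5 to every
#' cell instead.
#'
#' @param t a [contingency_table].
#' @param level confidence level.
#' @param haldane apply the 0.5 continuity correction to zero-cell tables
#'   (default FALSE: such tables are flagged not-applicable).
#' @return list with `applicable`, `dor`, `ci` (`c(lower, upper)`), and
#'   `reason` when not applicable.
#' @export
diagnostic_odds_ratio <- function(t, level = 0.95, haldane = FALSE) {
  stopifnot(inherits(t, "contingency_table"))
  cells <- c(t$TP, t$FP, t$FN, t$TN)
  if (any(cells == 0)) {
    if (!haldane) {
      return(list(applicable = FALSE, dor = NA_real_,
                  ci = c(NA_real_, NA_real_),
                  reason = "zero cell in 2x2 table"))
    }
    cells <- cells + 0.5
  }
  dor <- cells[1] * cells[4] / (cells[2] * cells[3])
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(sum(1 / cells))
  list(applicable = TRUE, dor = dor,
       ci = exp(log(dor) + c(-1, 1) * z * se), reason = NA_character_)
}

#' Reclassify proliferative false positives as abnormal-tissue detections
#'
#' Benign proliferative changes (hyperplasia, sclerosing adenosis, ...)
#' light up with PpIX; counting their detection as a desirable outcome
#' moves those biopsies from FP to TP, raising the PPV for "abnormal"
#' (malignant plus proliferative) tissue.
#'
#' @param t a [contingency_table].
#' @param n_proliferative_fp number of false positives with proliferative
#'   histology (0 <= n <= FP).
#' @return a [contingency_table] with `TP + n` and `FP - n`.
#' @export
reclassify_abnormal <- function(t, n_proliferative_fp) {
  stopifnot(inherits(t, "contingency_table"))
  if (n_proliferative_fp < 0 || n_proliferative_fp > t$FP) {
    stop("validation error: n_proliferative_fp must lie in [0, FP]")
  }
  contingency_table(t$TP + n_proliferative_fp, t$FP - n_proliferative_fp,
                    t$FN, t$TN, t$stratum, t$dose_group)
}

#' Full diagnostic summary of one stratum table
#'
#' Applies the study's reporting rules: NPV is suppressed for the
#' inside-border stratum (its denominator is dominated by near-zero
#' prevalence of normal tissue there), specificity is suppressed when
#' TN + FP = 0, and the DOR is suppressed for zero-cell tables.
#'
#' @param t a [contingency_table].
#' @param level confidence level.
#' @return object of class `diagnostic_summary` with fields `table`, `ppv`,
#'   `npv`, `sensitivity`, `specificity`, `dor`, and `suppressed` (named
#'   character vector of suppression reasons).
#' @export
diagnostic_summary <- function(t, level = 0.95) {
  pv <- predictive_values(t, level)
  ss <- sensitivity_specificity(t, level)
  dor <- diagnostic_odds_ratio(t, level)
  suppressed <- character(0)
  if (identical(t$stratum, "inside")) {
    pv$npv <- NULL
    suppressed["npv"] <-
      "NPV not reported inside the tumor border (near-zero prevalence of normal tissue)"
  } else if (pv$npv$undefined) {
    suppressed["npv"] <- "no fluorescence-negative biopsies"
  }
  if (pv$ppv$undefined) {
    suppressed["ppv"] <- "no fluorescence-positive biopsies"
  }
  if (t$TN + t$FP == 0) {
    suppressed["specificity"] <- "no cancer-negative biopsies in stratum"
  }
  if (!dor$applicable) suppressed["dor"] <- dor$reason
  structure(list(table = t, ppv = pv$ppv, npv = pv$npv,
                 sensitivity = ss$sensitivity,
                 specificity = ss$specificity,
                 dor = dor, suppressed = suppressed, level = level),
            class = "diagnostic_summary")
}

#' @export
print.diagnostic_summary <- function(x, ...) {
  t <- x$table
  cat(sprintf("Diagnostic accuracy (%s dose, %s): TP=%d FP=%d FN=%d TN=%d\n",
              t$dose_group, t$stratum, t$TP, t$FP, t$FN, t$TN))
  show <- function(name, ci) {
    if (is.null(ci) || !is.null(x$suppressed[name]) &&
          !is.na(x$suppressed[name])) {
      cat(sprintf("  %-12s N/A (%s)\n", name,
                  x$suppressed[[name]] %||% "suppressed"))
    } else {
      cat(sprintf("  %-12s %5.1f%% (%.1f - %.1f)\n", name,
                  round_half_away(100 * ci$estimate),
                  round_half_away(100 * ci$lower),
                  round_half_away(100 * ci$upper)))
    }
  }
  show("PPV", x$ppv)
  show("NPV", x$npv)
  show("sensitivity", x$sensitivity)
  show("specificity", x$specificity)
  if (x$dor$applicable) {
    cat(sprintf("  %-12s %.1f (%.2f - %.2f)\n", "DOR",
                round_half_away(x$dor$dor),
                round_half_away(x$dor$ci[1], 2),
                round_half_away(x$dor$ci[2], 2)))
  } else {
    cat(sprintf("  %-12s N/A (%s)\n", "DOR", x$dor$reason))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Stratified study summary from classified biopsy records
#'
#' Builds the six dose-by-stratum tables (low/high x inside/outside/
#' overall), applies [diagnostic_summary()] reporting rules to each, and
#' excludes the control group from accuracy reporting with a logged reason
#' (essentially all control biopsies are classified -RedFL, so accuracy
#' measures are uninformative there).
#'
#' @param records data frame with columns `dose_group`, `stratum`,
#'   `red_positive`, `histology`.
#' @param level confidence level.
#' @return object of class `study_summary`: list with `summaries` (named
#'   list, `<dose>_<stratum>`), and `log` (character vector of exclusions).
#' @export
summarize_study <- function(records, level = 0.95) {
  stopifnot(all(c("dose_group", "stratum", "red_positive", "histology")
                %in% names(records)))
  log <- character(0)
  n_control <- sum(records$dose_group == "control")
  if (n_control > 0) {
    log <- c(log, sprintf(
      "control group excluded from accuracy reporting (%d biopsies, -RedFL by design: no 5-ALA, no PpIX contrast)",
      n_control))
  }
  summaries <- list()
  for (dose in intersect(c("low", "high"), unique(records$dose_group))) {
    sub <- records[records$dose_group == dose, , drop = FALSE]
    tabs <- list()
    for (str in intersect(c("inside", "outside"), unique(sub$stratum))) {
      tabs[[str]] <- build_contingency(sub[sub$stratum == str, ,
                                           drop = FALSE], str, dose)
      summaries[[paste(dose, str, sep = "_")]] <-
        diagnostic_summary(tabs[[str]], level)
    }
    if (length(tabs) > 0) {
      overall <- do.call(pool_tables,
                         c(unname(tabs),
                           list(stratum = "overall", dose_group = dose)))
      summaries[[paste(dose, "overall", sep = "_")]] <-
        diagnostic_summary(overall, level)
    }
  }
  structure(list(summaries = summaries, log = log),
            class = "study_summary")
}

#' Round half away from zero
#'
#' Decimal rounding matching the convention used for the printed accuracy
#' tables (e.g. a DOR of 26.25 prints as 26.3), unlike base `round()`'s
#' round-half-to-even.
#'
#' @param x numeric.
#' @param digits decimal places (default 1).
#' @return rounded numeric.
#' @export
round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Contingency counts of the source phase II trial
#'
#' The punch-biopsy 2x2 counts, by 5-ALA dose arm (15 and 30 mg/kg) and
#' biopsy location relative to the grossly demarcated tumor border, from
#' the phase II randomized trial of handheld PpIX fluorescence imaging in
#' breast-conserving surgery that this package models. These printed counts
#' are the input from which all published accuracy measures are recomputed.
#'
#' @return data frame with columns `dose_group`, `stratum`, `TP`, `FP`,
#'   `FN`, `TN`, plus `proliferative_fp`: the dose-arm split (3 low / 2
#'   high) of the five false positives with benign proliferative histology,
#'   inferred from the published abnormal-tissue PPVs of 89% and 70%.
#' @export
ala_study_counts <- function() {
  data.frame(
    dose_group = c("low", "low", "high", "high"),
    stratum = c("inside", "outside", "inside", "outside"),
    TP = c(8L, 5L, 10L, 5L),
    FP = c(0L, 4L, 0L, 5L),
    FN = c(6L, 1L, 5L, 2L),
    TN = c(1L, 21L, 0L, 20L),
    proliferative_fp = c(0L, 3L, 0L, 2L))
}

#' Expand stratified counts into per-biopsy records
#'
#' Utility to turn 2x2 counts into the record format consumed by
#' [summarize_study()] (one row per biopsy).
#'
#' @param counts data frame like [ala_study_counts()].
#' @return biopsy record data frame.
#' @export
counts_to_records <- function(counts) {
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    ct <- counts[i, ]
    n <- c(ct$TP, ct$FP, ct$FN, ct$TN)
    data.frame(
      dose_group = rep(ct$dose_group, sum(n)),
      stratum = rep(ct$stratum, sum(n)),
      red_positive = rep(c(TRUE, TRUE, FALSE, FALSE), n),
      histology = rep(c("pos", "neg", "pos", "neg"), n))
  })
  do.call(rbind, rows)
}
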