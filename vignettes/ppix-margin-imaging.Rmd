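---
title: "Methods: PpIX fluorescence margin assessment, from pixels to diagnostic accuracy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PpIX fluorescence margin assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluormargin)
```

## The problem

In breast-conserving surgery the excised specimen is examined grossly, but
carcinoma at or near the cut surface is hard to see under white light.
Orally administered 5-aminolevulinic acid (5-ALA) leads cancer cells to
accumulate protoporphyrin IX (PpIX), which fluoresces red (peak emission
near 635 nm) under ~405 nm excitation, while healthy connective tissue
autofluoresces green and adipose tissue a dull pink/brown. A handheld
camera imaging the sliced specimen therefore shows the tumor as a bright
red region against green/pink background — when it works. The interesting
questions are quantitative: how well does "red" predict cancer inside and
outside the grossly demarcated tumor border, and what makes a cancerous
area fail to appear red?

`fluormargin` implements the complete analysis chain for this setting:

1. **Synthetic specimen generation** — tissue label maps with ground
   truth, spectrally rendered RGB images, punch-biopsy sampling, and
   fiberoptic point spectra.
2. **Colorimetry** — sRGB decoding to CIE XYZ and the tumor-to-normal
   chromaticity contrast statistic.
3. **Color classification** — a deterministic red / green / pink-brown
   rule standing in for the study team's visual call.
4. **Diagnostic accuracy** — stratified 2x2 tables, Clopper-Pearson exact
   intervals, and the diagnostic odds ratio with a log-scale interval.
5. **Spectra** — Savitzky-Golay smoothing and 635 nm peak detection.
6. **Composition** — carcinoma/connective/adipose area fractions and the
   carcinoma-to-connective ratio that explains masking false negatives.

## Diagnostic accuracy model

Each punch biopsy carries a binary imaging call (+RedFL / −RedFL) and a
blinded histology label (cancer-positive iff invasive or in situ disease).
Counts are tabulated per dose arm and per location stratum (inside vs
outside the demarcated border), because predictive values are
prevalence-dependent and prevalence differs sharply between strata:

* PPV = TP/(TP+FP), NPV = TN/(TN+FN), sensitivity = TP/(TP+FN),
  specificity = TN/(TN+FP), each with the exact (Clopper-Pearson) interval
  from Beta quantiles: lower = `qbeta(α/2, x, n−x+1)`, upper =
  `qbeta(1−α/2, x+1, n−x)`, with the closed-form corners `(α/2)^(1/n)` at
  x = n and `1 − (α/2)^(1/n)` at x = 0.
* DOR = (TP·TN)/(FP·FN) with
  CI = exp(log DOR ± z·sqrt(1/TP + 1/FP + 1/FN + 1/TN)); z is the exact
  normal quantile (1.959964), not 1.96.

Reporting rules mirror clinical practice for this design: NPV is never
reported inside the border (normal tissue is nearly absent there, so its
denominator is uninformative); any zero cell makes the DOR not-applicable
(a Haldane +0.5 correction is available behind an explicit flag, off by
default); specificity is suppressed when no cancer-negative biopsy exists
in a stratum; the no-5-ALA control arm is excluded from accuracy reporting
with a logged reason, since essentially every control biopsy is −RedFL.
Percentages are rounded half-away-from-zero to one decimal for display, so
e.g. a DOR of 26.25 prints as 26.3; all computations keep full precision.

`ala_study_counts()` ships the source trial's printed 2x2 counts as data.
Two published numbers are *not* reproducible from those counts and the
stated methods, and this package deliberately reports the count-derived
values instead: the low-dose pooled DOR (printed 13.6; the printed counts
give 10.2) and the high-dose inside PPV lower bound (printed 73.5%; TP=10
of n=10 gives 0.025^(1/10) = 69.2%, while 73.5% corresponds to n = 12).
The per-dose split (3 vs 2) of the five proliferative false positives used
by `reclassify_abnormal()` is inferred from the published abnormal-tissue
PPVs of 89% and 70%; it is not printed anywhere.

## Colorimetry

Images decode as standard sRGB: channel/255, the IEC 61966-2-1 inverse
transfer, then the sRGB-primaries/D65 matrix, scaled so white has Y = 1.
The camera is consumer-grade and the upstream analysis used a stock
RGB→XYZ conversion, so the sRGB assumption is the only self-consistent
choice. The tumor-to-normal contrast for one image is computed by
averaging X, Y, Z over each ROI *first* and projecting to chromaticity
second (a luminance-weighted chromaticity — the order matters and is
fixed), then taking the Euclidean distance between the two (x, y) points.
Distances can be re-expressed in just-noticeable-difference units by
dividing by a configurable MacAdam-style scalar (default 0.004); this is
reporting-only. Group comparison uses one-way ANOVA with Tukey HSD.
Specimens whose gross tumor border was ill-defined have no tumor ROI and
are excluded from contrast analysis with a logged reason.

Degenerate ANOVA inputs are handled explicitly: if all values are
identical the analysis errors; if groups differ but residual variance is
exactly zero, F is infinite and Tukey p-values degenerate to 0 for
unequal and 1 for equal group means.

The CIE 1931 2° color-matching functions are evaluated with the
piecewise-Gaussian analytic fit of Wyman, Sloan and Shirley (2013),
accurate to about 1%, which keeps the package free of embedded data
tables; the spectral locus for dominant-wavelength computation is built
from the same functions on a 1 nm grid over 420–700 nm.

## The color classification rule

The study categorized focal areas visually. The package replaces this
with a deterministic, intensity-invariant rule in chromaticity space: the
dominant wavelength and excitation purity of the site's median disc
chromaticity are computed by intersecting the ray from D65 through the
sample with the spectral locus. The call is **red** for dominant
wavelength ≥ 600 nm with purity ≥ 0.25, **green** for [490, 570) nm with
purity ≥ 0.25, and **dull pink/brown** otherwise (including low-purity
"dull" colors; purple-region chromaticities, which cannot occur for these
emission spectra but can for arbitrary input images, are flagged and fall
back to pink/brown). Band edges resolve to the longer-wavelength band.
Only "red" maps to +RedFL. The 600 nm red edge and the 0.25 purity floor
are explicit, tunable stand-ins for an unreported visual criterion: 600 nm
sits safely below the sRGB red primary (≈611 nm) that clipped saturated
PpIX renders to, and above the yellow-orange band where attenuated mixed
spectra land. The median (not mean) over disc pixels makes the call robust
to speckle and to a minority of dark or discolored pixels.

## The synthetic specimen generator

No real images or biopsies from the trial are distributable, so the
generator is a first-class, tested module that emulates the study
conditions; every downstream stage runs identically on real inputs in the
same formats.

**Anatomy.** Each specimen slice is a wobbled-ellipse tissue region
(default 110 × 140 pixels at 0.5 mm/pixel, i.e. a 5.5 × 7 cm slice —
a deliberately scaled-down lumpectomy slice that keeps cohort-level
simulations fast) of connective and adipose tissue in roughly equal parts,
a lobulated primary tumor (radius 14–20 px with low-order harmonic
lobulation), Poisson(1.5) grossly occult foci strictly outside the
demarcated border, at least one PpIX-expressing benign proliferative
focus, and a white scale sticker in a corner. The demarcated border is
the tumor outline with 8% clearance and is drawn with probability 0.8
(ill-defined otherwise).

**Sub-pixel tissue composition.** At 0.5 mm pixels carcinoma and stroma
interdigitate below pixel scale, so cancer-class pixels carry a
`cancer_cell_fraction` ∈ [0.1, 0.98]: the carcinoma area share of the
pixel, the remainder being stroma (85% connective by area). A fraction of
cancer foci (default 0.35) is stroma-rich with carcinoma fractions of
0.10–0.14; the rest are carcinoma-dense (0.25–0.90). Composition metrics
(percent cancer, percent connective, carcinoma-to-connective ratio) use
these fractional areas; for masks whose cancer pixels carry fraction 1
they reduce to plain pixel counting.

**Emission model.** Every pixel's spectrum is a non-negative mixture of
four basis spectra on a 500–800 nm grid: the PpIX doublet (Gaussians at
635 nm and, at 0.2 relative amplitude, 705 nm; σ = 12 nm), connective
green autofluorescence (520 nm, σ = 30 nm), a broad low-amplitude adipose
component spanning 500–700 nm, and a flat reflectance term for the scale
sticker. Peak positions are reported in the source literature; the shapes
are modeling choices. The PpIX amplitude is
`K × dose_gain × cancer_cell_fraction` with K = 120: PpIX-laden cancer
cells vastly outshine autofluorescence per unit area, which is what makes
grossly mixed tumor regions appear *homogeneously* bright red — a central
qualitative observation this generator reproduces. The no-5-ALA control
(dose gain 0) leaves cancer pixels with an autofluorescence blend matched
to the connective/adipose mix of normal tissue, reproducing the trial's
finding that control tumors are chromatically indistinguishable from
background (mean contrast distance ≈ 0.01–0.03, versus ≈ 0.2 with 5-ALA).
The two dose arms default to equal PpIX gain (g_low = g_high = 1): the
trial found no significant dose effect, and no quantitative
intensity-vs-dose relationship is available; these are calibration
choices, not facts.

**Masking false negatives.** Bright green connective autofluorescence can
mask PpIX where carcinoma is sparse. The generator operationalizes this
as a local attenuation: within a 9-pixel box, the carcinoma-to-connective
area ratio is computed (fractional areas as above); where it falls below
`masking_ratio_threshold` (default 0.20, the ratio reported for
green-classified cancer biopsies), the PpIX amplitude is multiplied by
`0.03 + 0.97 × 0.1 × (ratio/threshold)^4` — a steep roll-off that renders
sub-threshold cancer non-red while leaving supra-threshold cancer red.
Setting the threshold to 0 disables masking entirely, and in that regime
the generator's configured classification sensitivity and specificity are
both exactly 1 (every cancer disc is carcinoma-majority and every normal
disc is clear of PpIX), which is what the classifier-recovery test
checks. This design separates the two axes cleanly: ground-truth
histology comes from geometry (any cancer pixel in the punch disc),
imaging calls from rendered color.

**Rendering.** XYZ is linear in the spectrum, so each pixel's tristimulus
is a weighted sum of precomputed basis tristimuli; XYZ maps to linear
sRGB, exposure is normalized so the 99th-percentile linear value encodes
to 245, Gaussian sensor noise (sd 0.01 in normalized linear units; a
skipped draw when 0 keeps noiseless rendering bit-deterministic) is added
before gamma encoding and 8-bit quantization. Saturated emission colors
(pure PpIX, pure connective green) lie outside the sRGB gamut and are
clamped channel-wise, exactly as a real camera saturates; chromaticity
round-trip accuracy within 0.01 is therefore asserted only for in-gamut
spectra, and classification thresholds were placed with clamping in mind.
Images are written as lossless PNG rather than the camera's JPEG to avoid
compression confounds; JPEG-decoded arrays are accepted on ingest.

**Biopsy protocol.** One to four punches per specimen (2- or 4-mm,
non-overlapping discs): exactly one inside the border at the densest
carcinoma neighborhood, and 1–3 outside (counts 1/2/3 with probabilities
0.25/0.40/0.35, matching the trial's ≈3 biopsies per specimen). Outside
sites target an unused occult focus with probability 0.26, else a benign
proliferative focus with probability 0.18 (the false-positive rate
substrate), else normal tissue clear of cancer. Because each focus hosts
at most one punch, the expected outside-site cancer prevalence is
E[min(targets, foci)]/E[sites] (`expected_occult_prevalence()`, ≈ 0.19
at defaults, near the trial's ≈ 0.2 outside-border prevalence).

**Determinism.** Each specimen seeds its RNG stream from
`(seed, specimen_index)`; the whole pipeline report is reproducible from
one master seed, and re-running with the same seed yields byte-identical
JSON.

**What the generator does not emulate.** Physically accurate light
transport (no depth-resolved fluorescence, so sub-surface disease
detected through millimetres of tissue is out of scope), camera-specific
spectral response, illumination inhomogeneity, specular highlights, and
the histology-slide appearance underlying real composition measurements
(the published composition percentages derive from machine-classified
slides and serve only as calibration anchors here, never as test
targets). Passing tests therefore demonstrate internal consistency of the
analysis chain and correct statistical behavior under a plausible data
model — not performance on real specimens.

## Spectra

Point spectra are smoothed with a Savitzky-Golay filter (window 15
samples, order 3 — the study reports only that spectra were "smoothed",
so the method is a documented choice; a moving average is available).
Peak detection looks for a local maximum inside 625–645 nm with
topographic prominence ≥ 0.05 intensity units (about five times the
post-smoothing noise floor at the default noise level); the most
prominent qualifying maximum is reported. Spectroscopy is deliberately
more sensitive than the color call: a masked (visually green) cancer site
can still show a small but real 635 nm peak.

## Numerical and interface choices

* Pixel coordinates are (row, col), 1-based in R matrices; polygons share
  the frame; point-in-polygon uses the even-odd rule.
* Mann-Whitney comparisons use the exact null for combined n ≤ 20 without
  ties, otherwise the tie-corrected normal approximation with continuity
  correction.
* CSV for tables (case-insensitive code normalization on load, duplicate
  site detection), YAML for configuration (unknown fields rejected), JSON
  for reports (schema-versioned, byte-stable).
* Cohort sizes in the test suite are chosen to keep statistical power
  high at desk scale: 15 specimens/group across ≥ 10 seeds for the
  contrast ANOVA, ≥ 500 biopsies for classifier recovery, and ≥ 100
  cancer-positive biopsies per color arm over 20 seeds for the
  composition comparison.

## Limitations

The classification thresholds stand in for an unreported visual
criterion; real inter-observer behavior is not modeled. The generator's
effect sizes (PpIX gain, masking attenuation) are calibrated to reproduce
qualitative study findings, so downstream accuracy measures on synthetic
cohorts land near, but not exactly on, the published point estimates.
Per-margin (rather than per-biopsy) accuracy, Bayesian intervals, and
absolute PpIX quantification are out of scope.
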