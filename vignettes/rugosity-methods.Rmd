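---
title: "Quantifying fruit surface rugosity: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fruit surface rugosity: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rugosity)
library(dplyr)
```

## The measurement problem

Rugose (ridged-and-depressed) fruit surfaces, as seen in some pepper
genotypes, are traditionally scored by eye and touch on an ordinal 1–4
scale. That score is cheap but subjective. The quantitative alternative
implemented here works on a longitudinal section cut from the fruit
equator: trace the outer epidermal contour, measure its arc length, and
express the excess of that length over the straight section length as a
percentage — the **rugosity index**

$$ RI(\%) = 100 \cdot \frac{L_\mathrm{epidermis} - L_\mathrm{section}}{L_\mathrm{section}}. $$

A perfectly flat epidermis has $RI = 0$; ridges and depressions make the
traced contour longer than the chord and push $RI$ up. Fruits are then
binned into four ordinal levels at RI boundaries of 1.5, 2.5 and 3.5 %,
and the downstream statistics (ANOVA with Tukey HSD letters, Pearson
correlation panels, fold ratios between extreme levels) relate that level
to texture and cell-wall measurements. A companion set of operationally
defined transcriptome computations (FPKM, fold-change/FDR DEG filtering,
standardized K-means co-expression modules, sample PCA, and
$2^{-\Delta\Delta Ct}$ qPCR quantification) covers the expression side of
such a study.

Everything in this package is exercised on synthetic data with known
ground truth, so every stage has an oracle.

## Contours, arc length and the level scheme

A contour is an ordered open polyline in millimetres (`x_mm`, `y_mm`).
`polyline_length()` sums Euclidean segment lengths in input order — the
digital analogue of reading the traced polyline's length from a CAD
"LIST" query — with no smoothing, so what you measure is exactly the
polyline you supply. `slice_ri()` divides by a section length that is
either the nominal excision length (default 30 mm, i.e. a 3 cm slice) or
the endpoint chord; nominal is the default because the cutting protocol
fixes the slice length, while chord mode covers imperfect excisions.
`fruit_ri()` averages slices per fruit (four is the expected design; any
other count warns but is still aggregated).

Two conventions are deliberate and documented rather than implicit:

* **Boundary ties.** The printed level intervals are ambiguous at their
  shared endpoints, so classification uses left-closed/right-open
  intervals: Level 1 = [0, 1.5), Level 2 = [1.5, 2.5), Level 3 =
  [2.5, 3.5), Level 4 = [3.5, ∞). Every RI maps to exactly one level and
  the top class is the only unbounded one. `classify_level()` is monotone
  by construction, and a brute-force grid scan in the tests recovers the
  three boundaries exactly.
* **Negative RI.** Tracing noise can make the measured epidermal length
  fall slightly below the section length. The raw (negative) value is
  returned with a warning so measurements are never silently altered;
  values are clamped to 0 only at classification time.

The synthetic profile generator produces graph-like sinusoids (optionally
multi-harmonic) on a 30 mm section. Sinusoids were chosen because their
arc length has an independent oracle: `true_ri_quadrature()` integrates
$\sqrt{1 + y'(x)^2}$ by adaptive quadrature to a relative tolerance of
1e-9, is cross-checked in the tests against a dense trapezoidal
integrator (agreement to 1e-6 relative) and against the small-slope
closed form $RI \to 100\,\pi^2 a^2/\lambda^2$. Polyline measurements
converge to the quadrature value monotonically from below as the sampling
gets finer (a chord can never be longer than its arc), which is the
coastline effect in its benign, controlled form.

## Image-based contour extraction

The package replaces manual tracing with a deterministic pixel pipeline:
`binarize()` (fixed threshold or Otsu's between-class-variance criterion),
`trace_upper_boundary()` (per-column topmost tissue pixel, half-pixel
offset for binary masks, 0.5-intensity crossing interpolation for
grayscale, linear gap-filling up to `max_gap_px` columns), and
`resample_smooth()` (moving-average smoothing of `y` over a physical
window followed by arc-length resampling at fixed spacing, endpoints
preserved exactly). Images carry their calibration (`px_per_mm`) with
them, on disk as a JSON sidecar next to the PNG.

The defaults — 0.5 mm smoothing window, 0.1 mm resampling spacing — were
chosen once as a compromise: small relative to the millimetre-to-
centimetre ridge wavelengths of rugose fruit, large relative to pixel
quantization noise at 20 px/mm and above. Manual tracing implicitly
smooths in a way no published number pins down, so these are design
parameters, both configurable, and the package's accuracy claims are
stated *at these defaults*: across true RI from 0 to 6 % the full
render–extract–measure round trip stays within ±0.3 RI percentage points
at 40 px/mm (measured maxima: 0.16 / 0.12 / 0.08 points at 20 / 40 / 80
px/mm), and the maximum error does not increase with resolution. Without
smoothing, ±half-pixel quantization jitter inflates the arc length
noticeably — the tests demonstrate both the inflation and its removal.

Orientation follows plotting convention: image row 1 is the top of the
picture and larger physical `y` points outward, so the epidermis is the
first foreground pixel from the top of each column. Only the outer
boundary is traced; inner pericarp structure is out of scope.

## The synthetic population

`generate_population()` emulates an F2-scale fruit population (default
n = 277). Each fruit draws a true level from configurable proportions
(default 0.25 / 0.30 / 0.25 / 0.20), an RI from a truncated normal inside
that level's interval (Level 4 right-capped at a configurable 8 %), an
ordinal sensory grade that equals the true level except for misgrades to
a neighbouring level, and fourteen indicators following monotone level
trends plus Gaussian noise. Defaults encode the biology the statistics
stage is meant to detect: rupture force, hardness, adhesiveness and
chewiness fall with level; shear force is flat; β-galactosidase and
polygalacturonase rise; cell-wall fractions carry mild trends. The
default rupture-force means (65.5 / 40 / 20 / 10 N) put the
Level-1 : Level-4 mean ratio at exactly 6.55.

Two generator constants were calibrated once by large-sample simulation
and then frozen. With misgrading and indicator noise off, the population
R² of sensory grade on RI is ≈ 0.96 — the ceiling imposed by binning a
continuous index into four grades. The default misgrade probability of
0.37 lowers that population R² to ≈ 0.66, a realistic strength of
agreement between a human grader and the quantitative index; at n = 277
the fitted R² then fluctuates around 0.66 with a spread of about ±0.04,
and the test suite checks that 95 % of seeds land in [0.56, 0.76]. The
misclassification structure (symmetric nearest-neighbour misgrades) is a
modelling choice, not an estimate of any particular grader's behaviour.

What the generator does *not* emulate: genetic linkage between RI and
the indicators (each is driven by level independently), measurement
drift, batch effects, or non-Gaussian indicator noise. Passing tests
therefore certify the pipeline's arithmetic and calibration, not the
behaviour of any real population.

## Association statistics

`fit_ri_sensory_regression()` is ordinary least squares of the sensory
grade (numeric 1–4) on RI. The direction follows the validation model's
formulation; for simple regression R² is symmetric in the two variables,
so nothing hinges on it. `anova_tukey()` runs one-way ANOVA followed by
Tukey HSD (Tukey–Kramer for unbalanced groups, via the studentized-range
distribution) and summarises pairs as a compact letter display computed
with the insert-and-absorb algorithm, processing groups in descending
mean order so output is deterministic; the tests verify letters against
the adjusted-p matrix pair by pair, and the type-I rate of the whole
procedure is calibrated at 5 % ± 1.5 % over 2000 null simulations.
`pairwise_ttest()` defaults to the pooled-variance Student form (a Welch
flag is provided since published methods rarely say which was used).
`pearson_matrix()` reports r, p and the conventional star codes
(0.05 / 0.01 / 0.001) for all pairs on pairwise-complete rows, without
multiplicity correction across the matrix — matching how such correlation
panels are conventionally presented. `level_ratio()` is the plain ratio
of group means used for statements like "6.55 times higher".

## Expression computations

`fpkm()` implements $10^9 c_{gs} / (\ell_g N_s)$ with $N_s$ the
in-matrix column sum — the aligner's mapped-read total is not available
to a desk pipeline, and the convention is documented. `de_test()` is an
operational DE screen, not a reimplementation of any published DE
engine: median-of-ratios size factors (checked in the tests against the
reference implementation), log2 with pseudocount 1, pooled two-sample t
per gene. Its contract is (i) approximately uniform null p-values (KS
statistic < 0.05 at 2000 genes), (ii) near-complete recovery of strong
planted effects (≥ 45 / 50 at |log2FC| = 4, low dispersion, 3 vs 3
replicates), and (iii) a null pass fraction ≤ 0.02 after filtering —
nothing more. `bh_fdr()` is the Benjamini–Hochberg step-up;
`filter_degs()` applies the operational DEG definition with an inclusive
fold-change boundary (|FC| ≥ 2 passes at exactly 2) and a strict FDR
boundary (q = 0.01 fails).

`zscore_profiles()` averages log2(FPKM+1) over replicates within each
genotype–stage group and standardizes each gene across the six groups —
group means rather than individual samples, matching the six-condition
x-axis on which co-expression modules are conventionally displayed.
`kmeans_modules()` clusters those profiles with Euclidean K-means, best
of 25 restarts under a caller-supplied seed, modules relabelled by
decreasing size so output is reproducible; k is the caller's choice
because no principled k-selection rule is implied by the workflow being
emulated. `pca_samples()` runs PCA on gene-centred log2(FPKM+1).

`delta_delta_ct()` averages technical-replicate Ct values on the Ct
scale first, then forms ΔCt against the reference gene (a ubiquitin
control by default in the generator), ΔΔCt against the calibrator
sample, and returns $2^{-\Delta\Delta Ct}$; biological replicates, when
present, should be summarized as mean ± SE of per-replicate values after
this function.

## Numerical choices and degenerate inputs

* Quadrature: `stats::integrate`, relative tolerance 1e-9.
* Pseudocount 1 for every log2 transform of expression values.
* BH comparison tolerance in tests is 1e-12: two correct step-up
  implementations can differ in the last floating-point ulp because they
  multiply in different orders.
* Degenerate inputs are classed errors, not silent results: contours
  with < 2 points, zero section or chord length, all-foreground or
  all-background masks, boundary gaps wider than `max_gap_px`, groups
  with < 2 observations, constant regressors, zero library sizes,
  missing reference Ct values, k outside [2, n-genes].
* Constant indicator columns yield NA correlations with a warning;
  constant gene profiles are dropped from standardization with a warning.

## Problem sizes

The test and acceptance workloads were sized to what the method actually
needs for its guarantees: 12 amplitude–wavelength combinations for the
quadrature comparison; 12 RI values × 3 resolutions for the image round
trip; 2000 null simulations for ANOVA calibration; 500 seeds at n = 277
for R² recovery; 2000 genes × 18 samples for the DE, clustering and PCA
checks; 20 null count matrices for the false-positive rate. The complete
suite runs in well under a minute on a single core apart from the image
sweep, which takes a few tens of seconds.

## Known limitations

* RI is a 2-D, single-section summary; it ignores ridge anisotropy and
  3-D surface structure, and four slices per fruit is an averaging
  convention, not an optimum.
* The smoothing default trades a small negative bias at high RI (window
  attenuation of the waveform) against pixel-noise inflation; profiles
  with ridge wavelengths below ~2 mm would need a narrower window.
* The DE screen is a calibrated stand-in; counts from real experiments
  should be analysed with a dedicated DE package, and this package's DEG
  definition then applied to those results via `filter_degs()`.
* The sensory misgrade model is symmetric and memoryless; real graders
  may err asymmetrically near boundaries.
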