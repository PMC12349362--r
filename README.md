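# rugosity

Quantification of fruit surface rugosity from traced or imaged
cross-sections, with the association statistics and operational
transcriptome computations that accompany such a phenotype study.

Rugose fruit surfaces — ridges and depressions on the epidermis of, for
example, some pepper genotypes — are usually graded by eye on an ordinal
1–4 scale. This package implements the quantitative alternative: from a
longitudinal section cut at the fruit equator, the outer epidermal
contour is traced (or extracted from a calibrated image) as a polyline,
and surface roughness is summarised by the **rugosity index**

```
RI (%) = 100 × (epidermal length − section length) / section length
```

with the per-fruit value averaged over four slices and classified into
four levels at RI boundaries of 1.5, 2.5 and 3.5 % (left-closed
intervals, Level 4 unbounded). Around that core the package provides:

* **Synthetic data with known ground truth** for every stage: parametric
  wavy profiles with an adaptive-quadrature arc-length oracle, rendered
  calibrated section images, an F2-scale phenotype population with
  planted level effects, negative-binomial count matrices with planted
  DE genes, and qPCR Ct tables with a reference gene.
* **Image extraction**: Otsu or fixed-threshold binarization, subpixel
  upper-boundary tracing with gap filling, moving-average smoothing and
  arc-length resampling to control the coastline effect.
* **Association statistics**: sensory-validation regression (`Y = β₀ +
  β₁·RI + ε`), one-way ANOVA with Tukey HSD and compact letter displays,
  pooled/Welch t-tests, Pearson correlation panels with significance
  stars, and between-level fold ratios.
* **Expression computations**: FPKM, a calibrated DE screen with
  Benjamini–Hochberg FDR and the |FC| ≥ 2 & FDR < 0.01 DEG filter,
  standardized K-means co-expression modules, sample PCA, and
  2^−ΔΔCt relative qPCR quantification.

All user-facing functions take data frames and return tibbles; fitted
objects have `tidy()` / `glance()` and `autoplot()` methods.

## Worked example

Measure a synthetic slice and check it against the analytic oracle:

```r
library(rugosity)
library(dplyr)

profile <- wave_profile(amplitude_mm = 0.35, wavelength_mm = 5)
contour <- generate_contour(profile, spacing_mm = 0.05)
slice_ri(contour)
#> # A tibble: 1 × 3
#>   epidermal_mm section_mm ri_percent
#>          <dbl>      <dbl>      <dbl>
#> 1         31.4         30       4.67
true_ri_quadrature(profile)
#> [1] 4.6735

# render at 40 px/mm, re-extract the contour, re-measure
img <- render_section_image(contour, px_per_mm = 40)
slice_ri(extract_contour(img))
#> # A tibble: 1 × 3
#>   epidermal_mm section_mm ri_percent
#>          <dbl>      <dbl>      <dbl>
#> 1         31.4         30       4.60
```

The polyline measurement matches the quadrature oracle to three decimal
places, and the full image round trip recovers RI within 0.07 points
here (guaranteed within ±0.3 points for RI up to 6 % at this
resolution).

Simulate an F2-scale population, validate the index against sensory
grades, and run the level statistics:

```r
pop <- generate_population(population_config(seed = 1))
fit_ri_sensory_regression(pop)
#> <ri_regression> n = 277
#>   sensory = 0.8852 + 0.6253 * RI
#>   R^2 = 0.6199, slope p = 1.05e-59

pop <- pop |> mutate(level = classify_level(ri_percent))
tidy(anova_tukey(pop, "RF"))        # rupture force across levels
#> # A tibble: 4 × 5
#>   group     n  mean    se letters
#>   <chr> <int> <dbl> <dbl> <chr>
#> 1 1        73  65.1 0.640 a
#> 2 2        78  40.2 0.722 b
#> 3 3        80  20.1 0.610 c
#> 4 4        46  10.3 0.943 d
level_ratio(pop, "RF")              # Level-1 : Level-4 mean ratio
#> [1] 6.30555
```

The index explains ~62 % of the sensory variance at this seed (the
generator is calibrated so the population value is 0.66), rupture force
falls monotonically across levels with all four groups separated by
Tukey HSD (distinct letters), and smooth fruits rupture at ~6.3 times
the force of highly rugose ones (6.55 in expectation by construction).

Expression side, on simulated counts with 100 planted DE genes:

```r
sim  <- generate_counts(counts_config(seed = 1))
degs <- filter_degs(de_test(sim, "M", "G"))
sum(degs$pass)
#> [1] 100
pca_samples(fpkm(sim))
#> <sample_pca>
#>   variance explained: PC1 36.6%, PC2 4.6%, PC3 4.5%, PC4 4.4%, PC5 4.3%

ct <- generate_ct_table(2, 3, true_log2_ratios = c(0, 1, 2))
delta_delta_ct(ct)
#> # A tibble: 6 × 5
#>   gene  sample delta_ct delta_delta_ct rel_expression
#>   <chr> <chr>     <dbl>          <dbl>          <dbl>
#> 1 TG001 S01           4              0              1
#> 2 TG001 S02           3             -1              2
#> 3 TG001 S03           2             -2              4
#> ...
```

All 100 planted genes (and nothing else) pass the DEG filter, PC1
separates the two genotypes, and noise-free Ct tables recover the
configured expression ratios exactly.

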