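#' Default per-indicator level profiles
#'
#' Mean value of each texture / cell-wall / enzyme indicator at rugosity
#' levels 1-4, plus the per-observation Gaussian noise sd. Rupture force
#' (RF), hardness (HD), adhesiveness (AD) and chewiness (CH) decrease with
#' level; shear force (SF) is flat; beta-galactosidase (bGAL) and
#' polygalacturonase (PG) increase; the remaining cell-wall fractions and
#' enzymes carry mild trends. The default RF means put the Level-1 : Level-4
#' group-mean ratio at 65.5/10 = 6.55. Units: texture indicators in N (AD,
#' CH in mJ), pectin/cellulose/hemicellulose fractions in mg/g fresh
#' weight, enzyme activities in U/g.
#'
#' @return A tibble with columns `indicator`, `l1`..`l4`, `noise_sd`.
#' @export
default_indicator_profiles <- function() {
  tibble::tribble(
    ~indicator,   ~l1,   ~l2,   ~l3,   ~l4, ~noise_sd,
    "RF",        65.5,    40,    20,    10,       6.0,
    "HD",        30.0,    24,    18,    12,       3.0,
    "AD",         2.0,   1.6,   1.2,   0.8,       0.2,
    "CH",        15.0,    12,     9,     6,       1.5,
    "SF",        18.0,    18,    18,    18,       2.0,
    "WSP",        1.2,  1.35,   1.5,  1.65,       0.2,
    "ISP",        0.8,  0.95,   1.1,   1.3,      0.12,
    "CSP",        2.0,   1.9,   1.8,   1.7,      0.25,
    "CEL",       12.0,  11.5,  11.0,  10.5,       1.0,
    "HEM",        8.0,   7.8,   7.6,   7.4,       0.8,
    "bGAL",       5.0,   7.0,   9.0,  11.0,       0.8,
    "PG",        10.0,  14.0,  18.0,  24.0,       1.8,
    "CX",         3.0,   3.3,   3.6,   3.9,       0.5,
    "PME",        4.0,   4.2,   4.4,   4.6,       0.6
  )
}

#' Configuration for a synthetic segregating population
#'
#' Describes an F2-like fruit population (default n = 277) in which every
#' fruit has a true rugosity level, an RI drawn from a truncated normal
#' inside that level's interval, an ordinal sensory grade that equals the
#' true level except for occasional misgrades to a neighbouring level, and
#' texture / biochemical indicators following monotone level trends plus
#' noise.
#'
#' The default `sensory_misgrade_prob` of 0.37 was calibrated once, by
#' large-sample simulation under the default RI level distributions, so
#' that the population-level coefficient of determination of the sensory
#' grade regressed on RI is about 0.66 — the strength of agreement a
#' careful human grader achieves against the quantitative index. With
#' misgrading and indicator noise switched off the population R^2 is
#' about 0.96.
#'
#' @param n_fruits Number of fruits.
#' @param level_proportions Probabilities of true levels 1-4; must sum to 1.
#' @param ri_mean_by_level,ri_sd_by_level Truncated-normal location and sd
#'   of RI (percent) inside each level interval; means must be strictly
#'   increasing and lie inside their intervals.
#' @param ri_max_percent Right cap of the open Level-4 interval, percent.
#' @param sensory_misgrade_prob Probability a fruit's sensory grade moves to
#'   a neighbouring level.
#' @param indicator_profiles Per-indicator level means and noise sds; see
#'   [default_indicator_profiles()].
#' @param indicator_noise_scale Multiplier on every indicator's noise sd
#'   (0 = noise-free indicators).
#' @param scheme [level_scheme()] defining the level intervals.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return An object of class `population_config`.
#' @export
population_config <- function(n_fruits = 277,
                              level_proportions = c(0.25, 0.30, 0.25, 0.20),
                              ri_mean_by_level = c(0.8, 2.0, 3.1, 4.3),
                              ri_sd_by_level = c(0.22, 0.20, 0.20, 0.38),
                              ri_max_percent = 8,
                              sensory_misgrade_prob = 0.37,
                              indicator_profiles = default_indicator_profiles(),
                              indicator_noise_scale = 1,
                              scheme = level_scheme(),
                              seed = NULL) {
  check_finite_scalar(n_fruits, "n_fruits", positive = TRUE)
  if (length(level_proportions) != 4L || any(level_proportions < 0)) {
    stop_rugosity("`level_proportions` must be 4 non-negative numbers.",
                  "rugosity_invalid_parameter")
  }
  if (abs(sum(level_proportions) - 1) > 1e-9) {
    stop_rugosity("`level_proportions` must sum to 1 (within 1e-9).",
                  "rugosity_invalid_parameter")
  }
  if (length(ri_mean_by_level) != 4L ||
      is.unsorted(ri_mean_by_level, strictly = TRUE)) {
    stop_rugosity("`ri_mean_by_level` must be 4 strictly increasing values.",
                  "rugosity_invalid_parameter")
  }
  if (length(ri_sd_by_level) != 4L || any(ri_sd_by_level < 0)) {
    stop_rugosity("`ri_sd_by_level` must be 4 non-negative values.",
                  "rugosity_invalid_parameter")
  }
  if (sensory_misgrade_prob < 0 || sensory_misgrade_prob > 1) {
    stop_rugosity("`sensory_misgrade_prob` must be in [0, 1].",
                  "rugosity_invalid_parameter")
  }
  bounds <- level_bounds(scheme, ri_max_percent)
  if (any(ri_mean_by_level < bounds$lower | ri_mean_by_level >= bounds$upper)) {
    stop_rugosity("Each `ri_mean_by_level` must lie inside its level interval.",
                  "rugosity_invalid_parameter")
  }
  structure(
    list(n_fruits = as.integer(n_fruits),
         level_proportions = level_proportions,
         ri_mean_by_level = ri_mean_by_level,
         ri_sd_by_level = ri_sd_by_level,
         ri_max_percent = ri_max_percent,
         sensory_misgrade_prob = sensory_misgrade_prob,
         indicator_profiles = indicator_profiles,
         indicator_noise_scale = indicator_noise_scale,
         scheme = scheme,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "population_config"
  )
}

level_bounds <- function(scheme, ri_max_percent) {
  b <- scheme$boundaries_percent
  list(lower = c(0, b), upper = c(b, ri_max_percent))
}

#' Simulate a phenotype population with known ground truth
#'
#' Draws one record per fruit under a [population_config()]: a true level
#' from the level proportions, an RI from the level's truncated normal
#' (non-negative by construction), a sensory grade equal to the true level
#' or a neighbouring level with the configured misgrade probability, and
#' all indicators as level mean plus Gaussian noise.
#'
#' @param config A [population_config()].
#' @return A tibble with one row per fruit: `fruit_id`, `true_level`
#'   (ground truth, not part of the on-disk phenotype dialect),
#'   `ri_percent`, `sensory_level` and one column per indicator.
#' @examples
#' pop <- generate_population(population_config(n_fruits = 50, seed = 1))
#' dplyr::count(pop, true_level)
#' @export
generate_population <- function(config = population_config()) {
  stopifnot(inherits(config, "population_config"))
  with_seed_or_not(config$seed, {
    n <- config$n_fruits
    lev <- sample.int(4L, n, replace = TRUE, prob = config$level_proportions)
    bounds <- level_bounds(config$scheme, config$ri_max_percent)
    ri <- numeric(n)
    for (l in 1:4) {
      idx <- which(lev == l)
      if (length(idx)) {
        ri[idx] <- rtruncnorm(length(idx),
                              mean = config$ri_mean_by_level[l],
                              sd = config$ri_sd_by_level[l],
                              lower = bounds$lower[l],
                              upper = bounds$upper[l])
      }
    }
    sensory <- lev
    mis <- runif(n) < config$sensory_misgrade_prob
    if (any(mis)) {
      shift <- ifelse(lev[mis] == 1L, 1L,
                      ifelse(lev[mis] == 4L, -1L,
                             sample(c(-1L, 1L), sum(mis), replace = TRUE)))
      sensory[mis] <- lev[mis] + shift
    }
    out <- tibble(
      fruit_id = sprintf("F%04d", seq_len(n)),
      true_level = lev,
      ri_percent = ri,
      sensory_level = sensory
    )
    prof <- config$indicator_profiles
    means <- as.matrix(prof[, c("l1", "l2", "l3", "l4")])
    for (i in seq_len(nrow(prof))) {
      out[[prof$indicator[i]]] <- unname(means[i, lev]) +
        rnorm(n, sd = prof$noise_sd[i] * config$indicator_noise_scale)
    }
    out
  })
}
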