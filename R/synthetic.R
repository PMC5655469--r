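#' Synthetic input generators
#'
#' The published analysis consumed national inputs that are not deposited
#' with it: life tables, census population counts, and the age curve of
#' pain prevalence in people without knee OA. These generators produce
#' inputs with the statistical structure the analysis assumes — Gompertz
#' mortality that is monotone in age and closes at a maximum age,
#' census-like counts thinning geometrically with age, prevalence rising
#' with age, and a logistic-in-age pain curve — so the full pipeline runs
#' end to end and its properties can be tested.
#'
#' @name synthetic_data
NULL

# remaining-life-expectancy-at-40 calibration (years, approximate):
# non_maori male 39.7 / female 43.2; maori male 32.8 / female 36.0
DEFAULT_GOMPERTZ_LEVEL <- c(
  non_maori.male = 4.3e-5, non_maori.female = 3.1e-5,
  maori.male = 8.5e-5, maori.female = 6.2e-5
)
DEFAULT_GOMPERTZ_SHAPE <- 0.09

#' Generate a Gompertz life table
#'
#' Death hazard at age `a` is `level * exp(shape * a)`; the 5-year death
#' probability for the band starting at `a` is the closed-form
#' `1 - exp(-(level/shape) * (exp(shape*(a+5)) - exp(shape*a)))`. The band
#' starting at `closure_age` is forced to probability 1 so every simulated
#' life is finite. Deterministic given its parameters.
#'
#' @param gompertz_level Hazard scale; a single positive number, or a named
#'   vector/list with entries `"<ethnicity>.<sex>"` (defaults calibrated to
#'   plausible national life expectancies, with higher Maori mortality).
#' @param gompertz_shape Per-year log-hazard slope (> 0).
#' @param closure_age Closure age (>= 85, multiple-of-5 offset from 40).
#' @param seed Unused (the table is deterministic); accepted for interface
#'   uniformity with the other generators.
#' @return A [life_table()].
#' @export
#' @examples
#' lt <- generate_life_table()
#' head(subset(lt, sex == "male" & ethnicity == "non_maori"))
generate_life_table <- function(gompertz_level = DEFAULT_GOMPERTZ_LEVEL,
                                gompertz_shape = DEFAULT_GOMPERTZ_SHAPE,
                                closure_age = 110L, seed = NULL) {
  if (any(unlist(gompertz_level) <= 0)) stop("gompertz_level must be positive")
  if (gompertz_shape <= 0) stop("gompertz_shape must be positive")
  if (closure_age < 85) stop("closure_age must be at least 85")
  bands <- all_age_bands(closure_age)
  starts <- c(seq(40L, closure_age - 5L, by = 5L), closure_age)
  rows <- list()
  for (e in ETHNICITIES) for (s in SEXES) {
    lev <- if (length(gompertz_level) == 1L) unlist(gompertz_level) else {
      key <- paste(e, s, sep = ".")
      if (is.null(gompertz_level[[key]]) || is.na(gompertz_level[[key]])) {
        stop("gompertz_level has no entry for ", key)
      }
      gompertz_level[[key]]
    }
    p5 <- gompertz_p5(starts, lev, gompertz_shape)
    p5[length(p5)] <- 1
    rows[[paste(e, s)]] <- data.frame(
      ethnicity = e, sex = s, age_band = bands, p_death_5yr = p5,
      stringsAsFactors = FALSE)
  }
  life_table(do.call(rbind, rows), closure_age = closure_age)
}

# closed-form integral of the Gompertz hazard over [a, a+5)
gompertz_p5 <- function(a, level, shape) {
  1 - exp(-(level / shape) * (exp(shape * (a + 5)) - exp(shape * a)))
}

#' Generate census-style population counts
#'
#' Expected counts thin geometrically with age band (`age_decay` per band)
#' and are split by sex and ethnicity shares; fractional expected counts are
#' rounded half to even. Deterministic given its parameters.
#'
#' @param total Total population over all 36 strata (> 0).
#' @param age_decay Multiplicative factor between adjacent age bands (0.85
#'   default thins like a national 40+ age pyramid).
#' @param sex_split Proportion female.
#' @param maori_share Proportion Maori.
#' @param seed Unused; accepted for interface uniformity.
#' @return A [population_counts()].
#' @export
generate_population_counts <- function(total = 1900000, age_decay = 0.85,
                                       sex_split = 0.51, maori_share = 0.13,
                                       seed = NULL) {
  if (total <= 0) stop("total must be positive")
  if (sex_split < 0 || sex_split > 1) stop("sex_split must lie in [0, 1]")
  if (maori_share < 0 || maori_share > 1) stop("maori_share must lie in [0, 1]")
  if (age_decay <= 0) stop("age_decay must be positive")
  w_band <- age_decay^(0:8)
  w_band <- w_band / sum(w_band)
  g <- strata_grid()
  share_e <- ifelse(g$ethnicity == "maori", maori_share, 1 - maori_share)
  share_s <- ifelse(g$sex == "female", sex_split, 1 - sex_split)
  expected <- total * share_e * share_s * w_band[match(g$age_band, core_age_bands())]
  g$count <- round(expected)  # round() is half-to-even
  population_counts(g)
}

#' Generate a prevalence surface rising with age
#'
#' Band `k` (zero-based from 40-44) gets prevalence `base * slope^k`,
#' clipped to `[0, 1]`, identical across sex and ethnicity. Deterministic.
#'
#' @param base Prevalence in the 40-44 band (in `[0, 1]`).
#' @param slope Per-band multiplicative increase (>= 1 gives a non-decreasing
#'   surface; defaults mimic published knee-OA prevalence rising from ~1%
#'   at 40-44 to ~20% at 80-84).
#' @param seed Unused; accepted for interface uniformity.
#' @return A [prevalence_table()] (unadjusted).
#' @export
generate_prevalence <- function(base = 0.01, slope = 1.45, seed = NULL) {
  if (base < 0 || base > 1) stop("base prevalence must lie in [0, 1]")
  if (slope < 0) stop("slope must be non-negative")
  g <- strata_grid()
  k <- match(g$age_band, core_age_bands()) - 1L
  g$prevalence <- pmin(1, pmax(0, base * slope^k))
  prevalence_table(g, adjusted = FALSE)
}

#' Generate a logistic-in-age non-OA pain curve
#'
#' The proportion of the non-OA population in any pain follows a logistic
#' curve in age, evaluated at band midpoints and anchored at two ages. The
#' defaults (30% at 40 rising to 55% at 85) are deliberately on the high
#' side, matching general-population pain surveys. Deterministic.
#'
#' @param p_age40,p_age85 Anchor proportions at ages 40 and 85 (in (0, 1)).
#' @param moderate_share Of those in pain, the proportion in moderate (vs
#'   severe) pain; default 0.90.
#' @param closure_age Last band generated (default 110).
#' @param seed Unused; accepted for interface uniformity.
#' @return A [pain_curve()].
#' @export
generate_pain_curve <- function(p_age40 = 0.30, p_age85 = 0.55,
                                moderate_share = 0.90, closure_age = 110L,
                                seed = NULL) {
  if (any(c(p_age40, p_age85) <= 0 | c(p_age40, p_age85) >= 1)) {
    stop("anchor proportions must lie strictly in (0, 1)")
  }
  beta <- (stats::qlogis(p_age85) - stats::qlogis(p_age40)) / 45
  alpha <- stats::qlogis(p_age40) - 40 * beta
  starts <- c(seq(40L, closure_age - 5L, by = 5L), closure_age)
  mids <- starts + 2
  df <- data.frame(age_band = all_age_bands(closure_age),
                   p_in_pain = stats::plogis(alpha + beta * mids))
  pain_curve(df, moderate_share = moderate_share, closure_age = closure_age)
}
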