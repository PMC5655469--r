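#' Pain and health-related quality of life
#'
#' Knee pain is carried on the 0-100 WOMAC pain scale (100 = worst).
#' Individuals with knee OA are initialised from a clamped normal
#' distribution and drift upward by a small annual increment; the score is
#' collapsed to three severity levels — no pain (WOMAC < 1), moderate
#' (1-70), severe (> 70) — which index age-specific EQ-5D utilities.
#' People without knee OA draw a pain level from an age-band prevalence
#' curve instead, with a configurable moderate/severe split (default 90/10).
#'
#' @name health_states
NULL

#' Pain model parameters
#'
#' Defaults give a cohort with mild-to-moderate knee-OA pain (WOMAC mean 30,
#' SD 15 at initialisation) on a relatively stable trajectory (+0.5
#' points/year, SD 5). Draws are clamped to the WOMAC range rather than
#' resampled, so the nominal mean/SD are preserved as parameters.
#'
#' @param init_mean,init_sd Initialisation distribution (WOMAC points).
#' @param annual_increment_mean,annual_increment_sd Annual change
#'   distribution (WOMAC points/year).
#' @param floor,ceiling Scale bounds (0 and 100).
#' @return A `pain_model_params` list.
#' @export
pain_model_params <- function(init_mean = 30, init_sd = 15,
                              annual_increment_mean = 0.5,
                              annual_increment_sd = 5,
                              floor = 0, ceiling = 100) {
  if (init_sd < 0 || annual_increment_sd < 0) stop("sd parameters must be >= 0")
  if (floor >= ceiling) stop("floor must be below ceiling")
  structure(list(init_mean = init_mean, init_sd = init_sd,
                 annual_increment_mean = annual_increment_mean,
                 annual_increment_sd = annual_increment_sd,
                 floor = floor, ceiling = ceiling),
            class = "pain_model_params")
}

#' Collapse a WOMAC pain score to a severity level
#'
#' `womac < 1` is no pain, `1 <= womac <= 70` moderate, `womac > 70` severe.
#'
#' @param womac Numeric vector of WOMAC pain scores in `[0, 100]`.
#' @return Character vector in `c("none", "moderate", "severe")`.
#' @export
#' @examples
#' categorize_pain(c(0, 0.99, 1, 70, 70.01, 100))
categorize_pain <- function(womac) {
  if (any(womac < 0 | womac > 100)) stop("WOMAC scores must lie in [0, 100]")
  PAIN_LEVELS[1L + (womac >= 1) + (womac > 70)]
}

#' Look up the utility for an age and pain level
#'
#' Ages are mapped to their 5-year band; ages beyond the last tabulated band
#' (80-84) reuse that band's row, since individuals survive past the end of
#' the published table.
#'
#' @param age Age in years (>= 40).
#' @param level Pain level (`"none"`, `"moderate"`, `"severe"`).
#' @param table A [utility_table()].
#' @return Utility value(s) in `[0, 1]`.
#' @export
#' @examples
#' ut <- load_fixture_tables()$utilities
#' lookup_utility(62, "moderate", ut)
lookup_utility <- function(age, level, table) {
  stopifnot(inherits(table, "utility_table"))
  level <- match.arg(level, PAIN_LEVELS, several.ok = TRUE)
  m <- utility_matrix_core(table)
  m[cbind(core_band_index_of_age(age), match(level, PAIN_LEVELS))]
}

#' Transform a utility table between value sets
#'
#' Applies the power transform `u' = 1 - (1 - u)^exponent` cell-wise,
#' mapping VAS-elicited values toward trade-off-consistent (standard-gamble
#' -like) valuations; an exponent above 1 moves every utility up toward 1
#' (compressing pain-level gaps, hence smaller modelled losses), an exponent
#' of 1 is the identity, and the dead/perfect-health anchors 0 and 1 are
#' fixed points. The pain-level ordering within bands is preserved.
#'
#' @param table A [utility_table()] with value set `"vas"`.
#' @param exponent Positive power-transform exponent (default 1.61).
#' @return A [utility_table()] with value set `"transformed"`.
#' @export
transform_value_set <- function(table, exponent = 1.61) {
  stopifnot(inherits(table, "utility_table"))
  if (!identical(attr(table, "value_set"), "vas")) {
    stop("transform_value_set expects a table on the 'vas' value set")
  }
  if (exponent <= 0) stop("exponent must be positive")
  out <- as.data.frame(table)
  out$value <- 1 - (1 - out$value)^exponent
  utility_table(out, value_set = "transformed")
}

clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

#' Draw initial WOMAC pain scores for an OA cohort
#'
#' Normal draws with the configured initialisation mean/SD, clamped to the
#' WOMAC range.
#'
#' @param n Number of draws (>= 1).
#' @param params A [pain_model_params()].
#' @param seed Integer seed.
#' @return Numeric vector of `n` WOMAC scores in `[0, 100]`.
#' @export
draw_initial_pain <- function(n, params = pain_model_params(), seed = 1L) {
  if (n < 1) stop("n must be at least 1")
  set.seed(seed)
  clamp(stats::rnorm(n, params$init_mean, params$init_sd),
        params$floor, params$ceiling)
}

#' Advance WOMAC pain by one annual cycle
#'
#' Adds a normal annual increment and clamps to the scale. Draws come from
#' the caller's current RNG stream, so per-individual substreams stay
#' reproducible.
#'
#' @param womac Current score(s) in `[0, 100]`.
#' @param params A [pain_model_params()].
#' @return Updated score(s).
#' @export
progress_pain <- function(womac, params = pain_model_params()) {
  if (any(womac < 0 | womac > 100)) stop("WOMAC scores must lie in [0, 100]")
  inc <- stats::rnorm(length(womac), params$annual_increment_mean,
                      params$annual_increment_sd)
  clamp(womac + inc, params$floor, params$ceiling)
}

#' Draw pain levels for people without knee OA
#'
#' For age band `b` the level is none with probability `1 - p_in_pain(b)`,
#' moderate with `p_in_pain(b) * moderate_share`, and severe with the
#' remainder. Draws come from the caller's current RNG stream.
#'
#' @param age_band Band label(s) covered by the curve.
#' @param curve A [pain_curve()].
#' @param n Number of draws per band label (default 1, vectorised over
#'   `age_band` otherwise).
#' @return Character vector of pain levels.
#' @export
draw_non_oa_pain_level <- function(age_band, curve, n = length(age_band)) {
  stopifnot(inherits(curve, "pain_curve"))
  age_band <- normalize_age_band(age_band)
  idx <- match(age_band, curve$age_band)
  if (anyNA(idx)) {
    stop("pain curve does not cover band(s): ",
         paste(unique(age_band[is.na(idx)]), collapse = ", "))
  }
  if (n != length(idx)) idx <- rep_len(idx, n)
  p <- curve$p_in_pain[idx]
  m <- attr(curve, "moderate_share")
  u <- stats::runif(n)
  non_oa_level_from_uniform(u, p, m)
}

# shared threshold rule: u < 1-p -> none; u < 1-p+p*m -> moderate; else severe.
# Monotone in m: raising m reclassifies severe draws as moderate.
non_oa_level_from_uniform <- function(u, p_in_pain, moderate_share) {
  lev <- 1L + (u >= 1 - p_in_pain) + (u >= 1 - p_in_pain * (1 - moderate_share))
  PAIN_LEVELS[lev]
}
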