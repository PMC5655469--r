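#' Annual life-history microsimulation
#'
#' Each simulated individual passes through annual cycles from a starting
#' age until death or the life-table closure age. Every year begun accrues
#' the full year's utility for the individual's current age band and pain
#' level (no half-cycle correction, no discounting — this is a burden
#' analysis, not a costing); death is applied at year end with the
#' annualised life-table probability. QALYs lived are the sum of yearly
#' utilities; averaging over a cohort estimates quality-adjusted life
#' expectancy (QALE) for that stratum.
#'
#' @name microsim
NULL

#' Convert a 5-year death probability to an annual one
#'
#' Constant-hazard-within-band conversion: `1 - (1 - p5)^(1/5)`, the
#' standard actuarial annualisation (invertible by compounding five years).
#'
#' @param p5 Probability of death within 5 years, in `[0, 1]`.
#' @return Annual death probability.
#' @export
#' @examples
#' annual_mortality(0.226)       # ~0.05
#' 1 - (1 - annual_mortality(0.226))^5  # recovers 0.226
annual_mortality <- function(p5) {
  if (any(p5 < 0 | p5 > 1)) stop("5-year death probability must lie in [0, 1]")
  1 - (1 - p5)^(1 / 5)
}

# Precompute everything shared by individuals of one cohort: per-year annual
# death probabilities, per-band utility rows (last published band carried
# forward), and the non-OA pain curve aligned to band indices.
sim_context <- function(start_age, ethnicity, sex, tables) {
  utility <- tables$utility
  life <- tables$life_table
  curve <- tables$pain_curve
  stopifnot(inherits(utility, "utility_table"), inherits(life, "life_table"),
            inherits(curve, "pain_curve"))
  closure <- attr(life, "closure_age")
  if (attr(curve, "closure_age") != closure) {
    stop("pain curve covers bands to ", attr(curve, "closure_age"),
         " but the life table closes at ", closure)
  }
  if (start_age < 40 || start_age > 84) stop("start_age must lie in [40, 84]")
  bands <- all_age_bands(closure)
  n_bands <- length(bands)
  sub <- life[life$ethnicity == ethnicity & life$sex == sex, ]
  p5 <- sub$p_death_5yr[match(bands, sub$age_band)]
  if (anyNA(p5)) {
    stop("life table lacks band(s) ", paste(bands[is.na(p5)], collapse = ", "),
         " for ", ethnicity, "/", sex)
  }
  ages <- start_age:closure
  band_idx <- band_index_of_age(ages, closure)
  u_core <- utility_matrix_core(utility)
  u_all <- u_core[pmin(seq_len(n_bands), 9L), , drop = FALSE]
  p_pain <- curve$p_in_pain[match(bands, curve$age_band)]
  list(
    start_age = start_age, closure = closure, T = length(ages),
    band_idx = band_idx, p1_year = annual_mortality(p5[band_idx]),
    u_all = u_all, p_pain_band = p_pain,
    n_band_draws = n_bands - band_idx[1] + 1L,
    moderate_share = attr(curve, "moderate_share")
  )
}

# One individual under a prepared context. Draw order per stream: mortality
# uniforms (fixed count T) first, then pain draws — so OA and no-OA arms
# sharing a seed share their death year, and the no-OA arm's pain draws are
# identical across moderate-share values (common random numbers).
sim_one <- function(ctx, oa, params, seed, moderate_share = ctx$moderate_share,
                    detail = FALSE) {
  set.seed(seed)
  um <- stats::runif(ctx$T)
  years <- which.max(um < ctx$p1_year)  # closure-band p1 = 1 guarantees a hit
  if (oa) {
    w <- clamp(stats::rnorm(1, params$init_mean, params$init_sd),
               params$floor, params$ceiling)
    path <- w
    if (years > 1) {
      inc <- stats::rnorm(years - 1, params$annual_increment_mean,
                          params$annual_increment_sd)
      raw <- w + cumsum(inc)
      if (all(raw >= params$floor & raw <= params$ceiling)) {
        path <- c(w, raw)  # clamping never bound
      } else {
        path <- numeric(years)
        path[1] <- w
        for (t in 2:years) {
          path[t] <- clamp(path[t - 1] + inc[t - 1], params$floor, params$ceiling)
        }
      }
    }
    lev <- 1L + (path >= 1) + (path > 70)
    q <- sum(ctx$u_all[cbind(ctx$band_idx[seq_len(years)], lev)])
    if (detail) return(list(qalys = q, years = years, womac = path))
    return(q)
  }
  ub <- stats::runif(ctx$n_band_draws)  # one per band from entry to closure
  occ <- rle(ctx$band_idx[seq_len(years)])
  k <- length(occ$values)
  lev_chr <- non_oa_level_from_uniform(ub[seq_len(k)],
                                       ctx$p_pain_band[occ$values],
                                       moderate_share)
  lev <- match(lev_chr, PAIN_LEVELS)
  q <- sum(occ$lengths * ctx$u_all[cbind(occ$values, lev)])
  if (detail) {
    return(list(qalys = q, years = years, bands = occ$values,
                years_in_band = occ$lengths, u_draw = ub[seq_len(k)]))
  }
  q
}

#' Simulate one individual's remaining lifetime
#'
#' Runs annual cycles from `start_age` until death (or life-table closure):
#' individuals with knee OA progress their WOMAC score and are categorised
#' each year; individuals without OA draw a pain level from the non-OA curve
#' once per age band they enter. Returns the QALYs lived.
#'
#' @param start_age Starting age in `[40, 84]`.
#' @param ethnicity,sex Stratum identifiers.
#' @param oa_status `"oa"` or `"no_oa"`.
#' @param tables List with elements `utility` ([utility_table()]),
#'   `life_table` ([life_table()]), `pain_curve` ([pain_curve()]).
#' @param params A [pain_model_params()].
#' @param seed Integer seed for this individual's stream.
#' @return QALYs lived (numeric scalar, attribute `years` = years lived).
#' @export
simulate_individual <- function(start_age, ethnicity, sex,
                                oa_status = c("oa", "no_oa"), tables,
                                params = pain_model_params(), seed = 1L) {
  oa_status <- match.arg(oa_status)
  ethnicity <- match.arg(ethnicity, ETHNICITIES)
  sex <- match.arg(sex, SEXES)
  ctx <- sim_context(start_age, ethnicity, sex, tables)
  res <- sim_one(ctx, oa_status == "oa", params, seed, detail = TRUE)
  structure(res$qalys, years = res$years)
}

#' Closed-form QALE for a deterministic pain trajectory
#'
#' For a fixed per-year pain level sequence, QALE is the survival-weighted
#' utility sum `sum_t S(t-1) * u(age_t, level_t)`, with `S` compounded from
#' the annualised life-table probabilities. This is the analytic oracle the
#' stochastic simulator is tested against.
#'
#' @param start_age Starting age in `[40, 84]`.
#' @param ethnicity,sex Stratum identifiers.
#' @param levels Per-year pain levels (recycled to the full horizon).
#' @param tables As in [simulate_individual()] (`pain_curve` required only
#'   for context construction).
#' @return Expected QALYs (numeric scalar).
#' @export
qale_closed_form <- function(start_age, ethnicity, sex, levels, tables) {
  ctx <- sim_context(start_age, match.arg(ethnicity, ETHNICITIES),
                     match.arg(sex, SEXES), tables)
  lev <- match(rep_len(levels, ctx$T), PAIN_LEVELS)
  if (anyNA(lev)) stop("levels must be in: ", paste(PAIN_LEVELS, collapse = ", "))
  u <- ctx$u_all[cbind(ctx$band_idx, lev)]
  surv_begin <- cumprod(c(1, (1 - ctx$p1_year)[-ctx$T]))
  sum(surv_begin * u)
}

#' Simulate a cohort and summarise its QALE
#'
#' Simulates `n` individuals of one stratum and cohort arm on independent,
#' reproducible substreams derived from the master seed. Matched individuals
#' of the two arms (same stratum, same index) share mortality draws, so
#' paired comparisons are common-random-number coupled.
#'
#' @param ethnicity,sex,age_band Stratum (cohorts start at the band midpoint).
#' @param oa_status `"oa"` or `"no_oa"`.
#' @param n Number of individuals (>= 1).
#' @param tables,params As in [simulate_individual()].
#' @param seed Master seed.
#' @param return_individuals Keep the per-individual QALY vector?
#' @return A list (`cohort_result`): stratum fields, `oa_status`, `n`,
#'   `mean_qalys`, `se_qalys` (0 when `n = 1`), and optionally `qalys`.
#' @export
simulate_cohort <- function(ethnicity, sex, age_band,
                            oa_status = c("oa", "no_oa"), n, tables,
                            params = pain_model_params(), seed = 1L,
                            return_individuals = FALSE) {
  oa_status <- match.arg(oa_status)
  st <- check_stratum(ethnicity, sex, age_band)
  if (n < 1) stop("n must be at least 1")
  g <- strata_grid()
  stratum_id <- which(g$ethnicity == st$ethnicity & g$sex == st$sex &
                        g$age_band == st$age_band)
  ctx <- sim_context(band_start_age(st$age_band) + 2L, st$ethnicity, st$sex, tables)
  oa <- oa_status == "oa"
  q <- vapply(seq_len(n), function(i) {
    sim_one(ctx, oa, params, derive_seed(seed, stratum_id, i))
  }, numeric(1))
  res <- list(ethnicity = st$ethnicity, sex = st$sex, age_band = st$age_band,
              oa_status = oa_status, n = as.integer(n), mean_qalys = mean(q),
              se_qalys = if (n > 1) stats::sd(q) / sqrt(n) else 0)
  if (return_individuals) res$qalys <- q
  structure(res, class = "cohort_result")
}

# all 36 strata x both arms -> data.frame of cohort results
simulate_all_cohorts <- function(tables, params, n_per_stratum, seed) {
  g <- strata_grid()
  rows <- vector("list", 2L * nrow(g))
  k <- 0L
  for (arm in c("no_oa", "oa")) {
    for (i in seq_len(nrow(g))) {
      r <- simulate_cohort(g$ethnicity[i], g$sex[i], g$age_band[i], arm,
                           n_per_stratum, tables, params, seed)
      k <- k + 1L
      rows[[k]] <- as.data.frame(unclass(r), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
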