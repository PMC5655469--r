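#' Probabilistic sensitivity analysis
#'
#' The key structural assumption is the moderate/severe split of pain in
#' people *without* knee OA (base case: 90% moderate). `run_psa()` samples
#' that share from a uniform prior and re-evaluates the burden pipeline per
#' draw under common random numbers: the share enters only through the
#' non-OA pain-level thresholds, so the OA cohorts are simulated once and
#' the no-OA cohorts' parameter-independent structure (death year, band
#' occupancy, per-band pain uniforms) is precomputed and re-thresholded per
#' draw — exactly a full re-run with shared individual streams, but cheap.
#'
#' @name psa
NULL

# Parameter-independent no-OA cohort structure for all 36 strata: one long
# table of (stratum, individual, band, years-in-band, pain uniform).
precompute_no_oa <- function(tables, params, n_per_stratum, seed) {
  g <- strata_grid()
  acc <- vector("list", nrow(g))
  for (s in seq_len(nrow(g))) {
    ctx <- sim_context(band_start_age(g$age_band[s]) + 2L,
                       g$ethnicity[s], g$sex[s], tables)
    res <- lapply(seq_len(n_per_stratum), function(i) {
      sim_one(ctx, oa = FALSE, params, derive_seed(seed, s, i), detail = TRUE)
    })
    nb <- vapply(res, function(r) length(r$bands), integer(1))
    acc[[s]] <- data.frame(
      stratum = s,
      ind = rep(seq_len(n_per_stratum), nb),
      band = unlist(lapply(res, `[[`, "bands")),
      yrs = unlist(lapply(res, `[[`, "years_in_band")),
      u_draw = unlist(lapply(res, `[[`, "u_draw"))
    )
  }
  long <- do.call(rbind, acc)
  ctx0 <- sim_context(42L, g$ethnicity[1], g$sex[1], tables)
  list(long = long, n = n_per_stratum, n_strata = nrow(g),
       u_all = ctx0$u_all, p_pain_band = ctx0$p_pain_band,
       base_moderate_share = ctx0$moderate_share)
}

# mean no-OA QALE per stratum at a given moderate share (vector of 36)
no_oa_qale_at <- function(pre, moderate_share) {
  lg <- pre$long
  lev <- match(non_oa_level_from_uniform(lg$u_draw, pre$p_pain_band[lg$band],
                                         moderate_share), PAIN_LEVELS)
  contrib <- lg$yrs * pre$u_all[cbind(lg$band, lev)]
  gid <- (lg$stratum - 1L) * pre$n + lg$ind
  per_ind <- rowsum(contrib, gid)  # every individual contributes >= 1 row
  colMeans(matrix(per_ind[order(as.integer(rownames(per_ind)))],
                  nrow = pre$n, ncol = pre$n_strata))
}

# group + total per-person losses given per-stratum QALE vectors
losses_from_qale <- function(qale_no, qale_oa, prevalence, population) {
  g <- strata_grid()
  cohorts <- rbind(
    data.frame(g, oa_status = "no_oa", mean_qalys = qale_no),
    data.frame(g, oa_status = "oa", mean_qalys = qale_oa)
  )
  bt <- build_burden_tables(cohorts, prevalence, population)
  stats::setNames(bt$summary$per_person_loss,
                  paste(bt$summary$ethnicity, bt$summary$sex, sep = "."))
}

#' Run the probabilistic sensitivity analysis
#'
#' @param tables List with `utility`, `life_table`, `pain_curve` (the
#'   curve's `moderate_share` is the base case).
#' @param prevalence A [prevalence_table()] (the PPV-adjusted base case).
#' @param population A [population_counts()].
#' @param params A [pain_model_params()].
#' @param n_per_stratum Individuals per stratum per arm.
#' @param n_draws Number of prior draws (>= 2; default 500).
#' @param moderate_share_prior Uniform prior bounds for the non-OA moderate
#'   pain share (default `c(0.80, 1.00)`).
#' @param interval_level Coverage of the empirical uncertainty interval
#'   (default 0.95; endpoints are linearly interpolated order statistics).
#' @param prevalence_mode `"ppv_adjusted"` (use `prevalence` as given),
#'   `"unadjusted"` (divide by `ppv` first), or `"sample_both"` (each draw
#'   picks a mode with probability 1/2).
#' @param ppv Positive predictive value(s) used by the unadjusted mode.
#' @param seed Master seed (simulation streams and prior draws).
#' @return An `oa_psa` object: `draws` (per-draw losses by group), `point`
#'   (base-case losses), `interval` (lower/upper per group), plus settings.
#' @export
run_psa <- function(tables, prevalence, population,
                    params = pain_model_params(), n_per_stratum = 300,
                    n_draws = 500, moderate_share_prior = c(0.80, 1.00),
                    interval_level = 0.95,
                    prevalence_mode = c("ppv_adjusted", "unadjusted", "sample_both"),
                    ppv = 0.9, seed = 1L) {
  prevalence_mode <- match.arg(prevalence_mode)
  if (n_draws < 2) stop("n_draws must be at least 2")
  if (length(moderate_share_prior) != 2 ||
      moderate_share_prior[1] > moderate_share_prior[2] ||
      any(moderate_share_prior < 0 | moderate_share_prior > 1)) {
    stop("moderate_share_prior must be an interval within [0, 1]")
  }
  if (interval_level <= 0 || interval_level >= 1) {
    stop("interval_level must lie in (0, 1)")
  }
  prev_adj <- prevalence
  prev_unadj <- adjust_prevalence(prevalence, ppv, "unadjust")

  oa_cohorts <- simulate_all_cohorts(tables, params, n_per_stratum, seed)
  oa_qale <- oa_cohorts$mean_qalys[oa_cohorts$oa_status == "oa"]
  base_no_qale <- oa_cohorts$mean_qalys[oa_cohorts$oa_status == "no_oa"]
  pre <- precompute_no_oa(tables, params, n_per_stratum, seed)

  set.seed(derive_aux_seed(seed, 1))
  m_draws <- stats::runif(n_draws, moderate_share_prior[1], moderate_share_prior[2])
  mode_draws <- if (prevalence_mode == "sample_both") {
    ifelse(stats::runif(n_draws) < 0.5, "ppv_adjusted", "unadjusted")
  } else rep(prevalence_mode, n_draws)

  draws <- t(vapply(seq_len(n_draws), function(d) {
    qno <- no_oa_qale_at(pre, m_draws[d])
    pv <- if (mode_draws[d] == "ppv_adjusted") prev_adj else prev_unadj
    losses_from_qale(qno, oa_qale, pv, population)
  }, numeric(5)))

  base_prev <- if (prevalence_mode == "unadjusted") prev_unadj else prev_adj
  point <- losses_from_qale(base_no_qale, oa_qale, base_prev, population)
  alpha <- (1 - interval_level) / 2
  interval <- apply(draws, 2, stats::quantile, probs = c(alpha, 1 - alpha),
                    names = FALSE, type = 7)
  dimnames(interval) <- list(c("lower", "upper"), colnames(draws))
  structure(list(draws = draws, sampled_moderate_share = m_draws,
                 sampled_mode = mode_draws, point = point,
                 interval = interval, interval_level = interval_level,
                 moderate_share_prior = moderate_share_prior,
                 base_moderate_share = pre$base_moderate_share,
                 n_draws = n_draws, n_per_stratum = n_per_stratum,
                 prevalence_mode = prevalence_mode, seed = seed),
            class = "oa_psa")
}

#' @export
print.oa_psa <- function(x, ...) {
  cat("Probabilistic sensitivity analysis (", x$n_draws, " draws, ",
      x$n_per_stratum, " individuals/stratum)\n", sep = "")
  cat("Non-OA moderate-pain share ~ Uniform(",
      x$moderate_share_prior[1], ", ", x$moderate_share_prior[2],
      "); base case ", x$base_moderate_share, "\n", sep = "")
  lev <- paste0(format(100 * x$interval_level), "% UI")
  out <- data.frame(point = round(x$point, 3),
                    lower = round(x$interval["lower", ], 3),
                    upper = round(x$interval["upper", ], 3))
  names(out)[2:3] <- paste(lev, c("lower", "upper"))
  print(out, ...)
  invisible(x)
}

#' @export
plot.oa_psa <- function(x, ...) {
  graphics::hist(x$draws[, "all.all"], breaks = 30, main = "PSA draws",
                 xlab = "per-person QALY loss (overall)", ...)
  graphics::abline(v = x$point["all.all"], lwd = 2)
  graphics::abline(v = x$interval[, "all.all"], lty = 2)
  invisible(x)
}

#' Compare PPV-adjusted and unadjusted prevalence modes
#'
#' Builds the burden tables twice from the same cohort QALE: once with the
#' adjusted prevalence surface, once with the raw (unadjusted) one. With any
#' PPV below 1 the unadjusted mode has more prevalent cases everywhere, so
#' its population losses are at least as large in every stratum.
#'
#' @param cohorts Cohort results as in [build_burden_tables()].
#' @param prevalence The adjusted [prevalence_table()].
#' @param population A [population_counts()].
#' @param ppv PPV(s) relating the two surfaces (`raw = adjusted / ppv`).
#' @return List with elements `adjusted` and `unadjusted`, each a
#'   [build_burden_tables()] result.
#' @export
compare_prevalence_modes <- function(cohorts, prevalence, population, ppv = 0.9) {
  list(
    adjusted = build_burden_tables(cohorts, prevalence, population),
    unadjusted = build_burden_tables(
      cohorts, adjust_prevalence(prevalence, ppv, "unadjust"), population)
  )
}
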