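#' From cohort QALE to QALY burden
#'
#' Per-stratum QALE estimates for the with-OA and without-OA cohorts are
#' converted into the headline burden quantities. The per-person loss for a
#' group is the difference between the *counterfactual* QALE — the QALE of
#' people without knee OA, weighted by the age distribution of the people
#' who *have* knee OA — and the (OA-age-weighted) QALE of people with knee
#' OA. Population losses multiply the per-person loss by the number of
#' prevalent cases; whole-group QALE columns are weighted by the full
#' population age distribution.
#'
#' @name burden
NULL

#' Age distribution of prevalent knee OA within a group
#'
#' For one ethnicity x sex group, the weight of each age band is the number
#' of prevalent cases there (`prevalence x count`) normalised over the nine
#' bands.
#'
#' @param prevalence A [prevalence_table()].
#' @param population A [population_counts()].
#' @param ethnicity,sex Group identifiers.
#' @return Named numeric vector of nine weights summing to 1.
#' @export
oa_age_distribution <- function(prevalence, population, ethnicity, sex) {
  ethnicity <- match.arg(ethnicity, ETHNICITIES)
  sex <- match.arg(sex, SEXES)
  pr <- prevalence[prevalence$ethnicity == ethnicity & prevalence$sex == sex, ]
  po <- population[population$ethnicity == ethnicity & population$sex == sex, ]
  bands <- core_age_bands()
  cases <- pr$prevalence[match(bands, pr$age_band)] *
    po$count[match(bands, po$age_band)]
  if (anyNA(cases)) stop("prevalence/population do not cover all bands for ",
                         ethnicity, "/", sex)
  tot <- sum(cases)
  if (tot <= 0) stop("degenerate age distribution: no prevalent cases in ",
                     ethnicity, "/", sex)
  stats::setNames(cases / tot, bands)
}

#' Counterfactual QALE under a band weighting
#'
#' Dot product of band-level no-OA QALE with an age-distribution weight
#' vector (the QALE the OA sub-population would have had without OA).
#'
#' @param qale_no_oa_by_band Named numeric vector of no-OA QALE per band.
#' @param weights Named numeric vector of weights summing to 1.
#' @return Weighted QALE (numeric scalar).
#' @export
counterfactual_qale <- function(qale_no_oa_by_band, weights) {
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  nm <- names(weights)
  if (!is.null(nm) && !is.null(names(qale_no_oa_by_band))) {
    q <- qale_no_oa_by_band[nm]
    if (anyNA(q)) stop("QALE vector lacks band(s): ",
                       paste(nm[is.na(q)], collapse = ", "))
  } else {
    if (length(qale_no_oa_by_band) != length(weights)) {
      stop("QALE and weight vectors have different lengths and no names to align")
    }
    q <- qale_no_oa_by_band
  }
  sum(q * weights)
}

#' Per-person QALY loss
#'
#' @param qale_counterfactual Counterfactual (no-OA, OA-age-weighted) QALE.
#' @param qale_oa QALE of the cohort with knee OA.
#' @return `qale_counterfactual - qale_oa`.
#' @export
per_person_loss <- function(qale_counterfactual, qale_oa) {
  if (any(qale_counterfactual < 0 | qale_oa < 0)) stop("QALE must be non-negative")
  qale_counterfactual - qale_oa
}

#' Population QALY loss
#'
#' @param per_person Per-person QALY loss.
#' @param prevalence Proportion with knee OA, in `[0, 1]`.
#' @param count Persons in the stratum (>= 0).
#' @return `per_person * prevalence * count`.
#' @export
population_loss <- function(per_person, prevalence, count) {
  if (any(prevalence < 0 | prevalence > 1)) stop("prevalence must lie in [0, 1]")
  if (any(count < 0)) stop("count must be non-negative")
  per_person * prevalence * count
}

#' Proportion of counterfactual QALE lost
#'
#' @param per_person Per-person QALY loss.
#' @param qale_counterfactual Counterfactual QALE (> 0).
#' @return `per_person / qale_counterfactual`.
#' @export
proportion_lost <- function(per_person, qale_counterfactual) {
  if (any(qale_counterfactual <= 0)) stop("counterfactual QALE must be positive")
  per_person / qale_counterfactual
}

#' Apply (or undo) positive-predictive-value prevalence adjustment
#'
#' Self-reported prevalence overstates true prevalence; the adjustment
#' multiplies raw values by a PPV. Passing an adjusted table with
#' `direction = "unadjust"` divides instead, recovering the raw surface.
#'
#' @param prevalence A [prevalence_table()].
#' @param ppv Positive predictive value(s) in (0, 1]: a scalar, or a named
#'   vector keyed `"<ethnicity>.<sex>"`.
#' @param direction `"adjust"` (multiply) or `"unadjust"` (divide).
#' @return A [prevalence_table()] with the `adjusted` flag set accordingly.
#' @export
adjust_prevalence <- function(prevalence, ppv = 0.9,
                              direction = c("adjust", "unadjust")) {
  direction <- match.arg(direction)
  stopifnot(inherits(prevalence, "prevalence_table"))
  if (any(unlist(ppv) <= 0 | unlist(ppv) > 1)) stop("PPV must lie in (0, 1]")
  out <- as.data.frame(prevalence)
  p <- if (length(ppv) == 1L) rep(unlist(ppv), nrow(out)) else {
    key <- paste(out$ethnicity, out$sex, sep = ".")
    v <- unlist(ppv)[key]
    if (anyNA(v)) stop("ppv lacks entries for: ",
                       paste(unique(key[is.na(v)]), collapse = ", "))
    v
  }
  out$prevalence <- if (direction == "adjust") out$prevalence * p else
    pmin(1, out$prevalence / p)
  prevalence_table(out, adjusted = direction == "adjust")
}

#' Build the stratified burden tables
#'
#' Combines per-stratum cohort QALE with prevalence and population counts
#' into a per-band table plus ethnicity x sex totals and a grand total. Band
#' rows use the band's own no-OA QALE as counterfactual; aggregate rows
#' weight the no-OA QALE column by the full population age distribution and
#' both the OA QALE and the counterfactual by the prevalent-case age
#' distribution, then difference.
#'
#' @param cohorts Data frame of cohort results (as from repeated
#'   [simulate_cohort()] calls): columns `ethnicity`, `sex`, `age_band`,
#'   `oa_status`, `mean_qalys` — all 36 strata for both arms.
#' @param prevalence A [prevalence_table()].
#' @param population A [population_counts()].
#' @return List with data frames `by_stratum` (36 rows) and `summary`
#'   (four group rows plus an `all`/`all` grand total), both with columns
#'   `qale_no_oa`, `qale_oa`, `qale_counterfactual`, `per_person_loss`,
#'   `n_with_oa`, `population_loss`, `proportion_lost`.
#' @export
build_burden_tables <- function(cohorts, prevalence, population) {
  g <- strata_grid()
  key <- function(d) paste(d$ethnicity, d$sex, d$age_band)
  want <- key(g)
  miss_oa <- setdiff(want, key(cohorts[cohorts$oa_status == "oa", ]))
  miss_no <- setdiff(want, key(cohorts[cohorts$oa_status == "no_oa", ]))
  miss <- c(if (length(miss_oa)) paste0(miss_oa, " [oa]"),
            if (length(miss_no)) paste0(miss_no, " [no_oa]"))
  if (length(miss)) stop("cohort results incomplete; missing: ",
                         paste(miss, collapse = "; "))
  oa <- cohorts[cohorts$oa_status == "oa", ]
  no <- cohorts[cohorts$oa_status == "no_oa", ]
  df <- g
  df$qale_no_oa <- no$mean_qalys[match(want, key(no))]
  df$qale_oa <- oa$mean_qalys[match(want, key(oa))]
  df$prevalence <- prevalence$prevalence[match(want, key(prevalence))]
  df$count <- population$count[match(want, key(population))]
  df$qale_counterfactual <- df$qale_no_oa  # single band: trivial weighting
  df$per_person_loss <- per_person_loss(df$qale_counterfactual, df$qale_oa)
  df$n_with_oa <- df$prevalence * df$count
  df$population_loss <- population_loss(df$per_person_loss, df$prevalence, df$count)
  df$proportion_lost <- proportion_lost(df$per_person_loss, df$qale_counterfactual)

  agg_row <- function(sub, ethnicity, sex) {
    w_pop <- sub$count / sum(sub$count)
    w_oa <- sub$n_with_oa / sum(sub$n_with_oa)
    cf <- sum(w_oa * sub$qale_no_oa)
    q_oa <- sum(w_oa * sub$qale_oa)
    loss <- per_person_loss(cf, q_oa)
    data.frame(
      ethnicity = ethnicity, sex = sex, age_band = "all",
      qale_no_oa = sum(w_pop * sub$qale_no_oa), qale_oa = q_oa,
      qale_counterfactual = cf, per_person_loss = loss,
      n_with_oa = sum(sub$n_with_oa),
      population_loss = sum(sub$population_loss),
      proportion_lost = proportion_lost(loss, cf),
      stringsAsFactors = FALSE)
  }
  groups <- unique(g[c("ethnicity", "sex")])
  summary <- do.call(rbind, c(
    lapply(seq_len(nrow(groups)), function(i) {
      sub <- df[df$ethnicity == groups$ethnicity[i] & df$sex == groups$sex[i], ]
      agg_row(sub, groups$ethnicity[i], groups$sex[i])
    }),
    list(agg_row(df, "all", "all"))
  ))
  rownames(summary) <- NULL
  by_stratum <- df[c("ethnicity", "sex", "age_band", "prevalence", "qale_no_oa",
                     "qale_oa", "qale_counterfactual", "per_person_loss",
                     "n_with_oa", "population_loss", "proportion_lost")]
  list(by_stratum = by_stratum, summary = summary)
}
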