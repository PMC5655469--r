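#' Estimate the lifetime QALY burden of knee osteoarthritis
#'
#' The package's central estimator. Simulates matched cohorts with and
#' without knee OA for each of the 36 strata (nine 5-year age bands from
#' 40-84 x sex x ethnicity), averages individual lifetime QALYs into
#' per-stratum QALE, and assembles the stratified burden tables:
#' counterfactual-weighted QALE, per-person QALY loss, prevalent-case
#' counts, and population QALY losses, with ethnicity x sex totals and a
#' grand total.
#'
#' Any input left `NULL` falls back to the packaged published tables
#' (utilities, prevalence) or the synthetic generators' defaults (life
#' table, population counts, pain curve), so `oa_burden()` runs out of the
#' box.
#'
#' @param n_per_stratum Individuals simulated per stratum per arm.
#' @param seed Master seed; all randomness derives from it.
#' @param utility A [utility_table()] (default: packaged VAS value set).
#' @param life_table A [life_table()] (default: [generate_life_table()]).
#' @param prevalence A [prevalence_table()] (default: packaged, adjusted).
#' @param population A [population_counts()] (default:
#'   [generate_population_counts()]).
#' @param pain_curve A [pain_curve()] (default: [generate_pain_curve()]).
#' @param params A [pain_model_params()].
#' @param value_set `"vas"` uses the utility table as given;
#'   `"transformed"` first applies [transform_value_set()].
#' @param transform_exponent Exponent for the transformed value set.
#' @return An `oa_burden` object: `summary` and `by_stratum` burden tables,
#'   `cohorts` (per-stratum QALE with Monte Carlo standard errors), the
#'   inputs used, and the run settings. Methods: `print`, `summary`, `coef`
#'   (per-person losses), `plot` (loss by age band).
#' @export
#' @examples
#' \donttest{
#' fit <- oa_burden(n_per_stratum = 200, seed = 42)
#' fit
#' coef(fit)
#' }
oa_burden <- function(n_per_stratum = 1000, seed = 1L,
                      utility = NULL, life_table = NULL, prevalence = NULL,
                      population = NULL, pain_curve = NULL,
                      params = pain_model_params(),
                      value_set = c("vas", "transformed"),
                      transform_exponent = 1.61) {
  value_set <- match.arg(value_set)
  if (n_per_stratum < 1) stop("n_per_stratum must be at least 1")
  fx <- NULL
  if (is.null(utility) || is.null(prevalence)) fx <- load_fixture_tables()
  utility <- utility %||% fx$utilities
  prevalence <- prevalence %||% fx$prevalence
  life_table <- life_table %||% generate_life_table()
  population <- population %||% generate_population_counts()
  pain_curve <- pain_curve %||%
    generate_pain_curve(closure_age = attr(life_table, "closure_age"))
  if (value_set == "transformed") {
    utility <- transform_value_set(utility, transform_exponent)
  }
  tables <- list(utility = utility, life_table = life_table,
                 pain_curve = pain_curve)
  cohorts <- simulate_all_cohorts(tables, params, n_per_stratum, seed)
  bt <- build_burden_tables(cohorts, prevalence, population)
  structure(list(summary = bt$summary, by_stratum = bt$by_stratum,
                 cohorts = cohorts,
                 inputs = c(tables, list(prevalence = prevalence,
                                         population = population)),
                 params = params, n_per_stratum = as.integer(n_per_stratum),
                 seed = as.integer(seed), value_set = value_set,
                 transform_exponent = transform_exponent,
                 call = match.call()),
            class = "oa_burden")
}

#' @export
print.oa_burden <- function(x, digits = 3, ...) {
  tot <- x$summary[x$summary$ethnicity == "all", ]
  cat("Lifetime QALY burden of knee osteoarthritis (",
      x$value_set, " value set)\n", sep = "")
  cat("Monte Carlo microsimulation: ", x$n_per_stratum,
      " individuals/stratum/arm, 36 strata, seed ", x$seed, "\n\n", sep = "")
  cat("Per-person QALY loss:  ", round(tot$per_person_loss, digits), "\n")
  cat("Population QALY loss:  ", format(round(tot$population_loss), big.mark = ","),
      " (", format(round(tot$n_with_oa), big.mark = ","), " prevalent cases)\n",
      sep = "")
  cat("Proportion of counterfactual QALE lost: ",
      round(100 * tot$proportion_lost, 1), "%\n\n", sep = "")
  grp <- x$summary[x$summary$ethnicity != "all", ]
  cat("By group (per-person loss):\n")
  print(data.frame(group = paste(grp$ethnicity, grp$sex),
                   loss = round(grp$per_person_loss, digits)), row.names = FALSE)
  invisible(x)
}

#' @export
summary.oa_burden <- function(object, ...) {
  structure(list(summary = object$summary, by_stratum = object$by_stratum,
                 value_set = object$value_set, seed = object$seed,
                 n_per_stratum = object$n_per_stratum),
            class = "summary.oa_burden")
}

#' @export
print.summary.oa_burden <- function(x, digits = 2, ...) {
  cat("Group summary (", x$value_set, " value set):\n", sep = "")
  s <- x$summary
  num <- vapply(s, is.numeric, logical(1))
  s[num] <- lapply(s[num], round, digits)
  print(s, row.names = FALSE)
  cat("\nPer-stratum table: $by_stratum (36 rows)\n")
  invisible(x)
}

#' @export
coef.oa_burden <- function(object, ...) {
  s <- object$summary
  stats::setNames(s$per_person_loss, paste(s$ethnicity, s$sex, sep = "."))
}

#' @export
plot.oa_burden <- function(x, ...) {
  df <- x$by_stratum
  bands <- core_age_bands()
  groups <- unique(df[c("ethnicity", "sex")])
  m <- sapply(seq_len(nrow(groups)), function(i) {
    sub <- df[df$ethnicity == groups$ethnicity[i] & df$sex == groups$sex[i], ]
    sub$per_person_loss[match(bands, sub$age_band)]
  })
  graphics::matplot(seq_along(bands), m, type = "b", pch = 1:4, lty = 1,
                    xaxt = "n", xlab = "age band",
                    ylab = "per-person QALY loss", ...)
  graphics::axis(1, at = seq_along(bands), labels = bands, las = 2)
  graphics::legend("topright", legend = paste(groups$ethnicity, groups$sex),
                   pch = 1:4, col = 1:4, lty = 1, bty = "n")
  invisible(x)
}
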