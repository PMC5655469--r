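# Shared fixtures: the packaged tables plus small constructed inputs used by
# degenerate-configuration oracles. Everything here is built in code.

FIX <- load_fixture_tables()
LT_DEFAULT <- generate_life_table()
PC_DEFAULT <- generate_pain_curve()
POP_DEFAULT <- generate_population_counts()
CLOSURE <- attr(LT_DEFAULT, "closure_age")

default_tables <- function() {
  list(utility = FIX$utilities, life_table = LT_DEFAULT, pain_curve = PC_DEFAULT)
}

# identical utilities in every band
flat_utility <- function(u_none = 0.9, u_mod = 0.6, u_sev = 0.3) {
  utility_table(data.frame(
    age_band = rep(core_age_bands(), each = 3),
    level = rep(c("none", "moderate", "severe"), 9),
    value = rep(c(u_none, u_mod, u_sev), 9)
  ))
}

# constant 5-year death probability in every non-closure band
const_life_table <- function(p5, closure_age = 110L) {
  bands <- all_age_bands(closure_age)
  rows <- expand.grid(age_band = bands, sex = c("male", "female"),
                      ethnicity = c("non_maori", "maori"),
                      stringsAsFactors = FALSE)
  rows$p_death_5yr <- ifelse(grepl("\\+$", rows$age_band), 1, p5)
  life_table(rows, closure_age = closure_age)
}

# constant non-OA pain prevalence across bands
const_pain_curve <- function(p, moderate_share = 0.9, closure_age = 110L) {
  pain_curve(data.frame(age_band = all_age_bands(closure_age), p_in_pain = p),
             moderate_share = moderate_share, closure_age = closure_age)
}

uniform_prevalence <- function(p = 0.1) {
  g <- strata_grid()
  g$prevalence <- p
  prevalence_table(g)
}

uniform_population <- function(count = 1000) {
  g <- strata_grid()
  g$count <- count
  population_counts(g)
}

# deterministic WOMAC pain parameters (all SDs zero)
det_params <- function(init = 30, inc = 0.5) {
  pain_model_params(init_mean = init, init_sd = 0,
                    annual_increment_mean = inc, annual_increment_sd = 0)
}

# per-year pain levels of the deterministic OA trajectory from a start age
det_oa_levels <- function(start_age, params, closure_age = CLOSURE) {
  t <- seq_len(closure_age - start_age + 1)
  womac <- pmin(100, pmax(0, params$init_mean +
                            params$annual_increment_mean * (t - 1)))
  categorize_pain(womac)
}
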