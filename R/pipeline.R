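#' End-to-end pipeline
#'
#' `run_pipeline()` drives the whole analysis from a single configuration:
#' generate or load the four input tables, simulate all cohorts, build the
#' burden tables, optionally run the PSA, and write every result as plain
#' CSV plus a run-metadata JSON (seed, config hash, package version). All
#' randomness flows from the one master seed, so a fixed seed reproduces
#' every output byte for byte.
#'
#' @name pipeline
NULL

#' Default run configuration
#'
#' @return Nested list mirroring the YAML layout: blocks `inputs` (CSV paths
#'   or `NULL` for synthetic/fixture fallbacks), `synthetic` (generator
#'   parameters), `valuation` (`value_set`, `transform_exponent`), `pain`
#'   (pain-model overrides), `simulation` (`n_per_stratum`), `psa`
#'   (`enabled`, `n_draws`, `moderate_share_prior`, `interval_level`,
#'   `n_per_stratum`, `prevalence_mode`, `ppv`), and `seed`.
#' @export
default_run_config <- function() {
  list(
    inputs = list(utilities = NULL, prevalence = NULL, life_table = NULL,
                  population = NULL, pain_curve = NULL),
    synthetic = list(
      life_table = list(gompertz_shape = DEFAULT_GOMPERTZ_SHAPE,
                        closure_age = 110L),
      population = list(total = 1900000, age_decay = 0.85,
                        sex_split = 0.51, maori_share = 0.13),
      pain_curve = list(p_age40 = 0.30, p_age85 = 0.55, moderate_share = 0.90)
    ),
    valuation = list(value_set = "vas", transform_exponent = 1.61),
    pain = list(),
    simulation = list(n_per_stratum = 1000L),
    psa = list(enabled = FALSE, n_draws = 500L,
               moderate_share_prior = c(0.80, 1.00), interval_level = 0.95,
               n_per_stratum = 300L, prevalence_mode = "ppv_adjusted",
               ppv = 0.9),
    seed = 1L
  )
}

#' Read a run configuration from YAML
#'
#' Values given in the file override the defaults block-wise; unknown keys
#' are rejected so typos fail loudly.
#'
#' @param path Path to a YAML file.
#' @return A configuration list as in [default_run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  merge_config(default_run_config(), user, "")
}

merge_config <- function(base, user, where) {
  if (!is.list(user)) return(user)
  unknown <- setdiff(names(user), names(base))
  if (length(unknown)) {
    stop("unknown config field(s)", if (nzchar(where)) paste0(" in '", where, "'"),
         ": ", paste(unknown, collapse = ", "))
  }
  for (k in names(user)) {
    base[[k]] <- if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      merge_config(base[[k]], user[[k]], paste0(where, if (nzchar(where)) ".", k))
    } else user[[k]]
  }
  base
}

load_or_generate_inputs <- function(config) {
  ip <- config$inputs
  for (nm in names(ip)) {
    if (!is.null(ip[[nm]]) && !file.exists(ip[[nm]])) {
      stop("configured input '", nm, "' not found: ", ip[[nm]])
    }
  }
  syn <- config$synthetic
  fx <- if (is.null(ip$utilities) || is.null(ip$prevalence)) load_fixture_tables()
  utility <- if (!is.null(ip$utilities)) {
    utility_table(read_table(ip$utilities, "utility"))
  } else fx$utilities
  prevalence <- if (!is.null(ip$prevalence)) {
    prevalence_table(read_table(ip$prevalence, "prevalence"), adjusted = TRUE)
  } else fx$prevalence
  closure <- as.integer(syn$life_table$closure_age %||% 110L)
  lt <- if (!is.null(ip$life_table)) {
    life_table(read_table(ip$life_table, "life_table"), closure_age = closure)
  } else {
    generate_life_table(
      gompertz_level = syn$life_table$gompertz_level %||% DEFAULT_GOMPERTZ_LEVEL,
      gompertz_shape = syn$life_table$gompertz_shape, closure_age = closure)
  }
  pop <- if (!is.null(ip$population)) {
    population_counts(read_table(ip$population, "population"))
  } else {
    do.call(generate_population_counts, syn$population)
  }
  pc <- if (!is.null(ip$pain_curve)) {
    pain_curve(read_table(ip$pain_curve, "pain_curve"),
               moderate_share = syn$pain_curve$moderate_share %||% 0.90,
               closure_age = closure)
  } else {
    do.call(generate_pain_curve, c(syn$pain_curve, list(closure_age = closure)))
  }
  list(utility = utility, prevalence = prevalence, life_table = lt,
       population = pop, pain_curve = pc)
}

#' Run the full analysis pipeline
#'
#' @param config A configuration list ([default_run_config()]), or a path to
#'   a YAML file ([read_run_config()]), or `NULL` for pure defaults.
#' @param out_dir Output directory (created if absent).
#' @param seed Optional override of the config's master seed.
#' @return The fitted [oa_burden()] object, invisibly. Side effects: writes
#'   `life_table.csv`, `population.csv`, `prevalence.csv`, `pain_curve.csv`,
#'   `cohort_results.csv`, `burden_by_stratum.csv`, `burden_summary.csv`,
#'   `psa_draws.csv` / `psa_summary.csv` (when PSA is enabled), and
#'   `run_metadata.json` under `out_dir`.
#' @export
run_pipeline <- function(config = NULL, out_dir, seed = NULL) {
  config <- if (is.null(config)) default_run_config()
  else if (is.character(config)) read_run_config(config)
  else merge_config(default_run_config(), config, "")
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  t0 <- proc.time()["elapsed"]
  inputs <- load_or_generate_inputs(config)
  message(sprintf("[inputs] loaded/generated in %.1fs",
                  proc.time()["elapsed"] - t0))
  write_table(inputs$life_table, file.path(out_dir, "life_table.csv"))
  write_table(inputs$population, file.path(out_dir, "population.csv"))
  write_table(inputs$prevalence, file.path(out_dir, "prevalence.csv"))
  write_table(inputs$pain_curve, file.path(out_dir, "pain_curve.csv"))

  params <- do.call(pain_model_params, config$pain)
  t1 <- proc.time()["elapsed"]
  fit <- oa_burden(
    n_per_stratum = config$simulation$n_per_stratum, seed = config$seed,
    utility = inputs$utility, life_table = inputs$life_table,
    prevalence = inputs$prevalence, population = inputs$population,
    pain_curve = inputs$pain_curve, params = params,
    value_set = config$valuation$value_set,
    transform_exponent = config$valuation$transform_exponent)
  message(sprintf("[simulate] %d strata x 2 arms x %d individuals in %.1fs",
                  36L, as.integer(config$simulation$n_per_stratum),
                  proc.time()["elapsed"] - t1))
  write_table(format_num(fit$cohorts), file.path(out_dir, "cohort_results.csv"))
  write_table(format_num(fit$by_stratum), file.path(out_dir, "burden_by_stratum.csv"))
  write_table(format_num(fit$summary), file.path(out_dir, "burden_summary.csv"))

  psa_res <- NULL
  if (isTRUE(config$psa$enabled)) {
    t2 <- proc.time()["elapsed"]
    tables <- fit$inputs[c("utility", "life_table", "pain_curve")]
    psa_res <- run_psa(
      tables, inputs$prevalence, inputs$population, params,
      n_per_stratum = config$psa$n_per_stratum, n_draws = config$psa$n_draws,
      moderate_share_prior = config$psa$moderate_share_prior,
      interval_level = config$psa$interval_level,
      prevalence_mode = config$psa$prevalence_mode, ppv = config$psa$ppv,
      seed = config$seed)
    message(sprintf("[psa] %d draws in %.1fs", as.integer(config$psa$n_draws),
                    proc.time()["elapsed"] - t2))
    draws_df <- data.frame(draw = seq_len(psa_res$n_draws),
                           moderate_share = psa_res$sampled_moderate_share,
                           prevalence_mode = psa_res$sampled_mode,
                           psa_res$draws, check.names = FALSE)
    write_table(format_num(draws_df), file.path(out_dir, "psa_draws.csv"))
    psa_sum <- data.frame(group = colnames(psa_res$draws),
                          point = psa_res$point,
                          lower = psa_res$interval["lower", ],
                          upper = psa_res$interval["upper", ])
    rownames(psa_sum) <- NULL
    write_table(format_num(psa_sum), file.path(out_dir, "psa_summary.csv"))
  }

  meta <- list(seed = config$seed, config_md5 = config_hash(config),
               package = "oaburden",
               version = as.character(utils::packageVersion("oaburden")),
               r_version = paste(R.version$major, R.version$minor, sep = "."),
               n_per_stratum = as.integer(config$simulation$n_per_stratum),
               value_set = config$valuation$value_set,
               psa_enabled = isTRUE(config$psa$enabled))
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(fit)
}

# round-trippable fixed-precision formatting so re-runs are byte-identical
format_num <- function(df, digits = 10) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, digits))
  df
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(config), tmp)
  unname(tools::md5sum(tmp))
}
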