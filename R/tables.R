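#' Input tables
#'
#' All model inputs are small, plain CSV tables keyed by stratum fields:
#' an age-band x pain-level utility table, a life table of 5-year death
#' probabilities, knee-OA prevalence by stratum, population counts by
#' stratum, and an age-band curve of pain prevalence in the population
#' without knee OA. `read_table()` / `write_table()` validate against the
#' schemas below and report violations with row numbers.
#'
#' @name tables
NULL

PAIN_LEVELS <- c("none", "moderate", "severe")

TABLE_SCHEMAS <- list(
  utility = list(
    columns = c("age_band", "level", "value"),
    numeric = c(value = NA),
    range = list(value = c(0, 1))
  ),
  life_table = list(
    columns = c("ethnicity", "sex", "age_band", "p_death_5yr"),
    numeric = c(p_death_5yr = NA),
    range = list(p_death_5yr = c(0, 1))
  ),
  population = list(
    columns = c("ethnicity", "sex", "age_band", "count"),
    numeric = c(count = NA),
    range = list(count = c(0, Inf))
  ),
  prevalence = list(
    columns = c("ethnicity", "sex", "age_band", "prevalence"),
    numeric = c(prevalence = NA),
    range = list(prevalence = c(0, 1))
  ),
  pain_curve = list(
    columns = c("age_band", "p_in_pain"),
    numeric = c(p_in_pain = NA),
    range = list(p_in_pain = c(0, 1))
  )
)

#' Construct a utility table
#'
#' Health-related quality of life (utility) by 5-year age band and pain
#' level, on the dead = 0 / perfect health = 1 scale. One row per
#' (band, level); all nine core bands and all three levels must be present,
#' and within every band utilities must be ordered
#' none >= moderate >= severe.
#'
#' @param df Data frame with columns `age_band`, `level`, `value`.
#' @param value_set Which valuation the values come from: `"vas"`
#'   (visual-analog-scale value set) or `"transformed"` (trade-off
#'   approximating transform, see [transform_value_set()]).
#' @return A `utility_table` data frame (attribute `value_set`).
#' @export
utility_table <- function(df, value_set = c("vas", "transformed")) {
  value_set <- match.arg(value_set)
  stopifnot(all(c("age_band", "level", "value") %in% names(df)))
  df$age_band <- normalize_age_band(df$age_band)
  df$level <- as.character(df$level)
  if (!all(df$level %in% PAIN_LEVELS)) {
    stop("utility table levels must be one of: ", paste(PAIN_LEVELS, collapse = ", "))
  }
  need <- expand.grid(age_band = core_age_bands(), level = PAIN_LEVELS,
                      stringsAsFactors = FALSE)
  key <- paste(df$age_band, df$level)
  miss <- setdiff(paste(need$age_band, need$level), key)
  if (length(miss)) stop("utility table missing cells: ", paste(miss, collapse = "; "))
  if (anyDuplicated(key)) stop("utility table has duplicate (age_band, level) rows")
  if (any(df$value < 0 | df$value > 1)) stop("utilities must lie in [0, 1]")
  m <- utility_matrix_core(df)
  if (any(m[, "none"] < m[, "moderate"] | m[, "moderate"] < m[, "severe"])) {
    stop("utility ordering violated: need none >= moderate >= severe in every band")
  }
  out <- df[order(match(df$age_band, core_age_bands()), match(df$level, PAIN_LEVELS)),
            c("age_band", "level", "value")]
  rownames(out) <- NULL
  structure(out, value_set = value_set, class = c("utility_table", "data.frame"))
}

# 9 x 3 matrix (rows = core bands, cols = none/moderate/severe)
utility_matrix_core <- function(df) {
  m <- matrix(NA_real_, 9, 3, dimnames = list(core_age_bands(), PAIN_LEVELS))
  m[cbind(match(df$age_band, core_age_bands()), match(df$level, PAIN_LEVELS))] <- df$value
  m
}

#' Construct a life table
#'
#' Probability of death within five years, by ethnicity, sex, and 5-year age
#' band, for every band from 40-44 up to the closure band, where the
#' probability must equal 1 so that simulated lifetimes are finite. Within
#' each ethnicity x sex group the probabilities must be non-decreasing in age.
#'
#' @param df Data frame with columns `ethnicity`, `sex`, `age_band`,
#'   `p_death_5yr`.
#' @param closure_age Age at which the table closes (default 110).
#' @return A `life_table` data frame (attribute `closure_age`).
#' @export
life_table <- function(df, closure_age = 110L) {
  stopifnot(all(c("ethnicity", "sex", "age_band", "p_death_5yr") %in% names(df)))
  bands <- all_age_bands(closure_age)
  df$age_band <- normalize_age_band(df$age_band)
  for (e in ETHNICITIES) for (s in SEXES) {
    sub <- df[df$ethnicity == e & df$sex == s, ]
    p <- sub$p_death_5yr[match(bands, sub$age_band)]
    if (anyNA(p)) {
      stop("life table for ", e, "/", s, " missing bands: ",
           paste(bands[is.na(p)], collapse = ", "))
    }
    if (any(p < 0 | p > 1)) stop("death probabilities must lie in [0, 1]")
    if (any(diff(p) < 0)) stop("death probabilities must be non-decreasing in age (", e, "/", s, ")")
    if (p[length(p)] != 1) stop("closure band probability must equal 1 (", e, "/", s, ")")
  }
  ord <- order(match(df$ethnicity, ETHNICITIES), match(df$sex, SEXES),
               match(df$age_band, bands))
  out <- df[ord, c("ethnicity", "sex", "age_band", "p_death_5yr")]
  rownames(out) <- NULL
  structure(out, closure_age = as.integer(closure_age),
            class = c("life_table", "data.frame"))
}

#' Construct a stratum-keyed prevalence table
#'
#' Knee-OA prevalence (proportion in `[0, 1]`) for each of the 36 strata.
#'
#' @param df Data frame with columns `ethnicity`, `sex`, `age_band`,
#'   `prevalence`.
#' @param adjusted Logical; whether positive-predictive-value adjustment for
#'   self-report bias has been applied (see [adjust_prevalence()]).
#' @return A `prevalence_table` data frame (attribute `adjusted`).
#' @export
prevalence_table <- function(df, adjusted = FALSE) {
  out <- check_stratum_table(df, "prevalence")
  if (any(out$prevalence < 0 | out$prevalence > 1)) {
    stop("prevalence must lie in [0, 1]")
  }
  structure(out, adjusted = isTRUE(adjusted),
            class = c("prevalence_table", "data.frame"))
}

#' Construct a population-count table
#'
#' Census-style person counts per stratum (non-negative; positive in total).
#'
#' @param df Data frame with columns `ethnicity`, `sex`, `age_band`, `count`.
#' @return A `population_counts` data frame.
#' @export
population_counts <- function(df) {
  out <- check_stratum_table(df, "count")
  if (any(out$count < 0)) stop("population counts must be non-negative")
  if (sum(out$count) <= 0) stop("total population count must be positive")
  structure(out, class = c("population_counts", "data.frame"))
}

check_stratum_table <- function(df, value_col) {
  need <- c("ethnicity", "sex", "age_band", value_col)
  stopifnot(all(need %in% names(df)))
  df$age_band <- normalize_age_band(df$age_band)
  key <- paste(df$ethnicity, df$sex, df$age_band)
  g <- strata_grid()
  want <- paste(g$ethnicity, g$sex, g$age_band)
  miss <- setdiff(want, key)
  if (length(miss)) stop("missing strata: ", paste(miss, collapse = "; "))
  out <- df[match(want, key), need]
  rownames(out) <- NULL
  out
}

#' Construct a non-OA pain prevalence curve
#'
#' For the population without knee OA: the proportion of each age band in any
#' pain, and the share of those in pain whose pain is moderate (the remainder
#' severe). The curve must cover every band up to the life-table closure age.
#'
#' @param df Data frame with columns `age_band`, `p_in_pain`.
#' @param moderate_share Proportion of those in pain who are in moderate (vs
#'   severe) pain; default 0.90.
#' @param closure_age Closure age the curve must cover (default 110).
#' @return A `pain_curve` data frame (attributes `moderate_share`,
#'   `closure_age`).
#' @export
pain_curve <- function(df, moderate_share = 0.90, closure_age = 110L) {
  stopifnot(all(c("age_band", "p_in_pain") %in% names(df)))
  if (moderate_share < 0 || moderate_share > 1) stop("moderate_share must lie in [0, 1]")
  df$age_band <- normalize_age_band(df$age_band)
  bands <- all_age_bands(closure_age)
  p <- df$p_in_pain[match(bands, df$age_band)]
  if (anyNA(p)) {
    stop("pain curve missing bands: ", paste(bands[is.na(p)], collapse = ", "))
  }
  if (any(p < 0 | p > 1)) stop("p_in_pain must lie in [0, 1]")
  out <- data.frame(age_band = bands, p_in_pain = p)
  structure(out, moderate_share = moderate_share,
            closure_age = as.integer(closure_age),
            class = c("pain_curve", "data.frame"))
}

#' Read a validated input table from CSV
#'
#' Tolerates CRLF line endings and a UTF-8 byte-order mark; age-band labels
#' are dash-normalised. Schema violations (missing columns, non-numeric
#' cells, out-of-range values) are reported with row numbers.
#'
#' @param path Path to a CSV file.
#' @param schema One of `"utility"`, `"life_table"`, `"population"`,
#'   `"prevalence"`, `"pain_curve"`.
#' @return A validated data frame (plain; wrap with the matching constructor
#'   for class semantics).
#' @export
read_table <- function(path, schema) {
  schema <- match.arg(schema, names(TABLE_SCHEMAS))
  if (!file.exists(path)) stop("input file not found: ", path)
  sch <- TABLE_SCHEMAS[[schema]]
  txt <- read_text_normalized(path)
  df <- utils::read.csv(text = txt, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = TRUE)
  miss <- setdiff(sch$columns, names(df))
  if (length(miss)) {
    stop("file ", path, " lacks required column(s): ", paste(miss, collapse = ", "))
  }
  df <- df[sch$columns]
  if ("age_band" %in% names(df)) df$age_band <- normalize_age_band(df$age_band)
  for (col in names(sch$numeric)) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad)) {
      stop("file ", path, ", column '", col, "': non-numeric value at data row(s) ",
           paste(bad, collapse = ", "))
    }
    rng <- sch$range[[col]]
    out_of <- which(v < rng[1] | v > rng[2])
    if (length(out_of)) {
      stop("file ", path, ", column '", col, "': value outside [", rng[1], ", ",
           rng[2], "] at data row(s) ", paste(out_of, collapse = ", "))
    }
    df[[col]] <- v
  }
  df
}

# strip UTF-8 BOM and CR so dialects parse identically
read_text_normalized <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) >= 3 && identical(raw[1:3], as.raw(c(0xEF, 0xBB, 0xBF)))) {
    raw <- raw[-(1:3)]
  }
  txt <- rawToChar(raw)
  Encoding(txt) <- "UTF-8"
  gsub("\r", "", txt, fixed = TRUE)
}

#' Write a table to CSV
#'
#' Plain unquoted CSV with LF line endings; byte-identical output for
#' identical input, so fixed-seed runs round-trip exactly.
#'
#' @param table Data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_table <- function(table, path) {
  write_csv_plain(as.data.frame(table), path)
}

FIXTURE_MD5 <- c(
  table1_utilities.csv = "228e786bb8f31d9a4e55d0902d288a60",
  table2_prevalence.csv = "b78b390cdec8d38c357a610571ce40af",
  reference_qale_summary.csv = "2577015658a3eb089a835365d6555794",
  reference_qale_by_stratum.csv = "71bc4c0829eed15ed633682ac8c1ec6d"
)

fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "oaburden")
  if (p == "") stop("fixture ", name, " is missing from the installed package")
  expected <- FIXTURE_MD5[[name]]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeBin(charToRaw(read_text_normalized(p)), tmp)
  actual <- unname(tools::md5sum(tmp))
  if (!identical(actual, expected)) {
    stop("fixture ", name, " failed its integrity check: md5 ", actual,
         ", expected ", expected)
  }
  p
}

#' Load the packaged utility and prevalence fixtures
#'
#' The published New Zealand inputs shipped with the package: EQ-5D (VAS
#' value set) utilities by age band and pain level, and PPV-adjusted knee-OA
#' prevalence by stratum. Files are verified against stored md5 checksums.
#'
#' @return A list with elements `utilities` (a [utility_table()]) and
#'   `prevalence` (a [prevalence_table()], adjusted).
#' @export
#' @examples
#' tabs <- load_fixture_tables()
#' subset(tabs$utilities, age_band == "60-64")
load_fixture_tables <- function() {
  ut <- read_table(fixture_path("table1_utilities.csv"), "utility")
  pr <- utils::read.csv(text = read_text_normalized(fixture_path("table2_prevalence.csv")),
                        stringsAsFactors = FALSE)
  pr$prevalence <- pr$prevalence_pct / 100
  list(
    utilities = utility_table(ut, value_set = "vas"),
    prevalence = prevalence_table(pr[c("ethnicity", "sex", "age_band", "prevalence")],
                                  adjusted = TRUE)
  )
}

#' Load the published reference QALE / loss tables
#'
#' Reference quality-adjusted life expectancy and QALY-loss values for the
#' New Zealand adult population, shipped as fixtures: a per-stratum table
#' (36 rows) and an ethnicity-x-sex summary with a grand-total row. Used to
#' validate the burden arithmetic against published values.
#'
#' @return A list with elements `by_stratum` and `summary` (data frames).
#' @export
load_reference_qale <- function() {
  by_stratum <- utils::read.csv(
    text = read_text_normalized(fixture_path("reference_qale_by_stratum.csv")),
    stringsAsFactors = FALSE)
  summary <- utils::read.csv(
    text = read_text_normalized(fixture_path("reference_qale_summary.csv")),
    stringsAsFactors = FALSE)
  by_stratum$age_band <- normalize_age_band(by_stratum$age_band)
  list(by_stratum = by_stratum, summary = summary)
}
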