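#' Population strata
#'
#' The modelled population is tiled by 36 strata: nine contiguous 5-year age
#' bands covering ages 40-84, crossed with sex (male/female) and ethnicity
#' (Maori / non-Maori). Simulated individuals age past 84, so internal tables
#' (life table, pain curve) extend over further 5-year bands up to the life
#' table's closure age, where the death probability is forced to 1.
#'
#' @name strata
NULL

SEXES <- c("male", "female")
ETHNICITIES <- c("non_maori", "maori")

#' Core 5-year age band labels (ages 40-84)
#'
#' @return Character vector of the nine band labels, `"40-44"` ... `"80-84"`.
#' @export
core_age_bands <- function() {
  starts <- seq(40L, 80L, by = 5L)
  paste0(starts, "-", starts + 4L)
}

#' All age band labels up to a closure age
#'
#' Bands run in 5-year steps from 40; the final, open-ended band starts at
#' `closure_age` and is labelled e.g. `"110+"`.
#'
#' @param closure_age Age at which the life table closes (death probability 1).
#' @return Character vector of band labels.
#' @export
all_age_bands <- function(closure_age = 110L) {
  stopifnot(closure_age >= 85, (closure_age - 40) %% 5 == 0)
  starts <- seq(40L, closure_age - 5L, by = 5L)
  c(paste0(starts, "-", starts + 4L), paste0(closure_age, "+"))
}

# index of the band containing `age` within all_age_bands(closure_age)
band_index_of_age <- function(age, closure_age = 110L) {
  if (any(age < 40)) stop("age below 40 is outside the modelled range")
  n_bands <- (closure_age - 40L) %/% 5L + 1L
  pmin(floor((age - 40) / 5) + 1L, n_bands)
}

# map band index to the 9 core utility rows, carrying 80-84 forward
core_band_index_of_age <- function(age) {
  if (any(age < 40)) stop("age below 40 is outside the modelled range")
  pmin(floor((age - 40) / 5) + 1L, 9L)
}

#' Normalise age-band labels
#'
#' Published tables typeset band labels with en-dashes; files in the wild mix
#' en-dash, em-dash and hyphen. All are normalised to an ASCII hyphen, and
#' whitespace is stripped, so `"40–44"` and `"40-44"` compare equal.
#'
#' @param x Character vector of band labels.
#' @return Normalised character vector.
#' @export
normalize_age_band <- function(x) {
  x <- gsub("[–—]", "-", x)
  gsub("[[:space:]]", "", x)
}

#' Grid of the 36 modelled strata
#'
#' @return A data frame with columns `ethnicity`, `sex`, `age_band`, one row
#'   per stratum, ordered ethnicity > sex > age band.
#' @export
strata_grid <- function() {
  g <- expand.grid(
    age_band = core_age_bands(),
    sex = SEXES,
    ethnicity = ETHNICITIES,
    KEEP.OUT.ATTRS = FALSE,
    stringsAsFactors = FALSE
  )
  g[c("ethnicity", "sex", "age_band")]
}

# starting age of a cohort: band midpoint (integer), e.g. "40-44" -> 42
band_start_age <- function(age_band) {
  as.integer(sub("-.*$", "", sub("\\+$", "", normalize_age_band(age_band))))
}

check_stratum <- function(ethnicity, sex, age_band) {
  ethnicity <- match.arg(ethnicity, ETHNICITIES)
  sex <- match.arg(sex, SEXES)
  age_band <- normalize_age_band(age_band)
  if (!age_band %in% core_age_bands()) {
    stop("unknown age band '", age_band, "'; expected one of ",
         paste(core_age_bands(), collapse = ", "))
  }
  list(ethnicity = ethnicity, sex = sex, age_band = age_band)
}
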