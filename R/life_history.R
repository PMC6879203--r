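#' Construct a life table of age-specific annual mortality probabilities
#'
#' A life table holds the probability of dying within the year, `q[x]`, for
#' each age class `x = 0, 1, ..., A` where `A` is the maximum age. Age 0 is
#' the first year of life (egg to fledged one-year-old); individuals reaching
#' the maximum age breed once more and die at the next transition. No
#' senescence is modelled: mortality is typically constant from the age at
#' first breeding onwards.
#'
#' @param q Numeric vector of annual mortality probabilities, one per age
#'   class `0..max_age` (so `length(q) == max_age + 1`), each in `[0, 1]`.
#' @param max_age Maximum age in years. Defaults to `length(q) - 1`.
#' @return An object of class `auk_life_table` with fields `q` and `max_age`.
#' @seealso [life_table_from_rates()] for the structured three-rate
#'   parameterisation, [calibrate_life_table()] to fit one to demographic
#'   targets.
#' @export
#' @examples
#' lt <- life_table_from_rates(q0 = 0.35, q_juvenile = 0.125,
#'                             q_adult = 0.0105, first_breeding = 5)
#' lt
life_table <- function(q, max_age = length(q) - 1L) {
  stopifnot(is.numeric(q), length(q) >= 3)
  if (length(q) != max_age + 1L)
    stop("life table needs one mortality probability per age class 0..max_age (length(q) == max_age + 1)")
  if (anyNA(q) || any(q < 0) || any(q > 1))
    stop("all mortality probabilities must lie in [0, 1]")
  structure(list(q = as.numeric(q), max_age = as.integer(max_age)),
            class = "auk_life_table")
}

#' Build a life table from first-year, juvenile and adult mortality rates
#'
#' The standard three-parameter schedule used throughout the package:
#' first-year mortality `q0` for age class 0, a single juvenile rate for ages
#' `1..first_breeding - 1`, and a single adult rate for all ages at or above
#' the age at first breeding (no senescence).
#'
#' @param q0 First-year mortality probability (egg laid to age 1).
#' @param q_juvenile Annual mortality for immature age classes.
#' @param q_adult Annual mortality for mature age classes.
#' @param first_breeding Age (years) at first breeding; birds of this age and
#'   older breed.
#' @param max_age Maximum age in years (death at the cap). Default 25, a
#'   typical cap for a large alcid.
#' @return An `auk_life_table`.
#' @export
life_table_from_rates <- function(q0, q_juvenile, q_adult, first_breeding,
                                  max_age = 25L) {
  b <- as.integer(first_breeding)
  stopifnot(b >= 1, max_age > b)
  life_table(c(q0, rep(q_juvenile, b - 1L), rep(q_adult, max_age - b + 1L)),
             max_age = max_age)
}

#' @export
print.auk_life_table <- function(x, ...) {
  cat("Life table: max age", x$max_age, "years\n")
  cat("  q by age:", paste(format(round(x$q, 4)), collapse = " "), "\n")
  invisible(x)
}

# mortality probability for an age class (0-based age)
q_at_age <- function(life_table, age) life_table$q[age + 1L]

#' Breeding parameters
#'
#' Reproductive settings of the model. The great auk laid a single egg per
#' pair per season which was not replaced if removed, so the clutch size is
#' fixed at one. The deliberately optimistic conservative preset assumes all
#' mature birds breed (`p_breed = 1`) with full success (`p_success = 1`) and
#' no environmental variation (`ev_sd = 0`); the razorbill-based realistic
#' preset lowers success and adds annual variation.
#'
#' @param first_breeding Age (years) at first breeding; birds of this age and
#'   older are mature. 5 under the conservative preset ("older than 4
#'   years"), 6 under the realistic one.
#' @param p_breed Proportion of mature individuals breeding each year.
#' @param p_success Mean breeding success probability (egg to fledged chick).
#' @param sex_ratio Probability that an egg is female.
#' @param ev_sd Standard deviation of annual environmental variation in
#'   breeding success. Each year a success probability is drawn from a normal
#'   distribution truncated to `[0, 1]` with mean `p_success` and this SD;
#'   `0` disables environmental variation.
#' @param monogamous Pairing rule: pairs are limited by the scarcer sex.
#' @return An object of class `auk_breeding`.
#' @export
breeding_params <- function(first_breeding = 5L, p_breed = 1, p_success = 1,
                            sex_ratio = 0.5, ev_sd = 0, monogamous = TRUE) {
  stopifnot(first_breeding >= 1,
            p_breed >= 0, p_breed <= 1,
            p_success >= 0, p_success <= 1,
            sex_ratio >= 0, sex_ratio <= 1,
            ev_sd >= 0)
  structure(list(first_breeding = as.integer(first_breeding),
                 p_breed = p_breed, p_success = p_success,
                 clutch = 1L, sex_ratio = sex_ratio, ev_sd = ev_sd,
                 monogamous = isTRUE(monogamous)),
            class = "auk_breeding")
}

#' @export
print.auk_breeding <- function(x, ...) {
  cat(sprintf(
    "Breeding parameters: first breeding at age %d, p_breed %.2f, p_success %.2f, clutch 1, sex ratio %.2f, ev_sd %.2f\n",
    x$first_breeding, x$p_breed, x$p_success, x$sex_ratio, x$ev_sd))
  invisible(x)
}

#' Density-dependent mortality relief
#'
#' As the population declines, competition for food and breeding sites
#' relaxes. This is modelled as a multiplier on every age-specific mortality
#' probability that falls linearly with density from 1 at the reference
#' (starting) population size down to `floor` (default one half) as the
#' population approaches zero.
#'
#' @param floor Minimum mortality multiplier, in `(0, 1]`. Default 0.5:
#'   mortality is at most halved.
#' @param reference Reference population size `N0` at (or above) which the
#'   multiplier is 1. May be left `NA`; [scenario()] fills it with the
#'   scenario's starting size.
#' @param enabled Whether the relief is active.
#' @return An object of class `auk_dd`.
#' @seealso [dd_mortality_multiplier()]
#' @export
density_dependence <- function(floor = 0.5, reference = NA_real_,
                               enabled = TRUE) {
  stopifnot(floor > 0, floor <= 1)
  structure(list(enabled = isTRUE(enabled), floor = floor,
                 reference = reference),
            class = "auk_dd")
}

#' Mortality multiplier at a given population size
#'
#' Returns the factor applied to all age-specific mortality probabilities in
#' a given year: 1 when density dependence is disabled, otherwise
#' `clamp(floor + (1 - floor) * N / N0, floor, 1)` — a linear reduction of
#' natural mortality down to `floor` (one half by default) as density falls.
#'
#' @param n Current total population size (individuals), `>= 0`.
#' @param dd An [density_dependence()] object (or `NULL` for no relief).
#' @return A scalar multiplier in `[floor, 1]`.
#' @export
#' @examples
#' dd <- density_dependence(reference = 2e6)
#' dd_mortality_multiplier(2e6, dd)  # 1 at the starting size
#' dd_mortality_multiplier(1e6, dd)  # 0.75 at half the starting size
#' dd_mortality_multiplier(0, dd)    # 0.5 floor
dd_mortality_multiplier <- function(n, dd) {
  stopifnot(n >= 0)
  if (is.null(dd) || !inherits(dd, "auk_dd") || !dd$enabled) return(1)
  if (is.na(dd$reference) || dd$reference <= 0)
    stop("density dependence needs a positive reference population size")
  min(max(dd$floor + (1 - dd$floor) * n / dd$reference, dd$floor), 1)
}
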