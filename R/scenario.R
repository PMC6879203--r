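#' Define a harvest scenario
#'
#' One row of the viability grid: a starting population size, fixed annual
#' quotas of birds and eggs expressed as rates of the *starting* conditions,
#' optional density-dependent mortality relief, a horizon, an extinction
#' rule, and Monte-Carlo settings. Quotas are fixed counts, not proportions
#' of current size: the bird quota is `round(harvest_rate * n0)` and the egg
#' quota `round(egg_harvest_rate * egg_max)`, where `egg_max` is the maximum
#' annual egg production. If `egg_max` is not supplied it is computed at
#' simulation start from the realised initial population.
#'
#' @param n0 Starting population size (total individuals).
#' @param harvest_rate Fraction of `n0` taken annually as a fixed bird quota.
#' @param egg_harvest_rate Fraction of the maximum egg production taken
#'   annually as a fixed egg quota.
#' @param dd `TRUE`, `FALSE` or a [density_dependence()] object; the
#'   reference size defaults to `n0`.
#' @param horizon Simulation length in years. Default 350.
#' @param replicates Number of Monte-Carlo replicates. Default 100.
#' @param seed Master seed of the scenario; replicate `i` runs with seed
#'   `seed + i` (a documented counter scheme, so any replicate can be
#'   reproduced independently).
#' @param extinction_rule `"one_sex_remains"` (a replicate is extinct when
#'   either sex reaches zero individuals) or `"below_threshold"` (total falls
#'   below `extinction_threshold`).
#' @param extinction_threshold Threshold for the `"below_threshold"` rule.
#' @param harvest_policy How the bird quota is split between cohorts:
#'   `"all_ages"` (proportional to current abundance over all sex and age
#'   classes; the default) or `"adults_only"` (mature classes only).
#' @param egg_max Optional externally fixed maximum egg production used as
#'   the basis of the egg quota (the reference grid passes the published
#'   values).
#' @param initial_state Optional explicit `population_state` overriding the
#'   stable-age initial allocation (used by validation constructions).
#' @param escape_multiple Once the population exceeds
#'   `escape_multiple * n0` the replicate is scored as surviving and the
#'   simulation stops: with fixed quotas, a population hundreds of times the
#'   harvested count cannot reach extinction within the horizon, and
#'   stopping there keeps counts in exact-integer floating range. `NULL`
#'   disables the shortcut. Default 1000.
#' @param label Optional scenario label.
#' @return An object of class `auk_scenario`.
#' @export
scenario <- function(n0, harvest_rate, egg_harvest_rate = 0, dd = FALSE,
                     horizon = 350L, replicates = 100L, seed = 1L,
                     extinction_rule = c("one_sex_remains", "below_threshold"),
                     extinction_threshold = 50,
                     harvest_policy = c("all_ages", "adults_only"),
                     egg_max = NULL, initial_state = NULL,
                     escape_multiple = 1000, label = NULL) {
  extinction_rule <- match.arg(extinction_rule)
  harvest_policy <- match.arg(harvest_policy)
  stopifnot(n0 >= 2, harvest_rate >= 0, egg_harvest_rate >= 0,
            horizon >= 1, replicates >= 1)
  if (isTRUE(dd)) dd <- density_dependence(reference = n0)
  else if (identical(dd, FALSE)) dd <- NULL
  if (!is.null(dd)) {
    stopifnot(inherits(dd, "auk_dd"))
    if (is.na(dd$reference)) dd$reference <- n0
  }
  structure(list(
    n0 = n0, harvest_rate = harvest_rate,
    egg_harvest_rate = egg_harvest_rate, dd = dd,
    horizon = as.integer(horizon), replicates = as.integer(replicates),
    seed = as.integer(seed),
    extinction_rule = extinction_rule,
    extinction_threshold = extinction_threshold,
    harvest_policy = harvest_policy,
    egg_max = egg_max, initial_state = initial_state,
    escape_multiple = escape_multiple,
    bird_quota = round(harvest_rate * n0),
    label = label %||% sprintf("N0=%s, birds %.1f%%%s, eggs %.0f%%%s",
                               format(n0, big.mark = ","),
                               100 * harvest_rate,
                               "", 100 * egg_harvest_rate,
                               if (!is.null(dd)) ", DD" else "")),
    class = "auk_scenario")
}

#' @export
print.auk_scenario <- function(x, ...) {
  cat("Scenario:", x$label, "\n")
  cat(sprintf("  bird quota %s/yr, horizon %d y, %d replicates, rule '%s', seed %d\n",
              format(x$bird_quota, big.mark = ","), x$horizon, x$replicates,
              x$extinction_rule, x$seed))
  invisible(x)
}
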