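# Stochastic two-sex annual-cycle engine.
#
# Annual event order (Vortex-style): breed (with fixed egg quota) ->
# natural mortality (with the density-dependent multiplier computed from the
# pre-breeding total) -> bird harvest at fixed quota -> ageing (maximum age
# culled). Chicks hatched in step 1 face first-year mortality in step 2 and
# enter age class 1 at the ageing step, so the census holds ages 1..max_age.

# Vectorised binomial that stays valid for cohort sizes beyond the integer
# range: exact draws below 1e9, a clamped normal approximation above (where
# the binomial is indistinguishable from its normal limit).
rbinom_large <- function(size, prob) {
  stopifnot(all(size >= 0), all(prob >= 0), all(prob <= 1))
  prob <- rep_len(prob, length(size))
  out <- numeric(length(size))
  small <- size < 1e9
  if (any(small))
    out[small] <- rbinom(sum(small), size[small], prob[small])
  if (any(!small)) {
    n <- size[!small]; p <- prob[!small]
    mu <- n * p
    dev <- rnorm(sum(!small), 0, sqrt(pmax(n * p * (1 - p), 0)))
    out[!small] <- pmin(pmax(round(mu + dev), 0), n)
  }
  out
}

# Multivariate hypergeometric draw: sample k individuals without replacement
# from cells with the given counts. Sequential conditional rhyper while the
# total is within integer range; a count-capped multinomial approximation
# beyond it (where k is a vanishing fraction of the total).
rmvhyper <- function(counts, k) {
  total <- sum(counts)
  k <- min(k, total)
  take <- numeric(length(counts))
  if (k <= 0) return(take)
  if (total <= 2^31 - 2) {
    remaining_total <- total
    remaining_k <- k
    for (i in seq_along(counts)) {
      if (remaining_k <= 0) break
      if (i == length(counts)) { take[i] <- remaining_k; break }
      take[i] <- rhyper(1, counts[i], remaining_total - counts[i], remaining_k)
      remaining_total <- remaining_total - counts[i]
      remaining_k <- remaining_k - take[i]
    }
  } else {
    take <- as.numeric(rmultinom(1, size = k, prob = counts / total))
    over <- take > counts
    if (any(over)) {  # essentially unreachable at these population sizes
      excess <- sum(take[over] - counts[over])
      take[over] <- counts[over]
      room <- counts - take
      while (excess > 0 && any(room > 0)) {
        i <- which.max(room)
        add <- min(excess, room[i])
        take[i] <- take[i] + add
        room[i] <- room[i] - add
        excess <- excess - add
      }
    }
  }
  take
}

# Annual breeding-success deviate: normal truncated to [0, 1] by rejection.
rtrunc01 <- function(mean, sd) {
  if (sd <= 0) return(min(max(mean, 0), 1))
  for (i in 1:1000) {
    x <- rnorm(1, mean, sd)
    if (x >= 0 && x <= 1) return(x)
  }
  min(max(mean, 0), 1)
}

#' Breeding step with fixed egg harvest
#'
#' Monogamous breeding: the number of pairs is limited by the scarcer mature
#' sex; each breeding pair lays a single egg. The fixed egg quota is removed
#' from the eggs laid (an egg is not replaced if removed), the survivors
#' hatch with the (possibly environmentally varying) breeding success, and
#' hatchlings are assigned a sex binomially. The returned chicks have not
#' yet faced first-year mortality.
#'
#' @param state A `population_state`.
#' @param breeding A [breeding_params()].
#' @param egg_quota Fixed number of eggs harvested this year.
#' @return List with `chicks` (named vector `F`, `M`), `eggs_laid`,
#'   `eggs_harvested` and the realised `p_success`.
#' @export
breed <- function(state, breeding, egg_quota = 0) {
  stopifnot(inherits(state, "population_state"),
            inherits(breeding, "auk_breeding"), egg_quota >= 0)
  b <- breeding$first_breeding
  mature_f <- sum(state[1, b:ncol(state)])
  mature_m <- sum(state[2, b:ncol(state)])
  pairs <- if (breeding$monogamous) min(mature_f, mature_m)
           else floor((mature_f + mature_m) / 2)
  breeders <- if (breeding$p_breed >= 1) pairs
              else rbinom_large(pairs, breeding$p_breed)
  eggs_laid <- breeders * breeding$clutch
  eggs_harvested <- min(egg_quota, eggs_laid)
  p_success <- rtrunc01(breeding$p_success, breeding$ev_sd)
  hatched <- rbinom_large(eggs_laid - eggs_harvested, p_success)
  chicks_f <- rbinom_large(hatched, breeding$sex_ratio)
  list(chicks = c(F = chicks_f, M = hatched - chicks_f),
       eggs_laid = eggs_laid, eggs_harvested = eggs_harvested,
       p_success = p_success)
}

#' Natural mortality step
#'
#' Binomial survival for every sex-by-age cell: survivors are drawn as
#' `Binomial(count, 1 - q_age * multiplier)` where the multiplier is the
#' density-dependent mortality relief for the year (1 when disabled).
#'
#' @param state A `population_state`.
#' @param life_table An [life_table()].
#' @param multiplier Mortality multiplier in `(0, 1]`.
#' @return The surviving `population_state`, with attribute `"deaths"`
#'   holding the number of deaths.
#' @export
apply_natural_mortality <- function(state, life_table, multiplier = 1) {
  stopifnot(inherits(state, "population_state"),
            inherits(life_table, "auk_life_table"),
            multiplier > 0)
  ages <- seq_len(ncol(state))
  q <- life_table$q[ages + 1L] * multiplier  # q for census ages 1..A
  if (any(q > 1)) stop("mortality multiplier drives q above 1")
  p_surv <- rep(1 - q, each = 2)
  before <- sum(state)
  survivors <- rbinom_large(as.numeric(state), p_surv)
  new <- population_state(matrix(survivors, nrow = 2), year = attr(state, "year"))
  attr(new, "deaths") <- before - sum(new)
  new
}

#' Fixed-quota bird harvest step
#'
#' Removes `min(quota, total)` individuals, allocated across the eligible
#' sex-by-age cells without replacement (multivariate hypergeometric), i.e.
#' proportionally to current abundance in expectation. Under the default
#' `"all_ages"` policy every census age class (1 and older) is eligible;
#' under `"adults_only"` only mature classes are.
#'
#' @param state A `population_state`.
#' @param quota Fixed number of birds to remove.
#' @param policy `"all_ages"` or `"adults_only"`.
#' @param first_breeding Needed for the `"adults_only"` policy.
#' @return The harvested `population_state` with attribute `"harvested"`.
#' @export
apply_bird_harvest <- function(state, quota,
                               policy = c("all_ages", "adults_only"),
                               first_breeding = NULL) {
  policy <- match.arg(policy)
  stopifnot(inherits(state, "population_state"), quota >= 0)
  if (policy == "adults_only") {
    if (is.null(first_breeding))
      stop("the adults-only policy needs the age at first breeding")
    eligible <- seq(first_breeding, ncol(state))
  } else eligible <- seq_len(ncol(state))
  counts <- as.numeric(state[, eligible])
  take <- rmvhyper(counts, quota)
  new <- state
  new[, eligible] <- state[, eligible] - matrix(take, nrow = 2)
  new <- population_state(unclass(new)[, , drop = FALSE],
                          year = attr(state, "year"))
  attr(new, "harvested") <- sum(take)
  new
}

#' Advance the population one year
#'
#' Runs the annual cycle once: breeding with the fixed egg quota, natural
#' mortality under the density-dependent multiplier computed from the
#' pre-breeding total, fixed-quota bird harvest, and ageing (chicks enter
#' class 1; birds at the maximum age die). Quotas are fixed counts derived
#' from the starting conditions, not proportions of current size.
#'
#' @param state A `population_state`.
#' @param scn An [scenario()].
#' @param life_table An [life_table()].
#' @param breeding A [breeding_params()].
#' @param bird_quota,egg_quota Resolved fixed quotas; default to the
#'   scenario's bird quota and, for eggs, to the rate applied to the
#'   scenario's `egg_max` (or the state's own maximum egg production).
#' @return List with the advanced `state` and a one-row data frame `log`
#'   recording the year's bookkeeping (totals, recruits, deaths, harvest,
#'   multiplier). The identity
#'   `end_total = start_total + recruits - natural_deaths - age_cap_deaths -
#'   birds_harvested` holds exactly.
#' @export
step_year <- function(state, scn, life_table, breeding,
                      bird_quota = scn$bird_quota,
                      egg_quota = NULL) {
  stopifnot(inherits(state, "population_state"))
  if (is.null(egg_quota)) {
    basis <- scn$egg_max %||%
      max_annual_eggs(count_mature(state, breeding$first_breeding))
    egg_quota <- round(scn$egg_harvest_rate * basis)
  }
  start_total <- sum(state)
  mult <- dd_mortality_multiplier(start_total, scn$dd)

  br <- breed(state, breeding, egg_quota)

  # mortality on census classes, then on this year's chicks (age 0)
  state2 <- apply_natural_mortality(state, life_table, mult)
  q0 <- life_table$q[1] * mult
  chick_surv <- rbinom_large(br$chicks, 1 - q0)
  natural_deaths <- attr(state2, "deaths") + sum(br$chicks) - sum(chick_surv)

  state3 <- apply_bird_harvest(state2, bird_quota, scn$harvest_policy,
                               breeding$first_breeding)
  harvested <- attr(state3, "harvested")

  # ageing: class x -> x+1, the oldest class dies, chicks enter class 1
  A <- ncol(state3)
  age_cap_deaths <- sum(state3[, A])
  counts <- cbind(chick_surv, unclass(state3)[, -A, drop = FALSE])
  new_state <- population_state(counts, year = attr(state, "year") + 1L)

  log <- data.frame(
    year = attr(new_state, "year"),
    start_total = start_total,
    dd_multiplier = mult,
    eggs_laid = br$eggs_laid,
    eggs_harvested = br$eggs_harvested,
    recruits = sum(br$chicks),
    natural_deaths = natural_deaths,
    age_cap_deaths = age_cap_deaths,
    birds_harvested = harvested,
    end_total = sum(new_state))
  list(state = new_state, log = log)
}

is_extinct_state <- function(state, rule, threshold) {
  if (rule == "one_sex_remains")
    sum(state[1, ]) == 0 || sum(state[2, ]) == 0
  else
    sum(state) < threshold
}

# Core simulation shared by run_replicate() and extinction_probability():
# assumes quotas are resolved and the RNG is already seeded.
simulate_replicate <- function(state, scn, life_table, breeding,
                               bird_quota, egg_quota,
                               keep_trajectory = FALSE, keep_log = FALSE) {
  horizon <- scn$horizon
  escape_at <- if (is.null(scn$escape_multiple)) Inf
               else scn$escape_multiple * scn$n0
  trajectory <- if (keep_trajectory) numeric(horizon) else NULL
  logs <- if (keep_log) vector("list", horizon) else NULL
  extinct <- FALSE
  extinction_year <- NA_integer_
  years_run <- 0L
  for (t in seq_len(horizon)) {
    stp <- step_year(state, scn, life_table, breeding,
                     bird_quota = bird_quota, egg_quota = egg_quota)
    state <- stp$state
    years_run <- t
    if (keep_trajectory) trajectory[t] <- sum(state)
    if (keep_log) logs[[t]] <- stp$log
    if (is_extinct_state(state, scn$extinction_rule,
                         scn$extinction_threshold)) {
      extinct <- TRUE
      extinction_year <- t
      break
    }
    if (sum(state) > escape_at) break
  }
  structure(list(extinct = extinct, extinction_year = extinction_year,
                 years_run = years_run, final_total = sum(state),
                 final_state = state,
                 trajectory = if (keep_trajectory) trajectory[seq_len(years_run)],
                 log = if (keep_log) do.call(rbind, logs[seq_len(years_run)]),
                 bird_quota = bird_quota, egg_quota = egg_quota),
            class = "auk_replicate")
}

# Resolve the model, initial state and fixed quotas of a scenario once.
prepare_scenario <- function(scn, life_table, breeding, model = NULL) {
  state <- scn$initial_state
  if (is.null(state)) {
    if (is.null(model)) model <- build_leslie(life_table, breeding)
    state <- initial_population(scn$n0, model, breeding$sex_ratio)
  }
  basis <- scn$egg_max %||%
    max_annual_eggs(count_mature(state, breeding$first_breeding))
  list(state = state,
       bird_quota = round(scn$harvest_rate * scn$n0),
       egg_quota = round(scn$egg_harvest_rate * basis),
       egg_max = basis)
}

#' Run a single simulation replicate
#'
#' Simulates one trajectory of up to `horizon` years (stopping early at
#' extinction or once the escape threshold is passed). Deterministic given
#' the seed.
#'
#' @param scn An [scenario()].
#' @param life_table,breeding Demographic parameters.
#' @param seed Seed for this replicate. Defaults to the scenario seed.
#' @param keep_trajectory Record per-year totals.
#' @param keep_log Record the per-year bookkeeping data frame.
#' @param model Optional pre-built Leslie model (avoids rebuilding).
#' @return An `auk_replicate`: list with `extinct`, `extinction_year` (`NA`
#'   if surviving), `years_run`, `final_total`, the resolved quotas, and
#'   optionally `trajectory` and `log`.
#' @export
run_replicate <- function(scn, life_table, breeding, seed = scn$seed,
                          keep_trajectory = FALSE, keep_log = FALSE,
                          model = NULL) {
  stopifnot(inherits(scn, "auk_scenario"))
  prep <- prepare_scenario(scn, life_table, breeding, model)
  set.seed(seed)
  simulate_replicate(prep$state, scn, life_table, breeding,
                     prep$bird_quota, prep$egg_quota,
                     keep_trajectory = keep_trajectory, keep_log = keep_log)
}

#' @export
print.auk_replicate <- function(x, ...) {
  if (x$extinct)
    cat(sprintf("Replicate: extinct in year %d\n", x$extinction_year))
  else
    cat(sprintf("Replicate: surviving after %d years (total %s)\n",
                x$years_run, format(x$final_total, big.mark = ",")))
  invisible(x)
}

#' Monte-Carlo extinction probability
#'
#' Runs the scenario's replicates with seeds `seed + 1, ..., seed + n`
#' (each replicate independently reproducible) and returns the fraction that
#' went extinct within the horizon together with its binomial standard
#' error `sqrt(p (1 - p) / n)`.
#'
#' @param scn An [scenario()].
#' @param life_table,breeding Demographic parameters.
#' @param model Optional pre-built Leslie model.
#' @return An `auk_prob`: list with `p_ext`, `n_replicates`, `se`,
#'   `n_extinct`, per-replicate `extinction_years` and `final_totals`, and
#'   the resolved quotas.
#' @export
#' @examples
#' \donttest{
#' pre <- conservative_preset()
#' scn <- scenario(2e6, 0.105, 0.05, dd = TRUE, replicates = 20, seed = 1,
#'                 egg_max = 513766)
#' extinction_probability(scn, pre$life_table, pre$breeding)
#' }
extinction_probability <- function(scn, life_table, breeding, model = NULL) {
  stopifnot(inherits(scn, "auk_scenario"), scn$replicates >= 1)
  prep <- prepare_scenario(scn, life_table, breeding, model)
  n <- scn$replicates
  extinct <- logical(n)
  ext_year <- rep(NA_integer_, n)
  finals <- numeric(n)
  for (i in seq_len(n)) {
    set.seed(scn$seed + i)
    rep_i <- simulate_replicate(prep$state, scn, life_table, breeding,
                                prep$bird_quota, prep$egg_quota)
    extinct[i] <- rep_i$extinct
    ext_year[i] <- rep_i$extinction_year
    finals[i] <- rep_i$final_total
  }
  p <- mean(extinct)
  structure(list(p_ext = p, n_replicates = n,
                 se = sqrt(p * (1 - p) / n),
                 n_extinct = sum(extinct),
                 extinction_years = ext_year, final_totals = finals,
                 bird_quota = prep$bird_quota, egg_quota = prep$egg_quota,
                 egg_max = prep$egg_max, scenario = scn),
            class = "auk_prob")
}

#' @export
print.auk_prob <- function(x, ...) {
  cat(sprintf("P(extinction within %d years) = %.2f (SE %.3f, %d/%d replicates)\n",
              x$scenario$horizon, x$p_ext, x$se, x$n_extinct, x$n_replicates))
  cat(sprintf("  quotas: %s birds/yr, %s eggs/yr\n",
              format(x$bird_quota, big.mark = ","),
              format(x$egg_quota, big.mark = ",")))
  invisible(x)
}
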