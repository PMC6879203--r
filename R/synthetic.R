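# Synthetic input generation: life-table variants and degenerate scenarios
# with analytically known extinction probabilities, used to validate the
# Monte-Carlo estimator and to probe sensitivity to the mortality schedule.

#' Perturbed life-table variants
#'
#' Jitters every mortality probability of a base life table on the logit
#' scale (keeping values strictly inside `(0, 1)` without clipping
#' artefacts), revalidates each variant and records its asymptotic growth
#' rate. Deterministic given the seed.
#'
#' @param base An [life_table()].
#' @param sd Standard deviation of the logit-scale perturbation (`>= 0`).
#' @param n_variants Number of variants (`>= 1`).
#' @param seed Seed.
#' @param breeding Breeding parameters used to recompute the growth rate of
#'   each variant.
#' @return List of `auk_life_table` objects, each with attribute `"lambda"`.
#' @export
perturbed_life_tables <- function(base, sd, n_variants, seed = 1L,
                                  breeding = breeding_params()) {
  stopifnot(inherits(base, "auk_life_table"), sd >= 0, n_variants >= 1)
  set.seed(seed)
  eps <- 1e-8
  lapply(seq_len(n_variants), function(i) {
    q <- pmin(pmax(base$q, eps), 1 - eps)
    q <- plogis(qlogis(q) + rnorm(length(q), 0, sd))
    if (sd == 0) q <- base$q
    lt <- life_table(q, base$max_age)
    attr(lt, "lambda") <- build_leslie(lt, breeding)$lambda
    lt
  })
}

#' Degenerate scenario with an exactly known extinction probability
#'
#' Constructs a two-bird, one-year scenario whose extinction probability can
#' be computed in closed form, for validating the Monte-Carlo estimator. The
#' population holds one female and one male, nobody breeds, and both face
#' the same annual mortality `q = 1 - sqrt(1 - p)`; under the "one sex
#' remains" rule the replicate is extinct exactly when at least one of the
#' two dies, so `P(extinct) = 1 - (1 - q)^2 = p`.
#'
#' @param p Target single-year extinction probability in `[0, 1]`.
#' @param replicates Replicates the returned scenario will run.
#' @param seed Scenario master seed.
#' @return List with `scenario`, `life_table`, `breeding` and `p_exact`.
#' @export
#' @examples
#' ks <- known_probability_scenario(0.3, replicates = 200)
#' est <- extinction_probability(ks$scenario, ks$life_table, ks$breeding)
#' abs(est$p_ext - ks$p_exact) < 3 * sqrt(0.3 * 0.7 / 200)
known_probability_scenario <- function(p, replicates = 1000L, seed = 1L) {
  stopifnot(p >= 0, p <= 1)
  q <- 1 - sqrt(1 - p)
  max_age <- 5L
  lt <- life_table(rep(q, max_age + 1L), max_age)
  br <- breeding_params(first_breeding = 1L, p_breed = 0)
  counts <- matrix(0, 2, max_age)
  counts[, 1] <- 1  # one female and one male at age 1
  st <- population_state(counts)
  scn <- scenario(n0 = 2, harvest_rate = 0, horizon = 1L,
                  replicates = replicates, seed = seed,
                  initial_state = st,
                  label = sprintf("known p = %.3f", p))
  list(scenario = scn, life_table = lt, breeding = br, p_exact = p)
}
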