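#' Deterministic mean-field projection of the harvested annual cycle
#'
#' Projects expected sex-by-age counts through the same annual event order
#' as the stochastic engine (breed with fixed egg quota, density-dependent
#' natural mortality, fixed-quota bird harvest, ageing), replacing every
#' random draw by its expectation. With `pairing_correction = TRUE` the
#' expected number of monogamous pairs accounts for the binomial sex
#' imbalance accumulated in each cohort: sexes are assigned binomially at
#' hatching and the imbalance variance of a cohort is propagated through
#' survival and harvest thinning (`v' = s^2 v + n s (1 - s)`), giving
#' `E[min(F, M)] ~ m/2 - sqrt(2 V / pi) / 2` where `V` is the summed
#' imbalance variance of the mature classes. The starting population is
#' split exactly evenly, so `V` starts at zero and builds up as recruits
#' replace the founders. This is the deterministic oracle used to reason
#' about fixed-quota thresholds: with no harvest and no correction it
#' reduces to the Leslie projection of [build_leslie()].
#'
#' @param life_table,breeding Demographic parameters.
#' @param n0 Starting size (stable-age allocation), or supply `state`.
#' @param state Optional explicit starting `population_state` (or a 2-row
#'   numeric matrix of expected counts).
#' @param years Number of years to project.
#' @param bird_quota,egg_quota Fixed annual quotas (counts).
#' @param dd Optional [density_dependence()].
#' @param pairing_correction Apply the two-sex monogamy correction.
#' @param harvest_policy As in [scenario()].
#' @return Data frame with `year`, `total`, `females`, `males`, `mature`.
#' @export
deterministic_projection <- function(life_table, breeding, n0 = NULL,
                                     state = NULL, years = 100,
                                     bird_quota = 0, egg_quota = 0,
                                     dd = NULL, pairing_correction = TRUE,
                                     harvest_policy = "all_ages") {
  stopifnot(inherits(life_table, "auk_life_table"),
            inherits(breeding, "auk_breeding"), years >= 0)
  b <- breeding$first_breeding
  A <- life_table$max_age
  if (is.null(state)) {
    if (is.null(n0)) stop("supply n0 or state")
    model <- build_leslie(life_table, breeding)
    state <- initial_population(n0, model, breeding$sex_ratio)
  }
  x <- matrix(as.numeric(state), nrow = 2)
  q <- life_table$q
  v <- numeric(A)  # per-cohort Var(F - M), zero for the even founder split
  out <- data.frame(year = 0, total = sum(x), females = sum(x[1, ]),
                    males = sum(x[2, ]), mature = sum(x[, b:A]))
  for (t in seq_len(years)) {
    total <- sum(x)
    if (total <= 0) break
    mult <- dd_mortality_multiplier(total, dd)
    mature_f <- sum(x[1, b:A]); mature_m <- sum(x[2, b:A])
    m <- mature_f + mature_m
    pairs <- if (breeding$monogamous) {
      p <- min(mature_f, mature_m)
      if (pairing_correction && abs(mature_f - mature_m) < sqrt(m + 1))
        p <- m / 2 - sqrt(2 * sum(v[b:A]) / pi) / 2
      max(p, 0)
    } else m / 2
    eggs <- pairs * breeding$p_breed * breeding$clutch
    eggs <- max(eggs - egg_quota, 0) * breeding$p_success
    chicks_total <- eggs
    chicks <- chicks_total * c(breeding$sex_ratio, 1 - breeding$sex_ratio)
    v0 <- chicks_total  # binomial sex assignment at hatching
    # natural mortality (census classes, then chicks)
    s_age <- 1 - q[2:(A + 1)] * mult
    cohort <- colSums(x)
    x <- x * matrix(rep(s_age, each = 2), nrow = 2)
    v <- s_age^2 * v + cohort * s_age * (1 - s_age)
    s0 <- 1 - q[1] * mult
    chicks <- chicks * s0
    v0 <- s0^2 * v0 + chicks_total * s0 * (1 - s0)
    # proportional fixed-quota harvest
    if (bird_quota > 0) {
      eligible <- if (harvest_policy == "adults_only") b:A else 1:A
      pool <- sum(x[, eligible])
      frac <- min(bird_quota / max(pool, 1e-12), 1)
      cohort <- colSums(x)
      x[, eligible] <- x[, eligible] * (1 - frac)
      v[eligible] <- (1 - frac)^2 * v[eligible] +
        cohort[eligible] * frac * (1 - frac)
    }
    # ageing
    x <- cbind(chicks, x[, -A, drop = FALSE])
    v <- c(v0, v[-A])
    out <- rbind(out, data.frame(year = t, total = sum(x),
                                 females = sum(x[1, ]), males = sum(x[2, ]),
                                 mature = sum(x[, b:A])))
  }
  out
}
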