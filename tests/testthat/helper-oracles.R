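# Independent oracles and shared fixtures for the test suite.

# Power iteration: dominant eigenpair by brute-force repeated projection,
# independent of the eigen() decomposition used by the package.
power_iteration <- function(m, iters = 500) {
  v <- rep(1, nrow(m))
  lambda <- NA_real_
  for (i in seq_len(iters)) {
    w <- as.numeric(m %*% v)
    s <- sum(abs(w))
    if (s == 0) return(list(lambda = 0, v = rep(NA_real_, nrow(m))))
    lambda <- s / sum(abs(v))
    v <- w / s
  }
  list(lambda = lambda, v = v / sum(v))
}

# Growth factor of successive totals in a long brute-force vector
# projection; converges to the dominant eigenvalue.
projection_growth_rate <- function(m, years = 500) {
  v <- rep(1, nrow(m))
  for (i in seq_len(years - 1)) v <- as.numeric(m %*% v)
  w <- as.numeric(m %*% v)
  sum(w) / sum(v)
}

# The calibrated conservative preset is used all over the suite; build it
# once per test run.
local_preset_cache <- new.env(parent = emptyenv())
cons_preset <- function() {
  if (is.null(local_preset_cache$cons))
    local_preset_cache$cons <- conservative_preset()
  local_preset_cache$cons
}
real_preset <- function() {
  if (is.null(local_preset_cache$real))
    local_preset_cache$real <- realistic_preset()
  local_preset_cache$real
}

# A fast-growing toy life table (no mortality, breeding from age 1).
toy_immortal <- function(max_age = 25) {
  list(life_table = life_table(rep(0, max_age + 1), max_age),
       breeding = breeding_params(first_breeding = 1L))
}
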