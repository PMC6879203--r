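test_that("density-dependent mortality relief is linear with the stated endpoints", {
  expect_equal(dd_mortality_multiplier(12345, NULL), 1)
  dd <- density_dependence(reference = 2e6)
  expect_equal(dd_mortality_multiplier(2e6, dd), 1)
  expect_equal(dd_mortality_multiplier(0, dd), 0.5)
  expect_equal(dd_mortality_multiplier(1e6, dd), 0.75)
  expect_equal(dd_mortality_multiplier(5e6, dd), 1)  # clamped above N0
  dis <- density_dependence(reference = 2e6, enabled = FALSE)
  expect_equal(dd_mortality_multiplier(1e6, dis), 1)
})

test_that("monogamous breeding is limited by the scarcer sex and the egg quota by eggs laid", {
  br <- breeding_params(first_breeding = 2)
  mk <- function(f, m) {
    counts <- matrix(0, 2, 5)
    counts[1, 3] <- f; counts[2, 3] <- m
    population_state(counts)
  }
  set.seed(1)
  expect_equal(breed(mk(100, 0), br)$eggs_laid, 0)   # no males, no pairs
  out <- breed(mk(513766, 513766), br)               # published mature split
  expect_equal(out$eggs_laid, 513766)
  expect_equal(sum(out$chicks), 513766)              # p_success 1, quota 0
  # harvesting more eggs than laid leaves no recruits
  out <- breed(mk(100, 100), br, egg_quota = 150)
  expect_equal(out$eggs_harvested, 100)
  expect_equal(sum(out$chicks), 0)
})

test_that("natural mortality is binomial with the right mean, scaled by the multiplier", {
  lt <- life_table(c(0, 0.1, rep(0.1, 4)), 5)
  counts <- matrix(0, 2, 5); counts[1, 1] <- 10000
  st <- population_state(counts)
  # zero mortality leaves the state unchanged
  lt0 <- life_table(rep(0, 6), 5)
  set.seed(1)
  expect_equal(sum(apply_natural_mortality(st, lt0, 1)), 10000)
  # q = 0.1 on 10,000 birds: mean survivors 9,000 within 3 SE of the mean
  set.seed(42)
  surv <- replicate(1000, sum(apply_natural_mortality(st, lt, 1)))
  se_mean <- sqrt(10000 * 0.1 * 0.9 / 1000)
  expect_lt(abs(mean(surv) - 9000), 3 * se_mean)
  # multiplier 0.5 halves the effective mortality
  set.seed(43)
  surv2 <- replicate(1000, sum(apply_natural_mortality(st, lt, 0.5)))
  se2 <- sqrt(10000 * 0.05 * 0.95 / 1000)
  expect_lt(abs(mean(surv2) - 9500), 3 * se2)
  expect_error(apply_natural_mortality(st, life_table(rep(0.9, 6), 5), 1.2),
               "above 1")
})

test_that("fixed-quota harvest removes proportionally without replacement", {
  counts <- matrix(0, 2, 2)
  counts[1, 1] <- 600; counts[2, 1] <- 400
  st <- population_state(counts)
  set.seed(7)
  h0 <- apply_bird_harvest(st, 0)
  expect_equal(sum(h0), 1000)
  expect_equal(attr(h0, "harvested"), 0)
  hall <- apply_bird_harvest(st, 5000)   # quota above total empties the state
  expect_equal(sum(hall), 0)
  # expected removals 60/40 from a 600/400 split at quota 100
  set.seed(11)
  taken_f <- replicate(1000, {
    h <- apply_bird_harvest(st, 100)
    600 - h[1, 1]
  })
  var_hyper <- 100 * 0.6 * 0.4 * (1000 - 100) / (1000 - 1)
  expect_lt(abs(mean(taken_f) - 60), 3 * sqrt(var_hyper / 1000))
  # adults-only policy spares juveniles
  counts2 <- matrix(0, 2, 6)
  counts2[, 1] <- 50; counts2[, 6] <- 50
  st2 <- population_state(counts2)
  set.seed(3)
  h2 <- apply_bird_harvest(st2, 60, policy = "adults_only", first_breeding = 5)
  expect_equal(sum(h2[, 1]), 100)
  expect_equal(sum(h2[, 6]), 40)
})

test_that("a year conserves individuals exactly: recruits in, deaths and harvest out", {
  pre <- cons_preset()
  scn <- scenario(50000, 0.10, 0.05, dd = TRUE, horizon = 40,
                  replicates = 1, seed = 5)
  r <- run_replicate(scn, pre$life_table, pre$breeding, keep_log = TRUE)
  log <- r$log
  expect_true(all(log$end_total ==
    log$start_total + log$recruits - log$natural_deaths -
    log$age_cap_deaths - log$birds_harvested))
  expect_true(all(log$eggs_harvested <= log$eggs_laid))
})

test_that("with no harvest and no mortality the population only grows", {
  toy <- toy_immortal()
  model <- build_leslie(toy$life_table, toy$breeding)
  scn <- scenario(1000, 0, 0, horizon = 15, replicates = 1, seed = 2,
                  escape_multiple = NULL)
  r <- run_replicate(scn, toy$life_table, toy$breeding, keep_trajectory = TRUE,
                     model = model)
  expect_false(r$extinct)
  expect_true(all(diff(c(1000, r$trajectory)) > 0))
})

test_that("fixed quotas resolve from the published bases with nearest-integer rounding", {
  pre <- cons_preset()
  scn2 <- scenario(2e6, 0.105, 0.05, egg_max = 513766, horizon = 1,
                   replicates = 1, seed = 1)
  r2 <- run_replicate(scn2, pre$life_table, pre$breeding)
  expect_identical(r2$bird_quota, 210000)
  expect_identical(r2$egg_quota, 25688)
  scn6 <- scenario(6e6, 0.105, 0.05, egg_max = 1541297, horizon = 1,
                   replicates = 1, seed = 1)
  r6 <- run_replicate(scn6, pre$life_table, pre$breeding)
  expect_identical(r6$bird_quota, 630000)
  expect_identical(r6$egg_quota, 77065)  # round(77064.85)
})

test_that("a quota above the starting population extinguishes almost immediately", {
  pre <- cons_preset()
  scn <- scenario(1000, 2, 0, horizon = 10, replicates = 1, seed = 9)
  r <- run_replicate(scn, pre$life_table, pre$breeding)
  expect_true(r$extinct)
  # the bird quota spares the year's chicks, so the wipe-out of the census
  # classes in year 1 is completed in year 2 when no new chicks appear
  expect_lte(r$extinction_year, 2L)
  expect_equal(r$final_total, 0)
})

test_that("replicates are deterministic given the seed", {
  pre <- cons_preset()
  scn <- scenario(5000, 0.11, 0.05, dd = TRUE, horizon = 60,
                  replicates = 1, seed = 123)
  a <- run_replicate(scn, pre$life_table, pre$breeding, keep_trajectory = TRUE)
  b <- run_replicate(scn, pre$life_table, pre$breeding, keep_trajectory = TRUE)
  expect_identical(a, b)
  c <- run_replicate(scn, pre$life_table, pre$breeding, seed = 124,
                     keep_trajectory = TRUE)
  expect_false(identical(a$trajectory, c$trajectory))
})

test_that("a mean-growth population stays near the deterministic Leslie oracle", {
  pre <- cons_preset()
  model <- pre$model
  scn <- scenario(20000, 0, 0, horizon = 10, replicates = 1,
                  escape_multiple = NULL)
  det <- deterministic_projection(pre$life_table, pre$breeding, n0 = 20000,
                                  years = 10)
  tot <- vapply(1:25, function(i) {
    run_replicate(scn, pre$life_table, pre$breeding, seed = 2000 + i,
                  model = model)$final_total
  }, numeric(1))
  se <- sd(tot) / sqrt(length(tot))
  expect_lt(abs(mean(tot) - det$total[det$year == 10]), 3 * se)
})
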