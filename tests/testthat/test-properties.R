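# Behavioural properties of the stochastic engine at reduced population
# scale (decisive dynamics, fast runtimes). Full-scale counterparts run in
# test-acceptance.R.

test_that("extinction probability is monotone in the harvest rate (shared seeds)", {
  pre <- cons_preset()
  model <- pre$model
  p <- vapply(c(0.08, 0.10, 0.12), function(rate) {
    scn <- scenario(20000, rate, 0.05, horizon = 350, replicates = 25,
                    seed = 50)
    extinction_probability(scn, pre$life_table, pre$breeding, model)$p_ext
  }, numeric(1))
  expect_true(all(diff(p) >= 0))
  expect_equal(p[1], 0)   # below the deterministic threshold
  expect_equal(p[3], 1)   # far above it
})

test_that("density-dependent relief never makes extinction more likely", {
  pre <- cons_preset()
  model <- pre$model
  for (rate in c(0.10, 0.105)) {
    p <- vapply(c(FALSE, TRUE), function(dd) {
      scn <- scenario(20000, rate, 0.05, dd = dd, horizon = 350,
                      replicates = 30, seed = 60)
      extinction_probability(scn, pre$life_table, pre$breeding, model)$p_ext
    }, numeric(1))
    se <- sqrt(sum(p * (1 - p)) / 30 + 1e-12)
    expect_lte(p[2], p[1] + 3 * se)
  }
})

test_that("the extinction definition barely moves the estimate", {
  pre <- cons_preset()
  model <- pre$model
  for (rate in c(0.08, 0.11)) {
    p <- vapply(c("one_sex_remains", "below_threshold"), function(rule) {
      scn <- scenario(20000, rate, 0.05, horizon = 350, replicates = 25,
                      seed = 70, extinction_rule = rule,
                      extinction_threshold = 50)
      extinction_probability(scn, pre$life_table, pre$breeding, model)$p_ext
    }, numeric(1))
    expect_lt(abs(p[1] - p[2]), 0.1)
  }
})

test_that("the estimator recovers a known extinction probability within 3 binomial SE", {
  ks <- known_probability_scenario(0.3, replicates = 1000, seed = 99)
  est <- extinction_probability(ks$scenario, ks$life_table, ks$breeding)
  expect_lt(abs(est$p_ext - ks$p_exact), 3 * sqrt(0.3 * 0.7 / 1000))
})

test_that("the realistic preset sits at its harvest boundary rather than far past it", {
  re <- real_preset()
  boundary <- scenario(2e6, 0.02, 0, dd = TRUE, horizon = 350,
                       replicates = 15, seed = 31)
  p_boundary <- extinction_probability(boundary, re$life_table,
                                       re$breeding)$p_ext
  expect_lt(p_boundary, 1)  # 40,000 birds/yr is borderline, not certain doom
  heavy <- scenario(2e6, 0.06, 0, dd = TRUE, horizon = 350,
                    replicates = 15, seed = 32)
  p_heavy <- extinction_probability(heavy, re$life_table, re$breeding)$p_ext
  expect_equal(p_heavy, 1)  # three times the boundary quota is fatal
})
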