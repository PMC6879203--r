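test_that("life table construction validates its inputs", {
  expect_error(life_table(c(0.1, 0.2, 0.3), max_age = 3), "0..max_age")
  expect_error(life_table(c(0.1, 0.2, 1.2)), "\\[0, 1\\]")
  lt <- life_table_from_rates(0.4, 0.1, 0.02, first_breeding = 5, max_age = 25)
  expect_s3_class(lt, "auk_life_table")
  expect_length(lt$q, 26)
  expect_equal(lt$q[1], 0.4)
  expect_equal(unique(lt$q[2:5]), 0.1)
  expect_equal(unique(lt$q[6:26]), 0.02)
})

test_that("an immortal population breeding from age 1 grows at 1.5 per year", {
  # each female adds 0.5 daughters per year and never dies; with a long
  # age span the cap is irrelevant
  toy <- toy_immortal(max_age = 60)
  mod <- build_leslie(toy$life_table, toy$breeding)
  expect_equal(mod$lambda, 1.5, tolerance = 1e-6)
})

test_that("complete first-year mortality gives lambda 0, broken juvenile survival errors", {
  lt <- life_table(c(1, rep(0.1, 25)), 25)
  mod <- build_leslie(lt, breeding_params(first_breeding = 5))
  expect_equal(mod$lambda, 0)
  expect_true(all(is.na(mod$stable_age)))
  lt_bad <- life_table(c(0.3, 0.1, 1, rep(0.1, 23)), 25)
  expect_error(build_leslie(lt_bad, breeding_params(first_breeding = 5)),
               "no reproductive path")
})

test_that("dominant eigenpair matches closed forms and the power-iteration oracle", {
  # two-year cycle: lambda^2 = 0.5
  e <- dominant_eigen(matrix(c(0, 1, 0.5, 0), 2, 2))
  expect_equal(e$lambda, sqrt(0.5), tolerance = 1e-12)

  pre <- cons_preset()
  pi_oracle <- power_iteration(pre$model$matrix)
  expect_equal(pre$model$lambda, pi_oracle$lambda, tolerance = 1e-6)
  expect_equal(pre$model$stable_age, pi_oracle$v, tolerance = 1e-6)
  # brute-force growth factor of successive totals converges to lambda
  expect_equal(projection_growth_rate(pre$model$matrix, 500),
               pre$model$lambda, tolerance = 1e-6)
})

test_that("the stable age distribution is a fixed point up to lambda", {
  pre <- cons_preset()
  v <- pre$model$stable_age
  w <- as.numeric(pre$model$matrix %*% v)
  expect_lt(max(abs(w - pre$model$lambda * v)), 1e-9)
  expect_equal(sum(v), 1, tolerance = 1e-9)
})

test_that("calibration hits the growth-rate band and the mature-fraction target", {
  pre <- cons_preset()
  expect_gte(pre$lambda, 1.095)
  expect_lte(pre$lambda, 1.105)
  expect_equal(pre$lambda_eff, 1.10, tolerance = 1e-6)
  expect_lt(abs(pre$mature_fraction - 0.513766), 0.06)
  cal <- attr(pre$life_table, "calibration")
  expect_gt(cal$q_adult, 0.005)
  expect_lt(cal$q_adult, 0.10)
})

test_that("calibration is deterministic and rejects infeasible targets", {
  t1 <- calibrate_life_table(calibration_targets(lambda = 1.10))
  t2 <- calibrate_life_table(calibration_targets(lambda = 1.10))
  expect_identical(t1$q, t2$q)
  # zero mortality everywhere with fecundity 0.5 forces lambda 1.5
  expect_error(
    calibrate_life_table(
      calibration_targets(lambda = 1.0),
      structure = list(q0 = 0, q_juvenile = 0, first_breeding = 1L,
                       max_age = 60L, q_adult_range = c(0, 0))),
    "infeasible")
  expect_error(
    calibrate_life_table(calibration_targets(lambda = 3)),
    "achievable range")
})

test_that("initial population conserves the total and matches the published mature count", {
  pre <- cons_preset()
  st <- initial_population(2e6, pre$model)
  expect_identical(sum(st), 2e6)
  expect_equal(sum(st[1, ]), sum(st[2, ]), tolerance = 1e-6)
  mature <- count_mature(st, pre$breeding$first_breeding)
  expect_lt(abs(mature - 1027532), 60000)
  # conservation of odd totals under largest-remainder rounding
  for (n0 in c(2, 17, 1001, 123457)) {
    expect_identical(sum(initial_population(n0, pre$model)), as.numeric(n0))
  }
  expect_error(initial_population(0, pre$model), "at least 2")
  expect_error(initial_population(1, pre$model), "at least 2")
})

test_that("count_mature sums both sexes at and above the breeding age", {
  counts <- matrix(0, 2, 10)
  st <- population_state(counts)
  expect_equal(count_mature(st, 5), 0)
  counts[1, 6] <- 5   # females age 6
  counts[2, 5] <- 10  # males age 5
  counts[2, 1] <- 99  # juveniles do not count
  st <- population_state(counts)
  expect_equal(count_mature(st, 5), 15)
})

test_that("maximum egg production is one egg per pair and reproduces the published maxima", {
  expect_identical(max_annual_eggs(1027532), 513766)
  expect_identical(max_annual_eggs(3082594), 1541297)
  expect_identical(max_annual_eggs(0), 0)
  expect_identical(max_annual_eggs(1), 0)
  m <- 0:2000
  expect_true(all(diff(max_annual_eggs(m)) >= 0))  # monotone
})
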