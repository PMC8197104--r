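test_that("vapor pressure follows the Magnus saturation curve and is linear in rh", {
  expect_equal(vapor_pressure(ta = 35, rh = 0), 0)
  expect_equal(vapor_pressure(20, 100), 611.2 * exp(17.62 * 20 / (243.12 + 20)))
  expect_equal(vapor_pressure(20, 50), vapor_pressure(20, 100) / 2)
  expect_error(vapor_pressure(20, 101), "rh")
  expect_error(vapor_pressure(20, -1), "rh")
})

test_that("clothing area factor has the printed two-branch form", {
  expect_equal(clothing_area_factor(0), 1.00)
  expect_equal(clothing_area_factor(0.155), 1.05 + 0.645 * 0.155)
  # the branch boundary belongs to the lower branch
  expect_equal(clothing_area_factor(0.078), 1.00 + 1.290 * 0.078)
  expect_error(clothing_area_factor(-0.01), "icl")
  icl <- seq(0, 0.5, by = 0.001)
  expect_true(all(diff(clothing_area_factor(icl)) >= 0))
})

test_that("convective coefficient takes the larger of the two branches", {
  expect_equal(convective_coeff(tcl = 20, ta = 20, var = 1), 12.1)
  expect_equal(convective_coeff(30, 20, 0.01), 2.38 * 10^0.25)
  expect_equal(convective_coeff(20.0001, 20, 4), 24.2)
  set.seed(1)
  tcl <- runif(50, -10, 40); ta <- runif(50, -10, 40); v <- runif(50, 0, 10)
  expect_equal(convective_coeff(tcl, ta, v),
               pmax(2.38 * abs(tcl - ta)^0.25, 12.1 * sqrt(v)))
  expect_error(convective_coeff(20, 20, -1), "var")
})

test_that("clothing temperature matches the brute-force bisection oracle", {
  # zero-gradient fixed point: naked subject in a uniform environment at
  # skin temperature
  p0 <- person_state(met_watts = 80, clo = 0)
  tsk <- 35.7 - 0.028 * p0$met
  fit0 <- solve_clothing_temperature(
    env_state(ta = tsk, tmrt = tsk, v = 0, rh = 50), p0)
  expect_equal(fit0$tcl, tsk, tolerance = 1e-4)

  # frozen regression fixtures from the scalar bisection oracle
  p1 <- person_state(met_watts = 58.15 * 1.80, clo = 1)
  fit1 <- solve_clothing_temperature(
    env_state(ta = 22, tmrt = 22, v = 0.1, rh = 60), p1)
  expect_equal(fit1$tcl, 26.97719, tolerance = 1e-3)

  p2 <- person_state(met_watts = 80, clo = 0.9)
  fit2 <- solve_clothing_temperature(
    env_state(ta = 0, tmrt = 10, v = 3, rh = 50), p2)
  expect_equal(fit2$tcl, 8.18857, tolerance = 1e-3)
})

test_that("pmv matches an independent transcription and is monotone in ta", {
  p1 <- person_state(met_watts = 58.15 * 1.80, clo = 1)
  out <- pmv(env_state(ta = 22, tmrt = 22, v = 0.1, rh = 60), p1)
  expect_equal(out$pmv, -0.27797, tolerance = 1e-3)
  out5 <- pmv(env_state(ta = 27, tmrt = 22, v = 0.1, rh = 60), p1)
  expect_gt(out5$pmv, out$pmv)

  p2 <- person_state(met_watts = 80, clo = 0.9)
  out2 <- pmv(env_state(ta = 0, tmrt = 10, v = 3, rh = 50), p2)
  expect_equal(out2$pmv, -14.78274, tolerance = 1e-3)
})

test_that("pmv solver agrees with the oracle over a random state grid", {
  set.seed(42)
  n <- 200
  ta <- runif(n, -20, 40)
  tmrt <- ta + runif(n, -20, 30)
  v <- runif(n, 0, 10)
  rh <- runif(n, 0, 100)
  person <- person_state(met_watts = 80, clo = 0.9)
  got <- pmv(env_state(ta = ta, tmrt = tmrt, v = v, rh = rh), person)$pmv
  want <- mapply(oracle_pmv, ta, tmrt, v, rh,
                 MoreArgs = list(met = person$met, work = 0, icl = person$icl))
  expect_lt(max(abs(got - want)), 1e-3)
})

test_that("pmv is zero exactly when the load is zero", {
  p <- person_state(met_watts = 58.15 * 1.80, clo = 1)
  # bisect air temperature to the neutral point, then confirm both vanish
  f <- function(t) pmv(env_state(ta = t, tmrt = t, v = 0.1, rh = 50), p)$pmv
  t_neutral <- uniroot(f, c(10, 35), tol = 1e-10)$root
  out <- pmv(env_state(ta = t_neutral, tmrt = t_neutral, v = 0.1, rh = 50), p)
  expect_equal(out$pmv, 0, tolerance = 1e-8)
  expect_equal(out$load, 0, tolerance = 1e-7)
})

test_that("PET of the reference environment is its own air temperature", {
  ta <- seq(-20, 40, by = 5)
  env <- env_state(ta = ta, tmrt = ta, v = 0.1, pa = 1200)
  expect_lt(max(abs(pet(env)$pet - ta)), 0.02)
})

test_that("PET is strictly increasing in air temperature", {
  set.seed(7)
  for (i in 1:5) {
    ta <- sort(runif(8, -15, 35))
    dt <- runif(1, -5, 15); v <- runif(1, 0.2, 6); rh <- runif(1, 20, 95)
    p <- pet(env_state(ta = ta, tmrt = ta + dt, v = v, rh = rh))$pet
    expect_true(all(diff(p) > 0))
  }
})

test_that("stronger wind lowers PET below skin temperature", {
  p_calm <- pet(env_state(ta = 0, tmrt = 0, v = 0.5, rh = 50))$pet
  p_windy <- pet(env_state(ta = 0, tmrt = 0, v = 5, rh = 50))$pet
  expect_lt(p_windy, p_calm)
})

test_that("augment_thermal_comfort appends the computed columns", {
  df <- tibble::tibble(ta = c(20, 0), tmrt = c(25, 5), v = c(1, 3),
                       rh = c(50, 70))
  out <- augment_thermal_comfort(df)
  expect_named(out, c("ta", "tmrt", "v", "rh", "pa", "pmv", "tcl", "pet"))
  expect_equal(out$pa, vapor_pressure(df$ta, df$rh))
  expect_error(augment_thermal_comfort(df[, -1]), "missing columns")
})
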