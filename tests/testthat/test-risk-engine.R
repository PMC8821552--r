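test_that("radiation incidence rate reproduces hand arithmetic", {
  # flat background 100/100k, coefficient 0.6 with reference-age modifiers
  reg <- data.frame(tissue = "stomach", sex = "female", rho = 0.6,
                    rho_lo = NA, rho_hi = NA, eta = -1.66, gamma = 0.019,
                    upsilon = NA, form = "solid")
  rates <- flat_rate_table("stomach", 100, 50)
  r <- radiation_incidence_rate("stomach", "female", a_E = 30, a = 70,
                                h = 1, rates = rates, registry = reg)
  expect_equal(r, 0.6 * 100 / 1e5)
  # mortality rate scales by the background mortality/incidence ratio
  m <- radiation_mortality_rate("stomach", "female", 30, 70, 1, rates, reg)
  expect_equal(m, 0.5 * r)
})

test_that("rates vanish at zero dose and inside the latency window", {
  pop <- get_preset("api_male")
  expect_equal(radiation_incidence_rate("colon", "male", 30, 40:60, 0,
                                        pop$rates), rep(0, 21))
  # solid latency 5 y: age 34.9 after exposure at 30 contributes nothing
  r <- radiation_incidence_rate("colon", "male", 30.5, 35, 1, pop$rates)
  expect_equal(r, 0)
  r5 <- radiation_incidence_rate("colon", "male", 30, 35:36, 1, pop$rates)
  expect_true(all(r5 > 0))
  # leukemia latency 2 y
  rl <- radiation_incidence_rate("leukemia", "male", 30.5, 32, 1, pop$rates)
  expect_equal(rl, 0)
  rl2 <- radiation_incidence_rate("leukemia", "male", 30, 33, 1, pop$rates)
  expect_gt(rl2, 0)
})

test_that("zero background mortality gives zero radiation mortality", {
  rates <- flat_rate_table("colon", 100, 0)
  m <- radiation_mortality_rate("colon", "female", 30, 50, 1, rates)
  expect_equal(m, 0)
  bad <- cancer_rate_table(
    data.frame(age = 0:100, tissue = "colon", incidence = 0, mortality = 5),
    sex = "female")
  expect_error(radiation_mortality_rate("colon", "female", 30, 50, 1, bad),
               "undefined")
})

test_that("null exposure gives exactly zero lifetime risk", {
  pop <- get_preset("white_male")
  sched <- exposure_schedule(35, 0, 0)
  res <- lifetime_risk(sched, pop$life_table, pop$rates)
  expect_true(all(res$reic == 0))
  expect_true(all(res$reid == 0))
  expect_identical(attr(res, "total_reic"), 0)
})

test_that("a two-age toy universe matches explicit hand enumeration", {
  mu <- 0.01
  lt <- const_hazard_table(mu)
  inc <- rep(0, 101); inc[c(41, 42)] <- 200  # ages 40 and 41
  mort <- inc / 2
  rates <- cancer_rate_table(
    data.frame(age = 0:100, tissue = "esophagus",
               incidence = inc, mortality = mort), sex = "female")
  sched <- exposure_schedule(30, h_solid = 1, h_leukemia = 0)
  res <- lifetime_risk(sched, lt, rates)
  # esophagus: rho = 0.3, no age modifiers -> lambda_I = 0.3 * 200e-5
  li <- 0.3 * 200 / 1e5
  lm <- li / 2
  expected_reic <- 100 * (li * exp(-40 * mu) +
                          li * exp(-41 * mu) * exp(-lm))
  expected_reid <- 100 * (lm * exp(-40 * mu) +
                          lm * exp(-41 * mu) * exp(-lm))
  expect_equal(res$reic, expected_reic, tolerance = 1e-12)
  expect_equal(res$reid, expected_reid, tolerance = 1e-12)
})

test_that("engine agrees with brute-force enumeration on random instances", {
  set.seed(101)
  for (i in 1:100) {
    inst <- random_instance()
    res <- lifetime_risk(inst$sched, inst$lt, inst$rates)
    orc <- oracle_risk(inst$sched, inst$lt, inst$rates)
    expect_equal(stats::setNames(res$reic, res$tissue),
                 orc$reic[res$tissue], tolerance = 1e-10)
    expect_equal(stats::setNames(res$reid, res$tissue),
                 orc$reid[res$tissue], tolerance = 1e-10)
  }
})

test_that("REID never exceeds REIC and totals are exact tissue sums", {
  fx <- get_gcr_flux()
  sched <- mission_exposure(mission_gcr_1yr(fx), 35)
  for (nm in c("white_female", "black_male", "api_female")) {
    pop <- get_preset(nm)
    res <- lifetime_risk(sched, pop$life_table, pop$rates)
    expect_true(all(res$reid <= res$reic + 1e-15))
    expect_equal(attr(res, "total_reic"), sum(res$reic), tolerance = 1e-9)
    expect_equal(attr(res, "total_reid"), sum(res$reid), tolerance = 1e-9)
  }
})

test_that("small-dose response is linear to 0.1 percent in TE mode", {
  pop <- get_preset("hispanic_male")
  eps <- 1e-3
  r1 <- attr(lifetime_risk(exposure_schedule(35, eps, eps),
                           pop$life_table, pop$rates), "total_reic")
  r2 <- attr(lifetime_risk(exposure_schedule(35, 2 * eps, 2 * eps),
                           pop$life_table, pop$rates), "total_reic")
  expect_equal(r2 / r1, 2, tolerance = 1e-3)
})

test_that("risk is monotone in dose and in life expectancy", {
  pop <- get_preset("white_male")
  r_lo <- attr(lifetime_risk(exposure_schedule(35, 0.2, 0.1),
                             pop$life_table, pop$rates), "total_reic")
  r_hi <- attr(lifetime_risk(exposure_schedule(35, 0.4, 0.2),
                             pop$life_table, pop$rates), "total_reic")
  expect_gt(r_hi, r_lo)
  # same background rates, two life tables: longer-lived population has
  # more remaining lifetime in which risk can be expressed
  lt_long <- make_life_table(population_spec("l", "male", 82, 500))
  lt_short <- make_life_table(population_spec("l", "male", 72, 500))
  sched <- exposure_schedule(35, 0.5, 0.2)
  expect_gt(attr(lifetime_risk(sched, lt_long, pop$rates), "total_reic"),
            attr(lifetime_risk(sched, lt_short, pop$rates), "total_reic"))
})

test_that("the competing-mortality decrement is small at GCR doses, large at multi-Gy", {
  pop <- get_preset("white_female")
  no_mort <- cancer_rate_table(
    transform(as.data.frame(pop$rates), mortality = 0),
    population = attr(pop$rates, "population"), sex = "female")
  sched <- mission_exposure(mission_gcr_1yr(get_gcr_flux()), 35)
  with_d <- attr(lifetime_risk(sched, pop$life_table, pop$rates), "total_reic")
  without_d <- attr(lifetime_risk(sched, pop$life_table, no_mort), "total_reic")
  expect_gte(without_d, with_d)           # dropping it can only increase REIC
  # the decrement is second order: bounded by the cumulative radiation
  # mortality itself (REID scale), so at annual-GCR doses it shifts REIC by
  # far less than the risk totals it protects against double-counting
  annual_effect <- without_d / with_d - 1
  reid_with <- attr(lifetime_risk(sched, pop$life_table, pop$rates),
                    "total_reid")
  expect_lt(annual_effect, 2 * reid_with / 100)
  big <- exposure_schedule(35, 10, 4)
  big_with <- attr(lifetime_risk(big, pop$life_table, pop$rates), "total_reic")
  big_without <- attr(lifetime_risk(big, pop$life_table, no_mort), "total_reic")
  big_effect <- big_without / big_with - 1
  expect_gt(big_effect, 10 * annual_effect)  # grows steeply with dose
})

test_that("tissues missing from the ERR registry are reported", {
  pop <- get_preset("api_female")
  reg <- err_registry()
  reg <- reg[reg$tissue != "thyroid", ]
  sched <- exposure_schedule(35, 0.1, 0.1)
  expect_error(lifetime_risk(sched, pop$life_table, pop$rates, registry = reg),
               "thyroid")
})
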