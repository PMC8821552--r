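test_that("zero-spread PDFs always return the point estimates", {
  pdfs <- parameter_pdfs(spread_scale = 0)
  central <- sample_parameters(pdfs, 0)
  for (trial in c(1, 7, 500)) {
    b <- sample_parameters(pdfs, trial)
    expect_equal(b$registry$rho, central$registry$rho)
    expect_equal(b$qf_solid$ddref, central$qf_solid$ddref)
    expect_equal(b$flux_scale, 1)
  }
})

test_that("sampling is a deterministic function of seed and trial index", {
  pdfs <- parameter_pdfs()
  b1 <- sample_parameters(pdfs, 42, master_seed = 9)
  b2 <- sample_parameters(pdfs, 42, master_seed = 9)
  expect_identical(b1, b2)
  b3 <- sample_parameters(pdfs, 43, master_seed = 9)
  expect_false(identical(b1$registry$rho, b3$registry$rho))
  b4 <- sample_parameters(pdfs, 42, master_seed = 10)
  expect_false(identical(b1$registry$rho, b4$registry$rho))
})

test_that("sampled parameters respect their domains and shared draws", {
  pdfs <- parameter_pdfs()
  for (trial in 1:50) {
    b <- sample_parameters(pdfs, trial, master_seed = 3)
    expect_true(all(b$registry$rho >= 0))
    expect_gte(b$qf_solid$ddref, 1)
    expect_identical(b$qf_solid$ddref, b$qf_leukemia$ddref)
    expect_gte(b$flux_scale, 0)
    # shared-coefficient tissues keep identical sexes within a trial
    for (tis in c("leukemia", "esophagus")) {
      rows <- b$registry[b$registry$tissue == tis, ]
      expect_equal(rows$rho[1], rows$rho[2])
    }
  }
})

test_that("sampled coefficient means match the fitted family", {
  pdfs <- parameter_pdfs()
  # all-solid female: symmetric interval [0.49, 0.72] around 0.6 -> normal
  spec <- pdfs$rho[["all_solid.female"]]
  expect_identical(spec$family, "normal")
  draws <- vapply(1:5000, function(i) {
    sample_parameters(pdfs, i, master_seed = 11)$registry$rho[
      pdfs$registry$tissue == "all_solid" & pdfs$registry$sex == "female"]
  }, numeric(1))
  expect_equal(mean(draws), 0.6, tolerance = 0.02)
  # strongly right-skewed positive intervals get a lognormal
  expect_identical(pdfs$rho[["brain.male"]]$family, "lognormal")
  # entries without an interval stay fixed
  expect_identical(pdfs$rho[["stomach.female"]]$family, "point")
})

test_that("an interval that fails to bracket its point estimate is rejected", {
  reg <- err_registry()
  reg$rho_lo[reg$tissue == "colon" & reg$sex == "male"] <- 0.9
  expect_error(parameter_pdfs(registry = reg), "bracket")
})

test_that("Monte-Carlo percentiles match analytic quantiles on a linear model", {
  pdfs <- parameter_pdfs()
  idx <- which(pdfs$registry$tissue == "all_solid" &
                 pdfs$registry$sex == "female")
  fn <- function(b) c(y = b$registry$rho[idx])
  mc <- mc_interval(fn, pdfs, n_trials = 4000, master_seed = 5)
  spec <- pdfs$rho[["all_solid.female"]]
  expect_equal(mc$point[["y"]], 0.6)
  expect_equal(mc$lower[["y"]], stats::qnorm(0.025, spec$mean, spec$sd),
               tolerance = 0.02)
  expect_equal(mc$upper[["y"]], stats::qnorm(0.975, spec$mean, spec$sd),
               tolerance = 0.02)
  expect_lt(mc$lower[["y"]], mc$point[["y"]])
  expect_gt(mc$upper[["y"]], mc$point[["y"]])
})

test_that("zero-spread intervals collapse to the point estimate", {
  pdfs <- parameter_pdfs(spread_scale = 0)
  idx <- which(pdfs$registry$tissue == "lung" & pdfs$registry$sex == "male")
  fn <- function(b) c(y = b$registry$rho[idx])
  mc <- mc_interval(fn, pdfs, n_trials = 100, master_seed = 1)
  expect_equal(mc$lower[["y"]], mc$point[["y"]])
  expect_equal(mc$upper[["y"]], mc$point[["y"]])
})

test_that("mission intervals are reproducible and wider with NTEs", {
  pop <- get_preset("white_female")
  prof <- mission_mars_940d(get_gcr_flux())
  pdfs <- parameter_pdfs()
  te1 <- mission_risk_mc(prof, 35, pop$life_table, pop$rates, "TE",
                         pdfs, n_trials = 150, master_seed = 17)
  te2 <- mission_risk_mc(prof, 35, pop$life_table, pop$rates, "TE",
                         pdfs, n_trials = 150, master_seed = 17)
  expect_identical(te1, te2)  # bit-exact under a fixed seed
  nte <- mission_risk_mc(prof, 35, pop$life_table, pop$rates, "NTE",
                         pdfs, n_trials = 150, master_seed = 17)
  expect_gt(nte$point[["reic_total"]], te1$point[["reic_total"]])
  w_nte <- nte$upper[["reic_total"]] - nte$lower[["reic_total"]]
  w_te <- te1$upper[["reic_total"]] - te1$lower[["reic_total"]]
  expect_gt(w_nte, w_te)
  # intervals bracket the point estimates
  expect_lt(te1$lower[["reic_total"]], te1$point[["reic_total"]])
  expect_gt(te1$upper[["reic_total"]], te1$point[["reic_total"]])
})

test_that("doubling the trial count leaves the point estimate unchanged", {
  pdfs <- parameter_pdfs()
  idx <- which(pdfs$registry$tissue == "all_solid" &
                 pdfs$registry$sex == "female")
  fn <- function(b) c(y = b$registry$rho[idx])
  a <- mc_interval(fn, pdfs, n_trials = 400, master_seed = 2)
  b <- mc_interval(fn, pdfs, n_trials = 800, master_seed = 2)
  expect_identical(a$point, b$point)
  # percentile estimates drift only within Monte-Carlo standard error
  sd_q <- pdfs$rho[["all_solid.female"]]$sd *
    sqrt(0.025 * 0.975 / 400) / stats::dnorm(stats::qnorm(0.975))
  expect_lt(abs(a$lower[["y"]] - b$lower[["y"]]), 6 * sd_q)
})

test_that("runs rejecting too many trials fail loudly", {
  pdfs <- parameter_pdfs()
  fn <- function(b) c(y = NaN)
  expect_error(suppressMessages(mc_interval(fn, pdfs, 100, 1)), "1%")
})
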