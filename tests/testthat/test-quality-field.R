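test_that("effective charge and speed behave at the kinematic limits", {
  # ultrarelativistic proton: Z* -> 1 and beta -> 1, so x -> 1
  expect_equal(effective_charge_sq_over_beta_sq(1, 1e6), 1, tolerance = 1e-3)
  # slow ion: screening drives the effective charge to zero
  x_slow <- effective_charge_sq_over_beta_sq(10, 1e-4)
  expect_lt(sqrt(x_slow * particle_beta2(1e-4)), 0.2)  # Z* << Z
  expect_error(particle_beta2(0), "positive")
  expect_error(effective_charge_sq_over_beta_sq(0.5, 100), ">= 1")
})

test_that("iron kinematics match an independent transcription of the formulas", {
  Z <- 26; E <- 1000
  gam <- 1 + E / 931.494
  beta <- sqrt(1 - gam^-2)
  zstar <- Z * (1 - exp(-125 * beta * Z^(-2 / 3)))
  expect_equal(effective_charge_sq_over_beta_sq(Z, E), zstar^2 / beta^2,
               tolerance = 1e-12)
})

test_that("parametric LET reproduces benchmark stopping powers in water", {
  # reference values for protons in water (PSTAR scale), keV/um
  expect_equal(let_water(1, 10), 4.56, tolerance = 0.05)
  expect_equal(let_water(1, 100), 0.75, tolerance = 0.05)
  expect_equal(let_water(1, 1000), 0.22, tolerance = 0.05)
  # 1 GeV/u iron ~ 150 keV/um
  expect_equal(let_water(26, 1000), 150, tolerance = 0.05)
})

test_that("P(Z,E) is a probability-like weight with the documented limits", {
  qp <- qf_params("solid")
  expect_lt(p_function(1, 1e-4, qp), 1e-3)           # stopping-particle limit
  expect_gt(p_function(26, 5, qp), 0.999)            # saturated heavy ion
  p <- vapply(c(1, 2, 8, 14, 26), p_function, numeric(1), E = 600, params = qp)
  expect_true(all(diff(p) > 0))                      # monotone in x at fixed E
  expect_true(all(p >= 0 & p <= 1))
  # direct transcription of the closed form at a mid-range point
  x <- effective_charge_sq_over_beta_sq(14, 600)
  expect_equal(p_function(14, 600, qp),
               (1 - exp(-x / qp$kappa))^qp$m * (1 - exp(-600 / 0.2)))
})

test_that("R_QF tends to 1/DDREF in the low-LET limit", {
  qp <- qf_params("solid", ddref = 2)
  expect_equal(r_qf(1, 2000, qp), 1 / qp$ddref, tolerance = 1e-3)
  qp1 <- qf_params("solid", ddref = 1.5)
  expect_equal(r_qf(1, 2000, qp1), 1 / 1.5, tolerance = 1e-3)
})

test_that("R_QF and the TE cross section satisfy the algebraic identity", {
  qp <- qf_params("solid")
  for (Z in c(2, 14, 26)) {
    E <- 600
    p <- p_function(Z, E, qp)
    L <- let_water(Z, E)
    lhs <- r_qf(Z, E, qp)
    rhs <- 6.24 * (sigma_te(Z, E, qp) - L * (1 - p) / 6.24) / L +
      (1 - p) / qp$ddref
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
  expect_error(r_qf(26, 600, qf_params(), let = 0), "LET")
})

test_that("bystander term switches off and saturates as designed", {
  qp <- qf_params("solid")
  off <- nte_params(eta0_over_alpha = 0)
  expect_equal(sigma_nte(26, 600, 0.01, qp, off), sigma_te(26, 600, qp))
  on <- nte_params(eta0_over_alpha = 0.015)
  expect_gt(sigma_nte(26, 600, 0.01, qp, on), sigma_te(26, 600, qp))
  # high-fluence limit: eta/F -> 0
  expect_equal(sigma_nte(26, 600, 1e9, qp, on), sigma_te(26, 600, qp),
               tolerance = 1e-6)
  expect_error(sigma_nte(26, 600, 0, qp, on), "positive")
  # direct transcription of the eta formula
  x <- effective_charge_sq_over_beta_sq(26, 600)
  F <- 0.02
  eta <- on$eta0_over_alpha * x * exp(-on$eta1 * x) * (1 - exp(-F * on$a_bys))
  expect_equal(sigma_nte(26, 600, F, qp, on),
               sigma_te(26, 600, qp) + eta / F, tolerance = 1e-12)
})

test_that("a delta-like spectrum folds to sigma times fluence", {
  qp <- qf_params("solid")
  E0 <- 600
  E <- seq(E0 - 0.5, E0 + 0.5, length.out = 11)
  F0 <- 0.03
  flux <- particle_flux(list(list(Z = 26, E = E, phi = rep(F0, 11))))
  expect_equal(fold_te(flux, qp), sigma_te(26, E0, qp) * F0, tolerance = 1e-4)
})

test_that("NTE fold dominates TE fold for arbitrary fluxes", {
  qp <- qf_params("solid")
  nt <- nte_params()
  set.seed(7)
  for (i in 1:25) {
    zs <- sample(c(1, 2, 6, 8, 14, 20, 26), sample(1:3, 1))
    comps <- lapply(zs, function(z) {
      E <- sort(runif(20, 10, 3000))
      list(Z = z, E = E, phi = runif(20, 0, 1e-3))
    })
    flux <- particle_flux(comps)
    expect_gte(fold_nte(flux, qp, nt), fold_te(flux, qp))
  }
})

test_that("coarse-grid folding agrees with a 10x refined quadrature", {
  qp <- qf_params("solid")
  spectrum <- function(E, z) (E / 300)^1.2 * exp(-E / 300) * 1e-3 / z
  make <- function(n) {
    particle_flux(lapply(c(2, 26), function(z) {
      E <- exp(seq(log(10), log(5000), length.out = n))
      list(Z = z, E = E, phi = spectrum(E, z))
    }))
  }
  coarse <- fold_te(make(120), qp)   # the generator's default resolution
  fine <- fold_te(make(1200), qp)
  expect_equal(coarse, fine, tolerance = 1e-3)
})

test_that("absorbed dose from a flux reproduces hand arithmetic", {
  # one proton component, flat phi over a narrow band: D = F * L / 6.24
  E <- seq(999.5, 1000.5, length.out = 5)
  phi <- rep(2, 5)  # total fluence 2 /um^2
  flux <- particle_flux(list(list(Z = 1, E = E, phi = phi)))
  expect_equal(absorbed_dose(flux), 2 * let_water(1, 1000) / 6.24,
               tolerance = 1e-4)
})

test_that("gamma-equivalent dose has the documented low-LET and linear limits", {
  # pure high-energy proton field: P ~ 0, so H ~ D_physical / DDREF
  E <- exp(seq(log(500), log(4000), length.out = 40))
  flux <- particle_flux(list(list(Z = 1, E = E, phi = 1e-3 * exp(-E / 1000))))
  d <- absorbed_dose(flux)
  expect_equal(gamma_equivalent_dose(flux, qf_params("solid", ddref = 2)),
               d / 2, tolerance = 1e-3)
  expect_equal(gamma_equivalent_dose(flux, qf_params("solid", ddref = 1)),
               d, tolerance = 1e-3)
  # TE mode is exactly linear in fluence scale
  qp <- qf_params("solid")
  gf <- get_gcr_flux()
  expect_equal(gamma_equivalent_dose(scale_flux(gf, 3), qp),
               3 * gamma_equivalent_dose(gf, qp), tolerance = 1e-12)
  # NTE mode: H per unit fluence non-increasing in fluence (saturation)
  nt <- nte_params()
  h1 <- gamma_equivalent_dose(scale_flux(gf, 10), qp, "NTE", nt) / 10
  h2 <- gamma_equivalent_dose(scale_flux(gf, 100), qp, "NTE", nt) / 100
  expect_lte(h2, h1)
  expect_gte(gamma_equivalent_dose(gf, qp, "NTE", nt),
             gamma_equivalent_dose(gf, qp, "TE"))
})

test_that("flux objects validate their structure and support I/O", {
  expect_error(particle_flux(list(list(Z = 1, E = c(1, 1), phi = c(1, 1)))),
               "strictly increasing")
  expect_error(particle_flux(list(list(Z = 1, E = c(1, 2), phi = c(-1, 1)))),
               "non-negative")
  fx <- particle_flux(list(list(Z = 2, E = c(10, 20, 30), phi = c(1, 2, 1))))
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(Z = 2, E_MeV_u = c(10, 20, 30),
                              phi_per_um2_per_MeVu = c(1, 2, 1)),
                   path, row.names = FALSE)
  back <- read_flux(path)
  expect_equal(fold_te(back, qf_params()), fold_te(fx, qf_params()))
  expect_warning(fold_te(particle_flux(list()), qf_params()), "empty")
})
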