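# Independent oracles: naive reimplementations used only to check the
# package's vectorised paths. Kept deliberately loop-based and transcribed
# straight from the model definitions.

# fine-grid quadrature of E[min(T, 100)] for a piecewise-constant hazard
oracle_life_expectancy <- function(hazard, dt = 1e-3) {
  tt <- seq(0, 100, by = dt)
  a <- pmin(floor(tt), 100)
  cumh <- c(0, cumsum(hazard))          # integrated hazard at integer ages
  s <- exp(-(cumh[a + 1] + hazard[pmin(a, 100) + 1] * (tt - a)))
  pracma::trapz(tt, s)
}

# brute-force enumeration of the double lifetime-risk sum
oracle_risk <- function(sched, lt, rates, registry = err_registry(),
                        latency = c(solid = 5, leukemia = 2)) {
  sex <- attr(rates, "sex")
  tissues <- unique(rates$tissue)
  lam_i <- lam_m <- matrix(0, 100, length(tissues),
                           dimnames = list(NULL, tissues))
  for (ti in seq_along(tissues)) {
    tis <- tissues[ti]
    row <- registry[registry$tissue == tis & registry$sex == sex, ]
    sub <- rates[rates$tissue == tis, ]
    for (t in 0:99) {
      inc0 <- sub$incidence[sub$age == t]
      mort0 <- sub$mortality[sub$age == t]
      li <- 0
      for (j in seq_len(nrow(sched))) {
        aE <- sched$age[j]
        if (row$form == "leukemia") {
          if (t < aE + latency[["leukemia"]]) next
          e <- row$rho * sched$h_leukemia[j] * (t / 70)^row$eta *
            ((t - aE) / 40)^row$upsilon
        } else {
          if (t < aE + latency[["solid"]]) next
          eta <- if (is.na(row$eta)) 0 else row$eta
          gam <- if (is.na(row$gamma)) 0 else row$gamma
          e <- row$rho * sched$h_solid[j] * (t / 70)^eta *
            exp(gam * (aE - 30))
        }
        li <- li + e * inc0 / 1e5
      }
      lam_i[t + 1, ti] <- li
      lam_m[t + 1, ti] <- if (inc0 > 0) li * mort0 / inc0 else 0
    }
  }
  reic <- reid <- stats::setNames(numeric(length(tissues)), tissues)
  for (t in 0:99) {
    inner <- 0
    if (t > 0) for (z in 0:(t - 1)) inner <- inner + sum(lam_m[z + 1, ])
    w <- lt$survival[lt$age == t] * exp(-inner)
    for (ti in seq_along(tissues)) {
      reic[ti] <- reic[ti] + 100 * lam_i[t + 1, ti] * w
      reid[ti] <- reid[ti] + 100 * lam_m[t + 1, ti] * w
    }
  }
  list(reic = reic, reid = reid)
}
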