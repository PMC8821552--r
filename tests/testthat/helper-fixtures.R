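# Shared fixtures, built in code at test time.

# life table with constant all-cause hazard
const_hazard_table <- function(mu, sex = "female", population = "toy") {
  life_table(0:100, hazard = rep(mu, 101), population = population, sex = sex)
}

# rate table with age-flat incidence/mortality for the given tissues
flat_rate_table <- function(tissues, incidence, mortality,
                            sex = "female", population = "toy") {
  rows <- lapply(seq_along(tissues), function(i) {
    data.frame(age = 0:100, tissue = tissues[i],
               incidence = rep(incidence[min(i, length(incidence))], 101),
               mortality = rep(mortality[min(i, length(mortality))], 101))
  })
  cancer_rate_table(do.call(rbind, rows), population = population, sex = sex)
}

# randomised small risk-engine instance (deterministic given the RNG state)
random_instance <- function() {
  sex <- sample(c("female", "male"), 1)
  lt <- life_table(0:100, hazard = runif(101, 0, 0.08),
                   population = "rand", sex = sex)
  pool <- c("stomach", "colon", "liver", "esophagus", "leukemia", "lung")
  tissues <- sample(pool, sample(2:3, 1))
  rows <- lapply(tissues, function(tis) {
    base <- runif(1, 10, 300)
    inc <- base * (0.2 + runif(101))
    data.frame(age = 0:100, tissue = tis, incidence = inc,
               mortality = inc * runif(1, 0.1, 1 / 1.1))
  })
  rates <- cancer_rate_table(do.call(rbind, rows),
                             population = "rand", sex = sex)
  n_ev <- sample(1:3, 1)
  ages <- sort(runif(n_ev, 18, 60))
  while (any(diff(ages) <= 0.1)) ages <- sort(runif(n_ev, 18, 60))
  sched <- exposure_schedule(ages,
                             h_solid = runif(n_ev, 0, 2),
                             h_leukemia = runif(n_ev, 0, 1))
  list(lt = lt, rates = rates, sched = sched)
}

# cached default synthetic presets (generation is deterministic)
preset_cache <- new.env(parent = emptyenv())
get_preset <- function(name) {
  if (is.null(preset_cache[[name]])) {
    preset_cache[[name]] <- synthesize_population(name)
  }
  preset_cache[[name]]
}

flux_cache <- new.env(parent = emptyenv())
get_gcr_flux <- function() {
  if (is.null(flux_cache$fx)) flux_cache$fx <- make_gcr_flux(0.4)
  flux_cache$fx
}
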