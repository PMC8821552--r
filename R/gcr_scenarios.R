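#' Default GCR species groups
#'
#' Number-fluence fractions for the five ion groups used by the synthetic
#' GCR spectrum (hydrogen, helium, a C/O medium group, a Si group and an Fe
#' group), representative of a shielded free-space GCR field: protons and
#' helium dominate the particle count while the rare heavy groups carry a
#' disproportionate share of dose and dose equivalent (the defaults give a
#' dose-averaged quality factor near 4, on the scale reported for shielded
#' GCR fields). Editable configuration for the generator.
#'
#' @return Data frame with columns `species`, `Z`, `fraction` (sums to 1).
#' @export
gcr_species_mix <- function() {
  data.frame(species = c("H", "He", "CO-group", "Si-group", "Fe-group"),
             Z = c(1, 2, 8, 14, 26),
             fraction = c(0.89415, 0.10000, 0.00500, 0.00070, 0.00015))
}

#' Synthetic GCR-like mixed-ion flux
#'
#' Deterministic parametric stand-in for a transported galactic-cosmic-ray
#' spectrum behind nominal shielding (20 g/cm^2 aluminum): each species gets
#' a broad energy distribution \eqn{\phi(E) \propto (E/E_s)^{p} e^{-E/E_s}}
#' peaking at a few hundred MeV/u, and the whole field is scaled so the
#' physical absorbed-dose rate (via [absorbed_dose()]) equals
#' `dose_rate_target`. This is synthetic plumbing replacing environment and
#' transport codes, not a transport calculation; it reproduces the gross
#' features (mixed charges, broad spectra, chosen dose rate) that the risk
#' pipeline consumes.
#'
#' @param dose_rate_target Absorbed dose rate in mGy/day (> 0).
#' @param species_mix Data frame as in [gcr_species_mix()].
#' @param e_grid Energy grid in MeV/u (default 120 log-spaced points,
#'   10-5000 MeV/u, dense enough that trapezoidal folding is converged to
#'   about 1e-3 relative).
#' @param peak_energy Scale energy `E_s` in MeV/u.
#' @param power Low-energy power `p`.
#' @return A [particle_flux()] whose `phi` are daily fluence rates
#'   (um^-2 MeV/u^-1 day^-1), with attribute `dose_rate_mGy_day`.
#' @export
make_gcr_flux <- function(dose_rate_target = 0.4,
                          species_mix = gcr_species_mix(),
                          e_grid = exp(seq(log(10), log(5000),
                                           length.out = 120)),
                          peak_energy = 250, power = 1.2) {
  stopifnot(dose_rate_target > 0)
  if (abs(sum(species_mix$fraction) - 1) > 1e-8) {
    stop("species_mix fractions must sum to 1")
  }
  shape <- (e_grid / peak_energy)^power * exp(-e_grid / peak_energy)
  comps <- lapply(seq_len(nrow(species_mix)), function(i) {
    list(Z = species_mix$Z[i], E = e_grid,
         phi = species_mix$fraction[i] * shape,
         species = species_mix$species[i])
  })
  flux <- particle_flux(comps)
  d0 <- absorbed_dose(flux) * 1000  # mGy per day at unit scale
  flux <- scale_flux(flux, dose_rate_target / d0)
  attr(flux, "dose_rate_mGy_day") <- dose_rate_target
  attr(flux, "synthetic") <- TRUE
  attr(flux, "shield_label") <- "20 g/cm^2 aluminum (nominal, by construction)"
  flux
}

#' Mission exposure profile
#'
#' A sequence of mission segments, each with a duration in days and a flux
#' attenuation factor applied to the reference in-space flux (e.g. Mars
#' atmospheric shielding on surface segments; the attenuation is a single
#' multiplicative knob, not a transport result).
#'
#' @param segments Data frame with columns `label`, `duration_days`,
#'   `attenuation` (multiplier on the daily flux, 1 = free space).
#' @param flux Reference daily [particle_flux()] (e.g. [make_gcr_flux()]).
#' @param solar_condition Text label.
#' @param shield_label Text label.
#' @return Object of class `mission_profile`.
#' @export
mission_profile <- function(segments, flux,
                            solar_condition = "average solar minimum",
                            shield_label = "20 g/cm^2 aluminum") {
  need <- c("label", "duration_days", "attenuation")
  if (!all(need %in% names(segments))) {
    stop("segments must have columns: ", paste(need, collapse = ", "))
  }
  if (any(segments$duration_days <= 0)) stop("segment durations must be positive")
  if (any(segments$attenuation < 0)) stop("attenuation must be non-negative")
  structure(list(segments = segments, flux = flux,
                 solar_condition = solar_condition,
                 shield_label = shield_label,
                 total_days = sum(segments$duration_days)),
            class = "mission_profile")
}

#' @export
print.mission_profile <- function(x, ...) {
  cat(sprintf("Mission profile: %d segment(s), %g days total (%s, %s)\n",
              nrow(x$segments), x$total_days, x$solar_condition,
              x$shield_label))
  invisible(x)
}

#' Preset mission profiles
#'
#' `mission_gcr_1yr()` is a single 365-day deep-space segment at average
#' solar minimum. `mission_mars_940d()` is the 940-day Mars reference
#' mission: 400 days total transit plus 540 days on the surface, where the
#' Mars atmosphere is represented by a multiplicative flux attenuation.
#'
#' @param flux Daily reference flux; defaults to [make_gcr_flux()].
#' @param surface_attenuation Flux multiplier on the Mars surface.
#' @return A [mission_profile()].
#' @export
mission_gcr_1yr <- function(flux = make_gcr_flux()) {
  mission_profile(
    data.frame(label = "deep space", duration_days = 365, attenuation = 1),
    flux)
}

#' @rdname mission_gcr_1yr
#' @export
mission_mars_940d <- function(flux = make_gcr_flux(),
                              surface_attenuation = 0.45) {
  mission_profile(
    data.frame(label = c("transit", "mars surface"),
               duration_days = c(400, 540),
               attenuation = c(1, surface_attenuation)),
    flux)
}

#' Read a mission profile from a scenario YAML file
#'
#' Expects a top-level `mission:` block with `dose_rate_mGy_day`,
#' `solar_condition`, `shield_label` and a `segments:` list of
#' `label/duration_days/attenuation` entries. See the presets under
#' `inst/extdata/` for the format.
#'
#' @param path YAML file path.
#' @return A [mission_profile()].
#' @export
read_mission_profile <- function(path) {
  cfg <- yaml::read_yaml(path)$mission
  if (is.null(cfg)) stop("scenario file must contain a 'mission:' block")
  seg <- do.call(rbind, lapply(cfg$segments, as.data.frame))
  mission_profile(seg,
                  flux = make_gcr_flux(cfg$dose_rate_mGy_day %||% 0.4),
                  solar_condition = cfg$solar_condition %||% "average solar minimum",
                  shield_label = cfg$shield_label %||% "20 g/cm^2 aluminum")
}

#' Exposure schedule of discrete gamma-equivalent dose events
#'
#' Each mission segment is lumped into one acute exposure event at the
#' segment's midpoint age, carrying the segment's gamma-equivalent dose for
#' the solid-cancer and leukemia endpoint classes (distinct quality-factor
#' parameter sets).
#'
#' @param age Exposure ages in years (strictly increasing).
#' @param h_solid,h_leukemia Gamma-equivalent doses in Gy per event (>= 0).
#' @param mode `"TE"` or `"NTE"` (metadata).
#' @return Object of class `exposure_schedule` (a data frame).
#' @export
exposure_schedule <- function(age, h_solid, h_leukemia, mode = "TE") {
  stopifnot(length(age) == length(h_solid),
            length(age) == length(h_leukemia))
  if (length(age) > 1 && any(diff(age) <= 0)) {
    stop("exposure ages must be strictly increasing")
  }
  if (any(h_solid < 0) || any(h_leukemia < 0)) {
    stop("gamma-equivalent doses must be non-negative")
  }
  structure(data.frame(age = age, h_solid = h_solid, h_leukemia = h_leukemia),
            mode = mode,
            class = c("exposure_schedule", "data.frame"))
}

#' Convert a mission profile to an exposure schedule
#'
#' For each segment: cumulative fluence = daily flux x duration x
#' attenuation; the gamma-equivalent dose is computed per endpoint class via
#' [gamma_equivalent_dose()] (in NTE mode the bystander saturation sees the
#' segment's total fluence); the exposure age is the segment midpoint.
#'
#' @param profile A [mission_profile()].
#' @param crew_age_at_start Age in years at mission start.
#' @param solid_params,leukemia_params [qf_params()] per endpoint class.
#' @param mode `"TE"` or `"NTE"`.
#' @param nte A [nte_params()] (NTE mode).
#' @return An [exposure_schedule()].
#' @export
mission_exposure <- function(profile, crew_age_at_start,
                             solid_params = qf_params("solid"),
                             leukemia_params = qf_params("leukemia"),
                             mode = c("TE", "NTE"), nte = nte_params()) {
  stopifnot(inherits(profile, "mission_profile"))
  mode <- match.arg(mode)
  end_age <- crew_age_at_start + profile$total_days / 365.25
  if (crew_age_at_start < 0 || end_age > 100) {
    stop("mission schedule extends beyond the age grid 0..100")
  }
  offsets <- cumsum(c(0, profile$segments$duration_days))
  n <- nrow(profile$segments)
  age <- h_s <- h_l <- numeric(n)
  for (i in seq_len(n)) {
    seg <- profile$segments[i, ]
    seg_flux <- scale_flux(profile$flux, seg$duration_days * seg$attenuation)
    age[i] <- crew_age_at_start + (offsets[i] + seg$duration_days / 2) / 365.25
    h_s[i] <- gamma_equivalent_dose(seg_flux, solid_params, mode, nte)
    h_l[i] <- gamma_equivalent_dose(seg_flux, leukemia_params, mode, nte)
  }
  exposure_schedule(age, h_s, h_l, mode = mode)
}
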