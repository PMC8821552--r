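#' Specification for a synthetic population
#'
#' Bundles the calibration targets and shape parameters used to generate a
#' life table and a background cancer-rate table with the statistical
#' structure the risk projection assumes. Life tables are Gompertz-Makeham;
#' cancer-rate curves are power-law-onset in age (with a childhood-pattern
#' override for leukemia), scaled so the age-adjusted total matches the
#' target.
#'
#' @param population Population label.
#' @param sex `"female"` or `"male"`.
#' @param life_expectancy Target life expectancy at birth in years
#'   (must lie in (40, 100)).
#' @param age_adjusted_total Target age-adjusted total cancer incidence per
#'   100,000 under the package standard weights.
#' @param tissue_mix Named fractions of total incidence per tissue (summing
#'   to 1); defaults from [default_tissue_mix()].
#' @param mortality_to_incidence Named per-tissue mortality/incidence ratios
#'   in (0, 1/1.1]; defaults from [default_mortality_ratios()].
#' @param makeham_c Age-independent (Makeham) hazard component per year.
#' @param gompertz_theta Gompertz slope per year of age.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(population, sex = c("female", "male"),
                            life_expectancy, age_adjusted_total,
                            tissue_mix = NULL,
                            mortality_to_incidence = default_mortality_ratios(),
                            makeham_c = 2e-4, gompertz_theta = 0.095) {
  sex <- match.arg(sex)
  if (is.null(tissue_mix)) tissue_mix <- default_tissue_mix(sex)
  if (!(life_expectancy > 40 && life_expectancy < 100)) {
    stop("target life expectancy must lie in (40, 100) years")
  }
  if (age_adjusted_total <= 0) stop("age_adjusted_total must be positive")
  if (any(tissue_mix < 0)) stop("tissue_mix fractions must be non-negative")
  s <- sum(tissue_mix)
  if (abs(s - 1) > 1e-8) stop("tissue_mix fractions must sum to 1")
  bad <- setdiff(names(tissue_mix), cancer_tissues(sex))
  if (length(bad) > 0) {
    stop("tissue_mix names tissues not applicable to ", sex, ": ",
         paste(bad, collapse = ", "))
  }
  structure(list(population = population, sex = sex,
                 life_expectancy = life_expectancy,
                 age_adjusted_total = age_adjusted_total,
                 tissue_mix = tissue_mix,
                 mortality_to_incidence = mortality_to_incidence,
                 makeham_c = makeham_c, gompertz_theta = gompertz_theta),
            class = "population_spec")
}

#' Default tissue shares of total cancer incidence
#'
#' Coarse sex-specific site distribution of incident cancers across the
#' modelled sites, loosely patterned on published U.S. site distributions.
#' These are editable defaults for the synthetic generator, not survey
#' estimates. The `other` (remainder) share absorbs whatever the named sites
#' leave over.
#'
#' @param sex `"female"` or `"male"`.
#' @return Named numeric vector summing to 1.
#' @export
default_tissue_mix <- function(sex = c("female", "male")) {
  sex <- match.arg(sex)
  mix <- if (sex == "female") {
    c(breast = 0.290, lung = 0.120, colon = 0.080, thyroid = 0.060,
      ovary = 0.025, bladder = 0.025, stomach = 0.018, liver = 0.018,
      pancreas = 0.032, brain = 0.015, esophagus = 0.005, leukemia = 0.035)
  } else {
    c(prostate = 0.270, lung = 0.130, colon = 0.090, bladder = 0.060,
      stomach = 0.020, liver = 0.025, pancreas = 0.032, brain = 0.015,
      esophagus = 0.012, thyroid = 0.020, leukemia = 0.040)
  }
  c(mix, other = 1 - sum(mix))
}

#' Default mortality/incidence ratio per tissue
#'
#' Lethality profile used when generating synthetic mortality curves; all
#' values respect the 10 percent incidence-over-mortality margin, so the
#' mortality-consistency correction is never triggered on generated tables.
#'
#' @return Named numeric vector with entries in (0, 1/1.1].
#' @export
default_mortality_ratios <- function() {
  c(lung = 0.65, stomach = 0.65, colon = 0.40, liver = 0.85, bladder = 0.25,
    esophagus = 0.85, brain = 0.75, pancreas = 0.90, breast = 0.20,
    ovary = 0.60, prostate = 0.18, thyroid = 0.05, other = 0.45,
    leukemia = 0.55)
}

#' Generate a life table calibrated to a target life expectancy
#'
#' The all-cause hazard is Gompertz-Makeham,
#' \eqn{\mu(a) = c + b e^{\theta a}}, with the Makeham constant `c` and slope
#' `theta` fixed by the spec and the level `b` solved by one-dimensional root
#' finding so that the life expectancy at birth of the resulting table hits
#' the target. Deterministic given the spec.
#'
#' @param spec A [population_spec()].
#' @param tolerance Calibration tolerance on life expectancy in years.
#' @return A [life_table()].
#' @export
make_life_table <- function(spec, tolerance = 0.1) {
  stopifnot(inherits(spec, "population_spec"))
  ages <- 0:100
  le_of_b <- function(log_b) {
    h <- spec$makeham_c + exp(log_b) * exp(spec$gompertz_theta * ages)
    life_expectancy(life_table(ages, hazard = h))
  }
  lo <- log(1e-10); hi <- log(1)
  f_lo <- le_of_b(lo) - spec$life_expectancy  # low b -> high LE
  f_hi <- le_of_b(hi) - spec$life_expectancy
  if (f_lo < 0 || f_hi > 0) {
    stop(sprintf(
      "target life expectancy %.1f y infeasible for Gompertz-Makeham with c=%g, theta=%g (attainable range %.2f..%.2f)",
      spec$life_expectancy, spec$makeham_c, spec$gompertz_theta,
      le_of_b(hi), le_of_b(lo)))
  }
  root <- stats::uniroot(function(lb) le_of_b(lb) - spec$life_expectancy,
                         c(lo, hi), tol = 1e-10)
  b <- exp(root$root)
  h <- spec$makeham_c + b * exp(spec$gompertz_theta * ages)
  out <- life_table(ages, hazard = h,
                    population = spec$population, sex = spec$sex)
  achieved <- life_expectancy(out)
  if (abs(achieved - spec$life_expectancy) > tolerance) {
    stop(sprintf("calibration missed target: achieved %.3f vs %.3f",
                 achieved, spec$life_expectancy))
  }
  attr(out, "gompertz_b") <- b
  out
}

#' Generate background cancer rates calibrated to an age-adjusted total
#'
#' Per-tissue incidence curves are multistage-carcinogenesis power laws in
#' age with an old-age roll-off,
#' \eqn{\lambda_{0IT}(a) = A_T (a/70)^{k_T} e^{-\max(a - a_{pk,T}, 0)/8}},
#' with documented powers and peak ages per tissue and a childhood-pattern
#' override for leukemia (early-childhood peak plus adult rise). The
#' roll-off keeps old-age rates on the observed rise-and-plateau pattern
#' rather than growing without bound. Each tissue curve is
#' normalised so its age-adjusted rate equals its `tissue_mix` share of the
#' target total; the table's age-adjusted total therefore matches the target
#' by construction. Mortality is incidence times the per-tissue
#' mortality-to-incidence ratio, passed through the consistency correction.
#'
#' @param spec A [population_spec()].
#' @param life_table The matching [life_table()] (label/sex must agree).
#' @param weights Standardisation weights for the calibration (defaults to
#'   the package standard).
#' @return A [cancer_rate_table()].
#' @export
make_cancer_rates <- function(spec, life_table,
                              weights = us2000_standard_weights()) {
  stopifnot(inherits(spec, "population_spec"),
            inherits(life_table, "life_table"))
  if (!identical(attr(life_table, "population"), spec$population) ||
      !identical(attr(life_table, "sex"), spec$sex)) {
    stop("spec and life_table must refer to the same population and sex")
  }
  mi <- spec$mortality_to_incidence
  miss_mi <- setdiff(names(spec$tissue_mix), names(mi))
  if (length(miss_mi) > 0) {
    stop("mortality_to_incidence missing tissue(s): ",
         paste(miss_mi, collapse = ", "))
  }
  ages <- 0:100
  rows <- lapply(names(spec$tissue_mix), function(tis) {
    shp <- tissue_shape(tis, ages)
    aa <- sum(weights * shp)
    if (aa <= 0) stop("degenerate age shape for tissue ", tis)
    inc <- spec$age_adjusted_total * spec$tissue_mix[[tis]] * shp / aa
    data.frame(age = ages, tissue = tis, incidence = inc,
               mortality = inc * mi[[tis]])
  })
  tab <- cancer_rate_table(do.call(rbind, rows),
                           population = spec$population, sex = spec$sex)
  suppressMessages(apply_mortality_correction(tab))
}

# unit age-shape of incidence for one tissue (arbitrary scale): a
# multistage-carcinogenesis power of age with an old-age roll-off beyond a
# tissue-typical peak age, mimicking the rise-and-plateau of observed
# age-incidence curves; powers and peak ages are generator conventions
# patterned on gross epidemiologic shapes, not fitted values
tissue_shape <- function(tissue, ages) {
  if (tissue == "leukemia") {
    # childhood (ALL-like) peak near age 4 plus an adult (AML/CML-like) rise
    return(4 * exp(-((ages - 4) / 4)^2) +
             (ages / 60)^2.2 * exp(-pmax(ages - 85, 0) / 8))
  }
  pars <- list(
    lung      = c(k = 5.5, peak = 80),
    stomach   = c(k = 5.0, peak = 85),
    colon     = c(k = 5.0, peak = 85),
    liver     = c(k = 5.0, peak = 80),
    bladder   = c(k = 6.0, peak = 85),
    esophagus = c(k = 5.5, peak = 80),
    brain     = c(k = 1.6, peak = 80),
    pancreas  = c(k = 5.5, peak = 85),
    breast    = c(k = 3.0, peak = 70),
    ovary     = c(k = 3.5, peak = 75),
    prostate  = c(k = 9.0, peak = 75),
    thyroid   = c(k = 1.3, peak = 55),
    other     = c(k = 4.5, peak = 80)
  )[[tissue]]
  if (is.null(pars)) stop("no shape defined for tissue ", tissue)
  (ages / 70)^pars[["k"]] * exp(-pmax(ages - pars[["peak"]], 0) / 8)
}

#' Preset synthetic-population specifications
#'
#' Eight presets (four U.S. race/ethnicity groups x two sexes) whose
#' calibration targets are the published 2018 life expectancies and the
#' 2014-2018 age-adjusted total cancer incidence rates:
#' Asian-Pacific Islander (API) female/male 86/81 y and 328.2/311.2 per
#' 100,000; Black 78.0/71.3 y and 400.2/516.1; Hispanic (white and black)
#' 84.3/79.1 y and 355.9/371.0; White (non-Hispanic) 81.1/76.2 y and
#' 460.2/520.4.
#'
#' @param name Optional preset name such as `"api_female"`; with `NULL`,
#'   all eight specs are returned as a named list.
#' @return A [population_spec()] or a named list of them.
#' @export
population_presets <- function(name = NULL) {
  targets <- list(
    api      = list(le = c(female = 86.0, male = 81.0),
                    aa = c(female = 328.2, male = 311.2)),
    black    = list(le = c(female = 78.0, male = 71.3),
                    aa = c(female = 400.2, male = 516.1)),
    hispanic = list(le = c(female = 84.3, male = 79.1),
                    aa = c(female = 355.9, male = 371.0)),
    white    = list(le = c(female = 81.1, male = 76.2),
                    aa = c(female = 460.2, male = 520.4))
  )
  all <- list()
  for (pop in names(targets)) {
    for (sx in c("female", "male")) {
      all[[paste(pop, sx, sep = "_")]] <-
        population_spec(pop, sx,
                        life_expectancy = targets[[pop]]$le[[sx]],
                        age_adjusted_total = targets[[pop]]$aa[[sx]])
    }
  }
  if (is.null(name)) return(all)
  if (!name %in% names(all)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(all), collapse = ", "))
  }
  all[[name]]
}

#' Build the full synthetic input set for one preset population
#'
#' Convenience wrapper: generates the calibrated life table and cancer-rate
#' table for a preset (or explicit spec).
#'
#' @param spec A preset name (see [population_presets()]) or a
#'   [population_spec()].
#' @return List with elements `spec`, `life_table`, `rates`.
#' @export
synthesize_population <- function(spec) {
  if (is.character(spec)) spec <- population_presets(spec)
  lt <- make_life_table(spec)
  rates <- make_cancer_rates(spec, lt)
  list(spec = spec, life_table = lt, rates = rates)
}
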