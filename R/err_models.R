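#' Excess-relative-risk parameter registry
#'
#' Tissue- and sex-specific excess relative risk (ERR) coefficients from
#' recent Life Span Study (LSS) incidence analyses, as used by the risk
#' projection. For solid cancers the model is
#' \deqn{ERR(D, a, a_E) = \rho_{sex} D (a/70)^{\eta} \exp[\gamma (a_E - 30)]}
#' with `rho` the ERR per Gy, `eta` the attained-age power and `gamma` the
#' age-at-exposure coefficient per year. Leukemia (excluding CLL) replaces the
#' age-at-exposure modifier with a time-since-exposure factor with power
#' `upsilon` (default -0.81). Modifiers not reported for a tissue (e.g.
#' stomach, esophagus, pancreas, ovary, prostate age trends) are zero,
#' meaning no age dependence. Lung uses the zero-smoking limit of the LSS
#' generalized multiplicative smoking model, entering here as a plain
#' solid-cancer row. Thyroid carries BEIR-VII-style defaults (ERR/Gy 1.05
#' female / 0.53 male with exponential age-at-exposure decline), marked
#' configurable since this registry does not pin them to an LSS fit; the
#' remainder ("other") row is the LSS remainder grouping. The synthetic
#' `all_solid` row aggregates all solid cancers and is used for diagnostics,
#' not in the per-tissue risk engine. Uterine cancer is excluded (negligible
#' estimated radiogenic risk).
#'
#' 95\% confidence bounds on `rho` (`rho_lo`, `rho_hi`) and on `upsilon` feed
#' the Monte-Carlo uncertainty module; they are `NA` where unreported.
#'
#' @return Data frame with one row per tissue x sex: columns `tissue`, `sex`,
#'   `rho`, `rho_lo`, `rho_hi`, `eta`, `gamma`, `upsilon`, `form`.
#' @export
err_registry <- function() {
  row <- function(tissue, sex, rho, lo, hi, eta, gamma, upsilon = NA_real_,
                  form = "solid") {
    data.frame(tissue = tissue, sex = sex, rho = rho, rho_lo = lo,
               rho_hi = hi, eta = eta, gamma = gamma, upsilon = upsilon,
               form = form, stringsAsFactors = FALSE)
  }
  both <- function(tissue, rho_m, lo_m, hi_m, rho_f, lo_f, hi_f, eta, gamma,
                   ...) {
    rbind(row(tissue, "male", rho_m, lo_m, hi_m, eta, gamma, ...),
          row(tissue, "female", rho_f, lo_f, hi_f, eta, gamma, ...))
  }
  reg <- rbind(
    both("all_solid", 0.33, 0.25, 0.42, 0.60, 0.49, 0.72, -1.66, 0.019),
    both("leukemia", 0.79, 0.03, 1.93, 0.79, 0.03, 1.93, -1.09, 0,
         upsilon = -0.81, form = "leukemia"),
    both("lung", 0.42, 0.16, 0.84, 1.20, 0.74, 1.75, -2.50, -0.007),
    both("stomach", 0.21, NA, NA, 0.45, NA, NA, -1.93, 0),
    both("colon", 0.77, 0.36, 1.30, 0.50, 0.20, 0.90, -3.63, -0.0274),
    both("liver", 0.46, 0.19, 0.83, 0.70, 0.29, 1.23, -1.10, -0.027),
    both("bladder", 0.64, 0.18, 1.20, 2.20, 1.20, 3.50, -0.43, 0),
    both("esophagus", 0.30, 0.05, 0.65, 0.30, 0.05, 0.65, 0, 0),
    both("brain", 2.46, 1.00, 4.89, 0.77, 0.05, 1.95, -1.31, 0.028),
    both("pancreas", 0.13, -0.26, 0.75, 0.77, 0.16, 1.56, 0, 0),
    row("breast", "female", 1.12, 0.73, 1.59, -1.50, 0.0049),
    row("ovary", "female", 0.30, -0.22, 1.11, 0, 0),
    row("prostate", "male", 0.57, 0.21, 1.00, 0, 0),
    both("thyroid", 0.53, NA, NA, 1.05, NA, NA, 0, -0.083),
    both("other", 0.75, 0.31, 1.33, 1.08, 0.56, 1.80, -0.79, 0.023)
  )
  rownames(reg) <- NULL
  reg
}

#' Look up ERR parameters for one tissue and sex
#'
#' @param tissue Tissue label (see [cancer_tissues()], plus `"all_solid"`).
#' @param sex `"female"` or `"male"`.
#' @param registry Parameter registry data frame, default [err_registry()].
#' @return An object of class `err_params` (a one-row list).
#' @export
err_params <- function(tissue, sex = c("female", "male"),
                       registry = err_registry()) {
  sex <- match.arg(sex)
  hit <- registry[registry$tissue == tissue & registry$sex == sex, ]
  if (nrow(hit) == 0) {
    if (tissue %in% registry$tissue) {
      stop("tissue '", tissue, "' has no ERR entry for sex '", sex, "'")
    }
    stop("no ERR registry entry for tissue '", tissue, "'")
  }
  structure(as.list(hit[1, ]), class = "err_params")
}

#' Solid-cancer excess relative risk
#'
#' Evaluates \eqn{\rho D (a/70)^{\eta} e^{\gamma(a_E - 30)}}. An unreported
#' `gamma` or `eta` is treated as 0 (no modifier). The value is taken as-is
#' even when the confidence interval for `rho` spans zero; no truncation is
#' applied in the point-estimate path.
#'
#' @param params An [err_params()] with `form == "solid"`.
#' @param dose Gamma-equivalent dose in Gy (non-negative).
#' @param attained_age,exposure_age Ages in years, `attained_age >=
#'   exposure_age`. Vectorised over `attained_age`.
#' @return Dimensionless excess relative risk.
#' @export
err_solid <- function(params, dose, attained_age, exposure_age) {
  stopifnot(inherits(params, "err_params"))
  if (params$form != "solid") stop("err_solid requires a solid-form entry")
  if (any(dose < 0)) stop("dose must be non-negative")
  if (any(attained_age < exposure_age)) {
    stop("attained_age must be >= exposure_age")
  }
  eta <- if (is.na(params$eta)) 0 else params$eta
  gam <- if (is.na(params$gamma)) 0 else params$gamma
  params$rho * dose * (attained_age / 70)^eta * exp(gam * (exposure_age - 30))
}

#' Leukemia excess relative risk
#'
#' Time-since-exposure form: \eqn{\rho D (a/70)^{\eta} T(a - a_E)} where the
#' latency factor is, by default, the power law
#' \eqn{T(L) = (L/40)^{\upsilon}} with \eqn{\upsilon = -0.81}; the
#' alternative exponential reading \eqn{T(L) = e^{\upsilon L / 40}} is
#' available via `time_form = "exponential"`. Callers must gate exposures by
#' the minimum leukemia latency (2 years by default in the risk engine);
#' evaluating below `min_latency` is an error.
#'
#' @inheritParams err_solid
#' @param params An [err_params()] with `form == "leukemia"`.
#' @param time_form `"power"` (default) or `"exponential"`.
#' @param min_latency Minimum allowed time since exposure in years.
#' @return Dimensionless excess relative risk.
#' @export
err_leukemia <- function(params, dose, attained_age, exposure_age,
                         time_form = c("power", "exponential"),
                         min_latency = 2) {
  stopifnot(inherits(params, "err_params"))
  if (params$form != "leukemia") stop("err_leukemia requires the leukemia entry")
  time_form <- match.arg(time_form)
  if (any(dose < 0)) stop("dose must be non-negative")
  lat <- attained_age - exposure_age
  if (any(lat < min_latency)) {
    stop("time since exposure below minimum leukemia latency of ",
         min_latency, " years")
  }
  ups <- if (is.na(params$upsilon)) -0.81 else params$upsilon
  eta <- if (is.na(params$eta)) 0 else params$eta
  tf <- switch(time_form,
               power = (lat / 40)^ups,
               exponential = exp(ups * lat / 40))
  params$rho * dose * (attained_age / 70)^eta * tf
}

#' Evaluate ERR for any registry entry
#'
#' Dispatches on the entry's functional form (solid vs leukemia).
#'
#' @inheritParams err_solid
#' @param ... Passed to [err_leukemia()] for leukemia entries.
#' @export
err <- function(params, dose, attained_age, exposure_age, ...) {
  if (params$form == "leukemia") {
    err_leukemia(params, dose, attained_age, exposure_age, ...)
  } else {
    err_solid(params, dose, attained_age, exposure_age)
  }
}

#' Female-to-male ERR ratio at the reference ages
#'
#' Ratio of female to male ERR for exposure at age 30 and incidence at age
#' 70 (dose 1 Gy). Because the attained-age and age-at-exposure modifiers are
#' fit jointly for the sexes, both modifier factors equal 1 at this reference
#' point and the ratio reduces to \eqn{\rho_F / \rho_M}.
#'
#' @param tissue Tissue with entries for both sexes.
#' @param registry Parameter registry, default [err_registry()].
#' @return Dimensionless F/M ratio.
#' @export
fm_ratio <- function(tissue, registry = err_registry()) {
  ss <- sex_specific_tissues()
  if (tissue %in% names(ss)) {
    stop("tissue '", tissue, "' is sex-specific; F/M ratio undefined")
  }
  f <- err_params(tissue, "female", registry)
  m <- err_params(tissue, "male", registry)
  ev <- function(p) {
    if (p$form == "leukemia") err_leukemia(p, 1, 70, 30) else err_solid(p, 1, 70, 30)
  }
  ev(f) / ev(m)
}

#' Percent decline of ERR per decade of age at exposure
#'
#' The age-at-exposure modifier changes ERR by a factor \eqn{e^{10\gamma}}
#' per decade; the tabulated diagnostic is \eqn{100 (1 - e^{10\gamma})}
#' (positive = risk declines for older exposure ages).
#'
#' @param gamma Age-at-exposure coefficient per year.
#' @return Percent decline per decade.
#' @export
percent_decline_per_decade <- function(gamma) {
  stopifnot(all(is.finite(gamma)))
  100 * (1 - exp(10 * gamma))
}
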