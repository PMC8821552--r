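#' Parameter probability distributions for uncertainty propagation
#'
#' Builds the set of per-parameter sampling distributions used by the
#' Monte-Carlo interval machinery. ERR coefficients `rho` get distributions
#' matched to their registry central values and 95\% intervals: lognormal
#' (median at the central value, log-width from the interval) when the
#' interval is right-skewed by more than 20\% and strictly positive,
#' otherwise normal with sd = width/3.92; entries without a reported
#' interval stay fixed at their point value. The DDREF and the
#' \eqn{\Sigma_0/\alpha_\gamma} ratios are lognormal about their configured
#' medians (geometric standard deviations are configuration, reflecting that
#' the underlying Bayesian posteriors are not refit here); non-targeted
#' parameters default to wide lognormals; an overall flux-scale factor
#' carries dosimetry uncertainty. `spread_scale` multiplies every spread
#' (0 collapses all distributions to their point values).
#'
#' @param registry ERR registry, default [err_registry()].
#' @param qf_solid,qf_leukemia Central [qf_params()] per endpoint class.
#' @param nte Central [nte_params()].
#' @param ddref_gsd Geometric SD of the DDREF lognormal.
#' @param sigma0_gsd Geometric SD of the \eqn{\Sigma_0/\alpha_\gamma}
#'   lognormals.
#' @param nte_gsd Geometric SD of the bystander-amplitude lognormal.
#' @param flux_scale_sd SD of the (normal, mean-1) flux-scale factor.
#' @param spread_scale Global multiplier on all spreads.
#' @return Object of class `parameter_pdfs`.
#' @export
parameter_pdfs <- function(registry = err_registry(),
                           qf_solid = qf_params("solid"),
                           qf_leukemia = qf_params("leukemia"),
                           nte = nte_params(),
                           ddref_gsd = 1.3, sigma0_gsd = 1.4, nte_gsd = 2,
                           flux_scale_sd = 0.1, spread_scale = 1) {
  stopifnot(spread_scale >= 0, ddref_gsd >= 1, sigma0_gsd >= 1, nte_gsd >= 1)
  rho_pdf <- function(rho, lo, hi) {
    if (is.na(lo) || is.na(hi)) {
      return(list(family = "point", value = rho))
    }
    if (!(lo < rho && rho < hi)) {
      stop(sprintf("interval [%g, %g] does not bracket the point estimate %g",
                   lo, hi, rho))
    }
    skew <- (hi - rho) / (rho - lo)
    if (lo > 0 && skew > 1.2) {
      list(family = "lognormal", meanlog = log(rho),
           sdlog = spread_scale * log(hi / lo) / (2 * 1.959964))
    } else {
      list(family = "normal", mean = rho,
           sd = spread_scale * (hi - lo) / (2 * 1.959964))
    }
  }
  rho <- list()
  for (i in seq_len(nrow(registry))) {
    key <- paste(registry$tissue[i], registry$sex[i], sep = ".")
    rho[[key]] <- rho_pdf(registry$rho[i], registry$rho_lo[i],
                          registry$rho_hi[i])
  }
  lognorm <- function(median, gsd) {
    list(family = "lognormal", meanlog = log(median),
         sdlog = spread_scale * log(gsd))
  }
  structure(list(
    registry = registry,
    qf_solid = qf_solid, qf_leukemia = qf_leukemia, nte = nte,
    rho = rho,
    ddref = lognorm(qf_solid$ddref, ddref_gsd),
    sigma0_solid = lognorm(qf_solid$sigma0_over_alpha, sigma0_gsd),
    sigma0_leukemia = lognorm(qf_leukemia$sigma0_over_alpha, sigma0_gsd),
    nte_eta0 = lognorm(max(nte$eta0_over_alpha, 1e-12), nte_gsd),
    flux_scale = list(family = "normal", mean = 1,
                      sd = spread_scale * flux_scale_sd)
  ), class = "parameter_pdfs")
}

# draw from one pdf spec (assumes RNG state already set)
draw_pdf <- function(pdf) {
  switch(pdf$family,
         point = pdf$value,
         normal = stats::rnorm(1, pdf$mean, pdf$sd),
         lognormal = stats::rlnorm(1, pdf$meanlog, pdf$sdlog),
         stop("unknown pdf family: ", pdf$family))
}

central_pdf <- function(pdf) {
  switch(pdf$family,
         point = pdf$value,
         normal = pdf$mean,
         lognormal = exp(pdf$meanlog),
         stop("unknown pdf family: ", pdf$family))
}

#' Draw one Monte-Carlo parameter bundle
#'
#' Deterministic function of `(master_seed, trial_index)`: each trial owns
#' an independent substream keyed by a per-trial seed, so trials are
#' order-independent. Within a trial the DDREF, quality-factor and
#' non-targeted parameters are drawn once and shared across tissues, while
#' ERR coefficients are drawn independently per tissue and sex. Sampled
#' values are clamped to their physical domains: `rho` at 0 (negative ERR
#' draws are truncated in the sampling path only), the DDREF at 1, scale
#' factors at 0.
#'
#' @param pdfs A [parameter_pdfs()].
#' @param trial_index Trial number (>= 1). `trial_index = 0` returns the
#'   central (point-estimate) bundle.
#' @param master_seed Integer master seed.
#' @return List with elements `registry`, `qf_solid`, `qf_leukemia`, `nte`,
#'   `flux_scale`.
#' @export
sample_parameters <- function(pdfs, trial_index, master_seed = 1L) {
  stopifnot(inherits(pdfs, "parameter_pdfs"), trial_index >= 0)
  central <- trial_index == 0
  if (!central) {
    sub_seed <- (as.numeric(master_seed) * 48271 + trial_index * 16807) %%
      2147483647
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(sub_seed))
  }
  take <- function(pdf) if (central) central_pdf(pdf) else draw_pdf(pdf)
  reg <- pdfs$registry
  qs <- pdfs$qf_solid
  ql <- pdfs$qf_leukemia
  nt <- pdfs$nte
  qs$ddref <- ql$ddref <- max(take(pdfs$ddref), 1)
  qs$sigma0_over_alpha <- max(take(pdfs$sigma0_solid), 0)
  ql$sigma0_over_alpha <- max(take(pdfs$sigma0_leukemia), 0)
  nt$eta0_over_alpha <- if (pdfs$nte$eta0_over_alpha > 0) {
    max(take(pdfs$nte_eta0), 0)
  } else 0
  flux_scale <- max(take(pdfs$flux_scale), 0)
  for (i in seq_len(nrow(reg))) {
    key <- paste(reg$tissue[i], reg$sex[i], sep = ".")
    reg$rho[i] <- max(take(pdfs$rho[[key]]), 0)
  }
  # shared-value tissues stay shared across sexes after sampling
  for (tis in c("leukemia", "esophagus")) {
    rows <- which(reg$tissue == tis)
    reg$rho[rows] <- reg$rho[rows[1]]
  }
  list(registry = reg, qf_solid = qs, qf_leukemia = ql, nte = nt,
       flux_scale = flux_scale)
}

#' Monte-Carlo percentile intervals for an arbitrary risk computation
#'
#' Runs `engine_fn` once on the central parameter bundle (the point
#' estimate) and `n_trials` times on sampled bundles, and returns empirical
#' percentile intervals. Trials returning non-finite values are rejected
#' with a logged count; more than 1\% rejections is an error.
#'
#' @param engine_fn Function taking a sampled parameter bundle (see
#'   [sample_parameters()]) and returning a named numeric vector.
#' @param pdfs A [parameter_pdfs()].
#' @param n_trials Number of Monte-Carlo trials (>= 100).
#' @param master_seed Integer master seed.
#' @param percentiles Two percentiles in (0, 100), default `c(2.5, 97.5)`.
#' @return Object of class `mc_risk`: list with `point`, `lower`, `upper`
#'   (named vectors), `n_trials`, `n_rejected`, `percentiles`.
#' @export
mc_interval <- function(engine_fn, pdfs, n_trials = 1000, master_seed = 1L,
                        percentiles = c(2.5, 97.5)) {
  stopifnot(n_trials >= 100, length(percentiles) == 2,
            all(percentiles > 0 & percentiles < 100))
  point <- engine_fn(sample_parameters(pdfs, 0, master_seed))
  draws <- matrix(NA_real_, nrow = n_trials, ncol = length(point),
                  dimnames = list(NULL, names(point)))
  for (i in seq_len(n_trials)) {
    draws[i, ] <- engine_fn(sample_parameters(pdfs, i, master_seed))
  }
  ok <- apply(draws, 1, function(r) all(is.finite(r)))
  n_rej <- sum(!ok)
  if (n_rej > 0) {
    message(sprintf("rejected %d non-finite Monte-Carlo trial(s)", n_rej))
    if (n_rej > 0.01 * n_trials) {
      stop("more than 1% of Monte-Carlo trials were non-finite")
    }
  }
  draws <- draws[ok, , drop = FALSE]
  qs <- apply(draws, 2, stats::quantile, probs = percentiles / 100,
              names = FALSE)
  structure(list(point = point,
                 lower = stats::setNames(qs[1, ], names(point)),
                 upper = stats::setNames(qs[2, ], names(point)),
                 n_trials = n_trials, n_rejected = n_rej,
                 percentiles = percentiles),
            class = "mc_risk")
}

#' @export
print.mc_risk <- function(x, ...) {
  cat(sprintf("Monte-Carlo risk intervals (%g%%-%g%%, %d trials):\n",
              x$percentiles[1], x$percentiles[2], x$n_trials))
  df <- data.frame(quantity = names(x$point),
                   point = signif(x$point, 3),
                   lower = signif(x$lower, 3),
                   upper = signif(x$upper, 3))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Mission risk with Monte-Carlo uncertainty intervals
#'
#' End-to-end uncertainty propagation for one mission and population: per
#' trial, the flux is rescaled by the sampled dosimetry factor, the
#' exposure schedule is recomputed with the sampled quality-factor and NTE
#' parameters, and the lifetime risks are re-evaluated with the sampled ERR
#' coefficients. Reports total REIC and REID.
#'
#' @param profile A [mission_profile()].
#' @param crew_age_at_start Age at mission start in years.
#' @param life_table,rates Population inputs (see [lifetime_risk()]).
#' @param mode `"TE"` or `"NTE"`.
#' @param pdfs A [parameter_pdfs()].
#' @param n_trials,master_seed,percentiles See [mc_interval()].
#' @return An `mc_risk` object with elements `reic_total`, `reid_total`.
#' @export
mission_risk_mc <- function(profile, crew_age_at_start, life_table, rates,
                            mode = c("TE", "NTE"),
                            pdfs = parameter_pdfs(), n_trials = 1000,
                            master_seed = 1L, percentiles = c(2.5, 97.5)) {
  mode <- match.arg(mode)
  fn <- function(bundle) {
    prof <- profile
    prof$flux <- scale_flux(prof$flux, bundle$flux_scale)
    sched <- mission_exposure(prof, crew_age_at_start,
                              solid_params = bundle$qf_solid,
                              leukemia_params = bundle$qf_leukemia,
                              mode = mode, nte = bundle$nte)
    res <- lifetime_risk(sched, life_table, rates,
                         registry = bundle$registry)
    c(reic_total = attr(res, "total_reic"),
      reid_total = attr(res, "total_reid"))
  }
  mc_interval(fn, pdfs, n_trials, master_seed, percentiles)
}
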