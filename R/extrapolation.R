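#' Allometric interspecies extrapolation factor
#'
#' Caloric-demand (body-weight^0.75) scaling gives the dose-rate ratio between
#' species as `(bw_human / bw_animal)^0.25`. The pipeline's nominal factor is
#' this value rounded to the nearest integer (4 for a 70 kg human vs a 0.25 kg
#' rat).
#'
#' @param bw_human,bw_animal body weights in kg, > 0.
#' @return The unrounded allometric factor.
#' @examples
#' allometric_ef_inter(70, 0.25) # 4.0906, nominal 4
#' @export
allometric_ef_inter <- function(bw_human, bw_animal) {
  if (!is.finite(bw_human) || !is.finite(bw_animal) ||
      bw_human <= 0 || bw_animal <= 0) {
    stop("body weights must be positive", call. = FALSE)
  }
  (bw_human / bw_animal)^0.25
}

#' Lognormal GSD from an upper percentile
#'
#' Given the geometric mean of a lognormal uncertainty distribution and the
#' value of one upper percentile, returns the geometric standard deviation:
#' `GSD = exp(ln(upper/gm) / z_level)`.
#'
#' @param gm geometric mean, > 0.
#' @param upper value at the given percentile, > gm.
#' @param level percentile level in (0.5, 1), e.g. 0.99.
#' @return The geometric standard deviation (> 1).
#' @examples
#' gsd_from_upper_percentile(4, 10, 0.99) # 1.4827
#' @export
gsd_from_upper_percentile <- function(gm, upper, level) {
  if (!(gm > 0) || !(upper > gm)) {
    stop("need upper > gm > 0", call. = FALSE)
  }
  if (!(level > 0.5 && level < 1)) stop("level must be in (0.5, 1)", call. = FALSE)
  exp(log(upper / gm) / stats::qnorm(level))
}

#' Joint solve for the intraspecies variability GSD and its uncertainty df
#'
#' Human sensitivity is modelled lognormal with geometric mean 1; its log-sd
#' sigma is itself uncertain, with sampling model
#' `sigma^2 = sigma0^2 * nu / chisq(nu)`. The pair `(sigma0, nu)` is chosen so
#' that the central `coverage` uncertainty interval of the sensitivity ratio
#' of the `var_percentile` person to the average person, `exp(z_p * sigma)`,
#' equals `[lower, upper]`. `nu` comes from a 1-D root of the chi-square
#' quantile-ratio equation, after which `sigma0` is closed form.
#'
#' @param lower,upper bounds of the sensitivity-ratio uncertainty interval
#'   (defaults 2 and 10).
#' @param coverage central uncertainty coverage (default 0.95).
#' @param var_percentile which percentile of the variability distribution the
#'   ratio describes (default 0.95, the "95th percentile sensitive person").
#' @return List with `gsd` (nominal GSD `exp(sigma0)`), `sigma0`, `nu`, and
#'   `capped` (TRUE in the degenerate `lower == upper` limit where `nu` is
#'   capped at 200).
#' @examples
#' solve_intraspecies() # gsd 1.91, nu approx 6.2
#' @export
solve_intraspecies <- function(lower = 2, upper = 10, coverage = 0.95,
                               var_percentile = 0.95) {
  if (!(lower > 1) || upper < lower) stop("need 1 < lower <= upper", call. = FALSE)
  z_p <- stats::qnorm(var_percentile)
  a <- (1 - coverage) / 2
  if (upper == lower) {
    # no uncertainty about sigma: nu -> Inf limit
    return(list(gsd = exp(log(lower) / z_p), sigma0 = log(lower) / z_p,
                nu = 200, capped = TRUE))
  }
  target <- (log(upper) / log(lower))^2
  f <- function(nu) stats::qchisq(1 - a, nu) / stats::qchisq(a, nu) - target
  if (f(0.1) < 0 || f(200) > 0) stop("no root for nu in (0.1, 200)", call. = FALSE)
  nu <- stats::uniroot(f, c(0.1, 200), tol = 1e-12)$root
  # upper bound of the ratio corresponds to the lower chi-square quantile
  sigma0 <- log(upper) / (z_p * sqrt(nu / stats::qchisq(a, nu)))
  list(gsd = exp(sigma0), sigma0 = sigma0, nu = nu, capped = FALSE)
}

#' Extrapolation-factor model
#'
#' Bundles the three animal-to-sensitive-human extrapolation components with
#' their nominal values and uncertainty distributions:
#' * subchronic-to-chronic `EF_chronic`: nominal 1.475; uncertainty lognormal
#'   parameterized by its arithmetic mean (1.80) and sd (1.52);
#' * interspecies `EF_inter`: nominal 4 (allometric, rounded); uncertainty
#'   lognormal with geometric mean 4 and GSD derived from an assumed 99th
#'   percentile of 10;
#' * intraspecies variability `IEF_intra`: lognormal with geometric mean 1 and
#'   nominal GSD from [solve_intraspecies()]; uncertainty on the GSD via the
#'   scaled chi-square on `sigma^2`.
#'
#' @param bw_human,bw_animal body weights (kg) for the allometric factor.
#' @param chronic_nominal nominal subchronic-to-chronic factor.
#' @param chronic_mean,chronic_sd arithmetic mean and sd of the `EF_chronic`
#'   uncertainty lognormal.
#' @param inter_p99 assumed 99th percentile of the `EF_inter` uncertainty.
#' @param intra_lower,intra_upper sensitivity-ratio uncertainty bounds.
#' @return An `extrapolation_model` list.
#' @examples
#' extrapolation_model()
#' @export
extrapolation_model <- function(bw_human = 70, bw_animal = 0.25,
                                chronic_nominal = 1.475,
                                chronic_mean = 1.80, chronic_sd = 1.52,
                                inter_p99 = 10,
                                intra_lower = 2, intra_upper = 10) {
  stopifnot(chronic_nominal > 0, chronic_mean > 0, chronic_sd > 0)
  inter_nominal <- round(allometric_ef_inter(bw_human, bw_animal))
  if (!(inter_p99 > inter_nominal)) {
    stop("inter_p99 must exceed the nominal interspecies factor", call. = FALSE)
  }
  # arithmetic mean/sd -> lognormal (meanlog, sdlog)
  cv2 <- (chronic_sd / chronic_mean)^2
  chronic_sdlog <- sqrt(log1p(cv2))
  chronic_meanlog <- log(chronic_mean) - chronic_sdlog^2 / 2
  intra <- solve_intraspecies(intra_lower, intra_upper)
  structure(list(
    bw_human = bw_human, bw_animal = bw_animal,
    chronic_nominal = chronic_nominal,
    chronic_meanlog = chronic_meanlog, chronic_sdlog = chronic_sdlog,
    inter_nominal = inter_nominal,
    inter_gsd = gsd_from_upper_percentile(inter_nominal, inter_p99, 0.99),
    intra_gsd = intra$gsd, intra_sigma0 = intra$sigma0, intra_nu = intra$nu
  ), class = "extrapolation_model")
}

#' @export
print.extrapolation_model <- function(x, ...) {
  cat(sprintf(paste0(
    "Extrapolation model:\n",
    "  EF_chronic: nominal %.3f, uncertainty lognormal(meanlog %.4f, sdlog %.4f)\n",
    "  EF_inter:   nominal %d, uncertainty GSD %.3f\n",
    "  IEF_intra:  GM 1, nominal GSD %.3f (sigma0 %.4f, nu %.3f)\n"),
    x$chronic_nominal, x$chronic_meanlog, x$chronic_sdlog,
    x$inter_nominal, x$inter_gsd, x$intra_gsd, x$intra_sigma0, x$intra_nu))
  invisible(x)
}

#' Draw one hazard uncertainty sample
#'
#' One outer-loop draw of the uncertain hazard components: a BMD from the
#' pooled bootstrap set (uniform with replacement), an `EF_chronic`, an
#' `EF_inter`, and an intraspecies log-sd `sigma`. Each component can be held
#' at its nominal value instead of sampled, which is how the factorial
#' sensitivity analysis switches sources off. Uses the current RNG state.
#'
#' @param bmd_set a `bmd_uncertainty_set` (or a numeric vector of pooled BMDs,
#'   in which case `nominal` must be supplied via attribute or equals its
#'   median).
#' @param extrap an `extrapolation_model`.
#' @param sample_bmd,sample_chronic,sample_inter,sample_intra logical toggles;
#'   `FALSE` fixes the component at its nominal value.
#' @return A `hazard_sample` list: `bmd`, `ef_chronic`, `ef_inter`,
#'   `intra_sigma`, `intra_gsd`.
#' @export
sample_hazard <- function(bmd_set, extrap,
                          sample_bmd = TRUE, sample_chronic = TRUE,
                          sample_inter = TRUE, sample_intra = TRUE) {
  stopifnot(inherits(extrap, "extrapolation_model"))
  pool <- if (inherits(bmd_set, "bmd_uncertainty_set")) bmd_set$bmd else as.numeric(bmd_set)
  nominal <- if (inherits(bmd_set, "bmd_uncertainty_set")) bmd_set$nominal else stats::median(pool)
  if (length(pool) == 0) stop("empty BMD set", call. = FALSE)
  bmd <- if (sample_bmd) pool[sample.int(length(pool), 1)] else nominal
  ef_chronic <- if (sample_chronic) {
    stats::rlnorm(1, extrap$chronic_meanlog, extrap$chronic_sdlog)
  } else extrap$chronic_nominal
  ef_inter <- if (sample_inter) {
    stats::rlnorm(1, log(extrap$inter_nominal), log(extrap$inter_gsd))
  } else extrap$inter_nominal
  sigma <- if (sample_intra) {
    extrap$intra_sigma0 * sqrt(extrap$intra_nu / stats::rchisq(1, extrap$intra_nu))
  } else extrap$intra_sigma0
  structure(list(bmd = bmd, ef_chronic = ef_chronic, ef_inter = ef_inter,
                 intra_sigma = sigma, intra_gsd = exp(sigma)),
            class = "hazard_sample")
}

#' Draw individual benchmark doses for one hazard sample
#'
#' Inner (variability) loop of the hazard side: for a fixed uncertainty draw,
#' `IBMD_i = BMD / (EF_chronic * EF_inter * IEF_i)` with individual
#' `IEF_i ~ lognormal(GM 1, GSD exp(sigma))`. Uses the current RNG state.
#'
#' @param hazard a `hazard_sample`.
#' @param n number of individuals, >= 1.
#' @return Numeric vector of `n` positive IBMD values (same dose units as the
#'   BMD, mg/kg BW/day by default).
#' @export
sample_ibmd <- function(hazard, n) {
  stopifnot(inherits(hazard, "hazard_sample"), n >= 1)
  ief <- stats::rlnorm(n, 0, hazard$intra_sigma)
  hazard$bmd / (hazard$ef_chronic * hazard$ef_inter * ief)
}

#' Convert a mass-metric BMD to the particle-number metric
#'
#' Multiplies a BMD in mg/kg BW/day by the particle count per mg implied by
#' the dose-metric spec, reporting the result in 10^12 particles/kg BW/day.
#' Called with a mass-metric spec it returns the input unchanged with a
#' warning.
#'
#' @param bmd benchmark dose in mg/kg BW/day.
#' @param spec a [dose_metric_spec()].
#' @return BMD in 10^12 N/kg BW/day (or unchanged for the mass metric).
#' @examples
#' convert_bmd_metric(1160, dose_metric_spec("particle_number")) # approx 1007
#' @export
convert_bmd_metric <- function(bmd, spec) {
  stopifnot(inherits(spec, "dose_metric_spec"))
  if (spec$metric != "particle_number") {
    warning("mass metric: BMD returned unchanged", call. = FALSE)
    return(bmd)
  }
  bmd * particles_per_mass(spec) / 1e12
}
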