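#' Uncertainty-source toggles
#'
#' The seven named uncertainty sources of the outer Monte Carlo loop, in
#' fixed order: consumption (person-level survey bootstrap), concentration
#' (within-basic-product bootstrap), nanofraction (logistic-normal draw), bmd
#' (pooled parametric-bootstrap set), chronic, inter and intra (extrapolation
#' factors). `FALSE` holds a source at its nominal value.
#'
#' @param consumption,concentration,nanofraction,bmd,chronic,inter,intra
#'   logical flags.
#' @return Named logical vector of length 7.
#' @export
uncertainty_toggles <- function(consumption = TRUE, concentration = TRUE,
                                nanofraction = TRUE, bmd = TRUE,
                                chronic = TRUE, inter = TRUE, intra = TRUE) {
  c(consumption = consumption, concentration = concentration,
    nanofraction = nanofraction, bmd = bmd,
    chronic = chronic, inter = inter, intra = intra)
}

#' Names of the seven uncertainty sources, in fixed order
#' @return Character vector of length 7.
#' @export
uncertainty_sources <- function() {
  names(uncertainty_toggles())
}

IMOE_LEVELS <- c(0.1, 1, 5, 50, 95, 99, 99.9)
IMOE_COLS <- paste0("p", c("0.1", "1", "5", "50", "95", "99", "99.9"))

#' Configuration of the two-dimensional Monte Carlo run
#'
#' @param outer outer (uncertainty) iterations, >= 1 (default 500).
#' @param inner inner (variability) sample size, >= 1000 (default 1e5).
#' @param master_seed integer master seed; every stochastic stage of every
#'   iteration derives its own sub-stream from it.
#' @param dose_metric a [dose_metric_spec()].
#' @param toggles an [uncertainty_toggles()] vector.
#' @param nanofraction_model a [fit_nanofraction()] model for the uncertainty
#'   draw of F.
#' @param nominal_nanofraction nominal F used when its source is off
#'   (default 0.5).
#' @param percentile_pairs list of (lower, upper) percentile pairs for IMoE
#'   bars, percentages in (0, 100).
#' @param max_skip_frac maximum tolerated fraction of skipped iterations.
#' @return An `ipra_config` list.
#' @export
ipra_config <- function(outer = 500, inner = 1e5, master_seed = 1L,
                        dose_metric = dose_metric_spec(),
                        toggles = uncertainty_toggles(),
                        nanofraction_model = fit_nanofraction(0.5, 0.8),
                        nominal_nanofraction = 0.5,
                        percentile_pairs = list(c(0.1, 99.9), c(1, 99), c(5, 95)),
                        max_skip_frac = 0.05) {
  stopifnot(outer >= 1, inner >= 1000,
            inherits(dose_metric, "dose_metric_spec"),
            identical(names(toggles), uncertainty_sources()),
            inherits(nanofraction_model, "nanofraction_model"),
            nominal_nanofraction > 0, nominal_nanofraction <= 1)
  for (pp in percentile_pairs) {
    stopifnot(length(pp) == 2, all(pp > 0), all(pp < 100), pp[1] < pp[2])
  }
  structure(list(outer = outer, inner = inner, master_seed = master_seed,
                 dose_metric = dose_metric, toggles = toggles,
                 nanofraction_model = nanofraction_model,
                 nominal_nanofraction = nominal_nanofraction,
                 percentile_pairs = percentile_pairs,
                 max_skip_frac = max_skip_frac),
            class = "ipra_config")
}

# metric conversion constants applied at the risk-characterization boundary:
# IEXP is computed in ug/kg BW/day throughout; BMD draws are mg/kg BW/day
metric_conversions <- function(spec) {
  if (spec$metric == "particle_number") {
    c_bmd <- particles_per_mass(spec) / 1e12 # mg -> 10^12 N
    list(iexp = c_bmd / 1000, bmd = c_bmd)
  } else {
    list(iexp = 1 / 1000, bmd = 1) # ug -> mg
  }
}

#' Run the integrated probabilistic risk assessment
#'
#' The two-dimensional Monte Carlo: each outer iteration draws one state of
#' knowledge (bootstrapped survey and concentrations, a nanofraction, a BMD
#' from the pooled set, extrapolation factors -- each only if its toggle is
#' on, else held at nominal), then simulates the inner variability loop: a
#' fresh usual-intake population sample IEXP and an individual-benchmark-dose
#' sample IBMD, combined independently into `IMoE = IBMD / IEXP`. Each
#' iteration records the IMoE percentiles and the fraction at risk
#' (IMoE < 1). A nominal run with every source at its nominal value is always
#' included. Fully reproducible from the master seed: every stage of every
#' iteration uses its own named sub-stream, so switching one source off never
#' perturbs the draws of the others.
#'
#' @param survey a [consumption_survey()].
#' @param conc concentration table (data frame).
#' @param links product-link table (data frame).
#' @param bmd_set a [parametric_bootstrap_bmds()] result.
#' @param extrap an [extrapolation_model()].
#' @param config an [ipra_config()].
#' @return An `imoe_result`: `iterations` (one row per outer iteration with
#'   percentile columns p0.1 ... p99.9, `frac_at_risk`, and the uncertainty
#'   draws), `nominal` (single all-nominal row), `skipped`, and the config.
#' @export
run_ipra <- function(survey, conc, links, bmd_set, extrap, config = ipra_config()) {
  stopifnot(inherits(survey, "consumption_survey"),
            inherits(config, "ipra_config"),
            inherits(extrap, "extrapolation_model"))
  conv <- metric_conversions(config$dose_metric)
  tg <- config$toggles
  ms <- config$master_seed

  one_iteration <- function(iter, toggles) {
    surv_i <- if (toggles[["consumption"]]) {
      with_substream(ms, iter, "survey", expr = bootstrap_survey(survey))
    } else survey
    conc_i <- if (toggles[["concentration"]]) {
      with_substream(ms, iter, "conc", expr = bootstrap_concentrations(conc))
    } else conc
    f_i <- if (toggles[["nanofraction"]]) {
      with_substream(ms, iter, "nanofraction",
                     expr = sample_nanofraction(config$nanofraction_model, 1))
    } else config$nominal_nanofraction

    conc_map <- link_concentrations(conc_i, links)
    pde <- compute_person_day_exposures(surv_i, conc_map, nanofraction = f_i)
    uim <- fit_usual_intake(pde)
    iexp <- with_substream(ms, iter, "iexp", expr = {
      predict_usual_intakes(uim, "simulated-population", config$inner)$iexp
    }) * conv$iexp

    hz <- with_substream(ms, iter, "hazard", expr = {
      sample_hazard(bmd_set, extrap,
                    sample_bmd = toggles[["bmd"]],
                    sample_chronic = toggles[["chronic"]],
                    sample_inter = toggles[["inter"]],
                    sample_intra = toggles[["intra"]])
    })
    hz_metric <- hz
    hz_metric$bmd <- hz$bmd * conv$bmd
    ibmd <- with_substream(ms, iter, "ief", expr = {
      sample_ibmd(hz_metric, config$inner)
    })

    imoe <- ibmd / iexp
    q <- stats::quantile(imoe, IMOE_LEVELS / 100, type = 7, names = FALSE)
    row <- as.data.frame(as.list(stats::setNames(q, IMOE_COLS)),
                         check.names = FALSE)
    row$frac_at_risk <- mean(imoe < 1)
    row$nanofraction <- f_i
    row$bmd <- hz$bmd
    row$ef_chronic <- hz$ef_chronic
    row$ef_inter <- hz$ef_inter
    row$intra_gsd <- hz$intra_gsd
    row
  }

  all_off <- uncertainty_toggles(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE)
  nominal <- one_iteration(0L, all_off)
  nominal <- cbind(iter = 0L, nominal)

  rows <- vector("list", config$outer)
  skipped <- 0L
  for (i in seq_len(config$outer)) {
    rows[[i]] <- tryCatch(cbind(iter = i, one_iteration(i, tg)),
                          error = function(e) {
                            message("iteration ", i, " skipped: ", conditionMessage(e))
                            NULL
                          })
    if (is.null(rows[[i]])) skipped <- skipped + 1L
  }
  if (skipped > config$max_skip_frac * config$outer) {
    stop(sprintf("%d of %d outer iterations failed", skipped, config$outer),
         call. = FALSE)
  }
  iterations <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(iterations) <- NULL
  structure(list(iterations = iterations, nominal = nominal,
                 skipped = skipped, config = config),
            class = "imoe_result")
}

#' @export
print.imoe_result <- function(x, ...) {
  cat(sprintf("IMoE result: %d outer iterations (%d skipped), inner n = %d, metric %s\n",
              nrow(x$iterations), x$skipped, x$config$inner,
              x$config$dose_metric$metric))
  med <- vapply(x$iterations[IMOE_COLS], stats::median, 0)
  cat("median over iterations of IMoE percentiles:\n")
  print(signif(med, 4))
  invisible(x)
}

#' IMoE bar: variability box with one-sided uncertainty whiskers
#'
#' For a chosen pair of variability percentiles (e.g. p1 and p99), the box
#' spans the medians (over outer iterations) of the two percentiles; the left
#' whisker is the lower `levels[1]` uncertainty quantile of the lower
#' percentile, the right whisker the upper `levels[2]` uncertainty quantile
#' of the upper percentile; the centre line is the median of the nominal
#' variability distribution.
#'
#' @param result an `imoe_result`.
#' @param pair numeric pair of percentile levels in percent, e.g. `c(1, 99)`.
#' @param levels one-sided uncertainty levels (default `c(0.05, 0.95)`).
#' @return An `imoe_bar` list: `lower`, `upper` (box medians),
#'   `lower_whisker`, `upper_whisker`, `median` (nominal p50), `pair`.
#' @export
imoe_percentile_bounds <- function(result, pair, levels = c(0.05, 0.95)) {
  stopifnot(inherits(result, "imoe_result"), length(pair) == 2)
  cols <- IMOE_COLS[match(pair, IMOE_LEVELS)]
  if (anyNA(cols)) {
    stop("percentile pair not recorded: ", paste(pair, collapse = ", "),
         call. = FALSE)
  }
  it <- result$iterations
  if (nrow(it) < 20) {
    warning("fewer than 20 outer iterations: whisker quantiles are imprecise",
            call. = FALSE)
  }
  lo <- it[[cols[1]]]
  hi <- it[[cols[2]]]
  structure(list(
    pair = pair,
    lower = stats::median(lo),
    upper = stats::median(hi),
    lower_whisker = unname(stats::quantile(lo, levels[1], type = 7)),
    upper_whisker = unname(stats::quantile(hi, levels[2], type = 7)),
    median = result$nominal$p50
  ), class = "imoe_bar")
}

#' @export
print.imoe_bar <- function(x, ...) {
  cat(sprintf("IMoE bar p%s-p%s: [%.4g | %.4g -- %.4g | %.4g], median %.4g\n",
              x$pair[1], x$pair[2], x$lower_whisker, x$lower, x$upper,
              x$upper_whisker, x$median))
  invisible(x)
}

#' Fraction of individuals at risk
#'
#' An individual is at risk when their margin of exposure is below 1.
#'
#' @param imoe numeric vector of IMoE draws.
#' @return Fraction strictly below 1.
#' @export
fraction_at_risk <- function(imoe) {
  if (length(imoe) == 0) stop("empty IMoE draws", call. = FALSE)
  mean(imoe < 1)
}

#' Uncertainty probability that a population percentile is safe
#'
#' Fraction of outer iterations in which the stated IMoE variability
#' percentile exceeds 1 -- e.g. `prob_population_safe(res, 1) = 0.95` reads
#' "with 95% confidence at least 99% of the population is not at risk".
#'
#' @param result an `imoe_result`.
#' @param percentile percentile level in percent (one of 0.1, 1, 5, 50, 95,
#'   99, 99.9).
#' @return Probability in [0, 1].
#' @export
prob_population_safe <- function(result, percentile) {
  stopifnot(inherits(result, "imoe_result"))
  col <- IMOE_COLS[match(percentile, IMOE_LEVELS)]
  if (is.na(col)) stop("percentile not recorded: ", percentile, call. = FALSE)
  mean(result$iterations[[col]] > 1)
}
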