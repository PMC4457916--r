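# numeric ED50 oracle: root of p(d) = 0.5 (plain models) or midway between
# the explicit background and 1 (background models)
numeric_ed50 <- function(fit, upper = 1e9) {
  reg <- ipra:::quantal_registry(fit$model)
  p0 <- if (fit$model %in% c("logistic", "probit")) 0 else fit$params[["p0"]]
  target <- (p0 + 1) / 2
  uniroot(function(d) reg$prob(d, fit$params) - target,
          c(1e-9, upper), tol = 1e-12)$root
}

test_that("fitted ED50s agree with the generic numeric solver", {
  dr <- generate_dose_response(dose_response_params(
    doses = c(0, 500, 1500), rats_per_group = 25,
    true_params = logistic_truth(1000), seed = 17))
  fits <- suppressWarnings(fit_all_quantal_models(dr))
  expect_length(fits, 7)
  for (f in fits) {
    expect_equal(f$ed50, numeric_ed50(f), tolerance = 1e-8,
                 info = f$model)
  }
})

test_that("logistic ED50 is the closed-form -a/b and is recovered from data", {
  truth <- c(a = -2, b = 0.001) # ED50 = 2000
  dr <- generate_dose_response(dose_response_params(
    doses = c(0, 1000, 2000, 4000), rats_per_group = 100,
    true_params = truth, seed = 23))
  f <- fit_quantal_model(dr, "logistic")
  expect_equal(f$ed50, -f$params[["a"]] / f$params[["b"]])
  expect_equal(f$ed50, 2000, tolerance = 0.1) # large-n recovery
})

test_that("flat response data are rejected as a slope boundary", {
  dr <- dose_response_data(rep(c(0, 810, 819), each = 5),
                           rep(c(3, 3, 3), each = 5))
  expect_error(fit_quantal_model(dr, "logistic"), "flat|boundary|undefined")
})

test_that("AIC identity holds exactly and reproduces published summaries", {
  expect_equal(aic(-81.05, 3), 168.1)
  expect_equal(aic(-86.99, 2), 177.98)
  expect_equal(aic(0, 0), 0)
  dr <- generate_dose_response(dose_response_params(seed = 7))
  fits <- suppressWarnings(fit_all_quantal_models(dr))
  for (f in fits) {
    expect_identical(f$aic, 2 * f$k - 2 * f$logL)
  }
})

test_that("model selection minimizes AIC with deterministic tie-breaks", {
  mk <- function(model, logL, k) {
    structure(list(model = model, logL = logL, k = k, aic = 2 * k - 2 * logL,
                   converged = TRUE), class = "quantal_fit")
  }
  fits <- list(mk("gamma", -10, 3), mk("logistic", -12, 2), mk("probit", -10, 3))
  expect_equal(select_best(fits)$model, "probit") # AIC tie -> fixed name order
  fits2 <- list(mk("weibull", -9, 4), mk("gamma", -11, 2))
  expect_equal(select_best(fits2)$model, "gamma") # equal AIC, fewer params
  expect_error(select_best(list()), "no converged")
})

test_that("fitted logL never exceeds the saturated logL; GOF behaves", {
  dr <- generate_dose_response(dose_response_params(
    doses = c(0, 250, 500, 1000, 2000), rats_per_group = 10,
    true_params = logistic_truth(1000), seed = 19))
  f <- fit_quantal_model(dr, "logistic")
  gof <- goodness_of_fit(f)
  expect_gte(gof$statistic, 0) # logL_sat >= logL_fit
  expect_equal(gof$df, 5 - 2)
  expect_true(gof$p_value > 0 && gof$p_value < 1)
  # three group fractions lying exactly on one logistic curve: statistic ~ 0
  a <- qlogis(0.2); b <- (qlogis(0.8) - a) / 1000
  exact <- dose_response_data(rep(c(0, -a / b, 1000), each = 10),
                              rep(c(2, 5, 8), each = 10))
  fe <- fit_quantal_model(exact, "logistic")
  ge <- goodness_of_fit(fe)
  expect_lt(ge$statistic, 1e-6)
  expect_equal(ge$p_value, 1, tolerance = 1e-6)
  # more parameters than groups: saturated flag instead of a p-value
  f3 <- fit_quantal_model(generate_dose_response(dose_response_params(seed = 7)),
                          "log-logistic")
  expect_true(goodness_of_fit(f3)$saturated)
})

test_that("parametric bootstrap is seeded, pooled, and centred on the truth", {
  dr <- generate_dose_response(dose_response_params(
    doses = c(0, 500, 1000), rats_per_group = 50,
    true_params = logistic_truth(1000), seed = 29))
  fits <- suppressWarnings(fit_all_quantal_models(dr))
  set.seed(7)
  b1 <- suppressWarnings(parametric_bootstrap_bmds(fits, dr, reps = 30))
  set.seed(7)
  b2 <- suppressWarnings(parametric_bootstrap_bmds(fits, dr, reps = 30))
  expect_identical(b1$bmd, b2$bmd)
  expect_equal(length(b1$bmd) + sum(b1$dropped), 7 * 30)
  expect_true(all(b1$bmd > 0))
  expect_lt(abs(median(b1$bmd) / b1$nominal - 1), 0.25)
  # the nominal fitted ED50 lies inside its own bootstrap distribution
  ci <- quantile(b1$bmd[b1$model == "logistic"], c(0.025, 0.975))
  expect_true(fits$logistic$ed50 >= ci[1] && fits$logistic$ed50 <= ci[2])
})

test_that("allometric interspecies factor follows quarter-power scaling", {
  expect_equal(allometric_ef_inter(70, 0.25), 280^0.25)
  expect_equal(round(allometric_ef_inter(70, 0.25)), 4)
  expect_equal(allometric_ef_inter(3, 3), 1)
  expect_equal(allometric_ef_inter(4 * 7, 7), sqrt(2))
  expect_error(allometric_ef_inter(-1, 2), "positive")
})

test_that("GSD from an upper percentile inverts the lognormal quantile", {
  expect_equal(round(gsd_from_upper_percentile(4, 10, 0.99), 2), 1.48)
  gsd <- gsd_from_upper_percentile(2, 9, 0.95)
  expect_equal(2 * gsd^qnorm(0.95), 9, tolerance = 1e-12) # round trip
  expect_equal(gsd_from_upper_percentile(1, 10, 0.95),
               exp(log(10) / qnorm(0.95)), tolerance = 1e-12)
  expect_error(gsd_from_upper_percentile(4, 3, 0.99), "upper")
})

test_that("intraspecies joint solve hits both sensitivity-ratio bounds", {
  s <- solve_intraspecies(2, 10)
  expect_equal(round(s$gsd, 2), 1.91)
  # nu solves the chi-square quantile-ratio equation
  expect_equal(qchisq(0.975, s$nu) / qchisq(0.025, s$nu),
               (log(10) / log(2))^2, tolerance = 1e-8)
  # round trip: P(exp(z95 * sigma) < 2) = P(> 10) = 0.025
  z <- qnorm(0.95)
  p_lo <- pchisq(s$nu * s$sigma0^2 * z^2 / log(2)^2, s$nu, lower.tail = FALSE)
  p_hi <- pchisq(s$nu * s$sigma0^2 * z^2 / log(10)^2, s$nu)
  expect_equal(p_lo, 0.025, tolerance = 1e-4)
  expect_equal(p_hi, 0.025, tolerance = 1e-4)
  deg <- solve_intraspecies(3, 3)
  expect_true(deg$capped)
  expect_equal(deg$gsd, exp(log(3) / z))
})

test_that("hazard sampling combines the extrapolation chain multiplicatively", {
  pool <- structure(list(bmd = rep(1160, 5), model = rep("logistic", 5),
                         nominal = 1160, dropped = integer(0)),
                    class = "bmd_uncertainty_set")
  ex <- extrapolation_model()
  hz <- sample_hazard(pool, ex, FALSE, FALSE, FALSE, FALSE)
  expect_equal(hz$bmd, 1160)
  expect_equal(hz$ef_chronic, 1.475)
  expect_equal(hz$ef_inter, 4)
  hz$intra_sigma <- 0 # individual factor fixed at the geometric mean
  expect_equal(sample_ibmd(hz, 3), rep(1160 / 5.9, 3), tolerance = 1e-12)
  # doubling the interspecies factor halves every draw, same seed
  set.seed(3); d1 <- sample_ibmd(hz, 100)
  hz2 <- hz; hz2$ef_inter <- 8
  set.seed(3); d2 <- sample_ibmd(hz2, 100)
  expect_equal(d2, d1 / 2)
  # geometric mean of the individual draws is bmd / (chronic x inter)
  hz$intra_sigma <- log(1.91)
  set.seed(4)
  gm <- exp(mean(log(sample_ibmd(hz, 1e6))))
  expect_equal(gm, 1160 / 5.9, tolerance = 0.005)
})

test_that("BMD dose-metric conversion matches the particle count and inverts", {
  spec <- dose_metric_spec("particle_number", 100, 2.2)
  got <- convert_bmd_metric(1160, spec)
  expect_equal(got, 1160 * particles_per_mass(spec) / 1e12)
  expect_equal(got, 1007, tolerance = 1e-3)
  expect_equal(convert_bmd_metric(0, spec), 0)
  expect_equal(got / (particles_per_mass(spec) / 1e12), 1160)
  expect_warning(convert_bmd_metric(10, dose_metric_spec("mass")), "unchanged")
})
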