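make_engine_inputs <- function(n_persons = 100) {
  tab <- load_table1_fixture()
  list(survey = make_test_survey(n_persons = n_persons),
       conc = tab$concentrations, links = tab$links,
       bset = test_hazard_set(), extrap = extrapolation_model())
}

test_that("the engine is bitwise reproducible and percentile-monotone", {
  inp <- make_engine_inputs()
  cfg <- ipra_config(outer = 5, inner = 2000, master_seed = 123)
  r1 <- run_ipra(inp$survey, inp$conc, inp$links, inp$bset, inp$extrap, cfg)
  r2 <- run_ipra(inp$survey, inp$conc, inp$links, inp$bset, inp$extrap, cfg)
  expect_identical(r1$iterations, r2$iterations)
  expect_identical(r1$nominal, r2$nominal)
  q <- as.matrix(r1$iterations[imoe_quantile_cols()])
  expect_true(all(diff(t(q)) >= 0))
  expect_true(all(q > 0))
})

test_that("with all uncertainty off, iterations differ only by inner MC noise", {
  inp <- make_engine_inputs()
  # regular consumers (frequency near 1), as in a chronic-intake setting:
  # keeps the far IMoE tails light enough to be pinned down by the inner loop
  inp$survey <- make_test_survey(n_persons = 100, consume_prob = 0.8)
  off <- uncertainty_toggles(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE)
  cfg <- ipra_config(outer = 3, inner = 1e5, master_seed = 7, toggles = off)
  r <- run_ipra(inp$survey, inp$conc, inp$links, inp$bset, inp$extrap, cfg)
  q <- as.matrix(r$iterations[imoe_quantile_cols()])
  spread <- apply(q, 2, function(col) diff(range(col)) / median(col))
  expect_lt(max(spread), 0.05)
  expect_equal(r$iterations$bmd, rep(inp$bset$nominal, 3))
  expect_equal(r$iterations$nanofraction, rep(0.5, 3))
})

test_that("IMoE percentiles scale exactly inversely with concentration", {
  inp <- make_engine_inputs()
  cfg <- ipra_config(outer = 4, inner = 2000, master_seed = 11)
  base <- run_ipra(inp$survey, inp$conc, inp$links, inp$bset, inp$extrap, cfg)
  conc10 <- inp$conc
  conc10$total_silica_mg_per_g <- conc10$total_silica_mg_per_g * 10
  r10 <- run_ipra(inp$survey, conc10, inp$links, inp$bset, inp$extrap, cfg)
  q0 <- as.matrix(base$iterations[imoe_quantile_cols()])
  q10 <- as.matrix(r10$iterations[imoe_quantile_cols()])
  expect_equal(q10 * 10, q0, tolerance = 1e-10)
  # and scales proportionally with the BMD pool
  bset2 <- inp$bset
  bset2$bmd <- bset2$bmd * 3
  bset2$nominal <- bset2$nominal * 3
  r3 <- run_ipra(inp$survey, inp$conc, inp$links, bset2, inp$extrap, cfg)
  expect_equal(as.matrix(r3$iterations[imoe_quantile_cols()]), q0 * 3,
               tolerance = 1e-12)
})

test_that("mass and particle-number metrics give identical IMoE", {
  inp <- make_engine_inputs()
  cfg <- ipra_config(outer = 4, inner = 2000, master_seed = 19)
  cfg_p <- ipra_config(outer = 4, inner = 2000, master_seed = 19,
                       dose_metric = dose_metric_spec("particle_number"))
  rm_ <- run_ipra(inp$survey, inp$conc, inp$links, inp$bset, inp$extrap, cfg)
  rp <- run_ipra(inp$survey, inp$conc, inp$links, inp$bset, inp$extrap, cfg_p)
  expect_equal(as.matrix(rp$iterations[imoe_quantile_cols()]),
               as.matrix(rm_$iterations[imoe_quantile_cols()]),
               tolerance = 1e-12)
})

test_that("uncertainty widens the percentile spread across iterations", {
  inp <- make_engine_inputs()
  off <- uncertainty_toggles(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE)
  cfg_on <- ipra_config(outer = 15, inner = 2000, master_seed = 31)
  cfg_off <- ipra_config(outer = 15, inner = 2000, master_seed = 31,
                         toggles = off)
  r_on <- run_ipra(inp$survey, inp$conc, inp$links, inp$bset, inp$extrap, cfg_on)
  r_off <- run_ipra(inp$survey, inp$conc, inp$links, inp$bset, inp$extrap, cfg_off)
  sd_on <- sd(log10(r_on$iterations$p1))
  sd_off <- sd(log10(r_off$iterations$p1))
  expect_gt(sd_on, sd_off)
})

test_that("IMoE bars take whiskers from the iteration quantiles", {
  fake <- structure(list(
    iterations = data.frame(p1 = 1:5, p99 = c(10, 20, 30, 40, 50)),
    nominal = data.frame(p50 = 7)), class = "imoe_result")
  suppressWarnings(b <- imoe_percentile_bounds(fake, c(1, 99)))
  expect_equal(b$lower_whisker, 1.2) # interpolated order statistic at 0.05
  expect_equal(b$upper_whisker, 48)
  expect_equal(b$lower, 3)
  expect_lte(b$lower_whisker, b$upper_whisker)
  expect_error(imoe_percentile_bounds(fake, c(2, 98)), "not recorded")
  same <- structure(list(
    iterations = data.frame(p1 = rep(2, 25), p99 = rep(9, 25)),
    nominal = data.frame(p50 = 5)), class = "imoe_result")
  b2 <- imoe_percentile_bounds(same, c(1, 99))
  expect_equal(b2$lower_whisker, b2$lower) # degenerate: whisker on the box
  expect_equal(b2$upper_whisker, b2$upper)
})

test_that("risk summaries follow the IMoE < 1 rule", {
  expect_equal(fraction_at_risk(c(0.5, 2, 3, 4)), 0.25)
  expect_equal(fraction_at_risk(c(2, 3)), 0)
  fake <- structure(list(
    iterations = data.frame(p1 = c(0.5, 1.5, 2, 3), p99 = c(5, 6, 7, 8)),
    nominal = data.frame(p50 = 2)), class = "imoe_result")
  expect_equal(prob_population_safe(fake, 1), 0.75)
  expect_equal(prob_population_safe(fake, 99), 1)
})
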