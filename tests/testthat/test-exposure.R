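test_that("concentration linking multiplies fraction, mean and unit factor", {
  conc <- data.frame(basic_product = "Sauce powder",
                     measured_product = "m1", total_silica_mg_per_g = 5.4)
  links <- data.frame(food_code = "sauce dish", basic_product = "Sauce powder",
                      fraction = 0.18)
  expect_equal(unname(link_concentrations(conc, links)["sauce dish"]),
               5.4 * 0.18 * 1000) # 972 ug/g
})

test_that("linking averages measured products within a basic product", {
  tab <- load_table1_fixture()
  cmap <- link_concentrations(tab$concentrations, tab$links)
  # coffee creamers: measurements 5.1 and 4.9 mg/g at fraction 1
  expect_equal(unname(cmap["Pure creamer"]), 5000)
  bad_links <- data.frame(food_code = "x", basic_product = "no such", fraction = 1)
  expect_error(link_concentrations(tab$concentrations, bad_links),
               "unknown basic product")
})

test_that("person-day exposure follows the intake formula with zero defaults", {
  survey <- consumption_survey(
    persons = data.frame(person_id = 1:2, bw_kg = c(70, 60)),
    records = data.frame(person_id = 1, day = 1, food_code = "sauce dish",
                         amount_g = 140),
    n_days = 2)
  cmap <- c("sauce dish" = 972)
  pde <- compute_person_day_exposures(survey, cmap, nanofraction = 0.5)
  expect_equal(nrow(pde), 4)
  expect_equal(pde$idexp[pde$person_id == 1 & pde$day == 1],
               140 / 70 * 972 * 0.5) # 972 ug/kg BW/day
  expect_true(all(pde$idexp[!(pde$person_id == 1 & pde$day == 1)] == 0))
  # unknown food contributes nothing
  survey$records$food_code <- "unlisted"
  expect_true(all(compute_person_day_exposures(survey, cmap)$idexp == 0))
  expect_error(compute_person_day_exposures(survey, cmap, nanofraction = 1.2),
               "nanofraction")
})

test_that("particle count per mass follows spherical geometry", {
  expect_equal(particles_per_mass(dose_metric_spec("particle_number", 100, 1)),
               1.9099e12, tolerance = 1e-4)
  expect_equal(particles_per_mass(dose_metric_spec("particle_number", 100, 2.2)),
               1.9099e12 / 2.2, tolerance = 1e-4)
  s1 <- particles_per_mass(dose_metric_spec("particle_number", 50, 2.2))
  s2 <- particles_per_mass(dose_metric_spec("particle_number", 100, 2.2))
  expect_equal(s1 / s2, 8) # cubic scaling in diameter
  expect_error(dose_metric_spec("particle_number", -1), "positive")
})

test_that("particle-number exposures equal mass exposures times the conversion", {
  survey <- make_test_survey(n_persons = 30)
  cmap <- link_concentrations(load_table1_fixture()$concentrations,
                              load_table1_fixture()$links)
  spec <- dose_metric_spec("particle_number")
  mass <- compute_person_day_exposures(survey, cmap, 0.5)
  part <- compute_person_day_exposures(survey, cmap, 0.5, dose_metric = spec)
  expect_equal(part$idexp,
               mass$idexp * particles_per_mass(spec) / 1000 / 1e12)
})

test_that("exposure is homogeneous in amounts and nanofraction", {
  survey <- make_test_survey(n_persons = 25)
  cmap <- link_concentrations(load_table1_fixture()$concentrations,
                              load_table1_fixture()$links)
  base <- compute_person_day_exposures(survey, cmap, 0.4)
  survey2 <- survey
  survey2$records$amount_g <- survey2$records$amount_g * 3
  expect_equal(compute_person_day_exposures(survey2, cmap, 0.4)$idexp,
               base$idexp * 3)
  expect_equal(compute_person_day_exposures(survey, cmap, 0.8)$idexp,
               base$idexp * 2)
})

test_that("exceedance curve uses strict exceedance and is monotone", {
  expect_equal(fraction_exceeding(c(1, 2, 3), 0), 1)
  expect_equal(fraction_exceeding(c(1, 2, 3), 2), 1 / 3)
  ec <- exceedance_curve(c(1, 2, 2, 3))
  expect_equal(ec$exceedance, c(3, 1, 0) / 4)
  vals <- rlnorm(500)
  ec2 <- exceedance_curve(vals)
  expect_true(all(diff(ec2$exceedance) <= 0))
  expect_true(all(ec2$exceedance >= 0 & ec2$exceedance <= 1))
  # all-positive usual intakes: everyone exceeds zero
  expect_equal(fraction_exceeding(vals, 0), 1)
})

test_that("survey bootstrap preserves person count and degenerates to identity", {
  survey <- make_test_survey(n_persons = 20)
  set.seed(1)
  bs <- bootstrap_survey(survey)
  expect_equal(nrow(bs$persons), nrow(survey$persons))
  expect_s3_class(bs, "consumption_survey")
  one <- consumption_survey(
    persons = data.frame(person_id = 7, bw_kg = 70),
    records = data.frame(person_id = 7, day = 1:2, food_code = "f",
                         amount_g = c(10, 20)),
    n_days = 2)
  set.seed(2)
  b1 <- bootstrap_survey(one)
  expect_equal(b1$persons$bw_kg, one$persons$bw_kg)
  expect_equal(b1$records$amount_g, one$records$amount_g)
})

test_that("concentration bootstrap reproduces the exact resampling law", {
  # two measurements {4.9, 5.1}: the bootstrap mean takes values
  # {4.9, 5.0, 5.1} with probabilities {1/4, 1/2, 1/4} by enumeration of the
  # 2^2 equally likely resamples
  conc <- data.frame(basic_product = "Coffee creamers",
                     measured_product = c("a", "b"),
                     total_silica_mg_per_g = c(5.1, 4.9))
  set.seed(42)
  means <- replicate(2000, mean(bootstrap_concentrations(conc)$total_silica_mg_per_g))
  freq <- table(factor(means, levels = c(4.9, 5.0, 5.1))) / 2000
  expect_lt(max(abs(as.numeric(freq) - c(0.25, 0.5, 0.25))), 0.03)
  expect_equal(nrow(bootstrap_concentrations(conc)), 2)
})
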