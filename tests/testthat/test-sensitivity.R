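test_that("factorial design is complete, balanced and lexicographic", {
  d <- factorial_design()
  expect_equal(nrow(d), 128)
  expect_equal(names(d), uncertainty_sources())
  expect_equal(anyDuplicated(d), 0L)
  expect_true(all(colSums(d) == 64)) # each source on in exactly half the cells
  expect_true(all(!as.logical(d[1, ])))  # all-off first
  expect_true(all(as.logical(d[128, ]))) # all-on last
  # lexicographic: first column changes slowest
  expect_equal(sum(abs(diff(as.numeric(d$consumption)))), 1)
})

test_that("additive variance model is exact on exactly additive inputs", {
  d <- factorial_design()
  beta <- c(MC = 1, consumption = 2, concentration = 0, nanofraction = 0,
            bmd = 4, chronic = 0, inter = 0, intra = 1)
  d$variance <- as.numeric(beta[1] + as.matrix(d) %*% beta[-1])
  f <- fit_additive_variance_model(d)
  expect_equal(unname(f$coefficients), unname(beta), tolerance = 1e-10)
  expect_equal(f$variance_explained, 100)
  rss <- sum(residuals(f$lm)^2)
  expect_lt(rss / sum(d$variance^2), 1e-18)
  expect_equal(sum(f$contributions), 100)
  expect_equal(unname(f$contributions["bmd"]), 50) # 4 of 8 total
})

test_that("equal cell variances attribute everything to Monte Carlo noise", {
  d <- factorial_design()
  d$variance <- 0.37
  f <- fit_additive_variance_model(d)
  expect_equal(unname(f$contributions["MC"]), 100, tolerance = 1e-8)
  expect_true(all(f$contributions[-1] < 1e-8))
})

test_that("a known interaction degrades fit but not main-effect recovery", {
  d <- factorial_design()
  main <- c(5, 0, 0, 3, 0, 0, 2)
  d$variance <- as.numeric(1 + as.matrix(d[uncertainty_sources()]) %*% main +
    0.8 * d$bmd * d$chronic) # interaction about 10 % of the signal
  f <- fit_additive_variance_model(d)
  expect_lt(f$variance_explained, 100)
  expect_gt(f$variance_explained, 90)
  got <- f$coefficients[c("consumption", "bmd", "intra")]
  expect_true(all(abs(got - c(5, 3, 2)) / c(5, 3, 2) < 0.15))
})

test_that("rank-deficient or incomplete designs are rejected", {
  d <- factorial_design()
  d$variance <- 1
  dup <- rbind(d[1:127, ], d[127, ])
  expect_error(fit_additive_variance_model(dup), "duplicated")
  expect_error(fit_additive_variance_model(cbind(d[1:64, ])), "128")
})

test_that("end-to-end factorial run is reproducible and flags dead sources", {
  tab <- load_table1_fixture()
  survey <- make_test_survey(n_persons = 60)
  # degenerate BMD uncertainty: every pooled value identical
  bset <- test_hazard_set()
  bset$bmd <- rep(bset$nominal, length(bset$bmd))
  cfg <- ipra_config(outer = 10, inner = 1000, master_seed = 77)
  fr <- run_factorial(survey, tab$concentrations, tab$links, bset,
                      extrapolation_model(), cfg, target_percentile = 1,
                      reps = 10)
  expect_equal(nrow(fr$cells), 128)
  expect_equal(sum(fr$fit$contributions), 100)
  # a source whose uncertainty distribution has zero spread contributes ~0
  expect_lt(fr$fit$contributions[["bmd"]], 5)
  # matched sub-streams: turning sources on never lowers variance on average;
  # the paired differences share draws, so allow an absolute MC-noise margin
  noise <- stats::median(fr$cells$variance) * 0.25
  for (src in uncertainty_sources()) {
    on <- fr$cells$variance[fr$cells[[src]]]
    off <- fr$cells$variance[!fr$cells[[src]]]
    dd <- on - off # paired by construction of the lexicographic design order
    expect_gt(mean(dd), -noise)
  }
  # the dominant extrapolation-factor sources clearly add variance
  for (src in c("chronic", "intra")) {
    dd <- fr$cells$variance[fr$cells[[src]]] - fr$cells$variance[!fr$cells[[src]]]
    expect_gt(mean(dd), 0)
  }
  fr2 <- run_factorial(survey, tab$concentrations, tab$links, bset,
                       extrapolation_model(), cfg, target_percentile = 1,
                       reps = 10)
  expect_identical(fr$cells, fr2$cells)
})
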