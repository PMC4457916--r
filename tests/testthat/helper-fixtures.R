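# Shared fixture builders. Everything is generated in code at test time.

# small survey over a subset of the packaged link-table foods
make_test_survey <- function(n_persons = 150, seed = 5, consume_prob = 0.35) {
  links <- load_table1_fixture()$links
  generate_survey(survey_params(
    n_persons = n_persons,
    food_codes = links$food_code[c(1, 3, 9, 13, 16, 20)],
    consume_prob = consume_prob, seed = seed))
}

# simulate person-day exposures directly from the two-part usual-intake model
simulate_lnn <- function(n, alpha, tau, beta, su, se, days = 2, seed = 1) {
  set.seed(seed)
  u1 <- stats::rnorm(n, 0, tau)
  u2 <- stats::rnorm(n, 0, su)
  df <- expand.grid(person_id = seq_len(n), day = seq_len(days))
  p <- stats::plogis(alpha + u1[df$person_id])
  pos <- stats::runif(nrow(df)) < p
  df$idexp <- 0
  df$idexp[pos] <- exp(beta + u2[df$person_id[pos]] +
                         stats::rnorm(sum(pos), 0, se))
  df
}

# a well-behaved logistic truth: background 5 %, ED50 at `ed50`
logistic_truth <- function(ed50 = 1000) {
  a <- stats::qlogis(0.05)
  c(a = a, b = -a / ed50)
}

# one standard hazard side (fits + pooled bootstrap set) cached per session
test_hazard_set <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dr <- generate_dose_response(dose_response_params(seed = 5))
      fits <- suppressWarnings(fit_all_quantal_models(dr))
      set.seed(99)
      cache <<- suppressWarnings(parametric_bootstrap_bmds(fits, dr, reps = 100))
    }
    cache
  }
})

imoe_quantile_cols <- function() {
  paste0("p", c("0.1", "1", "5", "50", "95", "99", "99.9"))
}
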