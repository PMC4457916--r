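#' Parameters for the synthetic consumption survey generator
#'
#' Describes a two-day 24-hour-recall survey of the kind national food
#' consumption surveys produce: persons with body weights, and per
#' person-day-food a Bernoulli consumption indicator plus, when consumed, a
#' lognormal amount with person and day components. A shared person random
#' effect links the foods (and, with correlation `person_corr`, the
#' frequency and amount parts), so that fitting the usual-intake model to the
#' generated data is non-trivial.
#'
#' @param n_persons number of surveyed persons (>= 2).
#' @param n_days recall days per person (default 2).
#' @param bw_mean_kg,bw_sd_kg body-weight distribution (kg); weights are
#'   redrawn until positive.
#' @param food_codes character vector of food identifiers.
#' @param consume_prob marginal per-food consumption probability in [0, 1].
#' @param log_amount_mean mean of log amount (log g).
#' @param between_sd,within_sd between-person and within-person (day) sds of
#'   log amount, >= 0.
#' @param freq_sd logit-scale person sd of the consumption frequency.
#' @param person_corr correlation between the frequency and amount person
#'   effects (default 0.5).
#' @param seed integer seed.
#' @return A `survey_params` list.
#' @export
survey_params <- function(n_persons = 300, n_days = 2,
                          bw_mean_kg = 70, bw_sd_kg = 12,
                          food_codes = paste0("food_", 1:8),
                          consume_prob = 0.3,
                          log_amount_mean = log(50),
                          between_sd = 0.5, within_sd = 0.4,
                          freq_sd = 1, person_corr = 0.5,
                          seed = 1L) {
  stopifnot(n_persons >= 2, n_days >= 1,
            consume_prob >= 0, consume_prob <= 1,
            between_sd >= 0, within_sd >= 0, freq_sd >= 0,
            bw_mean_kg > 0, bw_sd_kg >= 0,
            abs(person_corr) <= 1, length(food_codes) >= 1)
  structure(as.list(environment()), class = "survey_params")
}

#' Generate a synthetic consumption survey
#'
#' Seeded generator emulating a two-day recall survey. Each person receives a
#' body weight and a pair of correlated person effects (frequency on the
#' logit scale, amount on the log scale) shared across foods; each
#' person-day-food is consumed with the person-specific probability and, if
#' consumed, contributes a lognormal amount. Deterministic given the seed.
#'
#' @param params a [survey_params()].
#' @return A [consumption_survey()].
#' @examples
#' s <- generate_survey(survey_params(n_persons = 10, seed = 42))
#' s
#' @export
generate_survey <- function(params) {
  stopifnot(inherits(params, "survey_params"))
  with_substream(params$seed, "survey", expr = {
    n <- params$n_persons
    bw <- stats::rnorm(n, params$bw_mean_kg, params$bw_sd_kg)
    while (any(bw <= 0)) {
      bad <- bw <= 0
      bw[bad] <- stats::rnorm(sum(bad), params$bw_mean_kg, params$bw_sd_kg)
    }
    persons <- data.frame(person_id = seq_len(n), bw_kg = bw)

    z1 <- stats::rnorm(n)
    z2 <- stats::rnorm(n)
    rho <- params$person_corr
    u_freq <- params$freq_sd * z1
    u_amt <- params$between_sd * (rho * z1 + sqrt(1 - rho^2) * z2)

    # person-specific consumption probability with the marginal level anchored
    # at consume_prob (logit shift of the person effect)
    p_i <- if (params$consume_prob <= 0) rep(0, n)
           else if (params$consume_prob >= 1) rep(1, n)
           else stats::plogis(stats::qlogis(params$consume_prob) + u_freq)

    grid <- expand.grid(person_id = seq_len(n),
                        day = seq_len(params$n_days),
                        food_code = params$food_codes,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid <- grid[order(grid$person_id, grid$day, grid$food_code), ]
    eaten <- stats::runif(nrow(grid)) < p_i[grid$person_id]
    rec <- grid[eaten, , drop = FALSE]
    amounts <- exp(params$log_amount_mean + u_amt[rec$person_id] +
                     stats::rnorm(nrow(rec), 0, params$within_sd))
    rec$amount_g <- amounts
    rownames(rec) <- NULL
    consumption_survey(persons, rec, n_days = params$n_days)
  })
}

#' Generate a synthetic concentration table
#'
#' Emulates the structure of a measured-product table: `n_basic` basic
#' products, each with between `reps_range[1]` and `reps_range[2]` measured
#' products whose total-silica concentrations (mg/g) are lognormal.
#' Deterministic given the seed.
#'
#' @param n_basic number of basic products.
#' @param reps_range integer pair within `[1, 10]`: min and max measured
#'   products per basic product.
#' @param meanlog,sdlog lognormal parameters of the concentrations (mg/g).
#' @param seed integer seed.
#' @return Data frame with columns `basic_product`, `measured_product`,
#'   `total_silica_mg_per_g`.
#' @examples
#' generate_concentration_table(3, c(1, 3), seed = 5)
#' @export
generate_concentration_table <- function(n_basic = 13, reps_range = c(1, 5),
                                         meanlog = log(5), sdlog = 0.6,
                                         seed = 1L) {
  stopifnot(n_basic >= 1, length(reps_range) == 2,
            reps_range[1] >= 1, reps_range[2] <= 10,
            reps_range[1] <= reps_range[2], sdlog >= 0)
  with_substream(seed, "concentration", expr = {
    reps <- sample(seq(reps_range[1], reps_range[2]), n_basic, replace = TRUE)
    basic <- rep(sprintf("basic_%02d", seq_len(n_basic)), times = reps)
    out <- data.frame(
      basic_product = basic,
      measured_product = paste0(basic, "_m", unlist(lapply(reps, seq_len))),
      total_silica_mg_per_g = stats::rlnorm(sum(reps), meanlog, sdlog)
    )
    rownames(out) <- NULL
    out
  })
}

#' Parameters for the synthetic dose-response generator
#'
#' @param doses dose levels in mg/kg BW/day (>= 2 distinct, defaults to the
#'   realized doses of the emulated 84-day rat study: 0, 810, 819).
#' @param rats_per_group animals per dose group (default 5).
#' @param slides_per_rat slides scored per animal (default 10).
#' @param true_model generating model, one of [quantal_model_names()].
#' @param true_params named parameters of the generating model on its natural
#'   scale (default: logistic with background 0.02 and ED50 1160).
#' @param overdispersion beta-binomial overdispersion parameter (0 = pure
#'   binomial; > 0 draws each rat's slide probability from a Beta with mean
#'   `p(dose)` and dispersion `1/(1+overdispersion)` shrinking towards 0).
#' @param seed integer seed.
#' @return A `dose_response_params` list.
#' @export
dose_response_params <- function(doses = c(0, 810, 819),
                                 rats_per_group = 5,
                                 slides_per_rat = 10,
                                 true_model = "logistic",
                                 true_params = NULL,
                                 overdispersion = 0,
                                 seed = 1L) {
  stopifnot(length(unique(doses)) >= 2, all(doses >= 0),
            rats_per_group >= 1, slides_per_rat >= 1, overdispersion >= 0)
  true_model <- match.arg(true_model, quantal_model_names())
  if (is.null(true_params)) {
    if (true_model != "logistic") {
      stop("true_params must be supplied for model '", true_model, "'",
           call. = FALSE)
    }
    a <- stats::qlogis(0.02) # background response of about 2 %
    true_params <- c(a = a, b = -a / 1160) # ED50 = 1160 mg/kg BW/day
  }
  structure(list(doses = doses, rats_per_group = rats_per_group,
                 slides_per_rat = slides_per_rat, true_model = true_model,
                 true_params = true_params, overdispersion = overdispersion,
                 seed = seed),
            class = "dose_response_params")
}

#' Generate synthetic quantal dose-response data
#'
#' Each rat's positive-slide count is Binomial(slides, p(dose)) under the
#' generating model, or beta-binomial when `overdispersion > 0` (the rat's
#' slide probability is drawn from a Beta with mean p(dose)). Deterministic
#' given the seed.
#'
#' @param params a [dose_response_params()].
#' @return A [dose_response_data()].
#' @examples
#' generate_dose_response(dose_response_params(seed = 3))
#' @export
generate_dose_response <- function(params) {
  stopifnot(inherits(params, "dose_response_params"))
  reg <- quantal_registry(params$true_model)
  with_substream(params$seed, "dose_response", expr = {
    dose <- rep(params$doses, each = params$rats_per_group)
    p <- reg$prob(dose, params$true_params)
    if (any(p < 0 | p > 1)) stop("true model gives probabilities outside [0,1]",
                                 call. = FALSE)
    if (params$overdispersion > 0) {
      theta <- params$overdispersion
      pc <- pmin(pmax(p, 1e-9), 1 - 1e-9)
      p <- stats::rbeta(length(dose), pc / theta, (1 - pc) / theta)
    }
    positive <- stats::rbinom(length(dose), params$slides_per_rat, p)
    dose_response_data(dose, positive, params$slides_per_rat)
  })
}
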