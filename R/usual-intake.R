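#' Fit the two-part usual-intake (logistic-normal-normal) model
#'
#' Converts person-day exposures from a short-term recall survey into a model
#' of long-term (usual) individual exposure. The model has two parts sharing
#' person-level random effects:
#' * frequency: `logit P(positive day | person) = alpha + u1`,
#' * amount: `ln(exposure | positive day) = beta + u2 + eps`,
#' with `(u1, u2)` bivariate normal (sds `tau`, `sigma_u`, correlation `rho`)
#' and `eps ~ N(0, sigma_eps^2)`. The frequency likelihood integrates the
#' person effect by fixed-order Gauss-Hermite quadrature; the amount part has
#' a closed-form marginal normal likelihood per person. By default the
#' correlation is fixed at 0 (the two parts separate, "LNN0"); with only two
#' recall days per person the correlation is weakly identified, but it can be
#' estimated on request via a joint 1-D quadrature likelihood.
#'
#' When every person-day is positive the frequency part is fixed at 1 and the
#' amount part reduces to a one-way random-effects decomposition on the log
#' scale. Log amounts are centred at their mean before optimisation (the
#' intercept is recovered afterwards), which makes the fit exactly
#' equivariant under rescaling of the exposures.
#'
#' @param exposures data frame with columns `person_id`, `day`, `idexp`
#'   (from [compute_person_day_exposures()]).
#' @param correlation `"zero"` (default) or `"estimate"`.
#' @param nodes Gauss-Hermite quadrature order (default 21).
#' @return A `usual_intake_model` with elements `freq_intercept`, `freq_sd`,
#'   `freq_fixed`, `amt_intercept`, `amt_sd`, `resid_sd`, `corr`, `logL`,
#'   `converged`, and per-person summaries used by the shrunken predictor.
#' @export
fit_usual_intake <- function(exposures, correlation = c("zero", "estimate"),
                             nodes = 21) {
  correlation <- match.arg(correlation)
  stopifnot(all(c("person_id", "day", "idexp") %in% names(exposures)))
  if (any(exposures$idexp < 0)) stop("negative exposures", call. = FALSE)
  ids <- unique(exposures$person_id)
  if (length(ids) < 2) stop("at least 2 persons are required", call. = FALSE)
  pos <- exposures$idexp > 0
  if (!any(pos)) stop("no positive exposures: usual-intake model is degenerate",
                      call. = FALSE)

  n_days <- vapply(split(exposures$day, exposures$person_id), length, 0L)[as.character(ids)]
  k_pos <- vapply(split(pos, exposures$person_id), sum, 0L)[as.character(ids)]

  gh <- pracma::gaussHermite(nodes)
  z <- sqrt(2) * gh$x
  w <- gh$w / sqrt(pi)

  # ---- amount part sufficient statistics (positive days, centred logs) ----
  pe <- exposures[pos, , drop = FALSE]
  ly <- log(pe$idexp)
  centre <- mean(ly)
  lyc <- ly - centre
  by_p <- split(lyc, pe$person_id)
  amt_ids <- names(by_p)
  m_i <- vapply(by_p, mean, 0)
  n_i <- vapply(by_p, length, 0L)
  ss_i <- vapply(by_p, function(v) sum((v - mean(v))^2), 0)

  amount_nll <- function(beta_c, su2, se2) {
    vtot <- se2 + n_i * su2
    0.5 * sum(n_i * log(2 * pi) + (n_i - 1) * log(se2) + log(vtot) +
                ss_i / se2 + n_i * (m_i - beta_c)^2 / vtot)
  }

  all_positive <- all(k_pos == n_days)

  freq_nll <- function(alpha, tau) {
    # sum over persons of -log integral of binomial likelihood over u1
    eta <- outer(rep(1, length(ids)), alpha + tau * z)
    p <- stats::plogis(eta)
    lik <- p^k_pos * (1 - p)^(n_days - k_pos)
    -sum(log(pmax(lik %*% w, .Machine$double.xmin)))
  }

  lb <- -15; ub <- 5 # bounds for log-sd parameters
  sd_floor <- exp(2 * lb + 1) # variances at the bound are reported as zero

  if (correlation == "zero" || all_positive) {
    # ---- separable fits ----
    if (all_positive) {
      freq <- list(alpha = Inf, tau = 0, fixed = TRUE, nll = 0)
    } else {
      p_bar <- min(max(sum(k_pos) / sum(n_days), 1e-3), 1 - 1e-3)
      of <- stats::optim(c(stats::qlogis(p_bar), log(0.5)),
                         function(ph) freq_nll(ph[1], exp(ph[2])),
                         method = "L-BFGS-B", lower = c(-30, lb), upper = c(30, ub),
                         control = list(maxit = 500))
      freq <- list(alpha = of$par[1], tau = exp(of$par[2]),
                   fixed = FALSE, nll = of$value, conv = of$convergence == 0)
    }
    if (max(ss_i) < 1e-20 && (length(m_i) < 2 || stats::sd(m_i) < 1e-10)) {
      am <- list(beta_c = mean(m_i), su = 0, se = 0, nll = 0, conv = TRUE)
    } else {
      v0 <- stats::var(lyc)
      oa <- stats::optim(c(0, log(sqrt(v0 / 2 + 1e-6)), log(sqrt(v0 / 2 + 1e-6))),
                         function(ph) amount_nll(ph[1], exp(2 * ph[2]), exp(2 * ph[3])),
                         method = "L-BFGS-B",
                         lower = c(-30, lb, lb), upper = c(30, ub, ub),
                         control = list(maxit = 500))
      am <- list(beta_c = oa$par[1],
                 su = if (exp(2 * oa$par[2]) < sd_floor) 0 else exp(oa$par[2]),
                 se = if (exp(2 * oa$par[3]) < sd_floor) 0 else exp(oa$par[3]),
                 nll = oa$value, conv = oa$convergence == 0)
    }
    fit <- list(alpha = freq$alpha, tau = freq$tau, freq_fixed = freq$fixed,
                beta_c = am$beta_c, su = am$su, se = am$se, rho = 0,
                nll = freq$nll + am$nll,
                conv = isTRUE(freq$conv %||% TRUE) && isTRUE(am$conv))
  } else {
    # ---- joint likelihood with correlated person effects ----
    # conditional on u1 = tau * z, u2 | z ~ N(rho*su*z, su^2*(1-rho^2)); the
    # amount integral over u2 is closed form, so one quadrature over z suffices
    joint_nll <- function(ph) {
      alpha <- ph[1]; tau <- exp(ph[2]); beta_c <- ph[3]
      su <- exp(ph[4]); se2 <- exp(2 * ph[5]); rho <- tanh(ph[6])
      su2c <- su^2 * (1 - rho^2)
      has_amt <- match(as.character(ids), amt_ids)
      total <- 0
      for (i in seq_along(ids)) {
        eta <- alpha + tau * z
        p <- stats::plogis(eta)
        li <- p^k_pos[i] * (1 - p)^(n_days[i] - k_pos[i])
        j <- has_amt[i]
        if (!is.na(j)) {
          vtot <- se2 + n_i[j] * su2c
          mu_z <- beta_c + rho * su * z
          la <- exp(-0.5 * (n_i[j] * log(2 * pi) + (n_i[j] - 1) * log(se2) +
                              log(vtot) + ss_i[j] / se2 +
                              n_i[j] * (m_i[j] - mu_z)^2 / vtot))
          li <- li * la
        }
        total <- total - log(max(sum(w * li), .Machine$double.xmin))
      }
      total
    }
    p_bar <- min(max(sum(k_pos) / sum(n_days), 1e-3), 1 - 1e-3)
    v0 <- stats::var(lyc)
    start <- c(stats::qlogis(p_bar), log(0.5), 0,
               log(sqrt(v0 / 2 + 1e-6)), log(sqrt(v0 / 2 + 1e-6)), 0)
    oj <- stats::optim(start, joint_nll, method = "L-BFGS-B",
                       lower = c(-30, lb, -30, lb, lb, -5),
                       upper = c(30, ub, 30, ub, ub, 5),
                       control = list(maxit = 1000))
    fit <- list(alpha = oj$par[1], tau = exp(oj$par[2]), freq_fixed = FALSE,
                beta_c = oj$par[3],
                su = if (exp(2 * oj$par[4]) < sd_floor) 0 else exp(oj$par[4]),
                se = if (exp(2 * oj$par[5]) < sd_floor) 0 else exp(oj$par[5]),
                rho = tanh(oj$par[6]), nll = oj$value,
                conv = oj$convergence == 0)
  }
  if (!isTRUE(fit$conv)) {
    stop("usual-intake fit did not converge", call. = FALSE)
  }

  persons <- data.frame(person_id = ids, n_days = n_days, k_pos = k_pos,
                        stringsAsFactors = FALSE)
  persons$n_pos <- n_i[match(as.character(ids), amt_ids)]
  persons$mean_log <- m_i[match(as.character(ids), amt_ids)] + centre
  persons$n_pos[is.na(persons$n_pos)] <- 0L

  structure(list(
    freq_intercept = fit$alpha, freq_sd = fit$tau, freq_fixed = fit$freq_fixed,
    amt_intercept = fit$beta_c + centre, amt_sd = fit$su, resid_sd = fit$se,
    corr = fit$rho, logL = -fit$nll, converged = fit$conv,
    nodes = nodes, persons = persons
  ), class = "usual_intake_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.usual_intake_model <- function(x, ...) {
  cat("Usual-intake (LNN) model\n")
  if (x$freq_fixed) {
    cat("  frequency: fixed at 1 (all person-days positive)\n")
  } else {
    cat(sprintf("  frequency: intercept %.4f, person sd %.4f\n",
                x$freq_intercept, x$freq_sd))
  }
  cat(sprintf("  amount:    intercept %.4f, person sd %.4f, residual sd %.4f\n",
              x$amt_intercept, x$amt_sd, x$resid_sd))
  cat(sprintf("  correlation: %.3f; logL = %.3f\n", x$corr, x$logL))
  invisible(x)
}

#' Predict usual intakes from a fitted model
#'
#' Two modes:
#' * `"simulated-population"`: draws `n` new individuals' person effects and
#'   returns `P(positive | u1) * exp(beta + u2 + sigma_eps^2 / 2)` -- the
#'   long-term mean intake of each simulated individual. Extreme population
#'   percentiles beyond the survey size are estimable in this mode. Uses the
#'   current RNG state.
#' * `"shrunken-persons"`: empirical-Bayes posterior-mean usual intake for
#'   each surveyed person (posterior over `u1` by Gauss-Hermite quadrature,
#'   closed-form normal posterior over `u2`; the person-effect correlation is
#'   ignored here).
#'
#' @param model a `usual_intake_model`.
#' @param mode `"simulated-population"` or `"shrunken-persons"`.
#' @param n number of simulated individuals (simulated-population mode).
#' @return A `usual_intake_distribution`: list with `iexp` (positive values,
#'   same units as the fitted exposures) and `mode` provenance tag.
#' @export
predict_usual_intakes <- function(model,
                                  mode = c("simulated-population", "shrunken-persons"),
                                  n = NULL) {
  stopifnot(inherits(model, "usual_intake_model"))
  mode <- match.arg(mode)
  if (mode == "simulated-population") {
    if (is.null(n) || n < 1) stop("n must be >= 1", call. = FALSE)
    z1 <- stats::rnorm(n)
    z2 <- stats::rnorm(n)
    u2 <- model$amt_sd * (model$corr * z1 + sqrt(1 - model$corr^2) * z2)
    freq <- if (model$freq_fixed) 1 else stats::plogis(model$freq_intercept + model$freq_sd * z1)
    iexp <- freq * exp(model$amt_intercept + u2 + model$resid_sd^2 / 2)
  } else {
    pr <- model$persons
    gh <- pracma::gaussHermite(model$nodes)
    z <- sqrt(2) * gh$x
    w <- gh$w / sqrt(pi)
    freq <- if (model$freq_fixed) rep(1, nrow(pr)) else {
      vapply(seq_len(nrow(pr)), function(i) {
        p <- stats::plogis(model$freq_intercept + model$freq_sd * z)
        lik <- p^pr$k_pos[i] * (1 - p)^(pr$n_days[i] - pr$k_pos[i])
        sum(w * lik * p) / sum(w * lik)
      }, 0)
    }
    su2 <- model$amt_sd^2; se2 <- model$resid_sd^2
    amt <- vapply(seq_len(nrow(pr)), function(i) {
      if (pr$n_pos[i] == 0 || su2 == 0) {
        return(exp(model$amt_intercept + su2 / 2 + se2 / 2))
      }
      if (se2 == 0) {
        return(exp(pr$mean_log[i]))
      }
      post_var <- 1 / (1 / su2 + pr$n_pos[i] / se2)
      post_mean <- post_var * (pr$n_pos[i] / se2) * (pr$mean_log[i] - model$amt_intercept)
      exp(model$amt_intercept + post_mean + post_var / 2 + se2 / 2)
    }, 0)
    iexp <- freq * amt
  }
  structure(list(iexp = iexp, mode = mode), class = "usual_intake_distribution")
}

#' @export
print.usual_intake_distribution <- function(x, ...) {
  cat(sprintf("Usual-intake distribution (%s): n = %d\n", x$mode, length(x$iexp)))
  print(round(stats::quantile(x$iexp, c(0.05, 0.5, 0.95)), 4))
  invisible(x)
}
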