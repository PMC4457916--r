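#' Fit a quantal dose-response model by maximum likelihood
#'
#' Maximizes the binomial log-likelihood
#' \deqn{\sum_i [y_i \ln p(d_i) + (n_i - y_i)\ln(1 - p(d_i)) + \ln C(n_i, y_i)]}
#' over the model's parameters, with dose slopes constrained positive via a
#' log transform. The benchmark dose is reported as the ED50: the dose at
#' which the response probability is 0.5 for the logistic and probit models,
#' and midway between the background `p0` and 1 (additional risk 50%) for the
#' five models carrying an explicit background parameter.
#'
#' @param data a [dose_response_data] object.
#' @param model one of [quantal_model_names()].
#' @return A `quantal_fit` with elements `model`, `params` (natural scale),
#'   `logL`, `k`, `aic`, `ed50`, `converged`, and the data's group summary.
#' @seealso [select_best()], [goodness_of_fit()], [parametric_bootstrap_bmds()]
#' @examples
#' dr <- generate_dose_response(dose_response_params(seed = 7))
#' fit_quantal_model(dr, "logistic")
#' @export
fit_quantal_model <- function(data, model) {
  stopifnot(inherits(data, "dose_response_data"))
  model <- match.arg(model, quantal_model_names())
  reg <- quantal_registry(model)
  g <- group_summary(data)

  if (diff(range(g$fraction)) < 1e-9) {
    stop("flat dose-response (identical group fractions at all doses): ",
         "slope at boundary, ED50 undefined", call. = FALSE)
  }

  # The likelihood depends on the data only through per-group totals. The
  # binomial-coefficient constant is added after optimisation: keeping it out
  # of the objective keeps optim's relative stopping rule on a stable scale.
  const <- sum(lchoose(data$total, data$positive))
  nll <- make_group_nll(model, g$dose, g$positive, g$total)

  phi0 <- reg$to_opt(reg$start(g))
  run_nm <- function(s) tryCatch(
    stats::optim(s, nll, method = "Nelder-Mead",
                 control = list(maxit = 1500, reltol = 1e-10)),
    error = function(e) NULL)

  # one complete optimisation attempt from a given start: Nelder-Mead, a BFGS
  # polish, and restarts while a flat likelihood direction (a background
  # parameter drifting to its boundary) keeps exhausting the iteration budget
  attempt <- function(start) {
    best <- run_nm(start)
    if (is.null(best) || !is.finite(best$value)) return(NULL)
    polish <- tryCatch(
      suppressWarnings(stats::optim(best$par, nll, method = "BFGS",
                                    control = list(maxit = 200, reltol = 1e-12))),
      error = function(e) NULL)
    if (!is.null(polish) && is.finite(polish$value) && polish$value <= best$value) {
      best <- polish
    }
    converged <- best$convergence == 0
    tries <- 0
    while (!converged && tries < 6) {
      tries <- tries + 1
      retry <- run_nm(best$par)
      if (is.null(retry) || !is.finite(retry$value)) break
      converged <- retry$value > best$value - 1e-6
      if (retry$value < best$value) best <- retry
    }
    best$converged <- converged
    th <- reg$from_opt(best$par)
    fitted_p <- reg$prob(g$dose, th)
    best$boundary <- diff(range(fitted_p)) < 1e-7
    best
  }

  best <- attempt(phi0)
  if (is.null(best) || !best$converged || best$boundary) {
    # a flat solution can be an inferior local mode; try perturbed starts and
    # keep the best likelihood among clean solutions, if any
    for (s in list(phi0 + 0.5, phi0 - 0.5, phi0 + c(0, 1, 0))) {
      alt <- attempt(s)
      if (is.null(alt)) next
      better_value <- is.null(best) || alt$value < best$value - 1e-8
      cleaner <- alt$converged && !alt$boundary &&
        (is.null(best) || !best$converged || best$boundary ||
           alt$value < best$value + 1e-6)
      if (cleaner || (better_value && (is.null(best) || !best$converged))) {
        best <- alt
        if (best$converged && !best$boundary) break
      }
    }
  }
  if (is.null(best) || !is.finite(best$value)) {
    stop("quantal model fit failed to converge", call. = FALSE)
  }
  converged <- best$converged

  th <- reg$from_opt(best$par)
  logL <- -best$value + const
  fitted_p <- reg$prob(g$dose, th)
  boundary <- best$boundary
  ed50 <- if (boundary) NA_real_ else unname(reg$ed50(th))
  if (!boundary && (!is.finite(ed50) || ed50 <= 0)) boundary <- TRUE

  structure(list(
    model = model,
    params = th,
    logL = logL,
    k = reg$k,
    aic = aic(logL, reg$k),
    ed50 = if (boundary) NA_real_ else ed50,
    converged = converged && !boundary,
    boundary = boundary,
    groups = g,
    data = data
  ), class = "quantal_fit")
}

#' @export
print.quantal_fit <- function(x, ...) {
  cat(sprintf("Quantal %s fit: logL = %.3f, k = %d, AIC = %.2f, ED50 = %s\n",
              x$model, x$logL, x$k, x$aic,
              if (is.na(x$ed50)) "undefined (boundary)" else sprintf("%.4g", x$ed50)))
  invisible(x)
}

#' Akaike information criterion
#'
#' `AIC = 2k - 2 logL`. Exposed as a plain function of the log-likelihood and
#' parameter count so that criterion values can also be formed from published
#' fit summaries.
#'
#' @param logL log-likelihood (or a `quantal_fit`, from which `k` is taken).
#' @param k number of estimated parameters.
#' @return Numeric AIC value.
#' @examples
#' aic(-81.05, 3) # 168.1
#' @export
aic <- function(logL, k) {
  if (inherits(logL, "quantal_fit")) {
    k <- logL$k
    logL <- logL$logL
  }
  2 * k - 2 * logL
}

#' Select the best-fitting quantal model
#'
#' Minimum AIC; ties broken first by fewer parameters, then by the fixed
#' model-name order of [quantal_model_names()].
#'
#' @param fits list of `quantal_fit` objects.
#' @return The selected `quantal_fit`.
#' @export
select_best <- function(fits) {
  fits <- Filter(function(f) isTRUE(f$converged), fits)
  if (length(fits) == 0) stop("no converged fits to select from", call. = FALSE)
  ord <- order(vapply(fits, function(f) f$aic, 0),
               vapply(fits, function(f) as.numeric(f$k), 0),
               match(vapply(fits, function(f) f$model, ""), quantal_model_names()))
  fits[[ord[1]]]
}

#' Likelihood-ratio goodness-of-fit test against the saturated model
#'
#' The saturated model assigns one free response probability per dose group.
#' The statistic `2 (logL_sat - logL_fit)` is referred to a chi-square
#' distribution with `(number of dose groups - k)` degrees of freedom.
#'
#' @param fit a `quantal_fit`.
#' @param data the `dose_response_data` it was fitted to (defaults to the data
#'   stored in the fit).
#' @return List with `statistic`, `df`, `p_value` (`NA` with `saturated = TRUE`
#'   when `df <= 0`).
#' @export
goodness_of_fit <- function(fit, data = fit$data) {
  g <- group_summary(data)
  p_hat <- clamp_p(g$fraction)
  logL_sat <- sum(g$positive * log(p_hat) + (g$total - g$positive) * log1p(-p_hat)) +
    sum(lchoose(data$total, data$positive))
  stat <- max(0, 2 * (logL_sat - fit$logL))
  df <- nrow(g) - fit$k
  if (df <= 0) {
    return(list(statistic = stat, df = df, p_value = NA_real_, saturated = TRUE))
  }
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df = df, lower.tail = FALSE),
       saturated = FALSE)
}

#' Pooled parametric-bootstrap BMD uncertainty set
#'
#' For each fitted model, simulates `reps` replicate datasets from the fitted
#' group response probabilities (binomial per rat at the original design),
#' refits the same model, and collects the replicate ED50s. The replicates of
#' all models are pooled into one set, so the pool carries both sampling
#' uncertainty and model uncertainty. Non-converged or boundary refits are
#' dropped and counted, never retried.
#'
#' @param fits list of converged `quantal_fit`s (typically all seven models).
#' @param data the original `dose_response_data`.
#' @param reps bootstrap replicates per model (default 100).
#' @return A `bmd_uncertainty_set`: list with `bmd` (pooled positive values),
#'   `model` (provenance label per value), `nominal` (ED50 of the AIC-best
#'   fit), and `dropped` (named count of discarded refits per model).
#' @export
parametric_bootstrap_bmds <- function(fits, data, reps = 100) {
  stopifnot(length(fits) >= 1, reps >= 1)
  nominal <- select_best(fits)$ed50
  out_bmd <- numeric(0)
  out_model <- character(0)
  dropped <- stats::setNames(integer(length(fits)),
                             vapply(fits, function(f) f$model, ""))
  for (fit in fits) {
    reg <- quantal_registry(fit$model)
    p_hat <- clamp_p(reg$prob(data$dose, fit$params))
    for (r in seq_len(reps)) {
      y_star <- stats::rbinom(nrow(data), data$total, p_hat)
      bmd_r <- tryCatch({
        sim <- data
        sim$positive <- y_star
        refit <- fit_quantal_model(sim, fit$model)
        if (!refit$converged || is.na(refit$ed50)) NA_real_ else refit$ed50
      }, error = function(e) NA_real_)
      if (is.na(bmd_r)) {
        dropped[fit$model] <- dropped[fit$model] + 1L
      } else {
        out_bmd <- c(out_bmd, bmd_r)
        out_model <- c(out_model, fit$model)
      }
    }
    if (dropped[fit$model] > 0.2 * reps) {
      warning(sprintf("model '%s': %d of %d bootstrap refits dropped",
                      fit$model, dropped[fit$model], reps), call. = FALSE)
    }
  }
  structure(list(bmd = out_bmd, model = out_model,
                 nominal = nominal, dropped = dropped),
            class = "bmd_uncertainty_set")
}

#' @export
print.bmd_uncertainty_set <- function(x, ...) {
  cat(sprintf("Pooled BMD uncertainty set: %d values (%d dropped), nominal %.4g\n",
              length(x$bmd), sum(x$dropped), x$nominal))
  print(round(stats::quantile(x$bmd, c(0.05, 0.5, 0.95)), 2))
  invisible(x)
}

#' Fit all seven quantal models
#'
#' Convenience wrapper returning the list of fits in the canonical order.
#' Models that fail outright are dropped with a warning.
#'
#' @inheritParams fit_quantal_model
#' @return Named list of `quantal_fit`s.
#' @export
fit_all_quantal_models <- function(data) {
  fits <- list()
  for (m in quantal_model_names()) {
    f <- tryCatch(fit_quantal_model(data, m), error = function(e) {
      warning("model '", m, "' failed: ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (!is.null(f)) fits[[m]] <- f
  }
  fits
}
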