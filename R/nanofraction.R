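#' Fit the logistic-normal nanofraction uncertainty model
#'
#' The fraction F of total silica present in nano-form is uncertain and
#' bounded in (0, 1); it is modelled logistic-normal: `logit(F) ~ N(mu,
#' sigma^2)`. The model is pinned down by two quantiles: `mu = logit(p50)` and
#' `sigma = (logit(p95) - mu) / z_0.95`.
#'
#' @param p50 median of F, in (0, 1) (default 0.5).
#' @param p95 95th percentile of F, > p50 (default 0.8).
#' @return A `nanofraction_model` list with `mu`, `sigma`, `p50`, `p95`.
#' @examples
#' fit_nanofraction(0.5, 0.8) # mu 0, sigma 0.8428
#' @export
fit_nanofraction <- function(p50 = 0.5, p95 = 0.8) {
  if (!(p50 > 0 && p50 < 1 && p95 > p50 && p95 < 1)) {
    stop("need 0 < p50 < p95 < 1", call. = FALSE)
  }
  mu <- stats::qlogis(p50)
  sigma <- (stats::qlogis(p95) - mu) / stats::qnorm(0.95)
  if (sigma < 1e-8) stop("degenerate nanofraction model: sigma below 1e-8", call. = FALSE)
  structure(list(mu = mu, sigma = sigma, p50 = p50, p95 = p95),
            class = "nanofraction_model")
}

#' @export
print.nanofraction_model <- function(x, ...) {
  cat(sprintf("Logistic-normal nanofraction: mu = %.4f, sigma = %.4f (p50 %.2f, p95 %.2f)\n",
              x$mu, x$sigma, x$p50, x$p95))
  invisible(x)
}

#' Logistic-normal density, CDF and quantiles of the nanofraction
#'
#' Density of the logistic-normal distribution on (0, 1):
#' \deqn{f(x) = \frac{1}{\sigma\sqrt{2\pi}}
#'   \exp\left(-\frac{(\mathrm{logit}(x)-\mu)^2}{2\sigma^2}\right)
#'   \frac{1}{x(1-x)}.}
#'
#' @param model a `nanofraction_model`.
#' @param x fraction(s) strictly inside (0, 1).
#' @param p probabilities in (0, 1).
#' @return Density, CDF value, or quantile respectively.
#' @examples
#' m <- fit_nanofraction(0.5, 0.8)
#' nanofraction_pdf(m, 0.5) # 1.8934
#' @export
nanofraction_pdf <- function(model, x) {
  stopifnot(inherits(model, "nanofraction_model"))
  if (any(x <= 0 | x >= 1)) stop("x must lie strictly in (0, 1)", call. = FALSE)
  stats::dnorm(stats::qlogis(x), model$mu, model$sigma) / (x * (1 - x))
}

#' @rdname nanofraction_pdf
#' @export
nanofraction_cdf <- function(model, x) {
  stopifnot(inherits(model, "nanofraction_model"))
  stats::pnorm(stats::qlogis(x), model$mu, model$sigma)
}

#' @rdname nanofraction_pdf
#' @export
nanofraction_quantile <- function(model, p) {
  stopifnot(inherits(model, "nanofraction_model"))
  stats::plogis(model$mu + model$sigma * stats::qnorm(p))
}

#' Sample nanofraction values
#'
#' Draws `logistic(mu + sigma Z)` with Z standard normal, using the current
#' RNG state.
#'
#' @param model a `nanofraction_model`.
#' @param n number of draws.
#' @return Numeric vector in (0, 1).
#' @export
sample_nanofraction <- function(model, n = 1) {
  stopifnot(inherits(model, "nanofraction_model"))
  stats::plogis(model$mu + model$sigma * stats::rnorm(n))
}

#' Tail probability of the nanofraction distribution
#'
#' Probability mass beyond a threshold, computed by the normal CDF on the
#' logit scale.
#'
#' @param model a `nanofraction_model`.
#' @param threshold fraction in (0, 1).
#' @param side `"upper"` for `P(F > threshold)`, `"lower"` for
#'   `P(F < threshold)`.
#' @return Probability.
#' @examples
#' tail_probability(fit_nanofraction(0.5, 0.8), 0.85, "upper") # 0.0198
#' @export
tail_probability <- function(model, threshold, side = c("upper", "lower")) {
  side <- match.arg(side)
  p <- nanofraction_cdf(model, threshold)
  if (side == "upper") 1 - p else p
}
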