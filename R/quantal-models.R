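#' Quantal dose-response data
#'
#' Container for per-animal quantal responses: each rat contributes a count of
#' positive liver-fibrosis slides out of a fixed number of slides scored, at
#' the dose its group received. The count is modelled Binomial(slides, p(dose)).
#'
#' @param dose numeric vector, administered dose per rat (mg/kg BW/day), >= 0.
#' @param positive integer vector, positive slides per rat.
#' @param total integer, slides scored per rat (default 10) or a vector.
#' @return A `dose_response_data` object (a validated data frame with columns
#'   `dose`, `positive`, `total`).
#' @examples
#' dose_response_data(dose = rep(c(0, 810, 819), each = 5),
#'                    positive = c(0,0,1,0,0, 3,5,4,6,2, 4,5,3,6,5))
#' @export
dose_response_data <- function(dose, positive, total = 10L) {
  d <- data.frame(dose = as.numeric(dose),
                  positive = as.integer(positive),
                  total = as.integer(total))
  if (any(!is.finite(d$dose)) || any(d$dose < 0)) {
    stop("doses must be finite and non-negative", call. = FALSE)
  }
  if (any(d$positive < 0) || any(d$positive > d$total)) {
    stop("positive-slide counts must lie in [0, total slides]", call. = FALSE)
  }
  if (length(unique(d$dose)) < 2) {
    stop("at least 2 distinct dose levels are required", call. = FALSE)
  }
  if (any(d$total < 1)) stop("slides per rat must be >= 1", call. = FALSE)
  class(d) <- c("dose_response_data", "data.frame")
  d
}

#' @export
print.dose_response_data <- function(x, ...) {
  g <- group_summary(x)
  cat("Quantal dose-response data:", nrow(x), "animals,",
      nrow(g), "dose groups\n")
  print(as.data.frame(g), row.names = FALSE)
  invisible(x)
}

# per-dose-group totals and observed response fractions
group_summary <- function(data) {
  doses <- sort(unique(data$dose))
  idx <- match(data$dose, doses)
  pos <- rowsum(data$positive, idx)[, 1]
  tot <- rowsum(data$total, idx)[, 1]
  data.frame(dose = doses, positive = pos, total = tot,
             fraction = pos / tot, row.names = NULL)
}

#' Supported quantal model names
#'
#' The seven candidate quantal dose-response models, in the fixed order used
#' for AIC tie-breaking: logistic, probit, log-logistic, log-probit, weibull,
#' gamma, two-stage. The logistic and probit act on dose directly (their
#' intercept implies the background response); the remaining five carry an
#' explicit background parameter `p0` and a dose-dependent part that is zero
#' at dose zero.
#'
#' @return Character vector of the seven model names.
#' @export
quantal_model_names <- function() {
  c("logistic", "probit", "log-logistic", "log-probit",
    "weibull", "gamma", "two-stage")
}

PMIN <- 1e-12

clamp_p <- function(p) pmin(pmax(p, PMIN), 1 - PMIN)

# cap the optimiser-scale exponentials so extreme excursions cannot overflow
bexp <- function(x) exp(pmin(pmax(x, -200), 200))

safe_log_dose <- function(d) {
  # log-dose models: dose 0 contributes G = 0 exactly (handled by the caller)
  log(pmax(d, .Machine$double.xmin))
}

# Fast negative log-likelihood on the optimiser scale, built once per fit
# from group totals (Y positive of Nn at dose d). Inlines the same model
# formulas as the registry `prob` functions, avoiding per-eval dispatch.
make_group_nll <- function(model, d, Y, Nn) {
  pos <- d > 0
  ld <- log(d[pos])
  binom <- function(p) {
    p <- pmin(pmax(p, PMIN), 1 - PMIN)
    -sum(Y * log(p) + (Nn - Y) * log1p(-p))
  }
  bg <- function(phi1, G) {
    p0 <- stats::plogis(phi1)
    p <- rep(p0, length(d))
    p[pos] <- p0 + (1 - p0) * G
    p
  }
  switch(model,
    "logistic" = function(phi) binom(stats::plogis(phi[1] + bexp(phi[2]) * d)),
    "probit" = function(phi) binom(stats::pnorm(phi[1] + bexp(phi[2]) * d)),
    "log-logistic" = function(phi)
      binom(bg(phi[1], stats::plogis(phi[2] + (1 + bexp(phi[3])) * ld))),
    "log-probit" = function(phi)
      binom(bg(phi[1], stats::pnorm(phi[2] + (1 + bexp(phi[3])) * ld))),
    "weibull" = function(phi)
      binom(bg(phi[1], -expm1(-exp(pmin(phi[2] + (1 + bexp(phi[3])) * ld, 200))))),
    "gamma" = function(phi)
      binom(bg(phi[1], stats::pgamma(d[pos], shape = 1 + bexp(phi[2]),
                                     rate = bexp(phi[3])))),
    "two-stage" = function(phi)
      binom(bg(phi[1], -expm1(-(bexp(phi[2]) * d[pos] + bexp(phi[3]) * d[pos]^2)))),
    stop("unknown quantal model: ", model, call. = FALSE)
  )
}

# Model registry. Each entry: k (free parameter count), prob(d, th) on the
# natural scale, to_opt/from_opt transforms, ed50(th), start(groups).
quantal_registry <- function(model) {
  switch(model,
    "logistic" = list(
      k = 2L,
      prob = function(d, th) stats::plogis(th[["a"]] + th[["b"]] * d),
      to_opt = function(th) c(th[["a"]], log(th[["b"]])),
      from_opt = function(phi) c(a = phi[1], b = bexp(phi[2])),
      ed50 = function(th) -th[["a"]] / th[["b"]],
      start = function(g) start_linear(g, stats::qlogis)
    ),
    "probit" = list(
      k = 2L,
      prob = function(d, th) stats::pnorm(th[["a"]] + th[["b"]] * d),
      to_opt = function(th) c(th[["a"]], log(th[["b"]])),
      from_opt = function(phi) c(a = phi[1], b = bexp(phi[2])),
      ed50 = function(th) -th[["a"]] / th[["b"]],
      start = function(g) start_linear(g, stats::qnorm)
    ),
    "log-logistic" = list(
      k = 3L,
      prob = function(d, th) {
        G <- ifelse(d > 0, stats::plogis(th[["a"]] + th[["b"]] * safe_log_dose(d)), 0)
        th[["p0"]] + (1 - th[["p0"]]) * G
      },
      to_opt = function(th) c(stats::qlogis(clamp_p(th[["p0"]])), th[["a"]],
                              log(max(th[["b"]] - 1, 1e-3))),
      from_opt = function(phi) c(p0 = stats::plogis(phi[1]), a = phi[2], b = 1 + bexp(phi[3])),
      ed50 = function(th) exp(-th[["a"]] / th[["b"]]),
      start = function(g) start_logdose(g, stats::qlogis)
    ),
    "log-probit" = list(
      k = 3L,
      prob = function(d, th) {
        G <- ifelse(d > 0, stats::pnorm(th[["a"]] + th[["b"]] * safe_log_dose(d)), 0)
        th[["p0"]] + (1 - th[["p0"]]) * G
      },
      to_opt = function(th) c(stats::qlogis(clamp_p(th[["p0"]])), th[["a"]],
                              log(max(th[["b"]] - 1, 1e-3))),
      from_opt = function(phi) c(p0 = stats::plogis(phi[1]), a = phi[2], b = 1 + bexp(phi[3])),
      ed50 = function(th) exp(-th[["a"]] / th[["b"]]),
      start = function(g) start_logdose(g, stats::qnorm)
    ),
    "weibull" = list(
      k = 3L,
      prob = function(d, th) {
        G <- ifelse(d > 0, 1 - exp(-exp(th[["a"]] + th[["b"]] * safe_log_dose(d))), 0)
        th[["p0"]] + (1 - th[["p0"]]) * G
      },
      to_opt = function(th) c(stats::qlogis(clamp_p(th[["p0"]])), th[["a"]],
                              log(max(th[["b"]] - 1, 1e-3))),
      from_opt = function(phi) c(p0 = stats::plogis(phi[1]), a = phi[2], b = 1 + bexp(phi[3])),
      ed50 = function(th) exp((log(log(2)) - th[["a"]]) / th[["b"]]),
      start = function(g) start_logdose(g, function(p) log(-log(1 - p)))
    ),
    "gamma" = list(
      k = 3L,
      prob = function(d, th) {
        th[["p0"]] + (1 - th[["p0"]]) * stats::pgamma(d, shape = th[["s"]], rate = th[["b"]])
      },
      to_opt = function(th) c(stats::qlogis(clamp_p(th[["p0"]])), log(max(th[["s"]] - 1, 1e-3)), log(th[["b"]])),
      from_opt = function(phi) c(p0 = stats::plogis(phi[1]), s = 1 + bexp(phi[2]), b = bexp(phi[3])),
      ed50 = function(th) stats::qgamma(0.5, shape = th[["s"]], rate = th[["b"]]),
      start = function(g) {
        st <- start_logdose(g, stats::qnorm)
        # shape 1 exponential start, rate matched to the midpoint dose
        mid <- stats::median(g$dose[g$dose > 0])
        c(p0 = unname(st[["p0"]]), s = 1, b = log(2) / mid)
      }
    ),
    "two-stage" = list(
      k = 3L,
      prob = function(d, th) {
        th[["p0"]] + (1 - th[["p0"]]) * (1 - exp(-(th[["b1"]] * d + th[["b2"]] * d^2)))
      },
      to_opt = function(th) c(stats::qlogis(clamp_p(th[["p0"]])), log(th[["b1"]]), log(th[["b2"]])),
      from_opt = function(phi) c(p0 = stats::plogis(phi[1]), b1 = bexp(phi[2]), b2 = bexp(phi[3])),
      ed50 = function(th) {
        b1 <- th[["b1"]]; b2 <- th[["b2"]]
        if (b2 < .Machine$double.eps * b1) return(log(2) / b1)
        (-b1 + sqrt(b1^2 + 4 * b2 * log(2))) / (2 * b2)
      },
      start = function(g) {
        mid <- stats::median(g$dose[g$dose > 0])
        c(p0 = max(g$fraction[1], 0.01), b1 = log(2) / (2 * mid), b2 = log(2) / (2 * mid^2))
      }
    ),
    stop("unknown quantal model: ", model, call. = FALSE)
  )
}

# crude linear-link start: straight line through the extreme group fractions
start_linear <- function(g, link) {
  f <- pmin(pmax(g$fraction, 0.02), 0.98)
  i <- which.min(g$dose); j <- which.max(g$dose)
  b <- (link(f[j]) - link(f[i])) / max(g$dose[j] - g$dose[i], 1e-12)
  b <- max(b, 1e-6 / max(g$dose[j], 1))
  c(a = link(f[i]) - b * g$dose[i], b = b)
}

# start for background + log-dose models
start_logdose <- function(g, link) {
  p0 <- max(min(g$fraction), 0.01) * 0.5
  pos <- g[g$dose > 0, , drop = FALSE]
  G <- pmin(pmax((pos$fraction - p0) / (1 - p0), 0.02), 0.98)
  ld <- log(pos$dose)
  if (nrow(pos) >= 2 && diff(range(ld)) > 1e-9) {
    b <- (link(G[which.max(ld)]) - link(G[which.min(ld)])) / diff(range(ld))
    b <- max(b, 1.2) # power parameters are constrained >= 1
    a <- link(G[which.max(ld)]) - b * max(ld)
  } else {
    b <- 1.2
    a <- link(G[1]) - b * ld[1]
  }
  c(p0 = p0, a = a, b = b)
}
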