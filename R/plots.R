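#' Exposure-hazard overlap plot
#'
#' Plots the usual-exposure (IEXP) exceedance curve against the cumulative
#' distribution of individual benchmark doses (IBMD) on a log dose axis; the
#' overlap of the two curves indicates the amount of risk present.
#'
#' @param iexp numeric usual intakes (mg/kg BW/day).
#' @param ibmd numeric individual benchmark doses (same units).
#' @return A ggplot object.
#' @export
plot_exposure_hazard <- function(iexp, ibmd) {
  ec <- exceedance_curve(iexp)
  ib <- sort(ibmd)
  df <- rbind(
    data.frame(x = ec$x, y = ec$exceedance, curve = "IEXP exceedance"),
    data.frame(x = ib, y = seq_along(ib) / length(ib), curve = "IBMD cumulative")
  )
  df <- df[df$x > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   linetype = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose (mg/kg BW/day)", y = "fraction of population",
                  linetype = NULL) +
    ggplot2::theme_minimal()
}

#' IMoE bar plot
#'
#' Draws the variability boxes (between percentile pairs) with one-sided
#' uncertainty whiskers and the nominal median, one bar per percentile pair,
#' on a log IMoE axis. IMoE = 1 (the risk threshold) is marked.
#'
#' @param result an `imoe_result`.
#' @return A ggplot object.
#' @export
plot_imoe_bars <- function(result) {
  stopifnot(inherits(result, "imoe_result"))
  bars <- lapply(result$config$percentile_pairs, function(pp) {
    b <- imoe_percentile_bounds(result, pp)
    data.frame(label = sprintf("p%s-p%s", pp[1], pp[2]),
               lower = b$lower, upper = b$upper,
               lw = b$lower_whisker, uw = b$upper_whisker, med = b$median)
  })
  df <- do.call(rbind, bars)
  df$label <- factor(df$label, levels = rev(df$label))
  ggplot2::ggplot(df, ggplot2::aes(y = .data$label)) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lw, xmax = .data$uw),
                            height = 0.2) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$lower, xmax = .data$upper,
                                    ymin = as.numeric(.data$label) - 0.3,
                                    ymax = as.numeric(.data$label) + 0.3),
                       fill = "grey80", colour = "black") +
    ggplot2::geom_point(ggplot2::aes(x = .data$med), shape = 3, size = 3) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "red") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "IMoE", y = NULL) +
    ggplot2::theme_minimal()
}

#' Uncertainty-contribution bar plot
#'
#' Percentage contribution of Monte Carlo noise and each uncertainty source
#' to the total uncertainty of the target IMoE percentile, from the additive
#' variance decomposition.
#'
#' @param result a `factorial_result`.
#' @return A ggplot object.
#' @export
plot_contributions <- function(result) {
  stopifnot(inherits(result, "factorial_result"))
  contr <- result$fit$contributions
  labels <- c(MC = "MC", consumption = "Indiv", concentration = "Conc",
              nanofraction = "Fact", bmd = "BMD", chronic = "Chronic",
              inter = "Inter", intra = "Intra")
  df <- data.frame(source = factor(labels[names(contr)],
                                   levels = unname(labels)),
                   contribution = as.numeric(contr))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$source, y = .data$contribution)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "contribution to uncertainty (%)",
                  subtitle = sprintf("additive model explains %.2f%% of variance",
                                     result$fit$variance_explained)) +
    ggplot2::theme_minimal()
}
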