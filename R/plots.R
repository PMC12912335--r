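# ggplot2 visualisations for the main result types.

#' Volcano plot of a proteome-wide screen
#'
#' Scaled MR estimate per protein against the negative log10 FDR q-value,
#' with selected proteins highlighted.
#'
#' @param object An `mr_screen` result from [step1_screen()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mr_screen
#' @export
autoplot.mr_screen <- function(object, ...) {
  dat <- as_tibble(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$beta,
                                    y = -log10(.data$fdr_q),
                                    colour = .data$selected)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "fdr_threshold")),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey60")) +
    ggplot2::labs(x = "MR estimate (per SD LDL reduction)",
                  y = expression(-log[10]~"FDR q"),
                  colour = "FDR < threshold") +
    ggplot2::theme_minimal()
}

#' Leave-one-out forest plot
#'
#' One IVW estimate per omitted variant with 95% confidence intervals;
#' the full-set estimate is shown as a vertical reference line.
#'
#' @param object An `mr_loo` result from [mr_leave_one_out()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mr_loo
#' @export
autoplot.mr_loo <- function(object, ...) {
  dat <- as_tibble(object)
  full <- attr(object, "full")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$beta, y = .data$omitted)) +
    ggplot2::geom_vline(xintercept = full$beta, colour = "grey40",
                        linetype = "dashed") +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$beta - qnorm(0.975) * .data$se,
      xmax = .data$beta + qnorm(0.975) * .data$se)) +
    ggplot2::labs(x = "IVW estimate with variant omitted",
                  y = "omitted variant") +
    ggplot2::theme_minimal()
}

#' Scatter plot of a harmonized instrument set
#'
#' Outcome versus exposure associations with error bars and optional
#' fitted estimator slopes through the origin.
#'
#' @param h An `mr_harmonized` set.
#' @param estimates Optional tibble of `mr_result` rows whose slopes are
#'   drawn.
#' @return A ggplot object.
#' @export
plot_mr_scatter <- function(h, estimates = NULL) {
  p <- ggplot2::ggplot(as_tibble(h),
                       ggplot2::aes(x = .data$beta_exposure,
                                    y = .data$beta_outcome)) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$beta_outcome - .data$se_outcome,
      ymax = .data$beta_outcome + .data$se_outcome),
      width = 0, colour = "grey70") +
    ggplot2::geom_errorbarh(ggplot2::aes(
      xmin = .data$beta_exposure - .data$se_exposure,
      xmax = .data$beta_exposure + .data$se_exposure),
      height = 0, colour = "grey70") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "effect on exposure", y = "effect on outcome") +
    ggplot2::theme_minimal()
  if (!is.null(estimates)) {
    p <- p + ggplot2::geom_abline(
      data = as_tibble(estimates),
      ggplot2::aes(slope = .data$beta, intercept = 0,
                   colour = .data$method))
  }
  p
}
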