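#' Plot cost-effectiveness acceptability curves
#'
#' Probability that each arm is cost-effective as a function of the
#' willingness-to-pay threshold, one line per arm.
#'
#' @param ceac A `pah_ceac` tibble from [compute_ceac()].
#' @param wtp_line Optional vertical reference at a willingness-to-pay
#'   value (e.g. the configured threshold).
#' @return A ggplot object.
#' @export
plot_ceac <- function(ceac, wtp_line = NULL) {
  p <- ggplot2::ggplot(ceac, ggplot2::aes(x = .data$wtp, y = .data$probability,
                                          colour = .data$drug)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (USD per QALY)",
                  y = "Probability cost-effective", colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(wtp_line)) {
    p <- p + ggplot2::geom_vline(xintercept = wtp_line, linetype = "dashed")
  }
  p
}

#' @rdname plot_ceac
#' @param object A `pah_ceac` object.
#' @param ... Unused.
#' @importFrom ggplot2 autoplot
#' @method autoplot pah_ceac
#' @export
autoplot.pah_ceac <- function(object, ...) plot_ceac(object)

#' Plot the incremental cost-effectiveness plane of a PSA
#'
#' Scatter of incremental discounted QALYs against incremental discounted
#' cost (sildenafil minus beraprost) per draw, with the willingness-to-pay
#' line.
#'
#' @param object A `pah_psa` from [run_psa()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pah_psa
#' @export
autoplot.pah_psa <- function(object, ...) {
  wide <- tidyr::pivot_wider(object, id_cols = "draw", names_from = "drug",
                             values_from = c("cost_disc", "qalys_disc"))
  inc <- tibble::tibble(
    dq = wide$qalys_disc_sildenafil - wide$qalys_disc_beraprost,
    dc = wide$cost_disc_sildenafil - wide$cost_disc_beraprost
  )
  wtp <- attr(object, "wtp")
  ggplot2::ggplot(inc, ggplot2::aes(x = .data$dq, y = .data$dc)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = wtp, intercept = 0, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::labs(x = "Incremental QALYs (discounted)",
                  y = "Incremental cost (USD, discounted)") +
    ggplot2::theme_minimal()
}

#' Tornado plot of a one-way sensitivity analysis
#'
#' Horizontal bars spanning the ICER range induced by each parameter's
#' low/high bound, sorted by swing, with the base-case ICER marked.
#'
#' @param owsa A `pah_owsa` from [one_way_analysis()].
#' @param top Number of parameters to show (default 12).
#' @return A ggplot object.
#' @export
plot_tornado <- function(owsa, top = 12) {
  d <- utils::head(owsa, top)
  d$id <- factor(d$id, levels = rev(d$id))
  ggplot2::ggplot(d, ggplot2::aes(y = .data$id)) +
    ggplot2::geom_segment(ggplot2::aes(x = pmin(.data$icer_low, .data$icer_high),
                                       xend = pmax(.data$icer_low, .data$icer_high),
                                       yend = .data$id),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = attr(owsa, "base_icer"),
                        linetype = "dashed") +
    ggplot2::labs(x = "ICER (USD per QALY)", y = NULL) +
    ggplot2::theme_minimal()
}
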