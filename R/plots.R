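#' Plot a simulated community trajectory
#'
#' Faceted time-series view of a simulation: abundances on a log10 scale
#' (zeros shown at the axis floor) and infection prevalence in percent.
#'
#' @param object a `plankton_sim` object.
#' @param vars which series to show (default: the non-zero state variables
#'   plus prevalence).
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot plankton_sim
#' @export
autoplot.plankton_sim <- function(object, vars = NULL, ...) {
  long <- tidy(object)
  if (is.null(vars)) {
    nonzero <- vapply(split(long$value, long$variable), function(x) any(x > 0),
                      logical(1))
    vars <- names(nonzero)[nonzero]
  }
  long <- long[long$variable %in% vars, ]
  long$variable <- factor(long$variable, levels = c(.state_names, "prevalence"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "time (d)", y = NULL,
                  title = object$scenario$label) +
    ggplot2::theme_minimal()
}

#' Plot Sobol' sensitivity rankings
#'
#' Horizontal bar chart of first-order indices (with bootstrap half-width
#' error bars) for the top-ranked parameters of each analysed output.
#'
#' @param object a `sobol_result` object (e.g. from [sobol_community()]).
#' @param top how many parameters per output.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot sobol_result
#' @export
autoplot.sobol_result <- function(object, top = 5, ...) {
  has_output <- "output" %in% names(object)
  df <- if (has_output) {
    purrr::map_dfr(unique(object$output),
                   function(v) rank_top_k(object[object$output == v, ], top))
  } else {
    rank_top_k(object, top)
  }
  df$parameter <- stats::reorder(df$parameter, df$S1)
  pl <- ggplot2::ggplot(df, ggplot2::aes(x = .data$S1, y = .data$parameter)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$S1 - .data$S1_ci,
                                         xmax = .data$S1 + .data$S1_ci),
                            height = 0.25, color = "grey60") +
    ggplot2::labs(x = "first-order Sobol' index", y = NULL) +
    ggplot2::theme_minimal()
  if (has_output) pl <- pl + ggplot2::facet_wrap(~output, scales = "free_y")
  pl
}

#' Plot integrated loss shares
#'
#' @param shares a tibble from [integrated_loss_shares()].
#' @return A ggplot object.
#' @export
plot_loss_shares <- function(shares) {
  shares$term <- stats::reorder(shares$term, shares$share)
  ggplot2::ggplot(shares, ggplot2::aes(x = .data$share, y = .data$term)) +
    ggplot2::geom_col(fill = "darkorange3") +
    ggplot2::labs(x = "share of integrated losses (%)", y = NULL) +
    ggplot2::theme_minimal()
}
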