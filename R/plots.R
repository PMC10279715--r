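# ggplot2 views of the result objects and broom-style summaries.

#' Plot the mixture single-step function
#'
#' Draws the analytic step density (optionally on a log ordinate, the usual
#' way free-path laws are inspected) over a grid of step lengths.
#'
#' @param params A [mixture_params()] object.
#' @param ctrl A [series_control()] object.
#' @param s_max Upper end of the abscissa (mm); defaults to the scale where
#'   all but 1e-6 of the mass lies.
#' @param n Grid size.
#' @param log_y Log-scale the ordinate.
#' @return A ggplot object.
#' @export
plot_ssf_mix <- function(params, ctrl = series_control(), s_max = NULL,
                         n = 512L, log_y = TRUE) {
  s <- if (is.null(s_max)) NULL else seq(0, s_max, length.out = n)
  tab <- ssf_table(params, s = s, ctrl = ctrl, n = n)
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$s, y = .data$pdf)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "step length s (mm)", y = "density (1/mm)",
                  title = "Single-step function of the binary mixture")
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' @describeIn histogram_steps Overlay of a step histogram and, when
#'   `params` is supplied, the analytic step density.
#' @param object A `step_histogram`.
#' @param params Optional [mixture_params()] for the analytic overlay.
#' @param ctrl A [series_control()] object for the overlay.
#' @param log_y Log-scale the ordinate.
#' @param ... Unused.
#' @export
autoplot.step_histogram <- function(object, params = NULL,
                                    ctrl = series_control(), log_y = TRUE, ...) {
  mids <- (object$bin_left + object$bin_right) / 2
  df <- tibble::tibble(s = mids, density = object$density)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$s, y = .data$density)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "step length s (mm)", y = "density (1/mm)",
                  title = "Monte Carlo step histogram")
  if (!is.null(params)) {
    grid <- tibble::tibble(s = seq(min(object$bin_left), max(object$bin_right),
                                   length.out = 512),
                           density = pdf_ssf_mix(
                             seq(min(object$bin_left), max(object$bin_right),
                                 length.out = 512), params, ctrl))
    p <- p + ggplot2::geom_line(data = grid, colour = "red", linetype = 2)
  }
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' @describeIn build_quantile_table Plot of the tabulated distribution
#'   function.
#' @param object An `ssf_quantile_table`.
#' @param ... Unused.
#' @export
autoplot.ssf_quantile_table <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$s, y = .data$cdf)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "step length s (mm)", y = "cumulative probability",
                  title = "Tabulated step-length distribution")
}

#' @export
tidy.step_histogram <- function(x, ...) {
  tibble::tibble(bin_left = x$bin_left, bin_right = x$bin_right,
                 count = x$count, density = x$density)
}

#' @export
glance.step_histogram <- function(x, ...) {
  w <- x$bin_right - x$bin_left
  tibble::tibble(n_samples = attr(x, "n_samples"),
                 n_bins = nrow(x),
                 total_mass = sum(x$density * w))
}

#' @export
tidy.ssf_quantile_table <- function(x, ...) {
  tibble::tibble(s = x$s, cdf = x$cdf)
}

#' @export
glance.ssf_quantile_table <- function(x, ...) {
  p <- attr(x, "params")
  tibble::tibble(table_size = nrow(x),
                 coverage = attr(x, "coverage"),
                 s_max = max(x$s),
                 mean_step = mean_step_mix(p))
}

#' @importFrom ggplot2 .data
NULL
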