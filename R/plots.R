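#' Plot an all-points amplitude histogram
#'
#' @param object An `all_points_histogram`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot all_points_histogram
#' @export
autoplot.all_points_histogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(bin_center, count)) +
    ggplot2::geom_col(width = diff(attr(object, "bin_edges"))[1],
                      fill = "grey30") +
    ggplot2::labs(x = "Current (pA)", y = "Samples",
                  title = "All-points amplitude histogram") +
    ggplot2::theme_minimal()
}

#' Plot a log-binned dwell histogram with its fitted components
#'
#' Shows the square-root ordinate convention common for dwell histograms
#' optionally (`sqrt_y = TRUE`); fitted peak-at-tau components are overlaid
#' when a fit is supplied.
#'
#' @param object A `log_histogram`, or a `dwell_fit` (its histogram is used).
#' @param sqrt_y Square-root counts axis (default FALSE).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot log_histogram
#' @export
autoplot.log_histogram <- function(object, sqrt_y = FALSE, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(log10_center, count)) +
    ggplot2::geom_col(width = 1 / attr(object, "bins_per_decade"),
                      fill = "grey60") +
    ggplot2::labs(x = "log10 dwell time (s)", y = "Dwells") +
    ggplot2::theme_minimal()
  if (sqrt_y) p <- p + ggplot2::scale_y_sqrt()
  p
}

#' @rdname autoplot.log_histogram
#' @method autoplot dwell_fit
#' @export
autoplot.dwell_fit <- function(object, sqrt_y = FALSE, ...) {
  p <- autoplot.log_histogram(object$hist, sqrt_y = sqrt_y)
  if (nrow(object$components) == 0) return(p)
  xg <- seq(min(object$hist$log10_center), max(object$hist$log10_center),
            length.out = 200)
  total_amp <- attr(object$hist, "n_dwells") / log(10) *
    (1 / attr(object$hist, "bins_per_decade"))
  comp <- purrr::imap_dfr(
    seq_len(nrow(object$components)),
    function(i, ...) tibble::tibble(
      component = paste0("tau=", signif(object$components$tau[i], 3), " s"),
      log10_center = xg,
      count = peak_component(
        xg, log(object$components$tau[i]),
        object$components$weight[i] * total_amp * log(10))))
  p +
    ggplot2::geom_line(data = comp,
                       ggplot2::aes(colour = component), linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = log10(object$components$tau),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(title = paste0("Dwell-time fit (", object$kind, ")"))
}

#' Plot the unitary current-voltage relation and its slope fit
#'
#' @param object A `conductance_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot conductance_fit
#' @export
autoplot.conductance_fit <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(voltage, unitary_current)) +
    ggplot2::geom_abline(slope = object$slope_conductance / 1000,
                         intercept = object$intercept, colour = "red") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Membrane potential (mV)", y = "Unitary current (pA)",
                  title = sprintf("Slope conductance %.0f pS (r2 = %.3f)",
                                  object$slope_conductance,
                                  object$r_squared)) +
    ggplot2::theme_minimal()
}

#' NPo- or Po-voltage activation curves by group
#'
#' Mean +/- SEM per voltage and group, the standard activation-curve layout.
#'
#' @param curves Tibble with `group`, `voltage` and a value column.
#' @param value Which column to plot (default `npo`).
#' @return A ggplot.
#' @export
plot_activation_curves <- function(curves, value = "npo") {
  stopifnot(value %in% names(curves))
  summ <- curves |>
    dplyr::group_by(group, voltage) |>
    dplyr::summarise(
      mean = mean(.data[[value]], na.rm = TRUE),
      sem = stats::sd(.data[[value]], na.rm = TRUE) /
        sqrt(sum(!is.na(.data[[value]]))),
      .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(voltage, mean, colour = group)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = mean - sem,
                                          ymax = mean + sem)) +
    ggplot2::labs(x = "Membrane potential (mV)", y = toupper(value)) +
    ggplot2::theme_minimal()
}

#' Plot a stretch of a current sweep
#'
#' @param sweep A `sweep`.
#' @param from,to Time window, s (defaults: whole sweep, capped at 1 s).
#' @return A ggplot.
#' @export
plot_sweep <- function(sweep, from = 0, to = NULL) {
  stopifnot(inherits(sweep, "sweep"))
  if (is.null(to)) to <- min(max(sweep$time), from + 1)
  keep <- sweep$time >= from & sweep$time <= to
  ggplot2::ggplot(tibble::tibble(time = sweep$time[keep],
                                 current = sweep$current[keep]),
                  ggplot2::aes(time, current)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "Time (s)", y = "Current (pA)",
                  title = sprintf("%g mV", sweep$voltage)) +
    ggplot2::theme_minimal()
}
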