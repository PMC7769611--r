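#' Plot an optimal-allocation sweep
#'
#' Log-log curves of the cost-minimal foldase level (blue), holdase level
#' (red) and their sum (magenta) against synthesis rate — the U-shaped
#' total-chaperone figure with its "Goldilocks zone" minimum.
#'
#' @param object A `chap_sweep` from [sweep_synthesis_rates()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.chap_sweep <- function(object, ...) {
  long <- object |>
    dplyr::filter(.data$feasible) |>
    dplyr::select("k_syn", foldase = "foldase_conc",
                  holdase = "holdase_conc", `foldase + holdase` = "total_conc") |>
    tidyr::pivot_longer(-"k_syn", names_to = "level", values_to = "conc")
  ggplot2::ggplot(long, ggplot2::aes(.data$k_syn, .data$conc,
                                     colour = .data$level)) +
    ggplot2::geom_line(linewidth = 0.9) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c(
      "foldase" = "#3366cc", "holdase" = "#cc3333",
      "foldase + holdase" = "#cc33cc")) +
    ggplot2::labs(x = expression(k[syn] ~ "(1/day)"),
                  y = "optimal level (µM)", colour = NULL,
                  title = "Cost-minimal chaperone allocation vs synthesis rate") +
    ggplot2::theme_minimal()
}

#' Plot a log-log scaling fit
#'
#' Abundance against rate on log axes with the fitted power law; excluded
#' outliers are drawn as open diamonds.
#'
#' @param object A `slope_fit` from [fit_loglog()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.slope_fit <- function(object, ...) {
  d <- object$data
  d$excluded <- d$sample_id %in% object$excluded_ids
  line <- tibble::tibble(
    rate = range(d$rate),
    abundance = 10^(object$intercept + object$slope * log10(range(d$rate)))
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$rate, .data$abundance)) +
    ggplot2::geom_line(data = line, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$excluded), size = 2.5,
                        colour = "#3366cc") +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 5),
                                guide = "none") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "rate", y = "abundance",
      title = sprintf("%s: slope = %.2f, R² = %.2f",
                      object$chaperone_class, object$slope,
                      object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Plot cumulative chaperone cost against run time
#'
#' Total per-molecule cost (synthesis plus accumulated running cost) for a
#' foldase and a holdase over run time, with the foldase breakeven time —
#' where cumulative ATPase spend equals the one-time synthesis cost —
#' marked.
#'
#' @param cost_f,cost_h [cost_params()] for the two classes.
#' @param t_max_hours Right edge of the time axis (default 48 h).
#' @return A ggplot object.
#' @export
plot_cost_curves <- function(cost_f = cost_params(),
                             cost_h = holdase_cost_params(),
                             t_max_hours = 48) {
  t <- seq(0, t_max_hours, length.out = 200)
  d <- dplyr::bind_rows(
    tibble::tibble(t = t, class = "foldase",
                   cost = synthesis_cost(cost_f) +
                     running_cost_rate(cost_f) * t),
    tibble::tibble(t = t, class = "holdase",
                   cost = synthesis_cost(cost_h) + 0 * t)
  )
  be <- breakeven_time(cost_f)
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$t, .data$cost,
                                       colour = .data$class)) +
    ggplot2::geom_line(linewidth = 0.9) +
    ggplot2::scale_colour_manual(values = c(foldase = "#3366cc",
                                            holdase = "#cc3333")) +
    ggplot2::labs(x = "run time (hours)", y = "cumulative cost (ATP)",
                  colour = NULL,
                  title = "Chaperone cost vs usage time") +
    ggplot2::theme_minimal()
  if (is.finite(be) && be <= t_max_hours)
    p <- p + ggplot2::geom_vline(xintercept = be, linetype = "dashed",
                                 colour = "grey50")
  p
}
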