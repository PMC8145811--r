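#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Plot a scattering curve
#'
#' Log-log intensity plot with error band.
#'
#' @param object A [saxs_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot saxs_curve
#' @export
autoplot.saxs_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$q, y = .data$I)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$I - .data$sigma,
                                      ymax = .data$I + .data$sigma),
                         alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(q ~ (ring(A)^-1)),
                  y = expression(I(q) ~ (cm^-1)))
}

#' Plot a frame series
#'
#' Overlays all frames colored by time on log-log axes.
#'
#' @param series List of [saxs_curve()] frames.
#' @return A ggplot.
#' @export
plot_series <- function(series) {
  df <- purrr::imap_dfr(series, function(cv, i) {
    dplyr::mutate(tibble::as_tibble(cv), frame = i,
                  time_s = curve_time(cv))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$q, y = .data$I,
                                   group = .data$frame,
                                   color = .data$time_s)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_color_viridis_c(trans = "log10", name = "t (s)") +
    ggplot2::labs(x = expression(q ~ (ring(A)^-1)),
                  y = expression(I(q) ~ (cm^-1)))
}

#' Plot fitted parameter trajectories from an unfolding series fit
#'
#' @param params The per-frame table from [fit_unfolding_series()].
#' @param which Parameter columns to show.
#' @return A ggplot, faceted by parameter, log time axis.
#' @export
plot_parameter_trajectories <- function(params,
                                        which = c("Npro", "Nmic", "s")) {
  df <- tidyr::pivot_longer(params[, c("time_s", intersect(which,
                                                           names(params)))],
                            -"time_s", names_to = "parameter")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "time since mixing (s)", y = "fitted value")
}

#' Plot species fraction trajectories from a refolding decomposition
#'
#' @param fractions The table from [decompose_series()].
#' @return A ggplot.
#' @export
plot_fractions <- function(fractions) {
  df <- tidyr::pivot_longer(fractions[, c("time_s", "a1", "a3", "a4")],
                            -"time_s", names_to = "scale")
  df$species <- c(a1 = "complex", a3 = "native", a4 = "chain")[df$scale]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$value,
                                   color = .data$species)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "time since mixing (s)", y = "mass fraction")
}

#' Plot a pair-distance distribution
#'
#' @param object A result from [pr_from_model_curve()].
#' @param ... Unused.
#' @return A ggplot with the maximum dimension marked.
#' @method autoplot pofr_result
#' @export
autoplot.pofr_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$r, y = .data$p)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = attr(object, "Dmax"),
                        linetype = "dashed") +
    ggplot2::labs(x = expression(r ~ (ring(A))), y = "p(r)")
}
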