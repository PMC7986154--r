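#' Plot a G-value time series
#'
#' @param object a [g_value_series()] result
#' @param ... unused
#' @return a ggplot: G-values against virtual time, one line per species,
#'   logarithmic time axis
#' @export
autoplot.gvalue_series <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$time_ps, y = .data$G,
                               colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "virtual time (ps)",
                  y = "G (molecules / 100 eV)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a damage-yield series
#'
#' @param object a [damage_yield_series()] result
#' @param ... unused
#' @return a ggplot of the cumulative damage per primary against virtual
#'   time
#' @export
autoplot.damage_series <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$time_ps, y = .data$cumulative)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "virtual time (ps)",
                  y = "cumulative damage per primary") +
    ggplot2::theme_minimal()
}

#' Plot a sampler-validation table
#'
#' @param check a [sampler_check()] result
#' @return a ggplot overlaying the empirical and analytic conditional CDFs
#' @export
plot_sampler_check <- function(check) {
  ggplot2::ggplot(check$cdf, ggplot2::aes(x = .data$time_ps)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$empirical,
                                    colour = "sampled")) +
    ggplot2::geom_line(ggplot2::aes(y = .data$analytic,
                                    colour = "analytic"),
                       linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "reaction time (ps)", y = "conditional CDF",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
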