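#' Plot a survival surface
#'
#' Survival fraction versus field strength, one curve per pulse number.
#'
#' @param object An `ep_surface` tibble from [survival_surface()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ep_surface
#' @export
autoplot.ep_surface <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$efs_v_cm, y = .data$survival,
                               colour = factor(.data$pulse_number))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Electric field strength (V/cm)",
                  y = "Survival fraction", colour = "Pulses") +
    ggplot2::theme_minimal()
}

#' Plot injury area ratios over the pulse train
#'
#' Electrical- and thermal-injury relative area ratios versus pulse
#' number.
#'
#' @param object An `ep_injury` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ep_injury
#' @export
autoplot.ep_injury <- function(object, ...) {
  long <- tidyr::pivot_longer(object$series,
                              c("s_ei_ratio", "s_ti_ratio"),
                              names_to = "kind", values_to = "ratio")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pulse_number,
                                     y = .data$ratio,
                                     colour = .data$kind)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_discrete(
      labels = c(s_ei_ratio = "Electrical", s_ti_ratio = "Thermal")) +
    ggplot2::labs(x = "Pulse number", y = "Relative area ratio",
                  colour = "Injury") +
    ggplot2::theme_minimal()
}

#' Map view of a simulated grid quantity
#'
#' Renders the field magnitude, final temperature, or an injury
#' probability map of an `ep_injury` result as a raster over the physical
#' domain (coordinates in mm).
#'
#' @param injury An `ep_injury` object.
#' @param what One of `"emag"`, `"temperature"`, `"p_ei"`, `"p_ti"`.
#' @return A ggplot object.
#' @export
plot_injury_map <- function(injury,
                            what = c("p_ei", "p_ti", "emag", "temperature")) {
  what <- match.arg(what)
  m <- switch(what, p_ei = injury$p_ei, p_ti = injury$p_ti,
              emag = injury$emag_v_cm, temperature = injury$temperature_c)
  d <- injury$domain
  df <- tidyr::expand_grid(xi = seq_len(d$nx), yi = seq_len(d$ny)) |>
    dplyr::mutate(x_mm = d$x[.data$xi] * 1000, y_mm = d$y[.data$yi] * 1000,
                  value = m[cbind(.data$xi, .data$yi)])
  ggplot2::ggplot(df, ggplot2::aes(.data$x_mm, .data$y_mm,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = what) +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
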