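# ggplot2 autoplot methods for the main result types.

#' @describeIn cylindrical_concentration plot a radial/cylindrical profile
#' @param object the profile.
#' @param ... unused.
#' @export
autoplot.ha_profile <- function(object, ...) {
  kind <- attr(object, "kind") %||% "profile"
  if (kind == "cylindrical_concentration") {
    ggplot2::ggplot(object, ggplot2::aes(x = .data$lambda, y = .data$concentration)) +
      ggplot2::geom_step() +
      ggplot2::labs(x = "distance from helix axis (Å)",
                    y = "concentration (mol/L)")
  } else if (kind == "tetrahedral") {
    ggplot2::ggplot(object[is.finite(object$sg), ],
                    ggplot2::aes(x = .data$lambda, y = .data$sg)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "distance from helix axis (Å)",
                    y = expression(S[g]))
  } else {
    ggplot2::ggplot(object, ggplot2::aes(x = .data$r, y = .data$g)) +
      ggplot2::geom_line() +
      ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
      ggplot2::labs(x = "r (Å)", y = "g(r)")
  }
}

#' @describeIn reconstruct_fes heat map of the (d, theta) surface; use
#'   `polar = TRUE` for the polar chart
#' @param object an `ha_fes`.
#' @param polar draw in polar coordinates (d as radius).
#' @export
autoplot.ha_fes <- function(object, polar = FALSE, ...) {
  df <- export_polar(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$theta, y = .data$d,
                                        fill = .data$F)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "F (kJ/mol)") +
    ggplot2::labs(x = expression(theta ~ "(rad)"), y = "d (nm)")
  if (polar) p <- p + ggplot2::coord_polar(theta = "x")
  p
}

#' @describeIn project_1d plot the projected free-energy profile
#' @param object an `ha_fes_profile`.
#' @export
autoplot.ha_fes_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$d, y = .data$F)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "interhelical distance d (nm)", y = "F (kJ/mol)")
}

#' @describeIn hill_series hill-height decay over time (convergence view)
#' @param object an `ha_hills`.
#' @export
autoplot.ha_hills <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$height)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::labs(x = "time (ps)", y = "Gaussian height (kJ/mol)")
}

#' @describeIn compute_dos plot DoS components against frequency
#' @param object an `ha_dos`.
#' @export
autoplot.ha_dos <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object), c("total", "trans", "rot", "vib"),
                            names_to = "component", values_to = "dos")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq, y = .data$dos,
                                   colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency (1/ps)", y = "DoS (ps)")
}

#' @describeIn energy_vs_distance stored-energy change along the path
#' @param object an `ha_energy_profile`.
#' @export
autoplot.ha_energy_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$d, y = .data$dU)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "d (nm)", y = expression(Delta * U[d] ~ "(kJ/mol)"))
}

#' @describeIn condensation_profile observable changes along the path
#' @param object an `ha_path_profile`.
#' @export
autoplot.ha_path_profile <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object), -c("d", "n_frames"),
                            names_to = "observable", values_to = "value")
  ggplot2::ggplot(df[is.finite(df$value), ],
                  ggplot2::aes(x = .data$d, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~observable, scales = "free_y") +
    ggplot2::labs(x = "d (nm)", y = NULL)
}
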