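#' @export
autoplot.isotherm <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$area, y = .data$pressure)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = expression(paste("Area per molecule (", ring(A)^2, ")")),
      y = "Lateral pressure (mN/m)",
      title = sprintf("%s isotherm, subphase pH %g",
                      attr(object, "lipid_label") %||% "",
                      attr(object, "subphase_ph") %||% NA)
    )
}

#' @export
autoplot.compressibility_profile <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$pressure, y = .data$kappa_T)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Lateral pressure (mN/m)",
                  y = expression(kappa[T] ~ "((mN/m)"^{-1} * ")"))
}

#' @export
autoplot.velocity_profile <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$pressure, y = .data$velocity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Lateral pressure (mN/m)", y = "Sound velocity (m/s)")
}

#' @export
autoplot.sigmoid_fit <- function(object, ...) {
  grid <- tibble(ph = seq(min(object$data$ph), max(object$data$ph),
                          length.out = 200))
  grid$transition_pressure <- predict(object, grid)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$ph, y = .data$transition_pressure)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = object$pka, linetype = "dashed") +
    ggplot2::labs(x = "Subphase pH", y = "Transition pressure (mN/m)",
                  title = sprintf("Boltzmann sigmoid fit, pKa = %.2f", object$pka))
}

#' @export
autoplot.pulse_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), -"time",
                              names_to = "channel", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~channel, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "Time (s)", y = NULL)
}

#' @export
autoplot.calibration_line <- function(object, ...) {
  rng <- object$valid_ph_range
  grid <- tibble(ph = seq(rng[1], rng[2], length.out = 50))
  grid$i_ratio <- object$intercept + object$slope * grid$ph
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$ph, y = .data$i_ratio)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "pH", y = expression(I[535] / I[605]))
  if (!is.null(object$data)) {
    p <- p + ggplot2::geom_point(data = object$data)
  }
  p
}
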