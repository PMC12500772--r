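#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a bifurcation diagram
#'
#' @param object An `ma_bifurcation` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ma_bifurcation
#' @export
autoplot.ma_bifurcation <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$tau, y = .data$a)) +
    ggplot2::geom_point(size = 0.1, alpha = 0.4, na.rm = TRUE) +
    ggplot2::labs(x = expression(tau), y = "algae density a",
                  title = "Flip bifurcation diagram") +
    ggplot2::theme_minimal()
}

#' Plot a maximum-Lyapunov curve
#'
#' @param object An `ma_lyapunov_curve` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ma_lyapunov_curve
#' @export
autoplot.ma_lyapunov_curve <- function(object, ...) {
  onset <- attr(object, "onset")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$tau, y = .data$mle)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = expression(tau), y = "maximum Lyapunov exponent") +
    ggplot2::theme_minimal()
  if (is.finite(onset)) {
    p <- p + ggplot2::geom_vline(xintercept = onset, colour = "red",
                                 linetype = 3)
  }
  p
}

#' Plot a Z_m curve with its Turing threshold
#'
#' @param object An `ma_turing_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ma_turing_report
#' @export
autoplot.ma_turing_report <- function(object, ...) {
  p <- ggplot2::ggplot(object$Zm_curve,
                       ggplot2::aes(x = .data$tau, y = .data$Zm)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = expression(tau), y = expression(Z[m](tau)),
                  title = "Turing instability indicator") +
    ggplot2::theme_minimal()
  if (!is.na(object$tau_prime)) {
    p <- p + ggplot2::geom_vline(xintercept = object$tau_prime,
                                 colour = "red", linetype = 3)
  }
  p
}

#' Raster plot of a lattice field
#'
#' @param state An `ma_lattice_state`.
#' @param species `"a"` (default) or `"m"`.
#' @return A ggplot.
#' @export
plot_field <- function(state, species = c("a", "m")) {
  species <- match.arg(species)
  f <- state[[species]]
  df <- tibble::tibble(
    i = rep(seq_len(nrow(f)), times = ncol(f)),
    j = rep(seq_len(ncol(f)), each = nrow(f)),
    value = as.vector(f)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = species) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%s field at t = %d",
                                  if (species == "a") "algae" else "mussel",
                                  state$t)) +
    ggplot2::theme_minimal()
}

#' Plot a trajectory's spatial-variability trace
#'
#' @param object An `ma_trajectory`.
#' @param ... Unused.
#' @return A ggplot of the spatial standard deviation of both fields
#'   over time (log scale).
#' @method autoplot ma_trajectory
#' @export
autoplot.ma_trajectory <- function(object, ...) {
  df <- tidyr_longer_sd(object$sd_trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$sd,
                                   colour = .data$field)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "step", y = "spatial sd") +
    ggplot2::theme_minimal()
}

# minimal long-format reshape (avoids a tidyr dependency for one call)
tidyr_longer_sd <- function(sd_trace) {
  dplyr::bind_rows(
    tibble::tibble(t = sd_trace$t, field = "m", sd = sd_trace$sd_m),
    tibble::tibble(t = sd_trace$t, field = "a", sd = sd_trace$sd_a)
  )
}
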