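#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a time activity curve
#' @param object A `region_tac`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.region_tac <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_min, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (min)", y = "Activity (kBq/mL)") +
    ggplot2::theme_minimal()
}

#' Plot an activation response profile
#' @param object An `arp_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.arp_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_min, .data$arp_pct)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (min)", y = "ARP (% of baseline efflux)") +
    ggplot2::theme_minimal()
}

#' Plot an lp-ntPET fit against its data
#' @param object An `lpntpet_fit`.
#' @param ... Unused.
#' @return A ggplot with the measured TAC (points) and fitted curve (line).
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.lpntpet_fit <- function(object, ...) {
  d <- tibble::tibble(time_min = object$time_min, measured = object$C_T,
                      fitted = object$fitted)
  ggplot2::ggplot(d, ggplot2::aes(.data$time_min)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$measured), size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::labs(x = "Time (min)", y = "Activity (kBq/mL)",
                  subtitle = sprintf("gamma = %.4f, t_d = %.1f, t_p = %.1f",
                                     object$gamma, object$t_d, object$t_p)) +
    ggplot2::theme_minimal()
}

#' Plot one parametric map
#' @param maps A `parametric_maps` object.
#' @param which One of "k2a", "gamma", "t_d", "t_p", "t_gamma".
#' @return A ggplot raster.
#' @export
plot_parametric_map <- function(maps, which = "gamma") {
  m <- maps[[which]]
  d <- tidyr::expand_grid(y = seq_len(ncol(m)), x = seq_len(nrow(m)))
  d$value <- as.vector(m)
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c(na.value = "grey20") +
    ggplot2::labs(fill = which) +
    ggplot2::theme_void()
}

#' Marginal posterior histograms of ABC samples
#' @param object An `abc_samples`.
#' @param ... Unused.
#' @return A faceted ggplot.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.abc_samples <- function(object, ...) {
  long <- tidyr::pivot_longer(object[, c("k2a", "gamma", "t_d", "t_p")],
                              dplyr::everything(),
                              names_to = "parameter", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$value)) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::theme_minimal()
}
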