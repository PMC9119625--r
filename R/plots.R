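#' Plot a kinetic trajectory
#'
#' Bound-species concentrations against time, one line per species — the
#' standard time-course view of network assembly.
#'
#' @param object An `abp_trajectory`.
#' @param species Character vector of species columns to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.abp_trajectory <- function(object,
                                    species = c("FpFm", "FcLFc", "FcMFc",
                                                "FcBFm", "G"),
                                    ...) {
  species <- intersect(species, names(object))
  long <- tidyr::pivot_longer(as_tibble(object)[, c("time", species)],
                              -"time", names_to = "species",
                              values_to = "concentration")
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$concentration,
                                     colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "concentration (uM)") +
    ggplot2::theme_minimal()
}

#' Plot a crosslink surface
#'
#' Heatmap of the crosslinked-site fraction over the (linker, affinity)
#' plane, on log axes normalized by the total binding-site concentration.
#'
#' @param object A `crosslink_surface`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.crosslink_surface <- function(object, ...) {
  fc <- attr(object, "Fc_total")
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$L / fc, .data$K * fc,
                               fill = .data$frac_crosslinked)) +
    ggplot2::geom_raster() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression("[L]"[T] / "[F"[c] * "]"[T]),
                  y = expression(K[c] %.% "[F"[c] * "]"[T]),
                  fill = "crosslinked\nsite fraction") +
    ggplot2::theme_minimal()
}

#' Plot a regime scan
#'
#' Phase-diagram view: finite-cluster probability as fill, regime label as
#' contour-like discrete overlay.
#'
#' @param object A `regime_scan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.regime_scan <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = factor(.data$regime))) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_d() +
    ggplot2::labs(x = "[L]_T (uM)", y = "[M]_T (uM)", fill = "regime") +
    ggplot2::theme_minimal()
}
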