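# ggplot2 autoplot methods for the package's result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot circulation waveforms
#'
#' Pressure and flow waveforms of a circulation run, faceted by quantity
#' type, for the final `cycles` cardiac cycles.
#'
#' @param object An `rom_sim` from [simulate_circulation()].
#' @param cycles How many of the last cycles to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rom_sim
#' @export
autoplot.rom_sim <- function(object, cycles = 2, ...) {
  wf <- dplyr::filter(object$waveforms,
                      .data$cycle > max(.data$cycle) - cycles)
  long <- tidyr::pivot_longer(wf, cols = -c("t_s", "cycle", "av_open"),
                              names_to = "variable", values_to = "value")
  long$kind <- ifelse(grepl("^P_", long$variable), "pressure (mmHg)",
                      "flow (mL/s)")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t_s, y = .data$value,
                                     colour = .data$variable)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(~kind, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL, colour = NULL,
                  title = "Closed-loop circulation waveforms") +
    ggplot2::theme_minimal()
}

#' Plot an HGO fit against its data
#'
#' Observed versus fitted in-plane Cauchy stresses, one panel per stress
#' component, with the identity line.
#'
#' @param object An `hgo_fit` from [fit_hgo()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hgo_fit
#' @export
autoplot.hgo_fit <- function(object, ...) {
  m <- biaxial_plane_stress(object$data$lambda1, object$data$lambda2,
                            object$params)
  d <- dplyr::bind_rows(
    tibble::tibble(observed = object$data$sigma11_kPa,
                   fitted = m$sigma11_kPa, component = "sigma11"),
    tibble::tibble(observed = object$data$sigma22_kPa,
                   fitted = m$sigma22_kPa, component = "sigma22")
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$observed, y = .data$fitted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::facet_wrap(~component, scales = "free") +
    ggplot2::labs(x = "observed stress (kPa)", y = "fitted stress (kPa)",
                  title = "HGO biaxial fit") +
    ggplot2::theme_minimal()
}

#' Plot crimping / expansion trajectories
#'
#' Frame diameter (in French) and stored elastic energy against time.
#'
#' @param object A `crimp_result` or `expand_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot crimp_result
#' @export
autoplot.crimp_result <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$trajectory[, c("t_s", "diameter_Fr", "energy_erg")],
    cols = -"t_s", names_to = "variable", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t_s, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~variable, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL, title = "Stent trajectory") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.crimp_result
#' @method autoplot expand_result
#' @export
autoplot.expand_result <- autoplot.crimp_result

#' @importFrom rlang .data
NULL
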