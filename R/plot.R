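#' Plot helpers
#'
#' ggplot2 visualisations of the package's result objects: cycle-convergence
#' history of a run, convergence curves of a manufactured-solution study,
#' a synthesised inflow waveform, and 2D element fields on triangulated
#' domains.
#'
#' @name mpet-plots
NULL

#' @param object an `mpet_run`.
#' @param ... unused.
#' @rdname mpet-plots
#' @export
autoplot.mpet_run <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(x = .data$cycle, y = .data$rel_diff,
                               colour = .data$field)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "cycle", y = "cycle-to-cycle relative L2 difference",
                  colour = "field",
                  title = "Approach to periodic steady state")
}

#' @rdname mpet-plots
#' @export
autoplot.mms_study <- function(object, ...) {
  sp <- dplyr::mutate(object$spatial, x = .data$h, study = "spatial")
  tp <- dplyr::mutate(object$temporal, x = .data$dt, study = "temporal")
  dat <- dplyr::bind_rows(dplyr::select(sp, "x", "field", "error", "study"),
                          dplyr::select(tp, "x", "field", "error", "study"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$error,
                                    colour = .data$field)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~study, scales = "free") +
    ggplot2::labs(x = "h  /  dt", y = "relative L2 error",
                  title = "Manufactured-solution convergence")
}

#' @param waveform an `mpet_waveform`.
#' @rdname mpet-plots
#' @export
plot_waveform <- function(waveform) {
  d <- tibble::tibble(t = waveform$time, Q = waveform$flow * 6e7)  # ml/min
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data$Q)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "inflow (ml/min)",
                  title = "Arterial inflow waveform")
}

#' @param mesh a 2D `brain_mesh`.
#' @param values per-element numeric field.
#' @param label legend label.
#' @rdname mpet-plots
#' @export
plot_field <- function(mesh, values, label = "value") {
  if (mesh$dim != 2) stop("plot_field draws 2D meshes")
  el <- mesh$elems
  d <- tibble::tibble(
    id = rep(seq_len(nrow(el)), each = 3),
    x = mesh$nodes[as.vector(t(el)), 1],
    y = mesh$nodes[as.vector(t(el)), 2],
    value = rep(values, each = 3))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y, group = .data$id,
                                  fill = .data$value)) +
    ggplot2::geom_polygon(colour = NA) +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = label, x = "x (m)", y = "y (m)")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
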