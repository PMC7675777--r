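#' Tidy and glance methods
#'
#' broom-style accessors for the package's result objects:
#' * `tidy(mpet_run)`: the per-cycle, per-field relative L2 convergence
#'   history; `glance(mpet_run)`: one-row run summary.
#' * `tidy(mms_study)`: observed convergence orders (spatial and temporal);
#'   `glance(mms_study)`: one-row pass/fail style summary.
#' * `tidy(terzaghi_benchmark)`: errors per resolution and time;
#'   `glance(terzaghi_benchmark)`: derived constants and worst error.
#'
#' @param x a result object.
#' @param ... unused.
#' @return a tibble.
#' @name mpet-tidiers
NULL

#' @rdname mpet-tidiers
#' @export
tidy.mpet_run <- function(x, ...) x$history

#' @rdname mpet-tidiers
#' @export
glance.mpet_run <- function(x, ...) {
  last <- if (nrow(x$history) > 0)
    max(x$history$rel_diff[x$history$cycle == max(x$history$cycle)]) else NA_real_
  tibble::tibble(
    cycles_run = x$cycles_run, steps_per_cycle = x$steps_per_cycle,
    converged = x$converged, diverged = x$diverged,
    final_rel_diff = last, period = x$period)
}

#' @rdname mpet-tidiers
#' @export
tidy.mms_study <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$spatial_orders, study = "spatial", nominal = x$nominal$spatial),
    dplyr::mutate(x$temporal_orders, study = "temporal", nominal = x$nominal$temporal))
}

#' @rdname mpet-tidiers
#' @export
glance.mms_study <- function(x, ...) {
  tibble::tibble(
    spatial_order_min = min(x$spatial_orders$order),
    spatial_order_max = max(x$spatial_orders$order),
    temporal_order_min = min(x$temporal_orders$order),
    temporal_order_max = max(x$temporal_orders$order))
}

#' @rdname mpet-tidiers
#' @export
tidy.terzaghi_benchmark <- function(x, ...) x$errors

#' @rdname mpet-tidiers
#' @export
glance.terzaghi_benchmark <- function(x, ...) {
  tibble::tibble(
    c_v = x$problem$c_v, p_init = x$problem$p_init, t_char = x$problem$t_char,
    max_error = max(x$errors$error),
    monotone = all(diff(vapply(split(x$errors$error, x$errors$n_elements), max,
                               numeric(1))) < 0))
}
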