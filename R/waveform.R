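#' Synthesise a pulsatile arterial inflow waveform
#'
#' Stands in for subject-specific blood-flow profiles driving the arterial
#' compartment: a raised-cosine systolic bump over a fixed fraction of the
#' cycle atop a diastolic baseline. The sampled waveform is normalised so
#' that its trapezoidal time-average equals `mean_flow` exactly and its
#' peak/mean ratio equals `1 + pulsatility` by construction. An optional
#' seeded smooth perturbation (`noise > 0`) emulates beat-shape variability;
#' the normalisation is re-imposed after perturbation.
#'
#' @param mean_flow cycle-averaged volumetric inflow, m^3 s^-1 (must be > 0).
#'   Study-condition magnitudes are of order 1e-5 m^3/s (several hundred
#'   ml/min, ICA+VA-like totals).
#' @param pulsatility peak/mean - 1, in `[0, 1)`; values >= 1 would force
#'   negative diastolic flow and are rejected.
#' @param period cardiac period, s.
#' @param n_samples number of samples covering one period (first at 0, last
#'   at `period`).
#' @param seed integer seed for the optional perturbation.
#' @param noise relative amplitude of the seeded smooth shape perturbation
#'   (0 = deterministic shape).
#' @param systole_fraction fraction of the cycle occupied by the systolic
#'   bump.
#' @return An object of class `mpet_waveform`: list with `period`, `time`,
#'   `flow` (non-negative, `time[1] == 0`, `time[n] == period`).
#' @export
synth_waveform <- function(mean_flow, pulsatility = 0.4, period = 1.0,
                           n_samples = 101, seed = 1L, noise = 0,
                           systole_fraction = 0.3) {
  stopifnot(mean_flow > 0, period > 0, n_samples >= 3)
  if (pulsatility < 0 || pulsatility >= 1)
    stop("pulsatility must lie in [0, 1): >= 1 would force negative flow")
  tt <- seq(0, period, length.out = n_samples)
  ts <- systole_fraction * period
  shape <- ifelse(tt <= ts, 0.5 * (1 - cos(2 * pi * tt / ts)), 0)
  if (noise > 0) {
    pert <- with_local_seed(seed, {
      a <- stats::runif(3, -1, 1)
      a[1] * sin(2 * pi * tt / period) + a[2] * sin(4 * pi * tt / period) +
        a[3] * cos(4 * pi * tt / period)
    })
    pert[c(1, n_samples)] <- pert[1]  # keep periodic endpoints identical
    shape <- pmax(shape + noise * pert, 0)
  }
  shape[n_samples] <- shape[1]
  trapz_mean <- function(y) sum(diff(tt) * (head(y, -1) + tail(y, -1)) / 2) / period
  sbar <- trapz_mean(shape)
  smax <- max(shape)
  if (pulsatility == 0) {
    flow <- rep(mean_flow, n_samples)
  } else {
    A <- mean_flow * pulsatility / (smax - sbar)
    b <- mean_flow - A * sbar
    if (b < 0) stop("pulsatility too large for this shape: negative diastolic flow")
    flow <- b + A * shape
  }
  new_waveform(period, tt, flow)
}

new_waveform <- function(period, time, flow) {
  if (any(diff(time) <= 0)) stop("waveform times must be strictly increasing")
  if (time[1] != 0 || abs(time[length(time)] - period) > 1e-12 * period)
    stop("waveform samples must span exactly [0, period]")
  if (any(flow < 0)) stop("waveform flow must be non-negative")
  structure(list(period = period, time = time, flow = flow),
            class = "mpet_waveform")
}

#' @method print mpet_waveform
#' @export
print.mpet_waveform <- function(x, ...) {
  cat(sprintf("<mpet_waveform> period %.3g s, %d samples\n", x$period, length(x$time)))
  cat(sprintf("  mean %.4g m^3/s, peak %.4g m^3/s (peak/mean %.3f)\n",
              waveform_mean(x), max(x$flow), max(x$flow) / waveform_mean(x)))
  invisible(x)
}

#' Trapezoidal time-average of a waveform over one period
#' @param waveform an `mpet_waveform`.
#' @return mean volumetric flow, m^3 s^-1.
#' @export
waveform_mean <- function(waveform) {
  with(waveform, sum(diff(time) * (head(flow, -1) + tail(flow, -1)) / 2) / period)
}

#' Evaluate a waveform at arbitrary times (periodic)
#'
#' Linear interpolation of the sampled waveform at `t mod period`; evaluation
#' at `t` and `t + period` agree exactly.
#'
#' @param waveform an `mpet_waveform`.
#' @param t times, s (non-negative).
#' @return volumetric flow, m^3 s^-1.
#' @export
waveform_value <- function(waveform, t) {
  if (any(t < 0)) stop("t must be non-negative")
  tm <- t %% waveform$period
  stats::approx(waveform$time, waveform$flow, xout = tm, rule = 2)$y
}

#' Arterial Neumann boundary datum from an inflow waveform
#'
#' Converts the instantaneous total inflow into the per-area pressure-gradient
#' datum imposed on the arterial network at the cortical surface: the waveform
#' value is divided by the total tagged skull area and by the arterial
#' mobility `k_a / mu_a`, so that the resulting normal Darcy influx
#' `(k_a/mu_a) * datum` integrates over the surface to the instantaneous
#' waveform value.
#'
#' @param waveform an `mpet_waveform`.
#' @param t time, s (non-negative).
#' @param surface_area total tagged skull surface measure, m^2 (> 0).
#' @param mobility arterial mobility `k_a / mu_a`, m^2 Pa^-1 s^-1.
#' @return Neumann gradient datum, Pa m^-1 (uniform over the surface).
#' @export
flux_density <- function(waveform, t, surface_area, mobility) {
  if (surface_area <= 0) stop("surface_area must be positive")
  if (mobility <= 0) stop("mobility must be positive")
  waveform_value(waveform, t) / (surface_area * mobility)
}

#' Read / write a waveform as a two-column CSV (t, Q)
#'
#' @param path CSV path with columns `t` (s) and `Q` (m^3/s).
#' @param period optionally override the period (defaults to the last time).
#' @return [read_waveform_csv()]: an `mpet_waveform`;
#'   [write_waveform_csv()]: `path`, invisibly.
#' @export
read_waveform_csv <- function(path, period = NULL) {
  d <- utils::read.csv(path)
  if (!all(c("t", "Q") %in% names(d))) stop("waveform CSV needs columns t, Q")
  new_waveform(period %||% d$t[nrow(d)], d$t, d$Q)
}

#' @param waveform an `mpet_waveform`.
#' @rdname read_waveform_csv
#' @export
write_waveform_csv <- function(waveform, path) {
  utils::write.csv(data.frame(t = waveform$time, Q = waveform$flow),
                   path, row.names = FALSE)
  invisible(path)
}
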