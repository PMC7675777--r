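#' Terzaghi consolidation benchmark problem
#'
#' Classical one-dimensional consolidation of a saturated poroelastic column:
#' a constant compressive load is applied at the drained end while the other
#' end is rigid and impermeable. The excess pore pressure diffuses with
#' consolidation coefficient
#' `c_v = (k/mu) M m_v / (m_v + alpha^2 M)` where `M = 1/c` is the Biot
#' modulus and `m_v = lambda + 2G` the constrained (oedometer) modulus, and
#' the initial undrained response carries the loading efficiency
#' `p_init = load * alpha M / (m_v + alpha^2 M)`.
#'
#' @param length column length, m.
#' @param load applied compressive traction at the drained end, Pa.
#' @param k intrinsic permeability, m^2.
#' @param mu fluid viscosity, Pa s.
#' @param c_storage constrained specific storage, m^2 N^-1.
#' @param alpha Biot--Willis coefficient.
#' @param lambda,G Lame parameters, Pa.
#' @param n_terms series truncation (>= 1).
#' @return An object of class `terzaghi_problem` with the derived constants
#'   `c_v`, `p_init` and characteristic time `t_char = length^2 / c_v`.
#' @export
terzaghi_problem <- function(length, load, k, mu, c_storage, alpha, lambda, G,
                             n_terms = 200) {
  stopifnot(length > 0, k > 0, mu > 0, c_storage > 0, G > 0, n_terms >= 1)
  M <- 1 / c_storage
  m_v <- lambda + 2 * G
  c_v <- (k / mu) * M * m_v / (m_v + alpha^2 * M)
  p_init <- load * alpha * M / (m_v + alpha^2 * M)
  structure(list(length = length, load = load, k = k, mu = mu,
                 c_storage = c_storage, alpha = alpha, lambda = lambda, G = G,
                 n_terms = n_terms, c_v = c_v, p_init = p_init,
                 t_char = length^2 / c_v),
            class = "terzaghi_problem")
}

#' Terzaghi series solution for excess pore pressure
#'
#' Fourier-series solution of the consolidation problem: with `z` the
#' distance from the drained boundary (here `x = length`, the skull end of
#' the column; the base `x = 0` is rigid and impermeable),
#' `p(z, t) = p_init * sum_m (2 / M_m) sin(M_m z / l) exp(-M_m^2 c_v t / l^2)`
#' with `M_m = pi (2m + 1) / 2`.
#'
#' @param problem a [terzaghi_problem()].
#' @param x positions along the column, m (in `[0, length]`).
#' @param t time, s (> 0).
#' @return excess pore pressure at `(x, t)`, Pa.
#' @export
terzaghi_pressure <- function(problem, x, t) {
  if (t <= 0) stop("t must be positive")
  if (any(x < 0 | x > problem$length)) stop("x outside the column")
  z <- problem$length - x
  l <- problem$length
  m <- seq_len(problem$n_terms) - 1
  Mm <- pi * (2 * m + 1) / 2
  decay <- exp(-Mm^2 * problem$c_v * t / l^2)
  out <- numeric(length(x))
  for (j in seq_along(Mm)) {
    out <- out + (2 / Mm[j]) * sin(Mm[j] * z / l) * decay[j]
  }
  problem$p_init * out
}

#' Reduce a parameter set to classical single-network poroelasticity
#'
#' Zeroes every intercompartmental transfer coefficient and removes the
#' solid coupling (`alpha = 0`) of all networks except the one kept, so that
#' the system degenerates to classical Biot poroelasticity in the remaining
#' network; the porosity bound is relaxed to match. The five uncoupled
#' networks, given sealed (homogeneous Neumann) boundaries, then stay at
#' their uniform initial pressures for all time.
#'
#' @param params an [mpet_params()].
#' @param keep network letter to keep coupled.
#' @return the reduced [mpet_params()].
#' @export
reduce_to_single_network <- function(params, keep = "e") {
  stopifnot(keep %in% MPET_NETWORKS)
  params$omega[] <- 0
  a <- params$alpha
  a[setdiff(MPET_NETWORKS, keep)] <- 0
  params$alpha <- a
  params$phi <- 0
  params
}

# sealed-boundary BC set for the reduced problem: consolidation column with
# traction at the drained skull end, single drained network
terzaghi_bcs <- function(params, keep, load) {
  b <- list(u = list(SKULL = bc_traction(load), VENTRICLE = bc_dirichlet(0)))
  for (nm in MPET_NETWORKS) {
    b[[nm]] <- if (nm == keep) {
      list(SKULL = bc_dirichlet(0), VENTRICLE = bc_neumann(0))
    } else {
      list(SKULL = bc_neumann(0), VENTRICLE = bc_neumann(0))
    }
  }
  structure(b, class = "mpet_bcs")
}

#' Run the reduced solver against the Terzaghi oracle
#'
#' Builds a uniform column, reduces the six-network system to a single
#' coupled network, applies the consolidation load and compares the computed
#' excess pore pressure with the analytic series at the requested
#' dimensionless times, reporting the L-infinity error relative to the
#' initial excess pressure. The time step is refined with the mesh
#' (`dt ~ t_char / (4 n)`) so both error components shrink together.
#'
#' @param n_elements integer vector of column resolutions.
#' @param keep network kept in the reduction.
#' @param load applied traction, Pa.
#' @param length column length, m.
#' @param times dimensionless evaluation times `T = c_v t / l^2`.
#' @param params base parameter set; elastic moduli are made uniform (grey
#'   values everywhere) so the column is homogeneous.
#' @return class `terzaghi_benchmark`: list with `errors` (tibble:
#'   `n_elements`, `T`, `error`) and the underlying [terzaghi_problem()].
#' @export
terzaghi_benchmark <- function(n_elements = c(64, 128, 256), keep = "e",
                               load = 1000, length = 0.05,
                               times = c(0.5, 1.0), params = mpet_params()) {
  params$E_white <- params$E_grey
  lam <- lame_from_young(params$E_grey, params$nu)
  params$lambda_white <- params$lambda_grey <- lam$lambda
  params$G_white <- params$G_grey <- lam$G
  red <- reduce_to_single_network(params, keep)
  tz <- terzaghi_problem(length, load,
                         k = params$k[[if (keep == "c") "c_grey" else keep]],
                         mu = params$mu[[keep]],
                         c_storage = params$c_storage[[keep]],
                         alpha = red$alpha[[keep]],
                         lambda = lam$lambda, G = lam$G)
  rows <- list()
  for (n in n_elements) {
    mesh <- make_column(length, n)
    red$dt <- tz$t_char / (4 * n)
    pb <- mpet_problem(mesh, red, graph = transfer_graph(red),
                       bcs = terzaghi_bcs(red, keep, load),
                       waveform = NULL, dt = red$dt, transit = FALSE)
    p0 <- matrix(0, pb$N, 6, dimnames = list(NULL, MPET_NETWORKS))
    p0[, keep] <- tz$p_init
    init <- field_state(mesh, 0, p = p0)
    init <- equilibrate_displacement(pb, init)
    rec <- solve_transient(pb, max(times) * tz$t_char, init,
                           record = times * tz$t_char)
    for (Td in times) {
      st <- rec$recorded[[sprintf("%.12g", Td * tz$t_char)]]
      exact <- terzaghi_pressure(tz, mesh$nodes[, 1], st$t)
      rows[[length(rows) + 1]] <- tibble::tibble(
        n_elements = n, T = Td,
        error = max(abs(st$p[, keep] - exact)) / tz$p_init)
    }
  }
  structure(list(errors = dplyr::bind_rows(rows), problem = tz,
                 keep = keep, length = length),
            class = "terzaghi_benchmark")
}

#' @method print terzaghi_benchmark
#' @export
print.terzaghi_benchmark <- function(x, ...) {
  cat("<terzaghi_benchmark> single-network consolidation vs analytic series\n")
  cat(sprintf("  c_v = %.4g m^2/s, p_init = %.4g Pa, t_char = %.4g s\n",
              x$problem$c_v, x$problem$p_init, x$problem$t_char))
  print(x$errors)
  invisible(x)
}

# -- manufactured solutions ----------------------------------------------------

# uniform-coefficient parameter set used by the manufactured-solution studies
mms_params <- function(omega_zero = FALSE) {
  p <- mpet_params()
  p$E_white <- p$E_grey
  lamg <- lame_from_young(p$E_grey, p$nu)
  p$lambda_white <- p$lambda_grey <- lamg$lambda
  p$G_white <- p$G_grey <- lamg$G
  p$k[["c_grey"]] <- p$k[["c_white"]] <- p$k[["a"]]
  if (omega_zero) p$omega[] <- 0
  p
}

# closed-form manufactured solution with analytically derived forcings.
# kind "trig": smooth trigonometric fields (spatial-order studies);
# kind "linear": fields linear in space (exact in space; temporal studies).
mms_solution <- function(params, kind = c("trig", "linear")) {
  kind <- match.arg(kind)
  alpha <- params$alpha; cst <- params$c_storage
  mob <- c(a = params$k[["a"]] / params$mu[["a"]],
           c = params$k[["c_grey"]] / params$mu[["c"]],
           e = params$k[["e"]] / params$mu[["e"]],
           v = params$k[["v"]] / params$mu[["v"]],
           l = params$k[["l"]] / params$mu[["l"]],
           g = params$k[["g"]] / params$mu[["g"]])
  lamG <- lame_from_young(params$E_grey, params$nu)
  G <- lamG$G; lam <- lamG$lambda
  om <- 2 * pi
  P <- 1000 * (1 + 0.1 * seq_along(MPET_NETWORKS))
  phs <- 0.3 * seq_along(MPET_NETWORKS)
  U <- 1e-4
  pair_omega <- setNames(params$omega, names(params$omega))

  if (kind == "trig") {
    a <- 40; b <- 50
    cph <- 0.1 * seq_along(MPET_NETWORKS); dph <- 0.2 * seq_along(MPET_NETWORKS)
    Tu <- function(t) 1 + 0.5 * sin(om * t)
    Tud <- function(t) 0.5 * om * cos(om * t)
    Tq <- function(t, q) 1 + 0.5 * sin(om * t + phs[q])
    Tqd <- function(t, q) 0.5 * om * cos(om * t + phs[q])
    u_ex <- function(x, t) U * Tu(t) * cbind(sin(a * x[, 1]) * sin(b * x[, 2]),
                                             cos(a * x[, 1]) * cos(b * x[, 2]))
    p_ex_q <- function(q) function(x, t)
      P[q] * Tq(t, q) * sin(a * x[, 1] + cph[q]) * cos(b * x[, 2] + dph[q])
    grad_p_q <- function(q, x, t)
      P[q] * Tq(t, q) * cbind(a * cos(a * x[, 1] + cph[q]) * cos(b * x[, 2] + dph[q]),
                              -b * sin(a * x[, 1] + cph[q]) * sin(b * x[, 2] + dph[q]))
    lap_p_q <- function(q, x, t) -(a^2 + b^2) * p_ex_q(q)(x, t)
    eps_dot <- function(x, t) U * Tud(t) * (a - b) * cos(a * x[, 1]) * sin(b * x[, 2])
    f_u <- function(x, t) {
      lap_u <- -(a^2 + b^2) * u_ex(x, t)
      grad_eps <- U * Tu(t) * (a - b) *
        cbind(-a * sin(a * x[, 1]) * sin(b * x[, 2]),
              b * cos(a * x[, 1]) * cos(b * x[, 2]))
      out <- -G * lap_u - (G + lam) * grad_eps
      for (q in seq_along(MPET_NETWORKS))
        out <- out + alpha[[MPET_NETWORKS[q]]] * grad_p_q(q, x, t)
      out
    }
    f_p <- lapply(seq_along(MPET_NETWORKS), function(q) {
      nm <- MPET_NETWORKS[q]
      function(x, t) {
        pdot <- P[q] * Tqd(t, q) * sin(a * x[, 1] + cph[q]) * cos(b * x[, 2] + dph[q])
        out <- cst[[nm]] * pdot + alpha[[nm]] * eps_dot(x, t) -
          mob[[nm]] * lap_p_q(q, x, t)
        for (pr in MPET_PAIRS) {
          if (!(nm %in% pr)) next
          other <- setdiff(pr, nm)
          w <- pair_omega[[mpet_pair_key(pr[1], pr[2])]]
          qo <- match(other, MPET_NETWORKS)
          out <- out - w * (p_ex_q(qo)(x, t) - p_ex_q(q)(x, t))
        }
        out
      }
    })
  } else {
    Lc <- 0.1
    Tu <- function(t) 1 + 0.5 * sin(om * t)
    Tud <- function(t) 0.5 * om * cos(om * t)
    Tq <- function(t, q) 1 + 0.5 * sin(om * t + phs[q])
    Tqd <- function(t, q) 0.5 * om * cos(om * t + phs[q])
    u_ex <- function(x, t) U * Tu(t) / Lc * cbind(x[, 1] + 0.5 * x[, 2],
                                                  0.3 * x[, 1] + 0.5 * x[, 2])
    p_ex_q <- function(q) function(x, t)
      P[q] * Tq(t, q) * (1 + (x[, 1] + x[, 2]) / Lc)
    grad_p_q <- function(q, x, t)
      P[q] * Tq(t, q) / Lc * cbind(rep(1, nrow(x)), rep(1, nrow(x)))
    eps_dot <- function(x, t) rep(U * Tud(t) * 1.5 / Lc, nrow(x))
    f_u <- function(x, t) {
      out <- matrix(0, nrow(x), 2)
      for (q in seq_along(MPET_NETWORKS))
        out <- out + alpha[[MPET_NETWORKS[q]]] * grad_p_q(q, x, t)
      out
    }
    f_p <- lapply(seq_along(MPET_NETWORKS), function(q) {
      nm <- MPET_NETWORKS[q]
      function(x, t) {
        pdot <- P[q] * Tqd(t, q) * (1 + (x[, 1] + x[, 2]) / Lc)
        out <- cst[[nm]] * pdot + alpha[[nm]] * eps_dot(x, t)
        for (pr in MPET_PAIRS) {
          if (!(nm %in% pr)) next
          other <- setdiff(pr, nm)
          w <- pair_omega[[mpet_pair_key(pr[1], pr[2])]]
          if (w == 0) next
          qo <- match(other, MPET_NETWORKS)
          out <- out - w * (p_ex_q(qo)(x, t) - p_ex_q(q)(x, t))
        }
        out
      }
    })
  }
  names(f_p) <- MPET_NETWORKS
  p_ex <- lapply(seq_along(MPET_NETWORKS), function(q) p_ex_q(q))
  names(p_ex) <- MPET_NETWORKS
  list(u = u_ex, p = p_ex, f_u = f_u, f_p = f_p)
}

mms_bcs <- function(sol) {
  b <- list(u = list(SKULL = bc_dirichlet(sol$u), VENTRICLE = bc_dirichlet(sol$u)))
  for (nm in MPET_NETWORKS)
    b[[nm]] <- list(SKULL = bc_dirichlet(sol$p[[nm]]),
                    VENTRICLE = bc_dirichlet(sol$p[[nm]]))
  structure(b, class = "mpet_bcs")
}

mms_initial <- function(pb, sol) {
  st <- field_state(pb$mesh, 0)
  st$u <- sol$u(pb$mesh$nodes, 0)
  for (nm in MPET_NETWORKS) st$p[, nm] <- sol$p[[nm]](pb$mesh$nodes, 0)
  st
}

mms_run_once <- function(resolution, dt, t_end, params, sol,
                         r_inner = 0.02, r_outer = 0.07) {
  mesh <- make_shell(r_inner, r_outer, resolution, dim = 2)
  params$dt <- dt
  graph <- transfer_graph(params, valves = list(
    ac = "bidirectional", cv = "bidirectional", al = "bidirectional"))
  pb <- mpet_problem(mesh, params, graph = graph, bcs = mms_bcs(sol),
                     waveform = NULL, dt = dt, transit = FALSE,
                     forcing = list(u = sol$f_u, p = sol$f_p))
  init <- mms_initial(pb, sol)
  fin <- solve_transient(pb, t_end, init)$final_state
  lump <- pb$lump
  err <- vapply(MPET_NETWORKS, function(nm) {
    ex <- sol$p[[nm]](mesh$nodes, fin$t)
    sqrt(sum(lump * (fin$p[, nm] - ex)^2)) / sqrt(sum(lump * ex^2))
  }, numeric(1))
  err
}

#' Manufactured-solution convergence study
#'
#' Injects a closed-form solution (all seven fields, including the transfer
#' terms) into the system via symbolically derived forcings and
#' exact-solution Dirichlet data on both boundaries of a 2D annulus, and
#' measures observed convergence orders:
#' * spatial: a smooth trigonometric solution on a refinement sequence, with
#'   the time step refined as `h^2` so the first-order temporal error does
#'   not saturate the nominal second-order (L2) pressure convergence;
#' * temporal: a spatially linear solution (captured exactly by the P1
#'   spaces, transfer off) so the backward-Euler order is measured cleanly
#'   against the exact solution.
#'
#' @param resolutions >= 3 annulus resolutions for the spatial study.
#' @param dt_list time steps for the temporal study.
#' @param t_end_spatial,t_end_temporal final times, s.
#' @param dt0 spatial-study time step at the coarsest resolution.
#' @param temporal_resolution fixed mesh resolution of the temporal study.
#' @return class `mms_study`: list with `spatial`, `spatial_orders`,
#'   `temporal`, `temporal_orders` tibbles (order = least-squares slope in
#'   log-log).
#' @export
mms_study <- function(resolutions = c(4, 8, 16), dt_list = c(0.04, 0.02, 0.01),
                      t_end_spatial = 0.2, t_end_temporal = 0.2,
                      dt0 = 0.02, temporal_resolution = 4) {
  if (length(resolutions) < 3) stop("need at least 3 resolutions")
  params <- mms_params()
  sol <- mms_solution(params, "trig")
  rows <- list()
  for (res in resolutions) {
    dt <- dt0 * (min(resolutions) / res)^2
    nsteps <- ceiling(t_end_spatial / dt)
    dt <- t_end_spatial / nsteps
    err <- mms_run_once(res, dt, t_end_spatial, params, sol)
    rows[[length(rows) + 1]] <- tibble::tibble(
      resolution = res, h = 0.05 / res, field = paste0("p_", names(err)),
      error = unname(err))
  }
  spatial <- dplyr::bind_rows(rows)
  spatial_orders <- dplyr::summarise(
    dplyr::group_by(spatial, .data$field),
    order = -stats::coef(stats::lm(log(error) ~ log(resolution),
                                   data = dplyr::pick(dplyr::everything())))[2],
    .groups = "drop")

  paramsT <- mms_params(omega_zero = TRUE)
  solT <- mms_solution(paramsT, "linear")
  rows <- list()
  for (dt in dt_list) {
    nsteps <- round(t_end_temporal / dt)
    if (abs(nsteps * dt - t_end_temporal) > 1e-9)
      stop("t_end_temporal must be a multiple of every dt")
    err <- mms_run_once(temporal_resolution, dt, t_end_temporal, paramsT, solT)
    rows[[length(rows) + 1]] <- tibble::tibble(
      dt = dt, field = paste0("p_", names(err)), error = unname(err))
  }
  temporal <- dplyr::bind_rows(rows)
  temporal_orders <- dplyr::summarise(
    dplyr::group_by(temporal, .data$field),
    order = stats::coef(stats::lm(log(error) ~ log(dt),
                                  data = dplyr::pick(dplyr::everything())))[2],
    .groups = "drop")
  structure(list(spatial = spatial, spatial_orders = spatial_orders,
                 temporal = temporal, temporal_orders = temporal_orders,
                 nominal = list(spatial = 2, temporal = 1)),
            class = "mms_study")
}

#' @method print mms_study
#' @export
print.mms_study <- function(x, ...) {
  cat("<mms_study> observed convergence orders (nominal: spatial 2, temporal 1)\n")
  cat("  spatial:\n")
  for (i in seq_len(nrow(x$spatial_orders)))
    cat(sprintf("    %-4s %.2f\n", x$spatial_orders$field[i], x$spatial_orders$order[i]))
  cat("  temporal:\n")
  for (i in seq_len(nrow(x$temporal_orders)))
    cat(sprintf("    %-4s %.2f\n", x$temporal_orders$field[i], x$temporal_orders$order[i]))
  invisible(x)
}

#' Discrete poroelastic energy of a state
#'
#' `E = 1/2 u' A_uu u + 1/2 sum_i c_i p_i' M p_i`: elastic strain energy plus
#' stored fluid (compressibility) energy. In the unforced reduced problem
#' with dissipative boundaries the implicit scheme makes this non-increasing.
#'
#' @param problem an [mpet_problem()].
#' @param state a [field_state()].
#' @return scalar energy, J (per unit out-of-plane measure below 3D).
#' @export
poroelastic_energy <- function(problem, state) {
  uv <- as.vector(state$u)
  e <- 0.5 * sum(uv * as.vector(problem$A_uu %*% uv))
  for (nm in MPET_NETWORKS) {
    e <- e + 0.5 * problem$params$c_storage[[nm]] *
      sum(state$p[, nm] * as.vector(problem$M_unit %*% state$p[, nm]))
  }
  e
}
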