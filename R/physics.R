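#' Intercompartmental transfer topology
#'
#' The six networks exchange fluid along exactly eight unordered pairs:
#' a-c, c-v, a-l, c-l, v-l, e-l, g-l and e-g (there is, for instance, no
#' direct a-e exchange). Each pair carries a transfer coefficient `omega`
#' (m^2 N^-1 s^-1) and a valve mode: `bidirectional` transfer
#' `omega * (p_x - p_y)`, or a one-way valve `omega * max(p_from - p_to, 0)`.
#' Default valve directions encode forward blood flow (a->c, c->v) and
#' periarterial influx (a->l); all pairs are configurable.
#'
#' @param params an [mpet_params()] supplying the `omega` coefficients.
#' @param valves named character vector over the pair keys
#'   (`ac, cv, al, cl, vl, el, gl, eg`) with values `"bidirectional"` or
#'   `"one_way_forward"` (from the first-named network to the second);
#'   missing entries fall back to the defaults.
#' @return A `transfer_graph`: tibble with columns `pair`, `x`, `y`, `omega`,
#'   `valve`, `from`, `to`.
#' @export
transfer_graph <- function(params = mpet_params(), valves = NULL) {
  keys <- vapply(MPET_PAIRS, function(p) paste0(p[1], p[2]), character(1))
  default_valves <- c(ac = "one_way_forward", cv = "one_way_forward",
                      al = "one_way_forward", cl = "bidirectional",
                      vl = "bidirectional", el = "bidirectional",
                      gl = "bidirectional", eg = "bidirectional")
  vv <- default_valves
  if (!is.null(valves)) {
    unknown <- setdiff(names(valves), keys)
    if (length(unknown) > 0) stop("unknown transfer pair(s): ", paste(unknown, collapse = ", "))
    vv[names(valves)] <- unname(unlist(valves))
  }
  omega <- params$omega[keys]
  if (anyNA(omega)) stop("omega must carry all eight pair coefficients")
  if (any(omega < 0)) stop("transfer coefficients must be non-negative")
  g <- tibble::tibble(
    pair = keys,
    x = vapply(MPET_PAIRS, `[[`, character(1), 1),
    y = vapply(MPET_PAIRS, `[[`, character(1), 2),
    omega = unname(omega),
    valve = unname(vv[keys]),
    from = unname(ifelse(vv[keys] == "one_way_forward",
                         vapply(MPET_PAIRS, `[[`, character(1), 1), NA_character_)),
    to = unname(ifelse(vv[keys] == "one_way_forward",
                       vapply(MPET_PAIRS, `[[`, character(1), 2), NA_character_)))
  class(g) <- c("transfer_graph", class(g))
  g
}

#' Pressure-driven intercompartmental transfer rate
#'
#' `transfer(graph, x, y, p_x, p_y)` returns the spatial rate density of
#' fluid transferred from network `x` into network `y` (positive into `y`):
#' `omega * (p_x - p_y)` for a bidirectional pair, a rectified
#' `omega * max(p_from - p_to, 0)` (with the appropriate sign) for a one-way
#' valve. Antisymmetry `S_xy = -S_yx` holds in every mode, so summing the
#' transfer terms over all six network equations cancels identically
#' (pointwise mass conservation of the exchange).
#'
#' @param graph a [transfer_graph()].
#' @param x,y single network letters from `a,c,e,v,l,g`; the unordered pair
#'   must belong to the topology (a direct a-e exchange, say, is an error).
#' @param p_x,p_y pressures of networks `x` and `y`, Pa (vectorised).
#' @return transfer rate density into `y` from `x`, s^-1 scale
#'   (m^2 N^-1 s^-1 times Pa).
#' @export
transfer <- function(graph, x, y, p_x, p_y) {
  key <- mpet_pair_key(x, y)
  if (is.na(key) || !key %in% graph$pair)
    stop("no direct ", x, "-", y, " exchange in the transfer topology")
  row <- graph[graph$pair == key, ]
  out <- if (row$valve == "bidirectional") {
    row$omega * (p_x - p_y)
  } else {
    # rectified on the forward direction, sign follows the (x -> y) convention
    forward <- isTRUE(row$from == x)
    fwd <- pmax(if (forward) p_x - p_y else p_y - p_x, 0)
    if (forward) row$omega * fwd else -row$omega * fwd
  }
  unname(out)
}

#' Darcy filtration velocity
#'
#' `v = -(K / mu) grad(p)` with `K` the intrinsic permeability (scalar or
#' SPD tensor) and `mu` the dynamic viscosity. The magnitude of this velocity
#' in the capillary network is the model's perfusion field.
#'
#' @param K scalar permeability (m^2), a `d x d` SPD matrix, or an
#'   `(n x d x d)` array of per-row tensors.
#' @param mu dynamic viscosity, Pa s (> 0).
#' @param grad_p pressure gradient: length-`d` vector or `(n x d)` matrix,
#'   Pa m^-1.
#' @return velocity with the shape of `grad_p`, m s^-1.
#' @export
darcy_velocity <- function(K, mu, grad_p) {
  if (any(mu <= 0)) stop("viscosity must be positive")
  gp <- if (is.matrix(grad_p)) grad_p else matrix(grad_p, nrow = 1)
  d <- ncol(gp)
  v <- if (is.array(K) && length(dim(K)) == 3) {
    check_spd(K[1, , ])
    out <- matrix(0, nrow(gp), d)
    for (i in seq_len(d)) for (j in seq_len(d))
      out[, i] <- out[, i] - K[, i, j] * gp[, j] / mu
    out
  } else if (is.matrix(K)) {
    check_spd(K)
    -gp %*% t(K) / mu
  } else {
    if (any(K <= 0)) stop("scalar permeability must be positive")
    -K * gp / mu
  }
  if (is.matrix(grad_p)) v else drop(v)
}

check_spd <- function(K) {
  if (max(abs(K - t(K))) > 1e-10 * max(abs(K), 1e-300))
    stop("permeability tensor must be symmetric")
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("permeability tensor must be positive definite")
  invisible(TRUE)
}

#' Compartmental fluid content (swelling/drainage measure)
#'
#' `zeta = alpha * div(u) + c * (p - p_ref)`: the linearised increment of
#' fluid volume per unit bulk volume stored in a network. Positive values
#' mark swelling, negative values drainage.
#'
#' @param alpha Biot--Willis coefficient of the network, dimensionless.
#' @param c_storage constrained specific storage, m^2 N^-1.
#' @param div_u dilatational strain `div(u)`, dimensionless (vectorised).
#' @param p network pore pressure, Pa (vectorised).
#' @param p_ref reference pressure (scalar or vectorised), Pa.
#' @return fluid content `zeta`, dimensionless.
#' @export
fluid_content <- function(alpha, c_storage, div_u, p, p_ref = 0) {
  alpha * div_u + c_storage * (p - p_ref)
}
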