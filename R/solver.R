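#' Solution state of the coupled system
#'
#' Holds displacement and the six pore-pressure fields at one time level,
#' together with the discrete time derivatives of the previous step.
#'
#' @param mesh a `brain_mesh`.
#' @param t time, s.
#' @param u displacement, `N x dim` matrix, m (default zero).
#' @param p pore pressures, `N x 6` matrix with columns in network order
#'   `a, c, e, v, l, g`, Pa (default zero).
#' @return An object of class `field_state`.
#' @export
field_state <- function(mesh, t = 0, u = NULL, p = NULL) {
  N <- nrow(mesh$nodes); d <- mesh$dim
  u <- u %||% matrix(0, N, d)
  p <- p %||% matrix(0, N, 6, dimnames = list(NULL, MPET_NETWORKS))
  if (is.null(colnames(p))) colnames(p) <- MPET_NETWORKS
  structure(list(t = t, u = u, p = p,
                 u_dot = matrix(0, N, d), p_dot = matrix(0, N, 6)),
            class = "field_state")
}

# -- boundary-condition constructors ------------------------------------------

#' Boundary-condition constructors
#'
#' Conditions are attached per variable (`u` or a network letter) and per
#' tagged surface (`SKULL`, `VENTRICLE`):
#' * `bc_dirichlet(value)` — strong value; a constant, or `function(x, t)`
#'   over boundary-node coordinates (for `u`: a matrix of components).
#' * `bc_neumann(influx)` — prescribed normal influx density, m s^-1
#'   (positive into the tissue); a constant, `function(t)`, or one of the
#'   special data `"waveform"` (arterial inflow divided by the tagged skull
#'   area) and `"csf_production"` (capillary-to-ventricle efflux `-Q_p/|Gamma_v|`).
#' * `bc_traction(p_ext)` — normal traction `-p_ext n` on the displacement.
#' * `bc_traction_pe()` — ventricular normal stress `-p_V n` with `p_V` the
#'   (previous-step) surface average of the CSF/ECF pressure on the wall.
#' * `bc_dirichlet_pe_outflow(Q_o)` — skull CSF/ECF value
#'   `p_v|skull + mu_e R Q_o` (outflow-resistance relation; `Q_o` defaults to
#'   the production rate).
#' * `bc_aqueduct()` — the nonlocal ventricular CSF/ECF balance: production
#'   partitions between Poiseuille aqueduct flow (conductance
#'   `pi d^4 / (128 mu_e L)` between the surface-averaged wall and skull
#'   values), ependymal wall permeation, and wall motion; only valid for the
#'   `e` network on `VENTRICLE`.
#' * `bc_dirichlet_linked(network)` — strong value linked to another
#'   network's (previous-step) nodal values on the same surface.
#'
#' @param value constant, `function(x, t)`, or for `u` a matrix/function.
#' @param influx constant, `function(t)`, `"waveform"` or `"csf_production"`.
#' @param p_ext external pressure, Pa (constant or `function(t)`).
#' @param Q_o CSF outflow rate, m^3 s^-1 (`NULL`: use `Q_p`).
#' @param network network letter whose values are imposed.
#' @return A `bc` condition object.
#' @name mpet_bc
NULL

#' @rdname mpet_bc
#' @export
bc_dirichlet <- function(value) structure(list(kind = "dirichlet", value = value), class = "bc")
#' @rdname mpet_bc
#' @export
bc_neumann <- function(influx = 0) structure(list(kind = "neumann", influx = influx), class = "bc")
#' @rdname mpet_bc
#' @export
bc_traction <- function(p_ext) structure(list(kind = "traction", p_ext = p_ext), class = "bc")
#' @rdname mpet_bc
#' @export
bc_traction_pe <- function() structure(list(kind = "traction_pe"), class = "bc")
#' @rdname mpet_bc
#' @export
bc_dirichlet_pe_outflow <- function(Q_o = NULL)
  structure(list(kind = "dirichlet_pe_outflow", Q_o = Q_o), class = "bc")
#' @rdname mpet_bc
#' @export
bc_aqueduct <- function() structure(list(kind = "aqueduct"), class = "bc")
#' @rdname mpet_bc
#' @export
bc_dirichlet_linked <- function(network)
  structure(list(kind = "dirichlet_linked", network = network), class = "bc")

#' Physiological boundary-condition set
#'
#' The default set encodes the reference table: rigid skull (`u = 0`) with
#' ventricular normal stress `-p_V n`; pulsatile arterial Neumann inflow at
#' the cortical surface; capillary CSF production efflux at the ventricular
#' wall; CSF/ECF skull value from the venous pressure plus the outflow
#' resistance, and the nonlocal aqueduct balance at the wall; venous
#' (sagittal-sinus-like) skull value `p_bp`; glymphatic values `p_ls` (skull)
#' and `p_lv` (wall); glial value linked to the CSF/ECF pressure at the skull
#' and `p_gv` at the wall.
#'
#' @param params an [mpet_params()].
#' @param Q_o CSF outflow rate used in the skull CSF/ECF relation
#'   (default: production rate `Q_p`, i.e. production = absorption).
#' @return A named list of class `mpet_bcs`: `bcs[[variable]][[surface]]`.
#' @export
mpet_bcs <- function(params, Q_o = params$Q_p) {
  structure(list(
    u = list(SKULL = bc_dirichlet(0), VENTRICLE = bc_traction_pe()),
    a = list(SKULL = bc_neumann("waveform"), VENTRICLE = bc_neumann(0)),
    c = list(SKULL = bc_neumann(0), VENTRICLE = bc_neumann("csf_production")),
    e = list(SKULL = bc_dirichlet_pe_outflow(Q_o), VENTRICLE = bc_aqueduct()),
    v = list(SKULL = bc_dirichlet(params$p_bp), VENTRICLE = bc_neumann(0)),
    l = list(SKULL = bc_dirichlet(params$p_ls), VENTRICLE = bc_dirichlet(params$p_lv)),
    g = list(SKULL = bc_dirichlet_linked("e"), VENTRICLE = bc_dirichlet(params$p_gv))
  ), class = "mpet_bcs")
}

check_bcs <- function(bcs) {
  vars <- c("u", MPET_NETWORKS)
  for (v in vars) {
    if (is.null(bcs[[v]])) stop("missing boundary conditions for variable ", v)
    for (s in c("SKULL", "VENTRICLE")) {
      if (!inherits(bcs[[v]][[s]], "bc"))
        stop("variable ", v, " needs exactly one condition on ", s)
    }
  }
  for (v in vars) for (s in c("SKULL", "VENTRICLE")) {
    if (bcs[[v]][[s]]$kind == "aqueduct" && !(v == "e" && s == "VENTRICLE"))
      stop("the aqueduct condition is attached only to p_e on VENTRICLE")
  }
  invisible(TRUE)
}

# -- problem construction ------------------------------------------------------

#' Discretised six-network poroelastic problem
#'
#' Builds the monolithic 7-field finite-element discretisation (equal-order
#' continuous piecewise-linear displacement and pressures) of the coupled
#' system on a tagged mesh: quasi-static momentum balance
#' `div(sigma_eff) = sum_i alpha_i grad(p_i)` and six parabolic mass balances
#' `c_i dp_i/dt + alpha_i d(div u)/dt - div(K_i grad p_i) = transfers (+ Q
#' terms)`, advanced by implicit first-order (backward Euler) steps with a
#' direct sparse factorisation reused across steps. Nonlocal couplings (the
#' aqueduct balance, the outflow-resistance skull value, the ventricular
#' normal-stress traction and the linked glial value) are lagged one time
#' step (splitting error O(dt)), with an optional fixed-point inner loop.
#'
#' @param mesh a `brain_mesh`.
#' @param params an [mpet_params()].
#' @param graph a [transfer_graph()].
#' @param bcs an [mpet_bcs()] set.
#' @param waveform an `mpet_waveform` driving the arterial Neumann condition
#'   (and the microcirculatory transit pair), or `NULL`.
#' @param dt time step, s.
#' @param E_field optional per-element Young's-modulus field (e.g. from
#'   [perturb_white_stiffness()]); default: unperturbed grey/white partition.
#' @param forcing optional manufactured/volumetric forcing: list with `u =
#'   function(x, t)` returning an `elements x dim` matrix (N m^-3) and `p = a
#'   named list of function(x, t)` source densities (s^-1) per network.
#' @param transit logical: carry the microcirculatory transit pair (volumetric
#'   arterial sink and matching venous source equal to the instantaneous
#'   boundary inflow, uniformly distributed) so that blood entering the
#'   arterial compartment at the cortex is delivered to the venous drainage.
#' @param u1_mode `"mean"` or `"max"`: ventricular normal displacement entering
#'   the aqueduct relation.
#' @param aqueduct_inner_loop logical: iterate the lagged nonlocal couplings
#'   to a fixed point within each step.
#' @param inner_tol fixed-point tolerance (relative), used when
#'   `aqueduct_inner_loop = TRUE`.
#' @return An object of class `mpet_problem` (an environment holding the
#'   assembled operators and caches).
#' @export
mpet_problem <- function(mesh, params = mpet_params(), graph = transfer_graph(params),
                         bcs = mpet_bcs(params), waveform = NULL, dt = params$dt,
                         E_field = NULL, forcing = NULL, transit = TRUE,
                         u1_mode = c("mean", "max"),
                         aqueduct_inner_loop = FALSE, inner_tol = 1e-8) {
  u1_mode <- match.arg(u1_mode)
  stopifnot(inherits(mesh, "brain_mesh"), dt > 0)
  check_bcs(bcs)
  vrep <- validate_params(params)
  if (nrow(vrep) > 0)
    stop("invalid parameter set: ", paste(vrep$message, collapse = "; "))

  pb <- new.env(parent = emptyenv())
  pb$mesh <- mesh; pb$params <- params; pb$graph <- graph; pb$bcs <- bcs
  pb$waveform <- waveform; pb$dt <- dt; pb$forcing <- forcing
  pb$transit <- transit && !is.null(waveform)
  pb$u1_mode <- u1_mode
  pb$inner_loop <- aqueduct_inner_loop; pb$inner_tol <- inner_tol

  N <- nrow(mesh$nodes); d <- mesh$dim
  pb$N <- N; pb$d <- d; pb$ndof <- d * N + 6 * N
  pb$geo <- p1_geometry(mesh)
  pb$fg <- facet_geometry(mesh)
  pb$A_skull <- sum(pb$fg$measure[mesh$facet_tag == "SKULL"])
  pb$A_vent <- sum(pb$fg$measure[mesh$facet_tag == "VENTRICLE"])
  if (pb$A_skull <= 0 || pb$A_vent <= 0) stop("a tagged surface has zero measure")
  pb$V_total <- sum(pb$geo$vol)

  # elasticity field
  if (is.null(E_field)) E_field <- ifelse(mesh$tissue == "WHITE", params$E_white, params$E_grey)
  lam <- lame_from_young(E_field, params$nu)
  pb$E_field <- E_field
  pb$A_uu <- p1_elasticity(mesh, pb$geo, lam$lambda, lam$G)
  pb$B <- p1_divergence(mesh, pb$geo)
  pb$Bt <- Matrix::t(pb$B)
  pb$M_unit <- p1_mass(mesh, pb$geo, 1)
  pb$lump <- p1_lumped_mass(mesh, pb$geo, 1)
  pb$vload <- p1_load(mesh, pb$geo, rep(1, nrow(mesh$elems)))  # int phi_i
  pb$bload <- list(SKULL = p1_boundary_load(mesh, pb$fg, "SKULL", 1),
                   VENTRICLE = p1_boundary_load(mesh, pb$fg, "VENTRICLE", 1))

  # per-network mobility (k/mu), capillary partitioned, e optionally tensorial
  pb$mobility <- network_mobilities(mesh, params)
  pb$K <- lapply(pb$mobility, function(mob) p1_stiffness(mesh, pb$geo, mob))

  pb$aqueduct_C <- pi * params$d^4 / (128 * params$mu[["e"]] * params$L)

  # nonlocal coupling functionals (ventricular traction, aqueduct balance):
  # tvec[(k-1)N+i] = int_Gv n_k phi_i; savg_* = surface-average weights
  pb$tvec <- -p1_traction_load(mesh, pb$fg, "VENTRICLE", 1)  # + int n phi
  pb$savg_V <- pb$bload$VENTRICLE / pb$A_vent
  pb$savg_S <- pb$bload$SKULL / pb$A_skull

  # dof bookkeeping
  pb$off_p <- function(q) d * N + (q - 1L) * N
  pb$dir <- resolve_dirichlet(pb)

  pb$matrix_cache <- NULL
  class(pb) <- "mpet_problem"
  pb
}

#' @method print mpet_problem
#' @export
print.mpet_problem <- function(x, ...) {
  cat(sprintf("<mpet_problem> %dD mesh, %d nodes, %d dof (7 fields), dt = %.3g s\n",
              x$d, x$N, x$ndof, x$dt))
  cat(sprintf("  transit pair: %s; aqueduct conductance %.3g m^3 Pa^-1 s^-1\n",
              if (x$transit) "on" else "off", x$aqueduct_C))
  invisible(x)
}

network_mobilities <- function(mesh, params) {
  k <- params$k; mu <- params$mu
  M <- nrow(mesh$elems)
  out <- list()
  for (q in seq_along(MPET_NETWORKS)) {
    nm <- MPET_NETWORKS[q]
    if (nm == "c") {
      kv <- ifelse(mesh$tissue == "GREY", k[["c_grey"]], k[["c_white"]])
      out[[nm]] <- kv / mu[["c"]]
    } else if (nm == "e" && params$Ke_tensor_mode == "field") {
      if (is.null(mesh$Ke)) stop("Ke_tensor_mode is 'field' but the mesh carries no Ke tensors")
      out[[nm]] <- mesh$Ke / mu[["e"]]
    } else {
      out[[nm]] <- rep(k[[nm]], M) / mu[[nm]]
    }
  }
  out
}

# resolve Dirichlet dof sets and value resolvers; values may depend on the
# lagged state (linked/nonlocal conditions), so resolvers take (pb, state, t)
resolve_dirichlet <- function(pb) {
  mesh <- pb$mesh; N <- pb$N; d <- pb$d
  out <- list()
  for (s in c("SKULL", "VENTRICLE")) {
    nodes <- boundary_nodes(mesh, s)
    xb <- mesh$nodes[nodes, , drop = FALSE]
    # displacement
    bu <- pb$bcs$u[[s]]
    if (bu$kind == "dirichlet") {
      local({
        dofs <- as.vector(vapply(seq_len(d), function(k) (k - 1L) * N + nodes,
                                 integer(length(nodes))))
        val <- bu$value; xb <- xb
        out[[length(out) + 1]] <<- list(
          var = "u", surface = s, dofs = dofs,
          resolve = function(state, t) {
            if (is.function(val)) as.vector(val(xb, t))
            else if (length(val) == 1) rep(val, length(dofs))
            else as.vector(val)
          })
      })
    }
    for (q in seq_along(MPET_NETWORKS)) {
      nm <- MPET_NETWORKS[q]
      bp <- pb$bcs[[nm]][[s]]
      if (!(bp$kind %in% c("dirichlet", "dirichlet_pe_outflow", "dirichlet_linked"))) next
      dofs <- pb$off_p(q) + nodes
      local({
        bp <- bp; nodes <- nodes; xb <- xb; s <- s; dofs <- dofs
        res <- switch(bp$kind,
          dirichlet = function(state, t) {
            if (is.function(bp$value)) bp$value(xb, t) else rep(bp$value, length(nodes))
          },
          dirichlet_pe_outflow = function(state, t) {
            Qo <- bp$Q_o %||% pb$params$Q_p
            pv_avg <- surface_average(pb$mesh, pb$fg, s, state$p[, "v"])
            rep(pv_avg + pb$params$mu[["e"]] * pb$params$R * Qo, length(nodes))
          },
          dirichlet_linked = function(state, t) state$p[nodes, bp$network]
        )
        out[[length(out) + 1]] <<- list(var = nm, surface = s, dofs = dofs, resolve = res)
      })
    }
  }
  out
}

# -- system assembly -----------------------------------------------------------

# monolithic matrix for the current valve state (nodal open indicators)
build_matrix <- function(pb, open_state) {
  N <- pb$N; d <- pb$d
  alpha <- pb$params$alpha; cst <- pb$params$c_storage; dt <- pb$dt
  trip_i <- list(); trip_j <- list(); trip_x <- list(); tk <- 0L
  add <- function(A, roff, coff) {
    T <- as(A, "TsparseMatrix")
    tk <<- tk + 1L
    trip_i[[tk]] <<- T@i + 1L + roff
    trip_j[[tk]] <<- T@j + 1L + coff
    trip_x[[tk]] <<- T@x
  }
  add(pb$A_uu, 0L, 0L)
  for (q in seq_along(MPET_NETWORKS)) {
    nm <- MPET_NETWORKS[q]; op <- pb$off_p(q)
    add(-alpha[[nm]] * pb$B, 0L, op)
    add((alpha[[nm]] / dt) * pb$Bt, op, 0L)
    add((cst[[nm]] / dt) * pb$M_unit + pb$K[[nm]], op, op)
  }
  # transfer coupling (lumped, valve-masked)
  for (r in seq_len(nrow(pb$graph))) {
    g <- pb$graph[r, ]
    if (g$omega == 0) next
    qx <- match(g$x, MPET_NETWORKS); qy <- match(g$y, MPET_NETWORKS)
    w <- g$omega * pb$lump * open_state[[g$pair]]
    nz <- which(w != 0)
    if (length(nz) == 0) next
    D <- Matrix::sparseMatrix(i = nz, j = nz, x = w[nz], dims = c(N, N))
    add(D, pb$off_p(qx), pb$off_p(qx)); add(-D, pb$off_p(qx), pb$off_p(qy))
    add(D, pb$off_p(qy), pb$off_p(qy)); add(-D, pb$off_p(qy), pb$off_p(qx))
  }
  # implicit nonlocal couplings (rank-one in surface functionals):
  qe <- match("e", MPET_NETWORKS); ope <- pb$off_p(qe)
  sp_outer <- function(a, b, roff, coff) {
    ia <- which(a != 0); ib <- which(b != 0)
    Matrix::sparseMatrix(i = rep(ia, length(ib)) + roff,
                         j = rep(ib, each = length(ia)) + coff,
                         x = as.vector(outer(a[ia], b[ib])),
                         dims = c(pb$ndof, pb$ndof))
  }
  Aextra <- NULL
  addx <- function(M) { Aextra <<- if (is.null(Aextra)) M else Aextra + M }
  if (pb$bcs$u$VENTRICLE$kind == "traction_pe") {
    # total traction -p_V n with p_V = surface-averaged p_e on the wall,
    # taken at the new time level: move p_V * tvec to the left-hand side
    addx(sp_outer(pb$tvec, pb$savg_V, 0L, ope))
  }
  if (pb$bcs$e$VENTRICLE$kind == "aqueduct") {
    # aqueduct Poiseuille term and wall-motion term implicit; reference
    # configuration (linear kinematics)
    addx(sp_outer((pb$aqueduct_C / pb$A_vent) * pb$bload$VENTRICLE,
                  pb$savg_V - pb$savg_S, ope, ope))
    if (pb$u1_mode == "mean") {
      addx(sp_outer(-(1 / (pb$A_vent * pb$dt)) * pb$bload$VENTRICLE,
                    pb$tvec, ope, 0L))
    }
  }
  A <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j), x = unlist(trip_x),
                            dims = c(pb$ndof, pb$ndof))
  if (!is.null(Aextra)) A <- A + Aextra
  A
}

valve_open_state <- function(pb, state) {
  out <- list()
  for (r in seq_len(nrow(pb$graph))) {
    g <- pb$graph[r, ]
    out[[g$pair]] <- if (g$valve == "bidirectional") rep(1, pb$N) else {
      as.numeric(state$p[, g$from] > state$p[, g$to])
    }
  }
  out
}

constrain <- function(pb, A) {
  dir_dofs <- unlist(lapply(pb$dir, `[[`, "dofs"))
  Acon <- A
  Acon[dir_dofs, ] <- 0
  Acon <- Acon + Matrix::sparseMatrix(i = dir_dofs, j = dir_dofs,
                                      x = rep(1, length(dir_dofs)),
                                      dims = dim(A))
  Acon
}

# nonlocal surface data evaluated from `state` (previous time level for the
# couplings that stay lagged; also used for diagnostics and equilibration)
nonlocal_data <- function(pb, state) {
  p_eV <- surface_average(pb$mesh, pb$fg, "VENTRICLE", state$p[, "e"])
  p_eS <- surface_average(pb$mesh, pb$fg, "SKULL", state$p[, "e"])
  u1 <- ventricle_normal_displacement(pb$mesh, pb$fg, state$u, pb$u1_mode)
  u1dot <- ventricle_normal_displacement(pb$mesh, pb$fg, state$u_dot, pb$u1_mode)
  list(p_V = p_eV, p_eV = p_eV, p_eS = p_eS, u1 = u1, u1dot = u1dot)
}

# right-hand side at the new time level t1, with nonlocal data `nl`
build_rhs <- function(pb, state, t1, nl) {
  N <- pb$N; d <- pb$d; dt <- pb$dt
  params <- pb$params
  b <- numeric(pb$ndof)
  # momentum: traction terms + forcing (traction_pe is implicit in the matrix)
  for (s in c("SKULL", "VENTRICLE")) {
    bu <- pb$bcs$u[[s]]
    if (bu$kind == "traction") {
      pe <- if (is.function(bu$p_ext)) bu$p_ext(t1) else bu$p_ext
      b[1:(d * N)] <- b[1:(d * N)] + p1_traction_load(pb$mesh, pb$fg, s, pe)
    }
  }
  if (!is.null(pb$forcing$u)) {
    fvals <- pb$forcing$u(pb$mesh$nodes, t1)  # nodal, consistent-mass load
    for (k in seq_len(d))
      b[((k - 1) * N + 1):(k * N)] <- b[((k - 1) * N + 1):(k * N)] +
        as.vector(pb$M_unit %*% fvals[, k])
  }
  Q_now <- if (!is.null(pb$waveform)) waveform_value(pb$waveform, t1) else 0
  for (q in seq_along(MPET_NETWORKS)) {
    nm <- MPET_NETWORKS[q]; op <- pb$off_p(q)
    idx <- (op + 1):(op + N)
    b[idx] <- b[idx] +
      (params$c_storage[[nm]] / dt) * as.vector(pb$M_unit %*% state$p[, nm]) +
      (params$alpha[[nm]] / dt) * as.vector(pb$Bt %*% as.vector(state$u))
    for (s in c("SKULL", "VENTRICLE")) {
      bp <- pb$bcs[[nm]][[s]]
      if (bp$kind == "neumann") {
        w <- influx_density(pb, bp$influx, s, t1, Q_now)
        if (w != 0) b[idx] <- b[idx] + w * pb$bload[[s]]
      } else if (bp$kind == "aqueduct") {
        if (pb$u1_mode == "mean") {
          # Poiseuille and wall-motion parts are implicit in the matrix; the
          # production and the old-level wall position remain on the load
          w <- pb$params$Q_p / pb$A_vent + nl$u1 / dt
        } else {
          w <- aqueduct_influx_density(pb, nl)
        }
        b[idx] <- b[idx] + w * pb$bload[[s]]
      }
    }
    if (pb$transit) {
      if (nm == "a") b[idx] <- b[idx] - (Q_now / pb$V_total) * pb$vload
      if (nm == "v") b[idx] <- b[idx] + (Q_now / pb$V_total) * pb$vload
    }
    if (!is.null(pb$forcing$p[[nm]])) {
      fv <- pb$forcing$p[[nm]](pb$mesh$nodes, t1)
      b[idx] <- b[idx] + as.vector(pb$M_unit %*% fv)
    }
  }
  b
}

influx_density <- function(pb, influx, surface, t1, Q_now) {
  if (is.character(influx)) {
    switch(influx,
      waveform = Q_now / pb$A_skull,
      csf_production = -pb$params$Q_p / pb$A_vent,
      stop("unknown special Neumann datum: ", influx))
  } else if (is.function(influx)) influx(t1) else influx
}

# ventricular CSF/ECF wall-permeation influx density from the aqueduct balance
# (ventricular cavity bookkeeping on the reference configuration): production
# splits between Poiseuille aqueduct flow C (p_e|V - p_e|S), cavity volume
# change |Gamma_v| u1dot, and ependymal permeation into the tissue -- the
# returned per-area influx.
aqueduct_influx_density <- function(pb, nl) {
  pb$params$Q_p / pb$A_vent - pb$aqueduct_C * (nl$p_eV - nl$p_eS) / pb$A_vent -
    nl$u1dot
}

dirichlet_values <- function(pb, state, t1) {
  vals <- lapply(pb$dir, function(dd) dd$resolve(state, t1))
  list(dofs = unlist(lapply(pb$dir, `[[`, "dofs")), values = unlist(vals))
}

#' Assemble the unconstrained linear system for one implicit step
#'
#' Exposes the raw discrete operator and load vector of the backward-Euler
#' step (before boundary constraints): the 7-block matrix with symmetric
#' alpha-coupling between displacement and each pressure, and the right-hand
#' side carrying storage history, Neumann/traction loads, transit sources and
#' any manufactured forcing. Used directly by the verification harness;
#' [mpet_step()] wraps it with constraint application and factor caching.
#'
#' @param problem an [mpet_problem()].
#' @param state the [field_state()] at the previous time level.
#' @param dt time step, s (defaults to the problem's).
#' @return list with `A` (unconstrained sparse matrix), `b` (load vector),
#'   `t1` (new time), `nl` (lagged nonlocal data), `open` (valve state).
#' @export
mpet_assemble <- function(problem, state, dt = problem$dt) {
  if (dt != problem$dt) stop("the assembled operator is built for the problem's dt")
  open <- valve_open_state(problem, state)
  nl <- nonlocal_data(problem, state)
  t1 <- state$t + dt
  A <- build_matrix(problem, open)
  b <- build_rhs(problem, state, t1, nl)
  list(A = A, b = b, t1 = t1, nl = nl, open = open)
}

#' Apply boundary constraints to an assembled system
#'
#' Strongly imposes all Dirichlet rows (including the lagged linked/nonlocal
#' values resolved from the previous-step state) on a system produced by
#' [mpet_assemble()].
#'
#' @param system list from [mpet_assemble()].
#' @param problem the owning [mpet_problem()].
#' @param state the previous-step [field_state()] (source of lagged values).
#' @return list with constrained `A`, `b` and the `dirichlet` values used.
#' @export
apply_bcs <- function(system, problem, state) {
  dv <- dirichlet_values(problem, state, system$t1)
  A <- constrain(problem, system$A)
  b <- system$b
  b[dv$dofs] <- dv$values
  list(A = A, b = b, dirichlet = dv)
}

# -- stepping ------------------------------------------------------------------

state_from_vector <- function(pb, x, t1, prev) {
  N <- pb$N; d <- pb$d
  u <- matrix(x[1:(d * N)], N, d)
  p <- matrix(x[(d * N + 1):pb$ndof], N, 6, dimnames = list(NULL, MPET_NETWORKS))
  structure(list(t = t1, u = u, p = p,
                 u_dot = (u - prev$u) / (t1 - prev$t),
                 p_dot = (p - prev$p) / (t1 - prev$t)),
            class = "field_state")
}

get_factor <- function(pb, open) {
  sig <- open
  cache <- pb$matrix_cache
  if (!is.null(cache) && identical(cache$sig, sig)) return(cache)
  A <- build_matrix(pb, open)
  Acon <- constrain(pb, A)
  cache <- list(sig = sig, A = A, Acon = Acon, lu = Matrix::lu(Acon))
  pb$matrix_cache <- cache
  cache
}

#' Advance the coupled system by one implicit time step
#'
#' Solves the constrained monolithic sparse system for the new time level
#' (direct sparse LU, factor reused while the valve state is unchanged).
#' With `aqueduct_inner_loop = TRUE` on the problem, the lagged nonlocal
#' couplings are iterated to a fixed point.
#'
#' @param problem an [mpet_problem()].
#' @param state [field_state()] at time `t`.
#' @param dt time step, s.
#' @param record_flux logical: attach per-network boundary/source flux
#'   decomposition (reaction residuals at Dirichlet rows) as attribute
#'   `"flux"` of the returned state.
#' @return the [field_state()] at `t + dt`.
#' @export
mpet_step <- function(problem, state, dt = problem$dt, record_flux = FALSE) {
  pb <- problem
  open <- valve_open_state(pb, state)
  fac <- get_factor(pb, open)
  nl <- nonlocal_data(pb, state)
  t1 <- state$t + dt
  lag_state <- state  # source of lagged linked Dirichlet values only
  repeat {
    b <- build_rhs(pb, state, t1, nl)  # storage history always from t_n
    dv <- dirichlet_values(pb, lag_state, t1)
    bcon <- b; bcon[dv$dofs] <- dv$values
    x <- as.vector(Matrix::solve(fac$lu, bcon))
    if (!all(is.finite(x))) stop("linear solver breakdown: non-finite solution")
    new_state <- state_from_vector(pb, x, t1, state)
    if (!pb$inner_loop) break
    # fixed-point loop on the nonlocal couplings: refresh lagged data from the
    # new iterate until the update is below tolerance
    nl_new <- nonlocal_data(pb, new_state)
    delta <- abs(nl_new$p_V - nl$p_V) / max(abs(nl_new$p_V), 1)
    if (delta < pb$inner_tol) break
    nl <- nl_new; lag_state <- new_state
  }
  if (record_flux) {
    attr(new_state, "flux") <- step_flux(pb, fac$A, b, x, t1, nl, new_state)
  }
  new_state
}

# per-network flux decomposition for one step (positive = into the network)
step_flux <- function(pb, A_unc, b_unc, x, t1, nl, new_state) {
  r <- as.vector(A_unc %*% x - b_unc)
  Q_now <- if (!is.null(pb$waveform)) waveform_value(pb$waveform, t1) else 0
  rows <- list()
  for (q in seq_along(MPET_NETWORKS)) {
    nm <- MPET_NETWORKS[q]
    for (s in c("SKULL", "VENTRICLE")) {
      bp <- pb$bcs[[nm]][[s]]
      nodes <- boundary_nodes(pb$mesh, s)
      dofs <- pb$off_p(q) + nodes
      flux <- if (bp$kind %in% c("dirichlet", "dirichlet_pe_outflow", "dirichlet_linked")) {
        sum(r[dofs])
      } else if (bp$kind == "neumann") {
        w <- influx_density(pb, bp$influx, s, t1, Q_now)
        w * sum(pb$bload[[s]][nodes])
      } else if (bp$kind == "aqueduct") {
        nlx <- if (pb$u1_mode == "mean") nonlocal_data(pb, new_state) else nl
        aqueduct_influx_density(pb, nlx) * sum(pb$bload[[s]][nodes])
      } else 0
      rows[[length(rows) + 1]] <- tibble::tibble(
        t = t1, network = nm, pathway = paste0(s, ":", bp$kind), flux = flux)
    }
    if (pb$transit) {
      tr <- if (nm == "a") -Q_now else if (nm == "v") Q_now else 0
      if (tr != 0)
        rows[[length(rows) + 1]] <- tibble::tibble(
          t = t1, network = nm, pathway = "transit", flux = tr)
    }
  }
  dplyr::bind_rows(rows)
}

#' Default initial state
#'
#' Hydrostatic constants compatible with the boundary data: arterial at the
#' arterial-like `p_ls`, capillary at ~18 mmHg, CSF/ECF at the skull outflow
#' value `p_bp + mu_e R Q_p`, venous at `p_bp`, glymphatic and glial at the
#' mid-values of their two surface conditions; displacement equilibrated
#' against the initial pressures.
#'
#' @param problem an [mpet_problem()].
#' @param equilibrate logical: solve the momentum block for a displacement in
#'   equilibrium with the initial pressures.
#' @return a [field_state()] at `t = 0`.
#' @export
initial_state <- function(problem, equilibrate = TRUE) {
  pm <- problem$params
  pe0 <- pm$p_bp + pm$mu[["e"]] * pm$R * pm$Q_p
  p0 <- c(a = pm$p_ls, c = 18 * 133.322, e = pe0, v = pm$p_bp,
          l = (pm$p_ls + pm$p_lv) / 2, g = (pe0 + pm$p_gv) / 2)
  st <- field_state(problem$mesh, 0,
                    p = matrix(rep(p0, each = problem$N), problem$N, 6,
                               dimnames = list(NULL, MPET_NETWORKS)))
  if (equilibrate) st <- equilibrate_displacement(problem, st)
  st
}

#' Solve the momentum block for displacement at fixed pressures
#'
#' @param problem an [mpet_problem()].
#' @param state a [field_state()]; its pressures are held fixed.
#' @return the state with `u` replaced by the elastic equilibrium.
#' @export
equilibrate_displacement <- function(problem, state) {
  pb <- problem; N <- pb$N; d <- pb$d
  nl <- nonlocal_data(pb, state)
  rhs <- numeric(d * N)
  for (s in c("SKULL", "VENTRICLE")) {
    bu <- pb$bcs$u[[s]]
    if (bu$kind == "traction_pe")
      rhs <- rhs + p1_traction_load(pb$mesh, pb$fg, s, nl$p_V)
    else if (bu$kind == "traction") {
      pe <- if (is.function(bu$p_ext)) bu$p_ext(state$t) else bu$p_ext
      rhs <- rhs + p1_traction_load(pb$mesh, pb$fg, s, pe)
    }
  }
  for (q in seq_along(MPET_NETWORKS)) {
    nm <- MPET_NETWORKS[q]
    rhs <- rhs + pb$params$alpha[[nm]] * as.vector(pb$B %*% state$p[, nm])
  }
  A <- pb$A_uu
  # strong u Dirichlet rows
  udir <- integer(0); uval <- numeric(0)
  for (dd in pb$dir) {
    if (dd$var != "u") next
    udir <- c(udir, dd$dofs); uval <- c(uval, dd$resolve(state, state$t))
  }
  if (length(udir) > 0) {
    A[udir, ] <- 0
    A <- A + Matrix::sparseMatrix(i = udir, j = udir, x = rep(1, length(udir)),
                                  dims = dim(A))
    rhs[udir] <- uval
  }
  u <- matrix(as.vector(Matrix::solve(A, rhs)), N, d)
  state$u <- u
  state
}

# -- cycle control -------------------------------------------------------------

#' Advance whole cardiac cycles to a periodic steady state
#'
#' Iterates implicit steps over repeated identical forcing cycles, recording
#' for every cycle and every field the phase-matched relative L2 difference
#' against the previous cycle, and stops at `n_cycles` or earlier once every
#' field's difference falls below `tol`. The first `exclude` cycles are
#' excluded from the convergence statistics (initial transient). A divergence
#' detector flags total-norm growth over three consecutive cycles.
#'
#' @param problem an [mpet_problem()] (the waveform supplies the period).
#' @param n_cycles maximum number of cycles.
#' @param tol relative cycle-to-cycle tolerance per field.
#' @param init initial [field_state()] (default [initial_state()]).
#' @param period cycle period, s (default: waveform period; required if no
#'   waveform).
#' @param exclude number of initial cycles excluded from convergence checks.
#' @param record_flux logical: record the per-step flux decomposition during
#'   every cycle's steps (needed by [mass_balance()]).
#' @param vtu_dir optional directory for per-step VTU snapshots (+ PVD).
#' @param vtu_stride write every `vtu_stride`-th step (0 = none).
#' @return An `mpet_run`: list with `final_state`, `history` (tibble: cycle,
#'   field, rel_diff), `converged`, `diverged`, `cycles_run`,
#'   `last_cycle_states`, `flux` (tibble or NULL), `problem`.
#' @export
run_cycles <- function(problem, n_cycles = 50, tol = 1e-4, init = NULL,
                       period = NULL, exclude = 2, record_flux = FALSE,
                       vtu_dir = NULL, vtu_stride = 0) {
  pb <- problem
  period <- period %||% (if (!is.null(pb$waveform)) pb$waveform$period else
    stop("no waveform on the problem: supply `period`"))
  spc <- round(period / pb$dt)
  if (abs(spc * pb$dt - period) > 1e-9 * period)
    stop("period must be an integer multiple of dt")
  state <- init %||% initial_state(pb)
  fields <- c("u", paste0("p_", MPET_NETWORKS))
  hist <- list(); flux <- list()
  prev_cycle <- NULL
  norms_total <- numeric(0)
  converged <- FALSE; diverged <- FALSE
  cyc <- 0
  vtu_files <- character(0); vtu_times <- numeric(0)
  for (cyc in seq_len(n_cycles)) {
    this_cycle <- vector("list", spc)
    for (k in seq_len(spc)) {
      state <- mpet_step(pb, state, record_flux = record_flux)
      this_cycle[[k]] <- state
      if (record_flux) flux[[length(flux) + 1]] <-
          dplyr::mutate(attr(state, "flux"), cycle = cyc)
      if (!is.null(vtu_dir) && vtu_stride > 0 &&
          (((cyc - 1) * spc + k) %% vtu_stride == 0)) {
        f <- sprintf("state_%05d.vtu", (cyc - 1) * spc + k)
        write_fields(pb$mesh, state, file.path(vtu_dir, f))
        vtu_files <- c(vtu_files, f); vtu_times <- c(vtu_times, state$t)
      }
    }
    if (!is.null(prev_cycle)) {
      rel <- cycle_rel_diff(this_cycle, prev_cycle)
      hist[[length(hist) + 1]] <- tibble::tibble(
        cycle = cyc, field = fields, rel_diff = rel)
      if (cyc > exclude && all(rel < tol)) { converged <- TRUE }
    }
    norms_total <- c(norms_total, sqrt(sum(vapply(this_cycle, function(s)
      sum(s$u^2) + sum(s$p^2), numeric(1)))))
    nn <- length(norms_total)
    if (nn >= 4 && all(diff(tail(norms_total, 4)) > 0) &&
        tail(norms_total, 1) > 1.5 * norms_total[nn - 3]) {
      diverged <- TRUE
      warning("divergence detected: cycle norms grew over 3 consecutive cycles")
    }
    prev_cycle <- this_cycle
    if (converged || diverged) break
  }
  if (!is.null(vtu_dir) && length(vtu_files) > 0)
    write_pvd(vtu_files, vtu_times, file.path(vtu_dir, "series.pvd"))
  structure(list(
    problem = pb, final_state = state,
    history = if (length(hist)) dplyr::bind_rows(hist) else
      tibble::tibble(cycle = integer(), field = character(), rel_diff = numeric()),
    converged = converged, diverged = diverged, cycles_run = cyc,
    steps_per_cycle = spc, period = period,
    last_cycle_states = prev_cycle,
    flux = if (record_flux) dplyr::bind_rows(flux) else NULL
  ), class = "mpet_run")
}

cycle_rel_diff <- function(cur, prev) {
  fields <- c("u", paste0("p_", MPET_NETWORKS))
  num <- den <- setNames(numeric(length(fields)), fields)
  for (what in fields) {
    for (k in seq_along(cur)) {
      a <- if (what == "u") cur[[k]]$u else cur[[k]]$p[, sub("p_", "", what)]
      b <- if (what == "u") prev[[k]]$u else prev[[k]]$p[, sub("p_", "", what)]
      num[what] <- num[what] + sum((a - b)^2)
      den[what] <- den[what] + sum(a^2)
    }
  }
  # fields at (numerically) zero amplitude are measured against the overall
  # state scale, not their own vanishing norm
  floor_scale <- 1e-10 * sqrt(max(den))
  sqrt(num) / pmax(sqrt(den), floor_scale, 1e-300)
}

#' @method print mpet_run
#' @export
print.mpet_run <- function(x, ...) {
  cat(sprintf("<mpet_run> %d cycle(s) of %d steps; %s\n", x$cycles_run,
              x$steps_per_cycle,
              if (x$converged) "converged to periodic steady state"
              else if (x$diverged) "DIVERGED" else "cycle budget exhausted"))
  if (nrow(x$history) > 0) {
    last <- dplyr::filter(x$history, .data$cycle == max(.data$cycle))
    cat("  final cycle-to-cycle relative L2 differences:\n")
    for (i in seq_len(nrow(last)))
      cat(sprintf("    %-4s %.3e\n", last$field[i], last$rel_diff[i]))
  }
  invisible(x)
}

#' Integrate a transient problem over a fixed time window
#'
#' Plain backward-Euler integration without cycle bookkeeping; used by the
#' verification harness (consolidation benchmark, manufactured solutions).
#'
#' @param problem an [mpet_problem()].
#' @param t_end final time, s.
#' @param init initial [field_state()].
#' @param record optional times at which to keep states (matched to the
#'   nearest completed step).
#' @return list with `final_state` and `recorded` (list of states).
#' @export
solve_transient <- function(problem, t_end, init, record = numeric(0)) {
  state <- init
  nsteps <- round((t_end - init$t) / problem$dt)
  recorded <- list()
  for (k in seq_len(nsteps)) {
    state <- mpet_step(problem, state)
    for (tr in record) {
      if (abs(state$t - tr) < problem$dt / 2 && is.null(recorded[[sprintf("%.12g", tr)]]))
        recorded[[sprintf("%.12g", tr)]] <- state
    }
  }
  list(final_state = state, recorded = recorded)
}

#' Cycle-integrated mass balance of a run
#'
#' Aggregates the per-step flux decomposition of the final recorded cycle:
#' boundary reactions at Dirichlet surfaces, prescribed Neumann/aqueduct
#' influxes and transit sources, per network and pathway (positive = into the
#' tissue). At a periodic steady state the total over all networks vanishes
#' up to the cycle-closure error, and the arterial boundary influx balances
#' the total efflux through the venous and CSF drainage pathways.
#'
#' @param run an `mpet_run` produced with `record_flux = TRUE`.
#' @return list with `by_pathway` (tibble: network, pathway, cycle-integrated
#'   volume, m^3), `influx`, `efflux` and `imbalance` (relative, vs influx).
#' @export
mass_balance <- function(run) {
  if (is.null(run$flux)) stop("run was not recorded with record_flux = TRUE")
  last <- dplyr::filter(run$flux, .data$cycle == max(.data$cycle))
  dtv <- run$problem$dt
  by_path <- dplyr::summarise(
    dplyr::group_by(last, .data$network, .data$pathway),
    volume = sum(.data$flux) * dtv, .groups = "drop")
  influx <- sum(by_path$volume[by_path$volume > 0])
  efflux <- -sum(by_path$volume[by_path$volume < 0])
  list(by_pathway = by_path, influx = influx, efflux = efflux,
       imbalance = abs(influx - efflux) / max(influx, 1e-300))
}
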