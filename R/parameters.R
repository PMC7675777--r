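#' Constitutive parameters of the six-network poroelastic model
#'
#' Builds the full coefficient set of the coupled displacement + six-pressure
#' system: Biot--Willis coefficients, constrained specific storages, intrinsic
#' permeabilities, viscosities, Lame parameters for the grey/white partition,
#' intercompartmental transfer coefficients for the eight coupled network
#' pairs, boundary pressures, the CSF production/outflow constants and the
#' aqueduct geometry. All values are SI. Defaults are the reference brain
#' parameterisation used throughout the package.
#'
#' Networks are indexed `a` (arterial/arteriole), `c` (capillary), `e`
#' (CSF/ECF), `v` (venule/venous), `l` (glymphatic/perivascular), `g` (glial).
#'
#' The capillary permeability is partitioned into grey and white values
#' (`k_c_grey`, `k_c_white`); the CSF/ECF network may carry a per-element
#' anisotropic permeability tensor field (`Ke_tensor_mode = "field"`),
#' otherwise its scalar `k_e` is used isotropically.
#'
#' Viscosities are not part of the reference table and default to CSF/water-like
#' values for the e/l/g networks and blood-like values for a/c/v; they are
#' explicit, documented assumptions and freely configurable.
#'
#' @param alpha named numeric, Biot--Willis coefficient per network
#'   (names `a,c,e,v,l,g`), dimensionless.
#' @param c_storage named numeric, constrained specific storage per network,
#'   m^2 N^-1.
#' @param k named numeric, intrinsic permeability, m^2; names
#'   `a, c_grey, c_white, e, v, l, g`.
#' @param mu named numeric, dynamic viscosity per network, Pa s.
#' @param E_grey,E_white Young's moduli of grey and white matter, Pa.
#' @param nu Poisson ratio (shared by both tissues), dimensionless.
#' @param stiffness_perturbation_amplitude half-width of the white-matter
#'   Young's-modulus perturbation, Pa.
#' @param omega named numeric, intercompartmental transfer coefficients for
#'   the eight pairs `ac, cv, al, cl, vl, el, gl, eg`, m^2 N^-1 s^-1.
#' @param phi total porosity, dimensionless (used in the Biot--Willis sum
#'   validity check).
#' @param p_ls,p_lv,p_gv,p_bp boundary pressures, Pa: glymphatic skull value
#'   (arterial-pressure-like), glymphatic ventricular value, glial ventricular
#'   value, venous (sagittal-sinus-like) skull value.
#' @param Q_p CSF production rate, m^3 s^-1.
#' @param R CSF outflow resistance constant; enters only through the product
#'   `mu_e * R * Q_o` (units of `mu_e * R`: Pa s m^-3).
#' @param d,L aqueduct diameter and length, m.
#' @param r_v ventricular reference radius, m.
#' @param dt time step, s.
#' @param Ke_tensor_mode `"isotropic"` or `"field"` (per-element tensor
#'   supplied on the mesh) for the CSF/ECF permeability.
#'
#' @return An object of class `mpet_params` (a named list). Lame parameters
#'   `lambda_grey, G_grey, lambda_white, G_white` are derived from
#'   `(E, nu)` via [lame_from_young()].
#' @seealso [validate_params()], [lame_from_young()],
#'   [perturb_white_stiffness()], [read_mpet_config()]
#' @export
#' @examples
#' p <- mpet_params()
#' round(c(p$lambda_grey, p$G_grey, p$G_white))
#' nrow(validate_params(p))  # 0: the reference set is valid
mpet_params <- function(alpha = c(a = 0.1, c = 0.2, e = 0.2, v = 0.1, l = 0.2, g = 0.2),
                        c_storage = c(a = 2.9e-4, c = 2.9e-4, e = 3.9e-4,
                                      v = 1.5e-5, l = 1.5e-5, g = 1.5e-5),
                        k = c(a = 1.0e-10, c_grey = 1.0e-8, c_white = 1.0e-10,
                              e = 1.0e-10, v = 1.0e-10, l = 2.0e-11, g = 5.0e-8),
                        mu = c(a = 3.5e-3, c = 3.5e-3, e = 8.9e-4,
                               v = 3.5e-3, l = 8.9e-4, g = 8.9e-4),
                        E_grey = 584, E_white = 1168, nu = 0.35,
                        stiffness_perturbation_amplitude = 10,
                        omega = c(ac = 1.5e-19, cv = 1.5e-19, al = 2.8e-14,
                                  cl = 4.1e-9, vl = 4.1e-9, el = 4.1e-9,
                                  gl = 4.1e-9, eg = 4.1e-9),
                        phi = 0.3,
                        p_ls = 13332.2, p_lv = 2445, p_gv = 1767, p_bp = 650,
                        Q_p = 5.8e-9, R = 8.5e13,
                        d = 3e-3, L = 70e-3, r_v = 0.02,
                        dt = 0.1,
                        Ke_tensor_mode = c("isotropic", "field")) {
  Ke_tensor_mode <- match.arg(Ke_tensor_mode)
  lame_g <- if (E_grey > 0 && nu > 0 && nu < 0.5) lame_from_young(E_grey, nu) else
    list(lambda = NA_real_, G = NA_real_)
  lame_w <- if (E_white > 0 && nu > 0 && nu < 0.5) lame_from_young(E_white, nu) else
    list(lambda = NA_real_, G = NA_real_)
  structure(list(
    alpha = alpha[MPET_NETWORKS],
    c_storage = c_storage[MPET_NETWORKS],
    k = k[c("a", "c_grey", "c_white", "e", "v", "l", "g")],
    mu = mu[MPET_NETWORKS],
    E_grey = E_grey, E_white = E_white, nu = nu,
    lambda_grey = lame_g$lambda, G_grey = lame_g$G,
    lambda_white = lame_w$lambda, G_white = lame_w$G,
    stiffness_perturbation_amplitude = stiffness_perturbation_amplitude,
    omega = omega[c("ac", "cv", "al", "cl", "vl", "el", "gl", "eg")],
    phi = phi,
    p_ls = p_ls, p_lv = p_lv, p_gv = p_gv, p_bp = p_bp,
    Q_p = Q_p, R = R, d = d, L = L, r_v = r_v, dt = dt,
    Ke_tensor_mode = Ke_tensor_mode
  ), class = "mpet_params")
}

#' @method print mpet_params
#' @export
print.mpet_params <- function(x, ...) {
  cat("<mpet_params> six-network poroelastic parameter set\n")
  cat("  alpha:", paste(sprintf("%s=%.3g", names(x$alpha), x$alpha), collapse = " "),
      sprintf("(sum %.3g, phi %.3g)\n", sum(x$alpha), x$phi))
  cat(sprintf("  elasticity: grey E=%.4g (lambda=%.4g, G=%.4g)  white E=%.4g (lambda=%.4g, G=%.4g)  nu=%.3g\n",
              x$E_grey, x$lambda_grey, x$G_grey, x$E_white, x$lambda_white, x$G_white, x$nu))
  cat(sprintf("  dt=%.3g s, Q_p=%.3g m^3/s, aqueduct d=%.3g m L=%.3g m\n",
              x$dt, x$Q_p, x$d, x$L))
  v <- validate_params(x)
  if (nrow(v) == 0) cat("  validation: OK\n") else
    cat(sprintf("  validation: %d violation(s) -- see validate_params()\n", nrow(v)))
  invisible(x)
}

#' Validate a parameter set
#'
#' Checks every structural invariant of the parameter set and reports all
#' violations as a tibble. Validation never raises: missing or malformed
#' fields are themselves reported as violations, so the return value is the
#' single source of truth on validity (zero rows iff valid).
#'
#' Invariants checked:
#' * `phi <= sum(alpha) <= 1` (Biot--Willis coefficients bounded by total
#'   porosity from below and unity from above),
#' * all storages, permeabilities and viscosities strictly positive; all
#'   transfer coefficients non-negative,
#' * `0 < nu < 0.5`; Lame parameters positive and consistent with `(E, nu)`
#'   to within 1 Pa after rounding,
#' * `dt > 0`; aqueduct diameter/length and ventricular radius positive.
#'
#' @param params an [mpet_params()] object (or any list with its fields).
#' @return A tibble with columns `field`, `value`, `message`; zero rows iff
#'   the set is valid.
#' @export
validate_params <- function(params) {
  bad <- list()
  note <- function(field, value, message) {
    bad[[length(bad) + 1]] <<- tibble::tibble(
      field = field,
      value = if (is.numeric(value) && length(value) == 1) value else NA_real_,
      message = message)
  }
  need <- function(field) {
    v <- params[[field]]
    if (is.null(v)) note(field, NA_real_, sprintf("missing field '%s'", field))
    v
  }

  alpha <- need("alpha"); phi <- need("phi")
  if (!is.null(alpha)) {
    if (length(alpha) != 6 || anyNA(alpha)) {
      note("alpha", NA_real_, "alpha must hold six finite values (a,c,e,v,l,g)")
    } else {
      s <- sum(alpha)
      if (!is.null(phi) && !is.na(phi) && s < phi)
        note("alpha", s, sprintf("Biot-Willis sum %.4g < total porosity %.4g", s, phi))
      if (s > 1)
        note("alpha", s, sprintf("Biot-Willis sum %.4g > 1", s))
      if (any(alpha < 0))
        note("alpha", min(alpha), "negative Biot-Willis coefficient")
    }
  }
  for (f in c("c_storage", "k", "mu")) {
    v <- need(f)
    if (!is.null(v)) {
      if (anyNA(v)) note(f, NA_real_, sprintf("'%s' contains missing values", f))
      else if (any(v <= 0))
        note(f, min(v), sprintf("'%s' must be strictly positive (min %.3g)", f, min(v)))
    }
  }
  om <- need("omega")
  if (!is.null(om)) {
    if (length(om) != 8 || anyNA(om))
      note("omega", NA_real_, "omega must hold the eight pair coefficients (ac,cv,al,cl,vl,el,gl,eg)")
    else if (any(om < 0))
      note("omega", min(om), "transfer coefficients must be non-negative")
  }
  nu <- need("nu")
  if (!is.null(nu) && !is.na(nu)) {
    if (nu <= 0 || nu >= 0.5)
      note("nu", nu, sprintf("Poisson ratio %.4g outside (0, 0.5)", nu))
  }
  for (tis in c("grey", "white")) {
    E <- params[[paste0("E_", tis)]]
    lam <- params[[paste0("lambda_", tis)]]
    G <- params[[paste0("G_", tis)]]
    if (is.null(E) || is.null(lam) || is.null(G) || anyNA(c(E, lam, G))) {
      note(paste0("E_", tis), NA_real_, sprintf("%s-matter elastic constants incomplete", tis))
      next
    }
    if (E <= 0) note(paste0("E_", tis), E, "Young's modulus must be positive")
    if (lam <= 0 || G <= 0)
      note(paste0("lambda_", tis), min(lam, G), "Lame parameters must be positive")
    if (E > 0 && !is.null(nu) && !is.na(nu) && nu > 0 && nu < 0.5) {
      ref <- lame_from_young(E, nu)
      if (abs(round(ref$lambda) - round(lam)) > 1 || abs(round(ref$G) - round(G)) > 1)
        note(paste0("lambda_", tis), lam,
             sprintf("Lame pair (%.4g, %.4g) inconsistent with E=%.4g, nu=%.4g beyond 1 Pa",
                     lam, G, E, nu))
    }
  }
  for (f in c("dt", "d", "L", "r_v")) {
    v <- need(f)
    if (!is.null(v) && !is.na(v) && v <= 0)
      note(f, v, sprintf("'%s' must be strictly positive", f))
  }
  if (length(bad) == 0)
    tibble::tibble(field = character(), value = numeric(), message = character())
  else dplyr::bind_rows(bad)
}

#' Isotropic Lame parameters from Young's modulus and Poisson ratio
#'
#' `lambda = E nu / ((1+nu)(1-2nu))`, `G = E / (2(1+nu))`. The grey-matter
#' modulus 584 Pa with `nu = 0.35` yields (504.7, 216.3) -> rounding (505, 216);
#' white matter 1168 Pa yields `G ~ 432.6` -> 433.
#'
#' @param E Young's modulus, Pa; must be positive.
#' @param nu Poisson ratio in (0, 0.5).
#' @return list with components `lambda` and `G` (Pa).
#' @seealso [young_from_lame()] for the inverse map.
#' @export
lame_from_young <- function(E, nu) {
  if (any(E <= 0)) stop("Young's modulus must be positive")
  if (any(nu >= 0.5)) stop("nu >= 0.5: incompressible limit, Lame lambda undefined")
  if (any(nu < 0)) stop("nu must be non-negative")
  list(lambda = E * nu / ((1 + nu) * (1 - 2 * nu)), G = E / (2 * (1 + nu)))
}

#' Young's modulus and Poisson ratio from Lame parameters
#'
#' Inverse of [lame_from_young()]: `E = G(3 lambda + 2 G)/(lambda + G)`,
#' `nu = lambda / (2 (lambda + G))`.
#'
#' @param lambda,G Lame parameters, Pa; `G` must be positive.
#' @return list with components `E` and `nu`.
#' @export
young_from_lame <- function(lambda, G) {
  if (any(G <= 0)) stop("shear modulus must be positive")
  list(E = G * (3 * lambda + 2 * G) / (lambda + G),
       nu = lambda / (2 * (lambda + G)))
}

#' Perturbed white-matter stiffness field
#'
#' Returns a per-element Young's-modulus field: grey elements keep `E_grey`
#' exactly; each white element receives `E_white + delta` with `delta` drawn
#' from the seeded generator, uniformly on `[-amplitude, +amplitude]`
#' (`mode = "iid"`, the default) or as a spatially smoothed variant of that
#' draw rescaled back to the same amplitude bound (`mode = "correlated"`).
#' The draw is deterministic for a fixed seed and leaves the global RNG
#' state untouched.
#'
#' @param mesh a [brain_mesh][make_shell()] carrying per-element `tissue`
#'   labels (`"GREY"`/`"WHITE"`).
#' @param params an [mpet_params()] object supplying `E_grey`, `E_white`.
#' @param amplitude perturbation half-width, Pa (default from `params`).
#' @param seed integer seed for the element-wise draw.
#' @param mode `"iid"` or `"correlated"`.
#' @return numeric vector, one Young's modulus per element, Pa.
#' @export
perturb_white_stiffness <- function(mesh, params, amplitude = params$stiffness_perturbation_amplitude,
                                    seed = 1L, mode = c("iid", "correlated")) {
  mode <- match.arg(mode)
  stopifnot(inherits(mesh, "brain_mesh"))
  if (is.null(mesh$tissue)) stop("mesh carries no grey/white tissue labels")
  if (amplitude < 0) stop("perturbation amplitude must be non-negative")
  E <- ifelse(mesh$tissue == "WHITE", params$E_white, params$E_grey)
  white <- which(mesh$tissue == "WHITE")
  if (length(white) > 0 && amplitude > 0) {
    delta <- with_local_seed(seed, stats::runif(length(white), -amplitude, amplitude))
    if (mode == "correlated") {
      # one smoothing pass over elements sharing a node, then rescale so the
      # field still honours the [-amplitude, amplitude] bound
      adj <- element_adjacency(mesh, white)
      sm <- vapply(seq_along(white), function(i) mean(delta[adj[[i]]]), numeric(1))
      if (max(abs(sm)) > 0) sm <- sm * (max(abs(delta)) / max(abs(sm)))
      delta <- sm
    }
    E[white] <- E[white] + delta
  }
  if (any(E <= 0)) stop("perturbation drove a Young's modulus non-positive")
  E
}

# indices (within `subset`) of elements sharing >=1 node, including self
element_adjacency <- function(mesh, subset) {
  el <- mesh$elems[subset, , drop = FALSE]
  node2el <- split(rep(seq_len(nrow(el)), ncol(el)), as.vector(el))
  lapply(seq_len(nrow(el)), function(i) {
    unique(unlist(node2el[as.character(el[i, ])], use.names = FALSE))
  })
}

# run expr under a private RNG stream; restore the caller's stream after
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
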