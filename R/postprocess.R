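#' Derivative biomarker fields
#'
#' From a converged solution state the package derives the biomarker fields
#' reported for perfused brain tissue: perfusion (magnitude of the capillary
#' Darcy velocity, with the grey/white-partitioned capillary permeability),
#' CSF/ECF clearance and paravenous filtration velocity (Darcy-velocity
#' magnitudes of the `e` and `v` networks; the `e` field uses the anisotropic
#' permeability tensor when supplied), and compartmental swelling/drainage
#' (signed fluid content). All fields are element-wise (P1 gradients are
#' piecewise constant).
#'
#' @name biomarkers
NULL

compartment_network <- function(compartment) {
  map <- c(arterial = "a", capillary = "c", "CSF/ECF" = "e", csf_ecf = "e",
           venous = "v", paravenous = "v", glymphatic = "l",
           perivascular = "l", glial = "g",
           a = "a", c = "c", e = "e", v = "v", l = "l", g = "g")
  nm <- map[compartment]
  if (is.na(nm)) stop("unknown compartment name: ", compartment)
  unname(nm)
}

#' Element-wise Darcy velocity of one network
#'
#' @param problem an [mpet_problem()].
#' @param state a [field_state()].
#' @param network network letter or compartment name.
#' @return `elements x dim` matrix of Darcy velocities, m s^-1.
#' @export
network_darcy <- function(problem, state, network) {
  nm <- compartment_network(network)
  gp <- element_gradient(problem$mesh, problem$geo, state$p[, nm])
  mob <- problem$mobility[[nm]]
  if (is.array(mob) && length(dim(mob)) == 3) {
    d <- problem$d
    out <- matrix(0, nrow(gp), d)
    for (i in seq_len(d)) for (j in seq_len(d))
      out[, i] <- out[, i] - mob[, i, j] * gp[, j]
    out
  } else {
    -mob * gp
  }
}

#' @rdname biomarkers
#' @param problem an [mpet_problem()].
#' @param state a [field_state()].
#' @return numeric vector over elements, m s^-1 (velocity fields) or
#'   dimensionless (fluid content).
#' @export
perfusion_field <- function(problem, state) {
  sqrt(rowSums(network_darcy(problem, state, "c")^2))
}

#' @rdname biomarkers
#' @export
clearance_field <- function(problem, state) {
  sqrt(rowSums(network_darcy(problem, state, "e")^2))
}

#' @rdname biomarkers
#' @export
paravenous_field <- function(problem, state) {
  sqrt(rowSums(network_darcy(problem, state, "v")^2))
}

#' @rdname biomarkers
#' @param compartment compartment name (`capillary`, `CSF/ECF`, `glymphatic`,
#'   `glial`, `paravenous`, ... or a network letter).
#' @param p_ref reference pressure for the fluid content: a scalar, a nodal
#'   vector, or a reference [field_state()] (typically the cycle average at
#'   periodic steady state).
#' @export
swelling_drainage <- function(problem, state, compartment, p_ref = 0) {
  nm <- compartment_network(compartment)
  q <- match(nm, MPET_NETWORKS)
  mesh <- problem$mesh
  div_u <- element_divergence(mesh, problem$geo, state$u)
  p_el <- rowMeans(matrix(state$p[mesh$elems, nm], nrow(mesh$elems)))
  pref_el <- if (inherits(p_ref, "field_state")) {
    rowMeans(matrix(p_ref$p[mesh$elems, nm], nrow(mesh$elems)))
  } else if (length(p_ref) == nrow(mesh$nodes)) {
    rowMeans(matrix(p_ref[mesh$elems], nrow(mesh$elems)))
  } else p_ref
  div_ref <- if (inherits(p_ref, "field_state"))
    element_divergence(mesh, problem$geo, p_ref$u) else 0
  fluid_content(problem$params$alpha[[nm]], problem$params$c_storage[[nm]],
                div_u - div_ref, p_el, pref_el)
}

#' Cycle-averaged state of a run
#'
#' Averages displacement and pressures over the final recorded cycle; the
#' natural reference state for swelling/drainage at periodic steady state.
#'
#' @param run an `mpet_run` from [run_cycles()].
#' @return a [field_state()] (time stamped at the cycle midpoint).
#' @export
cycle_average_state <- function(run) {
  sts <- run$last_cycle_states
  if (is.null(sts)) stop("run holds no recorded cycle")
  u <- Reduce(`+`, lapply(sts, `[[`, "u")) / length(sts)
  p <- Reduce(`+`, lapply(sts, `[[`, "p")) / length(sts)
  st <- field_state(run$problem$mesh, t = mean(vapply(sts, `[[`, numeric(1), "t")))
  st$u <- u; st$p <- p
  st
}

#' Per-region min/max summary of element fields
#'
#' @param mesh a `brain_mesh` with region labels.
#' @param fields named list of per-element numeric vectors.
#' @return tibble with columns `region`, `field`, `min`, `max`.
#' @export
regional_summary <- function(mesh, fields) {
  stopifnot(length(fields) > 0, !is.null(names(fields)))
  rows <- list()
  for (fn in names(fields)) {
    v <- fields[[fn]]
    if (length(v) != nrow(mesh$elems)) stop("field ", fn, " is not element-wise")
    for (r in seq_along(mesh$region_names)) {
      sel <- mesh$region == r
      if (!any(sel)) stop("region ", mesh$region_names[r], " contains no elements")
      rows[[length(rows) + 1]] <- tibble::tibble(
        region = mesh$region_names[r], field = fn,
        min = min(v[sel]), max = max(v[sel]))
    }
  }
  dplyr::bind_rows(rows)
}

#' Regional biomarker table for a run
#'
#' Builds the per-region derivative-quantity table: perfusion range and
#' swelling/drainage (fluid content) ranges for the capillary, CSF/ECF,
#' glymphatic, glial and paravenous compartments, relative to the
#' cycle-averaged reference state. Both the raw fluid content and a variant
#' normalised by its parenchymal maximum absolute value are reported.
#'
#' @param run an `mpet_run` from [run_cycles()].
#' @param state state to summarise (default: final state of the run).
#' @param p_ref reference state (default: cycle average).
#' @return tibble: `region`, `field`, `min`, `max` with fields `perfusion`,
#'   `swelling_<compartment>` and `swelling_norm_<compartment>`.
#' @export
region_table <- function(run, state = run$final_state,
                         p_ref = cycle_average_state(run)) {
  pb <- run$problem
  fields <- list(perfusion = perfusion_field(pb, state))
  for (cp in c("capillary", "CSF/ECF", "glymphatic", "glial", "paravenous")) {
    z <- swelling_drainage(pb, state, cp, p_ref)
    key <- gsub("[^a-zA-Z]", "_", cp)
    fields[[paste0("swelling_", key)]] <- z
    zmax <- max(abs(z))
    fields[[paste0("swelling_norm_", key)]] <- if (zmax > 0) z / zmax else z
  }
  regional_summary(pb$mesh, fields)
}

#' Write a regional summary as CSV
#' @param summary tibble from [regional_summary()] or [region_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_region_csv <- function(summary, path) {
  utils::write.csv(summary, path, row.names = FALSE)
  invisible(path)
}

#' Periventricular fluid-content (PVL) index
#'
#' Mean positive fluid content over the elements whose centroid lies within
#' `band_width` of the ventricular surface — a scalar measure of
#' periventricular lucency-like swelling for one compartment.
#'
#' @param mesh a `brain_mesh`.
#' @param zeta per-element signed fluid content (from [swelling_drainage()]).
#' @param band_width band thickness, m; default 10% of the domain's radial
#'   extent.
#' @return scalar PVL index (dimensionless).
#' @export
pvl_index <- function(mesh, zeta, band_width = NULL) {
  rad <- sqrt(rowSums(mesh$nodes^2))
  band_width <- band_width %||% (0.1 * (max(rad) - min(rad)))
  if (band_width <= 0) stop("band_width must be positive")
  cent <- element_centroids(mesh)
  vf <- mesh$facets[mesh$facet_tag == "VENTRICLE", , drop = FALSE]
  fcent <- matrix(0, nrow(vf), mesh$dim)
  for (i in seq_len(ncol(vf)))
    fcent <- fcent + mesh$nodes[vf[, i], , drop = FALSE] / ncol(vf)
  dmin <- apply(cent, 1, function(x)
    sqrt(min(rowSums(sweep(fcent, 2, x)^2))))
  sel <- dmin <= band_width
  if (!any(sel)) stop("no element centroid lies within the periventricular band")
  zb <- zeta[sel]
  mean(pmax(zb, 0))
}
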