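#' Idealised brain-like computational domains
#'
#' The solver operates on closed two-surface domains: an outer boundary tagged
#' `SKULL` (cortical surface) and an inner boundary tagged `VENTRICLE`
#' (cerebroventricular wall). Three generators are provided: a 1D column
#' (verification geometry), a 2D annulus and a 3D spherical shell (idealised
#' ventricle-in-skull domains). All generators return a `brain_mesh`: simplex
#' nodes/connectivity, tagged boundary facets, per-element `GREY`/`WHITE`
#' tissue labels and integer region labels (angular sectors standing in for an
#' anatomical atlas), all in metres.
#'
#' @name brain_mesh
NULL

new_brain_mesh <- function(dim, nodes, elems, facets, facet_tag,
                           tissue, region, region_names, structured = NULL) {
  m <- structure(list(
    dim = dim, nodes = nodes, elems = elems,
    facets = facets, facet_tag = facet_tag,
    tissue = tissue, region = as.integer(region),
    region_names = region_names,
    Ke = NULL, structured = structured
  ), class = "brain_mesh")
  m
}

#' @method print brain_mesh
#' @export
print.brain_mesh <- function(x, ...) {
  cat(sprintf("<brain_mesh> %dD: %d nodes, %d elements, %d boundary facets\n",
              x$dim, nrow(x$nodes), nrow(x$elems), nrow(x$facets)))
  cat(sprintf("  tags: %s\n", paste(sprintf("%s(%d)", names(table(x$facet_tag)),
                                            table(x$facet_tag)), collapse = " ")))
  cat(sprintf("  tissue: GREY %d / WHITE %d; regions: %d\n",
              sum(x$tissue == "GREY"), sum(x$tissue == "WHITE"),
              length(x$region_names)))
  if (!is.null(x$Ke)) cat("  per-element CSF/ECF permeability tensor attached\n")
  invisible(x)
}

#' One-dimensional column mesh
#'
#' Uniform interval mesh with the `VENTRICLE` tag at `x = 0` and the `SKULL`
#' tag at `x = length`; used by the consolidation verification harness.
#'
#' @param length column length, m.
#' @param n_elements number of elements (>= 1).
#' @param grey_fraction fraction of the column, on the skull side, labelled
#'   `GREY`.
#' @return A `brain_mesh` (dim 1).
#' @export
make_column <- function(length = 0.05, n_elements = 64, grey_fraction = 0.5) {
  stopifnot(length > 0, n_elements >= 1)
  x <- seq(0, length, length.out = n_elements + 1)
  nodes <- matrix(x, ncol = 1)
  elems <- cbind(seq_len(n_elements), seq_len(n_elements) + 1L)
  facets <- matrix(c(1L, n_elements + 1L), ncol = 1)
  cent <- (x[-1] + x[-(n_elements + 1)]) / 2
  tissue <- ifelse(cent > length * (1 - grey_fraction), "GREY", "WHITE")
  new_brain_mesh(1L, nodes, elems, facets, c("VENTRICLE", "SKULL"),
                 tissue, rep(1L, n_elements), "column")
}

#' Annulus (2D) or spherical-shell (3D) mesh
#'
#' The inner boundary (radius `r_inner`) is tagged `VENTRICLE`, the outer
#' (`r_outer`) `SKULL`. A radius threshold partitions the band into an inner
#' `WHITE` and outer `GREY` shell (`grey_fraction` of the thickness is grey).
#' Angular sectors provide integer region labels emulating a multi-region
#' stratification.
#'
#' In 2D the annulus is a structured polar grid triangulated with alternating
#' diagonals, which makes the mesh exactly mirror-symmetric about the x-axis
#' (used by the solver's symmetry checks). In 3D the shell is built from a
#' subdivided-icosahedron surface extruded radially, with each prism split
#' into three tetrahedra by a shared-edge rule that keeps the mesh conforming.
#'
#' @param r_inner,r_outer inner/outer radii, m; `0 < r_inner < r_outer`.
#' @param resolution number of radial element layers (angular/surface
#'   resolution scales with it).
#' @param dim 2 or 3.
#' @param grey_fraction outer-band thickness fraction labelled `GREY`.
#' @param n_region_sectors number of angular sector regions.
#' @return A `brain_mesh`.
#' @export
make_shell <- function(r_inner = 0.02, r_outer = 0.07, resolution = 8, dim = 2,
                       grey_fraction = 0.5, n_region_sectors = 5) {
  stopifnot(r_inner > 0, r_outer > r_inner, resolution >= 1)
  if (dim == 2) {
    make_annulus(r_inner, r_outer, resolution, grey_fraction, n_region_sectors)
  } else if (dim == 3) {
    make_shell3d(r_inner, r_outer, resolution, grey_fraction, n_region_sectors)
  } else stop("dim must be 2 or 3")
}

make_annulus <- function(r_inner, r_outer, nr, grey_fraction, n_sectors) {
  ntheta <- 2L * max(3L, as.integer(round(3 * nr)))  # even: mirror symmetry
  radii <- seq(r_inner, r_outer, length.out = nr + 1)
  theta <- 2 * pi * seq(0, ntheta - 1) / ntheta
  idx <- function(i, j) as.integer(i * ntheta + (j %% ntheta) + 1L)  # i in 0..nr, j in 0..ntheta-1
  nodes <- cbind(rep(radii, each = ntheta) * cos(rep(theta, nr + 1)),
                 rep(radii, each = ntheta) * sin(rep(theta, nr + 1)))
  elems <- matrix(0L, nrow = 2L * nr * ntheta, ncol = 3)
  row <- 0L
  for (i in 0:(nr - 1)) for (j in 0:(ntheta - 1)) {
    n00 <- idx(i, j); n10 <- idx(i + 1, j)
    n11 <- idx(i + 1, j + 1); n01 <- idx(i, j + 1)
    if ((i + j) %% 2 == 0) {
      elems[row + 1L, ] <- c(n00, n10, n11)
      elems[row + 2L, ] <- c(n00, n11, n01)
    } else {
      elems[row + 1L, ] <- c(n01, n00, n10)
      elems[row + 2L, ] <- c(n01, n10, n11)
    }
    row <- row + 2L
  }
  facets <- rbind(
    cbind(vapply(0:(ntheta - 1), function(j) idx(0, j), integer(1)),
          vapply(0:(ntheta - 1), function(j) idx(0, j + 1), integer(1))),
    cbind(vapply(0:(ntheta - 1), function(j) idx(nr, j), integer(1)),
          vapply(0:(ntheta - 1), function(j) idx(nr, j + 1), integer(1)))
  )
  facet_tag <- c(rep("VENTRICLE", ntheta), rep("SKULL", ntheta))
  m <- new_brain_mesh(2L, nodes, elems, facets, facet_tag,
                      tissue = "WHITE", region = 1L, region_names = "tmp",
                      structured = list(kind = "annulus", nr = nr, ntheta = ntheta))
  label_shell(m, r_inner, r_outer, grey_fraction, n_sectors)
}

label_shell <- function(mesh, r_inner, r_outer, grey_fraction, n_sectors) {
  cent <- element_centroids(mesh)
  r <- sqrt(rowSums(cent^2))
  r_split <- r_inner + (1 - grey_fraction) * (r_outer - r_inner)
  mesh$tissue <- ifelse(r > r_split, "GREY", "WHITE")
  ang <- atan2(cent[, 2], cent[, 1]) %% (2 * pi)
  mesh$region <- pmin(as.integer(floor(ang / (2 * pi) * n_sectors)) + 1L, n_sectors)
  stock <- c("CGM-like", "hippocampus-like", "thalamus-like",
             "amygdala-like", "brainstem-like")
  mesh$region_names <- if (n_sectors <= length(stock)) stock[seq_len(n_sectors)]
    else paste0("sector_", seq_len(n_sectors))
  mesh
}

# -- 3D shell: subdivided icosahedron surface, radial extrusion ----------------

icosphere <- function(n_subdiv) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
    c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(n_subdiv)) {
    mid_cache <- new.env(hash = TRUE)
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      hit <- mid_cache[[key]]
      if (!is.null(hit)) return(hit)
      p <- v[i, ] + v[j, ]
      p <- p / sqrt(sum(p^2))
      v <<- rbind(v, p)
      mid_cache[[key]] <- nrow(v)
      nrow(v)
    }
    nf <- matrix(0L, nrow = 4 * nrow(f), ncol = 3)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; cc <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf[4 * k - 3, ] <- c(a, ab, ca)
      nf[4 * k - 2, ] <- c(b, bc, ab)
      nf[4 * k - 1, ] <- c(cc, ca, bc)
      nf[4 * k, ] <- c(ab, bc, ca)
    }
    f <- nf
  }
  list(verts = v, faces = f)
}

make_shell3d <- function(r_inner, r_outer, nr, grey_fraction, n_sectors) {
  n_subdiv <- max(1L, as.integer(ceiling(log2(max(nr, 2)))))
  surf <- icosphere(n_subdiv)
  nv <- nrow(surf$verts)
  radii <- seq(r_inner, r_outer, length.out = nr + 1)
  nodes <- do.call(rbind, lapply(radii, function(r) surf$verts * r))
  lay <- function(layer, s) (layer * nv) + s  # layer in 0..nr, s surface index
  elems_list <- vector("list", nr * nrow(surf$faces))
  ei <- 0L
  for (i in 0:(nr - 1)) {
    for (k in seq_len(nrow(surf$faces))) {
      vs <- sort(surf$faces[k, ])  # ascending: shared-edge diagonal rule
      a <- lay(i, vs); b <- lay(i + 1, vs)
      ei <- ei + 1L
      elems_list[[ei]] <- rbind(
        c(a[1], a[2], a[3], b[3]),
        c(a[1], a[2], b[3], b[2]),
        c(a[1], b[2], b[3], b[1]))
    }
  }
  elems <- do.call(rbind, elems_list)
  # orient for positive volume
  vol <- tet_signed_volumes(nodes, elems)
  flip <- vol < 0
  if (any(flip)) elems[flip, c(3, 4)] <- elems[flip, c(4, 3)]
  facets <- rbind(matrix(lay(0L, t(surf$faces)), ncol = 3, byrow = TRUE),
                  matrix(lay(nr, t(surf$faces)), ncol = 3, byrow = TRUE))
  facet_tag <- c(rep("VENTRICLE", nrow(surf$faces)), rep("SKULL", nrow(surf$faces)))
  m <- new_brain_mesh(3L, nodes, elems, facets, facet_tag,
                      tissue = "WHITE", region = 1L, region_names = "tmp",
                      structured = list(kind = "shell3d", nr = nr, n_surface = nv))
  label_shell(m, r_inner, r_outer, grey_fraction, n_sectors)
}

tet_signed_volumes <- function(nodes, elems) {
  a <- nodes[elems[, 1], , drop = FALSE]
  b <- nodes[elems[, 2], , drop = FALSE] - a
  cc <- nodes[elems[, 3], , drop = FALSE] - a
  d <- nodes[elems[, 4], , drop = FALSE] - a
  (b[, 1] * (cc[, 2] * d[, 3] - cc[, 3] * d[, 2]) -
   b[, 2] * (cc[, 1] * d[, 3] - cc[, 3] * d[, 1]) +
   b[, 3] * (cc[, 1] * d[, 2] - cc[, 2] * d[, 1])) / 6
}

#' Element centroids
#' @param mesh a `brain_mesh`.
#' @return matrix (elements x dim) of centroid coordinates, m.
#' @export
element_centroids <- function(mesh) {
  d1 <- ncol(mesh$elems)
  out <- matrix(0, nrow(mesh$elems), mesh$dim)
  for (k in seq_len(d1)) out <- out + mesh$nodes[mesh$elems[, k], , drop = FALSE]
  out / d1
}

#' Element measures (length/area/volume)
#'
#' Signed measures are positive for correctly oriented simplices; generators
#' in this package always produce positive measures (positive-Jacobian check).
#'
#' @param mesh a `brain_mesh`.
#' @return numeric vector of element measures (m, m^2 or m^3).
#' @export
element_measures <- function(mesh) {
  n <- mesh$nodes; e <- mesh$elems
  if (mesh$dim == 1) {
    n[e[, 2], 1] - n[e[, 1], 1]
  } else if (mesh$dim == 2) {
    x1 <- n[e[, 1], ]; x2 <- n[e[, 2], ]; x3 <- n[e[, 3], ]
    ((x2[, 1] - x1[, 1]) * (x3[, 2] - x1[, 2]) -
     (x3[, 1] - x1[, 1]) * (x2[, 2] - x1[, 2])) / 2
  } else {
    tet_signed_volumes(n, e)
  }
}

#' Boundary facet measures and outward normals
#'
#' @param mesh a `brain_mesh`.
#' @return list with `measure` (facet length/area; 1 in 1D), `normal`
#'   (facets x dim outward unit normals) and `elem` (owning element per facet).
#' @export
facet_geometry <- function(mesh) {
  f <- mesh$facets; n <- mesh$nodes
  owner <- facet_owners(mesh)
  ecent <- element_centroids(mesh)[owner, , drop = FALSE]
  if (mesh$dim == 1) {
    meas <- rep(1, nrow(f))
    normal <- matrix(sign(n[f[, 1], 1] - ecent[, 1]), ncol = 1)
  } else if (mesh$dim == 2) {
    p1 <- n[f[, 1], , drop = FALSE]; p2 <- n[f[, 2], , drop = FALSE]
    dxy <- p2 - p1
    meas <- sqrt(rowSums(dxy^2))
    normal <- cbind(dxy[, 2], -dxy[, 1]) / meas
    fc <- (p1 + p2) / 2
    s <- sign(rowSums(normal * (fc - ecent)))
    normal <- normal * s
  } else {
    p1 <- n[f[, 1], , drop = FALSE]; p2 <- n[f[, 2], , drop = FALSE]
    p3 <- n[f[, 3], , drop = FALSE]
    u <- p2 - p1; v <- p3 - p1
    cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                u[, 3] * v[, 1] - u[, 1] * v[, 3],
                u[, 1] * v[, 2] - u[, 2] * v[, 1])
    meas <- sqrt(rowSums(cr^2)) / 2
    normal <- cr / (2 * meas)
    fc <- (p1 + p2 + p3) / 3
    s <- sign(rowSums(normal * (fc - ecent)))
    normal <- normal * s
  }
  list(measure = meas, normal = normal, elem = owner)
}

facet_owners <- function(mesh) {
  key <- function(m) apply(m, 1, function(r) paste(sort(r), collapse = "-"))
  nf <- ncol(mesh$facets)
  combs <- utils::combn(seq_len(ncol(mesh$elems)), nf)
  ekeys <- character(0); eids <- integer(0)
  for (j in seq_len(ncol(combs))) {
    sub <- mesh$elems[, combs[, j], drop = FALSE]
    ekeys <- c(ekeys, key(sub))
    eids <- c(eids, seq_len(nrow(mesh$elems)))
  }
  match(key(mesh$facets), ekeys) -> pos
  if (anyNA(pos)) stop("boundary facet not contained in any element")
  eids[pos]
}

#' Total measure of a tagged boundary surface
#' @param mesh a `brain_mesh`.
#' @param tag `"SKULL"` or `"VENTRICLE"`.
#' @return surface measure (2 pi r-like in 2D, 4 pi r^2-like in 3D; node
#'   count in 1D where facets are points of unit measure).
#' @export
boundary_measure <- function(mesh, tag) {
  fg <- facet_geometry(mesh)
  sum(fg$measure[mesh$facet_tag == tag])
}

#' Synthetic anisotropic CSF/ECF permeability tensor field
#'
#' Builds a per-element symmetric positive-definite permeability tensor with
#' principal axis radial (emulating preferential fluid pathways along
#' white-matter tracts): eigenvalue `k_parallel` along the radial direction
#' and `k_perp` in the tangential plane. With `k_parallel == k_perp` the field
#' reduces to `k * I` (the isotropic reference value).
#'
#' @param mesh a `brain_mesh` (dim 2 or 3; in 1D the tensor is scalar).
#' @param k_parallel,k_perp principal permeabilities, m^2; both positive.
#' @return array `(elements x dim x dim)` of SPD tensors; attach to the mesh
#'   as `mesh$Ke` and set `Ke_tensor_mode = "field"` in the parameters to use
#'   it for the CSF/ECF network.
#' @export
synth_anisotropic_Ke <- function(mesh, k_parallel, k_perp) {
  stopifnot(k_parallel > 0, k_perp > 0)
  d <- mesh$dim
  cent <- element_centroids(mesh)
  M <- nrow(cent)
  out <- array(0, c(M, d, d))
  if (d == 1) { out[, 1, 1] <- k_parallel; return(out) }
  r <- sqrt(rowSums(cent^2))
  r[r == 0] <- 1
  e1 <- cent / r
  for (i in seq_len(d)) for (j in seq_len(d)) {
    out[, i, j] <- k_perp * (i == j) + (k_parallel - k_perp) * e1[, i] * e1[, j]
  }
  out
}

#' Structural checks on a mesh
#'
#' Verifies the `brain_mesh` invariants: strictly positive element measures,
#' conforming connectivity (each interior facet shared by exactly two
#' elements), boundary facets each carrying exactly one of the two tags and
#' jointly covering the whole boundary, and (if present) symmetry and
#' positive-definiteness of the per-element permeability tensors.
#'
#' @param mesh a `brain_mesh`.
#' @return tibble of violations (`check`, `message`); zero rows iff sound.
#' @export
check_mesh <- function(mesh) {
  bad <- list()
  note <- function(check, message)
    bad[[length(bad) + 1]] <<- tibble::tibble(check = check, message = message)

  meas <- element_measures(mesh)
  if (any(meas <= 0))
    note("element_measures", sprintf("%d non-positive element measures", sum(meas <= 0)))

  # facet incidence: boundary facets appear in exactly 1 element, interior in 2
  nf <- mesh$dim  # nodes per facet
  combs <- utils::combn(seq_len(ncol(mesh$elems)), nf)
  all_facets <- do.call(rbind, lapply(seq_len(ncol(combs)), function(j)
    mesh$elems[, combs[, j], drop = FALSE]))
  fkey <- apply(all_facets, 1, function(r) paste(sort(r), collapse = "-"))
  counts <- table(fkey)
  if (any(counts > 2))
    note("conforming", "a facet is shared by more than two elements")
  bkey <- apply(mesh$facets, 1, function(r) paste(sort(r), collapse = "-"))
  boundary_keys <- names(counts)[counts == 1]
  if (!setequal(boundary_keys, unique(bkey)))
    note("boundary_cover", "tagged facets do not exactly cover the mesh boundary")
  if (anyDuplicated(bkey))
    note("boundary_tags", "a boundary facet is tagged more than once")
  if (!all(mesh$facet_tag %in% c("SKULL", "VENTRICLE")))
    note("boundary_tags", "facet tags outside {SKULL, VENTRICLE}")
  for (tag in c("SKULL", "VENTRICLE")) {
    if (!any(mesh$facet_tag == tag))
      note("boundary_tags", sprintf("boundary tag %s not found", tag))
  }
  if (!is.null(mesh$Ke)) {
    for (m in seq_len(dim(mesh$Ke)[1])) {
      Kf <- mesh$Ke[m, , ]
      if (max(abs(Kf - t(Kf))) > 1e-12 * max(abs(Kf)))
        { note("Ke_symmetric", sprintf("element %d tensor not symmetric", m)); break }
      if (any(eigen(Kf, symmetric = TRUE, only.values = TRUE)$values <= 0))
        { note("Ke_spd", sprintf("element %d tensor not positive definite", m)); break }
    }
  }
  if (length(bad) == 0) tibble::tibble(check = character(), message = character())
  else dplyr::bind_rows(bad)
}

#' Mirror permutation of an annulus mesh
#'
#' For the structured 2D annulus, returns the node permutation realising the
#' reflection about the x-axis (`theta -> -theta`); used to check that
#' symmetric boundary conditions produce mirror-symmetric solution fields.
#'
#' @param mesh an annulus from [make_shell()] with `dim = 2`.
#' @return integer vector `p` with `nodes[p, ] ~ (x, -y)` of `nodes`.
#' @export
annulus_mirror_permutation <- function(mesh) {
  st <- mesh$structured
  if (is.null(st) || st$kind != "annulus")
    stop("mirror permutation is defined for structured annulus meshes only")
  nr <- st$nr; ntheta <- st$ntheta
  idx <- function(i, j) i * ntheta + (j %% ntheta) + 1L
  p <- integer((nr + 1) * ntheta)
  for (i in 0:nr) for (j in 0:(ntheta - 1)) {
    p[idx(i, j)] <- idx(i, (ntheta - j) %% ntheta)
  }
  p
}
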