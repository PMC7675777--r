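# Vectorised P1 (piecewise-linear) finite elements on simplices, dim 1/2/3.
# All element loops are unrolled over local node pairs and vectorised over
# elements; global matrices are Matrix::sparseMatrix triplets (duplicates sum).

# barycentric shape-function gradients and element measures
p1_geometry <- function(mesh) {
  n <- mesh$nodes; e <- mesh$elems; d <- mesh$dim
  M <- nrow(e)
  grads <- array(0, c(M, d + 1, d))
  if (d == 1) {
    h <- n[e[, 2], 1] - n[e[, 1], 1]
    vol <- h
    grads[, 1, 1] <- -1 / h
    grads[, 2, 1] <- 1 / h
  } else if (d == 2) {
    x1 <- n[e[, 1], 1]; y1 <- n[e[, 1], 2]
    x2 <- n[e[, 2], 1]; y2 <- n[e[, 2], 2]
    x3 <- n[e[, 3], 1]; y3 <- n[e[, 3], 2]
    det <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
    vol <- det / 2
    grads[, 1, 1] <- (y2 - y3) / det; grads[, 1, 2] <- (x3 - x2) / det
    grads[, 2, 1] <- (y3 - y1) / det; grads[, 2, 2] <- (x1 - x3) / det
    grads[, 3, 1] <- (y1 - y2) / det; grads[, 3, 2] <- (x2 - x1) / det
  } else {
    a <- n[e[, 1], , drop = FALSE]
    r1 <- n[e[, 2], , drop = FALSE] - a
    r2 <- n[e[, 3], , drop = FALSE] - a
    r3 <- n[e[, 4], , drop = FALSE] - a
    # det and rows of D^{-1} (D rows r1,r2,r3): grad lambda_{k+1} = k-th row of D^{-T}
    cr23 <- cbind(r2[, 2] * r3[, 3] - r2[, 3] * r3[, 2],
                  r2[, 3] * r3[, 1] - r2[, 1] * r3[, 3],
                  r2[, 1] * r3[, 2] - r2[, 2] * r3[, 1])
    cr31 <- cbind(r3[, 2] * r1[, 3] - r3[, 3] * r1[, 2],
                  r3[, 3] * r1[, 1] - r3[, 1] * r1[, 3],
                  r3[, 1] * r1[, 2] - r3[, 2] * r1[, 1])
    cr12 <- cbind(r1[, 2] * r2[, 3] - r1[, 3] * r2[, 2],
                  r1[, 3] * r2[, 1] - r1[, 1] * r2[, 3],
                  r1[, 1] * r2[, 2] - r1[, 2] * r2[, 1])
    det <- rowSums(r1 * cr23)
    vol <- det / 6
    for (k in 1:3) {
      grads[, 2, k] <- cr23[, k] / det
      grads[, 3, k] <- cr31[, k] / det
      grads[, 4, k] <- cr12[, k] / det
    }
    grads[, 1, ] <- -(grads[, 2, ] + grads[, 3, ] + grads[, 4, ])
  }
  if (any(vol <= 0)) stop("non-positive element measure: mesh is not positively oriented")
  list(grads = grads, vol = vol)
}

# sparse N x N from triplets accumulated over local pairs
p1_accumulate <- function(mesh, val_fun, N = nrow(mesh$nodes)) {
  e <- mesh$elems; nl <- ncol(e)
  ii <- jj <- integer(0); xx <- numeric(0)
  for (i in seq_len(nl)) for (j in seq_len(nl)) {
    ii <- c(ii, e[, i]); jj <- c(jj, e[, j])
    xx <- c(xx, val_fun(i, j))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(N, N))
}

# stiffness with per-element mobility tensor Kel (M x d x d) or vector (isotropic)
p1_stiffness <- function(mesh, geo, Kel) {
  d <- mesh$dim
  if (!is.array(Kel) || length(dim(Kel)) != 3) {
    kv <- Kel
    Kel <- array(0, c(nrow(mesh$elems), d, d))
    for (k in seq_len(d)) Kel[, k, k] <- kv
  }
  p1_accumulate(mesh, function(i, j) {
    acc <- 0
    for (a in seq_len(d)) for (b in seq_len(d))
      acc <- acc + geo$grads[, i, a] * Kel[, a, b] * geo$grads[, j, b]
    geo$vol * acc
  })
}

# consistent mass with per-element coefficient
p1_mass <- function(mesh, geo, coef = 1) {
  d <- mesh$dim
  p1_accumulate(mesh, function(i, j) {
    coef * geo$vol * (1 + (i == j)) / ((d + 1) * (d + 2))
  })
}

# lumped mass diagonal (row sums of the P1 mass matrix)
p1_lumped_mass <- function(mesh, geo, coef = 1) {
  d <- mesh$dim
  N <- nrow(mesh$nodes)
  diag <- numeric(N)
  w <- coef * geo$vol / (d + 1)
  for (i in seq_len(d + 1)) {
    tv <- tapply(w, mesh$elems[, i], sum)
    diag[as.integer(names(tv))] <- diag[as.integer(names(tv))] + tv
  }
  diag
}

# divergence coupling: B[(k-1)N + i, j] = int phi_j d(phi_i)/dx_k
# (u dofs component-major: all x-components, then y, then z)
p1_divergence <- function(mesh, geo) {
  N <- nrow(mesh$nodes); d <- mesh$dim
  e <- mesh$elems; nl <- d + 1
  ii <- jj <- integer(0); xx <- numeric(0)
  for (k in seq_len(d)) for (i in seq_len(nl)) for (j in seq_len(nl)) {
    ii <- c(ii, (k - 1L) * N + e[, i])
    jj <- c(jj, e[, j])
    xx <- c(xx, geo$vol * geo$grads[, i, k] / (d + 1))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(d * N, N))
}

# linear elasticity (per-element lambda, G), vector P1, component-major dofs
p1_elasticity <- function(mesh, geo, lambda_el, G_el) {
  N <- nrow(mesh$nodes); d <- mesh$dim
  e <- mesh$elems; nl <- d + 1
  ii <- jj <- integer(0); xx <- numeric(0)
  gdot <- function(i, j) {
    acc <- 0
    for (a in seq_len(d)) acc <- acc + geo$grads[, i, a] * geo$grads[, j, a]
    acc
  }
  for (k in seq_len(d)) for (l in seq_len(d)) for (i in seq_len(nl)) for (j in seq_len(nl)) {
    val <- geo$vol * (G_el * ((k == l) * gdot(i, j) +
                              geo$grads[, i, l] * geo$grads[, j, k]) +
                      lambda_el * geo$grads[, i, k] * geo$grads[, j, l])
    ii <- c(ii, (k - 1L) * N + e[, i])
    jj <- c(jj, (l - 1L) * N + e[, j])
    xx <- c(xx, val)
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(d * N, d * N))
}

# volumetric load: f evaluated per element (vector over elements), spread to nodes
p1_load <- function(mesh, geo, f_el) {
  N <- nrow(mesh$nodes); d <- mesh$dim
  out <- numeric(N)
  w <- f_el * geo$vol / (d + 1)
  for (i in seq_len(d + 1)) {
    tv <- tapply(w, mesh$elems[, i], sum)
    out[as.integer(names(tv))] <- out[as.integer(names(tv))] + tv
  }
  out
}

# boundary load on a tagged surface: constant (or per-facet) influx density w
# returns nodal vector: int_Gamma w phi_i
p1_boundary_load <- function(mesh, fg, tag, w) {
  N <- nrow(mesh$nodes)
  sel <- which(mesh$facet_tag == tag)
  out <- numeric(N)
  if (length(sel) == 0) return(out)
  wv <- if (length(w) == 1) rep(w, length(sel)) else w
  nf <- ncol(mesh$facets)
  contrib <- wv * fg$measure[sel] / nf
  for (i in seq_len(nf)) {
    nd <- mesh$facets[sel, i]
    tv <- tapply(contrib, nd, sum)
    out[as.integer(names(tv))] <- out[as.integer(names(tv))] + tv
  }
  out
}

# nodal traction load for vector u dofs: int_Gamma (-p_V n) . v
p1_traction_load <- function(mesh, fg, tag, p_V) {
  N <- nrow(mesh$nodes); d <- mesh$dim
  sel <- which(mesh$facet_tag == tag)
  out <- numeric(d * N)
  if (length(sel) == 0) return(out)
  nf <- ncol(mesh$facets)
  for (k in seq_len(d)) {
    contrib <- -p_V * fg$normal[sel, k] * fg$measure[sel] / nf
    for (i in seq_len(nf)) {
      nd <- mesh$facets[sel, i]
      tv <- tapply(contrib, nd, sum)
      idx <- (k - 1L) * N + as.integer(names(tv))
      out[idx] <- out[idx] + tv
    }
  }
  out
}

# area-weighted surface average of a nodal scalar field over a tag
surface_average <- function(mesh, fg, tag, nodal) {
  sel <- which(mesh$facet_tag == tag)
  nf <- ncol(mesh$facets)
  fv <- rowMeans(matrix(nodal[mesh$facets[sel, ]], ncol = nf))
  sum(fv * fg$measure[sel]) / sum(fg$measure[sel])
}

# surface average (or max) of the outward-of-cavity normal displacement
# (u1 > 0: ventricular wall moves radially outward into the cavity space)
ventricle_normal_displacement <- function(mesh, fg, u, mode = "mean") {
  sel <- which(mesh$facet_tag == "VENTRICLE")
  nf <- ncol(mesh$facets); d <- mesh$dim
  un_f <- numeric(length(sel))
  for (k in seq_len(d)) {
    uk <- rowMeans(matrix(u[mesh$facets[sel, ], k], ncol = nf))
    un_f <- un_f + uk * (-fg$normal[sel, k])
  }
  if (mode == "max") max(un_f) else sum(un_f * fg$measure[sel]) / sum(fg$measure[sel])
}

# unique node indices on a tagged surface
boundary_nodes <- function(mesh, tag) {
  as.integer(sort(unique(as.vector(mesh$facets[mesh$facet_tag == tag, ]))))
}

# element-wise gradient of a nodal scalar field: (M x d)
element_gradient <- function(mesh, geo, nodal) {
  d <- mesh$dim; nl <- d + 1
  out <- matrix(0, nrow(mesh$elems), d)
  for (i in seq_len(nl)) for (k in seq_len(d)) {
    out[, k] <- out[, k] + geo$grads[, i, k] * nodal[mesh$elems[, i]]
  }
  out
}

# element-wise divergence of a nodal vector field u (N x d)
element_divergence <- function(mesh, geo, u) {
  d <- mesh$dim; nl <- d + 1
  out <- numeric(nrow(mesh$elems))
  for (i in seq_len(nl)) for (k in seq_len(d)) {
    out <- out + geo$grads[, i, k] * u[mesh$elems[, i], k]
  }
  out
}
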