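test_that("column meshes have the declared layout and exact total length", {
  m <- make_column(0.07, 7)
  expect_equal(nrow(m$nodes), 8)
  expect_equal(nrow(m$elems), 7)
  expect_equal(element_measures(m), rep(0.01, 7), tolerance = 1e-14)
  expect_equal(sum(element_measures(m)), 0.07, tolerance = 1e-15)
  expect_setequal(m$facet_tag, c("VENTRICLE", "SKULL"))
  expect_no_violations(check_mesh(m))

  m1 <- make_column(0.07, 1)   # single element still carries both tags
  expect_equal(nrow(m1$elems), 1)
  expect_setequal(m1$facet_tag, c("VENTRICLE", "SKULL"))
  expect_error(make_column(-1, 4))
})

test_that("annulus meshes are closed, positively oriented and labelled", {
  m <- make_shell(0.02, 0.07, resolution = 3, dim = 2)
  expect_no_violations(check_mesh(m))
  expect_true(all(element_measures(m) > 0))
  # Euler characteristic of an annulus is 0
  edges <- unique(t(apply(rbind(m$elems[, 1:2], m$elems[, 2:3], m$elems[, c(1, 3)]),
                          1, sort)))
  expect_equal(nrow(m$nodes) - nrow(edges) + nrow(m$elems), 0)
  # grey/white split: element-volume fraction close to the analytic band ratio
  r_split <- 0.02 + 0.5 * 0.05
  frac_analytic <- (0.07^2 - r_split^2) / (0.07^2 - 0.02^2)
  vols <- element_measures(m)
  frac_mesh <- sum(vols[m$tissue == "GREY"]) / sum(vols)
  expect_lt(abs(frac_mesh - frac_analytic) / frac_analytic, 0.10)
  expect_error(make_shell(0.07, 0.02), "r_inner")
})

test_that("ventricular boundary measure converges to the closed form at order >= 1", {
  err <- vapply(c(2, 4, 8), function(res) {
    m <- make_shell(0.02, 0.07, res, dim = 2)
    abs(boundary_measure(m, "VENTRICLE") - 2 * pi * 0.02)
  }, numeric(1))
  orders <- log2(err[-length(err)] / err[-1])
  expect_true(all(orders >= 1))
  # 3D: inner surface approaches 4 pi r^2 under subdivision refinement
  err3 <- vapply(c(2, 4), function(res) {
    m <- make_shell(0.02, 0.07, res, dim = 3)
    abs(boundary_measure(m, "VENTRICLE") - 4 * pi * 0.02^2)
  }, numeric(1))
  expect_lt(err3[2], err3[1])
})

test_that("3D spherical shells are conforming with positive volumes", {
  m <- make_shell(0.02, 0.07, resolution = 2, dim = 3)
  expect_true(all(element_measures(m) > 0))
  expect_no_violations(check_mesh(m))
  expect_setequal(unique(m$tissue), c("GREY", "WHITE"))
  expect_equal(sort(unique(m$region)), seq_along(m$region_names))
})

test_that("synthetic anisotropic permeability tensors are SPD with exact eigenvalues", {
  m <- coarse_annulus()
  Ke <- synth_anisotropic_Ke(m, k_parallel = 3e-10, k_perp = 1e-10)
  for (i in c(1, 57, nrow(m$elems))) {
    ev <- eigen(Ke[i, , ], symmetric = TRUE, only.values = TRUE)$values
    expect_equal(sort(ev), sort(c(1e-10, 3e-10)), tolerance = 1e-12)
  }
  # isotropy case: k_parallel == k_perp reduces to k * I everywhere
  Ki <- synth_anisotropic_Ke(m, 1e-10, 1e-10)
  expect_equal(max(abs(Ki[, 1, 2])), 0, tolerance = 1e-25)
  expect_equal(Ki[, 1, 1], rep(1e-10, nrow(m$elems)), tolerance = 1e-22)
  expect_error(synth_anisotropic_Ke(m, -1e-10, 1e-10))
})

test_that("rotating the mesh rotates the tensors as Q T Q^t", {
  m <- coarse_annulus()
  Ke <- synth_anisotropic_Ke(m, 3e-10, 1e-10)
  th <- 0.7
  Q <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  mrot <- m
  mrot$nodes <- m$nodes %*% t(Q)
  Krot <- synth_anisotropic_Ke(mrot, 3e-10, 1e-10)
  for (i in c(1, 100)) {
    expect_equal(Krot[i, , ], Q %*% Ke[i, , ] %*% t(Q), tolerance = 1e-10)
  }
})

test_that("MSH round-trip preserves connectivity, tags and labels", {
  m <- make_shell(resolution = 2)
  tf <- tempfile(fileext = ".msh")
  write_msh(m, tf)
  m2 <- read_msh(tf)
  expect_equal(m2$nodes, m$nodes, tolerance = 1e-15)
  expect_equal(m2$elems, m$elems, ignore_attr = TRUE)
  expect_equal(m2$tissue, m$tissue, ignore_attr = TRUE)
  expect_equal(m2$region, m$region, ignore_attr = TRUE)
  expect_equal(sort(table(m2$facet_tag)), sort(table(m$facet_tag)))
  # mm units are scaled explicitly, never implicitly
  m3 <- read_msh(tf, units = "mm")
  expect_equal(m3$nodes, m$nodes * 1e-3, tolerance = 1e-18)
})

test_that("a mesh file without the VENTRICLE group is rejected by name", {
  m <- make_column(0.05, 4)
  tf <- tempfile(fileext = ".msh")
  write_msh(m, tf)
  txt <- readLines(tf)
  txt <- sub('"VENTRICLE"', '"SOMETHING"', txt)
  writeLines(txt, tf)
  expect_error(read_msh(tf), "boundary tag VENTRICLE not found")
})

test_that("VTU snapshots carry one scalar per network plus the displacement vector", {
  m <- coarse_annulus()
  st <- field_state(m, t = 1)
  st$p[] <- matrix(rep(1:6 * 100, each = nrow(m$nodes)), ncol = 6)
  st$u[, 1] <- 1e-3
  tf <- tempfile(fileext = ".vtu")
  write_fields(m, st, tf)
  v <- read_vtu(tf)
  expect_setequal(names(v$point_data), c(paste0("p_", c("a", "c", "e", "v", "l", "g")), "u"))
  expect_equal(v$point_data$p_c, rep(200, nrow(m$nodes)))
  expect_equal(v$point_data$u[, 1], rep(1e-3, nrow(m$nodes)))
  expect_equal(v$elems, m$elems, ignore_attr = TRUE)
  expect_equal(v$cell_data$region, as.numeric(m$region))
})
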