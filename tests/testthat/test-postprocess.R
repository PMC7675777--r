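linear_column_problem <- function(n = 16) {
  params <- mpet_params()
  mesh <- make_column(0.05, n, grey_fraction = 0.5)
  mpet_problem(mesh, params, waveform = NULL, transit = FALSE)
}

test_that("perfusion is the capillary Darcy magnitude with the grey/white split", {
  pb <- linear_column_problem()
  mesh <- pb$mesh
  st <- field_state(mesh, 0)
  # uniform capillary pressure: zero perfusion everywhere
  st$p[, "c"] <- 2400
  expect_equal(perfusion_field(pb, st), rep(0, nrow(mesh$elems)))
  # linear drop Delta p over the column: uniform gradient, perfusion
  # (k_c/mu_c) |dp/dx| with the grey/white-partitioned permeability
  dp <- 1000; l <- 0.05
  st$p[, "c"] <- 2400 - dp * mesh$nodes[, 1] / l
  pf <- perfusion_field(pb, st)
  k <- ifelse(mesh$tissue == "GREY", 1.0e-8, 1.0e-10)
  expect_equal(pf, (k / 3.5e-3) * (dp / l), tolerance = 1e-12)
  # equal local gradients: grey perfusion is 100x white
  expect_equal(mean(pf[mesh$tissue == "GREY"]) / mean(pf[mesh$tissue == "WHITE"]),
               100, tolerance = 1e-10)
})

test_that("clearance uses the anisotropic tensor and is frame-invariant", {
  params <- mpet_params()
  mesh <- coarse_annulus()
  mesh$Ke <- synth_anisotropic_Ke(mesh, 3e-10, 1e-10)
  params$Ke_tensor_mode <- "field"
  pb <- mpet_problem(mesh, params, waveform = NULL, transit = FALSE)
  st <- field_state(mesh, 0)
  st$p[, "e"] <- 1000 * mesh$nodes[, 1] / 0.07
  cl <- clearance_field(pb, st)
  expect_true(all(cl >= 0))
  # isotropic tensor field reduces to the scalar-permeability formula
  params2 <- mpet_params()
  mesh2 <- coarse_annulus()
  mesh2$Ke <- synth_anisotropic_Ke(mesh2, 1e-10, 1e-10)
  params2$Ke_tensor_mode <- "field"
  pb2 <- mpet_problem(mesh2, params2, waveform = NULL, transit = FALSE)
  pb3 <- mpet_problem(mesh2, mpet_params(), waveform = NULL, transit = FALSE)
  st2 <- field_state(mesh2, 0)
  st2$p[, "e"] <- 500 + 1e4 * mesh2$nodes[, 2]
  expect_equal(clearance_field(pb2, st2), clearance_field(pb3, st2), tolerance = 1e-12)
  # rotating mesh + tensor field leaves the magnitude invariant
  th <- 0.6; Q <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  meshr <- coarse_annulus()
  meshr$nodes <- meshr$nodes %*% t(Q)
  meshr$Ke <- synth_anisotropic_Ke(meshr, 3e-10, 1e-10)
  pbr <- mpet_problem(meshr, params, waveform = NULL, transit = FALSE)
  str <- field_state(meshr, 0)
  # same radial pressure profile in both frames
  st$p[, "e"] <- 1000 * sqrt(rowSums(mesh$nodes^2)) / 0.07
  str$p[, "e"] <- 1000 * sqrt(rowSums(meshr$nodes^2)) / 0.07
  expect_equal(clearance_field(pbr, str), clearance_field(pb, st), tolerance = 1e-10)
})

test_that("paravenous filtration vanishes for uniform venous pressure", {
  pb <- linear_column_problem()
  st <- field_state(pb$mesh, 0)
  st$p[, "v"] <- 650
  expect_equal(paravenous_field(pb, st), rep(0, nrow(pb$mesh$elems)))
})

test_that("Darcy-derived fields are invariant under a global pressure offset", {
  pb <- linear_column_problem()
  st <- field_state(pb$mesh, 0)
  for (nm in c("a", "c", "e", "v", "l", "g"))
    st$p[, nm] <- 100 * match(nm, c("a","c","e","v","l","g")) +
      5e3 * pb$mesh$nodes[, 1]
  st2 <- st; st2$p <- st$p + 777
  expect_equal(perfusion_field(pb, st2), perfusion_field(pb, st))
  expect_equal(clearance_field(pb, st2), clearance_field(pb, st))
  expect_equal(paravenous_field(pb, st2), paravenous_field(pb, st))
})

test_that("swelling/drainage follows the fluid-content sign conventions", {
  pb <- linear_column_problem()
  mesh <- pb$mesh
  ref <- field_state(mesh, 0)
  ref$p[] <- 1000
  # reference state: identically zero
  expect_equal(swelling_drainage(pb, ref, "glial", ref),
               rep(0, nrow(mesh$elems)))
  # uniform pressure rise delta at fixed displacement: c * delta everywhere
  st <- ref; st$p[, "g"] <- 1000 + 50
  expect_equal(swelling_drainage(pb, st, "glial", ref),
               rep(1.5e-5 * 50, nrow(mesh$elems)), tolerance = 1e-15)
  # compression at reference pressure: negative (drainage)
  st2 <- ref
  st2$u[, 1] <- -0.001 * mesh$nodes[, 1] / 0.05
  z <- swelling_drainage(pb, st2, "glial", ref)
  expect_true(all(z < 0))
  expect_error(swelling_drainage(pb, st, "lymph-node"), "unknown compartment")
})

test_that("regional summaries match a brute-force scan and never widen under refinement", {
  mesh <- coarse_annulus()
  set.seed(42)
  f <- list(alpha_field = runif(nrow(mesh$elems)), beta_field = rnorm(nrow(mesh$elems)))
  rs <- regional_summary(mesh, f)
  for (i in seq_len(nrow(rs))) {
    sel <- mesh$region == match(rs$region[i], mesh$region_names)
    expect_equal(rs$min[i], min(f[[rs$field[i]]][sel]))
    expect_equal(rs$max[i], max(f[[rs$field[i]]][sel]))
  }
  # constant field in a region reports (f0, f0)
  f2 <- list(const = ifelse(mesh$region == 1, 7, 3))
  rs2 <- regional_summary(mesh, f2)
  expect_equal(rs2$min[rs2$region == mesh$region_names[1]], 7)
  expect_equal(rs2$max[rs2$region == mesh$region_names[1]], 7)
  # the global envelope over any partition equals the unpartitioned range
  expect_equal(min(rs$min[rs$field == "alpha_field"]), min(f$alpha_field))
  expect_equal(max(rs$max[rs$field == "alpha_field"]), max(f$alpha_field))
})

test_that("the PVL index averages positive periventricular content only", {
  mesh <- coarse_annulus()
  # zero swelling everywhere: index 0
  expect_equal(pvl_index(mesh, rep(0, nrow(mesh$elems)), band_width = 0.008), 0)
  # content localised at the ventricular band
  cent <- element_centroids(mesh)
  r <- sqrt(rowSums(cent^2))
  z <- ifelse(r < 0.03, 2, -1)
  idx <- pvl_index(mesh, z, band_width = 0.008)
  expect_equal(idx, 2)
  expect_error(pvl_index(mesh, z, band_width = -1), "positive")
})
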