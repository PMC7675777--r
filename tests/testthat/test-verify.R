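test_that("the consolidation series satisfies its boundary and limit behaviour", {
  tz <- terzaghi_problem(length = 0.05, load = 1000, k = 1e-10, mu = 8.9e-4,
                         c_storage = 3.9e-4, alpha = 0.2, lambda = 504.7, G = 216.3)
  # drained boundary: zero for all t > 0
  expect_equal(terzaghi_pressure(tz, 0.05, 0.01), 0, tolerance = 1e-12)
  # full consolidation: t -> infinity gives zero everywhere
  expect_lt(max(abs(terzaghi_pressure(tz, seq(0, 0.05, length.out = 11),
                                      100 * tz$t_char))), 1e-12 * tz$p_init)
  # early time: undrained value away from the drain
  expect_equal(terzaghi_pressure(tz, 0, 1e-4 * tz$t_char), tz$p_init,
               tolerance = 1e-6)
  expect_error(terzaghi_pressure(tz, 0.01, 0), "positive")
  expect_error(terzaghi_pressure(tz, 0.06, 1), "column")
})

test_that("series truncation at N = 200 is converged to 1e-10 for T >= 0.01", {
  base <- list(length = 1, load = 1, k = 1, mu = 1, c_storage = 1, alpha = 1e-9,
               lambda = 0.5, G = 0.25)
  tz200 <- do.call(terzaghi_problem, c(base, n_terms = 200))
  tz400 <- do.call(terzaghi_problem, c(base, n_terms = 400))
  x <- seq(0, 1, length.out = 21)
  for (T in c(0.01, 0.1, 1)) {
    expect_lt(max(abs(terzaghi_pressure(tz200, x, T / tz200$c_v * 1) -
                      terzaghi_pressure(tz400, x, T / tz400$c_v * 1))), 1e-10)
  }
})

test_that("the series matches an independent finite-difference oracle at T = 0.1", {
  # dimensionless mid-column value theta(1/2, 0.1): Crank-Nicolson oracle on a
  # fine grid with Richardson extrapolation, frozen from a pre-build run
  frozen_oracle <- 0.7356513152
  # normalised problem: c_v = 1, p_init = 1 (alpha -> 0 limit, M m_v scaling)
  tz <- terzaghi_problem(length = 1, load = 1e9, k = 1, mu = 1, c_storage = 1,
                         alpha = 1e-9, lambda = 0.5, G = 0.25)
  val <- terzaghi_pressure(tz, 0.5, 0.1 / tz$c_v) / tz$p_init
  expect_equal(val, frozen_oracle, tolerance = 1e-6)

  # live re-derivation of the oracle (coarser CN + Richardson, independent of
  # the series path)
  cn <- function(nz, nt, T = 0.1) {
    n <- nz + 1
    r <- (T / nt) / (2 * (1 / nz)^2)
    A <- matrix(0, n, n); B <- matrix(0, n, n)
    for (i in 2:(n - 1)) {
      A[i, i - 1] <- -r; A[i, i] <- 1 + 2 * r; A[i, i + 1] <- -r
      B[i, i - 1] <- r;  B[i, i] <- 1 - 2 * r; B[i, i + 1] <- r
    }
    A[1, 1] <- 1
    A[n, n - 1] <- -2 * r; A[n, n] <- 1 + 2 * r
    B[n, n - 1] <- 2 * r;  B[n, n] <- 1 - 2 * r
    th <- rep(1, n); th[1] <- 0
    Ai <- solve(A)
    for (k in seq_len(nt)) { th <- Ai %*% (B %*% th); th[1] <- 0 }
    stats::approx(seq(0, 1, length.out = n), th, xout = 0.5)$y
  }
  v1 <- cn(200, 200); v2 <- cn(400, 400)
  rich <- v2 + (v2 - v1) / 3
  expect_equal(rich, frozen_oracle, tolerance = 1e-7)
})

test_that("the reduced solver reproduces Terzaghi consolidation and seals the rest", {
  bench <- terzaghi_bench()
  errs <- bench$errors
  expect_true(all(errs$error < 0.01))
  # error decreases monotonically with refinement at every evaluation time
  for (Td in unique(errs$T)) {
    e <- errs$error[errs$T == Td][order(unique(errs$n_elements))]
    expect_true(all(diff(e) < 0))
  }
  g <- glance(bench)
  expect_true(g$monotone)
  expect_gt(g$c_v, 0)
})

test_that("sealed networks stay at their uniform initial pressures", {
  params <- reduce_to_single_network(mpet_params(), keep = "e")
  params$E_white <- params$E_grey
  lam <- lame_from_young(params$E_grey, params$nu)
  params$lambda_white <- params$lambda_grey <- lam$lambda
  params$G_white <- params$G_grey <- lam$G
  mesh <- make_column(0.05, 32)
  b <- list(u = list(SKULL = bc_traction(1000), VENTRICLE = bc_dirichlet(0)))
  for (nm in c("a", "c", "e", "v", "l", "g"))
    b[[nm]] <- if (nm == "e") list(SKULL = bc_dirichlet(0), VENTRICLE = bc_neumann(0))
      else list(SKULL = bc_neumann(0), VENTRICLE = bc_neumann(0))
  params$dt <- 0.05
  pb <- mpet_problem(mesh, params, bcs = structure(b, class = "mpet_bcs"),
                     waveform = NULL, transit = FALSE)
  p0 <- matrix(rep(c(10, 20, 500, 40, 50, 60), each = pb$N), pb$N, 6,
               dimnames = list(NULL, c("a","c","e","v","l","g")))
  st <- field_state(mesh, 0, p = p0)
  st <- equilibrate_displacement(pb, st)
  for (k in 1:20) st <- mpet_step(pb, st)
  for (nm in c("a", "c", "v", "l", "g"))
    expect_equal(st$p[, nm], p0[, nm], tolerance = 1e-8)
  expect_gt(max(abs(st$p[, "e"] - 500)), 1)  # the kept network did evolve
})

test_that("discrete poroelastic energy decays in the unforced reduced problem", {
  params <- reduce_to_single_network(mpet_params(), keep = "e")
  params$E_white <- params$E_grey
  lam <- lame_from_young(params$E_grey, params$nu)
  params$lambda_white <- params$lambda_grey <- lam$lambda
  params$G_white <- params$G_grey <- lam$G
  params$dt <- 0.02
  mesh <- make_column(0.05, 32)
  b <- list(u = list(SKULL = bc_dirichlet(0), VENTRICLE = bc_dirichlet(0)))
  for (nm in c("a", "c", "e", "v", "l", "g"))
    b[[nm]] <- if (nm == "e") list(SKULL = bc_dirichlet(0), VENTRICLE = bc_neumann(0))
      else list(SKULL = bc_neumann(0), VENTRICLE = bc_neumann(0))
  pb <- mpet_problem(mesh, params, bcs = structure(b, class = "mpet_bcs"),
                     waveform = NULL, transit = FALSE)
  p0 <- matrix(0, pb$N, 6, dimnames = list(NULL, c("a","c","e","v","l","g")))
  p0[, "e"] <- 300 * sin(pi * mesh$nodes[, 1] / 0.05)
  st <- field_state(mesh, 0, p = p0)
  st <- equilibrate_displacement(pb, st)
  en <- poroelastic_energy(pb, st)
  for (k in 1:25) {
    st <- mpet_step(pb, st)
    en2 <- poroelastic_energy(pb, st)
    expect_lte(en2, en * (1 + 1e-12))
    en <- en2
  }
})

test_that("observed convergence orders are near nominal", {
  st <- mms_result()
  expect_true(all(abs(st$spatial_orders$order - 2) < 0.3))
  expect_true(all(abs(st$temporal_orders$order - 1) < 0.3))
  td <- tidy(st)
  expect_setequal(unique(td$study), c("spatial", "temporal"))
  expect_error(mms_study(resolutions = c(2, 4)), "3 resolutions")
})

test_that("a spatially uniform manufactured constant is recovered to solver tolerance", {
  # constant exact solution: forcing reduces to the transfer sources; the
  # discrete solution must track it exactly (lumped and consistent quadrature
  # agree on constants)
  params <- mpet6:::mms_params()
  mesh <- coarse_annulus()
  Pc <- 1000 * (1:6)
  b <- list(u = list(SKULL = bc_dirichlet(0), VENTRICLE = bc_dirichlet(0)))
  for (q in 1:6)
    b[[c("a","c","e","v","l","g")[q]]] <-
      list(SKULL = bc_dirichlet(Pc[q]), VENTRICLE = bc_dirichlet(Pc[q]))
  # transfer sources for constant fields, per network
  graph <- transfer_graph(params, valves = list(
    ac = "bidirectional", cv = "bidirectional", al = "bidirectional"))
  fp <- lapply(1:6, function(q) {
    nm <- c("a","c","e","v","l","g")[q]
    function(x, t) {
      s <- 0
      for (pr in list(c("a","c"), c("c","v"), c("a","l"), c("c","l"),
                      c("v","l"), c("e","l"), c("g","l"), c("e","g"))) {
        if (!(nm %in% pr)) next
        other <- setdiff(pr, nm)
        qo <- match(other, c("a","c","e","v","l","g"))
        s <- s - transfer(graph, other, nm, Pc[qo], Pc[q])
      }
      rep(s, nrow(x))
    }
  })
  names(fp) <- c("a","c","e","v","l","g")
  pb <- mpet_problem(mesh, params, graph = graph,
                     bcs = structure(b, class = "mpet_bcs"),
                     waveform = NULL, dt = 0.1, transit = FALSE,
                     forcing = list(u = NULL, p = fp))
  st <- field_state(mesh, 0, p = matrix(rep(Pc, each = pb$N), pb$N, 6,
                                        dimnames = list(NULL, c("a","c","e","v","l","g"))))
  for (k in 1:5) st <- mpet_step(pb, st)
  for (q in 1:6)
    expect_equal(st$p[, q], rep(Pc[q], pb$N), tolerance = 1e-9)
})
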