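uniform_bcs <- function(P) {
  b <- list(u = list(SKULL = bc_dirichlet(0), VENTRICLE = bc_traction_pe()))
  for (nm in c("a", "c", "e", "v", "l", "g"))
    b[[nm]] <- list(SKULL = bc_dirichlet(P), VENTRICLE = bc_dirichlet(P))
  structure(b, class = "mpet_bcs")
}

test_that("uniform pressures with matching boundary data are a fixed point", {
  # zero waveform, zero production, all boundary pressures equal: p_i = P, u = 0
  P <- 1000
  params <- mpet_params()
  params$p_ls <- P; params$p_lv <- P; params$p_gv <- P; params$p_bp <- P
  params$Q_p <- 0; params$R <- 0
  mesh <- coarse_annulus()
  pb <- mpet_problem(mesh, params, bcs = mpet_bcs(params, Q_o = 0),
                     waveform = NULL, transit = FALSE)
  st <- field_state(mesh, 0,
                    p = matrix(P, pb$N, 6, dimnames = list(NULL, c("a","c","e","v","l","g"))))
  for (k in 1:3) st <- mpet_step(pb, st)
  expect_lt(max(abs(st$p - P)) / P, 1e-9)
  expect_lt(max(abs(st$u)), 1e-12)
})

test_that("a decoupled single network with sealed boundaries is stationary", {
  # all omega = 0, all alpha = 0: each pressure block is a pure heat equation;
  # a uniform field under homogeneous Neumann data is a steady state
  params <- mpet_params()
  params$omega[] <- 0; params$alpha[] <- 0; params$phi <- 0
  mesh <- make_column(0.05, 16)
  b <- list(u = list(SKULL = bc_dirichlet(0), VENTRICLE = bc_dirichlet(0)))
  for (nm in c("a", "c", "e", "v", "l", "g"))
    b[[nm]] <- list(SKULL = bc_neumann(0), VENTRICLE = bc_neumann(0))
  pb <- mpet_problem(mesh, params, bcs = structure(b, class = "mpet_bcs"),
                     waveform = NULL, transit = FALSE)
  p0 <- matrix(rep(c(100, 200, 300, 400, 500, 600), each = pb$N), pb$N, 6,
               dimnames = list(NULL, c("a","c","e","v","l","g")))
  st <- field_state(mesh, 0, p = p0)
  for (k in 1:5) st <- mpet_step(pb, st)
  expect_lt(max(abs(st$p - p0)) / max(p0), 1e-9)
})

test_that("constant Dirichlet driving converges to the stationary solution", {
  # fixed boundary values, no pulsation: repeated stepping reaches a state
  # whose update is at solver-tolerance level (steady-state fixed point)
  params <- mpet_params()
  mesh <- coarse_annulus()
  pb <- mpet_problem(mesh, params, waveform = NULL, transit = FALSE)
  st <- initial_state(pb)
  for (k in 1:400) st <- mpet_step(pb, st)
  st2 <- mpet_step(pb, st)
  expect_lt(max(abs(st2$p - st$p)) / max(abs(st$p)), 1e-5)
})

test_that("six identically parameterised uncoupled networks evolve identically", {
  params <- mpet_params()
  params$omega[] <- 0
  params$alpha[] <- 1 / 6; params$phi <- 0.3
  params$c_storage[] <- 2.9e-4
  params$k[] <- 1e-10
  params$mu[] <- 1e-3
  mesh <- coarse_annulus()
  b <- list(u = list(SKULL = bc_dirichlet(0), VENTRICLE = bc_traction(500)))
  for (nm in c("a", "c", "e", "v", "l", "g"))
    b[[nm]] <- list(SKULL = bc_dirichlet(800), VENTRICLE = bc_dirichlet(300))
  pb <- mpet_problem(mesh, params, bcs = structure(b, class = "mpet_bcs"),
                     waveform = NULL, transit = FALSE)
  st <- field_state(mesh, 0, p = matrix(500, pb$N, 6,
                                        dimnames = list(NULL, c("a","c","e","v","l","g"))))
  for (k in 1:10) st <- mpet_step(pb, st)
  for (nm in c("c", "e", "v", "l", "g"))
    expect_equal(st$p[, nm], st$p[, "a"], tolerance = 1e-8)
})

test_that("the assembled operator has the 7-block structure with zero sealed couplings", {
  params <- reduce_to_single_network(mpet_params(), keep = "e")
  mesh <- make_column(0.05, 8)
  b <- list(u = list(SKULL = bc_traction(100), VENTRICLE = bc_dirichlet(0)))
  for (nm in c("a", "c", "e", "v", "l", "g"))
    b[[nm]] <- list(SKULL = bc_neumann(0), VENTRICLE = bc_neumann(0))
  pb <- mpet_problem(mesh, params, bcs = structure(b, class = "mpet_bcs"),
                     waveform = NULL, transit = FALSE)
  st <- field_state(mesh, 0)
  sys <- mpet_assemble(pb, st)
  N <- pb$N; d <- pb$d
  off <- function(q) d * N + (q - 1) * N
  idx <- function(q) (off(q) + 1):(off(q) + N)
  A <- sys$A
  # sealed networks (alpha = 0, omega = 0) have zero coupling to u and e
  for (q in c(1, 2, 4, 5, 6)) {
    expect_equal(max(abs(A[idx(q), 1:(d * N)])), 0)
    expect_equal(max(abs(A[1:(d * N), idx(q)])), 0)
    expect_equal(max(abs(A[idx(q), idx(3)])), 0)
  }
  # the kept network couples to displacement both ways
  expect_gt(max(abs(A[idx(3), 1:(d * N)])), 0)
  expect_gt(max(abs(A[1:(d * N), idx(3)])), 0)
  expect_error(mpet_assemble(pb, st, dt = 99), "dt")
})

test_that("run_cycles flags convergence under constant driving and records history", {
  params <- mpet_params()
  mesh <- coarse_annulus()
  wf <- synth_waveform(1.25e-5, pulsatility = 0)  # constant driving
  pb <- mpet_problem(mesh, params, waveform = wf, dt = 0.1)
  run <- run_cycles(pb, n_cycles = 60, tol = 1e-4, exclude = 2)
  expect_true(run$converged)
  expect_false(run$diverged)
  expect_lt(run$cycles_run, 60)
  h <- tidy(run)
  expect_true(all(c("cycle", "field", "rel_diff") %in% names(h)))
  expect_equal(sort(unique(h$field)),
               sort(c("u", paste0("p_", c("a", "c", "e", "v", "l", "g")))))
  g <- glance(run)
  expect_true(g$converged)
  expect_equal(g$steps_per_cycle, 10)
})

test_that("two identical consecutive cycles trigger the convergence flag", {
  # a problem already at steady state: the second cycle matches the first
  P <- 1000
  params <- mpet_params()
  params$p_ls <- P; params$p_lv <- P; params$p_gv <- P; params$p_bp <- P
  params$Q_p <- 0; params$R <- 0
  mesh <- coarse_annulus()
  pb <- mpet_problem(mesh, params, bcs = mpet_bcs(params, Q_o = 0),
                     waveform = NULL, transit = FALSE)
  st <- field_state(mesh, 0,
                    p = matrix(P, pb$N, 6, dimnames = list(NULL, c("a","c","e","v","l","g"))))
  run <- run_cycles(pb, n_cycles = 10, tol = 1e-6, init = st,
                    period = 1.0, exclude = 0)
  expect_true(run$converged)
  expect_lte(run$cycles_run, 3)
})

test_that("boundary condition sets are validated structurally", {
  params <- mpet_params()
  b <- mpet_bcs(params)
  b$c <- NULL
  expect_error(mpet_problem(coarse_annulus(), params,
                            bcs = structure(b, class = "mpet_bcs")),
               "missing boundary conditions")
  b2 <- mpet_bcs(params)
  b2$v$SKULL <- bc_aqueduct()
  expect_error(mpet_problem(coarse_annulus(), params,
                            bcs = structure(b2, class = "mpet_bcs")),
               "aqueduct")
  # invalid parameters are rejected before assembly
  bad <- mpet_params(); bad$alpha[] <- 0.3
  expect_error(mpet_problem(coarse_annulus(), bad), "invalid parameter set")
})
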