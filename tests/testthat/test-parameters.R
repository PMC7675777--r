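test_that("the reference parameter set passes validation with alpha-sum at the bound", {
  p <- mpet_params()
  expect_no_violations(validate_params(p))
  expect_equal(sum(p$alpha), 1.0)
  expect_true(p$phi <= sum(p$alpha))
})

test_that("validation reports violations without raising", {
  p <- mpet_params()
  p$alpha[] <- 0.3
  rep <- validate_params(p)
  expect_gt(nrow(rep), 0)
  expect_true(any(grepl("sum 1.8 > 1", rep$message)))

  # boundary case: all-zero coefficients with zero porosity is valid
  p2 <- mpet_params()
  p2$alpha[] <- 0; p2$phi <- 0
  expect_no_violations(validate_params(p2))

  # missing field is itself a violation, not an error
  p3 <- unclass(mpet_params()); p3$alpha <- NULL
  expect_no_error(rep3 <- validate_params(p3))
  expect_true(any(grepl("missing field 'alpha'", rep3$message)))

  # inconsistent Lame pair
  p4 <- mpet_params()
  p4$lambda_grey <- 999
  expect_true(any(grepl("inconsistent", validate_params(p4)$message)))
})

test_that("lame_from_young reproduces the printed grey/white moduli", {
  g <- lame_from_young(584, 0.35)
  expect_equal(round(g$lambda), 505)
  expect_equal(round(g$G), 216)
  w <- lame_from_young(1168, 0.35)
  expect_equal(round(w$G), 433)
  # nu = 0 degenerate case: lambda vanishes
  z <- lame_from_young(100, 0)
  expect_equal(z$lambda, 0)
  expect_equal(z$G, 50)
  expect_error(lame_from_young(584, 0.5), "incompressible")
  expect_error(lame_from_young(-1, 0.3), "positive")
})

test_that("lame_from_young and its inverse are mutually consistent to 10 digits", {
  for (E in c(584, 1168, 3000)) for (nu in c(0.1, 0.35, 0.49)) {
    lg <- lame_from_young(E, nu)
    back <- young_from_lame(lg$lambda, lg$G)
    expect_equal(back$E, E, tolerance = 1e-10)
    expect_equal(back$nu, nu, tolerance = 1e-10)
  }
})

test_that("white-matter stiffness perturbation honours bounds, labels and seed", {
  mesh <- coarse_annulus()
  p <- mpet_params()
  E <- perturb_white_stiffness(mesh, p, amplitude = 10, seed = 7)
  white <- mesh$tissue == "WHITE"
  expect_true(all(E[!white] == p$E_grey))          # grey exactly untouched
  expect_true(all(E[white] >= p$E_white - 10))
  expect_true(all(E[white] <= p$E_white + 10))
  # mean within 3 standard errors of the nominal white modulus
  se <- (10 / sqrt(3)) / sqrt(sum(white))
  expect_lt(abs(mean(E[white]) - p$E_white), 3 * se)
  # determinism: same seed -> bitwise identical; different seed differs
  expect_identical(E, perturb_white_stiffness(mesh, p, amplitude = 10, seed = 7))
  expect_false(identical(E, perturb_white_stiffness(mesh, p, amplitude = 10, seed = 8)))
  # amplitude 0: exact piecewise-constant partition
  E0 <- perturb_white_stiffness(mesh, p, amplitude = 0, seed = 1)
  expect_identical(E0, ifelse(white, p$E_white, p$E_grey))
  # correlated mode stays within bounds too
  Ec <- perturb_white_stiffness(mesh, p, amplitude = 10, seed = 7, mode = "correlated")
  expect_true(all(abs(Ec[white] - p$E_white) <= 10))
})

test_that("perturbation does not disturb the caller's RNG stream", {
  set.seed(123)
  a <- runif(1)
  set.seed(123)
  invisible(perturb_white_stiffness(coarse_annulus(), mpet_params(), seed = 99))
  expect_identical(runif(1), a)
})

test_that("the bundled default configuration reproduces the reference table", {
  cfg <- read_mpet_config(default_config_path())
  p <- params_from_config(cfg)
  expect_no_violations(validate_params(p))
  ref <- mpet_params()
  for (f in c("alpha", "c_storage", "k", "omega"))
    expect_equal(p[[f]], ref[[f]])
  expect_equal(p$E_grey, 584); expect_equal(p$E_white, 1168)
  expect_equal(p$p_lv, 2445); expect_equal(p$p_gv, 1767); expect_equal(p$p_bp, 650)
  expect_equal(p$Q_p, 5.8e-9); expect_equal(p$R, 8.5e13)
  expect_equal(p$d, 3e-3); expect_equal(p$L, 70e-3); expect_equal(p$dt, 0.1)
})

test_that("mmHg-suffixed config values are converted to Pa", {
  tf <- tempfile(fileext = ".yaml")
  writeLines(c("boundary:", "  p_lv: 18.34 mmHg"), tf)
  cfg <- read_mpet_config(tf)
  expect_equal(cfg$boundary$p_lv, 18.34 * 133.322)
  # untouched entries fall back to bundled defaults
  expect_equal(cfg$boundary$p_bp, 650)
})
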