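test_that("blockade fraction follows its saturation curve and stays in [0, 1)", {
  expect_identical(blockade_fraction(0, bp0), 0)
  # half-saturation by construction: c1*a1 = K_A1
  a_half <- bp0$K_A1 / bp0$c1
  expect_equal(blockade_fraction(a_half, bp0), 0.5)
  # saturation limit
  expect_equal(blockade_fraction(1e6 * a_half, bp0), 1e6 / (1e6 + 1), tolerance = 1e-12)
  # monotone nondecreasing and bounded on a grid
  grid <- c(0, 10^seq(-3, 12, length.out = 60))
  vals <- blockade_fraction(grid, bp0)
  expect_true(all(diff(vals) >= 0))
  expect_true(all(vals >= 0 & vals < 1))
  expect_error(blockade_fraction(-1, bp0), "nonnegative")
})

test_that("checkpoint complex scales with T, epsilon and is depleted by Avelumab", {
  p <- base_params(q0 = 1)
  expect_identical(checkpoint_complex(v = 5, t = 0, a1 = 3, eps = 2, p), 0)
  # direct arithmetic with blockade 0: q0 * t * (t + eps v)
  expect_equal(checkpoint_complex(v = 3, t = 1, a1 = 0, eps = 2, p), 7)
  # blockade -> 1 drives the complex to 0
  huge <- 1e9 * p$K_A1 / p$c1
  expect_lt(checkpoint_complex(v = 3, t = 1, a1 = huge, eps = 2, p), 1e-8 * 7)
  # monotone nonincreasing in a1, nondecreasing in eps on random grids
  set.seed(42)
  for (i in 1:25) {
    v <- runif(1, 0, 500); t <- runif(1, 0, 50); eps <- runif(1, 0, 100)
    a1s <- sort(runif(5, 0, 1000))
    expect_true(all(diff(checkpoint_complex(v, t, a1s, eps, bp0)) <= 0))
    epss <- sort(runif(5, 0, 100))
    expect_true(all(diff(checkpoint_complex(v, t, 50, epss, bp0)) >= 0))
  }
  expect_error(checkpoint_complex(-1, 1, 0, 0, bp0), "nonnegative")
})

test_that("T-cell activation combines basal production, IL-12 stimulation and checkpoint suppression", {
  # both modulations inactive: t = 0 kills both the stimulation and the complex
  expect_equal(tcell_activation(v = 100, t = 0, a1 = 0, a2 = 0, eps = 46, bp0), bp0$delta)
  # strong suppression limit: huge complex
  p <- base_params(q0 = 1e12)
  expect_lt(tcell_activation(v = 100, t = 10, a1 = 0, a2 = 0, eps = 46, p), 1e-6)
  # Michaelis-Menten saturation in a2 with no suppression (t enters complex via q0 -> 0)
  p2 <- base_params(q0 = 1e-300)
  a2_huge <- 1e9 * bp0$K_A2 / bp0$c2
  expect_equal(tcell_activation(100, t = 2, 0, a2_huge, 46, p2),
               p2$delta + p2$lambda_T * 2, tolerance = 1e-6)
  # bounded above by delta + lambda_T * t, nonincreasing in the complex
  set.seed(7)
  for (i in 1:25) {
    v <- runif(1, 0, 500); t <- runif(1, 0, 50); a2 <- runif(1, 0, 20); eps <- runif(1, 0, 100)
    f <- tcell_activation(v, t, 0, a2, eps, bp0)
    expect_lte(f, bp0$delta + bp0$lambda_T * t + 1e-12)
    # larger eps -> larger complex -> smaller activation
    expect_gte(f, tcell_activation(v, t, 0, a2, eps + 10, bp0))
  }
})

test_that("base right-hand side reduces to its closed-form special cases", {
  # empty system: only basal T production survives
  expect_equal(unname(base_rhs(c(V = 0, T = 0, A1 = 0, A2 = 0), bp0, eps = 0)),
               c(0, bp0$delta, 0, 0))
  # eta = 0, no drugs: pure exponential tumor growth
  p <- base_params(eta = 1e-12)
  d <- base_rhs(c(V = 100, T = 1, A1 = 0, A2 = 0), p, eps = 46)
  expect_equal(unname(d["dV"]), p$r * 100, tolerance = 1e-9)
  # isolated drug compartment: first-order decay
  d2 <- base_rhs(c(V = 100, T = 1, A1 = 200, A2 = 0), bp0, eps = 46)
  expect_equal(unname(d2["dA1"]), -bp0$d_A1 * 200)
  expect_error(base_rhs(c(V = NaN, T = 0, A1 = 0, A2 = 0), bp0, eps = 0), "finite")
})

test_that("expression dynamics balance production and decay", {
  # no tumor, no drugs: only decay remains
  expect_equal(epsilon_rhs(eps = 3, v = 0, a1 = 0, a2 = 0, ep0, bp0), -ep0$d_eps * 3)
  # quasi-steady state by construction
  eqs <- ep0$k_basal * 100 / (ep0$d_eps * (ep0$K_V + 100))
  expect_equal(epsilon_rhs(eqs, v = 100, a1 = 0, a2 = 0, ep0, bp0), 0, tolerance = 1e-12)
  # direct evaluation at the fitted constants: k_basal * 100/150
  expect_equal(epsilon_rhs(0, v = 100, a1 = 0, a2 = 0, ep0, bp0),
               30.5441 * 100 / 150, tolerance = 1e-12)
  expect_equal(epsilon_rhs(0, v = 100, a1 = 0, a2 = 0, ep0, bp0), 20.363, tolerance = 1e-4)
})

test_that("quasi-steady-state initializer matches the root of the expression equation", {
  expect_identical(epsilon_qss_init(0, ep0), 0)
  expect_equal(epsilon_qss_init(100, ep0), 46.185, tolerance = 1e-4)
  # saturation limit k_basal / d_eps
  expect_equal(epsilon_qss_init(1e12, ep0), ep0$k_basal / ep0$d_eps, tolerance = 1e-6)
  expect_equal(epsilon_qss_init(1e12, ep0), 69.277, tolerance = 1e-4)
  # cross-check against root-finding on the rhs for random volumes and parameters
  set.seed(11)
  for (i in 1:100) {
    ep <- epsilon_params(k_basal = runif(1, 1, 100), K_V = runif(1, 5, 500),
                         alpha_A1 = runif(1, 1, 100), alpha_A2 = runif(1, 10, 1000),
                         d_eps = runif(1, 0.05, 5))
    v0 <- runif(1, 1, 2000)
    eqs <- epsilon_qss_init(v0, ep)
    expect_lt(abs(epsilon_rhs(eqs, v0, 0, 0, ep, bp0)), 1e-10)
    root <- uniroot(function(e) epsilon_rhs(e, v0, 0, 0, ep, bp0),
                    c(0, 2 * ep$k_basal / ep$d_eps + 1), tol = 1e-12)$root
    expect_equal(eqs, root, tolerance = 1e-8)
  }
})

test_that("half-life conversion gives the murine clearance rates", {
  expect_equal(decay_rate_from_half_life(1.86), 0.3726, tolerance = 0.0005 / 0.3726)
  expect_equal(decay_rate_from_half_life(9.5), 0.0730, tolerance = 0.0005 / 0.0730)
  expect_equal(decay_rate_from_half_life(log(2)), 1.0)
  expect_error(decay_rate_from_half_life(0), "positive")
  expect_error(decay_rate_from_half_life(-2), "positive")
})

test_that("parameter constructors validate positivity and expose presets", {
  expect_error(base_params(r = -1), "positive")
  expect_error(base_params(K_A1 = 0), "positive")
  expect_error(epsilon_params(d_eps = 0), "positive")
  # default clearance rates are ln(2)/half-life within 1e-3 relative
  expect_rel_equal(bp0$d_A1, log(2) / 1.86, 1e-3)
  expect_rel_equal(bp0$d_A2, log(2) / 9.5, 1e-3)
  mc38 <- epsilon_params(study = "MC38")
  expect_equal(mc38$k_basal, 12.64)
  expect_equal(mc38$K_V, 462.70)
  # explicit argument overrides the preset
  expect_equal(epsilon_params(k_basal = 5, study = "MC38")$k_basal, 5)
})

test_that("flat parameter configuration files round-trip", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_params_config(bp0, ep0, path)
  cfg <- read_params_config(path)
  expect_equal(unclass(cfg$base), unclass(bp0), tolerance = 1e-12)
  expect_equal(unclass(cfg$epsilon), unclass(ep0), tolerance = 1e-12)
  # unknown keys rejected
  writeLines("r: 1\nnot_a_parameter: 2", path)
  expect_error(read_params_config(path), "unknown configuration keys")
})
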