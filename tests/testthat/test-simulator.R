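test_that("untreated tumor with no killing grows exponentially", {
  p <- base_params(eta = 1e-300)  # removes T-cell killing without changing T dynamics
  traj <- simulate_arm(arms0$a, base = p, epsilon = ep0, t_end = 25, step = 0.5)
  expect_rel_equal(traj$V_mm3[traj$time_day == 25], 100 * exp(25 * p$r), 1e-6)
  # whole path, not just the endpoint
  expect_rel_equal(traj$V_mm3, 100 * exp(p$r * traj$time_day), 1e-6)
})

test_that("a single bolus decays with the configured half-life", {
  arm <- treatment_arm("av_once", dose_event(0, "Avelumab", 200))
  traj <- simulate_arm(arm, base = bp0, epsilon = ep0, t_end = 10, step = 0.01)
  expect_rel_equal(traj$A1, 200 * exp(-bp0$d_A1 * traj$time_day), 1e-8)
  # halved at one half-life
  a_half <- traj$A1[which.min(abs(traj$time_day - 1.86))]
  expect_equal(a_half, 100, tolerance = 1e-4)
})

test_that("drugs follow closed-form exponential decay between repeated doses", {
  traj <- simulate_arm(arms0$f, base = bp0, epsilon = ep0, t_end = 25, step = 0.1,
                       rtol = 1e-10, atol = 1e-12)
  jumps <- attr(traj, "jumps")
  post <- jumps[jumps$limit == "post", ]
  for (i in seq_len(nrow(post))) {
    t0 <- post$time_day[i]
    t1 <- min(c(post$time_day[post$time_day > t0], 25))
    seg <- traj[traj$time_day > t0 & traj$time_day < t1, ]
    expect_rel_equal(seg$A1, post$A1[i] * exp(-bp0$d_A1 * (seg$time_day - t0)), 1e-8)
    expect_rel_equal(seg$A2, post$A2[i] * exp(-bp0$d_A2 * (seg$time_day - t0)), 1e-8)
  }
  # every dose day is a grid point carrying the post-dose state
  expect_true(all(c(0, 3, 6) %in% traj$time_day))
  expect_equal(traj$A1[traj$time_day == 0], 200)
})

test_that("expression state solves its scalar linear ODE when T-cells are absent", {
  # delta = 0 and T(0) = 0 keep T identically zero, so V grows exponentially
  # and eps obeys eps' = k_basal V/(K_V+V) - d_eps eps. Oracle: integrating-
  # factor solution evaluated by adaptive quadrature.
  p <- base_params(delta = 1e-300)
  traj <- simulate_arm(arms0$a, base = p, epsilon = ep0, t_end = 25, v0 = 100,
                       t0_cells = 0, step = 0.5)
  expect_lt(max(traj$T_mm3), 1e-12)
  eps0 <- epsilon_qss_init(100, ep0)
  oracle <- vapply(traj$time_day, function(tt) {
    if (tt == 0) return(eps0)
    q <- integrate(function(s) {
      v <- 100 * exp(p$r * s)
      exp(-ep0$d_eps * (tt - s)) * ep0$k_basal * v / (ep0$K_V + v)
    }, 0, tt, rel.tol = 1e-10, abs.tol = 1e-12)$value
    eps0 * exp(-ep0$d_eps * tt) + q
  }, 0)
  expect_rel_equal(traj$eps, oracle, 1e-5)
})

test_that("states remain nonnegative across random parameter draws", {
  set.seed(99)
  for (i in 1:100) {
    jit <- function(x) x * 10^runif(1, -0.3, 0.3)
    p <- base_params(r = jit(0.13), eta = jit(0.05), delta = jit(0.35),
                     lambda_T = jit(4.15), d_T = jit(0.35), c1 = jit(1e-15),
                     c2 = jit(3.5e-14), K_TQ = jit(200), q0 = jit(0.1))
    ep <- epsilon_params(k_basal = jit(30.5), K_V = jit(50), alpha_A1 = jit(38.3),
                         alpha_A2 = jit(643.6), d_eps = jit(0.44))
    arm <- arms0[[sample(letters[1:6], 1)]]
    traj <- simulate_arm(arm, base = p, epsilon = ep, t_end = 25, step = 0.5)
    expect_true(all(as.matrix(traj[, -1]) >= 0))
  }
})

test_that("tightening integrator tolerances leaves the solution unchanged", {
  v_ref <- simulate_arm(arms0$e, base = bp0, epsilon = ep0, step = 0.5,
                        rtol = 1e-8, atol = 1e-10)
  v_tight <- simulate_arm(arms0$e, base = bp0, epsilon = ep0, step = 0.5,
                          rtol = 5e-9, atol = 5e-11)
  i <- which.max(v_ref$time_day)
  denom <- max(v_ref$V_mm3[i], 1)  # eliminated tumors compare on an absolute floor
  expect_lt(abs(v_ref$V_mm3[i] - v_tight$V_mm3[i]) / denom, 1e-4)
  # and a progressing arm compares relatively
  g_ref <- simulate_arm(arms0$a, base = bp0, epsilon = ep0, step = 0.5)
  g_tight <- simulate_arm(arms0$a, base = bp0, epsilon = ep0, step = 0.5,
                          rtol = 5e-9, atol = 5e-11)
  expect_rel_equal(g_ref$V_mm3[g_ref$time_day == 25],
                   g_tight$V_mm3[g_tight$time_day == 25], 1e-4)
})

test_that("static tumor relaxes the expression state to its quasi-steady value", {
  # r = 0 and eta = 0 freeze V, so eps converges monotonically to the QSS
  p <- base_params(r = 1e-300, eta = 1e-300)
  ep <- epsilon_params(k_basal = 60, d_eps = 0.3)  # start away from equilibrium
  traj <- simulate_arm(arms0$a, base = p, epsilon = ep, t_end = 25, v0 = 100, step = 0.1)
  target <- epsilon_qss_init(100, ep)
  expect_rel_equal(traj$eps[traj$time_day == 25], target, 1e-6)
  gap <- abs(traj$eps - target)
  expect_true(all(diff(gap) <= 1e-10))
})

test_that("compiled and pure-R right-hand sides integrate to the same trajectory", {
  for (mode_args in list(list(epsilon = ep0), list(epsilon = 46.185, mode = "constant"))) {
    a_c <- do.call(simulate_arm, c(list(arms0$e, base = bp0, step = 0.5, engine = "compiled"), mode_args))
    a_r <- do.call(simulate_arm, c(list(arms0$e, base = bp0, step = 0.5, engine = "R"), mode_args))
    expect_equal(as.data.frame(a_c), as.data.frame(a_r), tolerance = 1e-6)
  }
})

test_that("final outcome uses a strict elimination threshold", {
  mk <- function(v) tibble::tibble(time_day = c(0, 25), V_mm3 = c(100, v))
  expect_equal(final_outcome(mk(0))$outcome, "eliminated")
  expect_equal(final_outcome(mk(2000))$outcome, "progressing")
  # boundary: exactly at the threshold counts as progressing
  expect_equal(final_outcome(mk(1), elimination_threshold = 1)$outcome, "progressing")
  expect_equal(final_outcome(mk(0.999), elimination_threshold = 1)$outcome, "eliminated")
  expect_error(final_outcome(tibble::tibble()), "nonempty")
})

test_that("simulation rejects invalid inputs and exports cleanly", {
  expect_error(simulate_arm(arms0$a, t_end = -1), "positive")
  expect_error(simulate_arm(arms0$a, v0 = 0), "positive")
  expect_error(simulate_arm(arms0$a, epsilon = -2, mode = "constant"), "nonnegative")
  expect_error(simulate_arm("z"), "unknown arm")
  traj <- simulate_arm(arms0$b, step = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(traj, path)
  back <- utils::read.csv(path)
  expect_named(back, c("time_day", "V_mm3", "T_mm3", "A1", "A2", "eps"))
  expect_equal(nrow(back), nrow(traj))
})
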