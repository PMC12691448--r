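test_that("residual sum of squares matches hand-computed cases", {
  traj <- tibble::tibble(time_day = 0:25,
                         V_mm3 = 100 * exp(0.1 * (0:25)),
                         T_mm3 = 1, A1 = 0, A2 = 0, eps = 46)
  # identical curves
  obs <- tibble::tibble(day = c(0, 5, 10), volume_mm3 = 100 * exp(0.1 * c(0, 5, 10)))
  expect_equal(sse(obs, traj), 0)
  # single point: obs 10 vs sim 7 -> 9
  flat <- tibble::tibble(time_day = c(0, 10), V_mm3 = c(7, 7))
  expect_equal(sse(tibble::tibble(day = 5, volume_mm3 = 10), flat), 9)
  # residuals (1, 2, 2) -> 9
  obs3 <- tibble::tibble(day = c(1, 2, 3), volume_mm3 = 7 + c(1, 2, 2))
  expect_equal(sse(obs3, flat), 9)
  # observation outside the simulated window
  expect_error(sse(tibble::tibble(day = 30, volume_mm3 = 1), flat), "outside")
})

test_that("the arm-data reader validates structure and reports bad lines", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("arm,day,volume_mm3", "a,0,100", "a,5,163.2"), path)
  d <- read_arm_data(path)
  expect_equal(d$volume_mm3, c(100, 163.2))
  writeLines(c("arm,day,volume", "a,0,100"), path)
  expect_error(read_arm_data(path), "header")
  writeLines(c("arm,day,volume_mm3", "a,0,100", "a,five,200"), path)
  expect_error(read_arm_data(path), "line 3")
  writeLines(c("arm,day,volume_mm3", "a,0,-5"), path)
  expect_error(read_arm_data(path), "nonnegative")
})

test_that("a known constant expression level is recovered from noise-free data", {
  eps_true <- 60
  traj <- simulate_arm(arms0$b, base = bp0, epsilon = eps_true, mode = "constant",
                       times = obs_days)
  data <- tibble::tibble(arm = "b", day = obs_days,
                         volume_mm3 = traj$V_mm3[match(obs_days, traj$time_day)])
  fit <- fit_constant_epsilon(data, arm = arms0$b, base = bp0, n_starts = 10, seed = 0)
  expect_s3_class(fit, "pdl1_fit")
  expect_equal(fit$k, 1L)
  expect_equal(fit$n, 6L)
  expect_rel_equal(fit$estimates[["epsilon"]], eps_true, 0.01)
  expect_lt(fit$rss, 1e-6)
  # tidy/glance accessors
  expect_equal(tidy(fit)$term, "epsilon")
  expect_equal(glance(fit)$k, 1L)
  expect_equal(glance(fit)$aic, aic_rss(fit$rss, 6, 1))
})

test_that("constant-expression fitting enforces its preconditions and determinism", {
  expect_error(fit_constant_epsilon(tibble::tibble(arm = "b", day = 0, volume_mm3 = 100)),
               "at least two")
  two_arms <- tibble::tibble(arm = c("a", "b"), day = c(0, 0), volume_mm3 = c(100, 100))
  expect_error(fit_constant_epsilon(two_arms), "exactly one arm")
  traj <- simulate_arm(arms0$b, base = bp0, epsilon = 60, mode = "constant", times = obs_days)
  data <- tibble::tibble(arm = "b", day = obs_days,
                         volume_mm3 = traj$V_mm3[match(obs_days, traj$time_day)])
  f1 <- fit_constant_epsilon(data, arm = arms0$b, n_starts = 5, seed = 3)
  f2 <- fit_constant_epsilon(data, arm = arms0$b, n_starts = 5, seed = 3)
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$rss, f2$rss)
  # the returned optimum is never worse than any multistart initial point
  expect_true(all(f1$rss <= f1$starts$rss_start + 1e-9))
})

test_that("global dynamic fitting guards arm counts and structural identifiability", {
  s <- generate_study(noise = noise_spec("none"))
  expect_error(fit_dynamic_global(s[s$arm %in% c("a", "b"), ]), "expects 6 arms")
  # all-control study: drug-effect parameters cannot be identified
  ctrl_arms <- stats::setNames(lapply(letters[1:6], treatment_arm), letters[1:6])
  ctrl_data <- dplyr::bind_rows(lapply(letters[1:6], function(l) {
    tibble::tibble(arm = l, day = obs_days, volume_mm3 = 100 * exp(0.1 * obs_days))
  }))
  expect_error(fit_dynamic_global(ctrl_data, arms = ctrl_arms), "unidentifiable")
})

test_that("the global dynamic fit is deterministic and never returns uphill", {
  s <- generate_study(noise = noise_spec("none"))
  f1 <- fit_dynamic_global(s, n_starts = 3, seed = 11)
  f2 <- fit_dynamic_global(s, n_starts = 3, seed = 11)
  expect_identical(f1$estimates, f2$estimates)
  expect_equal(f1$k, 5L)
  expect_equal(f1$n, 36L)
  expect_named(f1$per_arm_rss, letters[1:6])
  expect_equal(sum(f1$per_arm_rss), f1$rss, tolerance = 1e-8)
  expect_true(all(f1$rss <= f1$starts$rss_start + 1e-9))
  expect_equal(f1$aic, aic_rss(f1$rss, 36, 5))
})

test_that("holding the half-saturation volume fixed gives the four-parameter variant", {
  s <- generate_study(noise = noise_spec("none"))
  f <- fit_dynamic_global(s, n_starts = 2, seed = 5, fit_KV = FALSE)
  expect_equal(f$k, 4L)
  expect_false("K_V" %in% names(f$estimates))
  ep_hat <- fitted_epsilon_params(f)
  expect_equal(ep_hat$K_V, ep0$K_V)
})
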