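#' Read an arm-level tumor-volume CSV
#'
#' Expects a UTF-8 comma-separated file with header exactly
#' `arm,day,volume_mm3`. Malformed files are rejected with the offending
#' line number.
#'
#' @param path CSV file path.
#' @return A tibble with columns `arm` (character), `day`, `volume_mm3`,
#'   sorted by arm and day.
#' @export
read_arm_data <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (!identical(names(raw), c("arm", "day", "volume_mm3"))) {
    rlang::abort(sprintf(
      "malformed data CSV '%s' at line 1: header must be 'arm,day,volume_mm3' (got '%s').",
      path, paste(names(raw), collapse = ",")))
  }
  for (col in c("day", "volume_mm3")) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(vals) & !is.na(raw[[col]]))
    if (length(bad) > 0 || anyNA(raw[[col]])) {
      line <- (c(bad, which(is.na(raw[[col]])))[1]) + 1L
      rlang::abort(sprintf("malformed data CSV '%s' at line %d: non-numeric `%s` field.",
                           path, line, col))
    }
    raw[[col]] <- vals
  }
  as_arm_data(tibble::as_tibble(raw))
}

#' Validate an arm-level dataset
#'
#' @param data A data frame with columns `arm`, `day`, `volume_mm3`.
#' @return The validated tibble, sorted by arm and day.
#' @export
as_arm_data <- function(data) {
  if (!is.data.frame(data) || !all(c("arm", "day", "volume_mm3") %in% names(data))) {
    rlang::abort("arm data must have columns arm, day, volume_mm3.")
  }
  if (any(!is.finite(data$day)) || any(data$day < 0)) rlang::abort("`day` must be nonnegative and finite.")
  if (any(!is.finite(data$volume_mm3)) || any(data$volume_mm3 < 0)) {
    rlang::abort("`volume_mm3` must be nonnegative and finite.")
  }
  dplyr::arrange(tibble::as_tibble(data), .data$arm, .data$day)
}

#' @rdname read_arm_data
#' @param data A validated arm dataset.
#' @export
write_arm_data <- function(data, path) {
  data <- as_arm_data(data)
  utils::write.csv(as.data.frame(data)[, c("arm", "day", "volume_mm3")], path, row.names = FALSE)
  invisible(path)
}

#' Residual sum of squares between observations and a simulated trajectory
#'
#' Interpolates the simulated tumor volume at each observation day
#' (linearly between grid points; exact when the grid contains the day) and
#' returns the unweighted sum of squared residuals. Tumor volume is the only
#' observed state.
#'
#' @param observed A tibble with columns `day` and `volume_mm3` (one arm).
#' @param simulated A [simulate_arm()] trajectory covering every observation
#'   day.
#' @return Residual sum of squares (mm^6).
#' @examples
#' traj <- simulate_arm("a")
#' obs <- tibble::tibble(day = c(0, 10), volume_mm3 = c(100, 300))
#' sse(obs, traj)
#' @export
sse <- function(observed, simulated) {
  if (!all(c("day", "volume_mm3") %in% names(observed))) {
    rlang::abort("`observed` must have columns day and volume_mm3.")
  }
  tr <- range(simulated$time_day)
  if (any(observed$day < tr[1]) || any(observed$day > tr[2])) {
    rlang::abort("observation day outside the simulated window.")
  }
  pred <- stats::approx(simulated$time_day, simulated$V_mm3, xout = observed$day)$y
  sum((observed$volume_mm3 - pred)^2)
}

.sim_V_at <- function(arm, days, base, epsilon, mode, v0, t0_cells, rtol, atol) {
  traj <- simulate_arm(arm, base = base, epsilon = epsilon, mode = mode,
                       t_end = max(days), v0 = v0, t0_cells = t0_cells,
                       times = days, rtol = rtol, atol = atol)
  stats::approx(traj$time_day, traj$V_mm3, xout = days)$y
}

.lhs_starts <- function(n_starts, lower, upper, seed) {
  # log-uniform Latin hypercube over the box [lower, upper]
  d <- length(lower)
  u <- withr::with_seed(seed, lhs::randomLHS(n_starts, d))
  t(log(lower) + t(u) * (log(upper) - log(lower)))
}

new_pdl1_fit <- function(estimates, rss, n, k, converged, n_starts, seed,
                         mode, starts, per_arm_rss = NULL, arms = NULL,
                         fit_KV = NA) {
  structure(list(
    estimates = estimates, rss = rss, n = as.integer(n), k = as.integer(k),
    aic = aic_rss(rss, n, k), converged = converged,
    n_starts = n_starts, seed = seed, mode = mode,
    starts = starts, per_arm_rss = per_arm_rss, arms = arms,
    fit_KV = fit_KV), class = "pdl1_fit")
}

#' @export
print.pdl1_fit <- function(x, ...) {
  cat(sprintf("<pdl1_fit> %s-epsilon model: n = %d, k = %d\n", x$mode, x$n, x$k))
  cat(sprintf("  RSS = %.4g   AIC = %.3f   converged = %s (%d multistarts, seed %d)\n",
              x$rss, x$aic, x$converged, x$n_starts, x$seed))
  print(tidy(x), n = Inf)
  invisible(x)
}

#' @method tidy pdl1_fit
#' @export
tidy.pdl1_fit <- function(x, ...) {
  tibble::tibble(term = names(x$estimates),
                 estimate = unname(x$estimates))
}

#' @method glance pdl1_fit
#' @export
glance.pdl1_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, n = x$n, k = x$k, aic = x$aic,
                 converged = x$converged, n_starts = x$n_starts, seed = x$seed)
}

.run_multistart <- function(starts_log, residual_fn, lower_log, upper_log, maxiter = 100) {
  runs <- vector("list", nrow(starts_log))
  for (i in seq_len(nrow(starts_log))) {
    th0 <- starts_log[i, ]
    rss0 <- sum(residual_fn(th0)^2)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = th0, fn = residual_fn,
                         lower = lower_log, upper = upper_log,
                         control = minpack.lm::nls.lm.control(maxiter = maxiter)),
      error = function(e) NULL)
    if (is.null(fit)) {
      runs[[i]] <- list(par = th0, rss = rss0, rss0 = rss0, converged = FALSE)
    } else {
      runs[[i]] <- list(par = fit$par, rss = fit$deviance, rss0 = rss0,
                        converged = fit$info %in% 1:3)
    }
  }
  runs
}

#' Fit the constant-expression model to one treatment arm
#'
#' Bounded nonlinear least squares over the single scalar `eps` of the
#' constant-expression model, minimizing the unweighted SSE between the
#' observed tumor volumes of one arm and the simulated trajectory
#' (`k = 1` fitted parameter). The best of `n_starts` seeded log-uniform
#' Latin-hypercube multistarts is returned; results are deterministic given
#' `(seed, data, configuration)`.
#'
#' @param data Tibble with columns `arm`, `day`, `volume_mm3` for a single
#'   arm (at least two observations).
#' @param arm The [treatment_arm()] to simulate; defaults to the standard
#'   arm matching the `arm` label in `data`.
#' @param base A [base_params()] object (held fixed).
#' @param bounds Length-2 search interval for `eps`; default
#'   `c(1e-4, 1e4) * eps_nominal` with `eps_nominal` the pre-treatment
#'   quasi-steady state of the default expression parameters.
#' @param n_starts Number of multistarts (default 20).
#' @param seed RNG seed for the multistart design (default 0).
#' @param v0,t0_cells,rtol,atol,study Passed to [simulate_arm()].
#' @return A `pdl1_fit` object (see [tidy()] / [glance()] methods).
#' @export
fit_constant_epsilon <- function(data, arm = NULL, base = base_params(),
                                 bounds = NULL, n_starts = 20, seed = 0,
                                 v0 = 100, t0_cells = NULL,
                                 rtol = 1e-8, atol = 1e-10, study = "EMT6") {
  data <- as_arm_data(data)
  labs <- unique(data$arm)
  if (length(labs) != 1L) rlang::abort("`data` must contain exactly one arm for a constant-epsilon fit.")
  if (nrow(data) < 2L) rlang::abort("need at least two observations to fit epsilon.")
  arm <- .as_arm(arm %||% labs, study)
  base <- .as_base_params(base)
  nominal <- epsilon_qss_init(v0, epsilon_params())
  bounds <- bounds %||% (c(1e-4, 1e4) * nominal)
  if (length(bounds) != 2L || any(bounds <= 0) || bounds[1] >= bounds[2]) {
    rlang::abort("`bounds` must be a positive increasing length-2 interval.")
  }
  days <- data$day
  resid_fn <- function(theta_log) {
    pred <- tryCatch(
      .sim_V_at(arm, days, base, exp(theta_log), "constant", v0, t0_cells, rtol, atol),
      error = function(e) NULL)
    if (is.null(pred)) return(rep(1e6, nrow(data)))
    data$volume_mm3 - pred
  }
  starts <- .lhs_starts(n_starts, bounds[1], bounds[2], seed)
  runs <- .run_multistart(starts, resid_fn, log(bounds[1]), log(bounds[2]))
  best <- runs[[which.min(vapply(runs, `[[`, 0, "rss"))]]
  starts_tbl <- tibble::tibble(
    start = exp(starts[, 1]),
    rss_start = vapply(runs, `[[`, 0, "rss0"),
    rss_final = vapply(runs, `[[`, 0, "rss"),
    converged = vapply(runs, `[[`, TRUE, "converged"))
  if (!any(starts_tbl$converged)) rlang::abort("no multistart converged; check data and bounds.")
  new_pdl1_fit(estimates = c(epsilon = unname(exp(best$par))),
               rss = best$rss, n = nrow(data), k = 1L,
               converged = best$converged, n_starts = n_starts, seed = seed,
               mode = "constant", starts = starts_tbl, arms = list(arm))
}

#' Fit the dynamic-expression model globally across all arms
#'
#' Simultaneous bounded nonlinear least squares over the parameters of the
#' dynamic PD-L1 expression equation (`k_basal`, `K_V`, `alpha_A1`,
#' `alpha_A2`, `d_eps`), minimizing the joint unweighted SSE over every
#' observation of all treatment arms (36 residuals at the standard design).
#' With `fit_KV = FALSE` the half-saturation volume `K_V` is held at its
#' nominal value and `k = 4`. Optimization runs in log-parameter space with
#' Levenberg-Marquardt least squares from `n_starts` seeded log-uniform
#' Latin-hypercube starts; deterministic given `seed`.
#'
#' @param data Tibble with columns `arm`, `day`, `volume_mm3` covering the
#'   six arms (each with at least two observations).
#' @param arms Named list of [treatment_arm()] objects matching the arm
#'   labels in `data`; defaults to [standard_arms()] of `study`.
#' @param base A [base_params()] object (held fixed; not refitted).
#' @param nominal An [epsilon_params()] object setting the per-parameter
#'   nominal scales for bounds and the fixed `K_V` when `fit_KV = FALSE`.
#' @param bounds Two-row matrix (lower/upper) or `NULL` for the default
#'   `[1e-4, 1e4]` times each nominal value.
#' @param n_starts Number of multistarts (default 20).
#' @param seed RNG seed (default 0).
#' @param fit_KV Fit `K_V` (`k = 5`, default) or hold it fixed (`k = 4`).
#' @param allow_partial Permit a study with fewer than six arms.
#' @param v0,t0_cells,rtol,atol,study Passed to [simulate_arm()].
#' @return A `pdl1_fit` object with per-arm residual sums in `per_arm_rss`.
#' @export
fit_dynamic_global <- function(data, arms = NULL, base = base_params(),
                               nominal = epsilon_params(), bounds = NULL,
                               n_starts = 20, seed = 0, fit_KV = TRUE,
                               allow_partial = FALSE,
                               v0 = 100, t0_cells = NULL,
                               rtol = 1e-8, atol = 1e-10, study = "EMT6") {
  data <- as_arm_data(data)
  base <- .as_base_params(base)
  nominal <- .as_epsilon_params(nominal)
  labs <- sort(unique(data$arm))
  if (length(labs) != 6L && !allow_partial) {
    rlang::abort(sprintf("global dynamic fit expects 6 arms, got %d (set allow_partial = TRUE to override).",
                         length(labs)))
  }
  arms <- arms %||% standard_arms(study)[labs]
  if (!all(labs %in% names(arms))) rlang::abort("`arms` must cover every arm label in `data`.")
  by_arm <- split(data, data$arm)
  if (any(vapply(by_arm, nrow, 0L) < 2L)) rlang::abort("every arm needs at least two observations.")

  all_events <- dplyr::bind_rows(lapply(arms[labs], `[[`, "events"))
  if (!any(all_events$drug == "Avelumab")) {
    rlang::abort("no Avelumab dose in any arm: `alpha_A1` is structurally unidentifiable.")
  }
  if (!any(all_events$drug == "NHS-muIL12")) {
    rlang::abort("no NHS-muIL12 dose in any arm: `alpha_A2` is structurally unidentifiable.")
  }

  par_names <- if (fit_KV) .eps_fields else setdiff(.eps_fields, "K_V")
  nom <- unlist(nominal[par_names], use.names = FALSE)
  if (is.null(bounds)) {
    lower <- 1e-4 * nom
    upper <- 1e4 * nom
  } else {
    if (!is.matrix(bounds) || nrow(bounds) != 2L || ncol(bounds) != length(par_names)) {
      rlang::abort(sprintf("`bounds` must be a 2 x %d matrix (lower row, upper row).", length(par_names)))
    }
    lower <- bounds[1, ]; upper <- bounds[2, ]
  }
  if (any(lower <= 0) || any(upper <= lower)) rlang::abort("bounds must be positive with upper > lower.")

  n_obs <- nrow(data)
  make_eps <- function(theta) {
    vals <- as.list(stats::setNames(theta, par_names))
    if (!fit_KV) vals$K_V <- nominal$K_V
    do.call(epsilon_params, vals[.eps_fields])
  }
  resid_arm <- function(eps_pars, lab) {
    d <- by_arm[[lab]]
    pred <- .sim_V_at(arms[[lab]], d$day, base, eps_pars, "dynamic", v0, t0_cells, rtol, atol)
    d$volume_mm3 - pred
  }
  resid_fn <- function(theta_log) {
    eps_pars <- tryCatch(make_eps(exp(theta_log)), error = function(e) NULL)
    if (is.null(eps_pars)) return(rep(1e6, n_obs))
    out <- tryCatch(unlist(lapply(labs, function(l) resid_arm(eps_pars, l)), use.names = FALSE),
                    error = function(e) NULL)
    if (is.null(out) || any(!is.finite(out))) return(rep(1e6, n_obs))
    out
  }

  starts <- .lhs_starts(n_starts, lower, upper, seed)
  runs <- .run_multistart(starts, resid_fn, log(lower), log(upper))
  best <- runs[[which.min(vapply(runs, `[[`, 0, "rss"))]]
  if (!any(vapply(runs, `[[`, TRUE, "converged"))) {
    rlang::abort("no multistart converged; check data, bounds, and identifiability.")
  }
  est <- stats::setNames(exp(best$par), par_names)
  eps_hat <- make_eps(est)
  per_arm <- vapply(labs, function(l) sum(resid_arm(eps_hat, l)^2), 0)
  starts_tbl <- tibble::tibble(
    start = lapply(seq_len(n_starts), function(i) stats::setNames(exp(starts[i, ]), par_names)),
    rss_start = vapply(runs, `[[`, 0, "rss0"),
    rss_final = vapply(runs, `[[`, 0, "rss"),
    converged = vapply(runs, `[[`, TRUE, "converged"))
  new_pdl1_fit(estimates = est, rss = best$rss, n = n_obs,
               k = length(par_names), converged = best$converged,
               n_starts = n_starts, seed = seed, mode = "dynamic",
               starts = starts_tbl, per_arm_rss = stats::setNames(per_arm, labs),
               arms = arms[labs], fit_KV = fit_KV)
}

#' Extract the fitted expression parameters from a dynamic fit
#'
#' @param fit A `pdl1_fit` from [fit_dynamic_global()].
#' @param nominal Source of `K_V` when the fit held it fixed.
#' @return An [epsilon_params()] object.
#' @export
fitted_epsilon_params <- function(fit, nominal = epsilon_params()) {
  if (!inherits(fit, "pdl1_fit") || fit$mode != "dynamic") {
    rlang::abort("`fit` must be a dynamic-model pdl1_fit.")
  }
  vals <- as.list(fit$estimates)
  if (!isTRUE(fit$fit_KV)) vals$K_V <- .as_epsilon_params(nominal)$K_V
  do.call(epsilon_params, vals[.eps_fields])
}
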