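.sweep_default_parameters <- c("k_basal", "alpha_A1", "alpha_A2", "K_A1", "K_A2",
                               "d_eps", "K_V", "d_A1", "d_A2")

.perturb_params <- function(base, epsilon, name, factor) {
  if (name %in% .base_fields) {
    base[[name]] <- base[[name]] * factor
    base <- do.call(base_params, unclass(base))
  } else if (name %in% .eps_fields) {
    epsilon[[name]] <- epsilon[[name]] * factor
    epsilon <- do.call(epsilon_params, unclass(epsilon)[.eps_fields])
  } else {
    rlang::abort(sprintf("unknown parameter name '%s'.", name))
  }
  list(base = base, epsilon = epsilon)
}

#' Local sensitivity sweep over treatment modes
#'
#' Perturbs each named parameter by `+frac` and `-frac` (relative), then
#' re-simulates every treatment arm in dynamic-expression mode and records
#' the final tumor volume and its outcome class. The default call covers
#' the seven expression/affinity parameters plus the two pharmacokinetic
#' clearance rates across all six arms: 9 parameters x 2 signs x 6 arms =
#' 108 simulations. The sweep is a pure function of its inputs; rerunning
#' yields identical records.
#'
#' @param base A [base_params()] object (nominal).
#' @param epsilon An [epsilon_params()] object (nominal).
#' @param parameters Character vector of parameter names to perturb.
#' @param frac Relative perturbation in `[0, 1)`; `frac = 0` reproduces the
#'   nominal trajectory for every record.
#' @param arms Named list of [treatment_arm()] objects (default the six
#'   standard EMT6 arms).
#' @param t_end,v0,step,rtol,atol Passed to [simulate_arm()].
#' @param elimination_threshold Volume cut-off for [final_outcome()].
#' @return A tibble with columns `parameter`, `perturbation` (signed
#'   fraction), `arm`, `final_V_mm3`, `outcome`.
#' @export
local_sweep <- function(base = base_params(), epsilon = epsilon_params(),
                        parameters = .sweep_default_parameters,
                        frac = 0.25, arms = standard_arms(),
                        t_end = 25, v0 = 100, step = 0.1,
                        rtol = 1e-8, atol = 1e-10,
                        elimination_threshold = 1) {
  if (!is.numeric(frac) || length(frac) != 1L || frac < 0 || frac >= 1) {
    rlang::abort("`frac` must be a single relative perturbation in [0, 1).")
  }
  bad <- setdiff(parameters, c(.base_fields, .eps_fields))
  if (length(bad) > 0) rlang::abort(sprintf("unknown parameter name(s): %s.", paste(bad, collapse = ", ")))
  grid <- tidyr::expand_grid(parameter = parameters, sign = c(-1, 1), arm = names(arms))
  rows <- purrr::pmap(grid, function(parameter, sign, arm) {
    p <- .perturb_params(base, epsilon, parameter, 1 + sign * frac)
    traj <- simulate_arm(arms[[arm]], base = p$base, epsilon = p$epsilon,
                         mode = "dynamic", t_end = t_end, v0 = v0, step = step,
                         rtol = rtol, atol = atol)
    out <- final_outcome(traj, elimination_threshold)
    tibble::tibble(parameter = parameter, perturbation = sign * frac, arm = arm,
                   final_V_mm3 = out$final_volume_mm3, outcome = out$outcome)
  })
  dplyr::bind_rows(rows)
}

#' Time-course sensitivity for one parameter in one arm
#'
#' Simulates the nominal system and the `+frac` / `-frac` perturbations of
#' a single parameter on a shared dense grid, returning the full tumor and
#' expression time courses with each variant's outcome class. Intended for
#' the high-dose combination arm, where elimination should be preserved
#' under moderate perturbation of the key mechanistic parameters.
#'
#' @param param Parameter name (any base or expression parameter).
#' @param arm A [treatment_arm()] or label; default the high-dose
#'   combination arm `"f"`.
#' @param frac Relative perturbation in `(0, 1)` (default 0.25).
#' @inheritParams local_sweep
#' @return A tibble of class `pdl1_sens_tc` in long format with columns
#'   `variant` (`nominal`, `plus`, `minus`), `time_day`, `V_mm3`, `eps`;
#'   attribute `outcomes` holds one row per variant with `final_V_mm3` and
#'   `outcome`.
#' @export
timecourse_sensitivity <- function(param, arm = "f", frac = 0.25,
                                   base = base_params(), epsilon = epsilon_params(),
                                   t_end = 25, v0 = 100, step = 0.1,
                                   rtol = 1e-8, atol = 1e-10,
                                   elimination_threshold = 1) {
  if (!is.numeric(frac) || length(frac) != 1L || frac <= 0 || frac >= 1) {
    rlang::abort("`frac` must be a single relative perturbation in (0, 1).")
  }
  arm <- .as_arm(arm)
  variants <- list(nominal = 1, plus = 1 + frac, minus = 1 - frac)
  sims <- purrr::imap(variants, function(factor, label) {
    p <- .perturb_params(base, epsilon, param, factor)
    traj <- simulate_arm(arm, base = p$base, epsilon = p$epsilon, mode = "dynamic",
                         t_end = t_end, v0 = v0, step = step, rtol = rtol, atol = atol)
    list(traj = traj, outcome = final_outcome(traj, elimination_threshold))
  })
  long <- dplyr::bind_rows(purrr::imap(sims, function(s, label) {
    tibble::tibble(variant = label, time_day = s$traj$time_day,
                   V_mm3 = s$traj$V_mm3, eps = s$traj$eps)
  }))
  outcomes <- dplyr::bind_rows(purrr::imap(sims, function(s, label) {
    dplyr::mutate(s$outcome, variant = label, .before = 1)
  }))
  structure(long, class = c("pdl1_sens_tc", class(long)),
            parameter = param, frac = frac, arm = arm, outcomes = outcomes)
}

#' Export a sensitivity sweep to CSV
#'
#' @param sweep A [local_sweep()] result.
#' @param path Output file path.
#' @export
write_sweep <- function(sweep, path) {
  utils::write.csv(as.data.frame(sweep), path, row.names = FALSE)
  invisible(path)
}
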