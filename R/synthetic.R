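#' Study design for synthetic data generation
#'
#' Describes the experimental layout emulated by [generate_study()]: the
#' six standard treatment arms of the chosen study, the per-arm observation
#' days, and the initial tumor volume. Defaults give six observations per
#' arm at days 0, 5, 10, 15, 20, 25 (36 observations total) starting from
#' 100 mm^3.
#'
#' @param study `"EMT6"` or `"MC38"` (selects the arm library).
#' @param days Observation days shared by all arms.
#' @param v0 Initial tumor volume (mm^3).
#' @return An object of class `pdl1_study_design`.
#' @export
study_design <- function(study = c("EMT6", "MC38"),
                         days = c(0, 5, 10, 15, 20, 25), v0 = 100) {
  study <- match.arg(study)
  if (!is.numeric(days) || length(days) < 2L || any(!is.finite(days)) || any(days < 0)) {
    rlang::abort("`days` must be at least two nonnegative observation days.")
  }
  if (!is.numeric(v0) || length(v0) != 1L || v0 <= 0) rlang::abort("`v0` must be positive.")
  structure(list(study = study, arms = standard_arms(study),
                 days = sort(unique(days)), v0 = v0),
            class = "pdl1_study_design")
}

#' Observation-noise specification
#'
#' @param kind `"lognormal_multiplicative"` (default; measurement error
#'   scales with tumor size), `"gaussian_additive"`, or `"none"`.
#' @param sigma Dispersion: the log-scale standard deviation for
#'   multiplicative noise, or the additive standard deviation in mm^3.
#' @param seed Default RNG seed used by [generate_study()].
#' @return An object of class `pdl1_noise_spec`.
#' @export
noise_spec <- function(kind = c("lognormal_multiplicative", "gaussian_additive", "none"),
                       sigma = 0.1, seed = 0) {
  kind <- match.arg(kind)
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma < 0) {
    rlang::abort("`sigma` must be a single nonnegative number.")
  }
  structure(list(kind = kind, sigma = sigma, seed = seed), class = "pdl1_noise_spec")
}

.apply_noise <- function(v, noise) {
  switch(noise$kind,
         none = v,
         lognormal_multiplicative = v * exp(stats::rnorm(length(v), 0, noise$sigma)),
         gaussian_additive = pmax(0, v + stats::rnorm(length(v), 0, noise$sigma)))
}

#' Generate a synthetic study with known ground truth
#'
#' Simulates every arm of the design in dynamic-expression mode at the
#' supplied (true) parameters, samples the tumor volume at the observation
#' days, and applies observation noise. The result stands in for the
#' digitized mouse data of the original experiments and is reproducible
#' given the seed.
#'
#' @param base A [base_params()] object (truth).
#' @param epsilon An [epsilon_params()] object (truth).
#' @param design A [study_design()].
#' @param noise A [noise_spec()].
#' @param seed RNG seed; defaults to the seed recorded in `noise`.
#' @param rtol,atol Integrator tolerances.
#' @return A tibble with columns `arm`, `day`, `volume_mm3` (volumes
#'   truncated at zero), carrying the generation settings in attributes
#'   `truth_base`, `truth_epsilon`, `design`, `noise`, `seed`.
#' @examples
#' head(generate_study(noise = noise_spec("none")))
#' @export
generate_study <- function(base = base_params(), epsilon = epsilon_params(),
                           design = study_design(), noise = noise_spec(),
                           seed = NULL, rtol = 1e-8, atol = 1e-10) {
  if (!inherits(design, "pdl1_study_design")) rlang::abort("`design` must come from study_design().")
  if (!inherits(noise, "pdl1_noise_spec")) rlang::abort("`noise` must come from noise_spec().")
  seed <- seed %||% noise$seed
  base <- .as_base_params(base)
  epsilon <- .as_epsilon_params(epsilon)
  sim_one <- function(lab) {
    v <- .sim_V_at(design$arms[[lab]], design$days, base, epsilon, "dynamic",
                   design$v0, NULL, rtol, atol)
    tibble::tibble(arm = lab, day = design$days, volume_mm3 = v)
  }
  clean <- dplyr::bind_rows(lapply(names(design$arms), sim_one))
  noisy <- withr::with_seed(seed, .apply_noise(clean$volume_mm3, noise))
  out <- dplyr::mutate(clean, volume_mm3 = pmax(0, noisy))
  structure(as_arm_data(out),
            truth_base = base, truth_epsilon = epsilon,
            design = design, noise = noise, seed = seed)
}

#' Write a synthetic study and its manifest
#'
#' Emits the same `arm,day,volume_mm3` CSV consumed by the fitting module,
#' plus a JSON manifest recording the true parameters, design, noise model,
#' and seed.
#'
#' @param study A [generate_study()] result.
#' @param path CSV output path; the manifest is written alongside with the
#'   extension `.manifest.json`.
#' @return The CSV path, invisibly.
#' @export
write_study <- function(study, path) {
  write_arm_data(study, path)
  design <- attr(study, "design")
  manifest <- list(
    truth_base = unclass(attr(study, "truth_base")),
    truth_epsilon = unclass(attr(study, "truth_epsilon")),
    study = design$study,
    days = design$days,
    v0 = design$v0,
    noise = unclass(attr(study, "noise")),
    seed = attr(study, "seed"))
  jsonlite::write_json(manifest, sub("\\.csv$", "", path) |> paste0(".manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Parameter-recovery experiment for the dynamic-expression fit
#'
#' For each noise level, generates `reps` synthetic studies at the true
#' parameters, refits the dynamic-expression model to each, and summarizes
#' the per-parameter recovery error. Non-converged replicates are recorded,
#' not hidden.
#'
#' @param truth An [epsilon_params()] object (generating values).
#' @param base A [base_params()] object (fixed in both generation and fit).
#' @param design A [study_design()].
#' @param noise_levels Numeric vector of noise sigmas; level 0 uses
#'   noiseless data, any other level uses multiplicative lognormal noise.
#' @param reps Replicates per noise level (>= 1).
#' @param seed Base RNG seed; replicate `j` of level `i` uses
#'   `seed + 1000*i + j`.
#' @param n_starts Multistarts per fit (default 5).
#' @param fit_KV Passed to [fit_dynamic_global()].
#' @return A tibble with one row per (noise level, parameter):
#'   `noise_sigma`, `parameter`, `truth`, `bias_rel` (mean relative error),
#'   `rmse_rel`, `median_abs_rel_err`, `n_reps`, `n_converged`. The full
#'   per-replicate estimates are in the `details` attribute.
#' @export
recovery_experiment <- function(truth = epsilon_params(), base = base_params(),
                                design = study_design(), noise_levels = c(0, 0.1),
                                reps = 1, seed = 0, n_starts = 5, fit_KV = TRUE) {
  if (!is.numeric(reps) || length(reps) != 1L || reps < 1) {
    rlang::abort("`reps` must be at least 1.")
  }
  truth <- .as_epsilon_params(truth)
  par_names <- if (fit_KV) .eps_fields else setdiff(.eps_fields, "K_V")
  details <- list()
  for (i in seq_along(noise_levels)) {
    sg <- noise_levels[i]
    nz <- if (sg == 0) noise_spec("none", 0) else noise_spec("lognormal_multiplicative", sg)
    for (j in seq_len(reps)) {
      rep_seed <- seed + 1000L * i + j
      data <- generate_study(base, truth, design, nz, seed = rep_seed)
      fit <- tryCatch(
        fit_dynamic_global(data, arms = design$arms, base = base, nominal = truth,
                           n_starts = n_starts, seed = rep_seed, fit_KV = fit_KV,
                           v0 = design$v0, study = design$study),
        error = function(e) NULL)
      details[[length(details) + 1L]] <- tibble::tibble(
        noise_sigma = sg, rep = j, parameter = par_names,
        truth = unlist(truth[par_names], use.names = FALSE),
        estimate = if (is.null(fit)) NA_real_ else unname(fit$estimates[par_names]),
        converged = if (is.null(fit)) FALSE else fit$converged)
    }
  }
  details <- dplyr::bind_rows(details)
  details <- dplyr::mutate(details, rel_err = (.data$estimate - .data$truth) / .data$truth)
  summary <- details |>
    dplyr::group_by(.data$noise_sigma, .data$parameter) |>
    dplyr::summarise(
      truth = .data$truth[1],
      bias_rel = mean(.data$rel_err, na.rm = TRUE),
      rmse_rel = sqrt(mean(.data$rel_err^2, na.rm = TRUE)),
      median_abs_rel_err = stats::median(abs(.data$rel_err), na.rm = TRUE),
      n_reps = dplyr::n(),
      n_converged = sum(.data$converged),
      .groups = "drop")
  structure(summary, details = details)
}
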