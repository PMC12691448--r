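#' Convert a drug half-life to a first-order clearance rate
#'
#' Bolus drugs are cleared exponentially, so the clearance rate is
#' `ln(2) / t_half`. The package defaults use the murine half-lives of
#' Avelumab (1.86 days) and NHS-muIL12 (9.5 days), giving clearance rates
#' of about 0.3726 and 0.0730 per day.
#'
#' @param t_half Half-life in days; strictly positive.
#' @return Clearance rate in day^-1.
#' @examples
#' decay_rate_from_half_life(1.86)
#' @export
decay_rate_from_half_life <- function(t_half) {
  if (!is.numeric(t_half) || any(!is.finite(t_half)) || any(t_half <= 0)) {
    rlang::abort("`t_half` must be a finite, strictly positive number of days.")
  }
  log(2) / t_half
}

.base_fields <- c("r", "eta", "delta", "lambda_T", "d_T", "c1", "c2",
                  "K_A1", "K_A2", "K_TQ", "q0", "d_A1", "d_A2")
.eps_fields <- c("k_basal", "K_V", "alpha_A1", "alpha_A2", "d_eps")

.check_positive_fields <- function(x, fields, what) {
  for (f in fields) {
    v <- x[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      rlang::abort(sprintf("%s field `%s` must be a single finite positive number.", what, f))
    }
  }
  invisible(x)
}

#' Base tumor-immune model parameters
#'
#' Rate and saturation constants of the four-state system (tumor volume V,
#' effector T-cell volume T, Avelumab A1, NHS-muIL12 A2). Defaults are the
#' package's nominal EMT6 configuration: the drug affinities `K_A1`, `K_A2`,
#' the T-cell stimulation ceiling `lambda_T`, and the murine clearance rates
#' `d_A1`, `d_A2` are literature values; the remaining constants are nominal
#' choices calibrated to the qualitative EMT6 treatment outcomes (see the
#' methods vignette) and are all overridable.
#'
#' @param r Tumor intrinsic growth rate (day^-1).
#' @param eta T-cell kill rate of tumor cells (mm^-3 day^-1, mass action).
#' @param delta Basal T-cell production (mm^3 day^-1).
#' @param lambda_T Maximum T-cell stimulation rate by NHS-muIL12 (day^-1).
#' @param d_T T-cell decay rate (day^-1).
#' @param c1,c2 Dose-amount to effective-concentration scale factors for
#'   Avelumab and NHS-muIL12 (per microgram).
#' @param K_A1,K_A2 Half-saturation constants of the Avelumab blockade and
#'   NHS-muIL12 stimulation responses (effective-concentration units).
#' @param K_TQ Half-saturation of T-cell suppression by the PD-1/PD-L1
#'   complex Q.
#' @param q0 Composite complex coefficient (the product of the complex
#'   association fraction and the PD-1 and PD-L1 expression levels, which
#'   enter the model only through this product).
#' @param d_A1,d_A2 Drug clearance rates (day^-1); defaults derive from the
#'   murine half-lives 1.86 and 9.5 days via [decay_rate_from_half_life()].
#' @return A validated named list of class `pdl1_base_params`.
#' @examples
#' base_params()
#' base_params(r = 0.2)
#' @export
base_params <- function(r = 0.13,
                        eta = 0.05,
                        delta = 0.35,
                        lambda_T = 4.15,
                        d_T = 0.35,
                        c1 = 1e-15,
                        c2 = 3.5e-14,
                        K_A1 = 1e-13,
                        K_A2 = 7e-14,
                        K_TQ = 200,
                        q0 = 0.1,
                        d_A1 = decay_rate_from_half_life(1.86),
                        d_A2 = decay_rate_from_half_life(9.5)) {
  p <- list(r = r, eta = eta, delta = delta, lambda_T = lambda_T, d_T = d_T,
            c1 = c1, c2 = c2, K_A1 = K_A1, K_A2 = K_A2, K_TQ = K_TQ, q0 = q0,
            d_A1 = d_A1, d_A2 = d_A2)
  .check_positive_fields(p, .base_fields, "base_params")
  structure(p, class = "pdl1_base_params")
}

#' Parameters of the dynamic PD-L1 expression equation
#'
#' The five constants governing the fifth state variable, the tumor's
#' functional immunosuppressive strength (effective PD-L1 expression
#' propensity) `eps`. Defaults are the EMT6 global fit; `study = "MC38"`
#' selects the refitted MC38 values. Explicit arguments override either
#' preset.
#'
#' @param k_basal Maximum basal production rate (day^-1).
#' @param K_V Half-saturation tumor volume of the production terms (mm^3).
#' @param alpha_A1 Maximum Avelumab-mediated suppression rate (day^-1).
#' @param alpha_A2 Maximum NHS-muIL12-driven production rate (day^-1).
#' @param d_eps Natural decay rate (day^-1).
#' @param study Preset supplying the defaults: `"EMT6"` or `"MC38"`.
#' @return A validated named list of class `pdl1_epsilon_params`.
#' @examples
#' epsilon_params()
#' epsilon_params(study = "MC38")
#' @export
epsilon_params <- function(k_basal = NULL, K_V = NULL, alpha_A1 = NULL,
                           alpha_A2 = NULL, d_eps = NULL,
                           study = c("EMT6", "MC38")) {
  study <- match.arg(study)
  preset <- switch(study,
    EMT6 = list(k_basal = 30.5441, K_V = 50, alpha_A1 = 38.2653,
                alpha_A2 = 643.6397, d_eps = 0.4409),
    MC38 = list(k_basal = 12.64, K_V = 462.70, alpha_A1 = 3.72,
                alpha_A2 = 1990.17, d_eps = 0.10))
  p <- list(k_basal = k_basal %||% preset$k_basal,
            K_V = K_V %||% preset$K_V,
            alpha_A1 = alpha_A1 %||% preset$alpha_A1,
            alpha_A2 = alpha_A2 %||% preset$alpha_A2,
            d_eps = d_eps %||% preset$d_eps)
  .check_positive_fields(p, .eps_fields, "epsilon_params")
  structure(p, class = "pdl1_epsilon_params")
}

#' @export
print.pdl1_base_params <- function(x, ...) {
  cat("<pdl1_base_params>\n")
  print(tibble::tibble(parameter = names(x), value = unlist(x, use.names = FALSE)), n = Inf)
  invisible(x)
}

#' @export
print.pdl1_epsilon_params <- function(x, ...) {
  cat("<pdl1_epsilon_params>\n")
  print(tibble::tibble(parameter = names(x), value = unlist(x, use.names = FALSE)), n = Inf)
  invisible(x)
}

.as_base_params <- function(x) {
  if (inherits(x, "pdl1_base_params")) return(x)
  if (is.list(x) && all(.base_fields %in% names(x))) {
    return(do.call(base_params, x[.base_fields]))
  }
  rlang::abort("expected `pdl1_base_params` (see `base_params()`).")
}

.as_epsilon_params <- function(x) {
  if (inherits(x, "pdl1_epsilon_params")) return(x)
  if (is.list(x) && all(.eps_fields %in% names(x))) {
    return(do.call(epsilon_params, x[.eps_fields]))
  }
  rlang::abort("expected `pdl1_epsilon_params` (see `epsilon_params()`).")
}

#' Read and write flat parameter configuration files
#'
#' Parameters are serialized as a flat key-value YAML mapping whose keys are
#' exactly the field names of [base_params()] and [epsilon_params()]. Keys
#' belonging to neither parameter set cause an error on read.
#'
#' @param path File path of the YAML configuration.
#' @return `read_params_config()` returns a list with elements `base`
#'   (`pdl1_base_params`) and `epsilon` (`pdl1_epsilon_params`, or `NULL` if
#'   the file holds no dynamic-expression keys).
#' @export
read_params_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) rlang::abort("configuration file must be a flat key-value mapping.")
  unknown <- setdiff(names(cfg), c(.base_fields, .eps_fields))
  if (length(unknown) > 0) {
    rlang::abort(sprintf("unknown configuration keys: %s", paste(unknown, collapse = ", ")))
  }
  base <- do.call(base_params, cfg[intersect(names(cfg), .base_fields)])
  eps_keys <- intersect(names(cfg), .eps_fields)
  epsilon <- if (length(eps_keys) > 0) do.call(epsilon_params, cfg[eps_keys]) else NULL
  list(base = base, epsilon = epsilon)
}

#' @rdname read_params_config
#' @param base A `pdl1_base_params` object.
#' @param epsilon A `pdl1_epsilon_params` object, or `NULL` to omit.
#' @export
write_params_config <- function(base, epsilon = NULL, path) {
  base <- .as_base_params(base)
  out <- unclass(base)
  if (!is.null(epsilon)) out <- c(out, unclass(.as_epsilon_params(epsilon)))
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}
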