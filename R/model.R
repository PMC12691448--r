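#' @keywords internal
"_PACKAGE"

#' @useDynLib pdl1dyn
#' @importFrom rlang %||% abort .data
#' @importFrom dplyr mutate filter select bind_rows arrange group_by summarise ungroup
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

.check_nonneg <- function(..., what = "input") {
  vals <- list(...)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || any(!is.finite(v))) {
      rlang::abort(sprintf("`%s` must be finite numeric.", nm))
    }
    if (any(v < 0)) {
      rlang::abort(sprintf("`%s` must be nonnegative.", nm))
    }
  }
  invisible(TRUE)
}

#' Avelumab blockade fraction
#'
#' Fraction of PD-1/PD-L1 complex formation blocked by the circulating
#' anti-PD-L1 antibody, a Michaelis-Menten response
#' `c1*a1 / (c1*a1 + K_A1)` in the drug amount `a1`. Strictly increasing in
#' `a1` and bounded in `[0, 1)`.
#'
#' @param a1 Avelumab amount (micrograms), nonnegative; vectorized.
#' @param params A [base_params()] object.
#' @return Blockade fraction(s) in `[0, 1)`.
#' @examples
#' blockade_fraction(200, base_params())
#' @export
blockade_fraction <- function(a1, params = base_params()) {
  params <- .as_base_params(params)
  .check_nonneg(a1 = a1)
  params$c1 * a1 / (params$c1 * a1 + params$K_A1)
}

#' PD-1/PD-L1 complex level
#'
#' Abundance of the inhibitory checkpoint complex,
#' `q0 * t * (t + eps*v) * (1 - blockade_fraction(a1))`: it grows with the
#' T-cell and tumor compartments (the latter weighted by the functional
#' PD-L1 expression `eps`) and is depleted by Avelumab blockade.
#'
#' @param v Tumor volume (mm^3).
#' @param t T-cell volume (mm^3).
#' @param a1 Avelumab amount (micrograms).
#' @param eps Functional PD-L1 expression propensity (dimensionless).
#' @param params A [base_params()] object.
#' @return Nonnegative complex level; nonincreasing in `a1`, nondecreasing
#'   in `eps`.
#' @export
checkpoint_complex <- function(v, t, a1, eps, params = base_params()) {
  params <- .as_base_params(params)
  .check_nonneg(v = v, t = t, a1 = a1, eps = eps)
  params$q0 * t * (t + eps * v) * (1 - blockade_fraction(a1, params))
}

#' T-cell production and stimulation rate
#'
#' The activation function combines basal production `delta` with saturating
#' NHS-muIL12 stimulation proportional to the T-cell volume, damped by
#' checkpoint suppression through `1 / (1 + Q/K_TQ)`:
#' `(delta + lambda_T*t*c2*a2/(K_A2 + c2*a2)) / (1 + Q/K_TQ)`.
#'
#' @inheritParams checkpoint_complex
#' @param a2 NHS-muIL12 amount (micrograms).
#' @return Production rate (mm^3 day^-1); decreasing in the complex level
#'   and bounded above by `delta + lambda_T*t`.
#' @export
tcell_activation <- function(v, t, a1, a2, eps, params = base_params()) {
  params <- .as_base_params(params)
  .check_nonneg(v = v, t = t, a1 = a1, a2 = a2, eps = eps)
  q <- checkpoint_complex(v, t, a1, eps, params)
  sat2 <- params$c2 * a2 / (params$K_A2 + params$c2 * a2)
  (params$delta + params$lambda_T * t * sat2) / (1 + q / params$K_TQ)
}

#' Right-hand side of the four-state base system
#'
#' Continuous dynamics between bolus doses: exponential tumor growth with
#' mass-action T-cell killing, T-cell production via [tcell_activation()]
#' with first-order decay, and first-order clearance of both drugs (dosing
#' enters as state jumps, not here).
#'
#' @param state Named numeric vector with components `V`, `T`, `A1`, `A2`
#'   (all nonnegative and finite).
#' @param params A [base_params()] object.
#' @param eps Functional PD-L1 expression held at this value.
#' @return Named vector of derivatives `(dV, dT, dA1, dA2)` (per day).
#' @examples
#' base_rhs(c(V = 100, T = 1, A1 = 0, A2 = 0), base_params(), eps = 46)
#' @export
base_rhs <- function(state, params = base_params(), eps) {
  params <- .as_base_params(params)
  if (!is.numeric(state) || length(state) < 4 || any(!is.finite(state[1:4]))) {
    rlang::abort("`state` must be a finite numeric vector (V, T, A1, A2).")
  }
  st <- if (!is.null(names(state)) && all(c("V", "T", "A1", "A2") %in% names(state))) {
    state[c("V", "T", "A1", "A2")]
  } else {
    stats::setNames(state[1:4], c("V", "T", "A1", "A2"))
  }
  .check_nonneg(state = unname(st))
  f <- tcell_activation(st[["V"]], st[["T"]], st[["A1"]], st[["A2"]], eps, params)
  c(dV = params$r * st[["V"]] - params$eta * st[["V"]] * st[["T"]],
    dT = f - params$d_T * st[["T"]],
    dA1 = -params$d_A1 * st[["A1"]],
    dA2 = -params$d_A2 * st[["A2"]])
}

#' Right-hand side of the dynamic PD-L1 expression equation
#'
#' Balance of production and loss for the functional immunosuppressive
#' strength `eps`: tumor-size-dependent basal production, NHS-muIL12-driven
#' production (adaptive immune resistance), Avelumab-mediated suppression,
#' and natural decay:
#' `k_basal*v/(K_V+v) + alpha_A2*(v/(K_V+v))*(c2*a2/(K_A2+c2*a2))
#'  - alpha_A1*(c1*a1/(K_A1+c1*a1))*eps - d_eps*eps`.
#'
#' @param eps Current expression propensity (dimensionless).
#' @param v Tumor volume (mm^3).
#' @param a1,a2 Drug amounts (micrograms).
#' @param epsilon An [epsilon_params()] object.
#' @param base A [base_params()] object (supplies `c1`, `c2`, `K_A1`, `K_A2`).
#' @return d(eps)/dt (day^-1).
#' @examples
#' epsilon_rhs(0, v = 100, a1 = 0, a2 = 0)
#' @export
epsilon_rhs <- function(eps, v, a1, a2, epsilon = epsilon_params(),
                        base = base_params()) {
  epsilon <- .as_epsilon_params(epsilon)
  base <- .as_base_params(base)
  .check_nonneg(eps = eps, v = v, a1 = a1, a2 = a2)
  satV <- v / (epsilon$K_V + v)
  sat2 <- base$c2 * a2 / (base$K_A2 + base$c2 * a2)
  phi <- blockade_fraction(a1, base)
  epsilon$k_basal * satV + epsilon$alpha_A2 * satV * sat2 -
    epsilon$alpha_A1 * phi * eps - epsilon$d_eps * eps
}

#' Pre-treatment quasi-steady-state initializer for PD-L1 expression
#'
#' Before treatment the expression propensity equilibrates at the fixed
#' initial tumor volume, giving the closed form
#' `eps(0) = (k_basal/d_eps) * v0/(K_V + v0)`; [epsilon_rhs()] evaluates to
#' zero at this value with no drugs present.
#'
#' @param v0 Initial tumor volume (mm^3), nonnegative.
#' @param epsilon An [epsilon_params()] object.
#' @return Initial expression propensity.
#' @examples
#' epsilon_qss_init(100)
#' @export
epsilon_qss_init <- function(v0, epsilon = epsilon_params()) {
  epsilon <- .as_epsilon_params(epsilon)
  .check_nonneg(v0 = v0)
  (epsilon$k_basal / epsilon$d_eps) * v0 / (epsilon$K_V + v0)
}
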