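#' Akaike information criterion from a residual sum of squares
#'
#' `AIC = n * ln(RSS/n) + 2k`, the least-squares form used for comparing
#' the constant- and dynamic-expression models; strictly increasing in RSS
#' for fixed `(n, k)` and in `k` for fixed `(RSS, n)`.
#'
#' @param rss Residual sum of squares (strictly positive); vectorized.
#' @param n Number of observations (>= 1).
#' @param k Number of fitted parameters (>= 0).
#' @return AIC value(s).
#' @examples
#' aic_rss(5367.9, n = 6, k = 1)
#' @export
aic_rss <- function(rss, n, k) {
  if (any(!is.finite(rss)) || any(rss <= 0)) rlang::abort("`rss` must be strictly positive (log domain).")
  if (any(n < 1) || any(k < 0)) rlang::abort("need n >= 1 and k >= 0.")
  n * log(rss / n) + 2 * k
}

#' Model-comparison table from per-arm residual sums of squares
#'
#' Builds the per-therapy and total comparison between the constant- and
#' dynamic-expression models. Per-arm AICs use `n_per_arm` observations with
#' `k = 1` (one epsilon per arm, constant model) and `k = k_dynamic` (all
#' global parameters charged to each arm, dynamic model). The totals row
#' computes each global AIC from the summed RSS over all observations:
#' constant with `k` equal to the number of arms (one epsilon each), dynamic
#' with `k = k_dynamic`. The sum of the per-arm constant AICs is also
#' reported (attribute `aic_constant_arm_sum`) since it is a distinct
#' quantity from the summed-RSS total.
#'
#' @param constant_rss,dynamic_rss Per-arm residual sums of squares (equal
#'   length).
#' @param original_rss Optional per-arm RSS of the unrefitted base model.
#' @param therapy Arm labels.
#' @param n_per_arm Observations per arm (default 6).
#' @param k_dynamic Fitted-parameter count of the dynamic model (default 5).
#' @return A tibble of class `pdl1_comparison` with one row per therapy and
#'   a `Total` row; attributes `delta_aic` (rounded difference of the global
#'   AICs, dynamic minus constant), `aic_constant_total`,
#'   `aic_dynamic_total`, `aic_constant_arm_sum`.
#' @export
comparison_table <- function(constant_rss, dynamic_rss, original_rss = NULL,
                             therapy = letters[seq_along(constant_rss)],
                             n_per_arm = 6, k_dynamic = 5) {
  n_arms <- length(constant_rss)
  if (length(dynamic_rss) != n_arms || length(therapy) != n_arms) {
    rlang::abort("`constant_rss`, `dynamic_rss` and `therapy` must have equal length.")
  }
  if (!is.null(original_rss) && length(original_rss) != n_arms) {
    rlang::abort("`original_rss` must match the arm count.")
  }
  aic_c <- aic_rss(constant_rss, n_per_arm, 1)
  aic_d <- aic_rss(dynamic_rss, n_per_arm, k_dynamic)
  n_tot <- n_arms * n_per_arm
  tot_c <- aic_rss(sum(constant_rss), n_tot, n_arms)
  tot_d <- aic_rss(sum(dynamic_rss), n_tot, k_dynamic)
  tbl <- tibble::tibble(
    therapy = c(therapy, "Total"),
    rss_original = if (is.null(original_rss)) NA_real_ else c(original_rss, sum(original_rss)),
    rss_constant = c(constant_rss, sum(constant_rss)),
    aic_constant = c(aic_c, tot_c),
    rss_dynamic = c(dynamic_rss, sum(dynamic_rss)),
    aic_dynamic = c(aic_d, tot_d))
  structure(tbl,
            class = c("pdl1_comparison", class(tbl)),
            delta_aic = round(tot_d - tot_c),
            aic_constant_total = tot_c,
            aic_dynamic_total = tot_d,
            aic_constant_arm_sum = sum(aic_c),
            aic_dynamic_arm_sum = sum(aic_d))
}

#' Model-comparison table from fitted models
#'
#' Convenience wrapper around [comparison_table()] that pulls the per-arm
#' RSS values out of six constant-model fits and one global dynamic fit.
#'
#' @param constant_fits List of per-arm `pdl1_fit` objects (constant mode).
#' @param dynamic_fit A global dynamic-mode `pdl1_fit`.
#' @param per_arm_dynamic_rss Per-arm RSS of the dynamic fit; defaults to
#'   the `per_arm_rss` recorded in `dynamic_fit`.
#' @param original_rss Optional per-arm RSS of the unrefitted base model.
#' @return See [comparison_table()].
#' @export
build_comparison <- function(constant_fits, dynamic_fit,
                             per_arm_dynamic_rss = NULL, original_rss = NULL) {
  if (!all(vapply(constant_fits, inherits, TRUE, "pdl1_fit"))) {
    rlang::abort("`constant_fits` must be a list of pdl1_fit objects.")
  }
  if (!inherits(dynamic_fit, "pdl1_fit") || dynamic_fit$mode != "dynamic") {
    rlang::abort("`dynamic_fit` must be a dynamic-mode pdl1_fit.")
  }
  per_arm_dynamic_rss <- per_arm_dynamic_rss %||% dynamic_fit$per_arm_rss
  if (length(per_arm_dynamic_rss) != length(constant_fits)) {
    rlang::abort("mismatched arm counts between constant fits and dynamic per-arm RSS.")
  }
  labels <- vapply(constant_fits, function(f) f$arms[[1]]$name, "")
  n_per_arm <- unique(vapply(constant_fits, function(f) as.numeric(f$n), 0))
  if (length(n_per_arm) != 1L) rlang::abort("constant fits must share one observation count per arm.")
  comparison_table(
    constant_rss = vapply(constant_fits, `[[`, 0, "rss"),
    dynamic_rss = unname(per_arm_dynamic_rss[labels]),
    original_rss = original_rss,
    therapy = labels, n_per_arm = n_per_arm, k_dynamic = dynamic_fit$k)
}

#' @export
print.pdl1_comparison <- function(x, ...) {
  cat("<pdl1_comparison>\n")
  NextMethod()
  cat(sprintf("Global AIC: constant %.3f, dynamic %.3f, delta (rounded) = %d\n",
              attr(x, "aic_constant_total"), attr(x, "aic_dynamic_total"),
              attr(x, "delta_aic")))
  invisible(x)
}

#' Export a comparison table to CSV
#'
#' @param comparison A [comparison_table()] result.
#' @param path Output file path.
#' @export
write_comparison <- function(comparison, path) {
  out <- as.data.frame(comparison)
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], round, digits = 3)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
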