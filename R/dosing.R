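.drugs <- c("Avelumab", "NHS-muIL12")

#' Construct bolus dose events
#'
#' A dose event is one instantaneous administration: the targeted drug
#' compartment jumps by `amount_ug` at time `day`, integration then restarts
#' from the post-jump state.
#'
#' @param day Administration time in days (nonnegative); vectorized.
#' @param drug `"Avelumab"` or `"NHS-muIL12"`; recycled against `day`.
#' @param amount_ug Dose in micrograms (strictly positive); recycled.
#' @return A tibble with columns `day`, `drug`, `amount_ug`, sorted by day.
#' @examples
#' dose_event(c(0, 3, 6), "Avelumab", 200)
#' @export
dose_event <- function(day, drug, amount_ug) {
  if (!is.numeric(day) || any(!is.finite(day)) || any(day < 0)) {
    rlang::abort("`day` must be nonnegative and finite.")
  }
  if (!all(drug %in% .drugs)) {
    rlang::abort(sprintf("`drug` must be one of: %s.", paste(.drugs, collapse = ", ")))
  }
  if (!is.numeric(amount_ug) || any(!is.finite(amount_ug)) || any(amount_ug <= 0)) {
    rlang::abort("`amount_ug` must be strictly positive and finite.")
  }
  dplyr::arrange(tibble::tibble(day = day, drug = drug, amount_ug = amount_ug), day)
}

#' Construct a treatment arm
#'
#' @param name Arm label (e.g. `"f"`).
#' @param events A tibble of dose events from [dose_event()]; may be empty
#'   (untreated control). Same-day co-administration is allowed.
#' @return An object of class `pdl1_arm` with fields `name` and `events`
#'   (sorted by day).
#' @export
treatment_arm <- function(name, events = dose_event(numeric(0), character(0), numeric(0))) {
  if (!is.character(name) || length(name) != 1L) rlang::abort("`name` must be a single string.")
  if (!is.data.frame(events) || !all(c("day", "drug", "amount_ug") %in% names(events))) {
    rlang::abort("`events` must have columns day, drug, amount_ug.")
  }
  if (nrow(events) > 0) events <- dose_event(events$day, events$drug, events$amount_ug)
  structure(list(name = name, events = tibble::as_tibble(events)), class = "pdl1_arm")
}

#' @export
print.pdl1_arm <- function(x, ...) {
  cat(sprintf("<pdl1_arm> %s (%d dose events)\n", x$name, nrow(x$events)))
  if (nrow(x$events) > 0) print(x$events, n = Inf)
  invisible(x)
}

#' The six standard treatment arms of the mouse studies
#'
#' Arm layout shared by both syngeneic studies: (a) isotype control,
#' (b) NHS-muIL12 2 ug on day 0, (c) NHS-muIL12 10 ug on day 0,
#' (d) Avelumab on days 0/3/6, (e) and (f) the low- and high-dose
#' combinations. The Avelumab dose is 200 ug per injection in the EMT6
#' study and 400 ug in the MC38 study.
#'
#' @param study `"EMT6"` or `"MC38"`.
#' @return Named list (`a`..`f`) of [treatment_arm()] objects.
#' @examples
#' standard_arms("EMT6")$f
#' @export
standard_arms <- function(study = c("EMT6", "MC38")) {
  study <- match.arg(study)
  av_dose <- switch(study, EMT6 = 200, MC38 = 400)
  av <- dose_event(c(0, 3, 6), "Avelumab", av_dose)
  nhs <- function(amt) dose_event(0, "NHS-muIL12", amt)
  list(
    a = treatment_arm("a"),
    b = treatment_arm("b", nhs(2)),
    c = treatment_arm("c", nhs(10)),
    d = treatment_arm("d", av),
    e = treatment_arm("e", dplyr::bind_rows(av, nhs(2))),
    f = treatment_arm("f", dplyr::bind_rows(av, nhs(10)))
  )
}

.as_arm <- function(x, study = "EMT6") {
  if (inherits(x, "pdl1_arm")) return(x)
  if (is.character(x) && length(x) == 1L) {
    arms <- standard_arms(study)
    if (!x %in% names(arms)) {
      rlang::abort(sprintf("unknown arm label '%s' (expected one of %s).",
                           x, paste(names(arms), collapse = ", ")))
    }
    return(arms[[x]])
  }
  rlang::abort("`arm` must be a pdl1_arm or a standard arm label ('a'..'f').")
}

#' Apply a bolus dose to a system state
#'
#' Increments the targeted drug compartment by the dose amount; every other
#' component is unchanged. Boluses are additive, so same-day events commute.
#'
#' @param state Named numeric state vector containing at least `A1` and `A2`.
#' @param event A one-row dose event (see [dose_event()]).
#' @return The post-jump state vector.
#' @examples
#' apply_dose(c(V = 100, T = 1, A1 = 0, A2 = 0), dose_event(0, "Avelumab", 200))
#' @export
apply_dose <- function(state, event) {
  if (!is.numeric(state) || is.null(names(state)) || !all(c("A1", "A2") %in% names(state))) {
    rlang::abort("`state` must be a named numeric vector with A1 and A2 components.")
  }
  if (!is.data.frame(event) || nrow(event) != 1L) {
    rlang::abort("`event` must be a single dose event row.")
  }
  target <- switch(as.character(event$drug),
                   "Avelumab" = "A1",
                   "NHS-muIL12" = "A2",
                   rlang::abort(sprintf("unknown drug label '%s'.", event$drug)))
  state[target] <- state[target] + event$amount_ug
  state
}
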