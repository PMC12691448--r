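.base_parm_vec <- function(base) {
  unlist(base[.base_fields], use.names = FALSE)
}

# R-language right-hand sides, used as the independent integration oracle
# for the compiled code and for exploratory work.
.rhs_r <- function(mode) {
  if (mode == "dynamic") {
    function(t, y, p) {
      phi <- p[6] * y[3] / (p[6] * y[3] + p[8])
      q <- p[11] * y[2] * (y[2] + y[5] * y[1]) * (1 - phi)
      sat2 <- p[7] * y[4] / (p[9] + p[7] * y[4])
      f <- (p[3] + p[4] * y[2] * sat2) / (1 + q / p[10])
      satV <- y[1] / (p[15] + y[1])
      list(c(p[1] * y[1] - p[2] * y[1] * y[2],
             f - p[5] * y[2],
             -p[12] * y[3],
             -p[13] * y[4],
             p[14] * satV + p[17] * satV * sat2 - p[16] * phi * y[5] - p[18] * y[5]))
    }
  } else {
    function(t, y, p) {
      phi <- p[6] * y[3] / (p[6] * y[3] + p[8])
      q <- p[11] * y[2] * (y[2] + p[14] * y[1]) * (1 - phi)
      sat2 <- p[7] * y[4] / (p[9] + p[7] * y[4])
      f <- (p[3] + p[4] * y[2] * sat2) / (1 + q / p[10])
      list(c(p[1] * y[1] - p[2] * y[1] * y[2],
             f - p[5] * y[2],
             -p[12] * y[3],
             -p[13] * y[4]))
    }
  }
}

.clip_negative <- function(m, thr, segment) {
  vals <- m[, -1, drop = FALSE]
  worst <- min(vals)
  if (worst < -thr) {
    rlang::abort(sprintf(
      "integration produced a negative state (%.3e) in segment [%g, %g]; positivity violation beyond solver tolerance.",
      worst, segment[1], segment[2]))
  }
  vals[vals < 0] <- 0
  m[, -1] <- vals
  m
}

#' Simulate a treatment arm
#'
#' Integrates the tumor-immune system for one treatment arm, restarting the
#' stiff-capable adaptive integrator (`deSolve::lsoda`, compiled right-hand
#' side) at every bolus dose. In `dynamic` mode the functional PD-L1
#' expression `eps` is a fifth state variable initialized at its
#' pre-treatment quasi-steady state ([epsilon_qss_init()]) before any day-0
#' dose is applied; in `constant` mode `eps` is held at a fixed scalar.
#'
#' The returned grid is strictly increasing and contains every dose day,
#' carrying the post-dose (right-continuous) state there; the pre-dose left
#' limits are recorded in the `jumps` attribute.
#'
#' @param arm A [treatment_arm()] or a standard arm label `"a"`..`"f"`.
#' @param base A [base_params()] object.
#' @param epsilon An [epsilon_params()] object (`dynamic` mode) or a single
#'   nonnegative number (`constant` mode).
#' @param mode `"auto"` (inferred from `epsilon`), `"dynamic"`, or
#'   `"constant"`.
#' @param t_end Simulation horizon in days (default 25).
#' @param v0 Initial tumor volume (mm^3, default 100).
#' @param t0_cells Initial T-cell volume; default `delta/d_T`, the drug-free
#'   basal balance.
#' @param times Optional explicit output times; otherwise a dense grid of
#'   spacing `step` is used.
#' @param step Output grid spacing in days (default 0.1).
#' @param rtol,atol Integrator tolerances.
#' @param study Study tag used only to resolve a character `arm` label.
#' @param engine `"compiled"` (default) or `"R"` (pure-R right-hand side;
#'   slower, used for cross-checking).
#' @return A tibble of class `pdl1_trajectory` with columns `time_day`,
#'   `V_mm3`, `T_mm3`, `A1`, `A2`, `eps`, plus attributes `arm`, `mode`,
#'   and `jumps`.
#' @examples
#' traj <- simulate_arm("f")
#' final_outcome(traj)
#' @export
simulate_arm <- function(arm, base = base_params(), epsilon = epsilon_params(),
                         mode = c("auto", "dynamic", "constant"),
                         t_end = 25, v0 = 100, t0_cells = NULL,
                         times = NULL, step = 0.1,
                         rtol = 1e-8, atol = 1e-10,
                         study = "EMT6", engine = c("compiled", "R")) {
  mode <- match.arg(mode)
  engine <- match.arg(engine)
  base <- .as_base_params(base)
  arm <- .as_arm(arm, study)
  if (mode == "auto") {
    mode <- if (is.numeric(epsilon) && length(epsilon) == 1L) "constant" else "dynamic"
  }
  if (!is.numeric(t_end) || length(t_end) != 1L || !is.finite(t_end) || t_end <= 0) {
    rlang::abort("`t_end` must be a single positive number of days.")
  }
  if (!is.numeric(v0) || length(v0) != 1L || !is.finite(v0) || v0 <= 0) {
    rlang::abort("`v0` must be a single positive volume (mm^3).")
  }
  t0_cells <- t0_cells %||% (base$delta / base$d_T)
  .check_nonneg(t0_cells = t0_cells)

  if (mode == "dynamic") {
    epsilon <- .as_epsilon_params(epsilon)
    parms <- c(.base_parm_vec(base), unlist(epsilon[.eps_fields], use.names = FALSE))
    y <- c(V = v0, T = t0_cells, A1 = 0, A2 = 0,
           eps = epsilon_qss_init(v0, epsilon))
    funcs <- list(func = "pdl1_derivs_dyn", initfunc = "pdl1_init_dyn")
  } else {
    if (!is.numeric(epsilon) || length(epsilon) != 1L || !is.finite(epsilon) || epsilon < 0) {
      rlang::abort("constant mode needs `epsilon` as a single nonnegative number.")
    }
    parms <- c(.base_parm_vec(base), epsilon)
    y <- c(V = v0, T = t0_cells, A1 = 0, A2 = 0)
    funcs <- list(func = "pdl1_derivs_const", initfunc = "pdl1_init_const")
  }

  grid <- if (is.null(times)) {
    unique(sort(c(seq(0, t_end, by = step), t_end)))
  } else {
    tt <- unique(sort(times))
    if (any(tt < 0) || max(tt) > t_end) rlang::abort("`times` must lie within [0, t_end].")
    unique(sort(c(0, tt, t_end)))
  }

  events <- arm$events[arm$events$day <= t_end, , drop = FALSE]
  breaks <- unique(sort(c(0, events$day, t_end)))
  grid <- unique(sort(c(grid, breaks)))
  clip_thr <- max(1e-12, 10 * atol)

  state_names <- names(y)
  jumps <- list()
  rows <- list()
  for (i in seq_len(length(breaks) - 1L)) {
    t0 <- breaks[i]; t1 <- breaks[i + 1L]
    todays <- events[events$day == t0, , drop = FALSE]
    if (nrow(todays) > 0) {
      pre <- y
      for (j in seq_len(nrow(todays))) y <- apply_dose(y, todays[j, , drop = FALSE])
      jumps[[length(jumps) + 1L]] <- tibble::tibble(
        time_day = t0,
        limit = c("pre", "post"),
        as.data.frame(rbind(pre, y), row.names = FALSE))
    }
    seg_times <- grid[grid >= t0 & grid <= t1]
    if (length(seg_times) < 2L) seg_times <- c(t0, t1)
    ode_args <- if (engine == "compiled") {
      list(y = y, times = seg_times, parms = parms,
           func = funcs$func, initfunc = funcs$initfunc,
           dllname = "pdl1dyn", method = "lsoda",
           rtol = rtol, atol = atol, maxsteps = 50000)
    } else {
      list(y = y, times = seg_times, parms = parms,
           func = .rhs_r(mode), method = "lsoda",
           rtol = rtol, atol = atol, maxsteps = 50000)
    }
    out <- tryCatch(
      do.call(deSolve::ode, ode_args),
      warning = function(w) rlang::abort(sprintf(
        "integrator failure in segment [%g, %g]: %s", t0, t1, conditionMessage(w))),
      error = function(e) rlang::abort(sprintf(
        "integrator failure in segment [%g, %g]: %s", t0, t1, conditionMessage(e))))
    out <- .clip_negative(unclass(out), clip_thr, c(t0, t1))
    y <- stats::setNames(out[nrow(out), -1], state_names)
    keep <- if (i == length(breaks) - 1L) seq_len(nrow(out)) else seq_len(nrow(out) - 1L)
    rows[[i]] <- out[keep, , drop = FALSE]
  }
  m <- do.call(rbind, rows)
  traj <- tibble::tibble(
    time_day = m[, "time"],
    V_mm3 = m[, "V"],
    T_mm3 = m[, "T"],
    A1 = m[, "A1"],
    A2 = m[, "A2"],
    eps = if (mode == "dynamic") m[, "eps"] else parms[14])
  if (!is.null(times)) traj <- traj[traj$time_day %in% unique(sort(c(0, times, t_end))), ]
  jumps <- if (length(jumps) > 0) dplyr::bind_rows(jumps) else tibble::tibble()
  structure(traj,
            class = c("pdl1_trajectory", class(traj)),
            arm = arm, mode = mode, jumps = jumps,
            base = base, epsilon = epsilon, v0 = v0, t_end = t_end)
}

#' Classify the end-of-simulation outcome
#'
#' A trajectory counts as `eliminated` when the final tumor volume is
#' strictly below the elimination threshold; otherwise `progressing` (a
#' final volume exactly at the threshold is progressing).
#'
#' @param traj A [simulate_arm()] trajectory.
#' @param elimination_threshold Volume cut-off in mm^3 (default 1).
#' @return A one-row tibble with `outcome`, `final_volume_mm3`, `t_end`.
#' @export
final_outcome <- function(traj, elimination_threshold = 1) {
  if (!is.data.frame(traj) || nrow(traj) == 0 || !"V_mm3" %in% names(traj)) {
    rlang::abort("`traj` must be a nonempty trajectory with a V_mm3 column.")
  }
  vf <- traj$V_mm3[which.max(traj$time_day)]
  tibble::tibble(
    outcome = if (vf < elimination_threshold) "eliminated" else "progressing",
    final_volume_mm3 = vf,
    t_end = max(traj$time_day))
}

#' Export a trajectory to CSV
#'
#' Writes the columns `time_day`, `V_mm3`, `T_mm3`, `A1`, `A2`, `eps`,
#' with state values rounded to four decimal places.
#'
#' @param traj A [simulate_arm()] trajectory.
#' @param path Output file path.
#' @export
write_trajectory <- function(traj, path) {
  out <- as.data.frame(traj)[, c("time_day", "V_mm3", "T_mm3", "A1", "A2", "eps")]
  out[-1] <- lapply(out[-1], round, digits = 4)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
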