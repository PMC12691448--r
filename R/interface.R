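#' Assemble a reproducible run configuration
#'
#' Bundles every setting a pipeline run depends on so that a run can be
#' reproduced from its serialized snapshot.
#'
#' @param base A [base_params()] object.
#' @param epsilon An [epsilon_params()] object.
#' @param design A [study_design()].
#' @param solver List of integrator settings (`rtol`, `atol`, `step`).
#' @param optimizer List of optimizer settings (`n_starts`, `seed`).
#' @param out_dir Output directory for command artifacts.
#' @return An object of class `pdl1_run_config`.
#' @export
run_config <- function(base = base_params(), epsilon = epsilon_params(),
                       design = study_design(),
                       solver = list(rtol = 1e-8, atol = 1e-10, step = 0.1),
                       optimizer = list(n_starts = 20, seed = 0),
                       out_dir = ".") {
  structure(list(base = .as_base_params(base),
                 epsilon = .as_epsilon_params(epsilon),
                 design = design, solver = solver, optimizer = optimizer,
                 out_dir = out_dir),
            class = "pdl1_run_config")
}

#' @rdname run_config
#' @param config A `pdl1_run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(precision = 15, list(
    base = unclass(config$base),
    epsilon = unclass(config$epsilon),
    study = config$design$study,
    days = config$design$days,
    v0 = config$design$v0,
    solver = config$solver,
    optimizer = config$optimizer,
    out_dir = config$out_dir), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  run_config(
    base = do.call(base_params, cfg$base),
    epsilon = do.call(epsilon_params, cfg$epsilon),
    design = study_design(cfg$study %||% "EMT6",
                          days = unlist(cfg$days), v0 = cfg$v0 %||% 100),
    solver = cfg$solver,
    optimizer = cfg$optimizer,
    out_dir = cfg$out_dir %||% ".")
}

.parse_argv <- function(argv) {
  opts <- list()
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--")) rlang::abort(sprintf("unexpected argument '%s'.", a))
    key <- sub("^--", "", a)
    if (i == length(argv) || startsWith(argv[i + 1L], "--")) {
      opts[[key]] <- TRUE
      i <- i + 1L
    } else {
      opts[[key]] <- argv[i + 1L]
      i <- i + 2L
    }
  }
  opts
}

.opt_num <- function(opts, key, default) {
  if (is.null(opts[[key]])) return(default)
  v <- suppressWarnings(as.numeric(opts[[key]]))
  if (is.na(v)) rlang::abort(sprintf("option --%s must be numeric.", key))
  v
}

.cli_log <- function(log_path, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
  message(msg)
  if (!is.null(log_path)) cat(msg, "\n", file = log_path, append = TRUE, sep = "")
  invisible(NULL)
}

#' Command-line entry point
#'
#' Thin dispatcher binding the pipeline stages into reproducible shell
#' commands; the installed script `exec/pdl1dyn` forwards to this function.
#' Subcommands: `simulate`, `synth`, `fit-constant`, `fit-dynamic`,
#' `compare`, `sensitivity`, `recover`. Common options: `--config` (YAML
#' run configuration), `--out` (output file), `--seed`, `--log`.
#'
#' @param argv Character vector of arguments, the first being the
#'   subcommand (default: the R session's trailing command-line arguments).
#' @return Exit status, invisibly (0 on success).
#' @examples
#' \donttest{
#' tmp <- tempfile(fileext = ".csv")
#' pdl1_cli(c("simulate", "--arm", "f", "--mode", "dynamic", "--out", tmp))
#' }
#' @export
pdl1_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) == 0) {
    rlang::abort("usage: pdl1dyn <simulate|synth|fit-constant|fit-dynamic|compare|sensitivity|recover> [--options]")
  }
  cmd <- argv[1]
  opts <- .parse_argv(argv[-1])
  log_path <- opts$log
  cfg <- if (!is.null(opts$config)) read_run_config(opts$config) else run_config()
  seed <- as.integer(.opt_num(opts, "seed", cfg$optimizer$seed %||% 0))
  n_starts <- as.integer(.opt_num(opts, "n-starts", cfg$optimizer$n_starts %||% 20))
  out <- opts$out %||% rlang::abort("--out is required.")
  .cli_log(log_path, "command '%s' starting", cmd)

  switch(cmd,
    "simulate" = {
      mode <- opts$mode %||% "dynamic"
      traj <- simulate_arm(opts$arm %||% "a", base = cfg$base,
                           epsilon = if (mode == "constant") .opt_num(opts, "epsilon", epsilon_qss_init(cfg$design$v0, cfg$epsilon)) else cfg$epsilon,
                           mode = mode, t_end = .opt_num(opts, "t-end", 25),
                           v0 = cfg$design$v0, step = cfg$solver$step %||% 0.1,
                           study = cfg$design$study)
      write_trajectory(traj, out)
    },
    "synth" = {
      nz <- noise_spec(opts$kind %||% "lognormal_multiplicative",
                       sigma = .opt_num(opts, "sigma", 0.1), seed = seed)
      study <- generate_study(cfg$base, cfg$epsilon, cfg$design, nz, seed = seed)
      write_study(study, out)
    },
    "fit-constant" = {
      data <- read_arm_data(opts$data %||% rlang::abort("--data is required."))
      if (!is.null(opts$arm)) data <- data[data$arm == opts$arm, ]
      fit <- fit_constant_epsilon(data, base = cfg$base, n_starts = n_starts,
                                  seed = seed, v0 = cfg$design$v0,
                                  study = cfg$design$study)
      .write_fit_json(fit, out)
    },
    "fit-dynamic" = {
      data <- read_arm_data(opts$data %||% rlang::abort("--data is required."))
      fit <- fit_dynamic_global(data, base = cfg$base, nominal = cfg$epsilon,
                                n_starts = n_starts, seed = seed,
                                fit_KV = !isTRUE(opts[["fix-KV"]]),
                                v0 = cfg$design$v0, study = cfg$design$study)
      .write_fit_json(fit, out)
    },
    "compare" = {
      paths <- strsplit(opts[["constant-fits"]] %||% rlang::abort("--constant-fits is required."), ",")[[1]]
      cfits <- lapply(paths, .read_fit_json)
      dfit <- .read_fit_json(opts[["dynamic-fit"]] %||% rlang::abort("--dynamic-fit is required."))
      cmp <- build_comparison(cfits, dfit)
      write_comparison(cmp, out)
    },
    "sensitivity" = {
      sweep <- local_sweep(cfg$base, cfg$epsilon, frac = .opt_num(opts, "frac", 0.25),
                           arms = cfg$design$arms)
      write_sweep(sweep, out)
    },
    "recover" = {
      rec <- recovery_experiment(cfg$epsilon, cfg$base, cfg$design,
                                 noise_levels = .opt_num(opts, "sigma", 0.1),
                                 reps = as.integer(.opt_num(opts, "reps", 1)),
                                 seed = seed, n_starts = n_starts)
      utils::write.csv(as.data.frame(rec), out, row.names = FALSE)
    },
    rlang::abort(sprintf("unknown subcommand '%s'.", cmd))
  )
  .cli_log(log_path, "command '%s' wrote %s", cmd, out)
  invisible(0L)
}

.write_fit_json <- function(fit, path) {
  jsonlite::write_json(list(
    mode = fit$mode, estimates = as.list(fit$estimates),
    rss = fit$rss, n = fit$n, k = fit$k, aic = fit$aic,
    converged = fit$converged, n_starts = fit$n_starts, seed = fit$seed,
    per_arm_rss = as.list(fit$per_arm_rss),
    arms = vapply(fit$arms, function(a) a$name, "")),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.read_fit_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_pdl1_fit(estimates = unlist(j$estimates), rss = j$rss, n = j$n, k = j$k,
               converged = j$converged, n_starts = j$n_starts, seed = j$seed,
               mode = j$mode, starts = tibble::tibble(),
               per_arm_rss = if (length(j$per_arm_rss)) unlist(j$per_arm_rss) else NULL,
               arms = lapply(j$arms, treatment_arm))
}
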