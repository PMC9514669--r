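# File formats and reproducible experiment bundles.  Time series travel as
# CSV (time in the first column, one column per state); a JSON sidecar
# carries grid, seeds, noise levels, the observation mask and parameters so
# every file is self-describing.

#' Write a trajectory as CSV with a JSON sidecar
#'
#' @param traj A `"trajectory"`.
#' @param file CSV path; the sidecar is written to `<file>.json`.
#' @param meta Extra named metadata merged into the sidecar.
#' @return `file`, invisibly.
#' @export
write_trajectory <- function(traj, file, meta = list()) {
  utils::write.csv(as.data.frame(traj), file, row.names = FALSE)
  side <- c(list(type = "trajectory", model = traj$model,
                 grid = traj$grid[c("t0", "dt", "n")],
                 state_names = rownames(traj$states)), meta)
  jsonlite::write_json(side, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(file)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param file CSV path (sidecar `<file>.json` must exist).
#' @return A `"trajectory"`.
#' @export
read_trajectory <- function(file) {
  side <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  d <- utils::read.csv(file)
  grid <- time_grid(side$grid$t0, side$grid$dt, side$grid$n)
  states <- t(as.matrix(d[, -1, drop = FALSE]))
  new_trajectory(grid, unname(states), side$model, side$state_names)
}

#' Write observations as CSV with a JSON sidecar
#'
#' Only observed columns are written to the CSV; the sidecar records the
#' mask, noise SD and seed.
#'
#' @param obs An `"observations"` object.
#' @param file CSV path.
#' @param meta Extra named metadata merged into the sidecar.
#' @return `file`, invisibly.
#' @export
write_observations <- function(obs, file, meta = list()) {
  nm <- rownames(obs$y)
  if (is.null(nm)) nm <- paste0("x", seq_len(nrow(obs$y)))
  d <- data.frame(time = obs$grid$t,
                  t(obs$y[obs$observed, , drop = FALSE]))
  names(d) <- c("time", nm[obs$observed])
  utils::write.csv(d, file, row.names = FALSE)
  side <- c(list(type = "observations", grid = obs$grid[c("t0", "dt", "n")],
                 D = nrow(obs$y), observed = obs$observed,
                 state_names = nm, sigma = obs$sigma, seed = obs$seed), meta)
  jsonlite::write_json(side, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(file)
}

#' Read observations written by [write_observations()]
#'
#' @param file CSV path (sidecar `<file>.json` must exist).
#' @return An `"observations"` object.
#' @export
read_observations <- function(file) {
  side <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  d <- utils::read.csv(file)
  grid <- time_grid(side$grid$t0, side$grid$dt, side$grid$n)
  y <- matrix(0, side$D, grid$n, dimnames = list(side$state_names, NULL))
  y[side$observed, ] <- t(as.matrix(d[, -1, drop = FALSE]))
  structure(list(grid = grid, y = y, observed = as.integer(side$observed),
                 sigma = side$sigma, seed = side$seed),
            class = "observations")
}

default_config <- function() {
  list(model = "lorenz96", model_args = list(),
       grid = list(t0 = 0, dt = 0.016, n = 501),
       stimulus = list(kind = "none"),
       observation = list(observed = c(1, 4, 7, 10), sigma = 1),
       estimation = list(method = "ocdspe", fit = NULL, Q = 2,
                         beta_max = 24, lambda0 = 1, alpha = 2,
                         maxit = 1000),
       process_noise = 0,
       transient = 10,
       seed = 1)
}

#' Run a complete twin experiment from a configuration
#'
#' Generates ground truth on the configured grid (after a discarded
#' transient), observes it with measurement noise, runs the configured
#' estimator with multistart, and writes a self-describing artifact bundle:
#' `truth.csv`, `observations.csv`, `stimulus.csv` (all with JSON
#' sidecars), `runs.json` (per-run parameters, E, residuals),
#' `recovery.json` (best-run estimates against the generative values) and
#' `log.json` (config, seeds, package version).  One master seed drives
#' every stochastic step through fixed named streams, so re-running an
#' identical config reproduces the bundle exactly.
#'
#' @param config Named list (see Details) or path to a JSON file; omitted
#'   entries take defaults.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the fit, observations, truth and the
#'   recovery report.
#' @details Config fields: `model` (+ `model_args`), `grid` (`t0`, `dt`,
#'   `n`), `stimulus` (`kind` = none/constant/chaotic + parameters),
#'   `observation` (`observed`, `sigma`), `process_noise` (current SD),
#'   `estimation` (`method`, `fit`, `Q`, `beta_max`, `lambda0`, `alpha`,
#'   `maxit`), `transient`, `seed`.
#' @export
run_experiment <- function(config = list(), out_dir) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- utils::modifyList(default_config(), config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- split_seed(cfg$seed, c("ic", "meas", "proc", "fit", "stim"))

  model <- do.call(get_model, c(list(cfg$model), cfg$model_args))
  grid <- time_grid(cfg$grid$t0, cfg$grid$dt, cfg$grid$n)
  stim <- switch(cfg$stimulus$kind,
                 none = NULL,
                 constant = constant_stimulus(grid, cfg$stimulus$value),
                 chaotic = chaotic_stimulus(
                   grid,
                   time_scale = cfg$stimulus$time_scale %||% 15,
                   amplitude = cfg$stimulus$amplitude %||% 20,
                   seed = seeds[["stim"]]),
                 stop("unknown stimulus kind: ", cfg$stimulus$kind))

  x0 <- attractor_state(model, seed = seeds[["ic"]],
                        transient = cfg$transient)
  truth <- if (cfg$process_noise > 0)
    integrate_noisy(model, x0, grid, stimulus = stim,
                    sd_noise = cfg$process_noise, seed = seeds[["proc"]])
  else integrate_model(model, x0, grid, stimulus = stim)
  obs <- observe(truth, observed = cfg$observation$observed,
                 sigma = cfg$observation$sigma, seed = seeds[["meas"]])

  est <- cfg$estimation
  fit <- assimilate(model, obs, method = est$method, stimulus = stim,
                    fit = est$fit,
                    schedule = annealing_schedule(lambda0 = est$lambda0,
                                                  alpha = est$alpha,
                                                  beta_max = est$beta_max),
                    Q = est$Q, seed = seeds[["fit"]],
                    control = list(maxit = est$maxit))
  rec <- recovery_report(fit)

  write_trajectory(truth, file.path(out_dir, "truth.csv"),
                   meta = list(seed_ic = seeds[["ic"]],
                               process_noise = cfg$process_noise))
  write_observations(obs, file.path(out_dir, "observations.csv"))
  if (!is.null(stim))
    utils::write.csv(data.frame(time = grid$t, I = stim$values),
                     file.path(out_dir, "stimulus.csv"), row.names = FALSE)
  runs <- lapply(seq_along(fit$runs), function(q) {
    r <- fit$runs[[q]]
    list(run = q, seed = r$seed, E = r$E,
         converged = r$converged,
         theta = as.list(r$theta[fit$fit_idx]),
         resid_rms = r$trace$resid_rms[nrow(r$trace)],
         objective_trace = r$trace$objective)
  })
  jsonlite::write_json(
    list(method = fit$method, Q = fit$Q, best_index = fit$best_index,
         runs = runs),
    file.path(out_dir, "runs.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  jsonlite::write_json(
    list(parameters = rec, E = attr(rec, "E"),
         best_index = attr(rec, "best_index")),
    file.path(out_dir, "recovery.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  jsonlite::write_json(
    list(config = cfg, seeds = as.list(seeds),
         package_version = as.character(utils::packageVersion("ocdspe"))),
    file.path(out_dir, "log.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(list(fit = fit, obs = obs, truth = truth, recovery = rec))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
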