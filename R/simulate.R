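# Twin-experiment data synthesis: forward integration, observation with
# Gaussian measurement noise, and fixed-step integration with injected
# current (process) noise.

new_trajectory <- function(grid, states, model_name = NULL,
                           state_names = NULL) {
  stopifnot(is.matrix(states), ncol(states) == grid$n,
            all(is.finite(states)))
  if (!is.null(state_names)) rownames(states) <- state_names
  structure(list(grid = grid, states = states, model = model_name),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d states x %d timepoints (dt = %g)%s\n",
              nrow(x$states), x$grid$n, x$grid$dt,
              if (is.null(x$model)) "" else paste0(", model ", x$model)))
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  nm <- rownames(x$states)
  if (is.null(nm)) nm <- paste0("x", seq_len(nrow(x$states)))
  out <- data.frame(time = x$grid$t, t(x$states))
  names(out) <- c("time", nm)
  out
}

#' Integrate a model forward on a time grid
#'
#' High-accuracy deterministic solution via the adaptive `lsoda` solver
#' (deSolve), sampled on the grid.  A time-varying stimulus is held
#' piecewise-constant between grid points (zero-order hold), in which case
#' integration proceeds interval by interval.
#'
#' @param model A `"dyn_model"`.
#' @param x0 Initial state (length `model$D`).
#' @param grid A [time_grid()].
#' @param stimulus `NULL`, a scalar, a grid-aligned vector, or a
#'   `"stimulus"` object.
#' @param theta Parameter values in registry order (default registry values).
#' @param rtol,atol Solver tolerances.
#' @return A `"trajectory"`.
#' @export
integrate_model <- function(model, x0, grid, stimulus = NULL, theta = NULL,
                            rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(model, "dyn_model"), length(x0) == model$D,
            all(is.finite(x0)), inherits(grid, "time_grid"))
  check_theta(model, theta)
  th <- cpp_theta_full(model, theta)
  sv <- stimulus_values(stimulus, grid)
  id <- model$model_id
  if (grid$n == 1L) {
    return(new_trajectory(grid, matrix(x0, ncol = 1), model$name,
                          model$state_names))
  }
  if (length(unique(sv)) == 1L) {
    func <- function(t, y, parms) list(cpp_model_rhs(id, y, th, sv[1]))
    sol <- deSolve::ode(y = x0, times = grid$t, func = func, parms = NULL,
                        method = "lsoda", rtol = rtol, atol = atol)
    check_solver(sol, grid$n)
    states <- t(unname(sol[, -1, drop = FALSE]))
  } else {
    # zero-order hold: restart the solver on each grid interval
    states <- matrix(NA_real_, model$D, grid$n)
    states[, 1] <- x0
    x <- x0
    for (n in seq_len(grid$n - 1L)) {
      func <- function(t, y, parms) list(cpp_model_rhs(id, y, th, sv[n]))
      sol <- deSolve::ode(y = x, times = grid$t[c(n, n + 1L)], func = func,
                          parms = NULL, method = "lsoda",
                          rtol = rtol, atol = atol)
      check_solver(sol, 2L)
      x <- unname(sol[2L, -1])
      states[, n + 1L] <- x
    }
  }
  new_trajectory(grid, states, model$name, model$state_names)
}

check_solver <- function(sol, n_expected) {
  if (nrow(sol) < n_expected || anyNA(sol) || any(!is.finite(sol)))
    stop("integration failed: ", paste(utils::capture.output(
      deSolve::diagnostics(sol)), collapse = " "), call. = FALSE)
  invisible(TRUE)
}

#' Observe a trajectory through a partial, noisy measurement operator
#'
#' Implements \eqn{y = Hx + R(t)} with a diagonal 0/1 mask \eqn{H} and
#' independent \eqn{N(0, \sigma^2)} draws on the observed rows only;
#' unobserved rows are identically zero by convention.
#'
#' @param traj A `"trajectory"`.
#' @param observed Integer indices of observed state dimensions.
#' @param sigma Measurement noise SD (>= 0); scalar or one per observed row.
#' @param seed Integer seed (reproducible draws).
#' @return An `"observations"` object with fields `grid`, `y` (D x N,
#'   zeros at unobserved rows), `observed`, `sigma`, `seed`.
#' @export
observe <- function(traj, observed, sigma = 0, seed = 1) {
  stopifnot(inherits(traj, "trajectory"), all(sigma >= 0))
  D <- nrow(traj$states)
  observed <- sort(unique(as.integer(observed)))
  stopifnot(all(observed >= 1), all(observed <= D))
  L <- length(observed)
  sigma <- rep(sigma, length.out = L)
  y <- matrix(0, D, traj$grid$n, dimnames = dimnames(traj$states))
  noise <- with_seed(seed,
    matrix(stats::rnorm(L * traj$grid$n, sd = sigma), L, traj$grid$n))
  y[observed, ] <- traj$states[observed, , drop = FALSE] + noise
  structure(list(grid = traj$grid, y = y, observed = observed,
                 sigma = sigma, seed = seed),
            class = "observations")
}

#' @export
print.observations <- function(x, ...) {
  cat(sprintf(
    "observations: %d of %d states observed (%s), %d timepoints, sigma = %s\n",
    length(x$observed), nrow(x$y), paste(x$observed, collapse = ","),
    x$grid$n, paste(unique(x$sigma), collapse = ",")))
  invisible(x)
}

#' Integrate with injected current (process) noise
#'
#' Fixed-step Runge-Kutta integration on the grid in which a fresh
#' \eqn{N(0, SD^2)} current draw is added to the stimulus on each step.
#' Following the discrete convention of the generating experiments, the
#' draw is per time step and is not rescaled by \eqn{\sqrt{dt}}; the grid
#' step is therefore part of the noise model and is recorded in the
#' returned object.
#'
#' @inheritParams integrate_model
#' @param sd_noise Noise current SD (pA, >= 0).
#' @param seed Integer seed.
#' @param substeps Internal RK4 substeps per grid interval (accuracy knob;
#'   the noise draw is held for the whole grid interval).
#' @return A `"trajectory"` with attribute `"sd_noise"`.
#' @export
integrate_noisy <- function(model, x0, grid, stimulus = NULL, sd_noise = 0,
                            seed = 1, theta = NULL, substeps = 4L) {
  stopifnot(inherits(model, "dyn_model"), length(x0) == model$D,
            sd_noise >= 0)
  check_theta(model, theta)
  th <- cpp_theta_full(model, theta)
  sv <- stimulus_values(stimulus, grid)
  noise <- if (sd_noise > 0)
    with_seed(seed, stats::rnorm(grid$n, sd = sd_noise))
  else rep(0, grid$n)
  states <- cpp_rk4(model$model_id, x0, th, grid$dt, sv, noise,
                    as.integer(substeps))
  out <- new_trajectory(grid, states, model$name, model$state_names)
  attr(out, "sd_noise") <- sd_noise
  attr(out, "dt") <- grid$dt
  out
}

#' A post-transient state on the model's attractor
#'
#' Integrates from a seeded random perturbation of a reference state and
#' discards a transient so twin-experiment windows start on the attractor
#' (or limit cycle).
#'
#' @param model A `"dyn_model"`.
#' @param seed Integer seed.
#' @param transient Discarded integration time (model time units;
#'   default 10 for Lorenz96, use ~50 ms for neuron models).
#' @param stimulus Constant current held during the transient (neuron
#'   models; default 0, i.e. relaxation to rest).
#' @return State vector of length `model$D`.
#' @export
attractor_state <- function(model, seed = 1, transient = 10, stimulus = 0) {
  if (model$model_id == 1L) {
    F <- model$params$value[1]
    x0 <- with_seed(seed, F + stats::rnorm(model$D))
  } else {
    x0 <- c(-60 + with_seed(seed, stats::rnorm(1)), 0.01)
  }
  g <- time_grid(0, transient / 200, 201L)
  traj <- integrate_model(model, x0, g, stimulus = stimulus)
  unname(traj$states[, g$n])
}
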