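#' Uniform time grid
#'
#' All trajectories, stimuli and observations in the package live on a
#' uniform grid \eqn{t_n = t_0 + n\,dt}, \eqn{n = 0,\dots,N-1}.
#'
#' @param t0 Start time.
#' @param dt Step size (> 0).
#' @param n Number of points (>= 1; a single-point grid is a degenerate
#'   window used e.g. for zero-length predictions).
#' @return An object of class `"time_grid"` with elements `t0`, `dt`, `n`
#'   and the vector of times `t`.
#' @examples
#' g <- time_grid(0, 0.016, 501)
#' range(g$t)
#' @export
time_grid <- function(t0 = 0, dt, n) {
  stopifnot(is.numeric(dt), length(dt) == 1L, dt > 0,
            is.numeric(n), length(n) == 1L, n >= 1)
  n <- as.integer(n)
  structure(list(t0 = t0, dt = dt, n = n, t = t0 + dt * (0:(n - 1L))),
            class = "time_grid")
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("time grid: %d points, t in [%g, %g], dt = %g\n",
              x$n, x$t0, x$t[x$n], x$dt))
  invisible(x)
}

grids_match <- function(a, b, tol = 1e-10) {
  a$n == b$n && abs(a$dt - b$dt) < tol && abs(a$t0 - b$t0) < tol
}

#' Constant stimulating current
#'
#' @param grid A [time_grid()].
#' @param value Current value (pA), held constant.
#' @return A `"stimulus"` object (grid-aligned values, zero-order hold
#'   between grid points).
#' @export
constant_stimulus <- function(grid, value) {
  stopifnot(inherits(grid, "time_grid"), is.numeric(value), length(value) == 1L)
  structure(list(grid = grid, values = rep(value, grid$n), kind = "constant"),
            class = "stimulus")
}

#' Custom stimulating current from grid-aligned values
#'
#' @param grid A [time_grid()].
#' @param values Numeric vector of length `grid$n`.
#' @return A `"stimulus"` object.
#' @export
custom_stimulus <- function(grid, values) {
  stopifnot(inherits(grid, "time_grid"), length(values) == grid$n,
            all(is.finite(values)))
  structure(list(grid = grid, values = as.numeric(values), kind = "custom"),
            class = "stimulus")
}

#' Chaotic stimulating current from a Lorenz96 component
#'
#' Builds a positive, aperiodic injected current
#' \eqn{I(t) = A\,|x_1(t/s)|}, where \eqn{x_1} is one component of a
#' 10-dimensional Lorenz96 run at forcing 8, started from a seeded random
#' state with a discarded transient.  Slowing the chaos down by the time
#' scale `s` and scaling by the amplitude `A` yields a current that sweeps
#' a neuron through many limit-cycle manifolds, which is what makes the
#' full nonlinear parameter set identifiable.
#'
#' @param grid A [time_grid()] (in ms for neuron experiments).
#' @param time_scale Temporal stretch factor (default 15).
#' @param amplitude Current scale in pA (default 20).
#' @param seed Integer seed for the Lorenz96 initial state.
#' @param transient Time (in Lorenz96 units) discarded before sampling.
#' @return A `"stimulus"` object with `kind = "chaotic"`.
#' @export
chaotic_stimulus <- function(grid, time_scale = 15, amplitude = 20, seed = 1,
                             transient = 10) {
  stopifnot(inherits(grid, "time_grid"), time_scale > 0, amplitude >= 0)
  mod <- lorenz96_model(D = 10, F = 8)
  x0 <- with_seed(seed, 8 + stats::rnorm(10))
  t_need <- grid$t[grid$n] / time_scale
  pre <- time_grid(0, 0.01, ceiling((transient + t_need + 1) / 0.01) + 1L)
  traj <- integrate_model(mod, x0, pre)
  tt <- transient + (grid$t - grid$t0) / time_scale
  vals <- amplitude * abs(stats::approx(pre$t, traj$states[1, ], xout = tt,
                                        rule = 2)$y)
  structure(list(grid = grid, values = vals, kind = "chaotic"),
            class = "stimulus")
}

stimulus_values <- function(stimulus, grid) {
  if (is.null(stimulus)) return(rep(0, grid$n))
  if (inherits(stimulus, "stimulus")) {
    stopifnot(grids_match(stimulus$grid, grid))
    return(stimulus$values)
  }
  if (is.numeric(stimulus) && length(stimulus) == 1L)
    return(rep(stimulus, grid$n))
  if (is.numeric(stimulus) && length(stimulus) == grid$n)
    return(as.numeric(stimulus))
  stop("stimulus must be NULL, a scalar, a grid-aligned vector, ",
       "or a 'stimulus' object on the same grid")
}

# Evaluate a seeded expression without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Split a master seed into named, independent sub-seeds (all < 2^31).
split_seed <- function(seed, labels) {
  s <- with_seed(seed, sample.int(.Machine$integer.max - 1L, length(labels)))
  names(s) <- labels
  s
}
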