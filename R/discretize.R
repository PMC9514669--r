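#' Hermite-Simpson residuals of an ODE constraint on a uniform grid
#'
#' Turns the continuous constraint \eqn{\dot z = \phi(z, t)} into one
#' algebraic residual per grid interval using the compressed Hermite-Simpson
#' rule: with \eqn{\phi_n = \phi(z_n, t_n)} and the Hermite-interpolated
#' midpoint
#' \deqn{z_{mid} = (z_n + z_{n+1})/2 + (dt/8)(\phi_n - \phi_{n+1}),}
#' the residual on interval \eqn{n} is
#' \deqn{g_n = z_{n+1} - z_n - (dt/6)(\phi_n + 4\phi(z_{mid}, t_{mid})
#'   + \phi_{n+1}).}
#' The rule is exact for trajectories polynomial in time up to cubic and has
#' local order 5.  The midpoint is eliminated through the Hermite
#' interpolant, so no extra unknowns are introduced.
#'
#' @param phi Function `phi(z, t, ...)` mapping an M-vector (and time) to an
#'   M-vector of derivatives.  Time-dependent data used inside `phi` should
#'   be interpolated linearly at midpoint times.
#' @param z M x N matrix: the variable path on the grid (rows = equations).
#' @param t Time vector of length N; must be uniformly spaced.
#' @param ... Extra arguments passed to `phi`.
#' @param scales Optional per-equation residual scales \eqn{R_i}
#'   (length M), attached to the result; used by the penalty
#'   \eqn{\lambda \sum_{i,n} R_i g_{i,n}^2}.
#' @return M x (N-1) residual matrix with attribute `"scales"`.
#' @examples
#' # exact for a cubic path
#' t <- seq(0, 1, by = 0.1)
#' z <- rbind(t^3)
#' g <- hermite_simpson_residual(function(z, t) 3 * t^2, z, t)
#' max(abs(g))
#' @export
hermite_simpson_residual <- function(phi, z, t, ..., scales = NULL) {
  if (is.vector(z)) z <- matrix(z, nrow = 1)
  N <- ncol(z)
  stopifnot(N >= 2, length(t) == N)
  dts <- diff(t)
  dt <- dts[1]
  if (any(abs(dts - dt) > 1e-8 * max(abs(dt), 1)))
    stop("hermite_simpson_residual requires a uniform grid")
  M <- nrow(z)
  if (is.null(scales)) scales <- rep(1, M)
  stopifnot(length(scales) == M)
  g <- matrix(NA_real_, M, N - 1L)
  phin <- vapply(seq_len(N), function(n) as.numeric(phi(z[, n], t[n], ...)),
                 numeric(M))
  phin <- matrix(phin, M, N)
  for (n in seq_len(N - 1L)) {
    zm <- (z[, n] + z[, n + 1L]) / 2 + (dt / 8) * (phin[, n] - phin[, n + 1L])
    phim <- as.numeric(phi(zm, t[n] + dt / 2, ...))
    g[, n] <- z[, n + 1L] - z[, n] -
      (dt / 6) * (phin[, n] + 4 * phim + phin[, n + 1L])
  }
  if (any(!is.finite(g))) stop("non-finite constraint residuals")
  attr(g, "scales") <- scales
  g
}
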