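# S3 methods for "assimilation" fits.

#' @export
print.assimilation <- function(x, digits = 4, ...) {
  cat(sprintf("%s fit of model '%s' (%d of %d parameters free)\n",
              toupper(x$method), x$model$name,
              length(x$fit_names), nrow(x$model$params)))
  cat(sprintf("  %d initialization(s); best run %d with E = %.6g%s\n",
              x$Q, x$best_index, x$best$E,
              if (x$best$converged) "" else " (optimizer flagged)"))
  cat("  estimated parameters (best run):\n")
  print(round(x$best$theta[x$fit_idx], digits))
  invisible(x)
}

#' Parameter estimates from an assimilation fit
#'
#' @param object An `"assimilation"` fit.
#' @param all If `TRUE`, return the full registry vector (fixed parameters
#'   at their frozen values); default returns only the fitted ones.
#' @param ... Unused.
#' @return Named numeric vector from the best (lowest-E) run.
#' @export
coef.assimilation <- function(object, all = FALSE, ...) {
  if (all) object$best$theta else object$best$theta[object$fit_idx]
}

#' @export
summary.assimilation <- function(object, ...) {
  runs <- object$runs
  tab <- data.frame(
    run = seq_along(runs),
    E = vapply(runs, `[[`, numeric(1), "E"),
    resid_rms = vapply(runs, function(r) r$trace$resid_rms[nrow(r$trace)],
                       numeric(1)),
    converged = vapply(runs, `[[`, logical(1), "converged"))
  th <- do.call(rbind, lapply(runs, function(r) r$theta[object$fit_idx]))
  colnames(th) <- object$fit_names
  out <- list(method = object$method, model = object$model$name,
              table = cbind(tab, th), best_index = object$best_index)
  class(out) <- "summary.assimilation"
  out
}

#' @export
print.summary.assimilation <- function(x, digits = 4, ...) {
  cat(sprintf("%s fit of '%s': %d runs (best = run %d, by lowest E)\n",
              toupper(x$method), x$model, nrow(x$table), x$best_index))
  print(format(x$table, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
fitted.assimilation <- function(object, ...) {
  object$best$x_hat
}

#' Residuals of an assimilation fit
#'
#' @param object An `"assimilation"` fit.
#' @param type `"constraint"` for the Hermite-Simpson residuals of the
#'   method's constrained dynamics (one row per equation, one column per
#'   interval, with attribute `"scales"`); `"measurement"` for
#'   \eqn{H\hat x - y} on observed rows.
#' @param ... Unused.
#' @return A numeric matrix.
#' @export
residuals.assimilation <- function(object, type = c("constraint",
                                                    "measurement"), ...) {
  type <- match.arg(type)
  if (type == "constraint") return(object$best$resid)
  idx <- object$obs$observed
  object$best$x_hat$states[idx, , drop = FALSE] -
    object$obs$y[idx, , drop = FALSE]
}

#' Forward prediction from an assimilation fit
#'
#' Integrates the model forward from the final state estimate
#' \eqn{\hat x(t_N)} using the estimated parameters (cross-validation on a
#' held-out window).
#'
#' @param object An `"assimilation"` fit.
#' @param grid Prediction [time_grid()]; defaults to a window of the same
#'   length as the estimation window, starting at its end.
#' @param stimulus Stimulus on the prediction grid.
#' @param x_end Override for the initial state (default: best-run
#'   \eqn{\hat x(t_N)}).
#' @param ... Unused.
#' @return A `"trajectory"` on `grid`.
#' @export
predict.assimilation <- function(object, grid = NULL, stimulus = NULL,
                                 x_end = NULL, ...) {
  og <- object$obs$grid
  if (is.null(grid)) grid <- time_grid(og$t[og$n], og$dt, og$n)
  if (is.null(x_end)) x_end <- object$best$x_hat$states[, og$n]
  integrate_model(object$model, x_end, grid, stimulus = stimulus,
                  theta = object$best$theta)
}

#' Plot an assimilation fit
#'
#' Observed data (points), the best-run state estimate (lines) and, when
#' supplied, the ground-truth trajectory (dashed), one panel per state.
#'
#' @param x An `"assimilation"` fit.
#' @param truth Optional ground-truth `"trajectory"`.
#' @param states Indices of states to show (default: all).
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.assimilation <- function(x, truth = NULL, states = NULL, ...) {
  D <- x$model$D
  if (is.null(states)) states <- seq_len(D)
  tt <- x$obs$grid$t
  old <- graphics::par(mfrow = c(length(states), 1),
                       mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(old))
  for (d in states) {
    est <- x$best$x_hat$states[d, ]
    yl <- range(est, if (d %in% x$obs$observed) x$obs$y[d, ],
                if (!is.null(truth)) truth$states[d, ])
    graphics::plot(tt, est, type = "l", col = "red3", ylim = yl,
                   xlab = "time", ylab = x$model$state_names[d], ...)
    if (d %in% x$obs$observed)
      graphics::points(tt, x$obs$y[d, ], pch = 16, cex = 0.3,
                       col = grDevices::adjustcolor("blue", 0.4))
    if (!is.null(truth))
      graphics::lines(tt, truth$states[d, ], lty = 2)
  }
  invisible(x)
}
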