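# Experiment-level analyses: cost-surface scans over a parameter, recovery
# statistics, the conjugate-momentum diagnostic, and spike-train metrics.

#' Cost-surface scan over a model parameter
#'
#' For each candidate value of one parameter, integrates the model from a
#' prescribed initial state -- optionally with constant nudging gains `u`
#' coupling the observations into the observed components -- and evaluates
#' the summed squared mismatch \eqn{C_u(F) = \sum_n \|y(t_n) -
#' Hx(t_n;F,u)\|^2} on observed rows.  With `u = 0` this is the naive
#' least-squares scan, typically rugged around the generative value for
#' chaotic dynamics; larger `u` smooths the surface.
#'
#' @param model A `"dyn_model"`.
#' @param obs An `"observations"` object.
#' @param values Grid of parameter values to scan.
#' @param u Constant nudging gain (>= 0; 0 disables control).
#' @param x0 Initial state used for every candidate integration (the true
#'   initial state in the twin experiments).
#' @param param Name of the scanned parameter (default: the model's first
#'   registry entry).
#' @param stimulus Stimulus on the observation grid.
#' @param integrator `"rk4"` (default): compiled fixed-step integration
#'   with 4 substeps per grid interval, ample for evaluating a bounded
#'   scan cost over thousands of candidates; `"lsoda"`: the adaptive
#'   solver used by [integrate_model()] / [nudged_trajectory()].
#' @param substeps RK4 substeps per grid interval.
#' @return A `"cost_scan"` data frame with columns `value` and `cost`,
#'   attributes `argmin`, `u`, `param`.  Integrations that blow up are
#'   recorded as `Inf`.
#' @export
cost_scan <- function(model, obs, values, u = 0, x0, param = NULL,
                      stimulus = NULL, integrator = c("rk4", "lsoda"),
                      substeps = 4L) {
  stopifnot(u >= 0, length(x0) == model$D)
  integrator <- match.arg(integrator)
  if (is.null(param)) param <- model$params$name[1]
  pi_ <- match(param, model$params$name)
  if (is.na(pi_)) stop("unknown parameter: ", param)
  idx <- obs$observed
  gains <- rep(u, length(idx))
  sv <- stimulus_values(stimulus, obs$grid)
  cost <- vapply(values, function(v) {
    th <- model$params$value
    th[pi_] <- v
    if (integrator == "rk4") {
      X <- cpp_rk4_nudged(model$model_id, x0, cpp_theta_full(model, th),
                          obs$grid$dt, sv, obs$y,
                          as.integer(idx - 1L), gains, as.integer(substeps))
      if (anyNA(X)) return(Inf)
      return(sum((X[idx, , drop = FALSE] - obs$y[idx, , drop = FALSE])^2))
    }
    tr <- tryCatch({
      if (u == 0)
        integrate_model(model, x0, obs$grid, stimulus = stimulus, theta = th)
      else
        nudged_from(model, obs, gains, x0, theta = th, stimulus = stimulus)
    }, error = function(e) NULL)
    if (is.null(tr)) return(Inf)
    sum((tr$states[idx, , drop = FALSE] - obs$y[idx, , drop = FALSE])^2)
  }, numeric(1))
  out <- data.frame(value = values, cost = cost)
  class(out) <- c("cost_scan", "data.frame")
  attr(out, "argmin") <- values[which.min(cost)]
  attr(out, "u") <- u
  attr(out, "param") <- param
  out
}

#' Count strict local minima of a scanned cost curve
#'
#' A grid point is a strict local minimum when its cost is lower than both
#' neighbours; endpoints are excluded.  Operationalizes "rugged" versus
#' "convex" cost sections.
#'
#' @param scan A `"cost_scan"` (or any data frame with a `cost` column).
#' @return Integer count.
#' @export
n_local_minima <- function(scan) {
  cost <- scan$cost
  n <- length(cost)
  if (n < 3) return(0L)
  inner <- 2:(n - 1)
  sum(cost[inner] < cost[inner - 1] & cost[inner] < cost[inner + 1])
}

#' Measurement error of an estimate
#'
#' \eqn{E = \sum_n \|H\hat x(t_n) - y(t_n)\|^2} over observed rows: the
#' only selection metric available across multistart runs when the truth
#' is unknown.
#'
#' @param x An `"assimilation"` fit, a `"trajectory"`, or a D x N matrix.
#' @param obs An `"observations"` object (taken from the fit if missing).
#' @return Scalar error.
#' @export
measurement_error <- function(x, obs = NULL) {
  if (inherits(x, "assimilation")) {
    if (is.null(obs)) obs <- x$obs
    x <- x$best$x_hat
  }
  X <- if (inherits(x, "trajectory")) x$states else x
  stopifnot(!is.null(obs), ncol(X) == obs$grid$n)
  measurement_error_mat(X, obs)
}

#' Conjugate-momentum diagnostic across multistart runs
#'
#' The momenta measure the marginal cost of violating the estimation
#' dynamics, so their average magnitude acts as a proxy for estimate
#' quality: runs whose parameters land near the truth show a dip in
#' mean \eqn{|p|}.  Only defined for OC-DSPE fits.
#'
#' @param fit An OC-DSPE `"assimilation"` fit.
#' @param truth Optional named vector of true parameter values; adds
#'   per-parameter absolute error columns (`err_<name>`).
#' @return Data frame with one row per run: `run`, `E`, `mean_abs_p`, the
#'   fitted parameters and (optionally) their errors.
#' @export
momentum_diagnostic <- function(fit, truth = NULL) {
  stopifnot(inherits(fit, "assimilation"))
  if (fit$method != "ocdspe")
    stop("momentum diagnostic requires an OC-DSPE fit")
  out <- data.frame(
    run = seq_along(fit$runs),
    E = vapply(fit$runs, `[[`, numeric(1), "E"),
    mean_abs_p = vapply(fit$runs, function(r) mean(abs(r$p_hat)), numeric(1)))
  th <- do.call(rbind, lapply(fit$runs, function(r) r$theta[fit$fit_idx]))
  colnames(th) <- fit$fit_names
  out <- cbind(out, th)
  if (!is.null(truth)) {
    for (nm in intersect(names(truth), fit$fit_names))
      out[[paste0("err_", nm)]] <- abs(out[[nm]] - truth[[nm]])
  }
  out
}

#' Spike detection and matching between two voltage traces
#'
#' Spikes are upward crossings of a voltage threshold; predicted and true
#' spikes are matched greedily within a time tolerance.
#'
#' @param pred,truth `"trajectory"` objects whose first state is the
#'   membrane voltage.
#' @param threshold Spike threshold (mV, default 0).
#' @param tol Matching tolerance (ms, default 2).
#' @return List with `n_spikes_pred`, `n_spikes_true`, `matched_fraction`
#'   (fraction of true spikes matched; 1 when both trains are empty).
#' @export
spike_metrics <- function(pred, truth, threshold = 0, tol = 2) {
  sp <- spike_times(pred, threshold)
  st <- spike_times(truth, threshold)
  matched <- 0L
  avail <- sp
  for (t0 in st) {
    if (!length(avail)) break
    i <- which.min(abs(avail - t0))
    if (abs(avail[i] - t0) <= tol) {
      matched <- matched + 1L
      avail <- avail[-i]
    }
  }
  list(n_spikes_pred = length(sp), n_spikes_true = length(st),
       matched_fraction = if (length(st)) matched / length(st) else 1)
}

#' Upward threshold-crossing times of a voltage trace
#'
#' @inheritParams spike_metrics
#' @param traj A `"trajectory"` (voltage = first state).
#' @return Numeric vector of crossing times (linear interpolation within
#'   the bracketing interval).
#' @export
spike_times <- function(traj, threshold = 0) {
  v <- traj$states[1, ]
  t <- traj$grid$t
  up <- which(v[-length(v)] < threshold & v[-1] >= threshold)
  if (!length(up)) return(numeric(0))
  t[up] + (threshold - v[up]) / (v[up + 1] - v[up]) * diff(t)[1]
}

#' Parameter-recovery report for a twin experiment
#'
#' @param fit An `"assimilation"` fit.
#' @param truth Named vector of generative parameter values (default: the
#'   model registry values, which hold the ground truth in twin
#'   experiments).
#' @return A `"recovery_report"` data frame with one row per fitted
#'   parameter: `truth`, `estimate`, `rel_error` (absolute error where
#'   truth is 0), plus attributes `E` and `best_index`.
#' @export
recovery_report <- function(fit, truth = NULL) {
  stopifnot(inherits(fit, "assimilation"))
  if (is.null(truth))
    truth <- stats::setNames(fit$model$params$value, fit$model$params$name)
  est <- coef(fit)
  tr <- truth[names(est)]
  err <- ifelse(tr != 0, abs(est - tr) / abs(tr), abs(est - tr))
  out <- data.frame(parameter = names(est), truth = unname(tr),
                    estimate = unname(est), rel_error = unname(err))
  class(out) <- c("recovery_report", "data.frame")
  attr(out, "E") <- fit$best$E
  attr(out, "best_index") <- fit$best_index
  out
}
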