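#' @useDynLib ocdspe, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Internal parameter-registry constructor. Roles tag how parameters enter
# the dynamics; "conductance" marks the linear conductances used in
# restricted fits.
param_registry <- function(name, value, lower, upper, role) {
  stopifnot(!anyDuplicated(name), all(lower <= value), all(value <= upper))
  data.frame(name = name, value = value, lower = lower, upper = upper,
             role = role, stringsAsFactors = FALSE)
}

new_dyn_model <- function(name, D, state_names, params, model_id,
                          cpp_theta, cpp_theta_idx, state_bounds) {
  structure(list(name = name, D = as.integer(D), state_names = state_names,
                 params = params, model_id = as.integer(model_id),
                 cpp_theta = cpp_theta, cpp_theta_idx = cpp_theta_idx,
                 state_bounds = state_bounds),
            class = "dyn_model")
}

#' @export
print.dyn_model <- function(x, ...) {
  cat(sprintf("dynamical model '%s': D = %d states (%s)\n", x$name, x$D,
              paste(x$state_names, collapse = ", ")))
  print(x$params, row.names = FALSE)
  invisible(x)
}

# Map registry values onto the full parameter vector the compiled code
# expects (the Morris-Lecar family shares one 14-slot layout).
cpp_theta_full <- function(model, theta = NULL) {
  th <- model$cpp_theta
  vals <- if (is.null(theta)) model$params$value else theta
  stopifnot(length(vals) == nrow(model$params))
  th[model$cpp_theta_idx] <- vals
  th
}

#' Lorenz96 model
#'
#' The cyclically coupled chaotic benchmark
#' \deqn{\dot x_d = (x_{d+1} - x_{d-2})\,x_{d-1} - x_d + F,}
#' with indices modulo \eqn{D} and a single forcing parameter \eqn{F};
#' values around 8 give chaotic dynamics.
#'
#' @param D State dimension (>= 4).
#' @param F Forcing parameter (ground-truth value stored in the registry).
#' @param F_bounds Search bounds on `F` used by the estimators.
#' @return A `"dyn_model"` object.
#' @examples
#' m <- lorenz96_model(D = 5, F = 8)
#' model_rhs(m, rep(8, 5))  # fixed point: all zeros
#' @export
lorenz96_model <- function(D = 10, F = 8, F_bounds = c(1, 20)) {
  if (D < 4) stop("Lorenz96 requires D >= 4")
  params <- param_registry("F", F, F_bounds[1], F_bounds[2], "forcing")
  new_dyn_model("lorenz96", D, paste0("x", seq_len(D)), params,
                model_id = 1L, cpp_theta = F, cpp_theta_idx = 1L,
                state_bounds = matrix(rep(c(-15, 15), each = D), ncol = 2))
}

ml_defaults <- function() {
  param_registry(
    name  = c("C", "g_fast", "g_slow", "g_leak", "E_Na", "E_K", "E_leak",
              "phi_w", "beta_w", "beta_m", "gamma_m", "gamma_w"),
    value = c(2.5, 20, 15, 2, 50, -100, -70, 0.12, 0, -1.2, 18, 10),
    lower = c(0.01, 0.01, 0.01, 0.01, -200, -200, -200, 0.01, -200, -200,
              0.01, 0.01),
    upper = c(200, 200, 200, 200, 200, 200, 200, 200, 200, 200, 200, 200),
    role  = c("capacitance", "conductance", "conductance", "conductance",
              "reversal-potential", "reversal-potential", "reversal-potential",
              "kinetic", "kinetic", "kinetic", "kinetic", "kinetic"))
}

#' Morris-Lecar neuron model (K+Na)
#'
#' Two-state conductance-based spiking neuron: membrane voltage \eqn{V} (mV)
#' driven by a fast Na-like instantaneous current, a slow K-like current
#' gated by \eqn{w}, a leak, and an injected current \eqn{I_{stim}} (pA):
#' \deqn{C\dot V = -g_{fast}\,m_\infty(V)(V - E_{Na}) - g_{slow}\,w\,(V - E_K)
#'   - g_{leak}(V - E_{leak}) + I_{stim},}
#' \deqn{\dot w = \phi_w\,(w_\infty(V) - w)/\tau_w(V),}
#' with sigmoidal steady-state activations and
#' \eqn{\tau_w(V) = 1/\cosh((V-\beta_w)/(2\gamma_w))}.  Parameter values,
#' voltages in mV, times in ms and currents in pA are treated as one
#' consistent unit system.  Defaults are the ground-truth set used in the
#' twin experiments.
#'
#' @param ... Named parameter overrides (e.g. `g_slow = 10`).
#' @return A `"dyn_model"` object with a 12-parameter registry.
#' @examples
#' m <- morris_lecar_model()
#' model_rhs(m, c(-60, 0.01), stim = 0)
#' @export
morris_lecar_model <- function(...) {
  params <- override_params(ml_defaults(), list(...))
  new_dyn_model("morris_lecar", 2L, c("V", "w"), params,
                model_id = 2L,
                cpp_theta = c(params$value, 0, 50),  # g_NaP = 0 slot
                cpp_theta_idx = 1:12,
                state_bounds = rbind(c(-100, 100), c(0, 1)))
}

#' Morris-Lecar neuron model with persistent sodium channel (K+Na+NaP)
#'
#' Adds a persistent Na current \eqn{-g_{NaP}\,m_\infty(V)(V - E_{NaP})}
#' to the voltage equation of [morris_lecar_model()]; used to generate
#' data from a richer model than the one being fit (model
#' misspecification experiments).
#'
#' @param g_NaP Persistent Na conductance (default 3).
#' @param E_NaP Persistent Na reversal potential (default 50 mV).
#' @param ... Further named overrides of the K+Na parameters.
#' @return A `"dyn_model"` object with a 14-parameter registry.
#' @export
morris_lecar_nap_model <- function(g_NaP = 3, E_NaP = 50, ...) {
  base <- override_params(ml_defaults(), list(...))
  extra <- param_registry(c("g_NaP", "E_NaP"), c(g_NaP, E_NaP),
                          c(0.01, -200), c(200, 200),
                          c("conductance", "reversal-potential"))
  params <- rbind(base, extra)
  new_dyn_model("morris_lecar_nap", 2L, c("V", "w"), params,
                model_id = 2L,
                cpp_theta = params$value,
                cpp_theta_idx = 1:14,
                state_bounds = rbind(c(-100, 100), c(0, 1)))
}

override_params <- function(params, overrides) {
  if (length(overrides)) {
    bad <- setdiff(names(overrides), params$name)
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    params$value[match(names(overrides), params$name)] <-
      as.numeric(unlist(overrides))
  }
  params
}

#' Look up a registered model by name
#'
#' @param name One of `"lorenz96"`, `"morris_lecar"`, `"morris_lecar_nap"`.
#' @param ... Passed to the model constructor.
#' @return A `"dyn_model"` object.
#' @export
get_model <- function(name, ...) {
  switch(name,
         lorenz96 = lorenz96_model(...),
         morris_lecar = morris_lecar_model(...),
         morris_lecar_nap = morris_lecar_nap_model(...),
         stop("unknown model: ", name))
}

#' Evaluate a model's vector field
#'
#' @param model A `"dyn_model"`.
#' @param x State vector of length `model$D`.
#' @param theta Parameter values in registry order (default: registry values).
#' @param stim Stimulus value at the evaluation time (ignored by Lorenz96).
#' @return Vector of time derivatives, length `model$D`.
#' @export
model_rhs <- function(model, x, theta = NULL, stim = 0) {
  stopifnot(inherits(model, "dyn_model"), length(x) == model$D,
            all(is.finite(x)))
  check_theta(model, theta)
  drop(cpp_model_rhs(model$model_id, x, cpp_theta_full(model, theta), stim))
}

#' State Jacobian of a model's vector field
#'
#' Analytic \eqn{D \times D} matrix \eqn{\partial f/\partial x}, used both
#' by the adjoint (momentum) dynamics and in the collocation gradients.
#'
#' @inheritParams model_rhs
#' @return A `D x D` matrix.
#' @export
model_jacobian <- function(model, x, theta = NULL, stim = 0) {
  stopifnot(inherits(model, "dyn_model"), length(x) == model$D,
            all(is.finite(x)))
  check_theta(model, theta)
  cpp_model_jac(model$model_id, x, cpp_theta_full(model, theta), stim)
}

check_theta <- function(model, theta) {
  if (!is.null(theta)) {
    stopifnot(length(theta) == nrow(model$params), all(is.finite(theta)))
    if (model$model_id == 2L) {
      gm <- theta[match(c("gamma_m", "gamma_w"), model$params$name,
                        nomatch = 0L)]
      if (any(gm == 0)) stop("gamma_m and gamma_w must be nonzero")
    }
  }
  invisible(TRUE)
}

#' Lorenz96 vector field (standalone)
#'
#' @param x State vector (length >= 4), cyclic indexing.
#' @param F Forcing parameter.
#' @return Vector of derivatives \eqn{(x_{d+1}-x_{d-2})x_{d-1} - x_d + F}.
#' @export
lorenz96_rhs <- function(x, F) {
  if (length(x) < 4) stop("Lorenz96 requires D >= 4")
  drop(cpp_model_rhs(1L, x, F, 0))
}

#' Morris-Lecar gating functions
#'
#' Steady-state activations and the gating time constant:
#' \eqn{w_\infty(V) = \tfrac12(1+\tanh((V-\beta_w)/\gamma_w))},
#' \eqn{m_\infty(V) = \tfrac12(1+\tanh((V-\beta_m)/\gamma_m))},
#' \eqn{\tau_w(V) = 1/\cosh((V-\beta_w)/(2\gamma_w))}.
#'
#' @param V Membrane voltage (mV), vectorised.
#' @param theta Named list/vector with `beta_w`, `beta_m`, `gamma_w`,
#'   `gamma_m` (defaults: ground-truth values).
#' @return A list with components `w_inf`, `m_inf`, `tau_w`.
#' @export
ml_gates <- function(V, theta = NULL) {
  d <- ml_defaults()
  th <- stats::setNames(d$value, d$name)
  if (!is.null(theta)) th[names(theta)] <- unlist(theta)
  if (th[["gamma_w"]] == 0 || th[["gamma_m"]] == 0)
    stop("gamma_m and gamma_w must be nonzero")
  list(w_inf = 0.5 * (1 + tanh((V - th[["beta_w"]]) / th[["gamma_w"]])),
       m_inf = 0.5 * (1 + tanh((V - th[["beta_m"]]) / th[["gamma_m"]])),
       tau_w = 1 / cosh((V - th[["beta_w"]]) / (2 * th[["gamma_w"]])))
}

#' Morris-Lecar vector field (standalone)
#'
#' @param state Numeric `c(V, w)`.
#' @param theta Parameter values in registry order of [morris_lecar_model()]
#'   (default ground truth).
#' @param stim Injected current (pA).
#' @return `c(dV/dt, dw/dt)`.
#' @export
ml_rhs <- function(state, theta = NULL, stim = 0) {
  model_rhs(morris_lecar_model(), state, theta, stim)
}

#' Morris-Lecar + persistent Na vector field (standalone)
#'
#' @param state Numeric `c(V, w)`.
#' @param theta Parameter values in registry order of
#'   [morris_lecar_nap_model()] (default ground truth).
#' @param stim Injected current (pA).
#' @return `c(dV/dt, dw/dt)`.
#' @export
ml_nap_rhs <- function(state, theta = NULL, stim = 0) {
  model_rhs(morris_lecar_nap_model(), state, theta, stim)
}
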