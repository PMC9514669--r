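# Shared fixtures: small twin experiments and a finite-difference oracle.

fd_gradient <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x))
    e[i] <- h * max(1, abs(x[i]))
    (f(x + e) - f(x - e)) / (2 * e[i])
  }, numeric(1))
}

# 5D Lorenz96 twin experiment (small, fast)
lorenz_twin <- function(n = 101, D = 5, F = 8, observed = c(1, 4), sigma = 1,
                        seed = 2) {
  mod <- lorenz96_model(D = D, F = F)
  g <- time_grid(0, 0.016, n)
  x0 <- attractor_state(mod, seed = seed)
  truth <- integrate_model(mod, x0, g)
  list(model = mod, grid = g, x0 = x0, truth = truth,
       obs = observe(truth, observed, sigma = sigma, seed = seed + 1))
}

# Morris-Lecar twin experiment under a step current
ml_twin <- function(n = 601, stim_value = 100, sigma = 2, seed = 4,
                    model = morris_lecar_model(), sd_noise = 0) {
  g <- time_grid(0, 0.05, n)
  x0 <- attractor_state(model, seed = seed, transient = 50)
  stim <- constant_stimulus(g, stim_value)
  truth <- if (sd_noise > 0)
    integrate_noisy(model, x0, g, stimulus = stim, sd_noise = sd_noise,
                    seed = seed + 2)
  else integrate_model(model, x0, g, stimulus = stim)
  list(model = model, grid = g, x0 = x0, stim = stim, truth = truth,
       obs = observe(truth, observed = 1, sigma = sigma, seed = seed + 1))
}

make_traj <- function(states, dt = 0.1) {
  g <- time_grid(0, dt, ncol(states))
  structure(list(grid = g, states = states, model = "test"),
            class = "trajectory")
}
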