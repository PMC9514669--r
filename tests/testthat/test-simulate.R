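test_that("integration preserves the Lorenz96 uniform fixed point", {
  mod <- lorenz96_model(D = 5, F = 8)
  g <- time_grid(0, 0.05, 41)
  traj <- integrate_model(mod, rep(8, 5), g)
  expect_lt(max(abs(traj$states - 8)), 1e-6)
})

test_that("output sampling density does not change the solution", {
  mod <- lorenz96_model(D = 5, F = 8)
  x0 <- attractor_state(mod, seed = 1)
  g1 <- time_grid(0, 0.02, 51)
  g2 <- time_grid(0, 0.01, 101)
  t1 <- integrate_model(mod, x0, g1)
  t2 <- integrate_model(mod, x0, g2)
  expect_lt(max(abs(t1$states - t2$states[, seq(1, 101, by = 2)])), 1e-5)
})

test_that("Morris-Lecar is silent at 0 pA and spikes at 100 pA", {
  mod <- morris_lecar_model()
  g <- time_grid(0, 0.05, 2001)
  x0 <- attractor_state(mod, seed = 4, transient = 50)
  quiet <- integrate_model(mod, x0, g, stimulus = 0)
  expect_equal(length(spike_times(quiet)), 0)
  tonic <- integrate_model(mod, x0, g, stimulus = constant_stimulus(g, 100))
  expect_gte(length(spike_times(tonic)), 1)
})

test_that("observation operator masks, perturbs, and reproduces", {
  tw <- lorenz_twin(n = 41)
  o0 <- observe(tw$truth, c(1, 4), sigma = 0, seed = 1)
  expect_equal(o0$y[c(1, 4), ], tw$truth$states[c(1, 4), ])
  o1 <- observe(tw$truth, c(1, 4), sigma = 3, seed = 1)
  expect_true(all(o1$y[c(2, 3, 5), ] == 0))           # mask contract
  o2 <- observe(tw$truth, c(1, 4), sigma = 3, seed = 1)
  expect_identical(o1$y, o2$y)                        # seeded reproducibility
  expect_false(identical(o1$y, observe(tw$truth, c(1, 4), 3, seed = 2)$y))
})

test_that("measurement noise has the requested scale and no correlation", {
  states <- matrix(0, 2, 10000)
  traj <- make_traj(states)
  obs <- observe(traj, 1, sigma = 1.5, seed = 7)
  r <- obs$y[1, ]
  expect_lt(abs(sd(r) - 1.5) / 1.5, 0.05)
  expect_lt(abs(cor(r[-1], r[-length(r)])), 0.05)  # lag-1 autocorrelation
})

test_that("process-noise integration is seeded and collapses to the ODE", {
  mod <- morris_lecar_model()
  g <- time_grid(0, 0.05, 401)
  x0 <- c(-69.4, 0.001)
  stim <- constant_stimulus(g, 100)
  det <- integrate_model(mod, x0, g, stimulus = stim)
  rk0 <- integrate_noisy(mod, x0, g, stimulus = stim, sd_noise = 0, seed = 1)
  expect_lt(max(abs(det$states - rk0$states)), 1e-3)  # fixed-step accuracy
  n1 <- integrate_noisy(mod, x0, g, stimulus = stim, sd_noise = 100, seed = 9)
  n2 <- integrate_noisy(mod, x0, g, stimulus = stim, sd_noise = 100, seed = 9)
  expect_identical(n1$states, n2$states)              # bit-identical
  n3 <- integrate_noisy(mod, x0, g, stimulus = stim, sd_noise = 100, seed = 10)
  expect_false(identical(n1$states, n3$states))
})

test_that("strong current noise perturbs spike timing", {
  tw <- ml_twin(n = 2001)
  noisy <- integrate_noisy(tw$model, tw$x0, tw$grid, stimulus = tw$stim,
                           sd_noise = 100, seed = 21)
  m <- spike_metrics(noisy, tw$truth)
  expect_true(m$n_spikes_pred != m$n_spikes_true || m$matched_fraction < 1)
})

test_that("chaotic stimulus is positive, seeded, and of the expected scale", {
  g <- time_grid(0, 0.5, 1201)  # 600 ms -> 40 Lorenz time units
  s <- chaotic_stimulus(g, seed = 5)
  expect_true(all(s$values >= 0))
  expect_identical(s$values, chaotic_stimulus(g, seed = 5)$values)
  m <- mean(s$values)
  expect_gt(m, 20 * 2)
  expect_lt(m, 20 * 6)
  s0 <- chaotic_stimulus(g, amplitude = 0, seed = 5)
  expect_equal(s0$values, rep(0, g$n))
})
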