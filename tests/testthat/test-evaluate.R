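test_that("strict local minima are counted between neighbours only", {
  expect_equal(n_local_minima(data.frame(cost = c(3, 1, 2, 0.5, 4))), 2L)
  expect_equal(n_local_minima(data.frame(cost = c(1, 2, 3, 4))), 0L)
  expect_equal(n_local_minima(data.frame(cost = c(4, 3, 2, 1))), 0L)  # endpoint
  expect_equal(n_local_minima(data.frame(cost = c(1, 1, 1))), 0L)     # ties
  expect_equal(n_local_minima(data.frame(cost = c(2, 1)))    , 0L)
})

test_that("measurement error follows its definition", {
  tw <- lorenz_twin(n = 25)
  X <- tw$obs$y
  expect_equal(measurement_error(X, tw$obs), 0)
  X2 <- X; X2[4, ] <- X2[4, ] + 3
  expect_equal(measurement_error(X2, tw$obs), 25 * 9)
  # unobserved rows do not contribute
  X3 <- X; X3[2, ] <- X3[2, ] + 100
  expect_equal(measurement_error(X3, tw$obs), 0)
})

test_that("the noiseless cost scan is minimized at the generative forcing", {
  tw <- lorenz_twin(n = 51, sigma = 0, seed = 5)
  grid_F <- seq(7.8, 8.2, by = 0.05)
  sc <- cost_scan(tw$model, tw$obs, grid_F, u = 0, x0 = tw$x0)
  expect_equal(attr(sc, "argmin"), 8)
  expect_lt(min(sc$cost), 1e-10)
  expect_s3_class(sc, "cost_scan")
  expect_error(cost_scan(tw$model, tw$obs, grid_F, u = 0, x0 = tw$x0,
                         param = "Z"), "unknown parameter")
})

test_that("nudged scans are smoother than naive scans", {
  # short noisy window: naive scan already rugged, control smooths it
  tw <- lorenz_twin(n = 201, D = 10, observed = c(1, 4, 7, 10), sigma = 1,
                    seed = 3)
  grid_F <- seq(4, 12, by = 0.25)
  n_min <- vapply(c(0, 4, 15), function(u)
    n_local_minima(cost_scan(tw$model, tw$obs, grid_F, u = u, x0 = tw$x0)),
    integer(1))
  expect_true(all(diff(n_min) <= 0))   # monotone smoothing in u
  expect_lte(n_min[3], 1)
})

test_that("spike detection and matching behave", {
  tw <- ml_twin(n = 2001)
  m <- spike_metrics(tw$truth, tw$truth)
  expect_gt(m$n_spikes_true, 3)
  expect_equal(m$matched_fraction, 1)
  flat <- make_traj(rbind(rep(-65, 100), rep(0, 100)), dt = 0.05)
  expect_equal(length(spike_times(flat)), 0)
  expect_equal(spike_metrics(flat, flat)$matched_fraction, 1)  # empty trains
  # +1 ms shift stays within the 2 ms matching tolerance
  shift <- 20  # samples of 0.05 ms
  sh <- make_traj(tw$truth$states[, -(1:shift)], dt = 0.05)
  tr <- make_traj(tw$truth$states[, 1:(2001 - shift)], dt = 0.05)
  m2 <- spike_metrics(sh, tr)
  expect_equal(m2$matched_fraction, 1)
})

test_that("momentum diagnostic summarizes runs and guards its method", {
  runs <- list(
    list(E = 2, p_hat = matrix(0, 2, 5), theta = c(F = 8)),
    list(E = 1, p_hat = matrix(c(0.3, -0.3), 2, 5), theta = c(F = 7)))
  fake <- structure(list(method = "ocdspe", runs = runs, fit_idx = 1,
                         fit_names = "F"), class = "assimilation")
  tab <- momentum_diagnostic(fake, truth = c(F = 8))
  expect_equal(tab$mean_abs_p, c(0, 0.3))
  expect_equal(tab$err_F, c(0, 1))
  fake$method <- "dspe"
  expect_error(momentum_diagnostic(fake), "OC-DSPE")
})

test_that("recovery reports compute relative errors against the registry", {
  tw <- lorenz_twin(n = 31, sigma = 1)
  fit <- assimilate(tw$model, tw$obs, method = "lsq", fit = "F", Q = 1,
                    seed = 2, schedule = annealing_schedule(beta_max = 6),
                    control = list(maxit = 100))
  rep_ <- recovery_report(fit)
  expect_equal(rep_$parameter, "F")
  expect_equal(rep_$truth, 8)
  expect_equal(rep_$rel_error, abs(rep_$estimate - 8) / 8)
  expect_equal(attr(rep_, "E"), fit$best$E)
})
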