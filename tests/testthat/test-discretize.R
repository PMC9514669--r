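test_that("Hermite-Simpson residuals vanish on polynomial solutions", {
  t <- seq(0, 2, by = 0.1)
  # zero field, constant path
  g <- hermite_simpson_residual(function(z, t) 0 * z, rbind(rep(3, 21)), t)
  expect_equal(max(abs(g)), 0)
  # constant field, linear path
  g <- hermite_simpson_residual(function(z, t) c(2, -1),
                                rbind(1 + 2 * t, 5 - t), t)
  expect_lt(max(abs(g)), 1e-14)
  # cubic path, exact by construction of the rule
  g <- hermite_simpson_residual(function(z, t) 3 * t^2 - 4 * t + 1,
                                rbind(t^3 - 2 * t^2 + t), t)
  expect_lt(max(abs(g)), 1e-13)
})

test_that("Hermite-Simpson local truncation error is fifth order", {
  resid_max <- function(dt) {
    t <- seq(0, 1, by = dt)
    max(abs(hermite_simpson_residual(function(z, t) z, rbind(exp(t)), t)))
  }
  r1 <- resid_max(0.1)
  r2 <- resid_max(0.05)
  expect_gt(r1 / r2, 25)   # ~2^5 = 32 for local order 5
  expect_lt(r1 / r2, 40)
})

test_that("residuals are linear in the path for linear fields and match FD", {
  t <- seq(0, 1, by = 0.125)
  A <- matrix(c(-1, 0.5, 0.2, -2), 2, 2)
  phi <- function(z, t) drop(A %*% z)
  set.seed(8)
  z1 <- matrix(rnorm(18), 2)
  z2 <- matrix(rnorm(18), 2)
  a <- 0.7
  g1 <- hermite_simpson_residual(phi, z1, t)
  g2 <- hermite_simpson_residual(phi, z2, t)
  g12 <- hermite_simpson_residual(phi, a * z1 + (1 - a) * z2, t)
  expect_equal(unclass(g12), a * unclass(g1) + (1 - a) * unclass(g2),
               tolerance = 1e-12, ignore_attr = TRUE)
  # gradient of one residual entry w.r.t. path entries vs finite differences
  f <- function(v) hermite_simpson_residual(phi, matrix(v, 2), t)[1, 3]
  gfd <- fd_gradient(f, as.vector(z1), h = 1e-6)
  # analytic: residual 3 depends on columns 3 and 4 only
  nz <- which(abs(gfd) > 1e-12)
  expect_true(all(nz %in% c(5, 6, 7, 8)))
  for (i in nz) {
    e <- numeric(18); e[i] <- 1
    lin <- (hermite_simpson_residual(phi, matrix(as.vector(z1) + e, 2), t) -
            g1)[1, 3]
    expect_equal(lin, gfd[i], tolerance = 1e-6)
  }
})

test_that("non-uniform grids are rejected", {
  expect_error(
    hermite_simpson_residual(function(z, t) z, rbind(1:4), c(0, 1, 2, 4)),
    "uniform grid")
})

test_that("R and compiled residuals agree on the built-in models", {
  # dual route: generic R collocation vs the compiled estimator residuals
  tw <- lorenz_twin(n = 31, observed = c(1, 4), sigma = 0.5)
  mod <- tw$model
  z <- tw$truth$states + 0.1
  r_cpp <- penalized_objective(mod, "lsq", z, tw$obs)$resid
  r_r <- hermite_simpson_residual(
    function(zz, t) model_rhs(mod, zz), z, tw$grid$t)
  expect_equal(unclass(r_cpp), unclass(r_r), tolerance = 1e-10,
               ignore_attr = TRUE)

  # OC-DSPE estimation dynamics route, with data interpolated at midpoints
  set.seed(2)
  zp <- rbind(z, matrix(rnorm(nrow(z) * ncol(z), 0, 0.3), nrow(z)))
  r_cpp <- penalized_objective(mod, "ocdspe", zp, tw$obs)$resid
  yf <- apply(tw$obs$y, 1, function(row) approxfun(tw$grid$t, row))
  phi <- function(zz, t) {
    D <- mod$D
    y <- vapply(yf, function(f) f(t), numeric(1))
    d <- estimation_dynamics(mod, zz[1:D], zz[D + 1:D], y,
                             observed = tw$obs$observed)
    c(d$xdot, d$pdot)
  }
  r_r <- hermite_simpson_residual(phi, zp, tw$grid$t)
  expect_equal(unclass(r_cpp), unclass(r_r), tolerance = 1e-10,
               ignore_attr = TRUE)
})
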