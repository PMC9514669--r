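test_that("Lorenz96 vector field matches hand evaluation with cyclic indexing", {
  expect_equal(lorenz96_rhs(rep(8, 5), F = 8), rep(0, 5))  # fixed point
  expect_equal(lorenz96_rhs(rep(0, 6), F = 8), rep(8, 6))  # only forcing
  # d = 1 component of Eq.-style hand evaluation: (x2 - x4) x5 - x1
  f <- lorenz96_rhs(c(1, 2, 3, 4, 5), F = 0)
  expect_equal(f[1], (2 - 4) * 5 - 1)
  expect_error(lorenz96_rhs(c(1, 2, 3), F = 8), "D >= 4")
  expect_error(lorenz96_model(D = 3), "D >= 4")
})

test_that("Lorenz96 rhs is equivariant under cyclic index shifts", {
  set.seed(11)
  for (D in c(5, 8, 10)) {
    x <- rnorm(D, 0, 4)
    f <- lorenz96_rhs(x, F = 8)
    for (k in c(1, 3)) {
      shift <- function(v) v[((seq_len(D) - 1 + k) %% D) + 1]
      expect_equal(lorenz96_rhs(shift(x), F = 8), shift(f), tolerance = 1e-12)
    }
  }
})

test_that("Morris-Lecar gating functions obey their limits", {
  g <- ml_gates(-1.2)           # V = beta_m
  expect_equal(g$m_inf, 0.5)
  g <- ml_gates(0)              # V = beta_w
  expect_equal(g$tau_w, 1)
  g <- ml_gates(1e4)
  expect_equal(g$w_inf, 1)
  expect_equal(g$m_inf, 1)
  V <- seq(-100, 100, by = 5)
  g <- ml_gates(V)
  expect_true(all(g$w_inf > 0 & g$w_inf < 1))
  expect_true(all(g$m_inf > 0 & g$m_inf < 1))
  expect_true(all(g$tau_w > 0))
  expect_error(ml_gates(0, theta = list(gamma_w = 0)), "nonzero")
})

test_that("Morris-Lecar vector field vanishes where every term vanishes", {
  mod <- morris_lecar_model()
  th <- mod$params$value
  # w at steady state -> dw/dt = 0
  V <- -20
  w <- ml_gates(V)$w_inf
  expect_equal(ml_rhs(c(V, w), stim = 0)[2], 0)
  # V = E_Na, w = 0, g_leak = 0, I = 0 -> dV/dt = 0
  th0 <- th
  th0[mod$params$name == "g_leak"] <- 0
  expect_equal(ml_rhs(c(50, 0), theta = th0, stim = 0)[1], 0)
})

test_that("Morris-Lecar resting point sits between E_K and spiking threshold", {
  # root of dV/dt = 0 with w = w_inf(V): numerically bracketed rest state
  f <- function(V) ml_rhs(c(V, ml_gates(V)$w_inf), stim = 0)[1]
  Vrest <- uniroot(f, c(-99, -60))$root
  expect_gt(Vrest, -100)   # above E_K
  expect_lt(Vrest, -60)    # subthreshold, near (slightly above) E_leak
  expect_lt(abs(Vrest - (-70)), 2)
})

test_that("persistent-Na variant differs from K+Na by exactly the NaP current", {
  base <- morris_lecar_model()
  nap <- morris_lecar_nap_model()
  set.seed(3)
  for (i in 1:5) {
    V <- runif(1, -80, 40); w <- runif(1); I <- runif(1, 0, 120)
    th_nap <- nap$params$value
    f_nap <- ml_nap_rhs(c(V, w), stim = I)
    f_base <- ml_rhs(c(V, w), stim = I)
    C <- 2.5; gnp <- 3; Enp <- 50
    expect_equal(f_nap[1] - f_base[1],
                 -gnp * ml_gates(V)$m_inf * (V - Enp) / C, tolerance = 1e-12)
    expect_equal(f_nap[2], f_base[2])
    # g_NaP = 0 makes the variants identical
    th0 <- th_nap; th0[nap$params$name == "g_NaP"] <- 0
    expect_equal(model_rhs(nap, c(V, w), theta = th0, stim = I),
                 f_base, tolerance = 1e-12)
  }
})

test_that("analytic state Jacobians match central finite differences", {
  set.seed(42)
  cases <- list(list(m = lorenz96_model(D = 7, F = 8),
                     draw = function() rnorm(7, 2, 4)),
                list(m = morris_lecar_model(),
                     draw = function() c(runif(1, -90, 40), runif(1))),
                list(m = morris_lecar_nap_model(),
                     draw = function() c(runif(1, -90, 40), runif(1))))
  for (cs in cases) {
    for (rep in 1:5) {
      x <- cs$draw()
      J <- model_jacobian(cs$m, x, stim = 60)
      for (d in seq_len(cs$m$D)) {
        Jfd <- fd_gradient(function(xx) model_rhs(cs$m, xx, stim = 60)[d], x)
        expect_equal(unname(J[d, ]), Jfd, tolerance = 1e-5)
      }
    }
  }
})

test_that("known analytic Jacobian entries hold", {
  x <- rnorm(6, 0, 3)
  expect_equal(unname(diag(model_jacobian(lorenz96_model(D = 6), x))),
               rep(-1, 6))
  V <- -35; w <- 0.3
  J <- model_jacobian(morris_lecar_model(), c(V, w))
  expect_equal(J[2, 2], -0.12 / ml_gates(V)$tau_w)  # dwdot/dw = -phi_w/tau_w
})

test_that("model registry and lookup behave", {
  m <- get_model("morris_lecar_nap")
  expect_s3_class(m, "dyn_model")
  expect_equal(nrow(m$params), 14)
  expect_true(all(m$params$lower <= m$params$value &
                  m$params$value <= m$params$upper))
  expect_error(get_model("hodgkin"), "unknown model")
  m2 <- morris_lecar_model(g_slow = 10)
  expect_equal(m2$params$value[m2$params$name == "g_slow"], 10)
  expect_error(morris_lecar_model(g_bogus = 1), "unknown parameter")
})
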