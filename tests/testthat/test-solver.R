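test_that("periodic Laplacian matches its discrete eigenstructure", {
  # constant field: identically zero
  expect_equal(periodic_laplacian(matrix(3.7, 8, 8)), matrix(0, 8, 8))
  # any field: sums to zero on a periodic domain (discrete divergence theorem)
  set.seed(42)
  F <- matrix(rnorm(144), 12, 12)
  expect_lt(abs(sum(periodic_laplacian(F))), 1e-9 * 144)
  # cosine mode is a discrete eigenfunction with eigenvalue -(2 sin(pi/n)/h)^2
  n <- 32; L <- 32; h <- L / n
  x <- (0:(n - 1)) * h
  F <- outer(cos(2 * pi * x / L), rep(1, n))
  eig <- -(2 * sin(pi / n) / h)^2
  expect_equal(periodic_laplacian(F, h), eig * F, tolerance = 1e-12)
  # spacing scaling
  expect_equal(periodic_laplacian(F, 2), periodic_laplacian(F, 1) / 4)
  expect_error(periodic_laplacian(matrix(1, 3, 4)), "square")
})

test_that("IMEX step reduces to implicit exponential decay without reactions", {
  # reaction terms switched (numerically) off: pure decay at rate mu_A
  p <- kinetic_params(G_A = 1e-15, G_H = 1e-15, D_A = 1e-15, D_H = 1e-9,
                      rho_A = 0, mu_A = 0.03, mu_H = 0.03)
  g <- sim_grid(8)
  A0 <- matrix(2, 8, 8)
  st <- field_state(A0, matrix(1, 8, 8))
  dt <- 0.05
  st1 <- imex_step(st, p, dt, g)
  expect_equal(st1$A, A0 / (1 + dt * p$mu_A), tolerance = 1e-9)
  # many steps track exp(-mu_A t) to O(dt)
  for (i in 2:200) st1 <- imex_step(st1, p, dt, g)
  t <- 200 * dt
  expect_equal(st1$A[1, 1], 2 * exp(-p$mu_A * t), tolerance = 5e-3)
  expect_equal(st1$t, t)
})

test_that("the homogeneous fixed point is preserved by both schemes", {
  p <- kinetic_params()
  ss <- homogeneous_steady_state(p)
  g <- sim_grid(16)
  st0 <- field_state(matrix(ss$A_star, 16, 16), matrix(ss$H_star, 16, 16))
  sti <- ste <- st0
  for (i in 1:50) {
    sti <- imex_step(sti, p, 0.5, g)
    ste <- euler_step(ste, p, 0.1, g)
  }
  expect_lt(max(abs(sti$A - ss$A_star)), 1e-8)
  expect_lt(max(abs(sti$H - ss$H_star)), 1e-8)
  expect_lt(max(abs(ste$A - ss$A_star)), 1e-8)
  expect_lt(max(abs(ste$H - ss$H_star)), 1e-8)
})

test_that("IMEX and Euler steps agree to first order as dt -> 0", {
  p <- kinetic_params()
  g <- sim_grid(16)
  A <- random_initial_A(g, seed = 3) + 0.5
  H <- random_initial_A(g, seed = 4)
  st <- field_state(A, H)
  for (dt in c(1e-3, 1e-4)) {
    si <- imex_step(st, p, dt, g)
    se <- euler_step(st, p, dt, g)
    gap <- max(abs(si$A - se$A), abs(si$H - se$H))
    # one-step (local) difference of two first-order schemes is O(dt^2)
    expect_lt(gap, 100 * dt^2)
    # change per unit time approximates reaction + diffusion
    rate <- (se$A - st$A) / dt
    expected <- reaction_terms(A, H, p)$dA + p$D_A * periodic_laplacian(A, 1)
    expect_equal(rate, expected, tolerance = 1e-8)
  }
})

test_that("steady-state criterion fires exactly where the decay rate crosses tol", {
  g16 <- matrix(1, 4, 4)
  same <- field_state(g16, g16)
  expect_true(steady_state_reached(same, same, dt = 1, tol = 1e-12))
  bumped <- g16; bumped[2, 2] <- 2
  expect_false(steady_state_reached(field_state(g16, g16),
                                    field_state(bumped, g16),
                                    dt = 1, tol = 1e-6))
  expect_error(steady_state_reached(field_state(g16, g16),
                                    field_state(matrix(1, 5, 5),
                                                matrix(1, 5, 5)),
                                    dt = 1, tol = 1))
  # exponential decay A(t) = A0 exp(-r t): change/(dt (1+max)) = A0 r e^{-rt}
  # (1-e^{-r dt})/(r dt) / (1+A0 e^{-r(t+dt)}); solve for the flip index
  A0 <- 5; r <- 0.1; dt <- 1; tol <- 1e-3
  flip <- NA
  for (i in 1:400) {
    prev <- A0 * exp(-r * (i - 1) * dt)
    cur <- A0 * exp(-r * i * dt)
    st_prev <- field_state(matrix(prev, 2, 2), matrix(0, 2, 2))
    st_cur <- field_state(matrix(cur, 2, 2), matrix(0, 2, 2))
    if (steady_state_reached(st_prev, st_cur, dt, tol)) { flip <- i; break }
  }
  analytic <- which(sapply(1:400, function(i) {
    prev <- A0 * exp(-r * (i - 1) * dt); cur <- A0 * exp(-r * i * dt)
    (prev - cur) / (dt * (1 + cur)) < tol
  }))[1]
  expect_equal(flip, analytic)
})

test_that("integration handles degenerate caps and preserves positivity", {
  g <- sim_grid(16)
  init <- field_state(random_initial_A(g, 1), zero_initial_H(g))
  out0 <- integrate_rd(init, kinetic_params(), g,
                       solver_control(t_end = 0))
  expect_identical(out0$state$A, init$A)
  expect_false(out0$converged)
  expect_identical(out0$n_steps, 0L)
  # positivity clamp holds through the violent transient of a strong scenario
  out <- integrate_rd(init, kinetic_params(G_A = 7), g,
                      solver_control(t_end = 500))
  expect_true(all(out$state$A >= 0))
  expect_true(all(out$state$H >= 0))
  expect_true(all(is.finite(out$state$A)))
})

test_that("identical seed and configuration give bit-identical fields", {
  g <- sim_grid(24)
  ctl <- solver_control(t_end = 300)
  s1 <- simulate_pattern("standard", grid = g, seed = 11, control = ctl)
  s2 <- simulate_pattern("standard", grid = g, seed = 11, control = ctl)
  expect_identical(s1$A, s2$A)
  expect_identical(s1$H, s2$H)
  s3 <- simulate_pattern("standard", grid = g, seed = 12, control = ctl)
  expect_false(identical(s1$A, s3$A))
})

test_that("equal diffusion collapses the field to the homogeneous state", {
  p <- kinetic_params(D_A = 0.5, D_H = 0.5, check_diffusion = FALSE)
  expect_false(dispersion_relation(p)$turing_unstable)
  g <- sim_grid(32)
  init <- field_state(random_initial_A(g, 5), zero_initial_H(g))
  out <- integrate_rd(init, p, g, solver_control(t_end = 5000))
  A <- out$state$A
  expect_lt(max(A) - min(A), 1e-3)
  ss <- homogeneous_steady_state(p)
  expect_lt(max(abs(A - ss$A_star)), 1e-3)
  expect_lt(max(abs(out$state$H - ss$H_star)), 1e-3)
})

test_that("snapshots are recorded at the requested cadence", {
  g <- sim_grid(16)
  init <- field_state(random_initial_A(g, 1), zero_initial_H(g))
  out <- integrate_rd(init, kinetic_params(), g,
                      solver_control(t_end = 100, save_every = 25,
                                     steady_tol = 1e-15))
  expect_gte(length(out$snapshots), 3)
  ts <- vapply(out$snapshots, `[[`, numeric(1), "t")
  expect_true(all(diff(ts) > 0))
})

test_that("blow-up and non-finite states raise actionable errors", {
  g <- sim_grid(8)
  # absurd step on the explicit scheme without limiter -> divergence
  init <- field_state(matrix(1e6, 8, 8), matrix(0, 8, 8))
  expect_error(
    integrate_rd(init, kinetic_params(G_A = 70), g,
                 solver_control(scheme = "euler", dt = 1e3, dt_max = 1e3,
                                dt_policy = "fixed", limiter = Inf,
                                t_end = 1e5, positivity = FALSE)),
    "blow-up|non-finite")
})
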