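test_that("parameter validation enforces the model's constraints", {
  expect_s3_class(kinetic_params(), "kinetic_params")
  expect_error(kinetic_params(G_A = 0), "strictly positive")
  expect_error(kinetic_params(k = -1), "strictly positive")
  expect_error(kinetic_params(rho_A = -0.1), "rho_A")
  expect_error(kinetic_params(D_A = 0.5, D_H = 0.5), "D_H must be larger")
  expect_error(kinetic_params(D_A = 0.6), "D_H must be larger")
  # escape hatch for stability negative controls only
  expect_silent(kinetic_params(D_A = 0.5, D_H = 0.5,
                               check_diffusion = FALSE))
})

test_that("reaction terms match direct evaluation of the rate laws", {
  p <- kinetic_params()
  r0 <- reaction_terms(0, 0, p)
  expect_equal(r0$dA, 0.01)  # basal production only
  expect_equal(r0$dH, 0)
  r1 <- reaction_terms(1, 0, p)
  expect_equal(r1$dA, 0.08 / 0.001 + 0.01 - 0.03)  # 79.98
  r2 <- reaction_terms(1, 4, p)
  expect_equal(r2$dH, 0.12 * 1 - 0.03 * 4)  # balanced at H = 4 A^2
  # elementwise on fields
  A <- matrix(runif(16), 4, 4); H <- matrix(runif(16), 4, 4)
  r <- reaction_terms(A, H, p)
  expect_equal(r$dA, p$G_A * A^2 / (H + p$k) + p$rho_A - p$mu_A * A)
  expect_error(reaction_terms(matrix(1, 2, 2), matrix(1, 3, 3), p),
               "same shape")
  expect_error(reaction_terms(-1, 0, p), "negative concentration")
})

test_that("homogeneous steady state agrees with the cubic-root oracle", {
  sets <- list(
    kinetic_params(),
    kinetic_params(G_A = 0.1632),
    kinetic_params(G_A = 0.66),
    kinetic_params(G_A = 2.712),
    kinetic_params(G_A = 7),
    kinetic_params(G_A = 70),
    kinetic_params(mu_A = 0.01),
    kinetic_params(G_A = 2.712, mu_A = 0.01))
  for (p in sets) {
    ss <- homogeneous_steady_state(p)
    orc <- steady_state_oracle(p)
    expect_equal(ss$A_star, orc$A_star, tolerance = 1e-9)
    expect_equal(ss$H_star, orc$H_star, tolerance = 1e-9)
    res <- reaction_terms(ss$A_star, ss$H_star, p)
    expect_lt(abs(res$dA), 1e-10)
    expect_lt(abs(res$dH), 1e-10)
    expect_equal(ss$H_star, (p$G_H / p$mu_H) * ss$A_star^2)
  }
  # the standard fixed point sits at (~1, ~4)
  ss <- homogeneous_steady_state(kinetic_params())
  expect_equal(ss$A_star, 1, tolerance = 1e-3)
  expect_equal(ss$H_star, 4, tolerance = 1e-3)
})

test_that("steady state without basal production still finds the positive branch", {
  p <- kinetic_params(rho_A = 0)
  ss <- homogeneous_steady_state(p)
  expect_gt(ss$A_star, 0)
  expect_lt(abs(reaction_terms(ss$A_star, ss$H_star, p)$dA), 1e-10)
  orc <- steady_state_oracle(p)
  expect_equal(ss$A_star, orc$A_star, tolerance = 1e-9)
})

test_that("A* is monotone in G_A and mu_A over the scenario ranges", {
  gas <- c(0.08, 0.1632, 0.66, 2.712, 7, 70)
  Astars <- vapply(gas, function(g)
    homogeneous_steady_state(kinetic_params(G_A = g))$A_star, numeric(1))
  expect_true(all(diff(Astars) >= 0))
  oracle <- vapply(gas, function(g)
    steady_state_oracle(kinetic_params(G_A = g))$A_star, numeric(1))
  expect_equal(Astars, oracle, tolerance = 1e-9)
  mus <- c(0.01, 0.02, 0.03, 0.05)
  Amu <- vapply(mus, function(m)
    homogeneous_steady_state(kinetic_params(mu_A = m))$A_star, numeric(1))
  expect_true(all(diff(Amu) <= 0))
})

test_that("the reaction Jacobian matches central differences", {
  p <- kinetic_params()
  ss <- homogeneous_steady_state(p)
  J <- jacobian_at(p, ss)
  h <- 1e-6
  fd <- function(f, wrt) {
    if (wrt == "A")
      (f(ss$A_star + h, ss$H_star) - f(ss$A_star - h, ss$H_star)) / (2 * h)
    else
      (f(ss$A_star, ss$H_star + h) - f(ss$A_star, ss$H_star - h)) / (2 * h)
  }
  fa <- function(A, H) reaction_terms(A, H, p)$dA
  ga <- function(A, H) reaction_terms(A, H, p)$dH
  expect_equal(J[["f_A"]], fd(fa, "A"), tolerance = 1e-6)
  expect_equal(J[["f_H"]], fd(fa, "H"), tolerance = 1e-6)
  expect_equal(J[["g_A"]], fd(ga, "A"), tolerance = 1e-6)
  expect_equal(J[["g_H"]], fd(ga, "H"), tolerance = 1e-6)
  # zero-state Jacobian collapses to pure decay
  z <- list(A_star = 0, H_star = 0)
  Jz <- jacobian_at(p, z)
  expect_equal(unname(Jz), c(-p$mu_A, 0, 0, -p$mu_H))
  # g_H is -mu_H regardless of the state
  expect_equal(jacobian_at(p, list(A_star = 3, H_star = 7))[["g_H"]],
               -p$mu_H)
})

test_that("dispersion relation reproduces the eigenvalue oracle and Turing onset", {
  p <- kinetic_params()
  ss <- homogeneous_steady_state(p)
  dr <- dispersion_relation(p, ss, n_q = 200)
  expect_length(dr$growth_rates, 200)
  expect_length(dr$wavenumbers, 200)
  # q = 0: growth equals the max real eigenvalue of the reaction Jacobian
  J <- jacobian_at(p, ss)
  lam0 <- max(Re(eigen(matrix(c(J[["f_A"]], J[["g_A"]], J[["f_H"]],
                                J[["g_H"]]), 2, 2),
                       only.values = TRUE)$values))
  expect_equal(dr$growth_rates[1], lam0, tolerance = 1e-12)
  # full curve against a numeric eigenvalue oracle
  oracle <- vapply(dr$wavenumbers, function(q) {
    M <- matrix(c(J[["f_A"]] - p$D_A * q^2, J[["g_A"]],
                  J[["f_H"]], J[["g_H"]] - p$D_H * q^2), 2, 2)
    max(Re(eigen(M, only.values = TRUE)$values))
  }, numeric(1))
  expect_equal(dr$growth_rates, oracle, tolerance = 1e-10)
  # standard set: unstable band at q > 0, stable uniform mode
  expect_true(dr$turing_unstable)
  expect_lt(dr$growth_rates[1], 0)
  expect_gt(sum(dr$growth_rates > 0 & dr$wavenumbers > 0), 3)
  # equal diffusion kills the instability
  peq <- kinetic_params(D_A = 0.5, D_H = 0.5, check_diffusion = FALSE)
  dreq <- dispersion_relation(peq)
  expect_false(dreq$turing_unstable)
  expect_true(all(dreq$growth_rates < 0))
  # non-fixed-point states are rejected
  expect_error(dispersion_relation(p, list(A_star = 5, H_star = 1)),
               "not a fixed point")
})

test_that("the fastest-growing wavelength predicts the observed spot spacing", {
  dr <- dispersion_relation(kinetic_params())
  wl <- 2 * pi / dr$q_max
  expect_gt(wl, 8)
  expect_lt(wl, 12)
})
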