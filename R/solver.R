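#' Solver configuration
#'
#' Controls time integration of the reaction-diffusion system. The default
#' scheme is a first-order semi-implicit IMEX step: diffusion and linear
#' decay are treated implicitly through the exact spectral diagonalization
#' of the periodic-grid Laplacian (2-D FFT), while the nonlinear reaction
#' terms are explicit. An explicit-Euler scheme is provided as an
#' independent reference.
#'
#' The adaptive step policy starts at `dt`, multiplies the step by
#' `dt_grow` after every accepted step up to `dt_max`, and additionally
#' limits every step so that the explicit reaction increment cannot exceed
#' `limiter * (1 + max(field))` for either species. The limiter is what
#' keeps the violent initial transient (inhibitor starts at zero, so the
#' saturable self-activation term is of order `A^2/k`) on the physical
#' trajectory at the strongly enhanced self-activation scenarios.
#'
#' @param scheme `"imex"` (default) or `"euler"`.
#' @param dt initial time step.
#' @param dt_policy `"adaptive"` (geometric ramp plus limiter, default) or
#'   `"fixed"` (always `dt`, limiter still applies as a safety net).
#' @param dt_max cap on the adaptive step.
#' @param dt_grow per-step growth factor of the adaptive ramp.
#' @param limiter explicit-increment limit as a fraction of the current
#'   field scale; `Inf` disables it.
#' @param t_end stopping-time cap (dimensionless time units).
#' @param steady_tol relative-change criterion for steady state; see
#'   [steady_state_reached()].
#' @param positivity clamp negative entries to zero after every step.
#' @param save_every if a positive number, snapshot the state every that
#'   many time units (approximately; at the step granularity).
#' @return An object of class `solver_control`.
#' @export
solver_control <- function(scheme = c("imex", "euler"), dt = 0.1,
                           dt_policy = c("adaptive", "fixed"),
                           dt_max = 5, dt_grow = 1.05, limiter = 0.5,
                           t_end = 20000, steady_tol = 1e-6,
                           positivity = TRUE, save_every = NULL) {
  scheme <- match.arg(scheme)
  dt_policy <- match.arg(dt_policy)
  stopifnot(dt > 0, t_end >= 0, steady_tol > 0, dt_max >= dt, dt_grow >= 1,
            limiter > 0)
  structure(list(scheme = scheme, dt = dt, dt_policy = dt_policy,
                 dt_max = dt_max, dt_grow = dt_grow, limiter = limiter,
                 t_end = t_end, steady_tol = steady_tol,
                 positivity = positivity, save_every = save_every),
            class = "solver_control")
}

#' Steady-state stopping criterion
#'
#' Declares steady state when the maximal field change per unit time,
#' relative to the activator scale, falls below `tol`:
#' `max(|cur$A - prev$A|, |cur$H - prev$H|) / (dt * (1 + max(cur$A))) < tol`.
#'
#' @param prev,cur `field_state` objects (or lists with matrices `A`, `H`)
#'   of matching shape.
#' @param dt the time step separating them.
#' @param tol relative-change tolerance.
#' @return Logical flag.
#' @export
steady_state_reached <- function(prev, cur, dt, tol) {
  stopifnot(dt > 0)
  if (!identical(dim(prev$A), dim(cur$A)))
    stop("states have mismatched shapes")
  ch <- max(max(abs(cur$A - prev$A)), max(abs(cur$H - prev$H)))
  ch / (dt * (1 + max(cur$A))) < tol
}

# one IMEX step given precomputed implicit denominators (fft ordering)
.imex_core <- function(A, H, GA_map, params, dt, denA, denH, positivity) {
  nn <- length(A)
  NA_ <- GA_map * A * A / (H + params$k) + params$rho_A
  NH_ <- params$G_H * A * A
  A2 <- Re(stats::fft(stats::fft(A + dt * NA_) / denA, inverse = TRUE)) / nn
  H2 <- Re(stats::fft(stats::fft(H + dt * NH_) / denH, inverse = TRUE)) / nn
  if (positivity) {
    A2[A2 < 0] <- 0
    H2[H2 < 0] <- 0
  }
  list(A = A2, H = H2)
}

.euler_core <- function(A, H, GA_map, params, dt, spacing, positivity) {
  NA_ <- GA_map * A * A / (H + params$k) + params$rho_A
  NH_ <- params$G_H * A * A
  A2 <- A + dt * (NA_ - params$mu_A * A +
                    params$D_A * periodic_laplacian(A, spacing))
  H2 <- H + dt * (NH_ - params$mu_H * H +
                    params$D_H * periodic_laplacian(H, spacing))
  if (positivity) {
    A2[A2 < 0] <- 0
    H2[H2 < 0] <- 0
  }
  list(A = A2, H = H2)
}

#' Advance the state by one semi-implicit IMEX step
#'
#' Diffusion and linear decay are solved implicitly in Fourier space
#' (periodic-grid spectral diagonalization); the nonlinear reaction terms
#' are explicit. Intended for tests and custom loops; [integrate_rd()] is
#' the production driver.
#'
#' @param state a [field_state()].
#' @param pfield a [parameter_field()] (or [kinetic_params()], taken as
#'   spatially uniform).
#' @param dt time step.
#' @param grid a [sim_grid()] matching the state (default inferred with
#'   unit-spacing `L = n`).
#' @param positivity clamp negatives to zero (default `TRUE`).
#' @return The advanced [field_state()] with `t` incremented by `dt`.
#' @export
imex_step <- function(state, pfield, dt, grid = NULL, positivity = TRUE) {
  stopifnot(dt > 0)
  pf <- as_parameter_field(pfield, n = nrow(state$A))
  n <- nrow(state$A)
  if (is.null(grid)) grid <- sim_grid(n, n)
  lam <- .laplacian_eigenvalues(n, grid$spacing)
  p <- pf$base
  denA <- 1 + dt * (p$mu_A - p$D_A * lam)
  denH <- 1 + dt * (p$mu_H - p$D_H * lam)
  st <- .imex_core(state$A, state$H, pf$GA_map, p, dt, denA, denH, positivity)
  .check_fields(st, state$t + dt)
  field_state(st$A, st$H, state$t + dt)
}

#' Advance the state by one explicit Euler step
#'
#' Reference scheme: all terms explicit, diffusion via the 5-point periodic
#' stencil. Subject to the usual stability limit
#' `dt <= spacing^2 / (4 * D_H)`.
#'
#' @inheritParams imex_step
#' @return The advanced [field_state()].
#' @export
euler_step <- function(state, pfield, dt, grid = NULL, positivity = TRUE) {
  stopifnot(dt > 0)
  pf <- as_parameter_field(pfield, n = nrow(state$A))
  n <- nrow(state$A)
  if (is.null(grid)) grid <- sim_grid(n, n)
  st <- .euler_core(state$A, state$H, pf$GA_map, pf$base, dt, grid$spacing,
                    positivity)
  .check_fields(st, state$t + dt)
  field_state(st$A, st$H, state$t + dt)
}

.check_fields <- function(st, t) {
  if (!all(is.finite(st$A)))
    stop("non-finite values in field A at t = ", format(t),
         " (time step too large)")
  if (!all(is.finite(st$H)))
    stop("non-finite values in field H at t = ", format(t),
         " (time step too large)")
  if (max(st$A, st$H) > 1e12)
    stop("solution blow-up (max field > 1e12) at t = ", format(t),
         "; use a smaller dt")
  invisible(TRUE)
}

#' Integrate the reaction-diffusion system to (near) steady state
#'
#' Advances the system with the configured scheme until the steady-state
#' criterion fires or `t >= t_end`. Deterministic for a given initial
#' state, parameter field and configuration.
#'
#' @param init a [field_state()] (see [random_initial_A()] and
#'   [zero_initial_H()] for the canonical initial conditions).
#' @param pfield a [parameter_field()] or [kinetic_params()].
#' @param grid a [sim_grid()] whose `n` matches the fields.
#' @param control a [solver_control()].
#' @return A list with `state` (final [field_state()]), `converged`
#'   (logical), `n_steps`, and `snapshots` (list of `field_state`, empty
#'   unless `control$save_every` is set).
#' @examples
#' g <- sim_grid(16)
#' init <- field_state(random_initial_A(g, seed = 1), zero_initial_H(g))
#' out <- integrate_rd(init, kinetic_params(), g,
#'                     solver_control(t_end = 10))
#' out$n_steps
#' @export
integrate_rd <- function(init, pfield, grid, control = solver_control()) {
  stopifnot(inherits(grid, "sim_grid"), inherits(control, "solver_control"))
  pf <- as_parameter_field(pfield, n = grid$n)
  if (nrow(init$A) != grid$n)
    stop("initial state shape does not match grid")
  p <- pf$base
  GA_map <- pf$GA_map
  imex <- control$scheme == "imex"
  lam <- if (imex) .laplacian_eigenvalues(grid$n, grid$spacing)
  A <- init$A; H <- init$H; t <- init$t
  dt_ramp <- control$dt
  n_steps <- 0L
  converged <- FALSE
  snapshots <- list()
  next_snap <- if (!is.null(control$save_every)) t + control$save_every else Inf
  dt_last <- -1
  denA <- denH <- NULL
  while (t < control$t_end) {
    dt <- if (control$dt_policy == "adaptive") dt_ramp else control$dt
    if (is.finite(control$limiter)) {
      NA_max <- max(GA_map * A * A / (H + p$k)) + p$rho_A
      NH_max <- max(p$G_H * A * A)
      if (NA_max > 0)
        dt <- min(dt, control$limiter * (1 + max(A)) / NA_max)
      if (NH_max > 0)
        dt <- min(dt, control$limiter * (1 + max(H)) / NH_max)
    }
    dt <- min(dt, control$t_end - t)
    if (imex) {
      if (dt != dt_last) {
        denA <- 1 + dt * (p$mu_A - p$D_A * lam)
        denH <- 1 + dt * (p$mu_H - p$D_H * lam)
        dt_last <- dt
      }
      st <- .imex_core(A, H, GA_map, p, dt, denA, denH, control$positivity)
    } else {
      st <- .euler_core(A, H, GA_map, p, dt, grid$spacing,
                        control$positivity)
    }
    .check_fields(st, t + dt)
    ch <- max(max(abs(st$A - A)), max(abs(st$H - H)))
    A <- st$A; H <- st$H
    t <- t + dt
    n_steps <- n_steps + 1L
    if (t >= next_snap) {
      snapshots[[length(snapshots) + 1L]] <- field_state(A, H, t)
      next_snap <- next_snap + control$save_every
    }
    if (ch / (dt * (1 + max(A))) < control$steady_tol) {
      converged <- TRUE
      break
    }
    if (control$dt_policy == "adaptive")
      dt_ramp <- min(control$dt_max, dt_ramp * control$dt_grow)
  }
  list(state = field_state(A, H, t), converged = converged,
       n_steps = n_steps, snapshots = snapshots)
}
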