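#' Kinetic parameters of the PeMYB11-PeMYBx interaction model
#'
#' Bundles the eight coefficients of the activator-inhibitor system
#' \deqn{\partial A/\partial t = G_A A^2/(H + k) + \rho_A + D_A \Delta A - \mu_A A}
#' \deqn{\partial H/\partial t = G_H A^2 + D_H \Delta H - \mu_H H}
#' where \eqn{A} is the activator (PeMYB11) and \eqn{H} the diffusible
#' inhibitor (PeMYBx), both in \eqn{\mu M}; time and space are dimensionless.
#' The defaults are the standard spotted-patterning set widely used for
#' MYB activator-inhibitor systems.
#'
#' @param G_A self-activation potency of the activator (concentration/time).
#' @param G_H potency of inhibitor production driven by \eqn{A^2}
#'   (1/(concentration time)).
#' @param D_A,D_H diffusion rates (area/time). Pattern formation requires
#'   `D_H > D_A`; the constructor enforces it.
#' @param mu_A,mu_H degradation rates (1/time).
#' @param rho_A basal activator production (concentration/time), may be zero.
#' @param k saturation constant in the self-activation term
#'   (concentration, \eqn{\mu M}); must be positive so that the term is
#'   finite at `H = 0`.
#' @param check_diffusion enforce `D_H > D_A` (default). Set to `FALSE`
#'   only for linear-stability negative controls (e.g. equal diffusion,
#'   which cannot produce a Turing pattern); configuration input always
#'   keeps the check on.
#' @return An object of class `kinetic_params` (a validated named list).
#' @examples
#' p <- kinetic_params()
#' p$G_A
#' @export
kinetic_params <- function(G_A = 0.08, G_H = 0.12, D_A = 0.01, D_H = 0.5,
                           mu_A = 0.03, mu_H = 0.03, rho_A = 0.01,
                           k = 0.001, check_diffusion = TRUE) {
  p <- list(G_A = G_A, G_H = G_H, D_A = D_A, D_H = D_H,
            mu_A = mu_A, mu_H = mu_H, rho_A = rho_A, k = k)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("kinetic parameter '", nm, "' must be a single finite number")
  }
  strict <- setdiff(names(p), "rho_A")
  bad <- strict[vapply(p[strict], function(v) v <= 0, logical(1))]
  if (length(bad))
    stop("kinetic parameter(s) must be strictly positive: ",
         paste(bad, collapse = ", "))
  if (p$rho_A < 0) stop("rho_A must be >= 0")
  if (check_diffusion && p$D_H <= p$D_A)
    stop("D_H must be larger than D_A (got D_A = ", p$D_A,
         ", D_H = ", p$D_H, ")")
  structure(p, class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Kinetic parameters (activator-inhibitor model):\n")
  print(unlist(x))
  invisible(x)
}

#' Reaction terms of the activator-inhibitor system
#'
#' Evaluates the reaction part of the model (diffusion excluded) pointwise:
#' `dA = G_A*A^2/(H + k) + rho_A - mu_A*A` and `dH = G_H*A^2 - mu_H*H`.
#'
#' @param A,H scalars or arrays of matching shape, nonnegative.
#' @param params a [kinetic_params()] object.
#' @return A list with components `dA` and `dH`, same shape as the inputs.
#' @examples
#' reaction_terms(1, 4, kinetic_params())
#' @export
reaction_terms <- function(A, H, params) {
  stopifnot(inherits(params, "kinetic_params"))
  if (!identical(dim(A), dim(H)) || length(A) != length(H))
    stop("A and H must have the same shape")
  if (any(A < 0) || any(H < 0))
    stop("negative concentration passed to reaction_terms ",
         "(positivity violated upstream)")
  list(dA = params$G_A * A^2 / (H + params$k) + params$rho_A - params$mu_A * A,
       dH = params$G_H * A^2 - params$mu_H * H)
}

# Scalar reaction balance for A on the nullcline H = (G_H/mu_H) A^2;
# its largest positive root is the homogeneous fixed point.
.ss_residual <- function(A, params) {
  H <- (params$G_H / params$mu_H) * A^2
  params$G_A * A^2 / (H + params$k) + params$rho_A - params$mu_A * A
}

#' Homogeneous steady state of the reaction system
#'
#' Finds the spatially uniform fixed point `(A*, H*)` of the reaction terms,
#' with `H* = (G_H/mu_H) A*^2`. The scalar balance for `A` is solved on a
#' bracket `[1e-8, A_hi]` with `A_hi = 10*(G_A/(mu_A*G_H/mu_H) + rho_A/mu_A)`,
#' which contains the positive root for every scenario of interest; the
#' largest sign change is bracketed, refined by [stats::uniroot()] and
#' polished by Newton steps until both reaction residuals are below `tol`.
#'
#' @param params a [kinetic_params()] object.
#' @param tol residual tolerance for the fixed point (default `1e-12`).
#' @return An object of class `homogeneous_state`: list with `A_star`,
#'   `H_star` and `residuals` (the two reaction rates at the fixed point).
#' @examples
#' homogeneous_steady_state(kinetic_params())
#' @export
homogeneous_steady_state <- function(params, tol = 1e-12) {
  stopifnot(inherits(params, "kinetic_params"))
  A_hi <- 10 * (params$G_A / (params$mu_A * params$G_H / params$mu_H) +
                  params$rho_A / params$mu_A)
  if (A_hi <= 1e-8) A_hi <- 1
  # scan a dense grid, keep the last sign change => largest (stable-branch) root
  As <- seq(1e-8, A_hi, length.out = 4096L)
  fs <- .ss_residual(As, params)
  sgn <- sign(fs)
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (!length(flips)) {
    exact <- which(fs == 0)
    if (length(exact))
      flips <- max(exact) - 1L
    else
      stop("no positive homogeneous fixed point found on (0, ",
           format(A_hi), "]; residual at bracket ends: ",
           format(fs[1]), ", ", format(fs[length(fs)]))
  }
  i <- max(flips)
  root <- stats::uniroot(.ss_residual, c(As[i], As[i + 1L]), params = params,
                         tol = .Machine$double.eps^0.75)$root
  # Newton polish to push the residual to ~machine precision
  for (it in 1:50) {
    f <- .ss_residual(root, params)
    if (abs(f) < tol) break
    h <- max(abs(root), 1) * 1e-7
    df <- (.ss_residual(root + h, params) - .ss_residual(root - h, params)) /
      (2 * h)
    if (!is.finite(df) || df == 0) break
    root <- root - f / df
  }
  A_star <- root
  H_star <- (params$G_H / params$mu_H) * A_star^2
  res <- reaction_terms(A_star, H_star, params)
  if (abs(res$dA) > tol * max(1, params$mu_A * A_star) || abs(res$dH) > tol)
    stop("fixed-point refinement failed: residuals ",
         format(res$dA), ", ", format(res$dH))
  structure(list(A_star = A_star, H_star = H_star,
                 residuals = c(dA = res$dA, dH = res$dH)),
            class = "homogeneous_state")
}

#' @export
print.homogeneous_state <- function(x, ...) {
  cat(sprintf("Homogeneous steady state: A* = %.6g, H* = %.6g uM\n",
              x$A_star, x$H_star))
  cat(sprintf("  reaction residuals: %.3g, %.3g\n",
              x$residuals[1], x$residuals[2]))
  invisible(x)
}

#' Reaction Jacobian at a homogeneous state
#'
#' Partial derivatives of the reaction terms at `(A*, H*)`:
#' `f_A = 2 G_A A*/(H* + k) - mu_A`, `f_H = -G_A A*^2/(H* + k)^2`,
#' `g_A = 2 G_H A*`, `g_H = -mu_H`.
#'
#' @param params a [kinetic_params()] object.
#' @param state a `homogeneous_state` (or list with `A_star`, `H_star`).
#' @return Named numeric vector `c(f_A, f_H, g_A, g_H)`.
#' @export
jacobian_at <- function(params, state) {
  stopifnot(inherits(params, "kinetic_params"))
  A <- state$A_star; H <- state$H_star
  c(f_A = 2 * params$G_A * A / (H + params$k) - params$mu_A,
    f_H = -params$G_A * A^2 / (H + params$k)^2,
    g_A = 2 * params$G_H * A,
    g_H = -params$mu_H)
}

#' Dispersion relation of the linearized reaction-diffusion system
#'
#' For each wavenumber `q` the growth rate is the largest real part of the
#' eigenvalues of
#' \deqn{\begin{pmatrix} f_A - D_A q^2 & f_H \\ g_A & g_H - D_H q^2 \end{pmatrix}}
#' evaluated at the homogeneous fixed point. The system is Turing unstable
#' when some `q > 0` grows (`lambda > 0`) while the uniform mode `q = 0`
#' decays. The fastest-growing wavenumber predicts the spot spacing
#' (wavelength `2*pi/q`).
#'
#' @param params a [kinetic_params()] object.
#' @param state optional `homogeneous_state`; computed from `params` when
#'   missing. A state whose reaction residuals exceed `1e-6` is rejected.
#' @param q_max upper end of the wavenumber grid, in inverse grid units
#'   (default `pi`, the Nyquist limit for unit spacing).
#' @param n_q number of wavenumbers on `[0, q_max]` (default 200).
#' @return An object of class `dispersion_result`: list with `wavenumbers`,
#'   `growth_rates`, `q_max` (argmax wavenumber), `lambda_max`, and
#'   `turing_unstable`.
#' @examples
#' dr <- dispersion_relation(kinetic_params())
#' dr$turing_unstable
#' @export
dispersion_relation <- function(params, state = NULL, q_max = pi, n_q = 200L) {
  stopifnot(inherits(params, "kinetic_params"), q_max > 0, n_q >= 2)
  if (is.null(state)) state <- homogeneous_steady_state(params)
  res <- reaction_terms(state$A_star, state$H_star, params)
  if (max(abs(res$dA), abs(res$dH)) > 1e-6)
    stop("state is not a fixed point of the reaction terms (residuals ",
         format(res$dA), ", ", format(res$dH), ")")
  J <- jacobian_at(params, state)
  q <- seq(0, q_max, length.out = n_q)
  a11 <- J[["f_A"]] - params$D_A * q^2
  a22 <- J[["g_H"]] - params$D_H * q^2
  tr <- a11 + a22
  det <- a11 * a22 - J[["f_H"]] * J[["g_A"]]
  disc <- tr^2 - 4 * det
  growth <- ifelse(disc >= 0, (tr + sqrt(pmax(disc, 0))) / 2, tr / 2)
  i <- which.max(growth)
  structure(list(wavenumbers = q,
                 growth_rates = growth,
                 q_max = q[i],
                 lambda_max = growth[i],
                 turing_unstable = growth[i] > 0 && q[i] > 0 && growth[1] < 0),
            class = "dispersion_result")
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat("Dispersion relation:\n")
  cat(sprintf("  lambda_max = %.6g at q = %.4g (wavelength %.3g grid units)\n",
              x$lambda_max, x$q_max,
              if (x$q_max > 0) 2 * pi / x$q_max else Inf))
  cat(sprintf("  q = 0 growth rate: %.6g\n", x$growth_rates[1]))
  cat("  Turing unstable:", x$turing_unstable, "\n")
  invisible(x)
}

#' @export
plot.dispersion_result <- function(x, ...) {
  graphics::plot(x$wavenumbers, x$growth_rates, type = "l",
                 xlab = "wavenumber q (1/grid units)",
                 ylab = expression(Re(lambda)(q)), ...)
  graphics::abline(h = 0, lty = 2, col = "grey40")
  graphics::points(x$q_max, x$lambda_max, pch = 19, col = "red3")
  invisible(x)
}
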