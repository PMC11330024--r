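#' Uniform periodic simulation grid
#'
#' The computational domain is the square `[0, L]^2` discretized by `n`
#' uniformly spaced points per side with periodic boundaries in both
#' directions. The default `n = 100`, `L = 100` gives unit spacing, i.e.
#' integer grid points `(i, j)` with `1 <= i, j <= 100`.
#'
#' @param n points per side (integer, at least 4).
#' @param L physical side length (dimensionless units); defaults to `n`,
#'   i.e. unit spacing at any resolution.
#' @return An object of class `sim_grid` with fields `n`, `L`, `spacing`.
#' @export
sim_grid <- function(n = 100L, L = n) {
  n <- as.integer(n)
  stopifnot(length(n) == 1L, n >= 4L, length(L) == 1L, L > 0)
  structure(list(n = n, L = L, spacing = L / n), class = "sim_grid")
}

#' @export
print.sim_grid <- function(x, ...) {
  cat(sprintf("Periodic grid: %d x %d points, side %g, spacing %g\n",
              x$n, x$n, x$L, x$spacing))
  invisible(x)
}

#' Concentration fields at a time point
#'
#' Container for the activator and inhibitor fields. Both must be square
#' matrices of equal shape, finite and nonnegative.
#'
#' @param A,H numeric matrices (\eqn{\mu M}).
#' @param t elapsed simulation time.
#' @return An object of class `field_state`.
#' @export
field_state <- function(A, H, t = 0) {
  stopifnot(is.matrix(A), is.matrix(H))
  if (!identical(dim(A), dim(H))) stop("A and H must have identical shape")
  if (nrow(A) != ncol(A)) stop("fields must be square matrices")
  if (!all(is.finite(A)) || !all(is.finite(H)))
    stop("fields must be finite")
  if (any(A < 0) || any(H < 0)) stop("fields must be nonnegative")
  structure(list(A = A, H = H, t = t), class = "field_state")
}

#' @export
print.field_state <- function(x, ...) {
  cat(sprintf("Field state at t = %g: %d x %d grid\n", x$t,
              nrow(x$A), ncol(x$A)))
  cat(sprintf("  A in [%.4g, %.4g], H in [%.4g, %.4g] uM\n",
              min(x$A), max(x$A), min(x$H), max(x$H)))
  invisible(x)
}

# wraparound shifts of a matrix by one cell in each direction
.shift_up <- function(M) rbind(M[-1L, , drop = FALSE], M[1L, , drop = FALSE])
.shift_down <- function(M) rbind(M[nrow(M), , drop = FALSE], M[-nrow(M), , drop = FALSE])
.shift_left <- function(M) cbind(M[, -1L, drop = FALSE], M[, 1L, drop = FALSE])
.shift_right <- function(M) cbind(M[, ncol(M), drop = FALSE], M[, -ncol(M), drop = FALSE])

#' Discrete Laplacian on a periodic grid
#'
#' Standard 5-point stencil with wraparound indexing, scaled by
#' `1/spacing^2`.
#'
#' @param field a square numeric matrix.
#' @param spacing grid spacing (default 1).
#' @return Matrix of the same shape.
#' @examples
#' periodic_laplacian(matrix(1, 4, 4))  # all zeros
#' @export
periodic_laplacian <- function(field, spacing = 1) {
  if (!is.matrix(field) || nrow(field) != ncol(field))
    stop("field must be a square matrix")
  stopifnot(all(is.finite(field)), spacing > 0)
  (.shift_up(field) + .shift_down(field) + .shift_left(field) +
     .shift_right(field) - 4 * field) / spacing^2
}

# eigenvalues of the periodic 5-point Laplacian under the 2-D DFT,
# as an n x n matrix aligned with fft() ordering
.laplacian_eigenvalues <- function(n, spacing = 1) {
  idx <- 0:(n - 1L)
  lam1 <- -(2 * sin(pi * idx / n))^2 / spacing^2
  outer(lam1, lam1, "+")
}
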