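# Seeded stochastic inputs. All generators are pure functions of
# (grid, parameters, seed) using R's default Mersenne-Twister RNG with
# runif(); the caller's RNG state is saved and restored.

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(),
                       inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Random initial activator field
#'
#' The activator is initialized i.i.d. uniform on `[0, 1]` per grid point,
#' reproducibly for a given seed (Mersenne-Twister).
#'
#' @param grid a [sim_grid()].
#' @param seed integer RNG seed.
#' @return `n x n` numeric matrix with entries in `[0, 1]`.
#' @export
random_initial_A <- function(grid, seed) {
  stopifnot(inherits(grid, "sim_grid"))
  with_seed(seed, matrix(stats::runif(grid$n^2), grid$n, grid$n))
}

#' Zero initial inhibitor field
#'
#' The inhibitor starts at zero everywhere: its biosynthesis is activated
#' by the activator, so none is present before the dynamics begin.
#'
#' @param grid a [sim_grid()].
#' @return `n x n` matrix of zeros.
#' @export
zero_initial_H <- function(grid) {
  stopifnot(inherits(grid, "sim_grid"))
  matrix(0, grid$n, grid$n)
}

# periodic Gaussian smoothing via the spectral transfer function
.smooth_periodic <- function(field, sigma) {
  n <- nrow(field)
  freq <- c(0:(n %/% 2), -((n - (n %/% 2 + 1)):1)) / n  # fft frequencies
  g1 <- exp(-2 * (pi * sigma * freq)^2)
  G <- outer(g1, g1)
  Re(stats::fft(stats::fft(field) * G, inverse = TRUE)) / n^2
}

#' Generate a binary mask
#'
#' Masks select the grid cells carrying the enhanced (`GA_pur`) versus
#' repressed (`GA_whi`) self-activation potency in heterogeneous scenarios.
#' Kinds:
#' \describe{
#'   \item{bernoulli}{each cell independently 1 with probability `p`.}
#'   \item{blocks}{the grid is tiled by `block x block` squares, each
#'     wholly 1 with probability `p` — coarse contiguous patches.}
#'   \item{blobs}{seeded white noise smoothed with a periodic Gaussian
#'     kernel (`smoothing` grid units) and thresholded at its empirical
#'     `1 - target_fraction` quantile, giving smooth contiguous patches
#'     whose covered fraction matches `target_fraction` up to quantile
#'     granularity.}
#'   \item{file}{read a 0/1 CSV written by [write_mask_csv()].}
#' }
#'
#' @param grid a [sim_grid()].
#' @param kind one of `"blobs"`, `"bernoulli"`, `"blocks"`, `"file"`.
#' @param seed integer RNG seed (ignored for `"file"`).
#' @param p coverage probability for `bernoulli`/`blocks`.
#' @param target_fraction target covered fraction for `blobs`, in (0, 1).
#' @param smoothing Gaussian smoothing length for `blobs`, grid units.
#' @param block side of the square tiles for `blocks`.
#' @param path CSV file for `kind = "file"`.
#' @return Integer `n x n` matrix of 0/1.
#' @examples
#' m <- make_mask(sim_grid(20), kind = "blobs", target_fraction = 0.3,
#'                seed = 7)
#' mean(m)
#' @export
make_mask <- function(grid, kind = c("blobs", "bernoulli", "blocks", "file"),
                      seed = 1L, p = 0.5, target_fraction = 0.5,
                      smoothing = 5, block = 10L, path = NULL) {
  stopifnot(inherits(grid, "sim_grid"))
  kind <- match.arg(kind)
  n <- grid$n
  mask <- switch(kind,
    bernoulli = {
      stopifnot(p >= 0, p <= 1)
      with_seed(seed, matrix(as.integer(stats::runif(n^2) < p), n, n))
    },
    blocks = {
      stopifnot(p >= 0, p <= 1, block >= 1)
      nb <- ceiling(n / block)
      coarse <- with_seed(seed,
                          matrix(as.integer(stats::runif(nb^2) < p), nb, nb))
      idx <- ceiling(seq_len(n) / block)
      coarse[idx, idx, drop = FALSE]
    },
    blobs = {
      stopifnot(target_fraction > 0, target_fraction < 1, smoothing > 0)
      noise <- with_seed(seed, matrix(stats::rnorm(n^2), n, n))
      sm <- .smooth_periodic(noise, smoothing)
      thr <- stats::quantile(sm, 1 - target_fraction, names = FALSE)
      matrix(as.integer(sm > thr), n, n)
    },
    file = {
      if (is.null(path)) stop("kind = 'file' requires a path")
      read_mask_csv(path, grid)
    })
  dimnames(mask) <- NULL
  mask
}

#' Write a binary mask as a 0/1 CSV
#'
#' Row-major single-channel CSV of 0/1 integers, no header — diffable and
#' language-neutral. Round-trips byte-identically through
#' [read_mask_csv()].
#'
#' @param mask integer 0/1 matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mask_csv <- function(mask, path) {
  if (!all(mask %in% c(0L, 1L))) stop("mask must be binary 0/1")
  utils::write.table(mask, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a binary mask from a 0/1 CSV
#'
#' @param path file written by [write_mask_csv()].
#' @param grid optional [sim_grid()]; when given, the shape is checked.
#' @return Integer 0/1 matrix.
#' @export
read_mask_csv <- function(path, grid = NULL) {
  if (!file.exists(path)) stop("mask file not found: ", path)
  m <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(m) <- NULL
  if (!all(m %in% c(0, 1)))
    stop("mask file contains non-binary values: ", path)
  storage.mode(m) <- "integer"
  if (!is.null(grid) && (nrow(m) != grid$n || ncol(m) != grid$n))
    stop("mask shape (", nrow(m), " x ", ncol(m),
         ") does not match grid (", grid$n, " x ", grid$n, ")")
  m
}
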