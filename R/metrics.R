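#' Threshold an activator field
#'
#' Binary mask of cells strictly above the visualization threshold
#' (2 \eqn{\mu M} by default, the conventional pigmentation cut-off).
#'
#' @param A numeric matrix.
#' @param threshold nonnegative concentration; cells with `A > threshold`
#'   (strict) are 1.
#' @return Integer 0/1 matrix.
#' @export
threshold_mask <- function(A, threshold = 2) {
  stopifnot(is.matrix(A), threshold >= 0)
  m <- matrix(as.integer(A > threshold), nrow(A), ncol(A))
  m
}

#' Relative threshold for the deep-colour layer
#'
#' For piece-wise `G_A` renderings a second, higher threshold marks the
#' deep colour layer. It is the `GA_whi/GA_pur` proportion of the maximum
#' activator level, clamped from below by the basic threshold so that the
#' deep layer always sits above the basic one.
#'
#' @param A activator field (nonempty matrix).
#' @param GA_whi,GA_pur the piece-wise potencies, `GA_pur > GA_whi > 0`.
#' @param basic basic threshold (\eqn{\mu M}).
#' @return A single concentration: `max(basic, (GA_whi/GA_pur) * max(A))`.
#' @examples
#' relative_threshold(matrix(10), GA_whi = 2.8, GA_pur = 7)  # 4
#' @export
relative_threshold <- function(A, GA_whi, GA_pur, basic = 2) {
  if (!is.matrix(A) || length(A) == 0) stop("A must be a nonempty matrix")
  if (!(GA_pur > GA_whi && GA_whi > 0))
    stop("need GA_pur > GA_whi > 0")
  max(basic, (GA_whi / GA_pur) * max(A))
}

# neighbor offsets for 4- and 8-connectivity
.conn_offsets <- function(connectivity) {
  if (connectivity == 4)
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  else
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L),
         c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))
}

#' Label connected spots in a binary mask
#'
#' Connected-component labelling by breadth-first search, with 4-neighbor
#' (default) or 8-neighbor connectivity. With `periodic = TRUE` components
#' touching across opposite edges are merged, consistent with the solver's
#' periodic boundary.
#'
#' @param mask integer/numeric 0/1 matrix.
#' @param connectivity 4 or 8.
#' @param periodic wrap neighbors around the edges (default `TRUE`).
#' @param A optional activator field used to record each spot's peak value
#'   and location.
#' @return An object of class `spot_set`: list with `label_map` (0 =
#'   background, spots labelled 1..n_spots), `n_spots`, `areas`,
#'   `centroids` (rows of (row, col), arithmetic means of cell indices),
#'   and `peaks` (data frame of peak value/location per spot, `NULL`
#'   without `A`).
#' @export
label_spots <- function(mask, connectivity = 4, periodic = TRUE, A = NULL) {
  stopifnot(is.matrix(mask))
  if (!all(mask %in% c(0, 1))) stop("mask must be binary 0/1")
  stopifnot(connectivity %in% c(4, 8))
  nr <- nrow(mask); nc <- ncol(mask)
  offs <- .conn_offsets(connectivity)
  lab <- matrix(0L, nr, nc)
  n_spots <- 0L
  areas <- integer()
  queue <- integer(nr * nc)
  fg <- which(mask == 1)
  for (start in fg) {
    if (lab[start] != 0L) next
    n_spots <- n_spots + 1L
    lab[start] <- n_spots
    queue[1L] <- start
    head <- 1L; tail <- 1L
    area <- 1L
    while (head <= tail) {
      cell <- queue[head]; head <- head + 1L
      r <- ((cell - 1L) %% nr) + 1L
      cc <- ((cell - 1L) %/% nr) + 1L
      for (off in offs) {
        r2 <- r + off[1L]; c2 <- cc + off[2L]
        if (periodic) {
          r2 <- ((r2 - 1L) %% nr) + 1L
          c2 <- ((c2 - 1L) %% nc) + 1L
        } else if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc) next
        nb <- r2 + (c2 - 1L) * nr
        if (mask[nb] == 1 && lab[nb] == 0L) {
          lab[nb] <- n_spots
          tail <- tail + 1L
          queue[tail] <- nb
          area <- area + 1L
        }
      }
    }
    areas <- c(areas, area)
  }
  centroids <- if (n_spots > 0) {
    t(vapply(seq_len(n_spots), function(s) {
      cells <- which(lab == s, arr.ind = TRUE)
      colMeans(cells)
    }, numeric(2)))
  } else matrix(numeric(0), 0, 2)
  colnames(centroids) <- c("row", "col")
  peaks <- NULL
  if (!is.null(A) && n_spots > 0) {
    stopifnot(identical(dim(A), dim(mask)))
    peaks <- do.call(rbind, lapply(seq_len(n_spots), function(s) {
      cells <- which(lab == s)
      top <- cells[which.max(A[cells])]
      data.frame(spot = s, peak = A[top],
                 row = ((top - 1L) %% nr) + 1L,
                 col = ((top - 1L) %/% nr) + 1L)
    }))
  }
  structure(list(label_map = lab, n_spots = n_spots, areas = areas,
                 centroids = centroids, peaks = peaks,
                 connectivity = connectivity, periodic = periodic),
            class = "spot_set")
}

#' @export
print.spot_set <- function(x, ...) {
  cat(sprintf("Spot set: %d spot(s), %d-connectivity, periodic = %s\n",
              x$n_spots, x$connectivity, x$periodic))
  if (x$n_spots > 0)
    cat("  areas:", paste(utils::head(sort(x$areas, decreasing = TRUE), 10),
                          collapse = ", "),
        if (x$n_spots > 10) "..." else "", "\n")
  invisible(x)
}

#' Summary metrics of a simulated pattern
#'
#' Thresholds the activator field, labels spots, and reports the metrics
#' that operationalize the qualitative pattern descriptions: spot count,
#' above-threshold area fraction, mean/max spot area, fusion index
#' (largest spot area over total above-threshold area; 1 = fully fused),
#' and the Pearson correlation of the activator and inhibitor fields
#' (positive correlation = the two species peak in phase).
#'
#' @param A activator field.
#' @param H inhibitor field of matching shape, or `NULL` to skip the
#'   correlation.
#' @param threshold concentration threshold (\eqn{\mu M}).
#' @param connectivity,periodic passed to [label_spots()].
#' @return An object of class `pattern_summary`: list with `n_spots`,
#'   `area_fraction`, `mean_area`, `max_area`, `fusion_index` (`NA` when
#'   no cell is above threshold), `ah_correlation` (`NA` without `H` or
#'   for constant fields), and `threshold`.
#' @export
pattern_summary <- function(A, H = NULL, threshold = 2, connectivity = 4,
                            periodic = TRUE) {
  stopifnot(is.matrix(A))
  if (!is.null(H) && !identical(dim(A), dim(H)))
    stop("A and H have mismatched shapes")
  mask <- threshold_mask(A, threshold)
  spots <- label_spots(mask, connectivity = connectivity,
                       periodic = periodic, A = A)
  total <- sum(mask)
  ahc <- NA_real_
  if (!is.null(H) && stats::sd(A) > 0 && stats::sd(H) > 0)
    ahc <- stats::cor(as.vector(A), as.vector(H))
  structure(list(
    n_spots = spots$n_spots,
    area_fraction = total / length(A),
    mean_area = if (spots$n_spots > 0) mean(spots$areas) else NA_real_,
    max_area = if (spots$n_spots > 0) max(spots$areas) else NA_real_,
    fusion_index = if (total > 0) max(spots$areas) / total else NA_real_,
    ah_correlation = ahc,
    threshold = threshold,
    spots = spots
  ), class = "pattern_summary")
}

#' @export
print.pattern_summary <- function(x, ...) {
  cat(sprintf("Pattern summary (threshold %g uM):\n", x$threshold))
  cat(sprintf("  spots: %d, area fraction: %.4f\n", x$n_spots,
              x$area_fraction))
  if (x$n_spots > 0)
    cat(sprintf("  spot area: mean %.1f, max %d cells; fusion index %.3f\n",
                x$mean_area, x$max_area, x$fusion_index))
  if (!is.na(x$ah_correlation))
    cat(sprintf("  activator-inhibitor correlation: %.3f\n",
                x$ah_correlation))
  invisible(x)
}

#' @export
as.data.frame.pattern_summary <- function(x, ...) {
  data.frame(n_spots = x$n_spots, area_fraction = x$area_fraction,
             mean_area = x$mean_area, max_area = x$max_area,
             fusion_index = x$fusion_index,
             ah_correlation = x$ah_correlation, threshold = x$threshold)
}

#' Radial decay of activator spots
#'
#' Each spot's concentration should be highest at its peak and decay
#' towards the rim. For every spot, cells are binned by rounded (toroidal)
#' distance from the peak cell; the per-spot score is the fraction of
#' consecutive ring pairs whose mean activator level is non-increasing
#' (ties count as non-increasing). Single-ring spots score 1.
#'
#' @param A activator field.
#' @param spots a [label_spots()] result computed from the same field.
#' @return List with `per_spot` (numeric vector of ring-monotonicity
#'   fractions) and `median` (median over spots; `NA` when there are no
#'   spots).
#' @export
radial_decay_check <- function(A, spots) {
  stopifnot(inherits(spots, "spot_set"),
            identical(dim(A), dim(spots$label_map)))
  nr <- nrow(A); nc <- ncol(A)
  per <- vapply(seq_len(spots$n_spots), function(s) {
    cells <- which(spots$label_map == s, arr.ind = TRUE)
    pk <- cells[which.max(A[cells]), ]
    dr <- abs(cells[, 1] - pk[1]); dr <- pmin(dr, nr - dr)
    dc <- abs(cells[, 2] - pk[2]); dc <- pmin(dc, nc - dc)
    ring <- round(sqrt(dr^2 + dc^2))
    means <- tapply(A[cells], ring, mean)
    if (length(means) < 2) return(1)
    mean(diff(means) <= 1e-12)
  }, numeric(1))
  list(per_spot = per,
       median = if (length(per)) stats::median(per) else NA_real_)
}
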