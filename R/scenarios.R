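#' Scale the standard self-activation potency by an experimental fold change
#'
#' The solo-LTR scenarios express enhanced *PeMYB11* transcription as a
#' multiple of the standard `G_A`; e.g. the 33.9-fold expression increase
#' measured in the purple regions gives `0.08 * 33.9 = 2.712`, and the
#' full-length *HORT1* repression gives `0.08 * 0.37 = 0.0296`.
#'
#' @param standard_GA baseline self-activation potency (> 0).
#' @param fold positive fold change.
#' @return The exact product.
#' @examples
#' fold_scaled_GA(0.08, 33.9)
#' @export
fold_scaled_GA <- function(standard_GA, fold) {
  if (!is.numeric(standard_GA) || standard_GA <= 0)
    stop("standard_GA must be positive")
  if (!is.numeric(fold) || fold <= 0) stop("fold must be positive")
  standard_GA * fold
}

#' Scale a self-activation potency by ploidy
#'
#' Harlequin cultivars are tetraploid, so scenario values may be multiplied
#' by a ploidy factor (e.g. `0.1632 * 4 = 0.6528`, registered in the preset
#' table as the conventional rounded value 0.66). The arithmetic here stays
#' exact; rounding lives only in the preset registry.
#'
#' @param GA self-activation potency (> 0).
#' @param ploidy_factor positive multiplier.
#' @return The exact product.
#' @examples
#' ploidy_scaled_GA(0.1632, 4)
#' @export
ploidy_scaled_GA <- function(GA, ploidy_factor) {
  if (!is.numeric(GA) || GA <= 0) stop("GA must be positive")
  if (!is.numeric(ploidy_factor) || ploidy_factor <= 0)
    stop("ploidy_factor must be positive")
  GA * ploidy_factor
}

#' Per-grid-cell kinetic parameters
#'
#' Couples a base [kinetic_params()] set with an `n x n` map of `G_A`
#' values; all other coefficients are spatially uniform. A uniform model is
#' the special case where every map entry equals `base$G_A`.
#'
#' @param base a [kinetic_params()] object.
#' @param GA_map `n x n` matrix of strictly positive `G_A` values, or
#'   `NULL` for a uniform field (the map is then materialized lazily by the
#'   solver at the grid size in use).
#' @return An object of class `parameter_field`.
#' @export
parameter_field <- function(base, GA_map = NULL) {
  stopifnot(inherits(base, "kinetic_params"))
  if (!is.null(GA_map)) {
    stopifnot(is.matrix(GA_map))
    if (any(!is.finite(GA_map)) || any(GA_map <= 0))
      stop("GA_map entries must be strictly positive and finite")
  }
  structure(list(base = base, GA_map = GA_map), class = "parameter_field")
}

# normalize kinetic_params / parameter_field to a field with a concrete map
as_parameter_field <- function(x, n) {
  if (inherits(x, "kinetic_params")) x <- parameter_field(x)
  stopifnot(inherits(x, "parameter_field"))
  if (is.null(x$GA_map)) {
    x$GA_map <- matrix(x$base$G_A, n, n)
  } else if (nrow(x$GA_map) != n || ncol(x$GA_map) != n) {
    stop("GA_map shape (", nrow(x$GA_map), " x ", ncol(x$GA_map),
         ") does not match grid (", n, " x ", n, ")")
  }
  x
}

#' @export
print.parameter_field <- function(x, ...) {
  cat("Parameter field:\n")
  print(x$base)
  if (is.null(x$GA_map)) {
    cat("  G_A: spatially uniform\n")
  } else {
    cat(sprintf("  G_A map: %d x %d, values in [%.4g, %.4g]\n",
                nrow(x$GA_map), ncol(x$GA_map), min(x$GA_map), max(x$GA_map)))
  }
  invisible(x)
}

#' Build a (possibly piece-wise) G_A parameter field
#'
#' Uniform specs fill the map with the base `G_A`; masked specs assign
#' `GA_pur` where the mask is 1 and `GA_whi` where it is 0, modelling the
#' heterogeneous distribution of the solo-LTR (enhancing) and full-length
#' (repressing) *HORT1* insertion across the tissue.
#'
#' @param ga_spec a list with `kind = "uniform"`, or
#'   `kind = "masked"` plus `GA_pur` and `GA_whi` (`GA_pur > GA_whi > 0`).
#' @param grid a [sim_grid()].
#' @param mask binary `n x n` matrix, required for masked specs (see
#'   [make_mask()]).
#' @param base base [kinetic_params()] for the remaining coefficients.
#' @return A [parameter_field()].
#' @examples
#' g <- sim_grid(10)
#' m <- make_mask(g, kind = "bernoulli", p = 0.5, seed = 1)
#' pf <- build_GA_field(list(kind = "masked", GA_pur = 7, GA_whi = 0.0296),
#'                      g, mask = m)
#' range(pf$GA_map)
#' @export
build_GA_field <- function(ga_spec, grid, mask = NULL,
                           base = kinetic_params()) {
  stopifnot(inherits(grid, "sim_grid"), is.list(ga_spec))
  kind <- ga_spec$kind %||% "uniform"
  if (kind == "uniform")
    return(parameter_field(base, matrix(base$G_A, grid$n, grid$n)))
  if (kind != "masked") stop("unknown ga_spec kind: ", kind)
  GA_pur <- ga_spec$GA_pur
  GA_whi <- ga_spec$GA_whi
  if (is.null(GA_pur) || is.null(GA_whi) || GA_whi <= 0)
    stop("masked ga_spec requires positive GA_pur and GA_whi")
  if (GA_pur <= GA_whi)
    stop("GA_pur (", GA_pur, ") must exceed GA_whi (", GA_whi, ")")
  if (is.null(mask)) stop("masked ga_spec requires a mask")
  if (!is.matrix(mask) || nrow(mask) != grid$n || ncol(mask) != grid$n)
    stop("mask shape does not match grid (", grid$n, " x ", grid$n, ")")
  if (!all(mask %in% c(0, 1))) stop("mask must be binary 0/1")
  GA_map <- matrix(ifelse(mask == 1, GA_pur, GA_whi), grid$n, grid$n)
  parameter_field(base, GA_map)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a named scenario
#'
#' A scenario is a fully specified, reproducible perturbation of the
#' standard parameter set: parameter overrides, an optional piece-wise
#' `G_A` specification, a default seed and visualization thresholds.
#'
#' @param name identifier.
#' @param overrides named list of [kinetic_params()] overrides.
#' @param ga_spec `G_A` field spec; see [build_GA_field()].
#' @param seed default RNG seed for the initial activator field.
#' @param thresholds list with `basic` (\eqn{\mu M}) and optional
#'   `relative` (`NULL`, a number, or `"auto"` for the
#'   [relative_threshold()] rule).
#' @return An object of class `scenario`.
#' @export
scenario <- function(name, overrides = list(),
                     ga_spec = list(kind = "uniform"), seed = 1L,
                     thresholds = list(basic = 2, relative = NULL)) {
  stopifnot(is.character(name), nzchar(name), is.list(overrides))
  unknown <- setdiff(names(overrides),
                     c("G_A", "G_H", "D_A", "D_H", "mu_A", "mu_H",
                       "rho_A", "k"))
  if (length(unknown))
    stop("unknown kinetic override(s): ", paste(unknown, collapse = ", "))
  if (identical(ga_spec$kind, "masked") &&
      (is.null(ga_spec$GA_pur) || is.null(ga_spec$GA_whi) ||
         ga_spec$GA_pur <= ga_spec$GA_whi))
    stop("masked ga_spec requires GA_pur > GA_whi")
  # validate that overrides produce legal parameters
  scenario_params(structure(list(overrides = overrides), class = "scenario"))
  structure(list(name = name, overrides = overrides, ga_spec = ga_spec,
                 seed = as.integer(seed), thresholds = thresholds),
            class = "scenario")
}

#' Kinetic parameters implied by a scenario
#'
#' @param scen a [scenario()] object.
#' @param base baseline parameters the overrides are applied to.
#' @return A [kinetic_params()] object.
#' @export
scenario_params <- function(scen, base = kinetic_params()) {
  args <- unclass(base)
  for (nm in names(scen$overrides)) args[[nm]] <- scen$overrides[[nm]]
  do.call(kinetic_params, args)
}

#' @export
print.scenario <- function(x, ...) {
  cat("Scenario:", x$name, "\n")
  if (length(x$overrides)) {
    cat("  overrides:",
        paste(names(x$overrides), unlist(x$overrides), sep = " = ",
              collapse = ", "), "\n")
  } else cat("  overrides: none (standard parameters)\n")
  if (identical(x$ga_spec$kind, "masked"))
    cat(sprintf("  piece-wise G_A: GA_pur = %g, GA_whi = %g\n",
                x$ga_spec$GA_pur, x$ga_spec$GA_whi))
  cat("  thresholds: basic =", x$thresholds$basic,
      if (!is.null(x$thresholds$relative))
        paste(", relative =", x$thresholds$relative) else "", "\n")
  invisible(x)
}

#' Registry of documented scenario presets
#'
#' Returns the named perturbations of the standard parameter set studied
#' for harlequin patterning:
#' \describe{
#'   \item{standard}{the baseline spotted pattern, `G_A = 0.08`.}
#'   \item{solo_ltr_2x}{solo-LTR promoter enhancement, `G_A = 0.1632`
#'     (about twofold of standard, from dual-luciferase data).}
#'   \item{tetraploid}{`G_A = 0.66`, the conventional rounded fourfold of
#'     0.1632 for tetraploid cultivars.}
#'   \item{yushan_expression}{`G_A = 2.712 = 33.9 x 0.08`, the measured
#'     expression increase in purple regions.}
#'   \item{vc_high, vc_veryhigh}{`G_A = 7` and `G_A = 70`, the high-end
#'     values used to track the rate of spot-size change.}
#'   \item{mir858_low}{reduced miR858, modelled as `mu_A = 0.01`.}
#'   \item{combined_066, combined_2712}{solo-LTR enhancement combined with
#'     reduced miR858 (`G_A` of 0.66 or 2.712 with `mu_A = 0.01`).}
#'   \item{heterogeneous}{piece-wise `G_A` (`GA_pur = 7`,
#'     `GA_whi = 0.0296`) with `mu_A = 0.01` and an automatic relative
#'     threshold for the deep-colour layer.}
#' }
#'
#' @return Named list of [scenario()] objects.
#' @examples
#' names(preset_scenarios())
#' @export
preset_scenarios <- function() {
  sc <- list(
    scenario("standard"),
    scenario("solo_ltr_2x", overrides = list(G_A = 0.1632)),
    scenario("tetraploid", overrides = list(G_A = 0.66)),
    scenario("yushan_expression", overrides = list(G_A = 2.712)),
    scenario("vc_high", overrides = list(G_A = 7)),
    scenario("vc_veryhigh", overrides = list(G_A = 70)),
    scenario("mir858_low", overrides = list(mu_A = 0.01)),
    scenario("combined_066", overrides = list(G_A = 0.66, mu_A = 0.01)),
    scenario("combined_2712", overrides = list(G_A = 2.712, mu_A = 0.01)),
    scenario("heterogeneous", overrides = list(mu_A = 0.01),
             ga_spec = list(kind = "masked", GA_pur = 7, GA_whi = 0.0296,
                            mask = "blobs"),
             thresholds = list(basic = 2, relative = "auto"))
  )
  stats::setNames(sc, vapply(sc, `[[`, character(1), "name"))
}

#' Write a scenario to a YAML file
#' @param scen a [scenario()] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scen, path) {
  stopifnot(inherits(scen, "scenario"))
  yaml::write_yaml(unclass(scen), path)
  invisible(path)
}

#' Read a scenario from a YAML file
#' @param path file written by [write_scenario()].
#' @return A [scenario()] object.
#' @export
read_scenario <- function(path) {
  x <- yaml::read_yaml(path)
  thr <- x$thresholds %||% list(basic = 2, relative = NULL)
  scenario(x$name, overrides = x$overrides %||% list(),
           ga_spec = x$ga_spec %||% list(kind = "uniform"),
           seed = x$seed %||% 1L, thresholds = thr)
}
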