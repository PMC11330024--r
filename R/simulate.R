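#' Simulate a pigmentation pattern scenario
#'
#' The main entry point: resolves a scenario (a preset name or a
#' [scenario()] object), builds the parameter field, draws the seeded
#' initial conditions (activator uniform on `[0, 1]`, inhibitor zero), and
#' integrates the activator-inhibitor system to (near) steady state.
#'
#' @param scen a preset name (see [preset_scenarios()]) or a [scenario()]
#'   object. Default `"standard"`.
#' @param grid a [sim_grid()] (default 100 x 100, unit spacing).
#' @param seed RNG seed for the initial activator field (and the default
#'   mask of heterogeneous scenarios). Overrides the scenario's own seed.
#' @param control a [solver_control()].
#' @param mask binary `n x n` matrix for masked scenarios; when `NULL` a
#'   seeded blob mask ([make_mask()] with `target_fraction = 0.5`,
#'   `smoothing = 5`) is generated from `seed`.
#' @param overrides additional named kinetic overrides applied on top of
#'   the scenario's.
#' @return An object of class `rd_pattern` with components `A`, `H`, `t`,
#'   `converged`, `n_steps`, `snapshots`, `scenario`, `params`, `pfield`,
#'   `grid`, `mask`, `seed`, `control`, `thresholds`. Methods: `print`,
#'   `summary`, `coef`, `plot`, `residuals`, `simulate`.
#' @examples
#' sim <- simulate_pattern("standard", grid = sim_grid(24), seed = 1,
#'                         control = solver_control(t_end = 200))
#' summary(sim)
#' @export
simulate_pattern <- function(scen = "standard", grid = sim_grid(),
                             seed = NULL, control = solver_control(),
                             mask = NULL, overrides = list()) {
  if (is.character(scen)) {
    presets <- preset_scenarios()
    if (!scen %in% names(presets))
      stop("unknown scenario '", scen, "'; available: ",
           paste(names(presets), collapse = ", "))
    scen <- presets[[scen]]
  }
  stopifnot(inherits(scen, "scenario"), inherits(grid, "sim_grid"))
  if (is.null(seed)) seed <- scen$seed
  if (length(overrides)) {
    ov <- scen$overrides
    ov[names(overrides)] <- overrides
    scen <- scenario(scen$name, overrides = ov, ga_spec = scen$ga_spec,
                     seed = seed, thresholds = scen$thresholds)
  }
  params <- scenario_params(scen)
  masked <- identical(scen$ga_spec$kind, "masked")
  if (masked && is.null(mask))
    mask <- make_mask(grid, kind = "blobs", target_fraction = 0.5,
                      smoothing = 5, seed = seed)
  pfield <- build_GA_field(scen$ga_spec, grid, mask = mask, base = params)
  init <- field_state(random_initial_A(grid, seed), zero_initial_H(grid))
  out <- integrate_rd(init, pfield, grid, control)
  thr <- scen$thresholds
  if (identical(thr$relative, "auto") && masked)
    thr$relative <- relative_threshold(out$state$A, scen$ga_spec$GA_whi,
                                       scen$ga_spec$GA_pur,
                                       basic = thr$basic)
  structure(list(A = out$state$A, H = out$state$H, t = out$state$t,
                 converged = out$converged, n_steps = out$n_steps,
                 snapshots = out$snapshots, scenario = scen,
                 params = params, pfield = pfield, grid = grid,
                 mask = if (masked) mask else NULL, seed = seed,
                 control = control, thresholds = thr,
                 call = match.call()),
            class = "rd_pattern")
}

#' @export
print.rd_pattern <- function(x, ...) {
  cat(sprintf("Reaction-diffusion pattern: scenario '%s', %d x %d grid, seed %d\n",
              x$scenario$name, x$grid$n, x$grid$n, x$seed))
  cat(sprintf("  t = %g after %d steps (%s)\n", x$t, x$n_steps,
              if (x$converged) "steady state reached" else "time cap hit"))
  cat(sprintf("  A in [%.3g, %.3g], H in [%.3g, %.3g] uM\n",
              min(x$A), max(x$A), min(x$H), max(x$H)))
  invisible(x)
}

#' @rdname simulate_pattern
#' @param object,x an `rd_pattern` object.
#' @param ... passed on / ignored.
#' @export
summary.rd_pattern <- function(object, ...) {
  s <- pattern_summary(object$A, object$H,
                       threshold = object$thresholds$basic, ...)
  s$scenario <- object$scenario$name
  s$converged <- object$converged
  s$t <- object$t
  class(s) <- c("summary.rd_pattern", class(s))
  s
}

#' @export
print.summary.rd_pattern <- function(x, ...) {
  cat(sprintf("Scenario '%s' (t = %g, %s)\n", x$scenario, x$t,
              if (x$converged) "converged" else "not converged"))
  NextMethod()
}

#' @export
coef.rd_pattern <- function(object, ...) {
  co <- unlist(object$params)
  ga <- object$pfield$GA_map
  if (!is.null(ga) && length(unique(as.vector(ga))) > 1L) {
    co <- co[names(co) != "G_A"]
    co <- c(G_A_pur = max(ga), G_A_whi = min(ga), co)
  }
  co
}

#' @export
residuals.rd_pattern <- function(object, ...) {
  pf <- as_parameter_field(object$pfield, object$grid$n)
  p <- pf$base
  rA <- pf$GA_map * object$A^2 / (object$H + p$k) + p$rho_A -
    p$mu_A * object$A +
    p$D_A * periodic_laplacian(object$A, object$grid$spacing)
  rH <- p$G_H * object$A^2 - p$mu_H * object$H +
    p$D_H * periodic_laplacian(object$H, object$grid$spacing)
  list(A = rA, H = rH)
}

#' @rdname simulate_pattern
#' @param type plot type: `"heatmap"` of the activator, `"contour"` at
#'   the basic threshold, or `"layers"` (three-tone rendering with the
#'   relative threshold, heterogeneous scenarios).
#' @param which field to show for heatmaps, `"A"` or `"H"`.
#' @export
plot.rd_pattern <- function(x, type = c("heatmap", "contour", "layers"),
                            which = c("A", "H"), ...) {
  type <- match.arg(type)
  which <- match.arg(which)
  F <- x[[which]]
  if (type == "heatmap") {
    graphics::image(seq_len(x$grid$n), seq_len(x$grid$n), t(F),
                    col = grDevices::hcl.colors(64, "Purples", rev = TRUE),
                    xlab = "", ylab = "", asp = 1,
                    main = sprintf("%s, %s", x$scenario$name, which), ...)
  } else if (type == "contour") {
    graphics::contour(seq_len(x$grid$n), seq_len(x$grid$n), t(F),
                      levels = x$thresholds$basic, drawlabels = FALSE,
                      xlab = "", ylab = "", asp = 1,
                      main = sprintf("%s, %s > %g uM", x$scenario$name,
                                     which, x$thresholds$basic), ...)
  } else {
    rel <- x$thresholds$relative
    if (is.null(rel) || identical(rel, "auto"))
      stop("'layers' rendering needs a resolved relative threshold")
    render_pattern(F, basic = x$thresholds$basic, relative = rel, ...)
  }
  invisible(x)
}

#' @rdname simulate_pattern
#' @param nsim number of replicate runs.
#' @param seed base seed; replicate `i` uses `seed + i - 1`.
#' @export
simulate.rd_pattern <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(seed)) seed <- object$seed + 1L
  lapply(seq_len(nsim), function(i)
    simulate_pattern(object$scenario, grid = object$grid,
                     seed = seed + i - 1L, control = object$control,
                     mask = object$mask))
}
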