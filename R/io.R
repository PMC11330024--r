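#' Write a concentration field as CSV
#'
#' Full-precision (17 significant digits) comma-separated matrix, no
#' header; lossless round trip through [read_field_csv()]. An optional
#' JSON metadata sidecar (`<path>.meta.json`) records time, grid,
#' parameters and seed, making the pair a self-describing container.
#'
#' @param field numeric matrix.
#' @param path output file.
#' @param meta optional named list written to `<path>.meta.json`.
#' @return `path`, invisibly.
#' @export
write_field_csv <- function(field, path, meta = NULL) {
  stopifnot(is.matrix(field))
  txt <- apply(field, 1L, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = ","))
  writeLines(txt, path)
  if (!is.null(meta))
    jsonlite::write_json(meta, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a concentration field written by [write_field_csv()]
#'
#' @param path CSV file.
#' @return Numeric matrix.
#' @export
read_field_csv <- function(path) {
  if (!file.exists(path)) stop("field file not found: ", path)
  m <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(m) <- NULL
  storage.mode(m) <- "double"
  m
}

.config_defaults <- function() {
  list(scenario = "standard", params = list(), grid = list(n = 100, L = 100),
       solver = list(), thresholds = NULL, seed = 1L, mask = NULL)
}

#' Load and validate a run configuration
#'
#' Reads a YAML file with any of the top-level keys `scenario`, `params`
#' (kinetic overrides), `grid` (`n`, `L`), `solver` (fields of
#' [solver_control()]), `thresholds`, `seed`, `mask` (path to a 0/1 CSV).
#' Missing keys take the documented defaults; unknown keys (top-level or
#' nested) are an error listing them; invalid parameter combinations
#' (e.g. `D_A >= D_H`) are rejected.
#'
#' @param path YAML file; an empty file yields all defaults (the standard
#'   preset on the 100 x 100 grid).
#' @return A list with `scenario` (a [scenario()]), `grid`, `control`,
#'   `thresholds`, `seed`, and `mask` (matrix or `NULL`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  defs <- .config_defaults()
  unknown <- setdiff(names(cfg), names(defs))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (nm in names(defs)) if (is.null(cfg[[nm]])) cfg[[nm]] <- defs[[nm]]

  presets <- preset_scenarios()
  if (is.character(cfg$scenario)) {
    if (!cfg$scenario %in% names(presets))
      stop("unknown scenario '", cfg$scenario, "'; available: ",
           paste(names(presets), collapse = ", "))
    scen <- presets[[cfg$scenario]]
  } else stop("config key 'scenario' must be a preset name")
  if (length(cfg$params)) {
    ov <- scen$overrides
    ov[names(cfg$params)] <- cfg$params
    scen <- scenario(scen$name, overrides = ov, ga_spec = scen$ga_spec,
                     seed = scen$seed, thresholds = scen$thresholds)
  }
  gk <- setdiff(names(cfg$grid), c("n", "L"))
  if (length(gk)) stop("unknown grid key(s): ", paste(gk, collapse = ", "))
  gn <- cfg$grid$n %||% 100L
  grid <- sim_grid(gn, cfg$grid$L %||% gn)
  sk <- setdiff(names(cfg$solver), names(formals(solver_control)))
  if (length(sk)) stop("unknown solver key(s): ", paste(sk, collapse = ", "))
  control <- do.call(solver_control, cfg$solver)
  thresholds <- cfg$thresholds %||% scen$thresholds
  mask <- if (!is.null(cfg$mask)) read_mask_csv(cfg$mask, grid)
  list(scenario = scen, grid = grid, control = control,
       thresholds = thresholds, seed = as.integer(cfg$seed), mask = mask)
}

#' Three-tone rendering of an activator field
#'
#' Renders the pattern as background (below `basic`), light layer
#' (`[basic, relative)`), and deep layer (at or above `relative`),
#' mimicking the floral colour gradient; with `relative = NULL` a
#' two-tone (single-threshold) rendering is produced. `type = "contour"`
#' draws the contour at the basic threshold instead.
#'
#' @param A activator field.
#' @param basic basic threshold (\eqn{\mu M}).
#' @param relative optional deep-layer threshold, must be `>= basic`.
#' @param type `"heatmap"` (tone classes) or `"contour"`.
#' @param file optional PNG path; when given, the plot is written there
#'   instead of the active device.
#' @return The integer tone-class matrix (0 background, 1 light, 2 deep),
#'   invisibly.
#' @export
render_pattern <- function(A, basic = 2, relative = NULL,
                           type = c("heatmap", "contour"), file = NULL) {
  stopifnot(is.matrix(A), basic >= 0)
  type <- match.arg(type)
  if (!is.null(relative) && relative < basic)
    stop("relative threshold (", relative,
         ") must be >= basic threshold (", basic, ")")
  tones <- threshold_mask(A, basic)
  if (!is.null(relative)) tones <- tones + as.integer(A >= relative)
  draw <- function() {
    n <- nrow(A)
    if (type == "heatmap") {
      cols <- if (is.null(relative)) c("white", "#8b1a89")
      else c("white", "#c77bc4", "#5e0d5c")
      graphics::image(seq_len(n), seq_len(ncol(A)), t(tones),
                      col = cols, zlim = c(0, if (is.null(relative)) 1 else 2),
                      xlab = "", ylab = "", asp = 1, axes = FALSE)
      graphics::box()
    } else {
      graphics::contour(seq_len(n), seq_len(ncol(A)), t(A), levels = basic,
                        drawlabels = FALSE, xlab = "", ylab = "", asp = 1)
    }
  }
  if (!is.null(file)) {
    grDevices::png(file, width = 600, height = 600)
    on.exit(grDevices::dev.off())
    draw()
  } else draw()
  invisible(tones)
}

#' Run a scenario and write its artifacts to disk
#'
#' Simulates the scenario and writes `A.csv`, `H.csv` (full precision,
#' with JSON metadata sidecars), `summary.json` (the pattern metrics),
#' `heatmap.png`, `contour.png`, `mask.csv` (masked scenarios only) and
#' `run.log` (parameters, seed, package version, convergence report) into
#' `outdir`. Identical invocations produce identical fields.
#'
#' @param scen preset name or [scenario()] object.
#' @param seed RNG seed.
#' @param outdir output directory, created if needed.
#' @param grid,control,mask,overrides passed to [simulate_pattern()].
#' @return The `rd_pattern` object, invisibly.
#' @export
run_scenario <- function(scen, seed = 1L, outdir, grid = sim_grid(),
                         control = solver_control(), mask = NULL,
                         overrides = list()) {
  t0 <- proc.time()[["elapsed"]]
  sim <- simulate_pattern(scen, grid = grid, seed = seed, control = control,
                          mask = mask, overrides = overrides)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(scenario = sim$scenario$name, t = sim$t, seed = sim$seed,
               grid = list(n = grid$n, L = grid$L),
               params = unclass(sim$params))
  write_field_csv(sim$A, file.path(outdir, "A.csv"), meta = meta)
  write_field_csv(sim$H, file.path(outdir, "H.csv"), meta = meta)
  if (!is.null(sim$mask))
    write_mask_csv(sim$mask, file.path(outdir, "mask.csv"))
  s <- summary(sim)
  jsonlite::write_json(as.data.frame(s), file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  rel <- sim$thresholds$relative
  grDevices::png(file.path(outdir, "heatmap.png"), width = 600, height = 600)
  render_pattern(sim$A, basic = sim$thresholds$basic,
                 relative = if (is.numeric(rel)) rel)
  grDevices::dev.off()
  grDevices::png(file.path(outdir, "contour.png"), width = 600, height = 600)
  render_pattern(sim$A, basic = sim$thresholds$basic, type = "contour")
  grDevices::dev.off()
  elapsed <- proc.time()[["elapsed"]] - t0
  log <- c(
    sprintf("scenario: %s", sim$scenario$name),
    sprintf("seed: %d", sim$seed),
    sprintf("grid: %d x %d (L = %g)", grid$n, grid$n, grid$L),
    sprintf("params: %s",
            paste(names(sim$params), unlist(sim$params), sep = "=",
                  collapse = ", ")),
    sprintf("solver: %s, dt=%g, policy=%s, dt_max=%g, t_end=%g, steady_tol=%g",
            control$scheme, control$dt, control$dt_policy, control$dt_max,
            control$t_end, control$steady_tol),
    sprintf("converged: %s at t = %g after %d steps", sim$converged,
            sim$t, sim$n_steps),
    sprintf("final residual (max |dA/dt|): %.3g",
            max(abs(residuals(sim)$A))),
    sprintf("package version: %s",
            as.character(utils::packageVersion("harlequin"))),
    sprintf("elapsed: %.1f s", elapsed))
  writeLines(log, file.path(outdir, "run.log"))
  invisible(sim)
}

#' Parameter sweep over G_A or mu_A
#'
#' Runs the standard scenario with one kinetic coefficient swept over
#' `values` for each seed, and returns one [pattern_summary()] row per
#' (value, seed) plus per-value median rows (`seed = NA`,
#' `stat = "median"`). This is how the monotone growth of spot coverage
#' with self-activation potency is reproduced quantitatively.
#'
#' @param parameter `"G_A"` or `"mu_A"`.
#' @param values positive values to sweep (nonempty).
#' @param seeds integer seeds.
#' @param grid,control passed to [simulate_pattern()].
#' @param outdir optional directory; when given, the table is written to
#'   `sweep.csv` there.
#' @return A data frame.
#' @export
sweep_scenarios <- function(parameter = c("G_A", "mu_A"), values,
                            seeds = 1:5, grid = sim_grid(),
                            control = solver_control(), outdir = NULL) {
  parameter <- match.arg(parameter)
  if (length(values) == 0) stop("empty values list")
  if (any(values <= 0)) stop("sweep values must be positive")
  rows <- list()
  for (v in values) {
    for (s in seeds) {
      ov <- stats::setNames(list(v), parameter)
      sim <- simulate_pattern("standard", grid = grid, seed = s,
                              control = control, overrides = ov)
      df <- as.data.frame(summary(sim))
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(parameter = parameter, value = v, seed = s,
                         stat = "run", converged = sim$converged), df)
    }
  }
  tab <- do.call(rbind, rows)
  med <- do.call(rbind, lapply(values, function(v) {
    sub <- tab[tab$value == v, ]
    data.frame(parameter = parameter, value = v, seed = NA, stat = "median",
               converged = all(sub$converged),
               n_spots = stats::median(sub$n_spots),
               area_fraction = stats::median(sub$area_fraction),
               mean_area = stats::median(sub$mean_area),
               max_area = stats::median(sub$max_area),
               fusion_index = stats::median(sub$fusion_index),
               ah_correlation = stats::median(sub$ah_correlation),
               threshold = sub$threshold[1])
  }))
  out <- rbind(tab, med)
  rownames(out) <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out, file.path(outdir, "sweep.csv"), row.names = FALSE)
  }
  out
}
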