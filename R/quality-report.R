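# Assembly of per-observable relative deviations into the cumulative
# force-field quality report.

.COMPONENT_ORDER <- c("formfactor_min1", "formfactor_min2", "palmitate_op",
                      "oleate_op", "diffusion", "density")

#' Quality profile of one observable component
#'
#' @param component one of `"palmitate_op"`, `"oleate_op"`,
#'   `"formfactor_min1"`, `"formfactor_min2"`, `"formfactor_sum"`,
#'   `"diffusion"`, `"density"`.
#' @param curve a [curve_1d()] of relative deviations in percent (>= 0).
#' @return An object of class `quality_profile`.
#' @export
quality_profile <- function(component, curve) {
  stopifnot(inherits(curve, "curve_1d"))
  if (any(curve$values < 0)) .stop_val("relative deviations must be >= 0")
  structure(list(component = component, curve = curve), class = "quality_profile")
}

#' @export
print.quality_profile <- function(x, ...) {
  cat(sprintf("<quality_profile> %s: mean %.2f%%, max %.2f%% over %g-%g mol%%\n",
              x$component, mean(x$curve$values), max(x$curve$values),
              min(x$curve$chol_grid), max(x$curve$chol_grid)))
  invisible(x)
}

#' Acyl-chain order parameter quality
#'
#' Relative deviation of a simulated order parameter surface from the
#' experimental one: at each concentration, the mean absolute deviation
#' over the chain's carbons normalized by the mean absolute experimental
#' value, in percent.
#'
#' @param sim,exp [surface_2d()] objects for one chain on matched grids.
#' @param chain `"palmitate"` or `"oleate"`; tags the component.
#' @return A [quality_profile()].
#' @export
op_quality <- function(sim, exp, chain = c("palmitate", "oleate")) {
  chain <- match.arg(chain)
  quality_profile(paste0(chain, "_op"), relative_deviation_curve(sim, exp))
}

#' Form-factor minima quality
#'
#' Relative deviation of the interpolated positions of the first two
#' form-factor minima, each normalized by the experimental position, plus
#' their sum.
#'
#' @param sim_min1,sim_min2 simulated minima position curves ([curve_1d()],
#'   nm^-1).
#' @param exp_min1,exp_min2 experimental counterparts on the same grid.
#' @return List with `min1`, `min2` (each a [quality_profile()]) and `sum`
#'   (their per-concentration total, component `"formfactor_sum"`).
#' @export
formfactor_quality <- function(sim_min1, sim_min2, exp_min1, exp_min2) {
  q1 <- quality_profile("formfactor_min1", relative_deviation_curve(sim_min1, exp_min1))
  q2 <- quality_profile("formfactor_min2", relative_deviation_curve(sim_min2, exp_min2))
  tot <- curve_1d(q1$curve$chol_grid, q1$curve$values + q2$curve$values)
  list(min1 = q1, min2 = q2, sum = quality_profile("formfactor_sum", tot))
}

#' Lateral diffusion quality
#'
#' Pointwise relative deviation of the finite-size-corrected diffusion
#' coefficients from experiment on a common concentration grid.  Only
#' PBC-corrected `D_inf` values are meaningful here: the finite-size
#' correction changes not only the magnitudes but the trend with
#' cholesterol, because its size depends on the membrane viscosity.
#'
#' @param sim_d,exp_d [curve_1d()] of D_inf (um^2/s) on matched grids.
#' @return A [quality_profile()] with component `"diffusion"`.
#' @export
diffusion_quality <- function(sim_d, exp_d) {
  quality_profile("diffusion", relative_deviation_curve(sim_d, exp_d))
}

#' Electron density quality
#'
#' Same reduction as [op_quality()] but over the z coordinate; off by
#' default in the cumulative report.
#'
#' @param sim,exp density [surface_2d()] objects (z x mol %).
#' @param coord_range optional z restriction, nm.
#' @return A [quality_profile()] with component `"density"`.
#' @export
density_quality <- function(sim, exp, coord_range = NULL) {
  quality_profile("density", relative_deviation_curve(sim, exp, coord_range))
}

#' Cumulative force-field quality
#'
#' Stacks per-component relative deviations into one table and a total
#' curve, the overall deviation of a force field from experiment as a
#' function of cholesterol concentration.  The stack order is fixed
#' (form-factor minima, palmitate, oleate, diffusion, density) so figures
#' are reproducible; the total is invariant under component order.
#'
#' @param profiles list of [quality_profile()]s on one shared grid.
#' @return An object of class `quality_report`: list with `components`
#'   (wide data frame, one column per component), `total` (a [curve_1d()])
#'   and `order`.
#' @export
cumulative_quality <- function(profiles) {
  if (!length(profiles)) .stop_val("need at least one quality profile")
  stopifnot(all(vapply(profiles, inherits, TRUE, "quality_profile")))
  grid <- profiles[[1]]$curve$chol_grid
  for (p in profiles)
    if (length(p$curve$chol_grid) != length(grid) ||
        max(abs(p$curve$chol_grid - grid)) > 1e-9)
      .stop_val("component grid mismatch: %s", p$component)
  comp <- vapply(profiles, function(p) p$component, "")
  if (anyDuplicated(comp)) .stop_val("duplicate components: %s",
                                     paste(comp[duplicated(comp)], collapse = ", "))
  ord <- order(match(comp, .COMPONENT_ORDER, nomatch = length(.COMPONENT_ORDER) + 1L))
  profiles <- profiles[ord]; comp <- comp[ord]
  wide <- data.frame(chol_mol_pct = grid)
  for (p in profiles) wide[[p$component]] <- p$curve$values
  total <- rowSums(as.matrix(wide[, -1, drop = FALSE]))
  structure(list(components = wide, total = curve_1d(grid, total), order = comp),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("<quality_report> %d components (%s)\n", length(x$order),
              paste(x$order, collapse = ", ")))
  cat(sprintf("  total deviation: mean %.2f%%, range %.2f-%.2f%%\n",
              mean(x$total$values), min(x$total$values), max(x$total$values)))
  invisible(x)
}

#' Write a quality report as CSV
#'
#' One row per concentration, one column per component plus the total.
#'
#' @param report a `quality_report` from [cumulative_quality()].
#' @param path output file.
#' @export
write_quality_report <- function(report, path) {
  stopifnot(inherits(report, "quality_report"))
  df <- report$components
  df$total <- report$total$values
  utils::write.csv(format(df, digits = 15, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a surface as a CSV matrix
#'
#' Rows are coordinates, columns concentrations (mol %).
#'
#' @param surface a [surface_2d()] (or deviation surface).
#' @param path output file.
#' @export
write_surface_csv <- function(surface, path) {
  stopifnot(inherits(surface, "surface_2d"))
  df <- data.frame(coord = surface$coord, surface$values)
  names(df)[-1] <- sprintf("chol_%g", surface$chol_grid)
  utils::write.csv(format(df, digits = 15, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

# --------------------------------------------------------------------------
# study configuration

#' Read a study configuration
#'
#' A YAML file lists the data sets of one comparison study: for each of
#' `sim` and `exp`, per observable (`order_parameters`, `density`,
#' `form_factor`, `diffusion`), a list of `{chol: <mol %>, path: <file>}`
#' entries (paths relative to the YAML file).
#'
#' @param path YAML file.
#' @return Data frame with columns `source`, `observable`, `chol`, `path`.
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rows <- list()
  for (src in intersect(names(cfg), c("sim", "exp"))) {
    for (obs in names(cfg[[src]])) {
      for (entry in cfg[[src]][[obs]]) {
        if (is.null(entry$chol) || is.null(entry$path))
          .stop_val("config entry under %s/%s needs both chol and path", src, obs)
        p <- entry$path
        if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(base, p)
        rows[[length(rows) + 1L]] <- data.frame(
          source = src, observable = obs, chol = as.numeric(entry$chol), path = p)
      }
    }
  }
  if (!length(rows)) .stop_val("no data sets found in %s", path)
  do.call(rbind, rows)
}

#' Run an order-parameter comparison study from a configuration
#'
#' Reads simulated and experimental order parameter tables per
#' concentration, interpolates both onto a common cholesterol grid, and
#' returns the per-chain quality profiles and the cumulative report.
#' Observables other than order parameters, if present in the
#' configuration, are currently combined by the caller from the individual
#' building blocks.
#'
#' @param config a file path or the data frame from [read_study_config()].
#' @param chol_grid target concentration grid, mol %; defaults to the part
#'   of 0-46 covered by both sources.
#' @param unsigned compare magnitudes (`-|S_CH|`), for sign-free
#'   experimental data.
#' @return A `quality_report` over the palmitate and oleate components.
#' @export
run_quality_study <- function(config, chol_grid = NULL, unsigned = TRUE) {
  if (is.character(config)) config <- read_study_config(config)
  oc <- config[config$observable == "order_parameters", , drop = FALSE]
  if (nrow(oc) == 0L) .stop_val("configuration has no order_parameters data sets")
  load_side <- function(src) {
    d <- oc[oc$source == src, , drop = FALSE]
    if (nrow(d) < 2L) .stop_val("need >= 2 concentrations for source '%s'", src)
    lapply(seq_len(nrow(d)), function(i)
      read_order_parameters(d$path[i], chol_frac = d$chol[i] / 100))
  }
  sim <- load_side("sim"); exp <- load_side("exp")
  if (is.null(chol_grid)) {
    lo <- max(min(oc$chol[oc$source == "sim"]), min(oc$chol[oc$source == "exp"]), 0)
    hi <- min(max(oc$chol[oc$source == "sim"]), max(oc$chol[oc$source == "exp"]), 46)
    chol_grid <- seq(ceiling(lo), floor(hi), by = 1)
  }
  profs <- lapply(c("palmitate", "oleate"), function(chain) {
    s <- build_surface_2d(op_surface_input(sim, chain, unsigned), chol_grid)
    e <- build_surface_2d(op_surface_input(exp, chain, unsigned), chol_grid)
    common <- intersect(s$coord, e$coord)
    s <- surface_2d(common, chol_grid, s$values[s$coord %in% common, , drop = FALSE])
    e <- surface_2d(common, chol_grid, e$values[e$coord %in% common, , drop = FALSE])
    op_quality(s, e, chain)
  })
  cumulative_quality(profs)
}
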