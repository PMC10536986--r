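# Interpolation of observables over cholesterol concentration and the
# deviation machinery built on top of it.

#' Observable surface over (coordinate x cholesterol concentration)
#'
#' @param coord first-axis grid: acyl-chain carbon index or distance from
#'   the bilayer center (nm); strictly increasing.
#' @param chol_grid cholesterol concentration grid in mol %, strictly
#'   increasing, within \[0, 46\].
#' @param values matrix, `length(coord)` x `length(chol_grid)`.
#' @return An object of class `surface_2d`.
#' @export
surface_2d <- function(coord, chol_grid, values) {
  .check_finite(coord, "coord"); .check_finite(chol_grid, "chol_grid")
  values <- as.matrix(values)
  .check_finite(values, "values")
  if (any(diff(coord) <= 0)) .stop_val("coord grid must be strictly increasing")
  if (any(diff(chol_grid) <= 0)) .stop_val("chol_grid must be strictly increasing")
  if (any(chol_grid < 0 | chol_grid > 46))
    .stop_val("chol_grid must lie within [0, 46] mol %%")
  if (!all(dim(values) == c(length(coord), length(chol_grid))))
    .stop_val("values must be a length(coord) x length(chol_grid) matrix")
  structure(list(coord = as.numeric(coord), chol_grid = as.numeric(chol_grid),
                 values = values),
            class = "surface_2d")
}

#' @export
print.surface_2d <- function(x, ...) {
  cat(sprintf("<%s> %d coord x %d CHOL points (%.0f-%.0f mol%%)\n",
              class(x)[1], length(x$coord), length(x$chol_grid),
              min(x$chol_grid), max(x$chol_grid)))
  invisible(x)
}

#' Curve over cholesterol concentration
#'
#' @param chol_grid mol % grid, strictly increasing.
#' @param values observable values or relative deviations (%).
#' @return An object of class `curve_1d`.
#' @export
curve_1d <- function(chol_grid, values) {
  .check_finite(chol_grid, "chol_grid"); .check_finite(values, "values")
  if (any(diff(chol_grid) <= 0)) .stop_val("chol_grid must be strictly increasing")
  if (length(chol_grid) != length(values))
    .stop_val("chol_grid and values must have equal length")
  structure(list(chol_grid = as.numeric(chol_grid), values = as.numeric(values)),
            class = "curve_1d")
}

#' Default cholesterol concentration grid (0-46 mol % in 1 % steps)
#' @export
default_chol_grid <- function() seq(0, 46, by = 1)

#' Interpolate per-concentration profiles into a 2D observable surface
#'
#' Builds the observable on a regular (coordinate x cholesterol) grid by
#' bilinear interpolation: each input profile is first resampled onto the
#' common coordinate grid, then columns at intermediate concentrations are
#' linear combinations of the two bracketing inputs.  Interpolation is
#' exact at input knots; queries outside the input concentration span are
#' refused (interpolation only, never extrapolation).
#'
#' @param profiles list of `list(chol = mol %, coord = grid, values = numeric)`
#'   entries, one per simulated/measured concentration.
#' @param chol_grid target concentration grid, mol %; default 0-46 in 1 %
#'   steps (clipped to the input span is the caller's responsibility).
#' @param coord_grid target coordinate grid; default the intersection of the
#'   input coordinate supports (for integer carbon grids, the common
#'   carbons).  Coordinates outside any profile's support are dropped with
#'   a message.
#' @return A [surface_2d()].
#' @export
build_surface_2d <- function(profiles, chol_grid = default_chol_grid(),
                             coord_grid = NULL) {
  if (!is.list(profiles) || length(profiles) < 2L)
    .stop_val("insufficient data: need profiles at >= 2 concentrations")
  chol_in <- vapply(profiles, function(p) as.numeric(p$chol), 0)
  if (anyDuplicated(chol_in)) .stop_val("duplicate input concentrations")
  ord <- order(chol_in)
  profiles <- profiles[ord]; chol_in <- chol_in[ord]
  if (min(chol_grid) < min(chol_in) - 1e-9 || max(chol_grid) > max(chol_in) + 1e-9)
    .stop_val("range error: chol_grid [%g, %g] exceeds input span [%g, %g]",
              min(chol_grid), max(chol_grid), min(chol_in), max(chol_in))
  sup_lo <- max(vapply(profiles, function(p) min(p$coord), 0))
  sup_hi <- min(vapply(profiles, function(p) max(p$coord), 0))
  if (is.null(coord_grid)) {
    # intersection of coordinate supports; for integer (carbon) grids take
    # the common integers, otherwise the first profile's grid restricted
    c0 <- profiles[[1]]$coord
    coord_grid <- c0[c0 >= sup_lo - 1e-9 & c0 <= sup_hi + 1e-9]
  } else {
    drop <- coord_grid < sup_lo - 1e-9 | coord_grid > sup_hi + 1e-9
    if (any(drop)) {
      message(sprintf("dropping %d coordinate(s) outside the common support [%g, %g]",
                      sum(drop), sup_lo, sup_hi))
      coord_grid <- coord_grid[!drop]
    }
  }
  if (length(coord_grid) == 0L) .stop_val("no coordinates in the common support")
  cols <- vapply(profiles, function(p)
    stats::approx(p$coord, p$values, xout = coord_grid, rule = 1)$y,
    numeric(length(coord_grid)))
  cols <- matrix(cols, nrow = length(coord_grid))
  vals <- vapply(chol_grid, function(cc) {
    j <- findInterval(cc, chol_in, rightmost.closed = TRUE)
    j <- min(max(j, 1L), length(chol_in) - 1L)
    w <- (cc - chol_in[j]) / (chol_in[j + 1] - chol_in[j])
    (1 - w) * cols[, j] + w * cols[, j + 1]
  }, numeric(length(coord_grid)))
  surface_2d(coord_grid, chol_grid, matrix(vals, nrow = length(coord_grid)))
}

#' Linear 1D interpolation over cholesterol concentration
#'
#' Piecewise-linear, exact at knots, no extrapolation.  Used for the
#' cholesterol dependence of form-factor minima locations and diffusion
#' coefficients.
#'
#' @param points data frame (or 2-column object) with concentrations
#'   (mol %) and values; >= 2 points.
#' @param chol_grid query grid, mol %, within the input span.
#' @return A [curve_1d()].
#' @export
interp_curve_1d <- function(points, chol_grid) {
  points <- as.data.frame(points)
  names(points)[1:2] <- c("chol", "value")
  if (nrow(points) < 2L) .stop_val("insufficient data: need >= 2 points")
  .check_finite(points$chol, "chol"); .check_finite(points$value, "value")
  if (anyDuplicated(points$chol)) .stop_val("duplicate concentrations")
  if (min(chol_grid) < min(points$chol) - 1e-9 ||
      max(chol_grid) > max(points$chol) + 1e-9)
    .stop_val("range error: query span [%g, %g] exceeds input span [%g, %g]",
              min(chol_grid), max(chol_grid), min(points$chol), max(points$chol))
  y <- stats::approx(points$chol, points$value, xout = chol_grid, rule = 1)$y
  curve_1d(chol_grid, y)
}

#' Signed deviation surface between simulation and experiment
#'
#' Computes `sim - exp` on identical grids.  Negative order parameter
#' deviations mean the simulated chains are too ordered (S_CH too
#' negative).  A companion logical `mask` marks cells whose absolute
#' deviation is within the experimental error band (default 0.02), the
#' cells rendered white in deviation maps.
#'
#' @param sim,exp [surface_2d()] objects on identical grids.
#' @param band half-width of the within-experimental-error band.
#' @return A `deviation_surface` (subclass of `surface_2d`) with elements
#'   `values` (signed differences), `mask` and `band`.
#' @export
deviation_surface <- function(sim, exp, band = 0.02) {
  stopifnot(inherits(sim, "surface_2d"), inherits(exp, "surface_2d"))
  if (length(sim$coord) != length(exp$coord) ||
      length(sim$chol_grid) != length(exp$chol_grid) ||
      max(abs(sim$coord - exp$coord)) > 1e-9 ||
      max(abs(sim$chol_grid - exp$chol_grid)) > 1e-9)
    .stop_val("shape error: sim and exp surfaces must share identical grids")
  d <- sim$values - exp$values
  out <- surface_2d(sim$coord, sim$chol_grid, d)
  out$mask <- abs(d) <= band
  out$band <- band
  class(out) <- c("deviation_surface", class(out))
  out
}

#' Relative deviation from experiment in percent
#'
#' For surfaces: at each concentration, the mean over the first axis of
#' `|sim - exp|` divided by the mean over the first axis of `|exp|`, times
#' 100.  For 1D curves: pointwise `|sim - exp| / |exp| * 100`.  The ratio
#' of two like reductions makes the measure invariant under joint rescaling
#' of simulation and experiment.
#'
#' @param sim,exp two [surface_2d()] or two [curve_1d()] objects on matched
#'   grids.
#' @param coord_range optional `c(lo, hi)` restriction of the first-axis
#'   average (surfaces only); default the full coordinate range.
#' @return A [curve_1d()] of relative deviations in percent.
#' @export
relative_deviation_curve <- function(sim, exp, coord_range = NULL) {
  if (inherits(sim, "surface_2d") && inherits(exp, "surface_2d")) {
    dev <- deviation_surface(sim, exp)   # also validates the grids
    sel <- rep(TRUE, length(sim$coord))
    if (!is.null(coord_range))
      sel <- sim$coord >= coord_range[1] & sim$coord <= coord_range[2]
    if (!any(sel)) .stop_val("coord_range selects no coordinates")
    num <- colMeans(abs(dev$values[sel, , drop = FALSE]))
    den <- colMeans(abs(exp$values[sel, , drop = FALSE]))
    bad <- den == 0
    if (any(bad))
      .stop_val("zero experimental normalizer at %g mol %%", sim$chol_grid[which(bad)[1]])
    return(curve_1d(sim$chol_grid, 100 * num / den))
  }
  if (inherits(sim, "curve_1d") && inherits(exp, "curve_1d")) {
    if (length(sim$chol_grid) != length(exp$chol_grid) ||
        max(abs(sim$chol_grid - exp$chol_grid)) > 1e-9)
      .stop_val("shape error: curves must share one chol grid")
    bad <- exp$values == 0
    if (any(bad))
      .stop_val("zero experimental normalizer at %g mol %%", sim$chol_grid[which(bad)[1]])
    return(curve_1d(sim$chol_grid, 100 * abs(sim$values - exp$values) / abs(exp$values)))
  }
  .stop_val("sim and exp must both be surface_2d or both curve_1d")
}

#' Per-carbon surface input from order parameter sets
#'
#' Converts a list of [order_parameter_set()]s (one per concentration) into
#' the per-chain profile list consumed by [build_surface_2d()].  Hydrogens
#' are averaged first (see [average_equivalent_hydrogens()]); the forked
#' oleate-C2 pair enters as its mean, which for deviation maps is
#' equivalent to averaging the two per-branch differences.
#'
#' @param ops_list list of [order_parameter_set()]s.
#' @param chain `"palmitate"` or `"oleate"` (headgroup/glycerol entries are
#'   excluded from acyl-chain quality metrics).
#' @param unsigned if `TRUE`, use `-|S_CH|` so that magnitude-only
#'   experimental data keep the "more ordered = more negative" sign
#'   convention.
#' @return list of profiles, one per concentration (`chol` in mol %).
#' @export
op_surface_input <- function(ops_list, chain = c("palmitate", "oleate"),
                             unsigned = FALSE) {
  chain <- match.arg(chain)
  lapply(ops_list, function(ops) {
    ops <- average_equivalent_hydrogens(ops)
    e <- ops$entries[ops$entries$chain == chain, , drop = FALSE]
    if (nrow(e) == 0L) .stop_val("no %s entries at %.3g mol %%", chain, 100 * ops$chol_frac)
    v <- tapply(e$s_ch, e$carbon, mean)   # collapses the forked C2 pair
    carbons <- as.numeric(names(v))
    vals <- as.numeric(v)
    if (unsigned) vals <- -abs(vals)
    o <- order(carbons)
    list(chol = 100 * ops$chol_frac, coord = carbons[o], values = vals[o])
  })
}
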