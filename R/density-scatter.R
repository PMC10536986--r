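# Structural observables: density smoothing, thickness from density maxima,
# form factors by Fourier transform, minima tracking, area per phospholipid
# and the partial molecular area of cholesterol.

#' Smooth an electron density profile with a centered moving mean
#'
#' 5-point moving mean by default.  At the edges the window shrinks
#' symmetrically (1, 3, 5, ... points), so the profile length is preserved
#' and a constant profile is unchanged.
#'
#' @param profile a [density_profile()].
#' @param window odd window size >= 1, <= number of grid points.
#' @return A smoothed [density_profile()].
#' @export
smooth_density <- function(profile, window = 5) {
  stopifnot(inherits(profile, "density_profile"))
  if (length(window) != 1L || window < 1 || window != round(window) ||
      window %% 2 == 0)
    .stop_val("window must be an odd integer >= 1")
  n <- length(profile$rho)
  if (window > n) .stop_val("window exceeds profile length")
  half <- (window - 1) / 2
  rho <- vapply(seq_len(n), function(i) {
    k <- min(half, i - 1, n - i)
    mean(profile$rho[(i - k):(i + k)])
  }, 0)
  density_profile(profile$z, rho, profile$solvent_rho)
}

# mirror-average a profile; requires a symmetric z range
.symmetrize_density <- function(profile, tol_asym = 0.02) {
  z <- profile$z
  dz <- z[2] - z[1]
  if (abs(z[1] + z[length(z)]) > dz / 2)
    .stop_val("asymmetric z-range: grid must be symmetric about z = 0")
  mirrored <- stats::approx(-z, profile$rho, xout = z, rule = 2)$y
  asym <- max(abs(profile$rho - mirrored)) / max(abs(profile$rho))
  if (asym > 2 * tol_asym)   # rho vs mirror differs by twice the leaflet asymmetry
    message(sprintf("leaflet asymmetry %.1f%% exceeds %.0f%%; symmetrizing",
                    50 * asym, 100 * tol_asym))
  density_profile(z, (profile$rho + mirrored) / 2, profile$solvent_rho)
}

# strict local maxima with a simple prominence filter: prominence is the
# height above the higher of the two valleys separating the peak from
# higher terrain (or from the profile ends)
.find_peaks <- function(y, prominence) {
  n <- length(y)
  idx <- which(diff(sign(diff(y))) == -2) + 1L   # strictly greater than both neighbours
  keep <- vapply(idx, function(i) {
    hi_l <- which(y[1:(i - 1)] > y[i])
    hi_r <- which(y[(i + 1):n] > y[i])
    jstar <- if (length(hi_l)) max(hi_l) else 1L
    kstar <- if (length(hi_r)) i + min(hi_r) else n
    y[i] - max(min(y[jstar:i]), min(y[i:kstar])) >= prominence
  }, TRUE)
  idx[keep]
}

#' Bilayer thickness from the electron density maxima
#'
#' The membrane thickness is twice the distance from the electron density
#' maximum (the headgroup peak) to the membrane center: the profile is
#' smoothed (5-point moving mean), symmetrized, and the highest local
#' maximum with prominence >= 1 percent of the profile range is located on
#' each side of z = 0; thickness = |z+| + |z-|.  If two maxima tie within
#' one grid spacing, the one at larger |z| wins.
#'
#' @param profile a [density_profile()].
#' @param smooth_window moving-mean window applied first (set 1 to skip).
#' @param prominence_frac minimum peak prominence as a fraction of the
#'   profile range.
#' @return Thickness in nm.
#' @export
bilayer_thickness <- function(profile, smooth_window = 5, prominence_frac = 0.01) {
  stopifnot(inherits(profile, "density_profile"))
  p <- smooth_density(profile, smooth_window)
  p <- .symmetrize_density(p)
  rng <- diff(range(p$rho))
  if (rng == 0) .stop_val("no headgroup peak: flat profile")
  peaks <- .find_peaks(p$rho, prominence = prominence_frac * rng)
  pick <- function(side) {
    cand <- peaks[side(p$z[peaks])]
    if (!length(cand)) .stop_val("no headgroup peak on one side of the bilayer center")
    top <- max(p$rho[cand])
    tied <- cand[p$rho[cand] >= top - 1e-9 * rng]   # height ties: larger |z| wins
    tied[which.max(abs(p$z[tied]))]
  }
  i_pos <- pick(function(z) z > 0)
  i_neg <- pick(function(z) z < 0)
  abs(p$z[i_pos]) + abs(p$z[i_neg])
}

#' X-ray form factor from an electron density profile
#'
#' \deqn{F(q) = \int (\rho(z) - \rho_{solvent}) \cos(qz)\, dz}
#' evaluated by trapezoidal quadrature over the profile support; the
#' magnitude |F(q)| is returned.  The z grid must be symmetric about 0 (the
#' profile is mirror-averaged first).
#'
#' @param profile a [density_profile()] with `solvent_rho` set.
#' @param q_grid wave vector grid in nm^-1 (default 0.01-10, step 0.005).
#' @param symmetrize mirror-average the profile first (default `TRUE`).
#' @return A [form_factor_curve()].
#' @export
form_factor <- function(profile, q_grid = seq(0.01, 10, by = 0.005),
                        symmetrize = TRUE) {
  stopifnot(inherits(profile, "density_profile"))
  .check_finite(q_grid, "q_grid")
  p <- if (symmetrize) .symmetrize_density(profile) else profile
  z <- p$z
  contrast <- p$rho - p$solvent_rho
  # trapezoid weights on the uniform grid
  dz <- z[2] - z[1]
  w <- rep(dz, length(z)); w[c(1, length(z))] <- dz / 2
  f <- as.numeric(cos(outer(q_grid, z)) %*% (contrast * w))
  form_factor_curve(q_grid, abs(f))
}

#' Locate the first minima of |F(q)|
#'
#' Finds the first `n` interior local minima of the form factor magnitude,
#' each refined by parabolic interpolation through the three points around
#' the grid minimum, and returns their positions ordered by q.
#'
#' @param ff a [form_factor_curve()]; a q spacing <= 0.01 nm^-1 is
#'   recommended.
#' @param n number of minima to return.
#' @return Numeric vector of minima positions, nm^-1.
#' @export
form_factor_minima <- function(ff, n = 2) {
  stopifnot(inherits(ff, "form_factor_curve"))
  y <- ff$f_abs
  idx <- which(diff(sign(diff(y))) == 2) + 1L
  if (length(idx) < n)
    .stop_val("insufficient minima: found %d, need %d", length(idx), n)
  idx <- idx[seq_len(n)]
  vapply(idx, function(i) {
    y1 <- y[i - 1]; y2 <- y[i]; y3 <- y[i + 1]
    denom <- y1 - 2 * y2 + y3
    delta <- if (denom > 0) 0.5 * (y1 - y3) / denom else 0
    ff$q[i] + delta * (ff$q[i + 1] - ff$q[i])
  }, 0)
}

#' Area per phospholipid with block-averaged standard error
#'
#' The area per phospholipid is the (time-averaged) membrane area divided
#' by the number of phospholipids in one leaflet; cholesterol does not
#' count toward the divisor.  The standard error is estimated by block
#' averaging: the area series is split into `n_blocks` contiguous blocks
#' and the standard deviation of the block means is divided by
#' `sqrt(n_blocks)`.
#'
#' @param box_area_series per-frame membrane (simulation box) areas, nm^2.
#' @param n_pl_leaflet phospholipids per leaflet (>= 1).
#' @param n_blocks number of blocks (series must be at least this long).
#' @param chol_frac optional cholesterol mole fraction tag.
#' @return An object of class `apl_point` with fields `apl` (nm^2), `se`
#'   (nm^2), `n_pl_leaflet`, `chol_frac`, `n_frames`.
#' @export
area_per_lipid <- function(box_area_series, n_pl_leaflet, n_blocks = 5,
                           chol_frac = NA_real_) {
  .check_finite(box_area_series, "box_area_series")
  if (n_pl_leaflet < 1) .stop_val("n_pl_leaflet must be >= 1")
  n <- length(box_area_series)
  if (n < n_blocks) .stop_val("series length %d is shorter than n_blocks = %d", n, n_blocks)
  blocks <- split(box_area_series, cut(seq_len(n), n_blocks, labels = FALSE))
  bm <- vapply(blocks, mean, 0)
  structure(list(apl = mean(box_area_series) / n_pl_leaflet,
                 se = stats::sd(bm) / sqrt(n_blocks) / n_pl_leaflet,
                 n_pl_leaflet = n_pl_leaflet, chol_frac = chol_frac,
                 n_frames = n),
            class = "apl_point")
}

#' @export
print.apl_point <- function(x, ...) {
  cat(sprintf("<apl_point> APL = %.4g +/- %.2g nm^2 (%d PL/leaflet, %d frames)\n",
              x$apl, x$se, x$n_pl_leaflet, x$n_frames))
  invisible(x)
}

#' Partial molecular area of cholesterol
#'
#' From the area per phospholipid as a function of cholesterol content:
#' the total leaflet area is `A_tot(x) = n_pc * apl(x)` (the phospholipid
#' count per leaflet is constant), the cholesterol count is
#' `N_chol(x) = n_pc * x / (1 - x)` with `x` the mole fraction, and the
#' partial area is `dA_tot/dN_chol`, evaluated by central finite
#' differences (one-sided at the ends).  A negative partial area is the
#' cholesterol condensing effect; zero means cholesterol can be added
#' without changing the total area.
#'
#' @param apl_curve data frame with concentrations in mol % and APL in nm^2
#'   (>= 2 concentrations).
#' @param n_pc_leaflet phosphatidylcholine molecules per leaflet.
#' @return A [curve_1d()] of partial areas (nm^2) on the input mol % grid.
#' @export
chol_partial_area <- function(apl_curve, n_pc_leaflet) {
  apl_curve <- as.data.frame(apl_curve)
  names(apl_curve)[1:2] <- c("chol", "apl")
  if (nrow(apl_curve) < 2L) .stop_val("need >= 2 concentrations")
  .check_finite(apl_curve$chol, "chol"); .check_finite(apl_curve$apl, "apl")
  o <- order(apl_curve$chol)
  x <- apl_curve$chol[o] / 100
  if (any(x >= 1)) .stop_val("singularity: cholesterol mole fraction must be < 1")
  A <- n_pc_leaflet * apl_curve$apl[o]
  N <- n_pc_leaflet * x / (1 - x)
  n <- length(x)
  dAdN <- numeric(n)
  dAdN[1] <- (A[2] - A[1]) / (N[2] - N[1])
  dAdN[n] <- (A[n] - A[n - 1]) / (N[n] - N[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    dAdN[i] <- (A[i + 1] - A[i - 1]) / (N[i + 1] - N[i - 1])
  }
  curve_1d(apl_curve$chol[o], dAdN)
}
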