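# Lateral dynamics: MSD with leaflet-drift removal, the linear MSD fit,
# the periodic Saffman-Delbrueck finite-size model, its two-parameter fit
# and Monte-Carlo error propagation.

# --------------------------------------------------------------------------
# Periodic finite-size correction.
#
# A lipid in a periodic box does not diffuse at the infinite-membrane rate:
# the hydrodynamic flow it sets up interacts with its periodic images and
# with the constraint of zero total momentum.  We model the membrane as a
# 2D fluid of surface viscosity mu_m*h embedded in water; the finite
# hydration layer screens in-plane momentum transport beyond the length
#   ell = sqrt(L_SD * H),   L_SD = mu_m*h / (2*mu_f),
# the geometric mean of the Saffman-Delbrueck length and the half water
# thickness.  The direction-averaged mobility kernel of the screened,
# incompressible 2D flow is 1 / (2 mu_m h (q^2 + kappa^2)), kappa = 1/ell,
# whose real-space trace is a modified Bessel function K0.  Summing over
# periodic images and subtracting the q = 0 mode (momentum removal) gives
#
#   D_PBC(L) = D_inf + kT/(8 pi mu_m h) * [ sum_{n != 0} K0(kappa L |n|)
#                                           - 2 pi / (kappa L)^2 ].
#
# The bracket behaves as ln(L / ell) + const for L << ell (the quasi-2D
# logarithmic finite-size effect) and vanishes as L -> infinity, so
# D_PBC -> D_inf in an infinite box.  Interleaflet friction is taken as
# infinite (the two leaflets move as one sheet).
# --------------------------------------------------------------------------

.psd_env <- new.env(parent = emptyenv())

# squared 2D theta function (sum_n exp(-s n^2))^2 with the modular
# transform for small s
.theta2d <- function(s) {
  raw <- function(s) 1 + 2 * (exp(-s) + exp(-4 * s) + exp(-9 * s) +
                                exp(-16 * s) + exp(-25 * s))
  out <- numeric(length(s))
  big <- s >= pi
  out[big] <- raw(s[big])
  sm <- s[!big]
  out[!big] <- sqrt(pi / sm) * raw(pi^2 / sm)
  out^2
}

# S(a) = sum over the square lattice (excluding the origin) of K0(a |n|),
# via S(a) = 1/2 int_0^inf e^{-t} (theta2d(a^2/(4t)) - 1) dt/t
.psd_lattice_sum <- function(a) {
  vapply(a, function(ai) {
    if (ai > 25) {   # only nearest images contribute
      r <- sqrt(c(1, 2, 4, 5, 8, 9))
      m <- c(4, 4, 4, 8, 4, 4)
      return(sum(m * besselK(pmin(ai * r, 700), 0)))
    }
    if (is.null(.psd_env$gl)) .psd_env$gl <- pracma::gaussLegendre(300, 0, 1)
    u <- log(ai^2 / 160) + .psd_env$gl$x * (log(45) - log(ai^2 / 160))
    w <- .psd_env$gl$w * (log(45) - log(ai^2 / 160))
    t <- exp(u)
    0.5 * sum(w * exp(-t) * (.theta2d(ai^2 / (4 * t)) - 1))
  }, 0)
}

# reduced periodic correction g(a) = S(a) - 2*pi/a^2 (negative, -> 0 as
# a -> inf, ~ ln a - 1.42646 as a -> 0); spline-cached on a log grid
.psd_g <- function(a) {
  if (is.null(.psd_env$spline)) {
    agrid <- exp(seq(log(1e-3), log(25), length.out = 900))
    gval <- .psd_lattice_sum(agrid) - 2 * pi / agrid^2
    .psd_env$spline <- stats::splinefun(log(agrid), gval, method = "fmm")
    .psd_env$c0 <- gval[1] - log(agrid[1])
  }
  out <- numeric(length(a))
  lo <- a < 1e-3; hi <- a > 25; mid <- !lo & !hi
  out[lo] <- log(a[lo]) + .psd_env$c0
  out[mid] <- .psd_env$spline(log(a[mid]))
  if (any(hi)) out[hi] <- .psd_lattice_sum(a[hi]) - 2 * pi / a[hi]^2
  out
}

#' Saffman-Delbrueck length
#'
#' \eqn{L_{SD} = \mu_m h / (2 \mu_f)}, the crossover length of 2D membrane
#' hydrodynamics embedded in a 3D solvent.
#'
#' @param mu_m membrane shear viscosity, mPa s.
#' @param h hydrodynamic membrane thickness, nm.
#' @param mu_f solvent (water) shear viscosity, mPa s.
#' @return Length in nm.
#' @export
saffman_delbrueck_length <- function(mu_m, h, mu_f = .MU_F_DEFAULT) {
  if (any(!is.finite(c(mu_m, h, mu_f))) || any(c(mu_m, h, mu_f) <= 0))
    .stop_val("mu_m, h and mu_f must be positive")
  mu_m * h / (2 * mu_f)
}

#' Finite-size lateral diffusion coefficient in a periodic box
#'
#' Forward evaluation of the periodic Saffman-Delbrueck correction: the
#' diffusion coefficient measured in a periodic box of edge `L` for a
#' membrane with infinite-system coefficient `d_inf` and shear viscosity
#' `mu_m`.  The correction sums the screened two-dimensional hydrodynamic
#' interaction with all periodic images (screening length
#' `sqrt(L_SD * H)` set by the finite hydration layer) and subtracts the
#' zero-momentum mode; it vanishes as `L` grows, so `D_PBC -> d_inf` in an
#' infinite box, and it is monotonically increasing in `L`.
#'
#' @param L box edge(s) in the membrane plane, nm.
#' @param d_inf infinite-system lateral diffusion coefficient, um^2/s.
#' @param mu_m membrane shear viscosity, mPa s.
#' @param geom a [membrane_geometry()] supplying `h`, `H`, `T`, `mu_f`.
#' @return D_PBC in um^2/s, one value per `L`.
#' @export
dpbc_model <- function(L, d_inf, mu_m, geom) {
  stopifnot(inherits(geom, "membrane_geometry"))
  .check_finite(L, "L")
  if (any(L <= 0) || !is.finite(d_inf) || d_inf <= 0 || !is.finite(mu_m) || mu_m <= 0)
    .stop_val("L, d_inf and mu_m must be positive")
  d_inf + .psd_correction(L, mu_m, geom)
}

# the correction term alone, um^2/s (negative)
.psd_correction <- function(L, mu_m, geom) {
  l_sd <- saffman_delbrueck_length(mu_m, geom$h, geom$mu_f)
  a <- L / sqrt(l_sd * geom$H)
  pref <- .kB * geom$T / (8 * pi * mu_m * 1e-3 * geom$h * 1e-9) * 1e12  # um^2/s
  pref * .psd_g(a)
}

#' Fit the finite-size model to D_PBC(L)
#'
#' Nonlinear least squares of [dpbc_model()] against diffusion
#' coefficients measured at several box sizes.  The two free parameters,
#' the infinite-system coefficient `D_inf` and the membrane shear
#' viscosity `mu_m`, are both positive; `mu_m` is optimized on a log scale
#' (profile likelihood: for fixed `mu_m` the optimal `D_inf` is linear
#' least squares), which makes the fit independent of starting values.
#'
#' If the fitted correction term is smaller than 1 percent of the mean
#' `d_pbc`, the series carries no size dependence and `mu_m` is
#' unidentifiable: the result is flagged `degenerate`.
#'
#' @param series a [finite_size_series()].
#' @param mu_range search range for `mu_m`, mPa s.
#' @param tol relative tolerance on the log-viscosity optimum.
#' @return A `pbc_fit_result` with `d_inf` (um^2/s), `mu_m` (mPa s),
#'   `l_sd` (nm), the residual sum of squares and the degeneracy flag.
#' @export
fit_finite_size <- function(series, mu_range = c(1e-2, 1e4), tol = 1e-11) {
  stopifnot(inherits(series, "finite_size_series"))
  L <- series$points$L
  d <- series$points$d_pbc
  geom <- series$geom
  corr <- function(lmu) .psd_correction(L, exp(lmu), geom)
  rss <- function(lmu) { r <- d - corr(lmu); sum((r - mean(r))^2) }
  grid <- seq(log(mu_range[1]), log(mu_range[2]), length.out = 80)
  v <- vapply(grid, rss, 0)
  if (any(!is.finite(v)))
    .stop_val("fit error: non-finite objective; inputs L = %s, d_pbc = %s",
              paste(signif(L, 4), collapse = ","), paste(signif(d, 4), collapse = ","))
  i <- which.min(v)
  o <- stats::optimize(rss, c(grid[max(1, i - 1)], grid[min(length(grid), i + 1)]),
                       tol = tol)
  mu_m <- exp(o$minimum)
  cvals <- corr(o$minimum)
  d_inf <- mean(d - cvals)
  cf <- mean(abs(cvals)) / mean(d)
  pbc_fit_result(d_inf, mu_m, geom$h, geom$mu_f,
                 degenerate = cf < 0.01, correction_frac = cf, rss = o$objective)
}

#' Monte-Carlo error propagation for the finite-size fit
#'
#' Repeats the fit `n` times on series perturbed by Gaussian noise with the
#' per-point standard deviations `d_err` (in the source data these come
#' from the difference between the two leaflets' diffusion coefficients).
#' The spread of the fitted `D_inf` sample gives its error estimate; the
#' viscosity samples are returned raw because their distribution is often
#' skewed and a Gaussian summary would misrepresent it.
#'
#' @param series a [finite_size_series()] whose points all carry `d_err`.
#' @param n number of Monte-Carlo fits (the source analysis used 10,000).
#' @param seed RNG seed; identical seeds give identical output.
#' @return The central `pbc_fit_result` augmented with `d_inf_err` (the
#'   standard deviation of the `d_inf` sample), `d_inf_samples` and
#'   `mu_m_samples`.
#' @export
mc_error_propagation <- function(series, n = 10000, seed = 1) {
  stopifnot(inherits(series, "finite_size_series"))
  if (anyNA(series$points$d_err))
    .stop_val("every point needs d_err for Monte-Carlo error propagation")
  central <- fit_finite_size(series)
  set.seed(seed)
  k <- nrow(series$points)
  noise <- matrix(stats::rnorm(n * k), nrow = n)
  L <- series$points$L
  geom <- series$geom
  lmu0 <- log(central$mu_m)
  span <- log(1e3)
  d_inf_s <- numeric(n)
  mu_m_s <- numeric(n)
  for (j in seq_len(n)) {
    dj <- series$points$d_pbc + noise[j, ] * series$points$d_err
    rss <- function(lmu) {
      r <- dj - .psd_correction(L, exp(lmu), geom)
      sum((r - mean(r))^2)
    }
    o <- stats::optimize(rss, c(lmu0 - span, lmu0 + span), tol = 1e-8)
    mu_m_s[j] <- exp(o$minimum)
    d_inf_s[j] <- mean(dj - .psd_correction(L, mu_m_s[j], geom))
  }
  central$d_inf_err <- stats::sd(d_inf_s)
  central$d_inf_samples <- d_inf_s
  central$mu_m_samples <- mu_m_s
  central
}

# --------------------------------------------------------------------------
# MSD

#' Mean squared displacement with leaflet-drift removal
#'
#' Subtracts each leaflet's mean displacement from its member particles
#' frame by frame (so collective leaflet sliding does not masquerade as
#' diffusion), then averages `|r(t+lag) - r(t)|^2` over both leaflets'
#' particles and all valid time origins.  The all-origin average is
#' computed with an FFT (Wiener-Khinchin), so the cost is
#' O(particles x frames log frames).
#'
#' @param traj a [planar_trajectory_set()].
#' @param origin_stride use every `origin_stride`-th time origin (1 = all;
#'   larger values switch to a direct evaluation and are only useful for
#'   very long trajectories).
#' @param per_particle if `TRUE`, attach the per-particle MSD matrix as
#'   attribute `"per_particle"` (lags x particles), e.g. for ensemble
#'   standard errors.
#' @return An [msd_curve()] with lags `0, dt, ..., (frames-1) dt`.
#' @export
compute_msd <- function(traj, origin_stride = 1, per_particle = FALSE) {
  stopifnot(inherits(traj, "planar_trajectory_set"))
  if (origin_stride < 1 || origin_stride != round(origin_stride))
    .stop_val("origin_stride must be a positive integer")
  x <- traj$x; y <- traj$y
  n <- nrow(x)
  # leaflet drift removal: subtract each leaflet's center-of-mass motion
  for (lf in unique(traj$leaflet)) {
    idx <- which(traj$leaflet == lf)
    cx <- rowMeans(x[, idx, drop = FALSE]); cy <- rowMeans(y[, idx, drop = FALSE])
    x[, idx] <- x[, idx] - (cx - cx[1])
    y[, idx] <- y[, idx] - (cy - cy[1])
  }
  dt <- traj$times[2] - traj$times[1]
  lag <- (seq_len(n) - 1) * dt
  if (origin_stride == 1L) {
    pp <- .msd_fft(x) + .msd_fft(y)
  } else {
    origins <- seq(1, n - 1, by = origin_stride)
    pp <- vapply(seq_len(n) - 1L, function(del) {
      o <- origins[origins + del <= n]
      if (!length(o)) return(rep(NA_real_, ncol(x)))
      colMeans((x[o + del, , drop = FALSE] - x[o, , drop = FALSE])^2 +
                 (y[o + del, , drop = FALSE] - y[o, , drop = FALSE])^2)
    }, numeric(ncol(x)))
    pp <- t(pp)
    keep <- !is.na(pp[, 1])
    pp <- pp[keep, , drop = FALSE]; lag <- lag[keep]
  }
  msd <- rowMeans(pp)
  msd[msd < 0] <- 0   # clip FFT round-off at ~1e-16
  out <- msd_curve(lag, msd)
  if (per_particle) attr(out, "per_particle") <- pp
  out
}

# per-particle all-origin MSD of one coordinate, lags x particles
.msd_fft <- function(m) {
  n <- nrow(m)
  pad <- rbind(m, matrix(0, n, ncol(m)))
  f <- stats::mvfft(pad)
  acf <- Re(stats::mvfft(f * Conj(f), inverse = TRUE))[seq_len(n), , drop = FALSE] / (2 * n)
  sq <- m^2
  css <- apply(sq, 2, cumsum)
  tot <- css[n, ]
  # SS(del) = sum_{t<=n-del} sq_t + sum_{t>del} sq_t
  ss <- css[n:1, , drop = FALSE] + rep(tot, each = n) -
    rbind(0, css[-n, , drop = FALSE])
  (ss - 2 * acf) / (n - (seq_len(n) - 1))
}

#' Linear fit of the MSD and the lateral diffusion coefficient
#'
#' Least-squares straight line `MSD = 4 D lag + b` restricted to the lag
#' window (10-100 ns by default); for two-dimensional lateral motion the
#' diffusion coefficient is slope/4.  The slope in nm^2/ns converts to
#' um^2/s by a factor 1000 (1 nm^2/ns = 1 um^2/ms).
#'
#' @param msd an [msd_curve()].
#' @param window `c(lo, hi)` lag window in ns; must lie within the data
#'   support and contain >= 3 points.
#' @return List with `d_pbc` (um^2/s), `intercept` (nm^2) and `d_se` (the
#'   ordinary least-squares standard error of `d_pbc`, um^2/s).
#' @export
fit_msd_linear <- function(msd, window = c(10, 100)) {
  stopifnot(inherits(msd, "msd_curve"))
  if (window[1] >= window[2]) .stop_val("window must be c(lo, hi) with lo < hi")
  if (window[1] < min(msd$lag) || window[2] > max(msd$lag))
    .stop_val("range error: window [%g, %g] outside lag support [%g, %g]",
              window[1], window[2], min(msd$lag), max(msd$lag))
  sel <- msd$lag >= window[1] & msd$lag <= window[2]
  if (sum(sel) < 3L) .stop_val("need >= 3 MSD points inside the fit window")
  fit <- stats::lm(m ~ l, data = data.frame(l = msd$lag[sel], m = msd$msd[sel]))
  co <- stats::coef(fit)
  # suppressWarnings: summary.lm warns on an exactly linear MSD
  se <- tryCatch(suppressWarnings(summary(fit)$coefficients["l", "Std. Error"]),
                 error = function(e) NA_real_)
  list(d_pbc = as.numeric(co["l"]) / 4 * 1000,
       intercept = as.numeric(co["(Intercept)"]),
       d_se = as.numeric(se) / 4 * 1000)
}
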