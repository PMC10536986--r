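# Synthetic observables with known ground truth.  The generators are
# structurally faithful stand-ins for the real observables (scattering
# density-profile style densities, cholesterol-ordered acyl chains, 2D
# Brownian motion, forward-modelled finite-size diffusion series); they do
# not attempt quantitative realism beyond typical magnitudes.  Every
# generator records its ground truth so recovery tests never re-derive it.

#' Specification of a scattering-density-profile style bilayer density
#'
#' The electron density is composed the way scattering density profile
#' models compose volume distributions -- individual Gaussians and error
#' functions: a Gaussian headgroup peak pair at `+/- z_h`, an
#' error-function hydrocarbon plateau, a Gaussian methyl trough at the
#' center, and the bulk water level outside.
#'
#' Defaults approximate a fluid PC bilayer: water 333 e/nm^3, chain
#' plateau 300 e/nm^3, headgroup maxima near 420 e/nm^3 at +/- 1.9 nm and
#' a methyl trough near 190 e/nm^3.
#'
#' @param z_h headgroup Gaussian center, nm (half the headgroup-peak
#'   thickness).
#' @param hg_width,hg_amp headgroup Gaussian width (nm) and amplitude
#'   (e/nm^3, added on top of the local plateau).
#' @param methyl_width,methyl_depth central trough width (nm) and depth
#'   (e/nm^3).
#' @param chain_rho hydrocarbon plateau density, e/nm^3.
#' @param chain_edge,edge_width position and width (nm) of the
#'   error-function edge between hydrocarbon and water.
#' @param solvent_rho bulk water electron density, e/nm^3.
#' @return An object of class `sdp_density_spec`.
#' @export
sdp_density_spec <- function(z_h = 1.9, hg_width = 0.3, hg_amp = 150,
                             methyl_width = 0.3, methyl_depth = 110,
                             chain_rho = 300, chain_edge = 2.4,
                             edge_width = 0.3, solvent_rho = 333) {
  spec <- list(z_h = z_h, hg_width = hg_width, hg_amp = hg_amp,
               methyl_width = methyl_width, methyl_depth = methyl_depth,
               chain_rho = chain_rho, chain_edge = chain_edge,
               edge_width = edge_width, solvent_rho = solvent_rho)
  .check_finite(unlist(spec), "sdp_density_spec fields")
  if (any(c(z_h, hg_width, methyl_width, chain_edge, edge_width) <= 0) ||
      solvent_rho <= 0 || chain_rho < 0 || hg_amp < 0 || methyl_depth < 0)
    .stop_val("invalid sdp_density_spec: lengths must be positive, densities >= 0")
  structure(spec, class = "sdp_density_spec")
}

#' Generate a synthetic bilayer electron density profile
#'
#' Deterministic; symmetric by construction.  The ground truth (the
#' headgroup peak position `z_h`) is recorded in attribute
#' `"ground_truth"`.
#'
#' @param spec an [sdp_density_spec()].
#' @param z_grid symmetric z grid, nm.
#' @return A [density_profile()].
#' @export
gen_sdp_density <- function(spec = sdp_density_spec(),
                            z_grid = seq(-4, 4, by = 0.01)) {
  stopifnot(inherits(spec, "sdp_density_spec"))
  z <- z_grid
  gauss <- function(c0, w) exp(-(z - c0)^2 / (2 * w^2))
  inside <- 0.5 * (pracma::erf((z + spec$chain_edge) / spec$edge_width) -
                     pracma::erf((z - spec$chain_edge) / spec$edge_width))
  rho <- spec$solvent_rho + (spec$chain_rho - spec$solvent_rho) * inside +
    spec$hg_amp * (gauss(spec$z_h, spec$hg_width) + gauss(-spec$z_h, spec$hg_width)) -
    spec$methyl_depth * gauss(0, spec$methyl_width)
  if (any(rho < 0)) .stop_val("spec error: negative electron density")
  edge_ok <- abs(rho[c(1, length(rho))] - spec$solvent_rho) <= 0.01 * spec$solvent_rho
  if (!all(edge_ok))
    .stop_val("spec error: density does not reach the solvent level at the grid edges")
  out <- density_profile(z, rho, spec$solvent_rho)
  # realized peak of the analytic composite (the erf edge can displace the
  # maximum slightly from z_h when the two overlap)
  zf <- seq(max(min(z), spec$z_h - 1), min(max(z), spec$z_h + 1), by = 1e-4)
  comp <- spec$solvent_rho +
    (spec$chain_rho - spec$solvent_rho) * 0.5 *
      (pracma::erf((zf + spec$chain_edge) / spec$edge_width) -
         pracma::erf((zf - spec$chain_edge) / spec$edge_width)) +
    spec$hg_amp * (exp(-(zf - spec$z_h)^2 / (2 * spec$hg_width^2)) +
                     exp(-(zf + spec$z_h)^2 / (2 * spec$hg_width^2))) -
    spec$methyl_depth * exp(-zf^2 / (2 * spec$methyl_width^2))
  z_peak <- zf[which.max(comp)]
  attr(out, "ground_truth") <- list(z_h = spec$z_h, z_peak = z_peak,
                                    thickness = 2 * spec$z_h)
  out
}

#' Generate a slab-contrast density profile (analytic form-factor oracle)
#'
#' Uniform contrast `contrast` on `|z| <= d` over the solvent background;
#' its form factor has the closed form `|F(q)| = |2 contrast sin(q d)/q|`
#' with zeros at `q = n pi / d`.
#'
#' @param d slab half-width, nm; must fit inside the grid.
#' @param contrast density contrast, e/nm^3.
#' @param z_grid symmetric z grid, nm.
#' @param solvent_rho background level, e/nm^3.
#' @return A [density_profile()] with attribute `"ground_truth"` holding
#'   `d`, `contrast` and the closed-form `f_abs(q)` function.
#' @export
gen_slab_density <- function(d, contrast, z_grid = seq(-4, 4, by = 0.001),
                             solvent_rho = 333) {
  .check_finite(c(d, contrast), "slab parameters")
  if (d < 0) .stop_val("slab half-width must be >= 0")
  if (d >= max(abs(z_grid))) .stop_val("slab half-width d exceeds the z grid")
  # midpoint convention at the discontinuity: a node that coincides with the
  # slab edge carries half the contrast, so trapezoidal quadrature of the
  # Fourier integral stays second-order accurate
  eps <- 0.25 * min(diff(z_grid))
  w <- if (d == 0) rep(0, length(z_grid)) else
    ifelse(abs(z_grid) < d - eps, 1,
           ifelse(abs(abs(z_grid) - d) <= eps, 0.5, 0))
  rho <- solvent_rho + contrast * w
  out <- density_profile(z_grid, rho, solvent_rho)
  attr(out, "ground_truth") <- list(
    d = d, contrast = contrast,
    f_abs = function(q) abs(2 * contrast * ifelse(q == 0, d, sin(q * d) / q)))
  out
}

#' Specification of the synthetic order parameter model
#'
#' Baseline per-carbon profiles with a cholesterol-induced ordering
#' response: `|S(c)| = |S0| (1 + gain * min(c, saturation))` plus seeded
#' Gaussian noise, emulating the experimentally observed increase of
#' acyl-chain order with cholesterol that saturates around 30 mol %.
#'
#' @param baseline named list of per-chain baseline profiles; default a
#'   plateau-and-decay POPC-like shape (palmitate C2-C16, oleate C2-C18
#'   with reduced order at the C9-C10 double bond, a forked oleate C2
#'   pair, and a few headgroup/glycerol values).
#' @param ordering_gain fractional increase of |S| per mol % cholesterol.
#' @param saturation concentration (mol %) beyond which the ordering gain
#'   saturates.
#' @param noise_sd Gaussian noise on each S_CH value.
#' @param seed RNG seed used by [gen_op_profiles()].
#' @return An object of class `op_model_spec`.
#' @export
op_model_spec <- function(baseline = NULL, ordering_gain = 0.02,
                          saturation = 30, noise_sd = 0, seed = 1) {
  if (is.null(baseline)) baseline <- .default_op_baseline()
  if (ordering_gain < 0 || saturation < 0 || noise_sd < 0)
    .stop_val("ordering_gain, saturation and noise_sd must be >= 0")
  structure(list(baseline = baseline, ordering_gain = ordering_gain,
                 saturation = saturation, noise_sd = noise_sd, seed = seed),
            class = "op_model_spec")
}

# plateau near -0.21 for the upper chain, decaying toward the terminal
# methyl; dip at the oleate double bond; small headgroup values
.default_op_baseline <- function() {
  pal_c <- 2:16
  pal_s <- -0.21 * exp(-pmax(pal_c - 8, 0) / 6)
  ole_c <- 2:18
  ole_s <- -0.19 * exp(-pmax(ole_c - 8, 0) / 6)
  ole_s[ole_c %in% c(9, 10)] <- -0.05
  list(
    palmitate = data.frame(carbon = pal_c, s_ch = pal_s,
                           n_h = ifelse(pal_c == 16, 3L, 2L)),
    oleate = data.frame(carbon = ole_c, s_ch = ole_s,
                        n_h = ifelse(ole_c == 18, 3L, ifelse(ole_c %in% c(9, 10), 1L, 2L))),
    # the oleate C2 pair is forked: the two hydrogens differ genuinely
    oleate_c2_fork = c(-0.06, 0.02),
    `headgroup-glycerol` = data.frame(carbon = 1:3, s_ch = c(0.04, -0.02, 0.01),
                                      n_h = c(2L, 2L, 2L)))
}

#' Generate order parameter sets across cholesterol concentrations
#'
#' @param spec an [op_model_spec()].
#' @param concentrations cholesterol mole fractions; default the simulated
#'   compositions 0, 0.11, 0.20, 0.29, 0.38, 0.47.
#' @return List of [order_parameter_set()]s with attribute
#'   `"ground_truth"` (the noise-free per-carbon surfaces).
#' @export
gen_op_profiles <- function(spec = op_model_spec(),
                            concentrations = c(0, 0.11, 0.20, 0.29, 0.38, 0.47)) {
  stopifnot(inherits(spec, "op_model_spec"))
  set.seed(spec$seed)
  scale_at <- function(frac) 1 + spec$ordering_gain * min(100 * frac, spec$saturation)
  truth <- list()
  out <- lapply(concentrations, function(frac) {
    fac <- scale_at(frac)
    rows <- list()
    for (chain in c("palmitate", "oleate", "headgroup-glycerol")) {
      b <- spec$baseline[[chain]]
      for (i in seq_len(nrow(b))) {
        if (chain == "oleate" && b$carbon[i] == 2) {
          s <- sign(spec$baseline$oleate_c2_fork) *
            pmin(abs(spec$baseline$oleate_c2_fork) * fac, 0.5)
          rows[[length(rows) + 1L]] <- data.frame(
            chain = chain, carbon = 2, hydrogen = 1:2, s_ch = s, err = NA_real_)
        } else {
          s <- sign(b$s_ch[i]) * abs(b$s_ch[i]) * fac
          rows[[length(rows) + 1L]] <- data.frame(
            chain = chain, carbon = b$carbon[i], hydrogen = seq_len(b$n_h[i]),
            s_ch = s, err = NA_real_)
        }
      }
    }
    e <- do.call(rbind, rows)
    if (any(abs(e$s_ch) > 0.5))
      .stop_val("spec error: |S| exceeds 0.5 at %.0f mol %%", 100 * frac)
    if (spec$noise_sd > 0)
      e$s_ch <- pmax(pmin(e$s_ch + stats::rnorm(nrow(e), 0, spec$noise_sd), 0.5), -0.5)
    order_parameter_set(frac, e)
  })
  attr(out, "ground_truth") <- list(
    scale = vapply(concentrations, scale_at, 0),
    baseline = spec$baseline, concentrations = concentrations)
  out
}

#' Generate 2D Brownian trajectories
#'
#' Independent Gaussian steps with per-axis variance `2 D dt`, split into
#' two leaflets, optionally with a constant collective drift per leaflet
#' (equal and opposite in the two leaflets, along x).
#'
#' @param d diffusion coefficient, um^2/s.
#' @param n_particles particle count (split half/half into leaflets).
#' @param n_steps number of steps (frames = steps + 1).
#' @param dt time step, ns.
#' @param leaflet_drift collective drift speed, nm/ns (upper leaflet +x,
#'   lower leaflet -x).
#' @param seed RNG seed.
#' @return A [planar_trajectory_set()] with attribute `"ground_truth"`.
#' @export
gen_brownian_traj <- function(d, n_particles = 64, n_steps = 500, dt = 1,
                              leaflet_drift = 0, seed = 1) {
  if (!is.finite(dt) || dt <= 0) .stop_val("dt must be positive")
  if (!is.finite(d) || d < 0) .stop_val("d must be >= 0")
  set.seed(seed)
  d_nm <- d / 1000                      # um^2/s -> nm^2/ns
  sd_step <- sqrt(2 * d_nm * dt)
  n_fr <- n_steps + 1L
  step_mat <- function() {
    s <- matrix(stats::rnorm(n_steps * n_particles, sd = sd_step), n_steps)
    rbind(0, apply(s, 2, cumsum))
  }
  x <- step_mat(); y <- step_mat()
  leaflet <- rep(c("upper", "lower"), length.out = n_particles)
  drift <- (seq_len(n_fr) - 1) * dt * leaflet_drift
  x[, leaflet == "upper"] <- x[, leaflet == "upper"] + drift
  x[, leaflet == "lower"] <- x[, leaflet == "lower"] - drift
  out <- planar_trajectory_set((seq_len(n_fr) - 1) * dt, x, y, leaflet)
  attr(out, "ground_truth") <- list(d = d, leaflet_drift = leaflet_drift)
  out
}

#' Generate a finite-size diffusion series from the periodic model
#'
#' Forward-models `D_PBC` at the requested box sizes with [dpbc_model()]
#' and applies multiplicative Gaussian noise; `d_err` is set to
#' `rel_noise * d_pbc`.
#'
#' @param d_inf infinite-system diffusion coefficient, um^2/s.
#' @param mu_m membrane shear viscosity, mPa s.
#' @param geom a [membrane_geometry()].
#' @param L_list box edges, nm; the default is the pure-POPC
#'   small/medium/large series 4.4, 9.0, 18.1 nm.
#' @param rel_noise relative noise level (0 = exact forward model).
#' @param seed RNG seed.
#' @return A [finite_size_series()] with attribute `"ground_truth"`.
#' @export
gen_finite_size_series <- function(d_inf, mu_m, geom,
                                   L_list = c(4.4, 9.0, 18.1),
                                   rel_noise = 0, seed = 1) {
  set.seed(seed)
  d <- dpbc_model(L_list, d_inf, mu_m, geom)
  if (rel_noise > 0) d <- d * (1 + stats::rnorm(length(d), 0, rel_noise))
  out <- finite_size_series(
    data.frame(L = L_list, d_pbc = d, d_err = rel_noise * d), geom)
  attr(out, "ground_truth") <- list(d_inf = d_inf, mu_m = mu_m)
  out
}
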