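---
title: "Benchmarking POPC-cholesterol simulations against NMR and X-ray observables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking POPC-cholesterol simulations against NMR and X-ray observables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Cholesterol orders phospholipid acyl chains, thickens bilayers and slows
lateral diffusion — the hallmarks of the liquid-ordered state.  Atomistic
force fields disagree quantitatively on all three effects, and the
disagreement grows with cholesterol content.  `cholbench` provides the
machinery to measure that disagreement: it turns tabulated simulation
observables and experimental reference data, each available only at a
handful of cholesterol concentrations, into continuous deviation measures
over the 0–46 mol % range, and collapses them into a per-force-field
quality profile.

This vignette documents the models and conventions behind each stage, the
defaults and why they were chosen, what the synthetic generators do and do
not emulate, and the package's numerical choices and known limitations.

```{r setup}
library(cholbench)
```

## Observables and their preprocessing

### C–H bond order parameters

The order parameter of a C–H bond,
$S_{CH} = \tfrac{1}{2}\langle 3\cos^2\theta - 1 \rangle$ with $\theta$ the
angle to the membrane normal, is measured per carbon by ²H or ¹³C NMR and
computed per hydrogen in simulations.  `order_parameter_set` stores the
values signed, indexed by chain (palmitate, oleate, or the
headgroup/glycerol region), carbon and hydrogen.

`average_equivalent_hydrogens()` implements the preprocessing convention
used throughout the package:

* the 2 (3) hydrogens of CH₂ (CH₃) groups in the acyl chains rotate
  freely, so their order parameters are averaged into one value per
  carbon;
* the two hydrogens on carbon 2 of the oleate chain lack that rotational
  averaging — their values genuinely differ ("fork") — so both are kept,
  ordered by magnitude;
* headgroup and glycerol entries pass through untouched, and are excluded
  from acyl-chain quality metrics.

The error of an averaged group is the *mean* of the member errors, not
mean/√n: the hydrogens are alternative measurements of the same rotating
group, not independent samples.

¹³C NMR yields only $|S_{CH}|$.  Because the sign convention matters for
deviation maps ("more ordered" = more negative), magnitude-only data are
mapped to $-|S_{CH}|$ when the `unsigned` flag of `op_surface_input()` is
set; this is the default in `run_quality_study()` since acyl-chain
$S_{CH}$ values are negative throughout the fluid phase, making the
magnitude comparison exact there.

### Interpolation over cholesterol concentration

Experiments and simulations rarely share compositions.
`build_surface_2d()` therefore interpolates each observable bilinearly
onto a regular (coordinate × concentration) grid — the coordinate being
the acyl-chain carbon index or the distance from the bilayer center — and
`interp_curve_1d()` does the same for scalar observables (form-factor
minima positions, diffusion coefficients).  Interpolation is exact at the
input knots and *never extrapolates*: queries outside the span of the
input concentrations raise an error.  The default grid is 0–46 mol % in
1 % steps; data at 47 mol % define the upper hull of the interpolation
but are not queried beyond 46.  When the coordinate supports differ
between concentrations (carbons missing at some compositions), the
surface is built on the intersection of supports and the dropped
coordinates are reported.

Both surfaces use plain linear interpolation on gridded input.
Triangulation-based scattered interpolation, smoothing splines and
uncertainty-aware schemes are deliberately out of scope: the inputs here
are gridded, and linearity guarantees no overshoot beyond the bracketing
profiles.

### Deviations and the quality measure

`deviation_surface()` computes signed `sim − exp` differences on matched
grids, with a companion mask marking cells within the experimental error
band of ±0.02 — the cells rendered white by `plot_deviation_map()`.
Negative values mean the simulated chains are too ordered.

`relative_deviation_curve()` reduces a deviation surface to one number
per concentration: the mean of |sim − exp| over the first axis divided by
the mean of |exp| over the same axis, × 100.  Dividing one reduction by
the like reduction (rather than averaging pointwise ratios) keeps the
measure finite when individual experimental values pass through zero and
makes it invariant under joint rescaling of both inputs.  For the density
surfaces the average runs over the full simulated z range by default;
`coord_range` restricts it to the membrane region when the solvent slab
would dilute the signal.

`cumulative_quality()` stacks the per-observable curves — first two
form-factor minima, palmitate and oleate order parameters, diffusion —
into a total deviation per concentration.  Electron-density quality is
computable (`density_quality()`) but off by default in the standard
component set.  The stack order is fixed for reproducible figures; the
total is order-invariant by construction.  Diffusion enters on the common
dense concentration grid, not only at the simulated compositions, so that
all components share one axis.

## Structure from densities and form factors

`bilayer_thickness()` defines the membrane thickness as twice the
distance from the electron density maximum (the headgroup phosphate
peak) to the bilayer center.  The profile is first smoothed with a
5-point moving mean — the window shrinks symmetrically (1, 3, 5 points)
at the edges — then mirror-averaged, and the highest local maximum with
prominence ≥ 1 % of the profile range is located on each side of z = 0.
If two maxima tie in height, the one at larger |z| wins (the outer
shoulder, not an inner packing ripple).  Monotone or flat profiles raise
a "no headgroup peak" error rather than returning a spurious number.
Profiles are symmetrized because the experimental reference (multilamellar
vesicles, and the scattering-density-profile models fitted to them) is
symmetric by construction; leaflet asymmetry beyond 2 % is reported.

`form_factor()` evaluates
$F(q) = \int (\rho(z) - \rho_{\mathrm{solvent}})\cos(qz)\,dz$
by trapezoidal quadrature and returns $|F(q)|$ on a default grid of
0.01–10 nm⁻¹ in 0.005 nm⁻¹ steps.  Because the absolute normalization of
experimental form factors is convention-dependent, comparisons use only
the *positions* of the first two minima of $|F|$, which are scale-free
and, unlike the full curve, insensitive to the simulation box size.
`form_factor_minima()` finds the interior grid minima and refines each by
parabolic interpolation through the three surrounding points, which
reduces the error well below one grid spacing.

`area_per_lipid()` divides the time-averaged box area by the number of
phospholipids in one leaflet (cholesterol does not count toward the
divisor) and estimates the standard error by block averaging over five
contiguous blocks.  `chol_partial_area()` converts an APL-vs-composition
curve into the partial molecular area of cholesterol,
$\partial A_{\mathrm{tot}}/\partial N_{\mathrm{chol}}$, by central finite
differences in the cholesterol count $N = n_{PC}\,x/(1-x)$: negative
values are the condensing effect, zero means cholesterol inserts without
expanding the leaflet.

## Lateral diffusion and the finite-size correction

### MSD

`compute_msd()` first removes each leaflet's center-of-mass motion frame
by frame, so collective leaflet sliding does not masquerade as diffusion,
then averages $|r(t+\Delta)-r(t)|^2$ over the particles of both leaflets
and over all time origins.  The all-origin average uses the
Wiener–Khinchin identity (FFT), so a 1024-particle, 1000-frame
trajectory costs a fraction of a second.  `fit_msd_linear()` fits a
straight line on the 10–100 ns lag window and reports $D = $ slope/4
(two-dimensional motion), converting nm²/ns to μm²/s.  The fit window is
a parameter, but the 10–100 ns default avoids both the sub-ns ballistic
and cage regimes and the noisy long-lag tail.

### The periodic Saffman–Delbrück model

A lipid diffusing in a periodic box interacts hydrodynamically with its
own images, so the measured $D_{PBC}$ underestimates the infinite-system
$D_\infty$, and the size of the bias depends on the membrane's shear
viscosity $\mu_m$.  The package models the membrane as a 2D fluid of
surface viscosity $\mu_m h$ embedded in water of viscosity $\mu_f$.  Two
lengths govern the hydrodynamics: the Saffman–Delbrück length
$L_{SD} = \mu_m h / (2\mu_f)$, and the screening length

$$\ell = \sqrt{L_{SD}\, H},$$

the geometric mean of $L_{SD}$ and the half water-layer thickness
$H = (L_z - h)/2$: a finite hydration layer cuts off in-plane momentum
transport beyond $\ell$.  The direction-averaged mobility kernel of the
screened, incompressible 2D flow is $1/\bigl(2\mu_m h (q^2 +
\kappa^2)\bigr)$ with $\kappa = 1/\ell$; its real-space trace is the
modified Bessel function $K_0$.  Summing the interaction over all
periodic images and subtracting the zero-wavevector mode (total momentum
is constrained to zero in simulations) gives the closed form implemented
by `dpbc_model()`:

$$D_{PBC}(L) = D_\infty + \frac{k_B T}{8\pi\,\mu_m h}\left[
  \sum_{\mathbf{n}\neq 0} K_0(\kappa L |\mathbf{n}|)
  - \frac{2\pi}{(\kappa L)^2}\right].$$

The two terms nearly cancel; their difference behaves as
$\frac{k_BT}{4\pi\mu_m h}\bigl[\ln(L/\ell) - 1.42647\bigr]$ for
$L \ll \ell$ — the familiar quasi-two-dimensional logarithmic finite-size
effect (the constant is the square-lattice analogue of the cubic-lattice
self-interaction constant, $\ln 2\pi - (\pi\gamma + 4\beta'(1))/2\pi$)
— and decays to zero as $L \to \infty$, so the model reproduces both the
strong suppression seen at simulation box sizes (4–20 nm) and the exact
infinite-box limit.  Interleaflet friction is taken as infinite: the two
leaflets move as one sheet, which is the accepted regime for lipid
bilayers.  Within one composition, $h$ and $H$ are fixed to their
averages over the box sizes, since they are constants of the model, not
fit parameters.

Numerically, the image sum is evaluated through a theta-function integral
representation,
$S(a) = \tfrac12\int_0^\infty e^{-t}\,[\vartheta(a^2\!/4t)^2-1]\,dt/t$
with the modular transform applied for small arguments, which agrees with
direct Bessel summation to machine precision and is cached on a log-grid
spline so that a model evaluation costs microseconds.

### Fitting and error propagation

`fit_finite_size()` fits $(D_\infty, \mu_m)$ to $D_{PBC}$ measured at two
or more box sizes.  Both parameters must be positive; $\mu_m$ is
optimized on a log scale, and for fixed $\mu_m$ the optimal $D_\infty$ is
linear least squares, so the two-parameter problem reduces to a
one-dimensional profiled optimization over a wide bracket
(10⁻²–10⁴ mPa s).  This makes the result independent of starting values
— on noiseless three-point input generated by `dpbc_model()` itself both
parameters are recovered to better than 10⁻⁶ relative.  If the fitted
correction term is below 1 % of the mean $D_{PBC}$, the series carries no
usable size dependence and the result is flagged `degenerate` instead of
reporting a meaningless viscosity.

`mc_error_propagation()` repeats the fit (10,000 times by default) on
series perturbed by Gaussian noise with the per-point error estimates —
in the source data, the difference between the two leaflets' diffusion
coefficients.  The spread of the $D_\infty$ sample is its error estimate;
the $\mu_m$ samples are returned raw because their distribution is often
strongly skewed and a Gaussian summary would misrepresent it.  The
whole procedure is seeded and bit-reproducible.

Temperature defaults to 298 K and the water viscosity to
$\mu_f = 0.3228$ mPa s (the TIP3P value interpolated to 298 K); both are
per-dataset overridable through `membrane_geometry()`.  Internally all
equations are evaluated in SI and converted at the boundary; the package
otherwise uses one unit system throughout (nm, ns, μm²/s, mPa s, K,
e/nm³) precisely because the correction mixes $k_BT$ with viscosities and
lengths, where silent unit errors are notoriously easy.

## Synthetic generators

Every pipeline stage is testable without trajectories or downloads:

* `gen_sdp_density()` composes an electron density the way
  scattering-density-profile models do — Gaussian headgroup peaks at
  ±z_h, an error-function hydrocarbon plateau, a Gaussian methyl trough —
  and records the ground-truth peak position.  Defaults (water
  333 e/nm³, plateau 300 e/nm³, headgroup maxima ≈ 450 e/nm³ at ±1.9 nm,
  trough ≈ 190 e/nm³) approximate a fluid PC bilayer.
* `gen_slab_density()` is the analytic oracle: a top-hat contrast whose
  form factor is $|2\Delta\rho \sin(qd)/q|$ in closed form.  A grid node
  that coincides with the slab edge carries half the contrast — the
  midpoint convention that keeps trapezoidal Fourier quadrature
  second-order accurate across the discontinuity.
* `gen_op_profiles()` applies a saturating cholesterol ordering response,
  $|S(c)| = |S_0|(1 + g\min(c, c_{sat}))$, to a POPC-like baseline
  (plateau near −0.21, decay toward the terminal methyl, reduced order at
  the oleate double bond, a forked oleate-C2 pair).  The defaults —
  gain 0.02 per mol %, saturation at 30 mol % — give the ~60 % rise of
  chain order over 0→30 mol % cholesterol typical of PC membranes, while
  respecting $|S| \le 0.5$.
* `gen_brownian_traj()` draws independent Gaussian steps of per-axis
  variance $2D\,dt$, optionally with equal-and-opposite collective drift
  per leaflet; `gen_finite_size_series()` forward-models $D_{PBC}(L)$
  with `dpbc_model()` plus multiplicative noise.

Each generator is seeded through a single per-call RNG and returns its
ground truth as an attribute; recovery tests compare against that ground
truth only.  The generators are structurally faithful, not biophysically
quantitative: passing tests demonstrate that the estimators recover what
the generators put in (interpolation exactness, fit recovery, drift
immunity, known minima), not that any force field reproduces real POPC
data.  Real data add features the fixtures lack — correlated noise along
the chain, non-Gaussian MSD statistics from lipid caging, undulation
broadening of densities, concentration-dependent viscosity — so
quantitative conclusions about force fields still require the real
reference tables.

## Numerical choices

* Interpolation knots are reproduced to 1e-12; queries outside the input
  span raise range errors rather than extrapolating.
* Readers reject NaN/Inf anywhere and name the offending line on parse
  errors; writers round-trip through text at better than 1e-9 relative.
* Peak prominence threshold: 1 % of the profile range; height ties
  resolved toward larger |z|.
* Form-factor minima: parabolic refinement through the three points
  around each grid minimum.
* The finite-size fit brackets log μ_m over [10⁻², 10⁴] mPa s with an
  80-point scan before the 1D optimization, and declares degeneracy below
  a 1 % correction fraction.
* Zero experimental normalizers abort the relative deviation with the
  concentration named, rather than returning infinities.

The test suite runs the full pipeline at reduced problem sizes (a few
hundred particles and frames for property tests) and at the study scale
where it matters: 1024 particles × 1000 frames for the Brownian
recovery, 10,000 Monte-Carlo fits, 0.001 nm density grids for the
form-factor oracle.

## Limitations

* The package evaluates *tabulated* observables; it does not read
  trajectories (XTC/TRR/PDB) or compute order parameters and densities
  from coordinates, and it does not fit scattering-density-profile
  models to raw scattered intensities.
* The finite-size model assumes a single flat membrane spanning a
  periodic box with infinite interleaflet friction; it is not applicable
  to supported bilayers, vesicles or membranes with free monolayer slip.
  At fixed hydration the true periodic hydrodynamics acquires additional
  quasi-2D contributions for boxes far wider than the water layer is
  thick; at simulation-typical aspect ratios (L ≲ 5 H to 7 H and
  L ≪ ℓ) the screened-image model is the controlling behavior.
* Form-factor comparisons are restricted to minima positions by design;
  amplitudes would require a normalization convention the experimental
  references do not share.
* No statistical significance testing between force fields: ranking is
  by deviation magnitude only.
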