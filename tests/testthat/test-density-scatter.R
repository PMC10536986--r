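test_that("moving-mean smoothing matches its definition including edges", {
  z <- seq(-1, 1, by = 0.1)
  const <- density_profile(z, rep(5, 21), 5)
  expect_equal(smooth_density(const)$rho, rep(5, 21))

  imp <- rep(0, 21); imp[11] <- 1
  sm <- smooth_density(density_profile(z, imp, 0), window = 5)
  expect_equal(sm$rho[9:13], rep(0.2, 5))
  expect_equal(sum(sm$rho), 1)   # interior impulse mass preserved

  prof <- density_profile(z, runif(21), 0.5)
  expect_equal(smooth_density(prof, window = 1)$rho, prof$rho)
  expect_error(smooth_density(prof, window = 4), "odd")
  expect_error(smooth_density(prof, window = 51), "exceeds")
})

test_that("thickness is twice the headgroup-maximum distance and mirror invariant", {
  z <- seq(-4, 4, by = 0.01)
  rho <- 300 + 100 * (exp(-(z - 2)^2 / 0.02) + exp(-(z + 2)^2 / 0.02))
  p <- density_profile(z, rho, 300)
  expect_equal(bilayer_thickness(p), 4.0, tolerance = 0.011)

  # mirror image: identical thickness
  pm <- density_profile(z, rev(rho), 300)
  expect_equal(bilayer_thickness(pm), bilayer_thickness(p))

  flat <- density_profile(z, rep(300, length(z)), 300)
  expect_error(bilayer_thickness(flat), "flat|no headgroup")
  mono <- density_profile(z, 300 + z, 300)
  expect_error(bilayer_thickness(mono), "no headgroup|asymmetric")
})

test_that("form factor matches the slab closed form and the q = 0 contrast integral", {
  slab <- gen_slab_density(2, 100, z_grid = seq(-4, 4, by = 0.001))
  truth <- attr(slab, "ground_truth")
  q <- seq(0.05, 7.5, by = 0.005)   # below the 5th zero at 5 pi / 2
  ff <- form_factor(slab, q)
  ref <- truth$f_abs(q)
  ok <- ref > 5e-3 * max(ref)       # relative comparison away from the zeros
  expect_lt(max(abs(ff$f_abs[ok] - ref[ok]) / ref[ok]), 0.005)

  # q -> 0 limit equals the integrated contrast (trapezoid oracle)
  ff0 <- form_factor(slab, q_grid = c(1e-6, 0.01))
  contrast_int <- pracma::trapz(slab$z, slab$rho - slab$solvent_rho)
  expect_equal(ff0$f_abs[1], abs(contrast_int), tolerance = 1e-6)

  # zero contrast everywhere -> |F| = 0
  z <- seq(-3, 3, by = 0.01)
  none <- density_profile(z, rep(333, length(z)), 333)
  expect_true(all(form_factor(none, q)$f_abs < 1e-10))

  asym <- density_profile(seq(0, 3, by = 0.01), rep(333, 301), 333)
  expect_error(form_factor(asym), "asymmetric")
})

test_that("form factor minima sit at the slab zeros and scale with 1/d", {
  q <- seq(0.01, 4, by = 0.002)
  slab2 <- gen_slab_density(2, 100, z_grid = seq(-4, 4, by = 0.001))
  m2 <- form_factor_minima(form_factor(slab2, q))
  expect_equal(m2, c(pi / 2, pi), tolerance = 0.002 / pi)   # within one grid spacing

  # doubling d halves each minimum position
  slab4 <- gen_slab_density(4, 100, z_grid = seq(-6, 6, by = 0.001))
  m4 <- form_factor_minima(form_factor(slab4, q))
  expect_equal(m4, m2 / 2, tolerance = 0.002)

  # parabolic refinement beats the grid argmin
  coarse <- seq(0.01, 4, by = 0.01)
  ffc <- form_factor(slab2, coarse)
  refined <- form_factor_minima(ffc, n = 1)
  argmin <- coarse[which(diff(sign(diff(ffc$f_abs))) == 2) + 1L][1]
  expect_lte(abs(refined - pi / 2), abs(argmin - pi / 2))

  # a Gaussian contrast transforms to a Gaussian |F|: no interior minima
  z <- seq(-4, 4, by = 0.005)
  gauss <- density_profile(z, 333 + 50 * exp(-z^2 / 0.5), 333)
  expect_error(form_factor_minima(form_factor(gauss, seq(0.01, 4, by = 0.005))),
               "insufficient minima")
})

test_that("area per phospholipid divides box area by leaflet phospholipids", {
  ap <- area_per_lipid(rep(19.36, 50), n_pl_leaflet = 32)
  expect_equal(ap$apl, 0.605)
  expect_equal(ap$se, 0)

  alt <- area_per_lipid(rep(c(19, 21), 10), n_pl_leaflet = 1, n_blocks = 5)
  expect_equal(alt$apl, 20)

  expect_error(area_per_lipid(1:3, 1, n_blocks = 5), "shorter")
  expect_error(area_per_lipid(rep(19, 10), 0), ">= 1")
})

test_that("cholesterol partial area tracks dA_tot/dN_chol including its sign", {
  # constant APL -> constant total area -> zero partial area
  const <- chol_partial_area(data.frame(chol = c(0, 10, 20, 30), apl = 0.65), 64)
  expect_equal(const$values, rep(0, 4), tolerance = 1e-12)

  # A_tot = A0 + a N_chol -> partial area a exactly (linear in N)
  a <- 0.27; n_pc <- 64
  x <- c(0, 0.1, 0.2, 0.3)
  apl <- (n_pc * 0.62 + a * n_pc * x / (1 - x)) / n_pc
  lin <- chol_partial_area(data.frame(chol = 100 * x, apl = apl), n_pc)
  expect_equal(lin$values, rep(a, 4), tolerance = 1e-9)

  # condensing: total area decreases upon adding cholesterol
  cond <- chol_partial_area(data.frame(chol = c(0, 10, 20), apl = c(0.68, 0.60, 0.54)), 64)
  expect_true(all(cond$values < 0))

  expect_error(chol_partial_area(data.frame(chol = c(0, 100), apl = 0.6), 64),
               "singularity")
})
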