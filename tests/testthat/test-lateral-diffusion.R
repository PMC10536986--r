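test_that("Saffman-Delbrueck length follows its definition", {
  expect_equal(saffman_delbrueck_length(80, 4, 0.3228), 80 * 4 / (2 * 0.3228))
  expect_equal(saffman_delbrueck_length(0.3228, 2, 0.3228), 1)
  expect_equal(saffman_delbrueck_length(80, 8, 0.3228),
               2 * saffman_delbrueck_length(80, 4, 0.3228))   # linear in h
  expect_error(saffman_delbrueck_length(-1, 4), "positive")
})

test_that("the periodic lattice sum matches a direct Bessel summation", {
  direct <- function(a, N) {
    g <- expand.grid(i = -N:N, j = -N:N)
    r <- sqrt(g$i^2 + g$j^2); r <- r[r > 0]
    sum(besselK(a * r, 0))
  }
  for (a in c(0.3, 1, 3)) {
    expect_equal(cholbench:::.psd_lattice_sum(a), direct(a, ceiling(60 / a) + 2),
                 tolerance = 1e-10)
  }
})

test_that("the finite-size model has the contracted limits and monotonicity", {
  geom <- test_geometry()   # h = 4 nm, H = 3 nm, T = 298 K
  d_inf <- 10; mu_m <- 80

  # infinite-box limit
  expect_lt(abs(dpbc_model(1e6, d_inf, mu_m, geom) - d_inf), 1e-6 * d_inf)

  # finite boxes diffuse slower, monotonically approaching d_inf
  L <- seq(4, 50, by = 0.5)
  d <- dpbc_model(L, d_inf, mu_m, geom)
  expect_true(all(d < d_inf))
  expect_true(all(diff(d) > 0))

  # doubling mu_m doubles L_SD exactly (definitional)
  f1 <- fit_finite_size(gen_finite_size_series(10, 80, geom))
  expect_equal(f1$l_sd, saffman_delbrueck_length(f1$mu_m, geom$h, geom$mu_f))

  expect_error(dpbc_model(-1, d_inf, mu_m, geom), "positive")
  expect_error(dpbc_model(10, d_inf, -5, geom), "positive")
})

test_that("fitting the finite-size model recovers the generating parameters", {
  geom <- test_geometry()
  s <- gen_finite_size_series(10, 80, geom, L_list = c(4.5, 9.2, 18.3), rel_noise = 0)
  f <- fit_finite_size(s)
  expect_lt(abs(f$d_inf - 10) / 10, 1e-6)
  expect_lt(abs(f$mu_m - 80) / 80, 1e-6)
  expect_false(f$degenerate)

  # two points, two parameters: exact interpolation
  s2 <- gen_finite_size_series(6, 120, geom, L_list = c(5, 15))
  f2 <- fit_finite_size(s2)
  expect_lt(f2$rss, 1e-12)

  # constant d_pbc: correction term unidentifiable
  flat <- finite_size_series(data.frame(L = c(5, 10, 20), d_pbc = 7), geom)
  expect_true(fit_finite_size(flat)$degenerate)
})

test_that("MSD is immune to collective motion and global translations", {
  # pure leaflet drift: drift removal annihilates the common motion
  drift <- gen_brownian_traj(0, n_particles = 16, n_steps = 100,
                             leaflet_drift = 0.3, seed = 1)
  expect_true(all(compute_msd(drift)$msd == 0))

  # single immobile particle per leaflet
  still <- planar_trajectory_set(0:9, matrix(1, 10, 2), matrix(-2, 10, 2),
                                 c("upper", "lower"))
  expect_lt(max(compute_msd(still)$msd), 1e-12)

  # a rigid per-frame translation of all coordinates changes nothing
  tr <- gen_brownian_traj(5, n_particles = 32, n_steps = 200, seed = 4)
  shift <- cumsum(rnorm(length(tr$times)))
  tr2 <- planar_trajectory_set(tr$times, tr$x + shift, tr$y - 2 * shift, tr$leaflet)
  expect_equal(compute_msd(tr2)$msd, compute_msd(tr)$msd, tolerance = 1e-9)

  expect_error(planar_trajectory_set(0:9, matrix(1, 10, 2), matrix(1, 10, 2),
                                     c("upper", "middle")), "upper.*lower|leaflet")
})

test_that("the FFT all-origin MSD matches a brute-force double loop", {
  tr <- gen_brownian_traj(5, n_particles = 4, n_steps = 40, seed = 9)
  m_fft <- compute_msd(tr)
  # brute-force oracle on the drift-removed coordinates
  x <- tr$x; y <- tr$y
  for (lf in c("upper", "lower")) {
    idx <- tr$leaflet == lf
    x[, idx] <- x[, idx] - (rowMeans(x[, idx, drop = FALSE]) - mean(x[1, idx]))
    y[, idx] <- y[, idx] - (rowMeans(y[, idx, drop = FALSE]) - mean(y[1, idx]))
  }
  n <- nrow(x)
  oracle <- vapply(0:(n - 1), function(del) {
    o <- seq_len(n - del)
    mean((x[o + del, ] - x[o, ])^2 + (y[o + del, ] - y[o, ])^2)
  }, 0)
  expect_equal(m_fft$msd, oracle, tolerance = 1e-10)

  # strided origins agree with the brute force restricted to those origins
  m_str <- compute_msd(tr, origin_stride = 3)
  oracle3 <- vapply(0:(n - 1), function(del) {
    o <- seq(1, n - 1, by = 3); o <- o[o + del <= n]
    mean((x[o + del, ] - x[o, ])^2 + (y[o + del, ] - y[o, ])^2)
  }, 0)
  expect_equal(m_str$msd, oracle3, tolerance = 1e-10)
})

test_that("the linear MSD fit returns slope/4 regardless of intercept and window", {
  lag <- 0:200
  exact <- msd_curve(lag, 4 * 0.005 * lag)            # D = 5 um^2/s in nm^2/ns
  expect_equal(fit_msd_linear(exact)$d_pbc, 5)
  offs <- msd_curve(1:200, 4 * 0.005 * (1:200) + 2)   # nonzero intercept
  expect_equal(fit_msd_linear(offs)$d_pbc, 5)
  expect_equal(fit_msd_linear(offs)$intercept, 2)
  for (w in list(c(20, 60), c(5, 150), c(100, 200)))
    expect_equal(fit_msd_linear(exact, w)$d_pbc, 5)
  expect_error(fit_msd_linear(exact, c(10, 500)), "range error")
})

test_that("Brownian trajectories yield the generating diffusion coefficient", {
  d_true <- 5
  tr <- gen_brownian_traj(d_true, n_particles = 256, n_steps = 400, dt = 1, seed = 11)
  m <- compute_msd(tr, per_particle = TRUE)
  fit <- fit_msd_linear(m, window = c(10, 100))
  pp <- attr(m, "per_particle")
  d_i <- apply(pp, 2, function(v) fit_msd_linear(msd_curve(m$lag, pmax(v, 0)),
                                                 c(10, 100))$d_pbc)
  se <- sd(d_i) / sqrt(length(d_i))
  expect_lt(abs(fit$d_pbc - d_true), 3 * se + 1e-12)
})

test_that("Monte-Carlo error propagation is seeded, unbiased and noise-monotone", {
  geom <- test_geometry()
  s0 <- gen_finite_size_series(10, 80, geom, L_list = c(4.5, 9.2, 18.3))

  # zero input error: zero spread
  z <- finite_size_series(transform(s0$points, d_err = 0), geom)
  r0 <- mc_error_propagation(z, n = 50, seed = 5)
  expect_equal(r0$d_inf_err, 0)
  expect_true(all(r0$d_inf_samples == r0$d_inf_samples[1]))

  # determinism under a fixed seed
  e <- finite_size_series(transform(s0$points, d_err = 0.05 * d_pbc), geom)
  ra <- mc_error_propagation(e, n = 100, seed = 42)
  rb <- mc_error_propagation(e, n = 100, seed = 42)
  expect_identical(ra$d_inf_samples, rb$d_inf_samples)
  expect_identical(ra$mu_m_samples, rb$mu_m_samples)

  # spread grows with the input error scale
  spreads <- vapply(c(0.01, 0.03, 0.09), function(rel) {
    si <- finite_size_series(transform(s0$points, d_err = rel * d_pbc), geom)
    mc_error_propagation(si, n = 150, seed = 8)$d_inf_err
  }, 0)
  expect_true(all(diff(spreads) > 0))

  # missing errors are rejected
  no_err <- finite_size_series(s0$points[, c("L", "d_pbc")], geom)
  expect_error(mc_error_propagation(no_err, n = 10), "d_err")
})
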