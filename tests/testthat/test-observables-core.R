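test_that("whitespace order parameter tables map rows to entries", {
  f <- write_lines_tmp(c("# chain carbon hydrogen value error",
                         "palmitate 5 1 -0.21 0.02",
                         "oleate 2 1 -0.05",
                         "headgroup-glycerol 1 2 0.04 0.01"))
  ops <- read_order_parameters(f, chol_frac = 0.2)
  expect_s3_class(ops, "order_parameter_set")
  expect_equal(ops$chol_frac, 0.2)
  expect_equal(nrow(ops$entries), 3L)
  r <- ops$entries[ops$entries$chain == "palmitate", ]
  expect_equal(c(r$carbon, r$hydrogen, r$s_ch, r$err), c(5, 1, -0.21, 0.02))
  expect_true(is.na(ops$entries$err[ops$entries$chain == "oleate"]))
})

test_that("csv dialect and empty/malformed/duplicate inputs behave as specified", {
  fcsv <- write_lines_tmp(c("chain,carbon,hydrogen,value,error",
                            "palmitate,5,1,-0.21,0.02"), ext = ".csv")
  expect_equal(read_order_parameters(fcsv)$entries$s_ch, -0.21)

  fempty <- write_lines_tmp("# nothing here")
  expect_warning(ops <- read_order_parameters(fempty), "empty")
  expect_equal(nrow(ops$entries), 0L)

  fbad <- write_lines_tmp(c("palmitate 5 1 -0.21", "oleate 3 oops"))
  expect_error(read_order_parameters(fbad), "line 2")

  fdup <- write_lines_tmp(c("palmitate 5 1 -0.21", "palmitate 5 1 -0.22"))
  expect_error(read_order_parameters(fdup), "duplicate")

  fnan <- write_lines_tmp("palmitate 5 1 NaN")
  expect_error(read_order_parameters(fnan))
  finf <- write_lines_tmp("palmitate 5 1 Inf")
  expect_error(read_order_parameters(finf))
})

test_that("container validators enforce the domain invariants", {
  expect_error(order_parameter_set(0, data.frame(
    chain = "palmitate", carbon = 17, hydrogen = 1, s_ch = -0.1)), "\\[2, 16\\]")
  expect_error(order_parameter_set(0, data.frame(
    chain = "oleate", carbon = 19, hydrogen = 1, s_ch = -0.1)), "\\[2, 18\\]")
  expect_error(order_parameter_set(0, data.frame(
    chain = "palmitate", carbon = 5, hydrogen = 1, s_ch = -0.6)), "0.5")
  expect_error(density_profile(c(0, 1, 0.5), c(1, 1, 1), 333), "increasing")
  expect_error(density_profile(c(0, 1, 3), c(1, 1, 1), 333), "spacing")
  expect_error(msd_curve(c(0, 1), c(0.5, 1)), "0 at lag 0")
  expect_error(form_factor_curve(c(0.1, 0.2), c(1, -1)), ">= 0")
})

test_that("hydrogen averaging collapses CH2/CH3 groups, forks oleate C2, passes headgroup", {
  avg <- average_equivalent_hydrogens(make_small_ops())
  e <- avg$entries
  p5 <- e[e$chain == "palmitate" & e$carbon == 5, ]
  expect_equal(p5$s_ch, -0.19)                # arithmetic mean of -0.18, -0.20
  expect_equal(p5$err, 0.03)                  # mean of member errors, not /sqrt(n)
  expect_equal(e[e$chain == "palmitate" & e$carbon == 16, ]$s_ch, -0.08)
  o2 <- e[e$chain == "oleate" & e$carbon == 2, ]
  expect_equal(nrow(o2), 2L)                  # forked pair retained
  expect_true(all(o2$forked))
  expect_equal(o2$s_ch, c(-0.05, 0.02))       # ordered by decreasing magnitude
  hg <- e[e$chain == "headgroup-glycerol", ]
  expect_equal(hg$s_ch, 0.04)                 # untouched

  # idempotence and carbon preservation
  avg2 <- average_equivalent_hydrogens(avg)
  expect_equal(avg2$entries, avg$entries)
  carbons <- function(x) {
    u <- unique(x$entries[, c("chain", "carbon")])
    u <- u[order(u$chain, u$carbon), ]
    rownames(u) <- NULL
    u
  }
  expect_equal(carbons(avg), carbons(make_small_ops()))
})

test_that("oleate C2 with a wrong hydrogen count is rejected", {
  bad <- order_parameter_set(0, data.frame(
    chain = "oleate", carbon = c(2, 2, 2), hydrogen = 1:3, s_ch = c(-0.05, 0.02, 0.01)))
  expect_error(average_equivalent_hydrogens(bad), "exactly 2 hydrogens")
})

test_that("observable files round-trip to 1e-9 relative", {
  prof <- gen_sdp_density(z_grid = seq(-4, 4, by = 0.05))
  f <- tempfile(fileext = ".csv")
  write_density_profile(prof, f)
  back <- read_density_profile(f)
  expect_equal(back$rho, prof$rho, tolerance = 1e-9)
  expect_equal(back$z, prof$z, tolerance = 1e-9)
  expect_equal(back$solvent_rho, prof$solvent_rho, tolerance = 1e-9)

  ff <- form_factor(prof, q_grid = seq(0.01, 2, by = 0.01))
  f2 <- tempfile(fileext = ".csv")
  write_form_factor(ff, f2)
  back2 <- read_form_factor(f2)
  expect_equal(back2$f_abs, ff$f_abs, tolerance = 1e-9)

  m <- msd_curve(0:10, 4 * 0.005 * (0:10))
  f3 <- tempfile(fileext = ".xvg")
  write_msd_xvg(m, f3)
  back3 <- read_msd_xvg(f3)
  expect_equal(back3$msd, m$msd, tolerance = 1e-9)

  ops <- make_small_ops(0.11)
  f4 <- tempfile()
  write_order_parameters(ops, f4)
  back4 <- read_order_parameters(f4, chol_frac = 0.11)
  expect_equal(back4$entries$s_ch, ops$entries$s_ch, tolerance = 1e-9)
})

test_that("xvg comment lines are skipped and grids validated on read", {
  f <- write_lines_tmp(c("@ title \"msd\"", "# comment", "0 0", "10 0.5", "20 1.1"),
                       ext = ".xvg")
  m <- read_msd_xvg(f)
  expect_equal(m$lag, c(0, 10, 20))
  expect_equal(m$msd[2], 0.5)

  fbad <- write_lines_tmp(c("z_nm,rho_e_nm3", "1,300", "0,300", "-1,300"), ext = ".csv")
  expect_error(read_density_profile(fbad), "increasing")
})

test_that("membrane geometry derives H and cross-checks it", {
  g <- membrane_geometry(L = 4.4, L_z = 8.9, h = 3.9)
  expect_equal(g$H, 2.5)
  expect_equal(g$mu_f, 0.3228)
  expect_silent(membrane_geometry(L = 4.4, L_z = 8.9, h = 3.9, H = 2.5))
  expect_error(membrane_geometry(L = 4.4, L_z = 8.9, h = 3.9, H = 2.6), "disagrees")
  expect_error(membrane_geometry(L = 4.4, L_z = 3.9, h = 4.0), "positive")
})
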