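# shared helpers: small in-code fixtures

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# minimal order parameter set covering both chains and the headgroup
make_small_ops <- function(chol_frac = 0) {
  order_parameter_set(chol_frac, data.frame(
    chain = c("palmitate", "palmitate", "palmitate", "palmitate", "palmitate",
              "oleate", "oleate", "headgroup-glycerol"),
    carbon = c(5, 5, 16, 16, 16, 2, 2, 1),
    hydrogen = c(1, 2, 1, 2, 3, 1, 2, 1),
    s_ch = c(-0.18, -0.20, -0.08, -0.08, -0.08, -0.05, 0.02, 0.04),
    err = c(0.02, 0.04, NA, NA, NA, 0.01, 0.01, NA)))
}

# geometry used across the diffusion tests: h = 4 nm, H = 3 nm
test_geometry <- function() membrane_geometry(L = 10, L_z = 10, h = 4)

# surfaces for the two-carbon worked example: exp = (0.10, 0.30),
# sim = (0.12, 0.28), one column per concentration
two_carbon_surfaces <- function(chol = c(0, 10)) {
  exp_s <- surface_2d(1:2, chol, matrix(c(0.10, 0.30), 2, length(chol)))
  sim_s <- surface_2d(1:2, chol, matrix(c(0.12, 0.28), 2, length(chol)))
  list(sim = sim_s, exp = exp_s)
}
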