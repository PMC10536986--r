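# Domain types for membrane observables and their file dialects.

#' Order parameter set at one cholesterol mole fraction
#'
#' Container for C-H bond order parameters \eqn{S_{CH}} of one membrane
#' composition, indexed by acyl chain (or headgroup/glycerol region), carbon
#' and hydrogen.  Values are stored signed; \eqn{^{13}}C NMR magnitudes can
#' be compared via the `unsigned` flag of [op_surface()].
#'
#' @param chol_frac cholesterol mole fraction in \[0, 1\].
#' @param entries data frame with columns `chain` (one of `"palmitate"`,
#'   `"oleate"`, `"headgroup-glycerol"`), `carbon` (integer; palmitate 2-16,
#'   oleate 2-18), `hydrogen` (integer >= 1), `s_ch` (signed, |s| <= 0.5) and
#'   optionally `err` (>= 0, `NA` allowed).
#' @return An object of class `order_parameter_set`.
#' @seealso [read_order_parameters()], [average_equivalent_hydrogens()]
#' @export
order_parameter_set <- function(chol_frac, entries) {
  if (!is.numeric(chol_frac) || length(chol_frac) != 1L || !is.finite(chol_frac) ||
      chol_frac < 0 || chol_frac > 1)
    .stop_val("chol_frac must be a mole fraction in [0, 1]")
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  need <- c("chain", "carbon", "hydrogen", "s_ch")
  if (!all(need %in% names(entries)))
    .stop_val("entries must have columns %s", paste(need, collapse = ", "))
  if (!"err" %in% names(entries)) entries$err <- NA_real_
  if (nrow(entries) > 0L) {
    bad <- !entries$chain %in% .CHAINS
    if (any(bad))
      .stop_val("unknown chain label(s): %s", paste(unique(entries$chain[bad]), collapse = ", "))
    .check_finite(entries$carbon, "carbon")
    .check_finite(entries$hydrogen, "hydrogen")
    .check_finite(entries$s_ch, "s_ch")
    if (any(entries$carbon != round(entries$carbon)) || any(entries$hydrogen != round(entries$hydrogen)))
      .stop_val("carbon and hydrogen must be integers")
    pal <- entries$chain == "palmitate"
    if (any(entries$carbon[pal] < 2 | entries$carbon[pal] > 16))
      .stop_val("palmitate carbons must lie in [2, 16]")
    ole <- entries$chain == "oleate"
    if (any(entries$carbon[ole] < 2 | entries$carbon[ole] > 18))
      .stop_val("oleate carbons must lie in [2, 18]")
    if (any(abs(entries$s_ch) > 0.5))
      .stop_val("|s_ch| must not exceed 0.5")
    e <- entries$err[!is.na(entries$err)]
    if (length(e) && (any(!is.finite(e)) || any(e < 0)))
      .stop_val("err must be finite and >= 0")
    key <- paste(entries$chain, entries$carbon, entries$hydrogen)
    if (anyDuplicated(key))
      .stop_val("duplicate (chain, carbon, hydrogen) entries: %s",
                paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  structure(list(chol_frac = chol_frac, entries = entries),
            class = "order_parameter_set")
}

#' @export
print.order_parameter_set <- function(x, ...) {
  cat(sprintf("<order_parameter_set> %.1f mol%% CHOL, %d C-H bonds (%s)\n",
              100 * x$chol_frac, nrow(x$entries),
              paste(unique(x$entries$chain), collapse = ", ")))
  invisible(x)
}

#' Electron density profile along the membrane normal
#'
#' @param z length grid in nm, strictly increasing with constant spacing,
#'   symmetric about the bilayer center at z = 0.
#' @param rho electron density in e/nm^3, same length as `z`, >= 0.
#' @param solvent_rho bulk water electron density in e/nm^3.
#' @return An object of class `density_profile`.
#' @export
density_profile <- function(z, rho, solvent_rho) {
  .check_finite(z, "z"); .check_finite(rho, "rho")
  .check_finite(solvent_rho, "solvent_rho")
  if (length(z) != length(rho)) .stop_val("z and rho must have equal length")
  if (length(z) < 2L) .stop_val("profile needs at least 2 points")
  dz <- diff(z)
  if (any(dz <= 0)) .stop_val("z grid must be strictly increasing")
  if (max(dz) - min(dz) > 1e-6 * mean(dz))
    .stop_val("z grid spacing must be constant")
  if (any(rho < 0)) .stop_val("electron density must be >= 0")
  structure(list(z = as.numeric(z), rho = as.numeric(rho),
                 solvent_rho = as.numeric(solvent_rho)),
            class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("<density_profile> %d points, z in [%.3f, %.3f] nm, solvent %.1f e/nm^3\n",
              length(x$z), min(x$z), max(x$z), x$solvent_rho))
  invisible(x)
}

#' X-ray form factor magnitude curve
#'
#' @param q wave vector grid in nm^-1, strictly increasing, >= 0.
#' @param f_abs |F(q)| in e/nm^2, >= 0.
#' @return An object of class `form_factor_curve`.
#' @export
form_factor_curve <- function(q, f_abs) {
  .check_finite(q, "q"); .check_finite(f_abs, "f_abs")
  if (length(q) != length(f_abs)) .stop_val("q and f_abs must have equal length")
  if (any(diff(q) <= 0)) .stop_val("q grid must be strictly increasing")
  if (any(q < 0)) .stop_val("q must be >= 0")
  if (any(f_abs < 0)) .stop_val("f_abs must be >= 0")
  structure(list(q = as.numeric(q), f_abs = as.numeric(f_abs)),
            class = "form_factor_curve")
}

#' Mean squared displacement curve
#'
#' @param lag lag times in ns, increasing, >= 0.
#' @param msd mean squared displacement in nm^2, >= 0; must be 0 at lag 0.
#' @return An object of class `msd_curve`.
#' @export
msd_curve <- function(lag, msd) {
  .check_finite(lag, "lag"); .check_finite(msd, "msd")
  if (length(lag) != length(msd)) .stop_val("lag and msd must have equal length")
  if (any(diff(lag) <= 0)) .stop_val("lag grid must be strictly increasing")
  if (any(lag < 0)) .stop_val("lag must be >= 0")
  if (any(msd < 0)) .stop_val("msd must be >= 0")
  if (lag[1] == 0 && abs(msd[1]) > 1e-12 * max(1, max(msd)))
    .stop_val("msd must be 0 at lag 0")
  structure(list(lag = as.numeric(lag), msd = as.numeric(msd)), class = "msd_curve")
}

#' Simulation box geometry entering the finite-size diffusion model
#'
#' `H`, half the thickness of the water layer, is derived as
#' `(L_z - h) / 2`; passing it explicitly only cross-checks consistency.
#'
#' @param L box edge in the membrane plane, nm.
#' @param L_z box dimension normal to the membrane, nm.
#' @param h hydrodynamic membrane thickness, nm (from the electron density
#'   maxima, see [bilayer_thickness()]).
#' @param T temperature, K.
#' @param mu_f water shear viscosity, mPa s (default 0.3228, the TIP3P value
#'   interpolated to 298 K).
#' @param H optional explicit half water-layer thickness, nm; must agree
#'   with `(L_z - h)/2` within 1e-9.
#' @return An object of class `membrane_geometry`.
#' @export
membrane_geometry <- function(L, L_z, h, T = 298, mu_f = .MU_F_DEFAULT, H = NULL) {
  for (v in list(L = L, L_z = L_z, h = h, T = T, mu_f = mu_f))
    .check_finite(v, "geometry field")
  H_calc <- (L_z - h) / 2
  if (!is.null(H)) {
    .check_finite(H, "H")
    if (abs(H - H_calc) > 1e-9)
      .stop_val("H = %.6g disagrees with (L_z - h)/2 = %.6g", H, H_calc)
  }
  if (any(c(L, L_z, h, H_calc, T, mu_f) <= 0))
    .stop_val("all geometry fields (L, L_z, h, H, T, mu_f) must be positive")
  structure(list(L = L, L_z = L_z, h = h, H = H_calc, T = T, mu_f = mu_f),
            class = "membrane_geometry")
}

#' Lateral diffusion coefficients at several box sizes
#'
#' @param points data frame with columns `L` (nm), `d_pbc` (um^2/s) and
#'   optionally `d_err` (um^2/s).  At least 2 distinct `L` values.
#' @param geom a [membrane_geometry()]; `h` and `H` are the averages over
#'   the system sizes.
#' @return An object of class `finite_size_series`.
#' @export
finite_size_series <- function(points, geom) {
  points <- as.data.frame(points)
  if (!all(c("L", "d_pbc") %in% names(points)))
    .stop_val("points must have columns L and d_pbc")
  if (!"d_err" %in% names(points)) points$d_err <- NA_real_
  .check_finite(points$L, "L"); .check_finite(points$d_pbc, "d_pbc")
  if (length(unique(points$L)) < 2L)
    .stop_val("need at least 2 distinct box sizes L for fitting")
  if (any(points$d_pbc <= 0)) .stop_val("d_pbc must be positive")
  e <- points$d_err[!is.na(points$d_err)]
  if (length(e) && (any(!is.finite(e)) || any(e < 0)))
    .stop_val("d_err must be finite and >= 0")
  if (!inherits(geom, "membrane_geometry")) .stop_val("geom must be a membrane_geometry")
  structure(list(points = points[order(points$L), , drop = FALSE], geom = geom),
            class = "finite_size_series")
}

# result container; l_sd derived from (mu_m, h, mu_f) so the identity
# l_sd = mu_m h / (2 mu_f) holds by construction
pbc_fit_result <- function(d_inf, mu_m, h, mu_f, d_inf_err = NA_real_,
                           mu_m_samples = NULL, d_inf_samples = NULL,
                           degenerate = FALSE, correction_frac = NA_real_,
                           rss = NA_real_) {
  if (!is.finite(d_inf) || d_inf <= 0) .stop_val("fitted d_inf must be positive")
  if (!is.finite(mu_m) || mu_m <= 0) .stop_val("fitted mu_m must be positive")
  structure(list(d_inf = d_inf, mu_m = mu_m,
                 l_sd = saffman_delbrueck_length(mu_m, h, mu_f),
                 d_inf_err = d_inf_err, mu_m_samples = mu_m_samples,
                 d_inf_samples = d_inf_samples, degenerate = degenerate,
                 correction_frac = correction_frac, rss = rss),
            class = "pbc_fit_result")
}

#' @export
print.pbc_fit_result <- function(x, ...) {
  cat(sprintf("<pbc_fit_result> D_inf = %.4g um^2/s%s, mu_m = %.4g mPa s, L_SD = %.4g nm\n",
              x$d_inf,
              if (is.finite(x$d_inf_err)) sprintf(" (+/- %.2g)", x$d_inf_err) else "",
              x$mu_m, x$l_sd))
  if (isTRUE(x$degenerate))
    cat("  degenerate: correction term ~ 0, mu_m unidentifiable\n")
  invisible(x)
}

#' In-plane trajectories of lipid centers of mass
#'
#' @param times uniform time grid in ns.
#' @param x,y matrices of unwrapped coordinates in nm, one row per frame,
#'   one column per particle.
#' @param leaflet character vector, one of `"upper"`/`"lower"` per particle.
#' @return An object of class `planar_trajectory_set`.
#' @export
planar_trajectory_set <- function(times, x, y, leaflet) {
  .check_finite(times, "times")
  x <- as.matrix(x); y <- as.matrix(y)
  .check_finite(x, "x"); .check_finite(y, "y")
  if (length(times) < 2L) .stop_val("need at least 2 frames")
  dt <- diff(times)
  if (any(dt <= 0) || max(dt) - min(dt) > 1e-6 * mean(dt))
    .stop_val("times must be a uniform increasing grid")
  if (!all(dim(x) == dim(y)) || nrow(x) != length(times))
    .stop_val("x and y must be frames x particles matrices matching times")
  if (length(leaflet) != ncol(x))
    .stop_val("leaflet must label every particle")
  if (any(!leaflet %in% c("upper", "lower")))
    .stop_val("unlabeled particles: leaflet must be 'upper' or 'lower'")
  structure(list(times = as.numeric(times), x = x, y = y,
                 leaflet = as.character(leaflet)),
            class = "planar_trajectory_set")
}

# ---------------------------------------------------------------------------
# readers / writers

.read_table_lines <- function(path, comment_chars = "#") {
  if (!file.exists(path)) .stop_val("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl(paste0("^\\s*([", comment_chars, "]|$)"), lines)
  list(lines = lines[keep], lineno = which(keep))
}

.parse_numeric <- function(tok, path, lineno) {
  v <- suppressWarnings(as.numeric(tok))
  if (anyNA(v) || any(!is.finite(v)))
    .stop_val("parse error in %s at line %d: non-finite or non-numeric value", path, lineno)
  v
}

#' Read a C-H order parameter table
#'
#' Whitespace dialect: one row per C-H bond,
#' `chain carbon hydrogen value [error]`, `#` comments ignored.  CSV dialect:
#' header `chain,carbon,hydrogen,value,error`.
#'
#' @param path file to read.
#' @param chol_frac cholesterol mole fraction of the data set.
#' @param dialect `"auto"` (by extension), `"table"` or `"csv"`.
#' @return An [order_parameter_set()].
#' @export
read_order_parameters <- function(path, chol_frac = 0,
                                  dialect = c("auto", "table", "csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "table"
  tl <- .read_table_lines(path)
  if (length(tl$lines) == 0L ||
      (dialect == "csv" && length(tl$lines) == 1L)) {
    warning(sprintf("empty order parameter file: %s", path), call. = FALSE)
    return(order_parameter_set(chol_frac, data.frame(
      chain = character(), carbon = integer(), hydrogen = integer(),
      s_ch = numeric(), err = numeric())))
  }
  if (dialect == "csv") {
    df <- utils::read.csv(text = tl$lines, stringsAsFactors = FALSE)
    if (!all(c("chain", "carbon", "hydrogen", "value") %in% names(df)))
      .stop_val("csv order parameter file %s needs header chain,carbon,hydrogen,value[,error]", path)
    entries <- data.frame(chain = df$chain, carbon = df$carbon,
                          hydrogen = df$hydrogen, s_ch = df$value,
                          err = if ("error" %in% names(df)) df$error else NA_real_)
  } else {
    rows <- lapply(seq_along(tl$lines), function(i) {
      tok <- strsplit(trimws(tl$lines[i]), "\\s+")[[1]]
      if (length(tok) < 4L || length(tok) > 5L)
        .stop_val("parse error in %s at line %d: expected 'chain carbon hydrogen value [error]'",
                  path, tl$lineno[i])
      num <- .parse_numeric(tok[2:length(tok)], path, tl$lineno[i])
      data.frame(chain = tok[1], carbon = num[1], hydrogen = num[2],
                 s_ch = num[3], err = if (length(num) >= 4) num[4] else NA_real_)
    })
    entries <- do.call(rbind, rows)
  }
  order_parameter_set(chol_frac, entries)
}

#' @rdname read_order_parameters
#' @param ops an [order_parameter_set()] to write (whitespace dialect).
#' @export
write_order_parameters <- function(ops, path) {
  stopifnot(inherits(ops, "order_parameter_set"))
  e <- ops$entries
  lines <- c(sprintf("# chain carbon hydrogen s_ch err (chol_frac %.6g)", ops$chol_frac),
             sprintf("%s %d %d %.15g %s", e$chain, as.integer(e$carbon),
                     as.integer(e$hydrogen), e$s_ch,
                     ifelse(is.na(e$err), "", sprintf("%.15g", e$err))))
  writeLines(trimws(lines, which = "right"), path)
  invisible(path)
}

#' Average order parameters of equivalent hydrogens
#'
#' The 2 (3) hydrogens of CH2 (CH3) groups in the acyl chains rotate freely,
#' so their order parameters are averaged into a single value per carbon.
#' The two hydrogens of the oleate C2 carbon lack rotational averaging and
#' are retained separately ("forked"), ordered by decreasing magnitude.
#' Headgroup/glycerol entries pass through unaveraged.  The error of an
#' averaged group is the mean of the member errors (the hydrogens are not
#' independent measurements).
#'
#' The operation is idempotent and never changes the set of carbons.
#'
#' @param ops an [order_parameter_set()].
#' @return An [order_parameter_set()] with one entry per acyl-chain carbon
#'   (two for oleate C2, carrying a logical `forked` column).
#' @export
average_equivalent_hydrogens <- function(ops) {
  stopifnot(inherits(ops, "order_parameter_set"))
  e <- ops$entries
  if (nrow(e) == 0L) return(ops)
  fork <- e$chain == "oleate" & e$carbon == 2
  if (any(fork) && sum(fork) != 2L)
    .stop_val("oleate C2 must carry exactly 2 hydrogens (found %d)", sum(fork))
  keep <- e[e$chain == "headgroup-glycerol" | fork, , drop = FALSE]
  if (nrow(keep)) keep$forked <- fork[e$chain == "headgroup-glycerol" | fork]
  if (any(fork)) {
    i <- which(keep$forked)
    ord <- order(-abs(keep$s_ch[i]))
    keep[i, ] <- keep[i[ord], ]
    keep$hydrogen[i] <- seq_along(i)
  }
  acyl <- e[e$chain %in% c("palmitate", "oleate") & !fork, , drop = FALSE]
  if (nrow(acyl)) {
    g <- interaction(acyl$chain, acyl$carbon, drop = TRUE)
    avg <- do.call(rbind, lapply(split(acyl, g), function(d) {
      data.frame(chain = d$chain[1], carbon = d$carbon[1], hydrogen = 1L,
                 s_ch = mean(d$s_ch),
                 err = if (all(is.na(d$err))) NA_real_ else mean(d$err, na.rm = TRUE),
                 forked = FALSE)
    }))
  } else avg <- NULL
  out <- rbind(keep, avg)
  out <- out[order(out$chain, out$carbon, out$hydrogen), , drop = FALSE]
  rownames(out) <- NULL
  order_parameter_set(ops$chol_frac, out)
}

#' Read and write two-column observable files
#'
#' `read_density_profile()` and `read_form_factor()` expect CSV with columns
#' `z_nm,rho_e_nm3` resp. `q_invnm,absF` (`#` comments ignored);
#' `read_msd_xvg()` reads the xvg dialect (two numeric columns, lines
#' starting with `#` or `@` skipped).  Writers round-trip to better than
#' 1e-9 relative.
#'
#' @param path file path.
#' @param solvent_rho bulk water electron density, e/nm^3; if `NULL`,
#'   estimated as the mean density over the outer 5 percent of each tail of
#'   the z range.
#' @return The corresponding observable object.
#' @export
read_density_profile <- function(path, solvent_rho = NULL) {
  m <- .read_two_columns(path, comment_chars = "#@")
  if (is.null(solvent_rho)) {
    # a "# solvent_rho <value>" comment (written by write_density_profile)
    # takes precedence over the edge estimate
    hdr <- grep("^#\\s*solvent_rho\\s", readLines(path, warn = FALSE), value = TRUE)
    if (length(hdr))
      solvent_rho <- suppressWarnings(as.numeric(strsplit(trimws(hdr[1]), "\\s+")[[1]][3]))
  }
  if (is.null(solvent_rho) || is.na(solvent_rho)) {
    zr <- range(m[, 1]); w <- 0.05 * diff(zr)
    edge <- m[, 1] <= zr[1] + w | m[, 1] >= zr[2] - w
    solvent_rho <- mean(m[edge, 2])
  }
  density_profile(m[, 1], m[, 2], solvent_rho)
}

.read_two_columns <- function(path, comment_chars = "#@") {
  tl <- .read_table_lines(path, comment_chars)
  if (length(tl$lines) == 0L) .stop_val("no data rows in %s", path)
  first <- strsplit(trimws(tl$lines[1]), "[,[:space:]]+")[[1]]
  header <- suppressWarnings(anyNA(as.numeric(first)))
  if (header) { tl$lines <- tl$lines[-1]; tl$lineno <- tl$lineno[-1] }
  if (length(tl$lines) == 0L) .stop_val("no data rows in %s", path)
  rows <- lapply(seq_along(tl$lines), function(i) {
    tok <- strsplit(trimws(tl$lines[i]), "[,[:space:]]+")[[1]]
    if (length(tok) < 2L)
      .stop_val("parse error in %s at line %d: expected 2 columns", path, tl$lineno[i])
    .parse_numeric(tok[1:2], path, tl$lineno[i])
  })
  do.call(rbind, rows)
}

#' @rdname read_density_profile
#' @export
read_form_factor <- function(path) {
  m <- .read_two_columns(path)
  form_factor_curve(m[, 1], m[, 2])
}

#' @rdname read_density_profile
#' @export
read_msd_xvg <- function(path) {
  m <- .read_two_columns(path, comment_chars = "#@")
  msd_curve(m[, 1], m[, 2])
}

#' @rdname read_density_profile
#' @param profile a [density_profile()] to write.
#' @export
write_density_profile <- function(profile, path) {
  stopifnot(inherits(profile, "density_profile"))
  writeLines(c(sprintf("# solvent_rho %.15g e/nm^3", profile$solvent_rho),
               "z_nm,rho_e_nm3",
               sprintf("%.15g,%.15g", profile$z, profile$rho)), path)
  invisible(path)
}

#' @rdname read_density_profile
#' @param ff a [form_factor_curve()] to write.
#' @export
write_form_factor <- function(ff, path) {
  stopifnot(inherits(ff, "form_factor_curve"))
  writeLines(c("q_invnm,absF", sprintf("%.15g,%.15g", ff$q, ff$f_abs)), path)
  invisible(path)
}

#' @rdname read_density_profile
#' @param msd an [msd_curve()] to write.
#' @export
write_msd_xvg <- function(msd, path) {
  stopifnot(inherits(msd, "msd_curve"))
  writeLines(c("@ title \"Mean squared displacement\"",
               "@ xaxis label \"lag (ns)\"", "@ yaxis label \"MSD (nm^2)\"",
               sprintf("%.15g %.15g", msd$lag, msd$msd)), path)
  invisible(path)
}
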