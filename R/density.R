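#' Construct a density grid
#'
#' A regular isotropic 3-D grid of density values. Grid node `(i, j, k)`
#' (1-based) sits at `origin + (i-1, j-1, k-1) * spacing` in orthogonal
#' angstrom space. Two grids are compatible when origin, spacing and
#' dimensions agree.
#'
#' @param origin Numeric length-3, angstroms.
#' @param spacing Grid step in angstroms, positive.
#' @param dims Integer length-3, positive.
#' @param values Array of dimension `dims`; defaults to zeros.
#' @return An object of class `density_grid`.
#' @export
density_grid <- function(origin, spacing, dims, values = NULL) {
  stopifnot(length(origin) == 3, length(dims) == 3, spacing > 0,
            all(dims >= 1))
  dims <- as.integer(dims)
  if (is.null(values)) values <- array(0, dim = dims)
  stopifnot(all(dim(values) == dims))
  if (!all(is.finite(values))) stop("non-finite density values")
  structure(list(origin = as.numeric(origin), spacing = as.numeric(spacing),
                 dims = dims, values = values),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("Density grid %d x %d x %d, spacing %.3f A, origin (%.2f, %.2f, %.2f)\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing,
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  values in [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

grids_compatible <- function(a, b) {
  isTRUE(all.equal(a$origin, b$origin)) &&
    isTRUE(all.equal(a$spacing, b$spacing)) && all(a$dims == b$dims)
}

check_compatible <- function(a, b) {
  if (!grids_compatible(a, b)) stop("incompatible density grids")
}

grid_axis <- function(g, k) g$origin[k] + (seq_len(g$dims[k]) - 1) * g$spacing

#' Grid geometry covering a set of atoms
#'
#' @param atoms Atom table.
#' @param spacing Grid step in angstroms (default 0.5).
#' @param margin Padding beyond the atom bounding box in angstroms
#'   (default 3, matching the coverage expected by [calc_model_map()]).
#' @return A zero-valued [density_grid()].
#' @export
grid_for_atoms <- function(atoms, spacing = 0.5, margin = 3) {
  stopifnot(nrow(atoms) > 0)
  lo <- c(min(atoms$x), min(atoms$y), min(atoms$z)) - margin
  hi <- c(max(atoms$x), max(atoms$y), max(atoms$z)) + margin
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  density_grid(lo, spacing, dims)
}

## Arithmetic between compatible grids.
grid_sub <- function(a, b) {
  check_compatible(a, b)
  density_grid(a$origin, a$spacing, a$dims, a$values - b$values)
}

grid_add <- function(a, b) {
  check_compatible(a, b)
  density_grid(a$origin, a$spacing, a$dims, a$values + b$values)
}

#' Synthesize a model density map
#'
#' Each atom contributes a single isotropic Gaussian
#' \deqn{\rho_i(r) = occ_i Z_i (2\pi(u^2+w^2))^{-3/2}
#'       \exp(-|r-r_i|^2 / (2(u^2+w^2)))}
#' with \eqn{u^2 = B_i/(8\pi^2)} and a fixed softening width `w`
#' (default 0.5 angstroms) added in quadrature. The total mass of each
#' contribution is `occ * Z` and the map is linear in occupancy. This is a
#' real-space stand-in for structure-factor based map synthesis; no Fourier
#' round trip is performed.
#'
#' @param atoms Atom table.
#' @param grid A [density_grid()] giving the geometry (values ignored).
#' @param omit Optional integer row indices of `atoms` to omit.
#' @param w Softening width in angstroms.
#' @param cutoff_sigmas Gaussian truncation radius in standard deviations.
#' @return A [density_grid()] with the summed density.
#' @export
calc_model_map <- function(atoms, grid, omit = NULL, w = 0.5,
                           cutoff_sigmas = 6) {
  vals <- array(0, dim = grid$dims)
  if (!is.null(omit) && length(omit) > 0)
    atoms <- atoms[-omit, , drop = FALSE]
  if (nrow(atoms) == 0)
    return(density_grid(grid$origin, grid$spacing, grid$dims, vals))

  lo <- grid$origin
  hi <- grid$origin + (grid$dims - 1) * grid$spacing
  mg <- 3 - 0.01   # tolerance absorbs coordinate rounding in file formats
  if (any(atoms$x < lo[1] + mg | atoms$x > hi[1] - mg |
            atoms$y < lo[2] + mg | atoms$y > hi[2] - mg |
            atoms$z < lo[3] + mg | atoms$z > hi[3] - mg))
    warning("grid does not cover all atoms with a 3 A margin")

  ax <- grid_axis(grid, 1); ay <- grid_axis(grid, 2); az <- grid_axis(grid, 3)
  zz <- atomic_number(atoms$element)
  for (i in seq_len(nrow(atoms))) {
    s2 <- atoms$b[i] / (8 * pi^2) + w^2
    amp <- atoms$occ[i] * zz[i] * (2 * pi * s2)^(-1.5)
    if (amp == 0) next
    rcut <- cutoff_sigmas * sqrt(s2)
    ix <- which(abs(ax - atoms$x[i]) <= rcut)
    iy <- which(abs(ay - atoms$y[i]) <= rcut)
    iz <- which(abs(az - atoms$z[i]) <= rcut)
    if (!length(ix) || !length(iy) || !length(iz)) next
    gx <- exp(-(ax[ix] - atoms$x[i])^2 / (2 * s2))
    gy <- exp(-(ay[iy] - atoms$y[i])^2 / (2 * s2))
    gz <- exp(-(az[iz] - atoms$z[i])^2 / (2 * s2))
    vals[ix, iy, iz] <- vals[ix, iy, iz] +
      amp * (gx %o% gy %o% gz)
  }
  density_grid(grid$origin, grid$spacing, grid$dims, vals)
}

#' Masking parameters
#'
#' Atomic mask radii follow a REFMAC-like form `r0(element) +
#' c_b * sqrt(B / (8 pi^2))`: a base radius per element inflated with the
#' atomic displacement. `neighbour_radius_inflation` is added to
#' environment-atom radii when excluding neighbour-contaminated points.
#'
#' @param r0 Named numeric vector of base radii per element, angstroms.
#' @param c_b Dimensionless B-scaling coefficient.
#' @param neighbour_radius_inflation Angstroms.
#' @return A list of class `mask_spec`.
#' @export
mask_spec <- function(r0 = c(C = 1.7, N = 1.6, O = 1.5, S = 1.8, P = 1.8),
                      c_b = 3.0, neighbour_radius_inflation = 0) {
  stopifnot(all(r0 > 0), c_b >= 0, neighbour_radius_inflation >= 0)
  structure(list(r0 = r0, c_b = c_b,
                 neighbour_radius_inflation = neighbour_radius_inflation),
            class = "mask_spec")
}

#' Atomic mask radius
#'
#' @param element Element symbol(s).
#' @param b B-factor(s), non-negative, squared angstroms.
#' @param spec A [mask_spec()].
#' @return Radius in angstroms; strictly increasing in `b`.
#' @export
mask_radius <- function(element, b, spec = mask_spec()) {
  stopifnot(all(b >= 0))
  r0 <- spec$r0[toupper(element)]
  if (anyNA(r0)) {
    warning("no base mask radius for element(s): ",
            paste(unique(element[is.na(r0)]), collapse = ", "),
            "; using 1.7 A")
    r0[is.na(r0)] <- 1.7
  }
  unname(r0 + spec$c_b * sqrt(b / (8 * pi^2)))
}

#' Grid points attributed to the ligand
#'
#' Returns the (sorted, linear, 1-based) indices of grid nodes lying within
#' the mask radius of at least one ligand atom and outside the inflated
#' mask radius of every environment atom — the correlation region with
#' neighbour density contributions masked out.
#'
#' @param grid A [density_grid()].
#' @param lig_atoms,env_atoms Atom tables.
#' @param spec A [mask_spec()].
#' @return Integer vector of linear grid indices.
#' @export
ligand_grid_points <- function(grid, lig_atoms, env_atoms,
                               spec = mask_spec()) {
  stopifnot(nrow(lig_atoms) > 0)
  inside <- array(FALSE, dim = grid$dims)
  ax <- grid_axis(grid, 1); ay <- grid_axis(grid, 2); az <- grid_axis(grid, 3)

  mark <- function(acc, atoms, radii, value) {
    for (i in seq_len(nrow(atoms))) {
      r <- radii[i]
      ix <- which(abs(ax - atoms$x[i]) <= r)
      iy <- which(abs(ay - atoms$y[i]) <= r)
      iz <- which(abs(az - atoms$z[i]) <= r)
      if (!length(ix) || !length(iy) || !length(iz)) next
      dx2 <- (ax[ix] - atoms$x[i])^2
      dy2 <- (ay[iy] - atoms$y[i])^2
      dz2 <- (az[iz] - atoms$z[i])^2
      d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
      sub <- acc[ix, iy, iz, drop = FALSE]
      acc[ix, iy, iz] <- sub | (d2 <= r * r)
    }
    acc
  }

  lr <- mask_radius(lig_atoms$element, lig_atoms$b, spec)
  inside <- mark(inside, lig_atoms, lr, TRUE)
  if (nrow(env_atoms) > 0) {
    er <- mask_radius(env_atoms$element, env_atoms$b, spec) +
      spec$neighbour_radius_inflation
    excl <- array(FALSE, dim = grid$dims)
    excl <- mark(excl, env_atoms, er, TRUE)
    inside <- inside & !excl
  }
  pts <- which(inside)
  if (length(pts) == 0) stop("ligand fully masked by environment")
  pts
}

#' Real-space correlation over selected grid points
#'
#' Pearson correlation of two compatible density grids restricted to a set
#' of grid points.
#'
#' @param a,b Compatible [density_grid()] objects.
#' @param points Linear grid indices, at least 2.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
map_correlation <- function(a, b, points) {
  check_compatible(a, b)
  if (length(points) < 2) stop("need at least 2 grid points")
  va <- a$values[points]
  vb <- b$values[points]
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop("undefined correlation: zero variance over the selected points")
  stats::cor(va, vb)
}

#' Difference-map correlation
#'
#' Correlation of the residual (observed minus full-model) density with the
#' ligand-only model density over the ligand points. Negative values
#' indicate excess modelled density at the ligand, e.g. an over-estimated
#' occupancy; positive values indicate unmodelled density.
#'
#' @param diff Difference density grid (observed - full model).
#' @param model_lig Ligand-only model density grid.
#' @param points Linear grid indices.
#' @return Correlation coefficient.
#' @export
diff_map_correlation <- function(diff, model_lig, points) {
  map_correlation(diff, model_lig, points)
}

#' Q-Q data for difference-map residuals
#'
#' Compares the distribution of difference-map values in the context of a
#' residue with a standard normal: the observed values are standardized by
#' their own mean and standard deviation, and quantiles are taken at
#' plotting positions `(i - 0.5) / n`. Departures from the diagonal flag
#' residuals that are not plain noise.
#'
#' @param diff Difference density grid.
#' @param points Linear grid indices.
#' @param n_quantiles Number of quantiles, `2 <= n_quantiles <= length(points)`.
#' @return A list of class `qq_data` with `theoretical`, `observed`, `n`.
#' @export
qq_data <- function(diff, points, n_quantiles = min(200L, length(points))) {
  stopifnot(n_quantiles >= 2, length(points) >= n_quantiles)
  v <- diff$values[points]
  s <- stats::sd(v)
  if (s == 0) stop("zero variance: Q-Q data undefined for constant residuals")
  std <- (v - mean(v)) / s
  probs <- (seq_len(n_quantiles) - 0.5) / n_quantiles
  structure(list(theoretical = stats::qnorm(probs),
                 observed = unname(stats::quantile(std, probs, names = FALSE)),
                 n = as.integer(n_quantiles)),
            class = "qq_data")
}

#' @export
plot.qq_data <- function(x, ...) {
  plot(x$theoretical, x$observed,
       xlab = "theoretical normal quantile",
       ylab = "observed standardized quantile", ...)
  abline(0, 1, lty = 2)
  invisible(x)
}

#' Build a reflection set
#'
#' @param f Amplitudes.
#' @param sig_f Standard deviations of the amplitudes (non-negative for
#'   observed records).
#' @param observed Logical; `FALSE` marks a missing reflection.
#' @param d_min Nominal resolution in angstroms.
#' @return A list of class `reflection_set`.
#' @export
reflection_set <- function(f, sig_f, observed = TRUE, d_min) {
  n <- length(f)
  observed <- rep_len(observed, n)
  sig_f <- rep_len(sig_f, n)
  if (any(observed & (is.na(sig_f) | sig_f < 0)))
    stop("observed reflections need sig_f >= 0")
  structure(list(f = as.numeric(f), sig_f = as.numeric(sig_f),
                 observed = observed, d_min = as.numeric(d_min)),
            class = "reflection_set")
}

#' Read a reflection set from CSV
#'
#' Columns `h,k,l,f,sig_f,observed`; `d_min` from the `d_min` column if
#' present, else supplied.
#'
#' @param path CSV path.
#' @param d_min Nominal resolution, used when the file has no `d_min` column.
#' @return A [reflection_set()].
#' @export
read_reflections_csv <- function(path, d_min = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(d_min)) {
    if (is.null(df$d_min)) stop("no d_min column and none supplied")
    d_min <- df$d_min[1]
  }
  reflection_set(df$f, df$sig_f, as.logical(df$observed), d_min)
}

#' Effective resolution
#'
#' The nominal resolution can overstate data quality when reflections are
#' missing or weak. The effective resolution inflates it for incompleteness
#' and amplitude error:
#' \deqn{N_{eff} = \sum_{obs} F^2 / (F^2 + \sigma(F)^2), \quad
#'       R_{eff} = d_{min} (N_{total}/N_{eff})^{1/3}.}
#' With complete, error-free data this reduces to the nominal resolution;
#' it never falls below it.
#'
#' @param refl A [reflection_set()].
#' @return Effective resolution in angstroms.
#' @export
effective_resolution <- function(refl) {
  if (!any(refl$observed)) stop("no observed reflections")
  f <- refl$f[refl$observed]
  s <- refl$sig_f[refl$observed]
  n_eff <- sum(f^2 / (f^2 + s^2))
  if (n_eff == 0) stop("effective reflection count is zero")
  refl$d_min * (length(refl$f) / n_eff)^(1 / 3)
}

#' Occupancy scan
#'
#' The ligand's occupancy is swept over a grid (default 0 to 1 in steps of
#' 0.05) without re-refinement; at each trial occupancy the full-model and
#' difference maps are recomputed and the direct-map and difference-map
#' correlations are evaluated over the masked ligand points. On data whose
#' true ligand occupancy is q*, the difference-map correlation changes sign
#' at q*: positive below (unmodelled density remains), negative above
#' (excess modelled density). Points where a correlation is undefined
#' (e.g. a zero difference map) are reported as `NA`.
#'
#' @param s An `lqc_structure`.
#' @param lig An `lqc_ligand`.
#' @param observed Observed density grid.
#' @param occupancies Trial occupancies in `[0, 1]`.
#' @param spec A [mask_spec()].
#' @param env_radius Environment radius (angstroms) for masking.
#' @param w Gaussian softening width passed to [calc_model_map()].
#' @return Data frame with columns `occ`, `cc_direct`, `cc_diff`.
#' @export
occupancy_scan <- function(s, lig, observed,
                           occupancies = seq(0, 1, by = 0.05),
                           spec = mask_spec(), env_radius = 6, w = 0.5) {
  stopifnot(all(occupancies >= 0 & occupancies <= 1))
  env <- neighbourhood(s, lig, env_radius)
  pts <- ligand_grid_points(observed, lig$atoms, env, spec)
  env_all_idx <- which(!(paste(s$atoms$chain, s$atoms$seq_id, s$atoms$name)
                         %in% paste(lig$atoms$chain, lig$atoms$seq_id,
                                    lig$atoms$name)))
  env_map <- calc_model_map(s$atoms[env_all_idx, , drop = FALSE], observed,
                            w = w)
  lig_ref <- lig$atoms
  lig_ref$occ <- 1
  lig_unit <- calc_model_map(lig_ref, observed, w = w)
  direct <- grid_sub(observed, env_map)

  ## residual variance below this fraction of the observed signal is
  ## treated as floating-point cancellation noise, not density
  noise_floor <- 1e-10 * max(stats::sd(observed$values[pts]), 1e-300)
  safe_cc <- function(a, b, p, floor = 0) {
    if (stats::sd(a$values[p]) <= floor) return(NA_real_)
    tryCatch(map_correlation(a, b, p), error = function(e) NA_real_)
  }
  res <- lapply(occupancies, function(q) {
    lig_q <- density_grid(lig_unit$origin, lig_unit$spacing, lig_unit$dims,
                          lig_unit$values * q)
    full <- grid_add(env_map, lig_q)
    diff <- grid_sub(observed, full)
    data.frame(occ = q,
               cc_direct = safe_cc(direct, lig_q, pts),
               cc_diff = safe_cc(diff, lig_unit, pts, noise_floor))
  })
  do.call(rbind, res)
}
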