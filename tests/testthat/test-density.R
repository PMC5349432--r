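test_that("model density is linear in occupancy and peaks at the atom", {
  g <- density_grid(c(-4, -4, -4), 0.5, c(17, 17, 17))
  at1 <- atom_table("C1", "C", 0, 0, 0, occ = 0.4, b = 20)
  at2 <- at1; at2$occ <- 0.8
  m1 <- calc_model_map(at1, g)
  m2 <- calc_model_map(at2, g)
  expect_equal(m2$values, 2 * m1$values)
  # atom sits on the grid node at index (9, 9, 9)
  expect_equal(which.max(m1$values),
               array(seq_len(17^3), dim = c(17, 17, 17))[9, 9, 9])
  # empty atom list -> all-zero grid
  expect_true(all(calc_model_map(empty_atom_table(), g)$values == 0))
})

test_that("the integrated Gaussian mass recovers occ * Z within 2%", {
  g <- density_grid(c(-6, -6, -6), 0.4, c(31, 31, 31))
  for (case in list(list(el = "C", occ = 1, b = 15),
                    list(el = "O", occ = 0.6, b = 40))) {
    at <- atom_table("A1", case$el, 0, 0, 0, occ = case$occ, b = case$b)
    m <- calc_model_map(at, g)
    mass <- sum(m$values) * g$spacing^3
    expect_equal(mass, case$occ * atomic_number(case$el),
                 tolerance = 0.02)
  }
})

test_that("mask radii follow the B-inflated closed form", {
  sp <- mask_spec()
  # zero-B limit is the bare element radius
  expect_equal(mask_radius("C", 0, sp), 1.7)
  expect_equal(mask_radius("O", 0, sp), 1.5)
  # direct arithmetic: r0 + c_b * sqrt(B / (8 pi^2))
  expect_equal(mask_radius("C", 30, sp), 1.7 + 3.0 * sqrt(30 / (8 * pi^2)))
  # doubling B adds c_b * (sqrt(2) - 1) * sqrt(B / (8 pi^2))
  inc <- mask_radius("C", 60, sp) - mask_radius("C", 30, sp)
  expect_equal(inc, 3.0 * (sqrt(2) - 1) * sqrt(30 / (8 * pi^2)))
  # strictly increasing in B; unknown element falls back with warning
  expect_true(mask_radius("N", 21, sp) > mask_radius("N", 20, sp))
  expect_warning(r <- mask_radius("Xq", 0, sp), "1.7")
  expect_equal(r, 1.7)
})

test_that("ligand grid points equal the brute-force double loop", {
  sp <- mask_spec()
  for (seed in 1:6) {
    tc <- toy_case(seed = seed, n_pocket = 5)
    lig <- toy_ligand(tc)
    env <- neighbourhood(tc$structure, lig, 5)
    g <- grid_for_atoms(lig$atoms, spacing = 0.8, margin = 2.5)
    got <- ligand_grid_points(g, lig$atoms, env, sp)
    expect_identical(got, ligand_points_oracle(g, lig$atoms, env, sp))
  }
  # no environment: every point inside the ligand radii is kept
  tc <- toy_case(seed = 9)
  lig <- toy_ligand(tc)
  g <- grid_for_atoms(lig$atoms, spacing = 0.8, margin = 2.5)
  no_env <- ligand_grid_points(g, lig$atoms, empty_atom_table(), sp)
  expect_identical(no_env,
                   ligand_points_oracle(g, lig$atoms, empty_atom_table(), sp))
  # an environment atom on top of a ligand atom with a huge inflation
  # swallows everything -> pathological-overlap error
  env1 <- lig$atoms[1, , drop = FALSE]
  sp_big <- mask_spec(neighbour_radius_inflation = 50)
  expect_error(ligand_grid_points(g, lig$atoms, env1, sp_big),
               "fully masked")
})

test_that("map correlation matches a hand Pearson and its invariances", {
  g <- density_grid(c(0, 0, 0), 1, c(5, 1, 1))
  a <- density_grid(g$origin, g$spacing, g$dims,
                    array(c(1.2, -0.3, 4.1, 0.0, 2.2), dim = g$dims))
  b <- density_grid(g$origin, g$spacing, g$dims,
                    array(c(0.9, 0.1, 3.0, -1.0, 1.5), dim = g$dims))
  pts <- 1:5
  expect_equal(map_correlation(a, b, pts),
               pearson_oracle(a$values[pts], b$values[pts]), tolerance = 1e-12)
  expect_equal(map_correlation(a, a, pts), 1.0, tolerance = 1e-12)
  neg <- b; neg$values <- -b$values
  expect_equal(map_correlation(b, neg, pts), -1.0, tolerance = 1e-12)
  # scale/offset invariance with sign flip
  for (alpha in c(2.5, -0.7)) {
    ab <- b; ab$values <- alpha * b$values + 3
    expect_equal(map_correlation(a, ab, pts),
                 sign(alpha) * map_correlation(a, b, pts), tolerance = 1e-12)
  }
  flat <- b; flat$values <- array(1, dim = g$dims)
  expect_error(map_correlation(a, flat, pts), "zero variance")
  expect_error(map_correlation(a, b, pts[1]), "at least 2")
  g2 <- density_grid(c(1, 0, 0), 1, c(5, 1, 1))
  expect_error(map_correlation(a, density_grid(g2$origin, 1, g2$dims), pts),
               "incompatible")
})

test_that("difference-map correlation signs track occupancy errors", {
  tc <- toy_case(seed = 12)
  lig <- toy_ligand(tc)
  s <- tc$structure
  g <- grid_for_atoms(s$atoms)
  env <- neighbourhood(s, lig, 6)
  pts <- ligand_grid_points(g, lig$atoms, env)
  at <- s$atoms
  in_lig <- !at$is_polymer
  lig_map <- calc_model_map(at[in_lig, , drop = FALSE], g)
  full <- calc_model_map(at, g)

  # observed at half occupancy, model at 1.0 -> excess model density
  obs_half <- render_observed_map(s, lig, 0.5, 0, g)
  d <- grid_sub(obs_half, full)
  expect_lt(diff_map_correlation(d, lig_map, pts), 0)

  # observed at 1.0, model at 0.5 -> unmodelled density, positive cc
  at_half <- at
  at_half$occ[in_lig] <- 0.5
  full_half <- calc_model_map(at_half, g)
  obs_full <- render_observed_map(s, lig, 1.0, 0, g)
  d2 <- grid_sub(obs_full, full_half)
  expect_gt(diff_map_correlation(d2, lig_map, pts), 0)

  # exact self-consistency -> zero residual -> undefined correlation
  d0 <- grid_sub(obs_full, full)
  expect_error(diff_map_correlation(d0, lig_map, pts), "zero variance")
})

test_that("Q-Q data is sorted, standardized and near-diagonal for noise", {
  g <- density_grid(c(0, 0, 0), 1, c(22, 22, 22))
  set.seed(42)
  g$values <- array(rnorm(prod(g$dims)), dim = g$dims)
  pts <- seq_len(10000)
  qq <- qq_data(g, pts, n_quantiles = 10000)
  expect_true(!is.unsorted(qq$observed))
  expect_true(!is.unsorted(qq$theoretical))
  expect_equal(length(qq$observed), length(qq$theoretical))
  central <- qq$theoretical > qnorm(0.01) & qq$theoretical < qnorm(0.99)
  expect_lt(max(abs(qq$observed[central] - qq$theoretical[central])), 0.1)
  # degenerate constant input errors cleanly
  flat <- g; flat$values <- array(2, dim = g$dims)
  expect_error(qq_data(flat, pts, 100), "zero variance")
})

test_that("effective resolution handles ideal, incomplete and noisy data", {
  # complete, error-free data: R_eff equals the nominal resolution
  r <- reflection_set(f = rep(10, 100), sig_f = 0, observed = TRUE,
                      d_min = 2.0)
  expect_equal(effective_resolution(r), 2.0)
  # half the records missing, observed error-free: d_min * 2^(1/3)
  r2 <- reflection_set(f = rep(10, 100), sig_f = 0,
                       observed = rep(c(TRUE, FALSE), 50), d_min = 2.0)
  expect_equal(effective_resolution(r2), 2.0 * 2^(1 / 3))
  # increasing sigma never decreases R_eff
  vals <- vapply(c(0, 2, 5, 10), function(sg)
    effective_resolution(reflection_set(rep(10, 50), sg, TRUE, 1.6)),
    numeric(1))
  expect_true(all(diff(vals) >= 0))
  expect_true(all(vals >= 1.6))
  # duplicating every record leaves R_eff unchanged
  r3 <- reflection_set(f = c(8, 12, 9), sig_f = c(1, 2, 0.5),
                       observed = c(TRUE, TRUE, FALSE), d_min = 2.2)
  r3d <- reflection_set(f = rep(c(8, 12, 9), 2), sig_f = rep(c(1, 2, 0.5), 2),
                        observed = rep(c(TRUE, TRUE, FALSE), 2), d_min = 2.2)
  expect_equal(effective_resolution(r3), effective_resolution(r3d))
  expect_error(effective_resolution(
    reflection_set(10, 1, FALSE, 2)), "no observed")
})

test_that("the occupancy scan recovers the true occupancy", {
  tc <- toy_case(seed = 13)
  lig <- toy_ligand(tc)
  g <- grid_for_atoms(tc$structure$atoms)
  # default grid is the 21-point 0.05 ladder
  sc0 <- occupancy_scan(tc$structure, lig,
                        render_observed_map(tc$structure, lig, 1, 0, g))
  expect_equal(nrow(sc0), 21)
  expect_equal(sc0$occ[1], 0)
  expect_equal(sc0$occ[21], 1)
  # self-consistency at the deposited occupancy
  expect_equal(sc0$cc_direct[21], 1.0, tolerance = 1e-9)

  # noise-free truth at 0.65: the cc_diff sign change brackets it
  obs <- render_observed_map(tc$structure, lig, 0.65, 0, g)
  sc <- occupancy_scan(tc$structure, lig, obs)
  pos <- sc$occ[which(sc$cc_diff > 0)]
  neg <- sc$occ[which(sc$cc_diff < 0)]
  expect_lt(max(pos), 0.65 + 0.051)
  expect_gt(min(neg), 0.65 - 0.051)
})

test_that("density grids round-trip through MRC and text formats", {
  tc <- toy_case(seed = 14)
  g <- grid_for_atoms(tc$structure$atoms, spacing = 0.9)
  m <- calc_model_map(tc$structure$atoms, g)
  f1 <- withr::local_tempfile(fileext = ".map")
  write_ccp4_map(m, f1)
  m2 <- read_ccp4_map(f1)
  expect_equal(m2$dims, m$dims)
  expect_equal(m2$origin, m$origin, tolerance = 1e-5)
  expect_equal(m2$spacing, m$spacing, tolerance = 1e-6)
  expect_equal(max(abs(m2$values - m$values)), 0, tolerance = 1e-5)
  f2 <- withr::local_tempfile(fileext = ".txt")
  write_grid_text(m, f2)
  m3 <- read_grid_text(f2)
  expect_equal(m3$values, m$values, tolerance = 1e-7)
})
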