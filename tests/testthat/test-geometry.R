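test_that("geometry Z applies the printed sigma floors", {
  # plain arithmetic, sigma above floor
  expect_equal(geometry_z(1.54, 1.50, 0.02, "bond"), 2.0)
  # sigma below the 0.015 A bond floor: the floor inflates sigma
  expect_equal(geometry_z(1.54, 1.50, 0.005, "bond"), 0.04 / 0.015)
  # 1 degree angle floor
  expect_equal(geometry_z(121.5, 120, 0.2, "angle"), 1.5)
  expect_equal(geometry_z(121.5, 120, 2.0, "angle"), 0.75)
  # zero numerator
  expect_equal(geometry_z(109.5, 109.5, 0.8, "angle"), 0)
  expect_error(geometry_z(1.5, 1.5, 0, "bond"))
})

test_that("flooring only ever weakens a distortion claim", {
  set.seed(31)
  for (i in 1:200) {
    obs <- runif(1, 1.2, 1.8)
    target <- 1.5
    sigma <- runif(1, 0.001, 0.05)
    with_floor <- abs(geometry_z(obs, target, sigma, "bond"))
    without <- abs((obs - target) / sigma)
    expect_lte(with_floor, without + 1e-12)
    if (sigma >= 0.015) expect_equal(with_floor, without)
  }
})

test_that("a ligand built at dictionary targets scores Z = 0 everywhere", {
  for (template in c("TGL", "TPU")) {
    tc <- toy_case(seed = 21, template = template)
    lig <- toy_ligand(tc)
    rep <- z_worst_report(lig, tc$dictionary)
    expect_gt(rep$n_features, 0)
    expect_equal(rep$n_skipped, 0)
    expect_lt(max(abs(rep$features$z)), 1e-6)
    expect_lt(abs(rep$z_worst$z), 1e-6)
  }
})

test_that("Z-worst matches brute-force recomputation on distorted ligands", {
  tc <- toy_case(seed = 22, template = "TPU")
  lig0 <- toy_ligand(tc)
  for (seed in 1:25) {
    lig <- distort_ligand(lig0, 2, 2, seed = seed)
    rep <- z_worst_report(lig, tc$dictionary)
    oracle <- geometry_oracle(lig, tc$dictionary)
    expect_equal(sort(rep$features$z), sort(oracle), tolerance = 1e-9)
    expect_equal(abs(rep$z_worst$z), max(abs(oracle)), tolerance = 1e-9)
  }
})

test_that("Z-worst is invariant under rigid motion of the ligand", {
  tc <- toy_case(seed = 23, template = "TPU")
  lig <- distort_ligand(toy_ligand(tc), 2, 1.5, seed = 5)
  r1 <- z_worst_report(lig, tc$dictionary)
  r2 <- z_worst_report(rotate_ligand(lig), tc$dictionary)
  expect_equal(r2$features$z, r1$features$z, tolerance = 1e-8)
  expect_equal(r2$z_worst$atoms, r1$z_worst$atoms)
})

test_that("amplifying one bond's deviation does not decrease Z-worst", {
  tc <- toy_case(seed = 24)
  lig <- toy_ligand(tc)
  e <- tc$dictionary[[lig$comp_id]]
  # displace O1 along the C1-O1 bond by growing multiples of sigma
  i_o <- match("O1", lig$atoms$name)
  i_c <- match("C1", lig$atoms$name)
  dir <- c(lig$atoms$x[i_o] - lig$atoms$x[i_c],
           lig$atoms$y[i_o] - lig$atoms$y[i_c],
           lig$atoms$z[i_o] - lig$atoms$z[i_c])
  dir <- dir / sqrt(sum(dir^2))
  zw <- vapply(c(0.01, 0.05, 0.1, 0.2), function(step) {
    lg <- lig
    lg$atoms$x[i_o] <- lg$atoms$x[i_o] + step * dir[1]
    lg$atoms$y[i_o] <- lg$atoms$y[i_o] + step * dir[2]
    lg$atoms$z[i_o] <- lg$atoms$z[i_o] + step * dir[3]
    abs(z_worst_report(lg, tc$dictionary)$z_worst$z)
  }, numeric(1))
  expect_true(all(diff(zw) >= -1e-9))
})

test_that("the worst feature is chosen by absolute Z with tie order", {
  # hand-built dictionary with one bond and one angle; the angle deviates
  # more strongly in |Z|
  entry <- list(
    atoms = data.frame(name = c("A1", "A2", "A3"), element = "C",
                       stringsAsFactors = FALSE),
    bonds = data.frame(atom1 = "A1", atom2 = "A2", target = 1.5,
                       sigma = 0.02, stringsAsFactors = FALSE),
    angles = data.frame(atom1 = "A1", atom2 = "A2", atom3 = "A3",
                        target = 100, sigma = 1.0, stringsAsFactors = FALSE))
  dict <- new_dictionary(list(XXX = entry))
  lig <- list(comp_id = "XXX",
              atoms = atom_table(c("A1", "A2", "A3"), "C",
                                 x = c(0, 1.52, 1.52 + cos(pi * 70 / 180) *
                                         1.5),
                                 y = c(0, 0, sin(pi * 70 / 180) * 1.5),
                                 z = c(0, 0, 0), comp_id = "XXX"))
  rep <- z_worst_report(lig, dict)
  # bond Z = 0.02/0.02 = 1; angle observed 110 vs 100 -> Z = 10
  expect_equal(rep$z_worst$kind, "angle")
  expect_equal(rep$z_worst$z, 10, tolerance = 1e-6)
})

test_that("missing atoms and hydrogens are skipped, not fatal", {
  entry <- list(
    atoms = data.frame(name = c("A1", "A2", "H1"),
                       element = c("C", "C", "H"), stringsAsFactors = FALSE),
    bonds = data.frame(atom1 = c("A1", "A1", "A2"),
                       atom2 = c("A2", "H1", "A3x"),
                       target = c(1.5, 1.0, 1.4), sigma = 0.02,
                       stringsAsFactors = FALSE),
    angles = data.frame(atom1 = character(), atom2 = character(),
                        atom3 = character(), target = numeric(),
                        sigma = numeric(), stringsAsFactors = FALSE))
  # A3x is not in the atom list -> dictionary invariant violated
  expect_error(new_dictionary(list(YYY = entry)), "unknown atom")
  entry$bonds$atom2[3] <- "A2"
  entry$bonds$atom1[3] <- "H1"
  dict <- new_dictionary(list(YYY = entry))
  lig <- list(comp_id = "YYY",
              atoms = atom_table(c("A1", "A2"), "C", c(0, 1.51), c(0, 0),
                                 c(0, 0), comp_id = "YYY"))
  rep <- z_worst_report(lig, dict)   # H restraints silently dropped
  expect_equal(rep$n_features, 1)
})

test_that("slider likelihood classes follow the 1-to-5 band", {
  cls <- z_likelihood_class(c(0.2, -1, 3, 5, -8))
  expect_equal(cls$label,
               c("likely", "likely", "intermediate", "unlikely", "unlikely"))
  expect_equal(cls$slider, c(0, 0, 0.5, 1, 1))
})

test_that("dictionaries round-trip through monomer-library mmCIF", {
  dict <- toy_dictionary()
  f <- withr::local_tempfile(fileext = ".cif")
  write_dictionary(dict, f)
  d2 <- load_dictionary(f)
  expect_setequal(names(d2), names(dict))
  for (comp in names(dict)) {
    expect_equal(d2[[comp]]$atoms$name, dict[[comp]]$atoms$name)
    expect_equal(d2[[comp]]$bonds$target, dict[[comp]]$bonds$target,
                 tolerance = 1e-4)
    expect_equal(d2[[comp]]$angles$target, dict[[comp]]$angles$target,
                 tolerance = 1e-3)
    expect_equal(d2[[comp]]$angles$sigma, dict[[comp]]$angles$sigma,
                 tolerance = 1e-3)
  }
})

test_that("dictionary integrity errors are raised at load time", {
  # a dictionary block with no angle rows keeps bonds intact
  f <- withr::local_tempfile(fileext = ".cif")
  writeLines(c(
    "data_comp_QQQ",
    "loop_",
    "_chem_comp_atom.comp_id", "_chem_comp_atom.atom_id",
    "_chem_comp_atom.type_symbol",
    "QQQ A1 C", "QQQ A2 C",
    "loop_",
    "_chem_comp_bond.comp_id", "_chem_comp_bond.atom_id_1",
    "_chem_comp_bond.atom_id_2", "_chem_comp_bond.value_dist",
    "_chem_comp_bond.value_dist_esd",
    "QQQ A1 A2 1.530 0.020"), f)
  d <- load_dictionary(f)
  expect_equal(nrow(d$QQQ$angles), 0)
  expect_equal(nrow(d$QQQ$bonds), 1)

  # duplicate bond row -> duplicate restraint error
  writeLines(c(
    "data_comp_QQQ",
    "loop_",
    "_chem_comp_atom.comp_id", "_chem_comp_atom.atom_id",
    "_chem_comp_atom.type_symbol",
    "QQQ A1 C", "QQQ A2 C",
    "loop_",
    "_chem_comp_bond.comp_id", "_chem_comp_bond.atom_id_1",
    "_chem_comp_bond.atom_id_2", "_chem_comp_bond.value_dist",
    "_chem_comp_bond.value_dist_esd",
    "QQQ A1 A2 1.530 0.020",
    "QQQ A2 A1 1.540 0.020"), f)
  expect_error(load_dictionary(f), "duplicate restraint")

  # missing sigma column -> error
  writeLines(c(
    "data_comp_QQQ",
    "loop_",
    "_chem_comp_atom.comp_id", "_chem_comp_atom.atom_id",
    "_chem_comp_atom.type_symbol",
    "QQQ A1 C", "QQQ A2 C",
    "loop_",
    "_chem_comp_bond.comp_id", "_chem_comp_bond.atom_id_1",
    "_chem_comp_bond.atom_id_2", "_chem_comp_bond.value_dist",
    "QQQ A1 A2 1.530"), f)
  expect_error(load_dictionary(f), "value_dist_esd")
})
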