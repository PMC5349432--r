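# Two-atom helper: a one-atom ligand and a one-atom environment at a
# chosen separation.
pair_case <- function(d, el_l = "C", el_e = "C") {
  lig <- list(comp_id = "LIG",
              atoms = atom_table("L1", el_l, 0, 0, 0, comp_id = "LIG",
                                 chain = "X", seq_id = 101L))
  env <- atom_table("E1", el_e, d, 0, 0, comp_id = "ALA", chain = "A",
                    seq_id = 1L, is_polymer = TRUE)
  list(lig = lig, env = env)
}

test_that("gap thresholds classify the four contact categories", {
  radii <- c(C = 1.7)   # example radii giving round gaps
  # 3.40 A between two r=1.7 atoms: gap exactly 0 -> small-overlap
  pc <- pair_case(3.40)
  ct <- find_contacts(pc$lig, pc$env, radii = radii)
  expect_equal(nrow(ct), 1)
  expect_equal(ct$gap, 0)
  expect_equal(ct$category, "small-overlap")
  # 2.90 A: gap -0.5 -> bad
  ct2 <- find_contacts(pc$lig, pair_case(2.90)$env, radii = radii)
  expect_equal(ct2$gap, -0.5)
  expect_equal(ct2$category, "bad")
  # gap slightly above 0.25 -> wide; slightly below -> close
  expect_equal(find_contacts(pc$lig, pair_case(3.66)$env,
                             radii = radii)$category, "wide")
  expect_equal(find_contacts(pc$lig, pair_case(3.60)$env,
                             radii = radii)$category, "close")
})

test_that("hydrogen-bond capable pairs get the relaxed classification", {
  radii <- c(N = 1.7, O = 1.7, C = 1.7)
  # N...O at gap -0.5: relaxation +0.2 reclassifies bad -> small-overlap
  pc <- pair_case(2.90, "N", "O")
  ct <- find_contacts(pc$lig, pc$env, radii = radii)
  expect_equal(ct$gap, -0.5)           # geometric gap is reported raw
  expect_equal(ct$category, "small-overlap")
  # turning the relaxation off restores the bad classification
  ct0 <- find_contacts(pc$lig, pc$env, radii = radii, hbond_relax = 0)
  expect_equal(ct0$category, "bad")
  # C...O pairs are not relaxed
  ctc <- find_contacts(pair_case(2.90, "C", "O")$lig, pc$env, radii = radii)
  expect_equal(ctc$category, "bad")
})

test_that("covalently linked pairs are excluded from the contact list", {
  pc <- pair_case(1.45)
  links <- data.frame(name1 = "L1", comp_id1 = "LIG", chain1 = "X",
                      seq_id1 = 101L, name2 = "E1", comp_id2 = "ALA",
                      chain2 = "A", seq_id2 = 1L, stringsAsFactors = FALSE)
  ct <- find_contacts(pc$lig, pc$env, links = links)
  expect_equal(nrow(ct), 0)
  ct2 <- find_contacts(pc$lig, pc$env)
  expect_equal(nrow(ct2), 1)
})

test_that("1-3 pairs through a link are excluded too", {
  lig <- list(comp_id = "LIG",
              atoms = atom_table(c("L1", "L2"), "C", c(0, 1.5), 0, 0,
                                 comp_id = "LIG", chain = "X",
                                 seq_id = 101L))
  # E1 bonded to L1 via a link; E2 bonded to E1 within its residue
  env <- atom_table(c("E1", "E2"), c("C", "O"), c(-1.5, -2.9), c(0, 0.5),
                    0, comp_id = "ALA", chain = "A", seq_id = 1L,
                    is_polymer = TRUE)
  links <- data.frame(name1 = "L1", comp_id1 = "LIG", chain1 = "X",
                      seq_id1 = 101L, name2 = "E1", comp_id2 = "ALA",
                      chain2 = "A", seq_id2 = 1L, stringsAsFactors = FALSE)
  ct <- find_contacts(lig, env, links = links, max_gap = 10)
  # L1-E1 (bonded) and L1-E2, L2-E1 (1-3) excluded; L2-E2 is 1-4, kept
  expect_equal(nrow(ct), 1)
  expect_equal(ct$lig_name, "L2")
  expect_equal(ct$env_name, "E2")
})

test_that("bad-contact counting applies the -0.4 A threshold", {
  expect_equal(count_bad_contacts(find_contacts(
    pair_case(100)$lig, empty_atom_table())), 0)
  # gaps {-0.5, -0.41, -0.3, +0.1} -> exactly 2 bad
  radii <- c(C = 1.7)
  lig <- list(comp_id = "LIG",
              atoms = atom_table("L1", "C", 0, 0, 0, comp_id = "LIG",
                                 chain = "X", seq_id = 101L))
  gaps <- c(-0.5, -0.41, -0.3, 0.1)
  env <- atom_table(paste0("E", 1:4), "C", x = 3.4 + gaps,
                    y = 0, z = 0, comp_id = "ALA", chain = "A",
                    seq_id = 1:4, is_polymer = TRUE)
  ct <- find_contacts(lig, env, radii = radii)
  expect_equal(count_bad_contacts(ct), 2)
  expect_equal(nrow(ct), 4)
})

test_that("contacts match a brute-force all-pairs oracle on fixtures", {
  radii <- default_vdw_radii()
  for (seed in 1:8) {
    tc <- toy_case(seed = seed, n_pocket = 10,
                   min_gap = if (seed %% 2) -0.6 else 0.1)
    lig <- toy_ligand(tc)
    env <- tc$structure$atoms[tc$structure$atoms$is_polymer, , drop = FALSE]
    ct <- find_contacts(lig, env, radii = radii, max_gap = 1.0)
    oracle <- contacts_oracle(lig$atoms, env, radii, 1.0, 0.2)
    expect_equal(nrow(ct), nrow(oracle))
    key <- function(df) sort(paste(df$lig_name, df$env_name,
                                   round(df$gap, 9), df$category))
    expect_equal(key(ct), key(oracle))
    expect_equal(count_bad_contacts(ct), sum(oracle$category == "bad"))
  }
})

test_that("the category partition is exhaustive and exclusive", {
  gaps <- seq(-1, 1, by = 0.01)
  cats <- contact_category(gaps)
  expect_true(all(cats %in% c("wide", "close", "small-overlap", "bad")))
  expect_equal(unname(table(cats)["bad"]), sum(gaps < -0.4))
  expect_equal(unname(table(cats)["wide"]), sum(gaps > 0.25))
  # boundary values land in exactly one class
  expect_equal(contact_category(0.25), "close")
  expect_equal(contact_category(-0.4), "small-overlap")
})

test_that("pushing the ligand into the pocket only adds bad contacts", {
  # one ligand atom approaching a wall of three atoms along x
  radii <- c(C = 1.9)
  env <- atom_table(paste0("E", 1:3), "C", x = 5, y = c(-1, 0, 1), z = 0,
                    comp_id = "ALA", chain = "A", seq_id = 1:3,
                    is_polymer = TRUE)
  counts <- vapply(seq(0, 3.5, by = 0.25), function(shift) {
    lig <- list(comp_id = "LIG",
                atoms = atom_table("L1", "C", shift, 0, 0, comp_id = "LIG",
                                   chain = "X", seq_id = 101L))
    count_bad_contacts(find_contacts(lig, env, radii = radii))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})
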