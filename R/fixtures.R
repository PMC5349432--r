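## Synthetic fixtures: toy protein-ligand complexes built from internal
## coordinates, with restraint dictionaries measured off the ideal
## geometry, plus synthetic "observed" maps and reference metric corpora.
## Everything is a pure function of its spec and seed.

## Run code with a locally seeded RNG, restoring global RNG state after.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

## Z-matrix templates for the bundled toy ligands. Columns: atom name,
## element, bond/angle/dihedral reference atoms (indices of already placed
## atoms; 0 = none) and the internal coordinate values.
toy_templates <- function() {
  list(
    ## glycerol-like triol, 6 heavy atoms, acyclic
    TGL = data.frame(
      name = c("C1", "O1", "C2", "O2", "C3", "O3"),
      element = c("C", "O", "C", "O", "C", "O"),
      r1 = c(0L, 1L, 1L, 3L, 3L, 5L),
      r2 = c(0L, 0L, 2L, 1L, 1L, 3L),
      r3 = c(0L, 0L, 0L, 2L, 2L, 1L),
      bond = c(NA, 1.42, 1.53, 1.42, 1.53, 1.43),
      angle = c(NA, NA, 109.5, 109.5, 111.0, 109.5),
      dihedral = c(NA, NA, NA, 60, 180, -60),
      stringsAsFactors = FALSE),
    ## purine-like composition (C5 N4 O2), 11 heavy atoms, acyclic tree
    TPU = data.frame(
      name = c("N1", "C2", "N3", "C4", "C5", "C6", "O6", "N7", "C8",
               "N9", "O2"),
      element = c("N", "C", "N", "C", "C", "C", "O", "N", "C", "N", "O"),
      r1 = c(0L, 1L, 2L, 3L, 4L, 5L, 6L, 5L, 8L, 4L, 2L),
      r2 = c(0L, 0L, 1L, 2L, 3L, 4L, 5L, 4L, 5L, 3L, 1L),
      r3 = c(0L, 0L, 0L, 1L, 2L, 3L, 4L, 3L, 4L, 2L, 3L),
      bond = c(NA, 1.34, 1.33, 1.35, 1.40, 1.40, 1.23, 1.38, 1.31,
               1.37, 1.24),
      angle = c(NA, NA, 120, 118, 122, 117, 120, 110, 104, 126, 121),
      dihedral = c(NA, NA, NA, 180, 180, 30, 180, -150, 180, 60, 180),
      stringsAsFactors = FALSE)
  )
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unit <- function(v) v / sqrt(sum(v^2))

## Natural-extension placement: new atom at distance `bond` from a, with
## angle new-a-b and dihedral new-a-b-c.
place_nerf <- function(a, b, c3, bond, angle_deg, dih_deg) {
  th <- angle_deg * pi / 180
  ph <- dih_deg * pi / 180
  u <- unit(a - b)
  n <- unit(cross3(b - c3, u))
  m <- cross3(n, u)
  a + bond * (-cos(th) * u + sin(th) * (cos(ph) * m + sin(ph) * n))
}

build_template_coords <- function(tpl) {
  n <- nrow(tpl)
  xyz <- matrix(0, n, 3)
  if (n >= 2) xyz[2, ] <- xyz[tpl$r1[2], ] + c(tpl$bond[2], 0, 0)
  if (n >= 3) {
    a <- xyz[tpl$r1[3], ]
    u <- unit(xyz[tpl$r2[3], ] - a)
    th <- tpl$angle[3] * pi / 180
    w <- c(0, 0, 1)
    xyz[3, ] <- a + tpl$bond[3] * (cos(th) * u + sin(th) * w)
  }
  for (i in seq_len(n)[-(1:min(3, n))]) {
    xyz[i, ] <- place_nerf(xyz[tpl$r1[i], ], xyz[tpl$r2[i], ],
                           xyz[tpl$r3[i], ], tpl$bond[i], tpl$angle[i],
                           tpl$dihedral[i])
  }
  xyz
}

## Bond edges and connected angle triples implied by a template tree.
template_topology <- function(tpl) {
  bonds <- data.frame(i = which(tpl$r1 > 0), j = tpl$r1[tpl$r1 > 0])
  nb <- lapply(seq_len(nrow(tpl)), function(k)
    sort(unique(c(bonds$i[bonds$j == k], bonds$j[bonds$i == k]))))
  angles <- list()
  for (j in seq_len(nrow(tpl))) {
    nbs <- nb[[j]]
    if (length(nbs) >= 2) {
      cmb <- utils::combn(nbs, 2)
      for (k in seq_len(ncol(cmb)))
        angles[[length(angles) + 1L]] <- c(cmb[1, k], j, cmb[2, k])
    }
  }
  list(bonds = bonds, angles = angles)
}

## Dictionary entry with targets measured from the ideal coordinates, so a
## freshly built ligand scores Z = 0 on every feature.
template_dictionary_entry <- function(tpl, xyz, bond_sigma = 0.02,
                                      angle_sigma = 2.0) {
  topo <- template_topology(tpl)
  bonds <- data.frame(
    atom1 = tpl$name[topo$bonds$i], atom2 = tpl$name[topo$bonds$j],
    target = vapply(seq_len(nrow(topo$bonds)), function(k)
      bond_length(xyz[topo$bonds$i[k], ], xyz[topo$bonds$j[k], ]),
      numeric(1)),
    sigma = bond_sigma, stringsAsFactors = FALSE)
  angles <- do.call(rbind, lapply(topo$angles, function(tr)
    data.frame(atom1 = tpl$name[tr[1]], atom2 = tpl$name[tr[2]],
               atom3 = tpl$name[tr[3]],
               target = bond_angle_deg(xyz[tr[1], ], xyz[tr[2], ],
                                       xyz[tr[3], ]),
               sigma = angle_sigma, stringsAsFactors = FALSE)))
  list(atoms = data.frame(name = tpl$name, element = tpl$element,
                          stringsAsFactors = FALSE),
       bonds = bonds, angles = angles)
}

#' Bundled toy-ligand restraint dictionary
#'
#' Dictionary entries for the built-in templates (`TGL`, a glycerol-like
#' triol with 6 heavy atoms; `TPU`, a purine-like 11-atom compound), with
#' bond/angle targets measured from the ideal template geometry.
#'
#' @param bond_sigma,angle_sigma Restraint sigmas (angstroms / degrees).
#' @return An `lqc_dictionary`.
#' @export
toy_dictionary <- function(bond_sigma = 0.02, angle_sigma = 2.0) {
  tpls <- toy_templates()
  new_dictionary(lapply(tpls, function(tpl)
    template_dictionary_entry(tpl, build_template_coords(tpl),
                              bond_sigma, angle_sigma)))
}

#' Specification for a synthetic protein-ligand complex
#'
#' @param seed RNG seed; the complex is a pure function of the spec.
#' @param n_pocket_atoms Number of surrounding pocket (pseudo-protein)
#'   atoms.
#' @param ligand_template `"TGL"` or `"TPU"`.
#' @param pocket_min_gap Minimum allowed vdW gap between ligand and pocket
#'   atoms, angstroms (may be negative to force clashes).
#' @param b_range B-factor range for pocket atoms, squared angstroms.
#' @param true_occupancy Ground-truth ligand occupancy used when rendering
#'   synthetic observed maps.
#' @return A list of class `toy_complex_spec`.
#' @export
toy_complex_spec <- function(seed = 1L, n_pocket_atoms = 8L,
                             ligand_template = "TGL", pocket_min_gap = 0.3,
                             b_range = c(10, 30), true_occupancy = 1.0) {
  stopifnot(pocket_min_gap > -1.0, all(b_range >= 0),
            true_occupancy >= 0, true_occupancy <= 1,
            ligand_template %in% names(toy_templates()))
  structure(list(seed = as.integer(seed),
                 n_pocket_atoms = as.integer(n_pocket_atoms),
                 ligand_template = ligand_template,
                 pocket_min_gap = pocket_min_gap, b_range = b_range,
                 true_occupancy = true_occupancy),
            class = "toy_complex_spec")
}

#' Generate a synthetic protein-ligand complex
#'
#' Builds the chosen toy ligand exactly at its dictionary targets, centred
#' at the origin, and scatters pocket atoms around it with every
#' ligand-pocket vdW gap at least `pocket_min_gap`. Deterministic given the
#' spec.
#'
#' @param spec A [toy_complex_spec()].
#' @return List with `structure` (an `lqc_structure`), `dictionary` (an
#'   `lqc_dictionary`) and the `spec`.
#' @export
make_toy_complex <- function(spec = toy_complex_spec()) {
  tpl <- toy_templates()[[spec$ligand_template]]
  xyz <- build_template_coords(tpl)
  xyz <- sweep(xyz, 2, colMeans(xyz))
  dict <- toy_dictionary()

  with_seed(spec$seed, {
    lig <- atom_table(
      name = tpl$name, element = tpl$element,
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      occ = 1, b = stats::runif(nrow(tpl), spec$b_range[1], spec$b_range[2]),
      comp_id = spec$ligand_template, chain = "X", seq_id = 101L,
      is_polymer = FALSE)

    radii <- default_vdw_radii()
    pocket <- list()
    pocket_xyz <- matrix(numeric(0), 0, 3)
    for (i in seq_len(spec$n_pocket_atoms)) {
      el <- sample(c("C", "N", "O"), 1)
      placed <- FALSE
      for (try in 1:300) {
        anchor <- sample(nrow(lig), 1)
        dir <- unit(stats::rnorm(3))
        gap <- spec$pocket_min_gap + stats::runif(1, 0, 1.2)
        dist <- radii[[lig$element[anchor]]] + radii[[el]] + gap
        pos <- c(lig$x[anchor], lig$y[anchor], lig$z[anchor]) + dir * dist
        gaps <- sqrt((lig$x - pos[1])^2 + (lig$y - pos[2])^2 +
                       (lig$z - pos[3])^2) -
          vdw_radius(lig$element, radii) - radii[[el]]
        if (min(gaps) < spec$pocket_min_gap) next
        if (nrow(pocket_xyz) > 0 &&
              min(sqrt(rowSums(sweep(pocket_xyz, 2, pos)^2))) < 2.6) next
        pocket[[i]] <- list(el = el, pos = pos,
                            b = stats::runif(1, spec$b_range[1],
                                             spec$b_range[2]))
        pocket_xyz <- rbind(pocket_xyz, pos)
        placed <- TRUE
        break
      }
      if (!placed) stop("infeasible pocket placement after bounded retries")
    }

    env <- if (length(pocket) > 0) atom_table(
      name = vapply(pocket, function(p)
        switch(p$el, C = "CA", N = "N", O = "O"), character(1)),
      element = vapply(pocket, function(p) p$el, character(1)),
      x = vapply(pocket, function(p) p$pos[1], numeric(1)),
      y = vapply(pocket, function(p) p$pos[2], numeric(1)),
      z = vapply(pocket, function(p) p$pos[3], numeric(1)),
      occ = 1, b = vapply(pocket, function(p) p$b, numeric(1)),
      comp_id = "ALA", chain = "A", seq_id = seq_along(pocket),
      is_polymer = TRUE) else empty_atom_table()

    list(structure = new_structure(rbind(env, lig)),
         dictionary = dict, spec = spec)
  })
}

## Least-squares rigid superposition (Kabsch) of mobile onto target.
superpose_coords <- function(mobile, target) {
  mc <- colMeans(mobile); tc <- colMeans(target)
  m0 <- sweep(mobile, 2, mc); t0 <- sweep(target, 2, tc)
  s <- svd(t(m0) %*% t0)
  d <- sign(det(s$v %*% t(s$u)))
  r <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(m0 %*% t(r), 2, tc, "+")
}

#' Distort a toy ligand's internal coordinates
#'
#' Perturbs every internal bond length by `N(0, (lambda * sigma_bond)^2)`
#' and every placement angle by `N(0, (mu * sigma_angle)^2)` (dictionary
#' sigmas), rebuilds the Cartesian coordinates, and superposes the result
#' onto the original pose. `lambda = mu = 0` is the identity.
#'
#' @param lig An `lqc_ligand` whose comp-id is a bundled template.
#' @param bond_sigma_mult,angle_sigma_mult Sigma multipliers, non-negative.
#' @param seed RNG seed.
#' @param bond_sigma,angle_sigma Dictionary sigmas.
#' @return The ligand with distorted coordinates.
#' @export
distort_ligand <- function(lig, bond_sigma_mult, angle_sigma_mult, seed,
                           bond_sigma = 0.02, angle_sigma = 2.0) {
  stopifnot(bond_sigma_mult >= 0, angle_sigma_mult >= 0)
  tpl <- toy_templates()[[lig$comp_id]]
  if (is.null(tpl)) stop("no template for comp-id ", lig$comp_id)
  with_seed(seed, {
    tpl$bond <- tpl$bond + c(NA, stats::rnorm(nrow(tpl) - 1, 0,
                                              bond_sigma_mult * bond_sigma))
    na_a <- is.na(tpl$angle)
    tpl$angle[!na_a] <- tpl$angle[!na_a] +
      stats::rnorm(sum(!na_a), 0, angle_sigma_mult * angle_sigma)
    xyz <- build_template_coords(tpl)
    ord <- match(lig$atoms$name, tpl$name)
    cur <- as.matrix(lig$atoms[, c("x", "y", "z")])
    new_xyz <- superpose_coords(xyz[ord, , drop = FALSE], cur)
    lig$atoms$x <- new_xyz[, 1]
    lig$atoms$y <- new_xyz[, 2]
    lig$atoms$z <- new_xyz[, 3]
    lig
  })
}

#' Render a synthetic observed map
#'
#' Full-model Gaussian synthesis with the ligand at `true_occupancy`, plus
#' i.i.d. normal grid noise. Provides the "observed" side of the map
#' correlations without any structure-factor round trip.
#'
#' @param s An `lqc_structure`.
#' @param lig The ligand instance whose occupancy is overridden.
#' @param true_occupancy Ground-truth occupancy in `[0, 1]`.
#' @param noise_sigma Noise standard deviation (map units), non-negative.
#' @param grid A [density_grid()] geometry.
#' @param seed RNG seed for the noise.
#' @param w Gaussian softening width, angstroms.
#' @return A [density_grid()].
#' @export
render_observed_map <- function(s, lig, true_occupancy, noise_sigma, grid,
                                seed = 1L, w = 0.5) {
  stopifnot(noise_sigma >= 0)
  at <- s$atoms
  in_lig <- paste(at$chain, at$seq_id, at$name) %in%
    paste(lig$atoms$chain, lig$atoms$seq_id, lig$atoms$name)
  at$occ[in_lig] <- true_occupancy
  m <- calc_model_map(at, grid, w = w)
  if (noise_sigma > 0) {
    m$values <- m$values + with_seed(seed,
      array(stats::rnorm(prod(grid$dims), 0, noise_sigma),
            dim = grid$dims))
  }
  m
}

## Smallest-median-matching Poisson rate: lambda = m + 0.4 gives integer
## median m for the small counts used here.
poisson_lambda_for_median <- function(m) {
  lam <- m + 0.4
  stopifnot(stats::qpois(0.5, lam) == m)
  lam
}

#' Generate a synthetic reference corpus of ligand metrics
#'
#' Metric values are drawn from documented parametric families whose
#' medians match `target_medians`: direct-map correlation from a shifted
#' Beta on `[-1, 1]` (second shape fixed at 2, first solved for the
#' median), difference-map correlation from a clamped normal, Z-worst from
#' a log-normal and bad contacts from a Poisson. Defaults anchor the
#' difference-map median at -0.073 and the bad-contact median at 1,
#' matching wwPDB-wide ligand statistics.
#'
#' @param n Number of records, at least 10.
#' @param seed RNG seed.
#' @param target_medians Named list with `cc_direct`, `cc_diff`, `z_worst`,
#'   `n_bad`.
#' @return A `metric_set` data frame with `n` rows.
#' @export
make_reference_corpus <- function(n, seed = 1L,
                                  target_medians = list(
                                    cc_direct = 0.92, cc_diff = -0.073,
                                    z_worst = 2.0, n_bad = 1)) {
  stopifnot(n >= 10)
  tm <- target_medians
  a <- stats::uniroot(function(a) stats::qbeta(0.5, a, 2) - (tm$cc_direct + 1) / 2,
                      c(1e-3, 1e3))$root
  with_seed(seed, {
    m <- metric_set(
      accession = sprintf("SYN%06d", seq_len(n)),
      comp_id = sample(c("TGL", "TPU", "LG1", "LG2"), n, replace = TRUE),
      cc_direct = 2 * stats::rbeta(n, a, 2) - 1,
      cc_diff = pmin(1, pmax(-1, stats::rnorm(n, tm$cc_diff, 0.15))),
      z_worst = stats::rlnorm(n, log(tm$z_worst), 0.6),
      n_bad = stats::rpois(n, poisson_lambda_for_median(tm$n_bad)),
      r_nom = round(stats::runif(n, 1.0, 3.2), 2)
    )
    m
  })
}
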