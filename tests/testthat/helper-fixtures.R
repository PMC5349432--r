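# Shared fixture helpers: everything is generated in code at test time.

toy_case <- function(seed = 1, template = "TGL", n_pocket = 8,
                     min_gap = 0.3) {
  make_toy_complex(toy_complex_spec(seed = seed, n_pocket_atoms = n_pocket,
                                    ligand_template = template,
                                    pocket_min_gap = min_gap))
}

toy_ligand <- function(tc) select_ligand(tc$structure, tc$dictionary)

# Independent brute-force Pearson correlation (sum formulas, no stats::cor).
pearson_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# Brute-force masked-point oracle: triple loop over every grid node.
ligand_points_oracle <- function(grid, lig_atoms, env_atoms, spec) {
  lr <- mask_radius(lig_atoms$element, lig_atoms$b, spec)
  er <- if (nrow(env_atoms) > 0)
    mask_radius(env_atoms$element, env_atoms$b, spec) +
      spec$neighbour_radius_inflation else numeric(0)
  keep <- integer(0)
  idx <- 0L
  for (k in seq_len(grid$dims[3])) {
    for (j in seq_len(grid$dims[2])) {
      for (i in seq_len(grid$dims[1])) {
        idx <- idx + 1L
        p <- grid$origin + (c(i, j, k) - 1) * grid$spacing
        dl <- sqrt((lig_atoms$x - p[1])^2 + (lig_atoms$y - p[2])^2 +
                     (lig_atoms$z - p[3])^2)
        if (!any(dl <= lr)) next
        if (nrow(env_atoms) > 0) {
          de <- sqrt((env_atoms$x - p[1])^2 + (env_atoms$y - p[2])^2 +
                       (env_atoms$z - p[3])^2)
          if (any(de <= er)) next
        }
        keep <- c(keep, idx)
      }
    }
  }
  keep
}

# Brute-force all-pairs contact oracle (no exclusions beyond linked pairs).
contacts_oracle <- function(lig_atoms, env, radii, max_gap, hbond_relax) {
  res <- list()
  for (i in seq_len(nrow(lig_atoms))) {
    for (j in seq_len(nrow(env))) {
      d <- sqrt((lig_atoms$x[i] - env$x[j])^2 +
                  (lig_atoms$y[i] - env$y[j])^2 +
                  (lig_atoms$z[i] - env$z[j])^2)
      gap <- d - radii[[toupper(lig_atoms$element[i])]] -
        radii[[toupper(env$element[j])]]
      if (gap > max_gap) next
      g <- gap
      if (toupper(lig_atoms$element[i]) %in% c("N", "O") &&
            toupper(env$element[j]) %in% c("N", "O"))
        g <- g + hbond_relax
      cat_lbl <- if (g > 0.25) "wide" else if (g > 0) "close"
        else if (g >= -0.4) "small-overlap" else "bad"
      res[[length(res) + 1L]] <- data.frame(
        lig_name = lig_atoms$name[i], env_name = env$name[j],
        gap = gap, category = cat_lbl, stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0) return(data.frame(lig_name = character(),
                                          env_name = character(),
                                          gap = numeric(),
                                          category = character()))
  do.call(rbind, res)
}

# Brute-force geometry oracle: measure every dictionary feature directly.
geometry_oracle <- function(lig, dict) {
  e <- dict[[lig$comp_id]]
  at <- lig$atoms
  p <- function(nm) {
    i <- match(nm, at$name)
    c(at$x[i], at$y[i], at$z[i])
  }
  zs <- c()
  for (i in seq_len(nrow(e$bonds))) {
    b <- e$bonds[i, ]
    obs <- sqrt(sum((p(b$atom1) - p(b$atom2))^2))
    zs <- c(zs, (obs - b$target) / max(b$sigma, 0.015))
  }
  for (i in seq_len(nrow(e$angles))) {
    a <- e$angles[i, ]
    v1 <- p(a$atom1) - p(a$atom2)
    v2 <- p(a$atom3) - p(a$atom2)
    obs <- acos(min(1, max(-1, sum(v1 * v2) /
                             sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
    zs <- c(zs, (obs - a$target) / max(a$sigma, 1.0))
  }
  zs
}

rotate_ligand <- function(lig, axis = c(0.3, -0.5, 0.8), angle = 1.1,
                          shift = c(5, -3, 2)) {
  u <- axis / sqrt(sum(axis^2))
  ca <- cos(angle); sa <- sin(angle)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
               byrow = TRUE)
  rot <- ca * diag(3) + sa * ux + (1 - ca) * (u %o% u)
  xyz <- as.matrix(lig$atoms[, c("x", "y", "z")]) %*% t(rot)
  lig$atoms$x <- xyz[, 1] + shift[1]
  lig$atoms$y <- xyz[, 2] + shift[2]
  lig$atoms$z <- xyz[, 3] + shift[3]
  lig
}
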