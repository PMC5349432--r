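#' Default united-atom van der Waals radii
#'
#' Heavy-atom (united-atom) radii in angstroms used for contact gaps;
#' configurable per element.
#'
#' @return Named numeric vector.
#' @export
default_vdw_radii <- function() {
  c(C = 1.90, N = 1.70, O = 1.60, S = 1.95, P = 1.95,
    F = 1.50, CL = 1.80, BR = 1.95, I = 2.10)
}

vdw_radius <- function(element, radii) {
  r <- radii[toupper(element)]
  if (anyNA(r)) {
    warning("no vdW radius for element(s): ",
            paste(unique(element[is.na(r)]), collapse = ", "),
            "; using 1.7 A")
    r[is.na(r)] <- 1.7
  }
  unname(r)
}

## Contact categories from the (possibly hydrogen-bond relaxed) gap.
contact_category <- function(gap) {
  ifelse(gap > 0.25, "wide",
         ifelse(gap > 0, "close",
                ifelse(gap >= -0.4, "small-overlap", "bad")))
}

## Adjacency pairs (i, j indices into the combined lig+env table) within
## graph distance 2, from dictionary bonds (ligand), distance-based
## intra-residue bonds (environment) and link records.
excluded_pairs <- function(lig_atoms, env, dict = NULL, links = NULL,
                           bond_cut = 1.8) {
  all_at <- rbind(lig_atoms, env)
  n <- nrow(all_at)
  key <- paste(all_at$chain, all_at$seq_id, all_at$name)
  adj <- matrix(FALSE, n, n)

  connect <- function(k1, k2) {
    i <- match(k1, key); j <- match(k2, key)
    ok <- !is.na(i) & !is.na(j)
    adj[cbind(i[ok], j[ok])] <<- TRUE
    adj[cbind(j[ok], i[ok])] <<- TRUE
  }

  ## ligand bonds from the dictionary when available, else by distance
  li <- seq_len(nrow(lig_atoms))
  e <- if (!is.null(dict)) dict[[lig_atoms$comp_id[1]]] else NULL
  if (!is.null(e) && nrow(e$bonds) > 0) {
    lk <- paste(lig_atoms$chain[1], lig_atoms$seq_id[1])
    connect(paste(lk, e$bonds$atom1), paste(lk, e$bonds$atom2))
  } else if (length(li) > 1) {
    d <- atom_dist(lig_atoms, lig_atoms)
    adj[li, li] <- adj[li, li] | (d < bond_cut & d > 0)
  }

  ## intra-residue environment bonds by distance
  if (nrow(env) > 0) {
    ei <- nrow(lig_atoms) + seq_len(nrow(env))
    res <- atom_res_key(env)
    for (r in unique(res)) {
      idx <- ei[res == r]
      if (length(idx) > 1) {
        d <- atom_dist(all_at[idx, ], all_at[idx, ])
        adj[idx, idx] <- adj[idx, idx] | (d < bond_cut & d > 0)
      }
    }
  }

  if (!is.null(links) && nrow(links) > 0)
    connect(paste(links$chain1, links$seq_id1, links$name1),
            paste(links$chain2, links$seq_id2, links$name2))

  ## graph distance <= 2: adjacency or shared neighbour
  near <- adj | ((adj %*% adj) > 0)
  near
}

#' Find ligand-environment contacts
#'
#' All ligand-environment atom pairs with gap (distance minus the two vdW
#' radii) at most `max_gap`, classified as wide (`gap > 0.25`), close
#' (`0 < gap <= 0.25`), small-overlap (`-0.4 <= gap <= 0`) or bad
#' (`gap < -0.4`). Pairs bonded through a covalent link record — or within
#' two bonds of one — are excluded. Nitrogen/oxygen pairs can hydrogen
#' bond, so their gap is relaxed by `hbond_relax` before classification
#' (the reported `gap` stays geometric).
#'
#' @param lig An `lqc_ligand`.
#' @param env Atom table of environment atoms.
#' @param radii Named vdW radius table, angstroms.
#' @param max_gap Largest (raw) gap reported, angstroms.
#' @param hbond_relax Gap relaxation for N/O-N/O pairs, angstroms.
#' @param links Link records (as in `lqc_structure$links`) for exclusion.
#' @param dict Optional dictionary for ligand bond connectivity.
#' @return Data frame of class `contact_list`: `lig_name`, `env_name`,
#'   `env_res`, `distance`, `gap`, `category`.
#' @export
find_contacts <- function(lig, env, radii = default_vdw_radii(),
                          max_gap = 1.0, hbond_relax = 0.2,
                          links = NULL, dict = NULL) {
  la <- lig$atoms
  heavy_l <- toupper(la$element) != "H"
  heavy_e <- if (nrow(env)) toupper(env$element) != "H" else logical(0)
  la <- la[heavy_l, , drop = FALSE]
  env <- env[heavy_e, , drop = FALSE]
  out <- data.frame(lig_name = character(), env_name = character(),
                    env_res = character(), distance = numeric(),
                    gap = numeric(), category = character(),
                    stringsAsFactors = FALSE)
  class(out) <- c("contact_list", "data.frame")
  if (nrow(la) == 0 || nrow(env) == 0) return(out)

  d <- atom_dist(la, env)
  rl <- vdw_radius(la$element, radii)
  re <- vdw_radius(env$element, radii)
  gap <- d - outer(rl, re, "+")
  excl <- excluded_pairs(la, env, dict = dict, links = links)
  excl_le <- excl[seq_len(nrow(la)), nrow(la) + seq_len(nrow(env)),
                  drop = FALSE]
  hb <- outer(toupper(la$element) %in% c("N", "O"),
              toupper(env$element) %in% c("N", "O"), "&")

  keep <- which(gap <= max_gap & !excl_le, arr.ind = TRUE)
  if (nrow(keep) == 0) return(out)
  g <- gap[keep]
  g_cls <- g + ifelse(hb[keep], hbond_relax, 0)
  out <- data.frame(
    lig_name = la$name[keep[, 1]],
    env_name = env$name[keep[, 2]],
    env_res = atom_res_key(env)[keep[, 2]],
    distance = d[keep],
    gap = g,
    category = contact_category(g_cls),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$gap), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("contact_list", "data.frame")
  out
}

#' Count bad contacts
#'
#' Number of ligand-environment pairs in the "bad" category; the integer
#' fed into the contacts percentile rank. Zero is the recommended target.
#'
#' @param contacts A `contact_list` from [find_contacts()].
#' @return Non-negative integer.
#' @export
count_bad_contacts <- function(contacts) {
  sum(contacts$category == "bad")
}

#' Export a contact list as TSV
#'
#' @param contacts A `contact_list`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contacts_tsv <- function(contacts, path) {
  utils::write.table(as.data.frame(contacts), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
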