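## Residue types never considered ligand candidates: waters, the 20
## standard amino acids and the standard (deoxy)ribonucleotides.
default_exclusions <- function() {
  c("HOH", "WAT", "DOD",
    "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
    "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
    "A", "C", "G", "U", "DA", "DC", "DG", "DT")
}

#' Select the ligand of interest
#'
#' Non-polymer residue types are enumerated and ranked by dictionary
#' non-hydrogen atom count (largest first, ties broken by comp-id, instances
#' by chain then sequence number). Each instance must pass four criteria:
#' the comp-id is not annotated obsolete, no atom of the instance appears in
#' a covalent link record, no atom has an alternate-location code, and the
#' experimental data are available and not twinned. On rejection the next
#' candidate is considered; every rejection is logged with its reason.
#'
#' @param s An `lqc_structure`.
#' @param dict Restraint dictionary used for the non-H atom counts; types
#'   without an entry are skipped with reason `"no-dictionary"`.
#' @param ccd_obsolete Character vector of obsolete comp-ids.
#' @param exclusions Residue types never treated as ligands.
#' @return An object of class `lqc_ligand` with fields `comp_id`, `chain`,
#'   `seq_id`, `atoms`, `n_heavy` and the `rejections` log. An empty
#'   selection has `NA` comp_id.
#' @export
select_ligand <- function(s, dict, ccd_obsolete = character(),
                          exclusions = default_exclusions()) {
  at <- s$atoms
  cand <- at[!at$is_polymer & !(at$comp_id %in% exclusions), , drop = FALSE]
  rejections <- data.frame(instance = character(), reason = character(),
                           stringsAsFactors = FALSE)
  add_rej <- function(instance, reason) {
    rejections <<- rbind(rejections,
                         data.frame(instance = instance, reason = reason,
                                    stringsAsFactors = FALSE))
  }

  if (nrow(cand) == 0) {
    add_rej("-", "no-ligand")
    return(empty_ligand(rejections))
  }

  types <- unique(cand$comp_id)
  n_heavy <- vapply(types, function(cc) dict_n_heavy(dict, cc), integer(1))
  for (cc in types[is.na(n_heavy)]) add_rej(cc, "no-dictionary")
  types <- types[!is.na(n_heavy)]
  n_heavy <- n_heavy[!is.na(n_heavy)]
  if (length(types) == 0) return(empty_ligand(rejections))
  ord <- order(-n_heavy, types)
  types <- types[ord]
  n_heavy <- n_heavy[ord]

  linked_key <- character()
  if (nrow(s$links) > 0)
    linked_key <- c(paste(s$links$chain1, s$links$seq_id1, s$links$name1),
                    paste(s$links$chain2, s$links$seq_id2, s$links$name2))

  for (k in seq_along(types)) {
    cc <- types[k]
    inst <- unique(cand[cand$comp_id == cc, c("chain", "seq_id")])
    inst <- inst[order(inst$chain, inst$seq_id), , drop = FALSE]
    for (i in seq_len(nrow(inst))) {
      lab <- paste0(cc, "/", inst$chain[i], "/", inst$seq_id[i])
      lig_at <- cand[cand$comp_id == cc & cand$chain == inst$chain[i] &
                       cand$seq_id == inst$seq_id[i], , drop = FALSE]
      if (cc %in% ccd_obsolete) { add_rej(lab, "obsolete"); next }
      if (any(paste(lig_at$chain, lig_at$seq_id, lig_at$name) %in%
                linked_key)) { add_rej(lab, "link record"); next }
      if (any(nzchar(lig_at$altloc))) {
        add_rej(lab, "alternate configurations"); next
      }
      if (!isTRUE(s$data_meta$data_available) ||
            isTRUE(s$data_meta$twinned)) {
        add_rej(lab, "data unavailable or twinned"); next
      }
      return(structure(
        list(comp_id = cc, chain = inst$chain[i], seq_id = inst$seq_id[i],
             atoms = lig_at, n_heavy = unname(n_heavy[k]),
             rejections = rejections),
        class = "lqc_ligand"))
    }
  }
  empty_ligand(rejections)
}

empty_ligand <- function(rejections) {
  structure(
    list(comp_id = NA_character_, chain = NA_character_,
         seq_id = NA_integer_, atoms = empty_atom_table(),
         n_heavy = NA_integer_, rejections = rejections),
    class = "lqc_ligand"
  )
}

#' @export
print.lqc_ligand <- function(x, ...) {
  if (is.na(x$comp_id)) {
    cat("No ligand selected;", nrow(x$rejections), "rejection(s)\n")
  } else {
    cat("Ligand", x$comp_id, "chain", x$chain, "residue", x$seq_id,
        "-", x$n_heavy, "non-H atoms (dictionary)\n")
  }
  if (nrow(x$rejections) > 0) {
    cat("Rejections:\n")
    for (i in seq_len(nrow(x$rejections)))
      cat(" ", x$rejections$instance[i], "->", x$rejections$reason[i], "\n")
  }
  invisible(x)
}

is_empty_ligand <- function(lig) is.na(lig$comp_id)

#' Environment atoms around a ligand
#'
#' All non-ligand atoms within `radius` of any ligand atom, in a
#' deterministic order (chain, sequence number, atom name).
#'
#' @param s An `lqc_structure`.
#' @param lig An `lqc_ligand`.
#' @param radius Cutoff in angstroms, positive.
#' @return Atom table of environment atoms.
#' @export
neighbourhood <- function(s, lig, radius) {
  stopifnot(radius > 0)
  at <- s$atoms
  lig_key <- paste(lig$atoms$chain, lig$atoms$seq_id, lig$atoms$name)
  env <- at[!(paste(at$chain, at$seq_id, at$name) %in% lig_key), ,
            drop = FALSE]
  if (nrow(env) == 0 || nrow(lig$atoms) == 0)
    return(env[order(env$chain, env$seq_id, env$name), , drop = FALSE])
  d <- atom_dist(env, lig$atoms)
  keep <- apply(d, 1, min) <= radius
  env <- env[keep, , drop = FALSE]
  env[order(env$chain, env$seq_id, env$name), , drop = FALSE]
}
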