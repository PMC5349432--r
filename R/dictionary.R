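#' Build a restraint dictionary in code
#'
#' A restraint dictionary holds, per chemical component id, the atom list
#' and the bond / angle restraints (target value and standard deviation)
#' used for geometry Z-scoring. It stands in for empirically derived
#' reference distributions: the target is the mean and sigma the spread of
#' the preferred values.
#'
#' @param entries Named list; each element is a list with data frames
#'   `atoms` (`name`, `element`), `bonds` (`atom1`, `atom2`, `target` in
#'   angstroms, `sigma` in angstroms) and `angles` (`atom1`, `atom2`,
#'   `atom3`, `target` in degrees, `sigma` in degrees).
#' @return An object of class `lqc_dictionary`.
#' @export
new_dictionary <- function(entries) {
  for (comp in names(entries)) {
    e <- entries[[comp]]
    validate_dict_entry(e, comp)
  }
  structure(entries, class = "lqc_dictionary")
}

validate_dict_entry <- function(e, comp) {
  stopifnot(is.data.frame(e$atoms), is.data.frame(e$bonds),
            is.data.frame(e$angles))
  known <- e$atoms$name
  check_names <- function(df, cols, kind) {
    for (cl in cols) {
      bad <- setdiff(df[[cl]], known)
      if (length(bad) > 0)
        stop("unknown atom name in ", kind, " restraint of ", comp, ": ",
             paste(bad, collapse = ", "))
    }
  }
  if (nrow(e$bonds) > 0) {
    check_names(e$bonds, c("atom1", "atom2"), "bond")
    if (any(e$bonds$sigma <= 0)) stop("non-positive bond sigma in ", comp)
    key <- apply(e$bonds[, c("atom1", "atom2")], 1,
                 function(r) paste(sort(r), collapse = "-"))
    if (anyDuplicated(key))
      stop("duplicate restraint: bond ", key[duplicated(key)][1],
           " in ", comp)
  }
  if (nrow(e$angles) > 0) {
    check_names(e$angles, c("atom1", "atom2", "atom3"), "angle")
    if (any(e$angles$sigma <= 0)) stop("non-positive angle sigma in ", comp)
    key <- apply(e$angles[, c("atom1", "atom2", "atom3")], 1, function(r)
      paste(r[2], paste(sort(r[c(1, 3)]), collapse = "-")))
    if (anyDuplicated(key))
      stop("duplicate restraint: angle ", key[duplicated(key)][1],
           " in ", comp)
  }
  invisible(e)
}

#' Number of non-hydrogen atoms in a dictionary entry
#'
#' The dictionary count is authoritative for ligand size ranking, not the
#' atoms present in any particular model instance.
#'
#' @param dict An `lqc_dictionary`.
#' @param comp_id Component id.
#' @return Integer count.
#' @export
dict_n_heavy <- function(dict, comp_id) {
  e <- dict[[comp_id]]
  if (is.null(e)) return(NA_integer_)
  sum(toupper(e$atoms$element) != "H")
}

#' Load a monomer-library style restraint dictionary
#'
#' Reads mmCIF restraint blocks: `_chem_comp_atom` (atom names and
#' elements), `_chem_comp_bond` (`value_dist`, `value_dist_esd`) and
#' `_chem_comp_angle` (`value_angle`, `value_angle_esd`), one or more
#' components per file.
#'
#' @param path Path to the dictionary mmCIF file.
#' @return An `lqc_dictionary`.
#' @export
load_dictionary <- function(path) {
  blocks <- read_cif(path)
  entries <- list()
  for (bn in names(blocks)) {
    blk <- blocks[[bn]]
    at <- blk$chem_comp_atom
    if (is.null(at)) next
    for (comp in unique(at$comp_id)) {
      atoms <- data.frame(
        name = at$atom_id[at$comp_id == comp],
        element = cif_col(at, "type_symbol", "type_energy")[at$comp_id == comp],
        stringsAsFactors = FALSE
      )
      bonds <- data.frame(atom1 = character(), atom2 = character(),
                          target = numeric(), sigma = numeric(),
                          stringsAsFactors = FALSE)
      bd <- blk$chem_comp_bond
      if (!is.null(bd) && any(bd$comp_id == comp)) {
        bd <- bd[bd$comp_id == comp, , drop = FALSE]
        if (is.null(bd$value_dist_esd))
          stop("missing sigma column value_dist_esd in ", path)
        bonds <- data.frame(
          atom1 = bd$atom_id_1, atom2 = bd$atom_id_2,
          target = as.numeric(bd$value_dist),
          sigma = as.numeric(bd$value_dist_esd),
          stringsAsFactors = FALSE
        )
      }
      angles <- data.frame(atom1 = character(), atom2 = character(),
                           atom3 = character(), target = numeric(),
                           sigma = numeric(), stringsAsFactors = FALSE)
      ag <- blk$chem_comp_angle
      if (!is.null(ag) && any(ag$comp_id == comp)) {
        ag <- ag[ag$comp_id == comp, , drop = FALSE]
        if (is.null(ag$value_angle_esd))
          stop("missing sigma column value_angle_esd in ", path)
        angles <- data.frame(
          atom1 = ag$atom_id_1, atom2 = ag$atom_id_2, atom3 = ag$atom_id_3,
          target = as.numeric(ag$value_angle),
          sigma = as.numeric(ag$value_angle_esd),
          stringsAsFactors = FALSE
        )
      }
      entries[[comp]] <- list(atoms = atoms, bonds = bonds, angles = angles)
    }
  }
  new_dictionary(entries)
}

#' Write a restraint dictionary as monomer-library mmCIF
#'
#' @param dict An `lqc_dictionary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dictionary <- function(dict, path) {
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  for (comp in names(dict)) {
    e <- dict[[comp]]
    writeLines(paste0("data_comp_", comp), con)
    cif_write_loop(con, "chem_comp_atom", data.frame(
      comp_id = comp, atom_id = e$atoms$name,
      type_symbol = e$atoms$element, stringsAsFactors = FALSE))
    if (nrow(e$bonds) > 0)
      cif_write_loop(con, "chem_comp_bond", data.frame(
        comp_id = comp, atom_id_1 = e$bonds$atom1, atom_id_2 = e$bonds$atom2,
        value_dist = sprintf("%.4f", e$bonds$target),
        value_dist_esd = sprintf("%.4f", e$bonds$sigma),
        stringsAsFactors = FALSE))
    if (nrow(e$angles) > 0)
      cif_write_loop(con, "chem_comp_angle", data.frame(
        comp_id = comp, atom_id_1 = e$angles$atom1,
        atom_id_2 = e$angles$atom2, atom_id_3 = e$angles$atom3,
        value_angle = sprintf("%.3f", e$angles$target),
        value_angle_esd = sprintf("%.3f", e$angles$sigma),
        stringsAsFactors = FALSE))
    writeLines("", con)
  }
  invisible(path)
}
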