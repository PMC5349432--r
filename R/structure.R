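#' Assemble a structure object
#'
#' A structure bundles an atom table, covalent link records (PDB `LINK` /
#' mmCIF `_struct_conn`), data-availability metadata and the nominal
#' resolution. Links whose endpoints cannot be matched to atoms are kept but
#' flagged dangling.
#'
#' @param atoms Atom table (see [atom_table()]).
#' @param links Data frame with columns `name1, comp_id1, chain1, seq_id1,
#'   name2, comp_id2, chain2, seq_id2`; may be empty.
#' @param data_meta List with logical flags `data_available` and `twinned`.
#' @param resolution_nominal Nominal resolution in angstroms, or `NA`.
#' @return An object of class `lqc_structure`.
#' @export
new_structure <- function(atoms = empty_atom_table(), links = empty_links(),
                          data_meta = list(data_available = TRUE,
                                           twinned = FALSE),
                          resolution_nominal = NA_real_) {
  validate_atoms(atoms)
  if (nrow(links) > 0) {
    key <- paste(atoms$chain, atoms$seq_id, atoms$name)
    found1 <- paste(links$chain1, links$seq_id1, links$name1) %in% key
    found2 <- paste(links$chain2, links$seq_id2, links$name2) %in% key
    links$dangling <- !(found1 & found2)
    if (any(links$dangling)) warning("dangling link record(s) flagged")
  } else {
    links <- empty_links()
  }
  structure(
    list(atoms = atoms, links = links, data_meta = data_meta,
         resolution_nominal = resolution_nominal),
    class = "lqc_structure"
  )
}

empty_links <- function() {
  data.frame(name1 = character(), comp_id1 = character(),
             chain1 = character(), seq_id1 = integer(),
             name2 = character(), comp_id2 = character(),
             chain2 = character(), seq_id2 = integer(),
             dangling = logical(), stringsAsFactors = FALSE)
}

#' @export
print.lqc_structure <- function(x, ...) {
  cat("Structure:", nrow(x$atoms), "atoms,", nrow(x$links), "links\n")
  np <- sum(!x$atoms$is_polymer)
  cat("  non-polymer atoms:", np,
      " nominal resolution:", x$resolution_nominal, "\n")
  invisible(x)
}

element_from_name <- function(name) {
  el <- sub("[^A-Za-z].*$", "", sub("^[0-9]*", "", name))
  substr(el, 1, 1)
}

#' Read a coordinate file
#'
#' PDB files are parsed with \pkg{bio3d}; mmCIF files with the package's CIF
#' reader. `LINK` records and `_struct_conn` rows of covalent type are both
#' captured. Only model 1 is used; polymer/non-polymer classification comes
#' from the record type (`ATOM` vs `HETATM` / `group_PDB`).
#'
#' @param path Path to the file.
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (by extension).
#' @param data_available,twinned Data-availability metadata; these are
#'   caller-supplied flags, not recomputed from reflection data.
#' @return An [new_structure()] object.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           data_available = TRUE, twinned = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif$|\\.mmcif$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  meta <- list(data_available = data_available, twinned = twinned)
  if (format == "pdb") read_structure_pdb(path, meta)
  else read_structure_mmcif(path, meta)
}

read_structure_pdb <- function(path, meta) {
  raw <- readLines(path, warn = FALSE)
  rec <- substr(raw, 1, 6)
  has_atoms <- any(rec %in% c("ATOM  ", "HETATM"))

  res_nom <- NA_real_
  rl <- grep("^REMARK   2 RESOLUTION", raw, value = TRUE)
  if (length(rl) > 0) {
    v <- suppressWarnings(as.numeric(
      sub(".*RESOLUTION\\.?\\s+([0-9.]+).*", "\\1", rl[1])))
    if (!is.na(v)) res_nom <- v
  }

  links <- empty_links()
  ll <- raw[startsWith(raw, "LINK")]
  if (length(ll) > 0) {
    fw <- function(s, a, b) trimws(substr(s, a, b))
    links <- data.frame(
      name1 = fw(ll, 13, 16), comp_id1 = fw(ll, 18, 20),
      chain1 = fw(ll, 22, 22),
      seq_id1 = as.integer(fw(ll, 23, 26)),
      name2 = fw(ll, 43, 46), comp_id2 = fw(ll, 48, 50),
      chain2 = fw(ll, 52, 52),
      seq_id2 = as.integer(fw(ll, 53, 56)),
      dangling = FALSE, stringsAsFactors = FALSE
    )
  }

  if (!has_atoms)
    return(new_structure(links = links, data_meta = meta,
                         resolution_nominal = res_nom))

  p <- tryCatch(
    bio3d::read.pdb(path, rm.alt = FALSE, multi = FALSE, verbose = FALSE),
    error = function(e) stop("failed to parse PDB file ", path, ": ",
                             conditionMessage(e))
  )
  a <- p$atom
  el <- a$elesy
  miss <- is.na(el) | !nzchar(trimws(el))
  if (any(miss)) {
    warning("element symbol missing for ", sum(miss),
            " atom(s); derived from atom name")
    el[miss] <- element_from_name(a$elety[miss])
  }
  atoms <- atom_table(
    name = a$elety, element = trimws(el),
    x = a$x, y = a$y, z = a$z,
    occ = ifelse(is.na(a$o), 1, a$o), b = ifelse(is.na(a$b), 0, a$b),
    altloc = ifelse(is.na(a$alt), "", a$alt),
    comp_id = a$resid, chain = ifelse(is.na(a$chain), "", a$chain),
    seq_id = a$resno, is_polymer = a$type == "ATOM"
  )
  new_structure(atoms, links, meta, res_nom)
}

cif_col <- function(tbl, ..., default = NULL) {
  for (nm in c(...)) if (!is.null(tbl[[nm]])) return(tbl[[nm]])
  default
}

read_structure_mmcif <- function(path, meta) {
  blocks <- tryCatch(read_cif(path),
                     error = function(e) stop("failed to parse mmCIF file ",
                                              path, ": ", conditionMessage(e)))
  if (length(blocks) == 0) return(new_structure(data_meta = meta))
  blk <- blocks[[1]]

  res_nom <- NA_real_
  for (cat_nm in c("refine", "reflns")) {
    v <- cif_col(blk[[cat_nm]], "ls_d_res_high", "d_resolution_high")
    if (!is.null(v)) {
      v <- suppressWarnings(as.numeric(v[1]))
      if (!is.na(v)) { res_nom <- v; break }
    }
  }

  atoms <- empty_atom_table()
  as_tbl <- blk$atom_site
  if (!is.null(as_tbl)) {
    if (!is.null(as_tbl$pdbx_PDB_model_num)) {
      m1 <- as_tbl$pdbx_PDB_model_num ==
        as_tbl$pdbx_PDB_model_num[1]
      as_tbl <- as_tbl[m1, , drop = FALSE]
    }
    alt <- cif_col(as_tbl, "label_alt_id", default = ".")
    alt[alt %in% c(".", "?")] <- ""
    el <- cif_col(as_tbl, "type_symbol", default = NA)
    nm <- cif_col(as_tbl, "auth_atom_id", "label_atom_id")
    if (any(is.na(el) | el %in% c(".", "?"))) {
      warning("element symbol missing in atom_site; derived from atom name")
      bad <- is.na(el) | el %in% c(".", "?")
      el[bad] <- element_from_name(nm[bad])
    }
    occ <- cif_col(as_tbl, "occupancy", default = "1")
    b <- cif_col(as_tbl, "B_iso_or_equiv", default = "0")
    atoms <- atom_table(
      name = nm, element = el,
      x = as.numeric(as_tbl$Cartn_x), y = as.numeric(as_tbl$Cartn_y),
      z = as.numeric(as_tbl$Cartn_z),
      occ = as.numeric(occ), b = as.numeric(b), altloc = alt,
      comp_id = cif_col(as_tbl, "auth_comp_id", "label_comp_id"),
      chain = cif_col(as_tbl, "auth_asym_id", "label_asym_id"),
      seq_id = as.integer(cif_col(as_tbl, "auth_seq_id", "label_seq_id")),
      is_polymer = cif_col(as_tbl, "group_PDB", default = "HETATM") == "ATOM"
    )
  }

  links <- empty_links()
  sc <- blk$struct_conn
  if (!is.null(sc)) {
    keep <- grepl("covale|metalc|link", sc$conn_type_id, ignore.case = TRUE)
    sc <- sc[keep, , drop = FALSE]
    if (nrow(sc) > 0) {
      links <- data.frame(
        name1 = cif_col(sc, "ptnr1_label_atom_id", "ptnr1_auth_atom_id"),
        comp_id1 = cif_col(sc, "ptnr1_auth_comp_id", "ptnr1_label_comp_id"),
        chain1 = cif_col(sc, "ptnr1_auth_asym_id", "ptnr1_label_asym_id"),
        seq_id1 = as.integer(cif_col(sc, "ptnr1_auth_seq_id",
                                     "ptnr1_label_seq_id")),
        name2 = cif_col(sc, "ptnr2_label_atom_id", "ptnr2_auth_atom_id"),
        comp_id2 = cif_col(sc, "ptnr2_auth_comp_id", "ptnr2_label_comp_id"),
        chain2 = cif_col(sc, "ptnr2_auth_asym_id", "ptnr2_label_asym_id"),
        seq_id2 = as.integer(cif_col(sc, "ptnr2_auth_seq_id",
                                     "ptnr2_label_seq_id")),
        dangling = FALSE, stringsAsFactors = FALSE
      )
    }
  }
  new_structure(atoms, links, meta, res_nom)
}

#' Write a structure to PDB or mmCIF
#'
#' @param s An `lqc_structure`.
#' @param path Output path; format from `format` or the extension.
#' @param format `"pdb"`, `"mmcif"` or `"auto"`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.cif$|\\.mmcif$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  if (format == "pdb") write_structure_pdb(s, path)
  else write_structure_mmcif(s, path)
  invisible(path)
}

format_link_record <- function(lk) {
  sprintf("LINK        %-4s %3s %1s%4d                %-4s %3s %1s%4d",
          lk$name1, lk$comp_id1, lk$chain1, lk$seq_id1,
          lk$name2, lk$comp_id2, lk$chain2, lk$seq_id2)
}

write_structure_pdb <- function(s, path) {
  at <- s$atoms
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  if (nrow(at) > 0) {
    bio3d::write.pdb(
      file = tmp,
      xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
      type = ifelse(at$is_polymer, "ATOM", "HETATM"),
      resno = at$seq_id, resid = at$comp_id, eleno = seq_len(nrow(at)),
      elety = at$name, chain = at$chain, alt = ifelse(nzchar(at$altloc),
                                                      at$altloc, ""),
      o = at$occ, b = at$b, elesy = at$element
    )
    body <- readLines(tmp, warn = FALSE)
  } else body <- "END"
  head <- character()
  if (!is.na(s$resolution_nominal))
    head <- c(head, sprintf("REMARK   2 RESOLUTION. %8.2f ANGSTROMS.",
                            s$resolution_nominal))
  if (nrow(s$links) > 0)
    head <- c(head, vapply(seq_len(nrow(s$links)),
                           function(i) format_link_record(s$links[i, ]),
                           character(1)))
  writeLines(c(head, body), path)
}

write_structure_mmcif <- function(s, path) {
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines("data_ligandqc", con)
  at <- s$atoms
  if (!is.na(s$resolution_nominal))
    writeLines(sprintf("_refine.ls_d_res_high %.3f", s$resolution_nominal),
               con)
  if (nrow(at) > 0) {
    tbl <- data.frame(
      group_PDB = ifelse(at$is_polymer, "ATOM", "HETATM"),
      id = seq_len(nrow(at)),
      type_symbol = at$element,
      label_atom_id = at$name,
      label_alt_id = ifelse(nzchar(at$altloc), at$altloc, "."),
      auth_comp_id = at$comp_id,
      auth_asym_id = at$chain,
      auth_seq_id = at$seq_id,
      Cartn_x = sprintf("%.4f", at$x),
      Cartn_y = sprintf("%.4f", at$y),
      Cartn_z = sprintf("%.4f", at$z),
      occupancy = sprintf("%.3f", at$occ),
      B_iso_or_equiv = sprintf("%.3f", at$b),
      stringsAsFactors = FALSE
    )
    cif_write_loop(con, "atom_site", tbl)
  }
  if (nrow(s$links) > 0) {
    lk <- s$links
    tbl <- data.frame(
      id = seq_len(nrow(lk)), conn_type_id = "covale",
      ptnr1_label_atom_id = lk$name1, ptnr1_auth_comp_id = lk$comp_id1,
      ptnr1_auth_asym_id = lk$chain1, ptnr1_auth_seq_id = lk$seq_id1,
      ptnr2_label_atom_id = lk$name2, ptnr2_auth_comp_id = lk$comp_id2,
      ptnr2_auth_asym_id = lk$chain2, ptnr2_auth_seq_id = lk$seq_id2,
      stringsAsFactors = FALSE
    )
    cif_write_loop(con, "struct_conn", tbl)
  }
}

#' Read an obsolete component-id list
#'
#' Plain-text stand-in for the Chemical Component Dictionary obsolescence
#' annotation: one comp-id per line, `#` comments allowed.
#'
#' @param path File path.
#' @return Character vector of comp-ids.
#' @export
read_obsolete_list <- function(path) {
  x <- trimws(sub("#.*$", "", readLines(path, warn = FALSE)))
  x[nzchar(x)]
}
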