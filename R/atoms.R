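#' @keywords internal
"_PACKAGE"

## Element data shared across the density, masking and contact code.
## Atomic numbers cover the elements that occur in ligands and protein
## pockets; anything else falls back with a warning.
.element_z <- c(
  H = 1, C = 6, N = 7, O = 8, F = 9, NA. = 11, MG = 12, P = 15, S = 16,
  CL = 17, K = 19, CA = 20, MN = 25, FE = 26, CO = 27, NI = 28, CU = 29,
  ZN = 30, SE = 34, BR = 35, I = 53
)

#' Atomic number of an element symbol
#'
#' @param element Character vector of element symbols (case-insensitive).
#' @return Integer vector of atomic numbers; unknown symbols return 6
#'   (carbon) with a warning.
#' @keywords internal
atomic_number <- function(element) {
  key <- toupper(element)
  key[key == "NA"] <- "NA."
  z <- .element_z[key]
  if (anyNA(z)) {
    warning("unknown element symbol(s): ",
            paste(unique(element[is.na(z)]), collapse = ", "),
            "; using Z = 6")
    z[is.na(z)] <- 6
  }
  unname(z)
}

#' Build an atom table
#'
#' Atoms are represented throughout the package as a plain data frame with
#' one row per atom. Coordinates are orthogonal angstroms.
#'
#' @param name Atom labels (e.g. `"C1"`).
#' @param element Element symbols; must be non-empty.
#' @param x,y,z Coordinates in angstroms.
#' @param occ Occupancies in `[0, 1]`.
#' @param b Isotropic displacement parameters (B-factors), in squared
#'   angstroms, non-negative.
#' @param altloc One-character alternate-location codes; `""` means blank.
#' @param comp_id Three-character residue (chemical component) codes.
#' @param chain Chain identifiers.
#' @param seq_id Residue sequence numbers.
#' @param is_polymer Logical; `TRUE` for polymer (ATOM) records.
#' @return A data frame with the twelve atom columns.
#' @export
atom_table <- function(name, element, x, y, z, occ = 1, b = 20,
                       altloc = "", comp_id = "LIG", chain = "A",
                       seq_id = 1L, is_polymer = FALSE) {
  n <- length(name)
  at <- data.frame(
    name = as.character(name),
    element = as.character(element),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    occ = rep_len(as.numeric(occ), n),
    b = rep_len(as.numeric(b), n),
    altloc = rep_len(as.character(altloc), n),
    comp_id = rep_len(as.character(comp_id), n),
    chain = rep_len(as.character(chain), n),
    seq_id = rep_len(as.integer(seq_id), n),
    is_polymer = rep_len(as.logical(is_polymer), n),
    stringsAsFactors = FALSE
  )
  validate_atoms(at)
  at
}

empty_atom_table <- function() {
  atom_table(character(), character(), numeric(), numeric(), numeric())
}

validate_atoms <- function(at) {
  stopifnot(is.data.frame(at))
  if (nrow(at) == 0) return(invisible(at))
  if (any(!nzchar(at$element))) stop("atoms with empty element symbol")
  if (any(at$occ < 0 | at$occ > 1)) stop("occupancy outside [0, 1]")
  if (any(at$b < 0)) stop("negative B-factor")
  invisible(at)
}

## Unique residue key used for grouping and ordering.
atom_res_key <- function(at) paste(at$chain, at$seq_id, at$comp_id, sep = "|")

## n x m matrix of pairwise distances between two atom tables.
atom_dist <- function(a, b) {
  dx <- outer(a$x, b$x, "-")
  dy <- outer(a$y, b$y, "-")
  dz <- outer(a$z, b$z, "-")
  sqrt(dx * dx + dy * dy + dz * dz)
}
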