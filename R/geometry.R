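## Sigma floors for geometry Z-scores: reference spreads derived from few
## observations can be implausibly tight, which would overstate distortion,
## so sigmas are floored before the Z is formed.
.sigma_floor <- c(bond = 0.015, angle = 1.0)

#' Geometry Z-score with sigma floor
#'
#' `Z = (observed - target) / max(sigma, floor)` with floors of 0.015
#' angstroms for bonds and 1 degree for angles. Flooring can only shrink
#' `|Z|`: weak reference data never strengthens a distortion claim.
#'
#' @param observed Measured value (angstroms or degrees).
#' @param target Reference mean.
#' @param sigma Reference standard deviation, positive.
#' @param kind `"bond"` or `"angle"`.
#' @return Signed dimensionless Z.
#' @export
geometry_z <- function(observed, target, sigma, kind = c("bond", "angle")) {
  kind <- match.arg(kind)
  stopifnot(all(sigma > 0))
  (observed - target) / pmax(sigma, .sigma_floor[[kind]])
}

bond_length <- function(p1, p2) sqrt(sum((p1 - p2)^2))

bond_angle_deg <- function(p1, p2, p3) {
  v1 <- p1 - p2
  v2 <- p3 - p2
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) return(NA_real_)
  cosang <- sum(v1 * v2) / (n1 * n2)
  acos(max(-1, min(1, cosang))) * 180 / pi
}

#' Likelihood class of a geometry Z-value
#'
#' Slider convention: `|Z| <= 1` is "likely", `|Z| >= 5` "unlikely", with a
#' linear scale in between. The numeric slider value runs 0 (likely) to 1
#' (unlikely).
#'
#' @param z Z-value(s).
#' @return Data frame with `slider` in `[0, 1]` and `label`.
#' @export
z_likelihood_class <- function(z) {
  a <- pmin(1, pmax(0, (abs(z) - 1) / 4))
  data.frame(slider = a,
             label = ifelse(abs(z) <= 1, "likely",
                            ifelse(abs(z) >= 5, "unlikely", "intermediate")),
             stringsAsFactors = FALSE)
}

#' Geometry Z report for a ligand
#'
#' Measures every dictionary bond (Euclidean length) and angle (arccos of
#' the normalized dot product, degrees) on the ligand coordinates, forms
#' floored Z-scores, and reports the feature with the largest absolute Z
#' ("Z-worst"). Restraints involving hydrogens, atoms missing from the
#' instance, or degenerate zero-length vectors are skipped with a warning
#' and counted. Ties on `|Z|` keep the first feature in dictionary order,
#' bonds before angles.
#'
#' @param lig An `lqc_ligand` (or a list with `comp_id` and `atoms`).
#' @param dict An `lqc_dictionary` containing the ligand's comp-id.
#' @return Object of class `geometry_z_report` with `features`, `z_worst`,
#'   `n_features`, `n_skipped`.
#' @export
z_worst_report <- function(lig, dict) {
  e <- dict[[lig$comp_id]]
  if (is.null(e)) stop("no dictionary entry for ", lig$comp_id)
  at <- lig$atoms
  pos <- function(nm) {
    i <- match(nm, at$name)
    if (is.na(i)) return(NULL)
    c(at$x[i], at$y[i], at$z[i])
  }
  h_names <- e$atoms$name[toupper(e$atoms$element) == "H"]
  n_skipped <- 0L
  rows <- list()

  add_feature <- function(kind, atoms_lbl, observed, target, sigma) {
    rows[[length(rows) + 1L]] <<- data.frame(
      kind = kind, atoms = atoms_lbl, observed = observed, target = target,
      sigma_raw = sigma, sigma_eff = max(sigma, .sigma_floor[[kind]]),
      z = geometry_z(observed, target, sigma, kind),
      stringsAsFactors = FALSE)
  }

  for (i in seq_len(nrow(e$bonds))) {
    b <- e$bonds[i, ]
    if (b$atom1 %in% h_names || b$atom2 %in% h_names) next
    p1 <- pos(b$atom1); p2 <- pos(b$atom2)
    if (is.null(p1) || is.null(p2)) {
      warning("bond ", b$atom1, "-", b$atom2, " skipped: atom missing")
      n_skipped <- n_skipped + 1L
      next
    }
    add_feature("bond", paste(b$atom1, b$atom2, sep = "-"),
                bond_length(p1, p2), b$target, b$sigma)
  }
  for (i in seq_len(nrow(e$angles))) {
    a <- e$angles[i, ]
    if (any(c(a$atom1, a$atom2, a$atom3) %in% h_names)) next
    p1 <- pos(a$atom1); p2 <- pos(a$atom2); p3 <- pos(a$atom3)
    if (is.null(p1) || is.null(p2) || is.null(p3)) {
      warning("angle ", a$atom1, "-", a$atom2, "-", a$atom3,
              " skipped: atom missing")
      n_skipped <- n_skipped + 1L
      next
    }
    obs <- bond_angle_deg(p1, p2, p3)
    if (is.na(obs)) {
      warning("angle ", a$atom1, "-", a$atom2, "-", a$atom3,
              " skipped: zero-length bond vector")
      n_skipped <- n_skipped + 1L
      next
    }
    add_feature("angle", paste(a$atom1, a$atom2, a$atom3, sep = "-"),
                obs, a$target, a$sigma)
  }

  features <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(kind = character(), atoms = character(), observed = numeric(),
               target = numeric(), sigma_raw = numeric(),
               sigma_eff = numeric(), z = numeric(), stringsAsFactors = FALSE)
  z_worst <- if (nrow(features) > 0)
    features[which.max(abs(features$z)), , drop = FALSE] else NULL
  structure(list(features = features, z_worst = z_worst,
                 n_features = nrow(features), n_skipped = n_skipped),
            class = "geometry_z_report")
}

#' @export
print.geometry_z_report <- function(x, ...) {
  cat("Geometry Z report:", x$n_features, "feature(s),",
      x$n_skipped, "skipped\n")
  if (!is.null(x$z_worst))
    cat(sprintf("  Z-worst: %s %s  obs %.3f  target %.3f  Z = %+.2f\n",
                x$z_worst$kind, x$z_worst$atoms, x$z_worst$observed,
                x$z_worst$target, x$z_worst$z))
  invisible(x)
}

#' Export a geometry report
#'
#' @param rep A `geometry_z_report`.
#' @param path Output path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_geometry_report <- function(rep, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(
      list(features = rep$features, z_worst = rep$z_worst,
           n_features = rep$n_features, n_skipped = rep$n_skipped),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(rep$features, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
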