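#' Validate a ligand in a structure
#'
#' Runs the full validation pipeline: select the ligand of interest,
#' compute the masked direct-map and difference-map correlations against an
#' observed density grid, score the internal geometry against the restraint
#' dictionary (Z-worst), count bad contacts with the environment, and — if
#' a reference store is supplied — percentile-rank the four metrics and
#' combine them into the overall score.
#'
#' The "direct map" is the observed grid minus the density synthesized from
#' all non-ligand atoms (a real-space ligand-omit map); the difference map
#' is observed minus the full model. A stage that cannot be computed (for
#' example a zero difference map on perfectly self-consistent data) yields
#' `NA` for its metric rather than failing the run.
#'
#' @param s An `lqc_structure`.
#' @param dict An `lqc_dictionary`.
#' @param observed Observed [density_grid()]; if `NULL`, a self-consistent
#'   map is synthesized from the model itself.
#' @param store Optional `metric_store` for percentile ranking.
#' @param accession Identifier recorded in the metric set.
#' @param refl Optional [reflection_set()] for the effective resolution.
#' @param ccd_obsolete Obsolete comp-id list for selection.
#' @param spec A [mask_spec()].
#' @param env_radius Environment radius in angstroms (masking, Q-Q context
#'   and contacts).
#' @param vdw_radii vdW radius table for contacts.
#' @param orientations Metric orientations for ranking.
#' @param w Gaussian softening width for map synthesis.
#' @return Object of class `ligand_validation`: the selection, metric set,
#'   contact list, geometry report, Q-Q data and (optionally) rank report.
#' @export
validate_ligand <- function(s, dict, observed = NULL, store = NULL,
                            accession = "unknown", refl = NULL,
                            ccd_obsolete = character(),
                            spec = mask_spec(), env_radius = 4,
                            vdw_radii = default_vdw_radii(),
                            orientations = default_orientations(),
                            w = 0.5) {
  lig <- select_ligand(s, dict, ccd_obsolete)
  if (is_empty_ligand(lig))
    return(structure(list(ligand = lig, metrics = NULL, rank = NULL),
                     class = "ligand_validation"))

  if (is.null(observed)) {
    observed <- calc_model_map(s$atoms, grid_for_atoms(s$atoms), w = w)
  }
  env <- neighbourhood(s, lig, env_radius)
  pts <- ligand_grid_points(observed, lig$atoms, env, spec)

  at <- s$atoms
  in_lig <- paste(at$chain, at$seq_id, at$name) %in%
    paste(lig$atoms$chain, lig$atoms$seq_id, lig$atoms$name)
  env_map <- calc_model_map(at[!in_lig, , drop = FALSE], observed, w = w)
  lig_map <- calc_model_map(lig$atoms, observed, w = w)
  full_map <- calc_model_map(at, observed, w = w)
  direct <- grid_sub(observed, env_map)
  ## full model recomputed in one pass so that an observed map rendered from
  ## the model itself cancels exactly (identically zero difference grid)
  diff <- grid_sub(observed, full_map)

  safe <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  cc_direct <- safe(map_correlation(direct, lig_map, pts))
  cc_diff <- safe(diff_map_correlation(diff, lig_map, pts))
  qq <- tryCatch(qq_data(diff, pts), error = function(e) NULL)

  geom <- z_worst_report(lig, dict)
  z_worst <- if (is.null(geom$z_worst)) NA_real_ else geom$z_worst$z

  contacts <- find_contacts(lig, env, radii = vdw_radii, links = s$links,
                            dict = dict)
  n_bad <- count_bad_contacts(contacts)

  r_eff <- if (!is.null(refl)) effective_resolution(refl) else NA_real_
  m <- metric_set(accession, lig$comp_id, cc_direct, cc_diff, z_worst,
                  n_bad, chain = lig$chain, seq_id = lig$seq_id,
                  r_eff = r_eff, r_nom = s$resolution_nominal)

  rank <- NULL
  if (!is.null(store) && store_size(store) > 0 && rankable(m))
    rank <- rank_report(store, m, orientations)

  structure(list(ligand = lig, metrics = m, geometry = geom,
                 contacts = contacts, qq = qq, rank = rank,
                 n_points = length(pts)),
            class = "ligand_validation")
}

#' @export
print.ligand_validation <- function(x, ...) {
  if (is_empty_ligand(x$ligand)) {
    cat("No rankable ligand.\n")
    print(x$ligand)
    return(invisible(x))
  }
  m <- x$metrics
  cat(sprintf("Ligand %s %s/%d (%s)\n", m$comp_id, m$chain, m$seq_id,
              m$accession))
  cat(sprintf("  direct-map correlation  cc_direct = %s\n",
              format(m$cc_direct, digits = 4)))
  cat(sprintf("  diff-map correlation    cc_diff   = %s\n",
              format(m$cc_diff, digits = 4)))
  cat(sprintf("  geometry Z-worst        z_worst   = %s\n",
              format(m$z_worst_signed, digits = 4)))
  cat(sprintf("  bad contacts            n_bad     = %d\n", m$n_bad))
  if (!is.na(m$r_eff))
    cat(sprintf("  effective resolution    r_eff     = %.3f A\n", m$r_eff))
  if (!is.null(x$rank)) print(x$rank)
  invisible(x)
}

#' Serialize a validation result to JSON
#'
#' Versioned machine-readable report: the selection, the four metrics, the
#' geometry features and the percentile ranks when present.
#'
#' @param x A `ligand_validation`.
#' @param path Optional output path; if `NULL` the JSON string is returned.
#' @return `path`, or the JSON string.
#' @export
validation_to_json <- function(x, path = NULL) {
  body <- list(schema = "ligandqc-report/1")
  if (is_empty_ligand(x$ligand)) {
    body$ligand <- NULL
    body$rejections <- x$ligand$rejections
  } else {
    m <- x$metrics
    body$ligand <- list(comp_id = m$comp_id, chain = m$chain,
                        seq_id = m$seq_id, accession = m$accession,
                        n_heavy = x$ligand$n_heavy)
    body$metrics <- list(cc_direct = m$cc_direct, cc_diff = m$cc_diff,
                         z_worst = m$z_worst_signed, n_bad = m$n_bad,
                         r_eff = m$r_eff, r_nom = m$r_nom)
    body$geometry <- list(n_features = x$geometry$n_features,
                          n_skipped = x$geometry$n_skipped,
                          z_worst = x$geometry$z_worst)
    body$rejections <- x$ligand$rejections
    if (!is.null(x$rank)) body$ranks <- rank_report_to_list(x$rank)
  }
  js <- jsonlite::toJSON(body, auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null", pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}
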