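#' Assemble a metric set
#'
#' The four scored metrics for one ligand — direct-map correlation,
#' difference-map correlation, geometry Z-worst (absolute value is ranked;
#' the signed value is kept alongside) and the bad-contact count — plus
#' optional resolution metadata.
#'
#' @param accession Free-text structure id.
#' @param comp_id Component id.
#' @param cc_direct,cc_diff Correlations in `[-1, 1]`.
#' @param z_worst Signed Z-worst value.
#' @param n_bad Non-negative integer bad-contact count.
#' @param chain,seq_id Instance identifiers (optional).
#' @param r_eff,r_nom Effective / nominal resolution in angstroms (optional).
#' @param deposition_date Optional `"YYYY-MM-DD"` string.
#' @return A one-row data frame of class `metric_set`.
#' @export
metric_set <- function(accession, comp_id, cc_direct, cc_diff, z_worst,
                       n_bad, chain = NA_character_, seq_id = NA_integer_,
                       r_eff = NA_real_, r_nom = NA_real_,
                       deposition_date = NA_character_) {
  if (any(abs(cc_direct) > 1, na.rm = TRUE)) stop("cc_direct outside [-1, 1]")
  if (any(abs(cc_diff) > 1, na.rm = TRUE)) stop("cc_diff outside [-1, 1]")
  if (any(n_bad < 0 | n_bad != round(n_bad), na.rm = TRUE))
    stop("n_bad must be a non-negative integer")
  n <- length(accession)
  m <- data.frame(accession = accession,
                  comp_id = rep_len(comp_id, n),
                  chain = rep_len(chain, n),
                  seq_id = rep_len(as.integer(seq_id), n),
                  cc_direct = rep_len(cc_direct, n),
                  cc_diff = rep_len(cc_diff, n),
                  z_worst = rep_len(abs(z_worst), n),
                  z_worst_signed = rep_len(z_worst, n),
                  n_bad = rep_len(as.integer(n_bad), n),
                  r_eff = rep_len(r_eff, n), r_nom = rep_len(r_nom, n),
                  deposition_date = rep_len(deposition_date, n),
                  stringsAsFactors = FALSE)
  class(m) <- c("metric_set", "data.frame")
  m
}

rankable <- function(m) {
  !is.na(m$cc_direct) && !is.na(m$cc_diff) && !is.na(m$z_worst) &&
    !is.na(m$n_bad)
}

.store_version <- "1"

#' Create an empty metric store
#'
#' The store is a reference corpus of per-ligand metric sets against which
#' new ligands are percentile-ranked. It lives in memory as a data frame
#' and persists as versioned CSV ([write_store()] / [read_store()]).
#'
#' @return An object of class `metric_store`.
#' @export
metric_store <- function() {
  structure(list(records = metric_set(character(), character(), numeric(),
                                      numeric(), numeric(), integer())[0, ],
                 version = .store_version),
            class = "metric_store")
}

#' @export
print.metric_store <- function(x, ...) {
  cat("Metric store (schema v", x$version, "): ", nrow(x$records),
      " record(s)\n", sep = "")
  invisible(x)
}

#' Number of records in a metric store
#'
#' @param store A `metric_store`.
#' @return Integer count.
#' @export
store_size <- function(store) nrow(store$records)

#' Add a metric set to a store
#'
#' A record with the same (accession, comp_id, chain, seq_id) key replaces
#' the existing one with a warning.
#'
#' @param store A `metric_store`.
#' @param m A [metric_set()] (one or more rows).
#' @return The updated store.
#' @export
store_metrics <- function(store, m) {
  if (!rankable(m[1, ]) && nrow(m) == 1)
    stop("record is not rankable: missing metric value(s)")
  key <- function(df) paste(df$accession, df$comp_id, df$chain, df$seq_id)
  dup <- key(store$records) %in% key(m)
  if (any(dup)) {
    warning("replacing ", sum(dup), " existing record(s)")
    store$records <- store$records[!dup, , drop = FALSE]
  }
  store$records <- rbind(store$records, as.data.frame(m))
  rownames(store$records) <- NULL
  store
}

#' Query a store by accession
#'
#' @param store A `metric_store`.
#' @param accession Accession id.
#' @return The matching records.
#' @export
store_query <- function(store, accession) {
  store$records[store$records$accession == accession, , drop = FALSE]
}

#' Persist / load a metric store as CSV
#'
#' The first line is a `# ligandqc-store v<version>` comment; the rest is
#' plain CSV, one record per row.
#'
#' @param store A `metric_store`.
#' @param path File path.
#' @return `path` (write) or the store (read).
#' @export
write_store <- function(store, path) {
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(paste0("# ligandqc-store v", store$version), con)
  utils::write.csv(store$records, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_store
#' @export
read_store <- function(path) {
  first <- readLines(path, n = 1)
  if (!grepl("^# ligandqc-store v", first))
    stop("not a ligandqc store file: ", path)
  version <- sub("^# ligandqc-store v", "", first)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  st <- metric_store()
  st$version <- version
  df$chain <- as.character(df$chain)
  df$accession <- as.character(df$accession)
  df$comp_id <- as.character(df$comp_id)
  st$records <- df
  st
}

## Orient metric values so that larger is better.
orient_values <- function(x, orientation) {
  switch(orientation,
         "higher-better" = x,
         "lower-better" = -x,
         "nearer-zero-better" = -abs(x),
         stop("unknown orientation: ", orientation))
}

#' Default metric orientations
#'
#' Direct-map correlation: higher is better. Difference-map correlation:
#' nearer zero is better (either sign flags mismodelling). Z-worst and bad
#' contacts: lower is better.
#'
#' @return Named character vector.
#' @export
default_orientations <- function() {
  c(cc_direct = "higher-better", cc_diff = "nearer-zero-better",
    z_worst = "lower-better", n_bad = "lower-better")
}

#' Percentile rank of a metric value against a store
#'
#' After orienting so larger is better, the mid-rank percentile is
#' `100 * (n_worse + 0.5 * n_equal) / N`.
#'
#' @param store A non-empty `metric_store`.
#' @param metric One of `"cc_direct"`, `"cc_diff"`, `"z_worst"`, `"n_bad"`.
#' @param value The probe value.
#' @param orientation Orientation string; defaults per
#'   [default_orientations()].
#' @return Percentile in `[0, 100]`.
#' @export
percentile_rank <- function(store, metric, value,
                            orientation = default_orientations()[[metric]]) {
  ref <- store$records[[metric]]
  ref <- ref[!is.na(ref)]
  if (length(ref) == 0) stop("empty store for metric ", metric)
  ov <- orient_values(value, orientation)
  or <- orient_values(ref, orientation)
  100 * (sum(or < ov) + 0.5 * sum(or == ov)) / length(or)
}

## Percentiles of every stored record against the store itself
## (vectorized mid-rank: rank_avg - 0.5 equals n_worse + n_eq/2).
store_self_percentiles <- function(store, metric, orientation) {
  or <- orient_values(store$records[[metric]], orientation)
  100 * (rank(or, ties.method = "average") - 0.5) / length(or)
}

#' Combined ligand score
#'
#' Merges the four percentile ranks into a single score
#' `S = (R_dir^2 + R_diff^2 + R_mogul^2 + R_bumps^2) / 400`, in
#' `[0, 100]`. The squared form spreads out the top end relative to a
#' linear sum: a ligand excellent on three metrics and mediocre on one
#' outscores one mediocre-plus on all four with the same linear sum.
#'
#' @param r_dir,r_diff,r_mogul,r_bumps Percentile ranks in `[0, 100]`.
#' @return Score in `[0, 100]`, strictly increasing in each rank.
#' @export
combined_score <- function(r_dir, r_diff, r_mogul, r_bumps) {
  r <- cbind(r_dir, r_diff, r_mogul, r_bumps)
  if (any(r < 0 | r > 100)) stop("ranks must lie in [0, 100]")
  as.numeric((r_dir^2 + r_diff^2 + r_mogul^2 + r_bumps^2) / 400)
}

#' Percentile-rank report for a ligand
#'
#' Ranks the four metrics of `m` against the store, combines them with
#' [combined_score()], and expresses the combined score as an overall
#' percentile against the combined scores of every stored record.
#'
#' @param store A non-empty `metric_store`.
#' @param m A [metric_set()].
#' @param orientations Named orientation vector.
#' @return Object of class `rank_report` with `R_dir`, `R_diff`, `R_mogul`,
#'   `R_bumps`, `S`, `overall_percentile`.
#' @export
rank_report <- function(store, m, orientations = default_orientations()) {
  if (store_size(store) == 0) stop("empty store")
  r_dir <- percentile_rank(store, "cc_direct", m$cc_direct,
                           orientations[["cc_direct"]])
  r_diff <- percentile_rank(store, "cc_diff", m$cc_diff,
                            orientations[["cc_diff"]])
  r_mogul <- percentile_rank(store, "z_worst", m$z_worst,
                             orientations[["z_worst"]])
  r_bumps <- percentile_rank(store, "n_bad", m$n_bad,
                             orientations[["n_bad"]])
  s <- combined_score(r_dir, r_diff, r_mogul, r_bumps)
  s_all <- combined_score(
    store_self_percentiles(store, "cc_direct", orientations[["cc_direct"]]),
    store_self_percentiles(store, "cc_diff", orientations[["cc_diff"]]),
    store_self_percentiles(store, "z_worst", orientations[["z_worst"]]),
    store_self_percentiles(store, "n_bad", orientations[["n_bad"]]))
  overall <- 100 * (sum(s_all < s) + 0.5 * sum(s_all == s)) / length(s_all)
  structure(list(R_dir = r_dir, R_diff = r_diff, R_mogul = r_mogul,
                 R_bumps = r_bumps, S = s, overall_percentile = overall),
            class = "rank_report")
}

#' @export
print.rank_report <- function(x, ...) {
  cat("Percentile ranks (0 = worst, 100 = best):\n")
  cat(sprintf("  direct-map cc   R_dir   = %6.2f\n", x$R_dir))
  cat(sprintf("  diff-map cc     R_diff  = %6.2f\n", x$R_diff))
  cat(sprintf("  geometry Z      R_mogul = %6.2f\n", x$R_mogul))
  cat(sprintf("  bad contacts    R_bumps = %6.2f\n", x$R_bumps))
  cat(sprintf("  combined score  S = %.2f (overall percentile %.1f)\n",
              x$S, x$overall_percentile))
  invisible(x)
}

rank_report_to_list <- function(x) {
  list(R_dir = x$R_dir, R_diff = x$R_diff, R_mogul = x$R_mogul,
       R_bumps = x$R_bumps, S = x$S,
       overall_percentile = x$overall_percentile)
}

#' Histogram counts of a metric by nominal-resolution bin
#'
#' Partition the stored records into nominal-resolution bins and return the
#' per-bin histogram of a metric. Resolution is descriptive only; it plays
#' no part in scoring.
#'
#' @param store A `metric_store`.
#' @param metric Metric column name.
#' @param res_breaks Numeric bin edges for `r_nom`, angstroms.
#' @param metric_breaks Bin edges for the metric (default 10 equal bins).
#' @return Matrix of counts, resolution bins by metric bins.
#' @export
store_resolution_bins <- function(store, metric,
                                  res_breaks = c(0, 1.5, 2, 2.5, 3, Inf),
                                  metric_breaks = NULL) {
  df <- store$records[!is.na(store$records$r_nom), , drop = FALSE]
  v <- df[[metric]]
  if (is.null(metric_breaks))
    metric_breaks <- seq(min(v), max(v), length.out = 11)
  rb <- cut(df$r_nom, res_breaks, include.lowest = TRUE)
  mb <- cut(v, metric_breaks, include.lowest = TRUE)
  table(rb, mb)
}
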