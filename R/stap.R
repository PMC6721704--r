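#' Spatial aggregation scoring configuration
#'
#' @param sphere_radius Angstrom; residues whose centers lie within this
#'   distance of a central residue contribute to its score (default 10,
#'   the conventional sphere for structural aggregation analysis).
#' @param burial_cutoff RSA below which a residue's own score is nulled:
#'   a residue essentially without solvent exposure cannot nucleate
#'   surface aggregation.
#' @param distance_weight `"linear"` (w(d) = 1 - d/sphere_radius) or a
#'   function of the distance vector; must satisfy w(0) = 1,
#'   w(sphere_radius) = 0 and be non-increasing.
#' @return List of class `stap_config`.
#' @export
stap_config <- function(sphere_radius = 10, burial_cutoff = 0.05,
                        distance_weight = "linear") {
  stopifnot(sphere_radius > 0, burial_cutoff >= 0, burial_cutoff < 1)
  w <- if (is.function(distance_weight)) {
    distance_weight
  } else if (identical(distance_weight, "linear")) {
    function(d) { w <- 1 - d / sphere_radius; w[w < 0] <- 0; w }
  } else {
    stop_stapr("invalid_config", "unknown distance_weight '%s'",
               as.character(distance_weight))
  }
  if (abs(w(0) - 1) > 1e-12 || abs(w(sphere_radius)) > 1e-12) {
    stop_stapr("invalid_config",
               "distance weight must satisfy w(0)=1 and w(sphere_radius)=0")
  }
  structure(list(sphere_radius = sphere_radius,
                 burial_cutoff = burial_cutoff,
                 weight = w,
                 weight_name = if (is.function(distance_weight)) "custom"
                               else distance_weight),
            class = "stap_config")
}

#' Effective residue centers
#'
#' The spatial position of a residue for sphere construction: the centroid
#' of its side-chain heavy atoms; the C-alpha for glycine or when no
#' side-chain heavy atoms are present (including coarse C-alpha-only
#' models).
#'
#' @param record a `structure_record`.
#' @return Numeric matrix, one row per residue (x, y, z in Angstrom).
#' @export
residue_centers <- function(record) {
  at <- record$atoms
  backbone <- c("N", "CA", "C", "O", "OXT")
  pos <- residue_positions(record)
  out <- matrix(NA_real_, length(pos), 3,
                dimnames = list(NULL, c("x", "y", "z")))
  for (k in seq_along(pos)) {
    sel <- at$position == pos[k]
    side <- sel & !(at$atom_name %in% backbone) & at$element != "H"
    use <- if (any(side) && at$aa[sel][1] != "G") side else sel & at$atom_name == "CA"
    if (!any(use)) use <- sel  # degenerate residue: all atoms
    out[k, ] <- colMeans(at[use, c("x", "y", "z")])
  }
  out
}

#' Structural aggregation propensity (STAP) of a chain
#'
#' For every residue i with relative exposure at or above the burial
#' cutoff, the spatial score is the exposure- and distance-weighted sum of
#' intrinsic propensities over all residues within the sphere:
#' \deqn{score_i = \sum_{j: d_{ij} \le R} w(d_{ij}) \, e_j \, a3v(aa_j)}
#' with \eqn{d_{ij}} the distance between effective residue centers,
#' \eqn{e_j} the (clamped) relative solvent accessibility of residue j and
#' w the configured distance kernel (w(0) = 1, so residue i contributes its
#' own full exposure-weighted propensity).  Buried residues score exactly
#' 0.  The protein-level STAP is the arithmetic mean of the per-residue
#' scores over all residues, buried zeros included.
#'
#' @param record a `structure_record`.
#' @param exposure an `exposure_profile` computed on the same record
#'   (computed on the fly when omitted).
#' @param scale intrinsic propensity scale (named numeric, 20 entries).
#' @param config a [stap_config()].
#' @return Object of class `stap_result`: data.frame columns position, aa,
#'   relative_sasa, score; plus fields `average_score` and `config`.
#' @export
stap <- function(record, exposure = NULL, scale = a3v_scale(),
                 config = stap_config()) {
  if (n_residues(record) == 0L) stop_stapr("empty_chain", "empty structure")
  if (is.null(exposure)) exposure <- relative_exposure(record)
  stopifnot(inherits(exposure, "exposure_profile"),
            nrow(exposure) == n_residues(record))
  aa <- record_sequence(record, collapse = FALSE)
  e <- pmin(exposure$relative_sasa, 1)
  intr <- unname(scale[aa])

  ctr <- residue_centers(record)
  D <- as.matrix(stats::dist(ctr))
  W <- config$weight(D)
  dim(W) <- dim(D)  # scalar-recycling kernels may drop dims
  W[D > config$sphere_radius] <- 0
  score <- as.numeric(W %*% (e * intr))
  score[e < config$burial_cutoff] <- 0

  structure(list(table = data.frame(position = exposure$position, aa = aa,
                                    relative_sasa = exposure$relative_sasa,
                                    score = score, stringsAsFactors = FALSE),
                 score = score,
                 average_score = mean(score),
                 config = config),
            class = "stap_result")
}

#' @export
print.stap_result <- function(x, ...) {
  cat(sprintf("<stap_result> %d residues, average score (STAP) = %.3f\n",
              length(x$score), x$average_score))
  invisible(x)
}

#' Apply naive point mutations to a structure
#'
#' Relabels the residue identity at the given positions and discards atoms
#' beyond the C-beta (no side-chain rebuilding); exposure must be
#' recomputed by the caller on the returned record.
#'
#' @param record a `structure_record`.
#' @param mutations data.frame with columns `position`, `wt_aa`, `new_aa`
#'   (one-letter codes), or a list of `c(position, wt, new)` triplets.
#' @return A new `structure_record` with `source_id` suffixed by the
#'   mutation string.
#' @export
apply_mutations <- function(record, mutations) {
  if (!is.data.frame(mutations)) {
    mutations <- do.call(rbind, lapply(mutations, function(m) {
      data.frame(position = as.integer(m[[1]]), wt_aa = m[[2]],
                 new_aa = m[[3]], stringsAsFactors = FALSE)
    }))
  }
  at <- record$atoms
  keep_names <- c("N", "CA", "C", "O", "OXT", "CB")
  for (k in seq_len(nrow(mutations))) {
    p <- mutations$position[k]
    sel <- at$position == p
    if (!any(sel)) {
      stop_stapr("position_not_found", "position %d absent from '%s'",
                 p, record$source_id)
    }
    if (at$aa[sel][1] != mutations$wt_aa[k]) {
      stop_stapr("mutation_mismatch",
                 "position %d is %s, not %s", p, at$aa[sel][1],
                 mutations$wt_aa[k])
    }
    at$aa[sel] <- mutations$new_aa[k]
    drop <- sel & !(at$atom_name %in% keep_names)
    if (any(drop)) at <- at[!drop, , drop = FALSE]
  }
  tag <- paste(sprintf("%s%d%s", mutations$wt_aa, mutations$position,
                       mutations$new_aa), collapse = ",")
  structure_record(paste0(record$source_id, ":", tag), at,
                   resolution = record$resolution,
                   model_index = record$model_index)
}

#' Score a chain end to end (exposure + STAP)
#'
#' Convenience wrapper: computes the exposure profile and the spatial
#' score in one call; optionally writes the per-residue TSV and a
#' score-coloured PDB.
#'
#' @param pdb path or PDB text, or an already-parsed `structure_record`.
#' @param chain_id chain to score (ignored for a parsed record).
#' @param config a [stap_config()].
#' @param surface_threshold RSA surface flag threshold.
#' @param tsv,colored_pdb optional output paths.
#' @return A `stap_result` (with the exposure profile attached as
#'   `$exposure`).
#' @export
score_structure <- function(pdb, chain_id = "A", config = stap_config(),
                            surface_threshold = 0.25,
                            tsv = NULL, colored_pdb = NULL) {
  record <- if (inherits(pdb, "structure_record")) pdb
            else read_structure(pdb, chain_id)
  exposure <- relative_exposure(record, surface_threshold = surface_threshold)
  result <- stap(record, exposure, config = config)
  result$exposure <- exposure
  result$source_id <- record$source_id
  if (!is.null(tsv)) {
    utils::write.table(result$table, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(colored_pdb)) write_scored_structure(record, result, colored_pdb)
  result
}
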