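#' Read / write a proteome annotation table
#'
#' Tab-separated, one row per protein, with the documented header:
#' id, average_score, na4vss, abundance_log10, length, location, n_ts,
#' essential, operon_id, oligomeric_state.  Missing values are empty or
#' NA.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_proteome_table <- function(path) {
  t <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  required <- c("id", "average_score")
  miss <- setdiff(required, names(t))
  if (length(miss)) {
    stop_stapr("invalid_table", "missing column(s): %s",
               paste(miss, collapse = ", "))
  }
  if (anyDuplicated(t$id)) stop_stapr("invalid_table", "duplicate protein ids")
  t
}

#' @rdname read_proteome_table
#' @param table data.frame to write.
#' @export
write_proteome_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Score every PDB file of a directory
#'
#' Batch STAP scoring: each `*.pdb` file is read, scored and summarized in
#' one table that can be merged with an annotation TSV by id.
#'
#' @param dir directory of PDB files.
#' @param chain_id chain to score in each file.
#' @param config a [stap_config()].
#' @return data.frame: id (file stem), n_residues, average_score.
#' @export
score_structure_dir <- function(dir, chain_id = "A", config = stap_config()) {
  files <- sort(list.files(dir, pattern = "\\.pdb$", full.names = TRUE))
  if (!length(files)) stop_stapr("empty_input", "no PDB files in '%s'", dir)
  rows <- lapply(files, function(f) {
    res <- score_structure(f, chain_id, config = config)
    data.frame(id = sub("\\.pdb$", "", basename(f)),
               n_residues = length(res$score),
               average_score = res$average_score,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run one named proteome analysis
#'
#' Dispatcher over the statistical layer: "abundance" and "length" run the
#' quartile stratification of the structural score (plus the sequence
#' score when present), "operon" the dispersion and LA/HA analyses,
#' "location" the per-compartment stratification, "composition" the
#' surface amino-acid comparison (requires exposure profiles), "ssi" the
#' supersaturation analysis by oligomeric state.  Membrane proteins are
#' excluded from the abundance, length, operon and composition analyses
#' (they differ systematically in charge and hydrophobicity); the location
#' analysis uses all rows.
#'
#' @param table proteome table.
#' @param analysis one of "abundance", "length", "operon", "location",
#'   "composition", "ssi".
#' @param fraction tail fraction for stratified comparisons.
#' @param seed RNG seed (permutation tests).
#' @param exposure_groups for "composition": list with `low` and `high`
#'   lists of `exposure_profile` objects.
#' @return Analysis-specific result list; every element carries a
#'   `manifest` entry with row counts and exclusions.
#' @export
run_analysis <- function(table,
                         analysis = c("abundance", "length", "operon",
                                      "location", "composition", "ssi"),
                         fraction = 0.25, seed = 1L,
                         exposure_groups = NULL) {
  analysis <- match.arg(analysis)
  soluble <- table[!table$location %in% c("inner_membrane", "outer_membrane"), ,
                   drop = FALSE]
  res <- switch(analysis,
    abundance = {
      out <- list(stap = stratify_and_compare(soluble, "average_score",
                                              "abundance_log10", fraction),
                  correlation = correlation(soluble, "abundance_log10",
                                            "average_score"))
      if ("na4vss" %in% names(soluble)) {
        out$na4vss <- stratify_and_compare(soluble, "na4vss",
                                           "abundance_log10", fraction)
      }
      out
    },
    length = {
      out <- list(stap = stratify_and_compare(soluble, "average_score",
                                              "length", fraction),
                  length_by_stap = stratify_and_compare(soluble, "length",
                                                        "average_score",
                                                        fraction))
      if ("na4vss" %in% names(soluble)) {
        out$na4vss <- stratify_and_compare(soluble, "na4vss", "length",
                                           fraction)
      }
      out
    },
    operon = list(dispersion = operon_dispersion(soluble, seed = seed),
                  la_ha = la_ha_split(soluble)),
    location = {
      locs <- split(table$average_score, table$location)
      list(by_location = lapply(locs, .group_summary),
           im_by_ts = if (any(table$n_ts > 0))
             correlation(table[table$location == "inner_membrane", ,
                               drop = FALSE], "n_ts", "average_score")
           else NULL)
    },
    composition = {
      if (is.null(exposure_groups)) {
        stop_stapr("empty_input",
                   "composition analysis needs exposure_groups")
      }
      list(composition = surface_composition_compare(exposure_groups$low,
                                                     exposure_groups$high))
    },
    ssi = list(ssi = ssi_group_analysis(soluble, fraction = fraction))
  )
  res$manifest <- run_manifest(analysis,
                               config = list(fraction = fraction, seed = seed),
                               n_rows = nrow(table),
                               n_analyzed = if (analysis == "location")
                                 nrow(table) else nrow(soluble),
                               n_excluded_membrane = nrow(table) - nrow(soluble))
  res
}

#' Build a run manifest
#'
#' A plain-list record of what produced an output: the analysis name, the
#' effective configuration, seeds, software version and row counts, so
#' every reported number is traceable.
#'
#' @param subcommand analysis / pipeline step name.
#' @param config effective configuration (list).
#' @param ... further fields (row counts, exclusions, input digests).
#' @return List of class `run_manifest`.
#' @export
run_manifest <- function(subcommand, config = list(), ...) {
  structure(list(subcommand = subcommand,
                 config = config,
                 version = as.character(utils::packageVersion("stapr")),
                 ...),
            class = "run_manifest")
}

#' Write a manifest (or any result list) as JSON
#' @param x list to serialize.
#' @param path output path.
#' @export
write_manifest <- function(x, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("jsonlite is required to write manifests")
  }
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
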