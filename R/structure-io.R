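#' @importFrom bio3d read.pdb write.pdb
NULL

#' Construct a structure record
#'
#' A `structure_record` holds one protein chain: an ordered atom table with
#' author residue numbering preserved verbatim, plus the crystallographic
#' resolution (NA for NMR) and the model index the coordinates came from.
#'
#' @param source_id identifier, e.g. "1ABC_A".
#' @param atoms data.frame with columns `position` (integer residue number),
#'   `aa` (one-letter code), `atom_name`, `element`, `x`, `y`, `z` (Angstrom).
#' @param resolution numeric (Angstrom) or NA.
#' @param model_index integer, which model the coordinates were taken from.
#' @return An object of class `structure_record`.
#' @export
structure_record <- function(source_id, atoms, resolution = NA_real_,
                             model_index = 1L) {
  stopifnot(is.data.frame(atoms),
            all(c("position", "aa", "atom_name", "element",
                  "x", "y", "z") %in% names(atoms)))
  if (nrow(atoms) == 0L) {
    stop_stapr("empty_chain", "no atoms in structure '%s'", source_id)
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop_stapr("invalid_coordinates",
               "non-finite coordinates in structure '%s'", source_id)
  }
  pos <- unique(atoms$position)
  if (any(diff(pos) <= 0)) {
    stop_stapr("invalid_numbering",
               "residue positions must be strictly increasing in '%s'",
               source_id)
  }
  bad <- setdiff(unique(atoms$aa), amino_acids())
  if (length(bad)) {
    stop_stapr("invalid_residue", "non-standard residue code(s): %s",
               paste(bad, collapse = ", "))
  }
  structure(list(source_id = source_id,
                 atoms = atoms[, c("position", "aa", "atom_name",
                                   "element", "x", "y", "z")],
                 resolution = resolution,
                 model_index = as.integer(model_index)),
            class = "structure_record")
}

#' @export
print.structure_record <- function(x, ...) {
  cat(sprintf("<structure_record> %s: %d residues, %d atoms, %s\n",
              x$source_id, n_residues(x), nrow(x$atoms),
              if (is.na(x$resolution)) "NMR/unknown resolution"
              else sprintf("%.2f A", x$resolution)))
  invisible(x)
}

#' Residue positions of a structure record
#' @param record a `structure_record`.
#' @return Integer vector of author residue numbers, in chain order.
#' @export
residue_positions <- function(record) unique(record$atoms$position)

#' Number of residues in a structure record
#' @param record a `structure_record`.
#' @return Integer.
#' @export
n_residues <- function(record) length(residue_positions(record))

#' One-letter sequence of a structure record
#' @param record a `structure_record`.
#' @param collapse collapse to a single string?
#' @return Character vector of one-letter codes, or a single string.
#' @export
record_sequence <- function(record, collapse = TRUE) {
  aa <- record$atoms$aa[!duplicated(record$atoms$position)]
  if (collapse) paste(aa, collapse = "") else aa
}

# coerce path-or-text input into a path bio3d can read, returning also the
# raw lines (for REMARK parsing)
.pdb_input <- function(pdb) {
  if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb)) {
    return(list(path = pdb, lines = readLines(pdb, warn = FALSE)))
  }
  lines <- unlist(strsplit(pdb, "\n", fixed = TRUE))
  path <- tempfile(fileext = ".pdb")
  writeLines(lines, path)
  list(path = path, lines = lines)
}

.parse_resolution <- function(lines) {
  rem <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (!length(rem)) return(NA_real_)
  txt <- sub("^.*RESOLUTION\\.", "", rem[1])
  m <- regmatches(txt, regexpr("[0-9]+\\.?[0-9]*", txt))
  if (!length(m)) NA_real_ else as.numeric(m)
}

#' Read one chain of a PDB file
#'
#' Parses a PDB file (via bio3d) and returns the requested chain as a
#' `structure_record`.  For multi-model files only model 1 is used.
#' Alternate locations are resolved per atom by highest occupancy, ties by
#' alphabetical altloc id.  HETATM records and waters are excluded, except
#' that substitutable non-standard residues (MSE and friends) are mapped to
#' their standard parent; non-mappable non-standard residues are dropped
#' with a warning.
#'
#' @param pdb path to a PDB file, or PDB text (a string containing newlines,
#'   or a character vector of lines).
#' @param chain_id single chain identifier, e.g. "A".
#' @return A `structure_record`.
#' @export
read_structure <- function(pdb, chain_id) {
  stopifnot(is.character(chain_id), length(chain_id) == 1L)
  inp <- .pdb_input(pdb)
  p <- suppressWarnings(bio3d::read.pdb(inp$path, rm.alt = FALSE,
                                        verbose = FALSE))
  at <- p$atom
  if (!chain_id %in% unique(at$chain)) {
    stop_stapr("chain_not_found", "chain '%s' not found (chains: %s)",
               chain_id, paste(unique(at$chain), collapse = ", "))
  }
  at <- at[at$chain == chain_id, , drop = FALSE]

  # HETATM policy: drop waters and any HETATM residue without a standard parent
  resid3 <- toupper(at$resid)
  mapped <- ifelse(resid3 %in% names(.nonstandard_parent),
                   .nonstandard_parent[resid3], resid3)
  keep <- at$type == "ATOM" | resid3 %in% names(.nonstandard_parent)
  keep <- keep & mapped %in% names(.aa3to1)
  dropped <- unique(resid3[!keep & resid3 != "HOH"])
  if (length(dropped)) {
    warning(sprintf("dropping non-standard residue(s) without standard parent: %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
  }
  at <- at[keep, , drop = FALSE]
  aa1 <- unname(.aa3to1[mapped[keep]])
  if (nrow(at) == 0L) {
    stop_stapr("empty_chain", "no standard residues in chain '%s'", chain_id)
  }

  # altloc resolution: per (residue, atom name) keep highest occupancy,
  # ties broken by alphabetical altloc id
  occ <- ifelse(is.na(at$o), 1, at$o)
  alt <- ifelse(is.na(at$alt), "", at$alt)
  key <- paste(at$resno, at$elety, sep = "\r")
  ord <- order(key, -occ, alt)
  pick <- ord[!duplicated(key[ord])]
  pick <- sort(pick)  # restore file order
  at <- at[pick, , drop = FALSE]
  aa1 <- aa1[pick]

  elesy <- at$elesy
  missing_el <- is.na(elesy) | trimws(elesy) == ""
  # fall back to first letter of the atom name when the element column is blank
  elesy[missing_el] <- substr(trimws(at$elety[missing_el]), 1, 1)

  atoms <- data.frame(position = at$resno, aa = aa1,
                      atom_name = trimws(at$elety),
                      element = toupper(trimws(elesy)),
                      x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  structure_record(source_id = chain_id, atoms = atoms,
                   resolution = .parse_resolution(inp$lines),
                   model_index = 1L)
}

#' Write a structure with per-residue scores in the B-factor column
#'
#' Emits PDB text in which every atom's B-factor carries its residue's
#' spatial aggregation score rounded to 2 decimals — the conventional way
#' structure viewers colour a surface by score.  Round-trips through
#' [read_structure()].
#'
#' @param record a `structure_record`.
#' @param scores a `stap_result` (or numeric vector) with exactly one score
#'   per residue of `record`, in chain order.
#' @param file optional path; when given the text is also written there.
#' @return PDB text as a single string (invisibly when `file` is given).
#' @export
write_scored_structure <- function(record, scores, file = NULL) {
  sc <- if (inherits(scores, "stap_result")) scores$score else as.numeric(scores)
  if (length(sc) != n_residues(record)) {
    stop_stapr("score_mismatch",
               "got %d scores for %d residues", length(sc), n_residues(record))
  }
  at <- record$atoms
  b <- round(sc, 2)[match(at$position, residue_positions(record))]
  path <- if (is.null(file)) tempfile(fileext = ".pdb") else file
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                   resno = at$position,
                   resid = unname(.aa1to3[at$aa]),
                   eleno = seq_len(nrow(at)),
                   elety = at$atom_name,
                   chain = rep(if (nchar(record$source_id) == 1L)
                                 record$source_id else "A", nrow(at)),
                   o = rep(1, nrow(at)),
                   b = b,
                   elesy = at$element)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (is.null(file)) txt else invisible(txt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read back B-factor scores from a scored PDB
#'
#' @param pdb path or PDB text as in [read_structure()].
#' @param chain_id chain identifier.
#' @return data.frame with `position` and `score` (one row per residue).
#' @export
read_structure_scores <- function(pdb, chain_id) {
  inp <- .pdb_input(pdb)
  p <- suppressWarnings(bio3d::read.pdb(inp$path, rm.alt = FALSE,
                                        verbose = FALSE))
  at <- p$atom[p$atom$chain == chain_id & p$atom$type == "ATOM", , drop = FALSE]
  first <- !duplicated(at$resno)
  data.frame(position = at$resno[first], score = at$b[first])
}
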