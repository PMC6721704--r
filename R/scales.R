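#' Intrinsic amino-acid aggregation propensity scale (a3v)
#'
#' The AGGRESCAN per-residue aggregation propensity values, derived
#' experimentally from in vivo aggregation of Abeta42 point mutants in
#' *E. coli* (Conchillo-Sole et al. 2007, BMC Bioinformatics 8:65;
#' de Groot et al. 2006, FEBS J 273:658-668).  Dimensionless; positive
#' values mark aggregation-promoting residues, negative values
#' solubilizing ones.
#'
#' @return Named numeric vector of length 20 (one-letter codes).
#' @export
#' @examples
#' a3v_scale()[c("I", "D")]
a3v_scale <- function() {
  c(A = -0.036, C =  0.604, D = -1.836, E = -1.412, F =  1.754,
    G = -0.535, H = -1.033, I =  1.822, K = -0.931, L =  1.380,
    M =  0.910, N = -0.850, P = -0.334, Q = -1.231, R = -1.240,
    S = -0.294, T = -0.159, V =  1.594, W =  1.037, Y =  1.159)
}

#' Maximum accessible surface area per residue type
#'
#' Theoretical maximum ASA of residue X in an extended Gly-X-Gly
#' tripeptide (Tien et al. 2013, PLoS ONE 8:e80635, "theoretical" column),
#' in Angstrom^2.  Used as the denominator of relative solvent
#' accessibility; glycine has its own entry.
#'
#' @return Named numeric vector of length 20 (one-letter codes), Angstrom^2.
#' @export
max_asa_reference <- function() {
  c(A = 129, C = 167, D = 193, E = 223, F = 240,
    G = 104, H = 224, I = 197, K = 236, L = 201,
    M = 224, N = 195, P = 159, Q = 225, R = 274,
    S = 155, T = 172, V = 174, W = 285, Y = 263)
}

# van der Waals radii by element symbol (Bondi 1964), Angstrom
.vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20,
                P = 1.80, SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85)
.vdw_default <- 1.70

vdw_radius <- function(element) {
  el <- toupper(trimws(element))
  r <- .vdw_radii[el]
  unknown <- is.na(r)
  if (any(unknown)) {
    warning(sprintf("unknown element(s) %s: using default vdW radius %.2f A",
                    paste(unique(el[unknown]), collapse = ", "), .vdw_default),
            call. = FALSE)
    r[unknown] <- .vdw_default
  }
  unname(r)
}

# three-letter -> one-letter amino acid codes, plus substitutable
# non-standard parents (MSE -> MET etc.)
.aa3to1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
.aa1to3 <- structure(names(.aa3to1), names = unname(.aa3to1))
.nonstandard_parent <- c(MSE = "MET", SEC = "CYS", PYL = "LYS",
                         CSO = "CYS", SEP = "SER", TPO = "THR",
                         PTR = "TYR", HYP = "PRO", MLY = "LYS")

#' Standard amino-acid one-letter codes
#' @return Character vector of the 20 standard one-letter codes.
#' @export
amino_acids <- function() unname(.aa3to1)

# split a sequence string into validated one-letter residues
split_residues <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) == 0L) {
    stop_stapr("empty_input", "sequence is empty")
  }
  aa <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(unique(aa), amino_acids())
  if (length(bad)) {
    stop_stapr("invalid_residue",
               sprintf("non-standard residue(s): %s",
                       paste(bad, collapse = ", ")))
  }
  aa
}

# classed conditions: every contract violation raises a condition of class
# c("stapr_<what>", "stapr_error", "error")
stop_stapr <- function(what, msg, ...) {
  stop(structure(class = c(paste0("stapr_", what), "stapr_error",
                           "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}
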