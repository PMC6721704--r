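#' Window size for the sliding propensity average
#'
#' The window grows with sequence length in steps, following the published
#' AGGRESCAN convention: 5 for sequences of up to 75 residues, 7 for
#' 76–175, 9 for 176–300, 11 above 300.
#'
#' @param n sequence length (residues).
#' @return Odd integer window size.
#' @export
aggrescan_window <- function(n) {
  stopifnot(n >= 1)
  if (n <= 75) 5L else if (n <= 175) 7L else if (n <= 300) 9L else 11L
}

#' Per-residue aggregation propensity profile (a4v)
#'
#' Sliding-window average of the intrinsic a3v scale along a sequence.
#' Windows are truncated one-sidedly at the termini (position i averages
#' over the residues within `(window-1)/2` of i that exist), so a
#' homopolymer's profile is exactly flat.
#'
#' @param sequence residue string (one-letter codes).
#' @param window odd integer window size; default from [aggrescan_window()].
#' @return List of class `sequence_profile`: `sequence`, `window`, `a4v`
#'   (numeric, one value per residue).
#' @export
a4v_profile <- function(sequence, window = NULL) {
  aa <- split_residues(sequence)
  n <- length(aa)
  if (is.null(window)) window <- aggrescan_window(n)
  stopifnot(window >= 1, window %% 2 == 1)
  if (n < window) {
    stop_stapr("sequence_too_short",
               "sequence length %d < window %d", n, window)
  }
  v <- unname(a3v_scale()[aa])
  h <- (window - 1L) / 2L
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  a4v <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  structure(list(sequence = paste(aa, collapse = ""),
                 window = as.integer(window), a4v = a4v),
            class = "sequence_profile")
}

#' Length-normalized sequence aggregation score (Na4vSS)
#'
#' The a4v profile summed over the sequence and normalized per 100
#' residues: `100 * sum(a4v) / N`.  Being an average rescaled to a fixed
#' length, it compares the intrinsic (sequence-level) aggregation load of
#' proteins of different sizes.
#'
#' @inheritParams a4v_profile
#' @return Single numeric score (dimensionless).
#' @export
na4vss <- function(sequence, window = NULL) {
  p <- a4v_profile(sequence, window)
  100 * sum(p$a4v) / length(p$a4v)
}

#' Score every sequence of a FASTA file with Na4vSS
#'
#' @param fasta path to a FASTA file of amino-acid sequences.
#' @return data.frame: id, length, window, na4vss.
#' @export
na4vss_fasta <- function(fasta) {
  seqs <- read_fasta(fasta)
  out <- lapply(names(seqs), function(id) {
    s <- seqs[[id]]
    data.frame(id = id, length = nchar(s),
               window = aggrescan_window(nchar(s)),
               na4vss = na4vss(s), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' FASTA reader/writer (seqinr-backed)
#'
#' @param fasta path to a FASTA file.
#' @return Named list of sequence strings.
#' @keywords internal
#' @export
read_fasta <- function(fasta) {
  s <- seqinr::read.fasta(fasta, seqtype = "AA", as.string = TRUE,
                          forceDNAtolower = FALSE)
  stats::setNames(lapply(s, function(x) toupper(as.character(x))), names(s))
}

#' @rdname read_fasta
#' @param seqs named character vector or list of sequences.
#' @param file output path.
#' @export
write_fasta <- function(seqs, file) {
  seqinr::write.fasta(lapply(seqs, function(s) strsplit(s, "")[[1]]),
                      names = names(seqs), file.out = file)
  invisible(file)
}
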