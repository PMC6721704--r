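#' Global pairwise sequence identity
#'
#' Needleman–Wunsch global alignment (match +1, mismatch −1, gap −2,
#' linear gap penalty); identity is the number of identical aligned
#' positions divided by the alignment length (gap columns count in the
#' denominator).
#'
#' @param seq_a,seq_b residue strings (one-letter codes).
#' @return Fraction in \[0, 1\].
#' @export
#' @examples
#' pairwise_identity("ACDEF", "ACDEF")  # 1
pairwise_identity <- function(seq_a, seq_b) {
  a <- split_residues(seq_a)
  b <- split_residues(seq_b)
  n <- length(a); m <- length(b)
  gap <- -2; match <- 1; mismatch <- -1

  # DP over alignment score; traceback tie order: diagonal, up, left
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- gap * (0:n)
  S[1, ] <- gap * (0:m)
  sub <- outer(a, b, function(u, v) ifelse(u == v, match, mismatch))
  for (i in seq_len(n)) {
    # vectorized over j is not possible (left-dependency); row loop in j
    row_prev <- S[i, ]
    row_cur <- S[i + 1, ]
    for (j in seq_len(m)) {
      row_cur[j + 1] <- max(row_prev[j] + sub[i, j],
                            row_prev[j + 1] + gap,
                            row_cur[j] + gap)
    }
    S[i + 1, ] <- row_cur
  }

  i <- n; j <- m; matches <- 0L; len <- 0L
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 && S[i + 1, j + 1] == S[i, j] + sub[i, j]) {
      matches <- matches + (a[i] == b[j])
      i <- i - 1L; j <- j - 1L
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] + gap) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
    len <- len + 1L
  }
  matches / len
}

# best NW alignment score under the same scoring (used by filter tests)
nw_score <- function(seq_a, seq_b, match = 1, mismatch = -1, gap = -2) {
  a <- split_residues(seq_a); b <- split_residues(seq_b)
  n <- length(a); m <- length(b)
  prev <- gap * (0:m)
  for (i in seq_len(n)) {
    cur <- numeric(m + 1)
    cur[1] <- gap * i
    for (j in seq_len(m)) {
      cur[j + 1] <- max(prev[j] + ifelse(a[i] == b[j], match, mismatch),
                        prev[j + 1] + gap, cur[j] + gap)
    }
    prev <- cur
  }
  prev[m + 1]
}

#' Dataset-construction filter configuration
#'
#' The structure-set filters: X-ray resolution cutoff, minimum coverage of
#' the reference full-length sequence, and the redundancy ceiling on global
#' pairwise identity.
#'
#' @param max_resolution Angstrom; X-ray records above this are excluded
#'   (NMR records, resolution NA, pass).
#' @param min_coverage fraction of the full-length sequence that must be
#'   observed in the structure.
#' @param max_identity redundancy ceiling on pairwise identity.
#' @return List of class `dataset_filter_config`.
#' @export
dataset_filter_config <- function(max_resolution = 3.5,
                                  min_coverage = 0.90,
                                  max_identity = 0.40) {
  stopifnot(min_coverage > 0, min_coverage <= 1,
            max_identity > 0, max_identity < 1,
            max_resolution > 0)
  structure(list(max_resolution = max_resolution,
                 min_coverage = min_coverage,
                 max_identity = max_identity),
            class = "dataset_filter_config")
}

#' Apply the dataset-construction filters to a set of structures
#'
#' Drops records by resolution, then by coverage of the reference sequence
#' length, then removes redundancy greedily: records are ranked by
#' resolution (best, i.e. lowest Angstrom, first; NMR last; ties broken by
#' source_id) and each record is kept only if its identity to every
#' already-kept record is at or below the ceiling.
#'
#' @param records list of `structure_record`.
#' @param full_lengths numeric vector of reference full-sequence lengths,
#'   one per record (NA skips the coverage filter for that record, with a
#'   warning).
#' @param config a [dataset_filter_config()].
#' @return List with `kept` (the retained records) and `log`, a data.frame
#'   (source_id, rule, value, threshold) with one row per exclusion.
#' @export
filter_dataset <- function(records, full_lengths = NULL,
                           config = dataset_filter_config()) {
  if (length(records) == 0L) {
    return(list(kept = list(),
                log = data.frame(source_id = character(), rule = character(),
                                 value = numeric(), threshold = numeric())))
  }
  ids <- vapply(records, function(r) r$source_id, character(1))
  if (is.null(full_lengths)) {
    warning("no reference full-sequence lengths supplied: coverage filter skipped",
            call. = FALSE)
    full_lengths <- rep(NA_real_, length(records))
  }
  stopifnot(length(full_lengths) == length(records))

  log <- data.frame(source_id = character(), rule = character(),
                    value = numeric(), threshold = numeric(),
                    stringsAsFactors = FALSE)
  add_log <- function(id, rule, value, threshold) {
    log[nrow(log) + 1L, ] <<- list(id, rule, value, threshold)
  }

  res <- vapply(records, function(r) r$resolution %||% NA_real_, numeric(1))
  keep <- rep(TRUE, length(records))
  for (k in seq_along(records)) {
    if (!is.na(res[k]) && res[k] > config$max_resolution) {
      keep[k] <- FALSE
      add_log(ids[k], "resolution", res[k], config$max_resolution)
      next
    }
    if (!is.na(full_lengths[k])) {
      cov <- n_residues(records[[k]]) / full_lengths[k]
      if (cov < config$min_coverage) {
        keep[k] <- FALSE
        add_log(ids[k], "coverage", cov, config$min_coverage)
      }
    }
  }

  idx <- which(keep)
  # greedy redundancy removal: best resolution first, NMR last, ties by id
  ord <- idx[order(ifelse(is.na(res[idx]), Inf, res[idx]), ids[idx])]
  kept_idx <- integer()
  for (k in ord) {
    sk <- record_sequence(records[[k]])
    redundant_with <- NA_real_
    for (j in kept_idx) {
      idy <- pairwise_identity(sk, record_sequence(records[[j]]))
      if (idy > config$max_identity) { redundant_with <- idy; break }
    }
    if (is.na(redundant_with)) {
      kept_idx <- c(kept_idx, k)
    } else {
      add_log(ids[k], "identity", redundant_with, config$max_identity)
    }
  }
  kept_idx <- sort(kept_idx)  # preserve input order in the output
  list(kept = records[kept_idx], log = log)
}
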