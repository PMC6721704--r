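#' Derive a child seed from a master seed
#'
#' Fixed splitting rule (one Lehmer step plus an offset) used to expand one
#' user-supplied seed into independent per-component seeds; every derived
#' seed stays a valid 32-bit integer.
#'
#' @param seed master seed (integer).
#' @param k child index.
#' @return Integer seed.
#' @export
derive_seed <- function(seed, k) {
  m <- 2147483629
  as.integer((((as.double(seed) %% m) * 48271) %% m + k) %% m)
}

# run `expr` under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv, inherits = FALSE))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = .GlobalEnv)
    else assign(".Random.seed", old, .GlobalEnv)
  })
  set.seed(seed)
  expr
}

.charged_aa <- c("D", "E", "K", "R")
.aromatic_aa <- c("F", "Y", "W")
.neutral_surface_aa <- c("S", "T", "N", "Q", "G", "P", "H", "A")
.buried_aa <- c("L", "I", "V", "M", "A", "C")

#' Generate a coarse-grained compact globular chain
#'
#' Builds a C-alpha-only chain by a seeded self-avoiding random walk with
#' 3.8 Angstrom steps, then collapses it toward its centroid until the
#' radius of gyration reaches the globular target
#' (`compactness * 2.2 * n^0.38` Angstrom), relaxing steric overlaps
#' between collapse steps.  Residues are then classified buried/surface by
#' relative exposure in the coarse SASA mode, and surface residues are
#' assigned charged (D/E/K/R), aromatic (F/Y/W) or neutral identities
#' according to the configured fractions; buried residues are drawn from
#' hydrophobics.  Fully deterministic for a fixed seed.
#'
#' @param n_residues chain length (>= 5).
#' @param surface_charged_fraction,surface_aromatic_fraction expected
#'   fractions of charged / aromatic residues among surface positions
#'   (non-negative, sum <= 1).
#' @param compactness multiplier on the globular radius-of-gyration target.
#' @param seed integer RNG seed.
#' @param surface_threshold RSA threshold for the buried/surface call.
#' @param source_id identifier for the generated record.
#' @return List: `record` (a C-alpha-only `structure_record`), `sequence`
#'   (one-letter string), `exposure` (the `exposure_profile` used for the
#'   surface classification).
#' @export
generate_structure <- function(n_residues,
                               surface_charged_fraction = 0.30,
                               surface_aromatic_fraction = 0.10,
                               compactness = 1.0,
                               seed = 1L,
                               surface_threshold = 0.25,
                               source_id = sprintf("synth%06d", seed %% 1000000L)) {
  stopifnot(n_residues >= 5,
            surface_charged_fraction >= 0, surface_aromatic_fraction >= 0,
            surface_charged_fraction + surface_aromatic_fraction <= 1)
  xyz <- with_seed(derive_seed(seed, 1L),
                   .saw_collapse(n_residues, compactness))
  atoms <- data.frame(position = seq_len(n_residues),
                      aa = "A", atom_name = "CA", element = "C",
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      stringsAsFactors = FALSE)
  rec0 <- structure_record(source_id, atoms)
  expo <- relative_exposure(rec0, surface_threshold = surface_threshold)

  aa <- with_seed(derive_seed(seed, 2L), {
    sapply(expo$is_surface, function(surf) {
      if (surf) {
        u <- stats::runif(1)
        if (u < surface_charged_fraction) sample(.charged_aa, 1)
        else if (u < surface_charged_fraction + surface_aromatic_fraction)
          sample(.aromatic_aa, 1)
        else sample(.neutral_surface_aa, 1)
      } else sample(.buried_aa, 1)
    })
  })
  atoms$aa <- aa
  rec <- structure_record(source_id, atoms)
  expo$aa <- aa
  list(record = rec, sequence = paste(aa, collapse = ""), exposure = expo)
}

# self-avoiding walk + centroid collapse; caller controls the RNG state
.saw_collapse <- function(n, compactness, step = 3.8, min_sep = 3.6,
                          max_restarts = 25L) {
  for (attempt in seq_len(max_restarts)) {
    xyz <- .saw_walk(n, step, min_sep)
    if (!is.null(xyz)) {
      if (attempt > 1L) {
        message(sprintf("self-avoiding walk restarted %d time(s)", attempt - 1L))
      }
      return(.collapse(xyz, compactness * 2.2 * n^0.38, min_sep = 3.2))
    }
  }
  stop_stapr("generation_failed",
             "self-avoiding walk failed after %d restarts", max_restarts)
}

.saw_walk <- function(n, step, min_sep, tries_per_step = 30L) {
  xyz <- matrix(0, n, 3)
  for (i in 2:n) {
    placed <- FALSE
    for (t in seq_len(tries_per_step)) {
      u <- stats::rnorm(3)
      cand <- xyz[i - 1L, ] + step * u / sqrt(sum(u^2))
      prev <- xyz[seq_len(i - 2L), , drop = FALSE]
      if (i == 2L || all(rowSums((prev - matrix(cand, nrow(prev), 3,
                                                byrow = TRUE))^2) >= min_sep^2)) {
        xyz[i, ] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed) return(NULL)
  }
  xyz
}

.collapse <- function(xyz, target_rg, min_sep, shrink = 0.98,
                      max_iter = 400L) {
  rg <- function(m) {
    c0 <- colMeans(m)
    sqrt(mean(rowSums((m - matrix(c0, nrow(m), 3, byrow = TRUE))^2)))
  }
  it <- 0L
  while (rg(xyz) > target_rg && it < max_iter) {
    c0 <- colMeans(xyz)
    xyz <- matrix(c0, nrow(xyz), 3, byrow = TRUE) +
      shrink * (xyz - matrix(c0, nrow(xyz), 3, byrow = TRUE))
    # push sterically clashing pairs back apart
    d <- as.matrix(stats::dist(xyz))
    diag(d) <- Inf
    clash <- which(d < min_sep, arr.ind = TRUE)
    clash <- clash[clash[, 1] < clash[, 2], , drop = FALSE]
    if (nrow(clash)) {
      for (k in seq_len(nrow(clash))) {
        i <- clash[k, 1]; j <- clash[k, 2]
        v <- xyz[j, ] - xyz[i, ]
        dn <- sqrt(sum(v^2))
        if (dn < 1e-9) { v <- c(1, 0, 0); dn <- 1 }
        push <- (min_sep - dn) / 2
        xyz[i, ] <- xyz[i, ] - push * v / dn
        xyz[j, ] <- xyz[j, ] + push * v / dn
      }
    }
    it <- it + 1L
  }
  xyz
}
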