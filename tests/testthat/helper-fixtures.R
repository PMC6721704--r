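# programmatic fixtures and independent oracles shared across test files

# build minimal PDB text; atoms: list of lists with name, resid3, resno,
# xyz, and optional alt, occ, chain, hetatm
pdb_text <- function(atoms, chain = "A", resolution = NULL, models = NULL) {
  fmt <- function(a, i) {
    sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            if (isTRUE(a$hetatm)) "HETATM" else "ATOM", i,
            substr(paste0(" ", a$name), 1, 4), a$alt %||% " ",
            a$resid3, a$chain %||% chain, a$resno,
            a$xyz[1], a$xyz[2], a$xyz[3], a$occ %||% 1, 10,
            a$element %||% substr(a$name, 1, 1))
  }
  `%||%` <- function(x, y) if (is.null(x)) y else x
  body <- vapply(seq_along(atoms), function(i) fmt(atoms[[i]], i), character(1))
  lines <- character()
  if (!is.null(resolution)) {
    lines <- c(lines, sprintf("REMARK   2 RESOLUTION.    %.2f ANGSTROMS.",
                              resolution))
  }
  if (is.null(models)) {
    lines <- c(lines, body)
  } else {
    for (m in seq_along(models)) {
      lines <- c(lines, sprintf("MODEL     %4d", m), models[[m]], "ENDMDL")
    }
  }
  paste(c(lines, "END"), collapse = "\n")
}

# standard 3-residue CA-only fixture (ALA, GLY, LEU), chain A
three_residue_pdb <- function(resolution = NULL) {
  pdb_text(list(
    list(name = "CA", resid3 = "ALA", resno = 1L, xyz = c(0, 0, 0), element = "C"),
    list(name = "CA", resid3 = "GLY", resno = 2L, xyz = c(3.8, 0, 0), element = "C"),
    list(name = "CA", resid3 = "LEU", resno = 3L, xyz = c(7.6, 0, 0), element = "C")
  ), resolution = resolution)
}

# build a CA-only structure_record directly from coordinates and sequence
ca_record <- function(xyz, aa, id = "fix") {
  stapr::structure_record(id, data.frame(
    position = seq_len(nrow(xyz)), aa = aa, atom_name = "CA", element = "C",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], stringsAsFactors = FALSE))
}

# hand-built exposure profile (fixes e values independently of geometry)
manual_exposure <- function(record, rsa, threshold = 0.25) {
  out <- data.frame(position = residue_positions(record),
                    aa = record_sequence(record, collapse = FALSE),
                    sasa = rsa * 100, relative_sasa = rsa,
                    is_surface = rsa >= threshold, stringsAsFactors = FALSE)
  class(out) <- c("exposure_profile", "data.frame")
  out
}

# --- oracles -----------------------------------------------------------

# brute-force O(N^2) spatial score: explicit double loop over residue pairs
brute_stap <- function(record, exposure, scale = a3v_scale(),
                       sphere_radius = 10, burial_cutoff = 0.05) {
  ctr <- residue_centers(record)
  aa <- record_sequence(record, collapse = FALSE)
  e <- pmin(exposure$relative_sasa, 1)
  n <- nrow(ctr)
  score <- numeric(n)
  for (i in seq_len(n)) {
    if (e[i] < burial_cutoff) next
    s <- 0
    for (j in seq_len(n)) {
      d <- sqrt(sum((ctr[i, ] - ctr[j, ])^2))
      if (d <= sphere_radius) {
        s <- s + (1 - d / sphere_radius) * e[j] * scale[[aa[j]]]
      }
    }
    score[i] <- s
  }
  list(score = score, average_score = mean(score))
}

# Monte-Carlo SASA backend: random (seeded) surface points, independent of
# the deterministic lattice implementation
mc_sasa <- function(record, probe = 1.4, n_pts = 4000L, seed = 42L,
                    radii = NULL) {
  at <- record$atoms
  xyz <- as.matrix(at[, c("x", "y", "z")])
  r <- if (is.null(radii)) {
    vdw <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20)
    unname(ifelse(at$element %in% names(vdw), vdw[at$element], 1.70))
  } else rep(radii, length.out = nrow(xyz))
  re <- r + probe
  set.seed(seed)
  sasa <- numeric(nrow(xyz))
  for (i in seq_len(nrow(xyz))) {
    u <- matrix(rnorm(3 * n_pts), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    p <- u * re[i] + matrix(xyz[i, ], n_pts, 3, byrow = TRUE)
    free <- rep(TRUE, n_pts)
    for (j in seq_len(nrow(xyz))) {
      if (j == i) next
      free <- free & (rowSums((p - matrix(xyz[j, ], n_pts, 3,
                                          byrow = TRUE))^2) >= re[j]^2)
    }
    sasa[i] <- 4 * pi * re[i]^2 * mean(free)
  }
  sasa
}

# exact two-sided rank-sum p by exhaustive enumeration of all group
# assignments (tie-free samples only)
wilcox_enum_p <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  stopifnot(!any(duplicated(pooled)))
  u_of <- function(idx) {
    rx <- rank(pooled)[idx]
    sum(rx) - n * (n + 1) / 2
  }
  obs <- u_of(seq_len(n))
  all_u <- apply(utils::combn(n + m, n), 2, u_of)
  mu <- n * m / 2
  mean(abs(all_u - mu) >= abs(obs - mu) - 1e-9)
}

# hypergeometric upper tail by direct choose() arithmetic
hyper_tail <- function(n_l, p_l, n_b, p_b) {
  k <- n_l:min(p_l, n_b)
  sum(choose(n_b, k) * choose(p_b - n_b, p_l - k)) / choose(p_b, p_l)
}

# enumerate all global alignments of two short sequences; returns the best
# score and the set of identity fractions attained by optimal alignments
nw_enum <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  best <- list(score = -Inf, idents = numeric())
  rec <- function(i, j, score, matches, len) {
    if (i > length(a) && j > length(b)) {
      if (score > best$score + 1e-9) {
        best <<- list(score = score, idents = matches / len)
      } else if (abs(score - best$score) < 1e-9) {
        best$idents <<- unique(c(best$idents, matches / len))
      }
      return(invisible())
    }
    if (i <= length(a) && j <= length(b)) {
      s <- if (a[i] == b[j]) match else mismatch
      rec(i + 1, j + 1, score + s, matches + (a[i] == b[j]), len + 1)
    }
    if (i <= length(a)) rec(i + 1, j, score + gap, matches, len + 1)
    if (j <= length(b)) rec(i, j + 1, score + gap, matches, len + 1)
  }
  rec(1L, 1L, 0, 0L, 0L)
  best
}

# random 3D rotation matrix (seeded by caller)
random_rotation <- function() {
  qr.Q(qr(matrix(rnorm(9), 3)))
}

rotate_record <- function(record, R = random_rotation(), shift = c(0, 0, 0)) {
  at <- record$atoms
  xyz <- as.matrix(at[, c("x", "y", "z")]) %*% t(R)
  at$x <- xyz[, 1] + shift[1]
  at$y <- xyz[, 2] + shift[2]
  at$z <- xyz[, 3] + shift[3]
  stapr::structure_record(record$source_id, at, record$resolution,
                          record$model_index)
}
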