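# Deterministic quasi-uniform unit-sphere lattice (Fibonacci / golden-angle
# spiral).  The same n always yields the same points, which makes every SASA
# value in the package reproducible to the bit.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Per-atom solvent-accessible surface area (Shrake–Rupley)
#'
#' Classic sphere-point SASA: each atom is expanded by the probe radius,
#' covered with a deterministic quasi-uniform point lattice, and the
#' fraction of points not buried inside any neighbouring expanded sphere
#' gives its accessible area.  Van der Waals radii are looked up by element
#' (Bondi values); unknown elements fall back to 1.70 Angstrom with a
#' warning.
#'
#' @param record a `structure_record`.
#' @param probe_radius solvent probe radius, Angstrom (water: 1.4).
#' @param n_points lattice points per atom (>= 92; more points, finer area
#'   resolution).
#' @param radii optional explicit per-atom radii (Angstrom), overriding the
#'   element lookup — used by the C-alpha-only coarse mode.
#' @param oriented express the point lattice in a molecule-covariant frame
#'   (the principal axes of the atom cloud, with covariant sign fixing) so
#'   that areas are invariant under rigid motion of the input; `FALSE`
#'   keeps the lattice in laboratory axes.
#' @return Numeric vector, one SASA value (Angstrom^2) per atom of `record`.
#' @export
shrake_rupley_sasa <- function(record, probe_radius = 1.4, n_points = 960L,
                               radii = NULL, oriented = TRUE) {
  stopifnot(probe_radius > 0, n_points >= 92)
  at <- record$atoms
  xyz <- as.matrix(at[, c("x", "y", "z")])
  n <- nrow(xyz)
  r <- if (is.null(radii)) vdw_radius(at$element) else rep(radii, length.out = n)
  re <- r + probe_radius
  pts <- fibonacci_sphere(as.integer(n_points))
  if (oriented) pts <- pts %*% t(.molecular_frame(xyz))

  d2 <- as.matrix(stats::dist(xyz))^2
  sasa <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (re[i] + re)^2 & seq_len(n) != i)
    if (!length(nb)) {
      sasa[i] <- 4 * pi * re[i]^2
      next
    }
    p <- pts * re[i]
    p[, 1] <- p[, 1] + xyz[i, 1]
    p[, 2] <- p[, 2] + xyz[i, 2]
    p[, 3] <- p[, 3] + xyz[i, 3]
    free <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(free)) break
      dx <- p[free, 1] - xyz[j, 1]
      dy <- p[free, 2] - xyz[j, 2]
      dz <- p[free, 3] - xyz[j, 3]
      free[free] <- (dx * dx + dy * dy + dz * dz) >= re[j]^2
    }
    sasa[i] <- 4 * pi * re[i]^2 * sum(free) / n_points
  }
  sasa
}

# molecule-covariant orthonormal frame: principal axes of the centered atom
# cloud, signs fixed against the most distal atoms, third axis by cross
# product (right-handed).  Rotating/translating the molecule rotates this
# frame identically, which makes the lattice SASA rigid-motion invariant.
.molecular_frame <- function(xyz) {
  n <- nrow(xyz)
  if (n < 3L) return(diag(3))
  X <- sweep(xyz, 2, colMeans(xyz))
  C <- crossprod(X) / n
  if (max(abs(C)) < 1e-12) return(diag(3))
  V <- eigen(C, symmetric = TRUE)$vectors
  ord <- order(-rowSums(X^2))
  fix_sign <- function(v) {
    for (i in ord) {
      s <- sum(v * X[i, ])
      if (abs(s) > 1e-8) return(v * sign(s))
    }
    v
  }
  v1 <- fix_sign(V[, 1])
  v2 <- fix_sign(V[, 2])
  v3 <- c(v1[2] * v2[3] - v1[3] * v2[2],
          v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  cbind(v1, v2, v3)
}

# is a record a coarse C-alpha-only model?
is_calpha_only <- function(record) all(record$atoms$atom_name == "CA")

# pseudo-atom radius used for coarse C-alpha-only residues, Angstrom
CALPHA_PSEUDO_RADIUS <- 3.4

#' Per-residue exposure profile
#'
#' Sums per-atom SASA into residues and divides by the residue-type
#' theoretical maximum ASA ([max_asa_reference()]) to obtain relative
#' solvent accessibility (RSA).  Values slightly above 1 (possible for
#' terminal or distorted residues) are clamped to 1 and counted.  For
#' C-alpha-only coarse models the denominator is instead the area of an
#' isolated pseudo-atom, so a free-floating residue has RSA 1 by
#' construction.
#'
#' @param record a `structure_record`.
#' @param atom_sasa per-atom areas from [shrake_rupley_sasa()]; computed on
#'   the fly when omitted.
#' @param surface_threshold RSA at or above which a residue is flagged as
#'   surface (conventional 25% definition; configurable).
#' @param probe_radius,n_points forwarded to [shrake_rupley_sasa()] when
#'   `atom_sasa` is missing.
#' @return data.frame of class `exposure_profile`: position, aa, sasa,
#'   relative_sasa, is_surface; attribute `n_clamped` counts RSA values
#'   clamped at 1.
#' @export
relative_exposure <- function(record, atom_sasa = NULL,
                              surface_threshold = 0.25,
                              probe_radius = 1.4, n_points = 960L) {
  ca_mode <- is_calpha_only(record)
  if (is.null(atom_sasa)) {
    atom_sasa <- shrake_rupley_sasa(record, probe_radius, n_points,
                                    radii = if (ca_mode) CALPHA_PSEUDO_RADIUS)
  }
  stopifnot(length(atom_sasa) == nrow(record$atoms))
  pos <- residue_positions(record)
  idx <- match(record$atoms$position, pos)
  sasa <- as.numeric(tapply(atom_sasa, factor(idx, seq_along(pos)), sum))
  aa <- record_sequence(record, collapse = FALSE)
  max_asa <- if (ca_mode) {
    rep(4 * pi * (CALPHA_PSEUDO_RADIUS + probe_radius)^2, length(pos))
  } else {
    unname(max_asa_reference()[aa])
  }
  rsa <- sasa / max_asa
  n_clamped <- sum(rsa > 1)
  rsa <- pmin(rsa, 1)
  out <- data.frame(position = pos, aa = aa, sasa = sasa,
                    relative_sasa = rsa,
                    is_surface = rsa >= surface_threshold,
                    stringsAsFactors = FALSE)
  attr(out, "n_clamped") <- n_clamped
  attr(out, "surface_threshold") <- surface_threshold
  class(out) <- c("exposure_profile", "data.frame")
  out
}
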