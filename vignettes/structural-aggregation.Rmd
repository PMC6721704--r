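---
title: "Structural aggregation propensity: the model, its parameters, and what the synthetic benchmark shows"
author: "stapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural aggregation propensity: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stapr)
```

## The problem

Sequence-based aggregation predictors score the unfolded chain: the
aggregation-prone regions they find are usually buried once the protein
folds, so they say little about the aggregation risk of a *native* globular
protein. A folded protein aggregates through sticky patches on its solvent
exposed surface — patches that may be assembled from residues far apart in
sequence. `stapr` scores that surface risk directly on 3D structures and
provides the statistical layer needed to relate it, across a proteome, to
abundance, length, operon structure, essentiality, subcellular location,
surface composition and quaternary state.

## The spatial score

Every residue carries an intrinsic aggregation propensity `a3v` — an
experimentally derived, dimensionless per-amino-acid scale (aggregation of
Abeta42 variants in *E. coli*; see `a3v_scale()`), positive for
aggregation-promoting residues (I, F, V, L, ...) and negative for
solubilizing ones (D, E, K, R, ...). For a residue *i* of a chain, the
spatial score sums the exposure- and distance-weighted propensities of all
residues within a sphere of radius *R* around it:

    score_i = sum over j with d_ij <= R of  w(d_ij) * e_j * a3v(aa_j)

where

* `d_ij` is the distance between *effective residue centers* — the centroid
  of the side-chain heavy atoms, or the C-alpha for glycine and for coarse
  models;
* `e_j` is the residue's relative solvent accessibility (RSA), clamped to
  [0, 1];
* `w(d) = 1 - d/R` is a linear distance kernel with `w(0) = 1` and
  `w(R) = 0`.

A residue that is essentially buried (RSA below `burial_cutoff`) cannot
nucleate surface aggregation and its own score is set to exactly 0 (it still
contributes, weakly, to its neighbours through its small `e_j`). The
protein-level score — the structural aggregation propensity, STAP — is the
arithmetic mean of the per-residue scores over *all* residues, buried zeros
included. Averaging over all residues (rather than exposed residues only) is
a declared convention, recorded in the result object; because every
comparative analysis in the package depends only on score *ordering*, the
choice shifts all proteins monotonically and does not affect any downstream
conclusion.

The published structure-corrected predictor whose rationale this score
follows combines the same three ingredients (intrinsic propensities, surface
exposure, effective distance in 10 Å spheres) but does not print its exact
combination rule, and its pipeline energy-minimizes the input with an
external force field first. The linear-kernel sphere sum above is therefore
this package's own declared scoring rule: simple enough to verify against a
brute-force double loop, monotone in the intrinsic scale, and invariant
under rigid motion. An externally minimized PDB can be supplied as input
where that pre-processing matters; numerical equality with the original
server's averages is not claimed.

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `sphere_radius` | 10 Å | neighbourhood defining an aggregation patch |
| `burial_cutoff` | 0.05 RSA | below this a residue's own score is nulled |
| `distance_weight` | linear | `w(d) = 1 - d/R`; any `w(0)=1, w(R)=0`, non-increasing kernel may be supplied |
| `probe_radius` | 1.4 Å | water probe for SASA |
| `n_points` | 960 | sphere-lattice resolution (≈2% area error at 92 points, well below 1% at 960) |
| `surface_threshold` | 0.25 RSA | surface call for the composition analysis |

The 10 Å radius is the conventional default for this family of methods; the
25% RSA surface threshold is the common surface definition in structural
bioinformatics (the original predictor's internal exposure cutoff is not
published, so surface calls agree with it only approximately — this is
logged prominently wherever composition results are reported).

### Solvent accessibility

SASA uses the classic Shrake–Rupley sphere-point construction with Bondi
van der Waals radii and a deterministic Fibonacci lattice, so every area is
bit-reproducible. The lattice is expressed in a molecule-covariant frame
(principal axes of the atom cloud with sign fixing against the most distal
atoms), which makes areas invariant under rigid motion of the input to
numerical precision rather than only up to lattice discretization. RSA
divides residue SASA by the theoretical Gly-X-Gly maximum (`max_asa_reference()`);
values marginally above 1 (distorted or terminal residues) are clamped with
a counted warning. For coarse C-alpha-only models each residue is one
pseudo-atom of radius 3.4 Å and RSA is taken against the isolated
pseudo-atom area, so a free residue has RSA exactly 1.

## The sequence score

`na4vss()` is the length-normalized sequence aggregation score: the sliding
window mean (`a4v`) of the intrinsic scale, summed and rescaled per 100
residues, `100 * sum(a4v) / N`. The window grows with length (5 / 7 / 9 / 11
at ≤75 / ≤175 / ≤300 / >300 residues), following the published convention of
the sequence predictor the scale comes from; windows truncate one-sidedly at
the termini, which keeps a homopolymer's profile exactly flat and makes the
score length-invariant on homopolymers. Hot-spot detection outputs of the
original tool are deliberately not computed — only the per-protein score is
used downstream.

## The supersaturation index

Aggregation risk in the cell depends jointly on surface stickiness and
concentration. With `C` the min–max-rescaled log10 abundance and `A` the
min–max-rescaled STAP over the analyzed set,

    SSI = (C + A) / 2

so the protein at the joint minimum scores 0 and at the joint maximum 1.
Min–max rescaling makes SSI invariant under any affine transformation of
either raw column; its values are only meaningful relative to the analyzed
set.

## The statistical layer

All two-group comparisons use the Wilcoxon rank-sum test (exact enumeration
for tie-free samples with n + m ≤ 12, tie-corrected normal approximation
with continuity correction otherwise, via `stats::wilcox.test`). Stratified
comparisons take the bottom and top `floor(n * fraction)` rows of the
ordering column, ties broken by stable row order. Operon dispersion compares
each operon's sample SD (n−1 denominator, operons with ≥2 scored members)
with the global SD of all operon-assigned proteins and attaches a label
permutation p-value; the LA/HA split classifies operons by mean score
against the grand mean, with equality assigned to HA by convention. Fold
enrichment is the hit-rate ratio `(n_l/p_l)/(n_b/p_b)` with an upper-tail
hypergeometric p-value computed locally on a user-supplied annotation
table. The correlation between log abundance and score is Pearson by
default (the estimator used on the log-transformed scale), with Spearman as
a sensitivity option. The surface-composition comparison reports raw
rank-test p-values per amino acid plus Benjamini–Hochberg FDR as an added
safeguard. Missing annotations are excluded listwise per analysis and
counted in each result's manifest; membrane proteins are excluded from the
abundance, length, operon and composition analyses because they differ
systematically in charge and hydrophobicity, and are analyzed separately in
the location stratification.

## The synthetic study set

Nothing in this package downloads data. `generate_proteome()` draws an
annotated proteome whose defaults encode the study conditions the analysis
layer is designed for: 500 proteins; score marginal mean −0.88 and SD 0.4;
a planted abundance–score correlation of −0.3 (Gaussian copula with an
empirical orthogonalization step, so the realized sample correlation hits
the target by construction rather than only in expectation); 41 operons of
2–8 members whose members share their abundance driver and score level
exactly, with a within-operon SD of 0.1 — 25% of the global SD; essentiality
annotated for about half the proteins with odds 3:1 per SD of decreasing
score; oligomer labels drawn through a noisy supersaturation latent
calibrated to a mean SSI shift of 0.15; a location mixture in which
inner-membrane proteins gain 0.08 score units per transmembrane segment; a
mild positive length–score coupling (r ≈ 0.35 inside the copula residual,
so the abundance target is untouched); and ~1% missing abundance.

`generate_structure()` builds C-alpha-only chains: a seeded self-avoiding
walk (3.8 Å steps) collapsed toward its centroid to the globular
radius-of-gyration target `2.2 n^0.38` Å with steric relaxation between
collapse steps. Residues are classified buried/surface by coarse-mode RSA;
surface residues are assigned charged (D/E/K/R), aromatic (F/Y/W) or
neutral identities at configured fractions, buried residues are drawn from
hydrophobics. Decile-matched structures give the bottom score decile
charge-rich surfaces (45% charged / 5% aromatic) and the top decile
aromatic-rich surfaces (10% / 35%), planting the compositional contrast the
surface analysis is meant to find.

What the generator deliberately does *not* emulate: real side-chain
packing and secondary structure, realistic fold topologies, membrane
geometry, sequence-dependent abundance, or the long-tailed abundance
distributions of real proteomes. Passing the planted-effect suite therefore
shows that the pipeline *recovers known effects of realistic size from data
with the right statistical shape* — it does not validate the scoring rule
against experimental aggregation data.

## Numerical choices and degenerate inputs

* All randomness flows from one user seed through a fixed splitting rule
  (`derive_seed()`, one Lehmer step plus offset), logged in manifests;
  identical seeds give byte-identical outputs.
* Structure parsing keeps model 1 of multi-model files, resolves altlocs by
  highest occupancy then alphabetical id, drops waters, maps substitutable
  non-standard residues (MSE → MET, ...) to their parents and drops the
  rest with a warning.
* Redundancy filtering aligns globally (match +1, mismatch −1, gap −2;
  identity = matches / alignment length) and removes redundancy greedily in
  order of resolution (best first, NMR last, ties by id) — a declared
  convention, since the source study does not state its clustering method.
* Degenerate statistics fail loudly with classed errors: constant columns
  (`stapr_undefined_correlation`), min = max normalizations
  (`stapr_degenerate_normalization`), tail groups under 3 rows
  (`stapr_group_too_small`), identical samples warn and return p = 1.
* Problem sizes used by the validation suite: brute-force score equivalence
  on 100 chains of 8–30 residues; rank-test enumeration up to n + m = 10;
  2000-replicate null simulations for type-I error; planted-effect recovery
  on the 500-protein set with 42 + 42 decile structures. These sizes were
  chosen to bound each check's Monte-Carlo error well below the effect
  sizes being detected.

## Known limitations

* The scoring rule is a documented variant: printed averages from the
  original structure-based server are reproduced in sign and ordering, not
  numerically, and no force-field minimization is performed.
* Naive point mutation relabels the residue and truncates beyond C-beta;
  no side-chain rebuilding or repacking, so mutant scores are directional
  estimates.
* Coarse C-alpha SASA is a trend-level exposure model; full-atom inputs
  should be used where absolute RSA matters.
* The rank-sum normal approximation is used for all large samples; exact
  p-values are only computed for small tie-free inputs.
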