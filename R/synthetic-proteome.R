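#' Generate an annotated proteome table with planted effects
#'
#' Draws a synthetic proteome carrying the statistical structure the
#' analysis layer is designed to detect: a negative abundance–score
#' association (Gaussian copula at the configured target correlation),
#' operon blocks sharing a common score mean with small within-operon
#' spread, essentiality enriched among low-score proteins, oligomer labels
#' selected by a noisy supersaturation latent so oligomer subunits sit at
#' higher SSI, a mild positive length–score coupling (carried inside the
#' copula residual so the abundance correlation target is untouched), and
#' a subcellular-location mixture in which inner-membrane proteins gain a
#' score offset per transmembrane segment.  Fully deterministic per seed.
#'
#' @param n_proteins number of rows.
#' @param target_abundance_stap_correlation planted abundance–score
#'   correlation, in (-1, 1).
#' @param length_stap_correlation planted length–score coupling inside the
#'   copula residual, in (-1, 1).
#' @param n_operons,operon_size_range operon block structure; sizes drawn
#'   uniformly from the range.
#' @param within_operon_sd SD of member scores around their operon mean,
#'   on the score scale.
#' @param essentiality_low_stap_odds odds ratio of essentiality per SD
#'   decrease of the score (annotated proteins only).
#' @param annotated_fraction fraction of proteins with known essentiality.
#' @param oligomer_fraction fraction labelled oligomer.
#' @param oligomer_ssi_shift target mean SSI difference (oligomer minus
#'   monomer), on the 0–1 SSI scale.
#' @param location_mixture named fractions for cytoplasm, periplasm,
#'   inner_membrane, outer_membrane (must sum to 1).
#' @param n_ts_score_offset score increment per transmembrane segment of
#'   inner-membrane proteins.
#' @param abundance_missing_fraction fraction of rows with missing
#'   abundance.
#' @param score_mean,score_sd marginal mean/SD of the structural score.
#' @param abundance_mean,abundance_sd marginal mean/SD of log10 abundance.
#' @param seed integer RNG seed.
#' @return data.frame (proteome table): id, average_score, na4vss,
#'   abundance_log10, length, location, n_ts, essential, operon_id,
#'   oligomeric_state.
#' @export
generate_proteome <- function(n_proteins = 500L,
                              target_abundance_stap_correlation = -0.3,
                              length_stap_correlation = 0.35,
                              n_operons = 41L,
                              operon_size_range = c(2L, 8L),
                              within_operon_sd = 0.1,
                              essentiality_low_stap_odds = 3,
                              annotated_fraction = 0.5,
                              oligomer_fraction = 0.5,
                              oligomer_ssi_shift = 0.15,
                              location_mixture = c(cytoplasm = 0.72,
                                                   periplasm = 0.10,
                                                   inner_membrane = 0.11,
                                                   outer_membrane = 0.07),
                              n_ts_score_offset = 0.08,
                              abundance_missing_fraction = 0.012,
                              score_mean = -0.88, score_sd = 0.4,
                              abundance_mean = 1.5, abundance_sd = 1.2,
                              seed = 1L) {
  rho <- target_abundance_stap_correlation
  lam <- length_stap_correlation
  stopifnot(abs(rho) < 1, abs(lam) < 1,
            oligomer_fraction >= 0, oligomer_fraction <= 1,
            abs(sum(location_mixture) - 1) < 1e-6)
  n <- as.integer(n_proteins)

  op_sizes <- with_seed(derive_seed(seed, 10L),
    sample(seq(operon_size_range[1], operon_size_range[2]),
           n_operons, replace = TRUE))
  if (sum(op_sizes) > n) {
    stop_stapr("config_infeasible",
               "operon members (%d) exceed n_proteins (%d)",
               sum(op_sizes), n)
  }

  with_seed(derive_seed(seed, 11L), {
    id <- sprintf("P%04d", seq_len(n))
    len <- pmax(50L, as.integer(round(stats::rlnorm(n, log(250), 0.45))))
    z_len <- as.numeric(scale(log(len)))

    operon_id <- rep(NA_character_, n)
    operon_id[seq_len(sum(op_sizes))] <-
      rep(sprintf("op%03d", seq_len(n_operons)), op_sizes)
    in_op <- !is.na(operon_id)

    # operon members share their abundance driver and their score-side
    # residual exactly (co-regulation is the planted premise); member-level
    # spread enters only through within_operon_sd below
    k_op <- match(operon_id, sprintf("op%03d", seq_len(n_operons)))
    free <- !in_op
    b_ab <- stats::rnorm(max(n_operons, 1L))
    eps_op <- stats::rnorm(max(n_operons, 1L))
    z_ab <- numeric(n)
    z_ab[in_op] <- b_ab[k_op[in_op]]
    z_ab[free] <- stats::rnorm(sum(free))
    e <- numeric(n)
    e[in_op] <- eps_op[k_op[in_op]]
    e[free] <- lam * z_len[free] + sqrt(1 - lam^2) * stats::rnorm(sum(free))
    # empirical Gaussian copula: orthogonalize the residual against the
    # realized abundance so the sample correlation hits the target by
    # construction, then add the member-level within-operon spread
    za <- as.numeric(scale(z_ab))
    e_perp <- as.numeric(scale(e - (sum(za * e) / sum(za * za)) * za))
    z_sc <- rho * za + sqrt(1 - rho^2) * e_perp
    z_sc[in_op] <- z_sc[in_op] +
      (within_operon_sd / score_sd) * stats::rnorm(sum(in_op))

    location <- sample(names(location_mixture), n, replace = TRUE,
                       prob = location_mixture)
    n_ts <- integer(n)
    im <- location == "inner_membrane"
    n_ts[im] <- sample(0:12, sum(im), replace = TRUE,
                       prob = c(0.25, 0.20, rep(0.05, 11)))

    average_score <- score_mean + score_sd * z_sc + n_ts_score_offset * n_ts
    abundance_log10 <- abundance_mean + abundance_sd * z_ab
    abundance_log10[stats::runif(n) < abundance_missing_fraction] <- NA_real_

    # sequence-level score: correlated with the structural score but noisier
    z_sc_std <- as.numeric(scale(average_score))
    na4vss <- -12 + 8 * (0.5 * z_sc_std + sqrt(0.75) * stats::rnorm(n))

    essential <- rep("unknown", n)
    ann <- stats::runif(n) < annotated_fraction
    p_ess <- stats::plogis(-log(essentiality_low_stap_odds) * z_sc_std[ann])
    essential[ann] <- ifelse(stats::runif(sum(ann)) < p_ess, "yes", "no")

    # oligomer labels drawn by a noisy SSI latent so the planted mean SSI
    # shift comes out at the configured value
    ok <- is.finite(abundance_log10)
    minmax <- function(v) (v - min(v)) / (max(v) - min(v))
    ssi0 <- rep(NA_real_, n)
    ssi0[ok] <- (minmax(abundance_log10[ok]) + minmax(average_score[ok])) / 2
    ssi0[!ok] <- stats::median(ssi0[ok])
    p_olig <- oligomer_fraction
    if (p_olig > 0 && p_olig < 1 && oligomer_ssi_shift > 0) {
      zq <- stats::qnorm(1 - p_olig)
      fac <- stats::dnorm(zq) / (p_olig * (1 - p_olig))
      r_lat <- min(0.95, oligomer_ssi_shift / (stats::sd(ssi0) * fac))
      latent <- r_lat * as.numeric(scale(ssi0)) +
        sqrt(1 - r_lat^2) * stats::rnorm(n)
      oligomer <- latent >= stats::quantile(latent, 1 - p_olig)
    } else {
      oligomer <- stats::runif(n) < p_olig
    }

    data.frame(id = id,
               average_score = average_score,
               na4vss = na4vss,
               abundance_log10 = abundance_log10,
               length = len,
               location = location,
               n_ts = n_ts,
               essential = essential,
               operon_id = operon_id,
               oligomeric_state = ifelse(oligomer, "oligomer", "monomer"),
               stringsAsFactors = FALSE)
  })
}

#' Generate structures matched to the score deciles of a proteome table
#'
#' For the bottom and top `fraction` of proteins by structural score,
#' generates coarse globular structures whose surface composition mirrors
#' the planted compositional signal: low-score (soluble) proteins carry
#' charge-rich surfaces, high-score (aggregation-prone) proteins
#' aromatic-rich surfaces.
#'
#' @param table proteome table from [generate_proteome()].
#' @param fraction tail fraction per group (default 0.10: deciles).
#' @param n_residues_range chain lengths drawn uniformly from this range.
#' @param low_charged,low_aromatic surface composition of the low group.
#' @param high_charged,high_aromatic surface composition of the high group.
#' @param seed integer RNG seed.
#' @return List with `low` and `high`: each a named list (by protein id)
#'   of [generate_structure()] outputs.
#' @export
generate_matched_structures <- function(table, fraction = 0.10,
                                        n_residues_range = c(60L, 100L),
                                        low_charged = 0.45, low_aromatic = 0.05,
                                        high_charged = 0.10, high_aromatic = 0.35,
                                        seed = 1L) {
  ord <- order(table$average_score, seq_len(nrow(table)))
  k <- floor(nrow(table) * fraction)
  low_ids <- table$id[ord[seq_len(k)]]
  high_ids <- table$id[ord[seq(nrow(table) - k + 1L, nrow(table))]]
  lens <- with_seed(derive_seed(seed, 20L),
    sample(seq(n_residues_range[1], n_residues_range[2]), 2L * k,
           replace = TRUE))
  gen <- function(ids, charged, aromatic, offset) {
    out <- lapply(seq_along(ids), function(i) {
      generate_structure(lens[offset + i],
                         surface_charged_fraction = charged,
                         surface_aromatic_fraction = aromatic,
                         seed = derive_seed(seed, 100L + offset + i),
                         source_id = ids[i])
    })
    stats::setNames(out, ids)
  }
  list(low = gen(low_ids, low_charged, low_aromatic, 0L),
       high = gen(high_ids, high_charged, high_aromatic, k))
}

#' Simulate the full study: proteome table plus decile structures
#'
#' One-call generator for the complete synthetic study set under its
#' default conditions, used by the analysis drivers and the end-to-end
#' validation.
#'
#' @param n_proteins rows in the proteome table.
#' @param seed integer RNG seed.
#' @param structures also generate decile-matched structures?
#' @param ... forwarded to [generate_proteome()].
#' @return List: `table`, and when requested `structures`
#'   (from [generate_matched_structures()]).
#' @export
simulate_full <- function(n_proteins = 500L, seed = 1L, structures = TRUE,
                          ...) {
  table <- generate_proteome(n_proteins = n_proteins, seed = seed, ...)
  out <- list(table = table, seed = seed)
  if (structures) {
    # decile structures follow the analysis convention: membrane proteins
    # are excluded from the compositional comparison
    soluble <- table[!table$location %in% c("inner_membrane",
                                            "outer_membrane"), , drop = FALSE]
    out$structures <- generate_matched_structures(soluble,
                                                  seed = derive_seed(seed, 2L))
  }
  out
}
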