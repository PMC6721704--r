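#' Wilcoxon rank-sum comparison of two groups
#'
#' Thin, contract-enforcing wrapper around [stats::wilcox.test()]: exact
#' enumeration for small tie-free samples (n + m <= 12), tie-corrected
#' normal approximation with continuity correction otherwise.  Two
#' identical constant samples cannot separate and return p = 1 with a
#' warning.
#'
#' @param x,y numeric samples (non-empty; NA dropped).
#' @return List of class `group_comparison` fields `statistic` (W, the
#'   Mann-Whitney U of x), `p_value` (two-sided), `n_x`, `n_y`, `method`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (!length(x) || !length(y)) {
    stop_stapr("empty_input", "both samples must be non-empty")
  }
  if (length(unique(c(x, y))) == 1L) {
    warning("all values identical across both groups; p = 1", call. = FALSE)
    return(list(statistic = length(x) * length(y) / 2, p_value = 1,
                n_x = length(x), n_y = length(y), method = "degenerate"))
  }
  ties <- any(duplicated(c(x, y)))
  exact <- (length(x) + length(y) <= 12) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)
  )
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_x = length(x), n_y = length(y),
       method = if (exact) "exact" else "normal approximation (tie-corrected)")
}

# group summary used by the stratified comparisons
.group_summary <- function(v) {
  c(n = length(v), median = stats::median(v), mean = mean(v),
    sd = stats::sd(v))
}

# cumulative-frequency curve: fraction of values <= x, at the sorted values
cumulative_curve <- function(v) {
  v <- sort(v)
  data.frame(x = v, cum_freq = seq_along(v) / length(v))
}

#' Structural supersaturation index (SSI)
#'
#' Min-max rescales log10 abundance to C and the structural score to A
#' over the analyzed set, then SSI = (C + A) / 2: a protein at the joint
#' minimum has SSI 0, at the joint maximum SSI 1.  SSI proxies the risk of
#' aggregation at physiological concentration — high propensity at high
#' abundance.  Rows without abundance are excluded (count reported in the
#' `n_excluded` attribute).
#'
#' @param table proteome table with columns `id`, `abundance_log10`,
#'   `average_score`.
#' @return data.frame: id, C, A, ssi; attribute `n_excluded`.
#' @export
compute_ssi <- function(table) {
  ok <- is.finite(table$abundance_log10) & is.finite(table$average_score)
  n_excluded <- sum(!ok)
  t2 <- table[ok, , drop = FALSE]
  if (length(unique(t2$abundance_log10)) < 2 ||
      length(unique(t2$average_score)) < 2) {
    stop_stapr("degenerate_normalization",
               "need >= 2 distinct abundance and score values")
  }
  minmax <- function(v) (v - min(v)) / (max(v) - min(v))
  out <- data.frame(id = t2$id,
                    C = minmax(t2$abundance_log10),
                    A = minmax(t2$average_score))
  out$ssi <- (out$C + out$A) / 2
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Compare a value between the bottom and top fraction of another column
#'
#' Orders the table by `group_column` (ties broken by stable `id` order),
#' takes the bottom and top `floor(n * fraction)` rows, and compares
#' `value_column` between the two groups with the Wilcoxon rank-sum test.
#' This is the quartile-stratification pattern used for abundance and
#' length: e.g. STAP in the 25% most vs least abundant proteins.
#'
#' @param table proteome table (data.frame with an `id` column).
#' @param value_column column compared between groups.
#' @param group_column numeric column defining the stratification.
#' @param fraction fraction per tail, in (0, 0.5].
#' @return List of class `group_comparison`: `low`, `high` (row subsets),
#'   `summary` (2-row matrix of n/median/mean/sd), `test` (the rank test),
#'   `curves` (cumulative-frequency curves per group).
#' @export
stratify_and_compare <- function(table, value_column, group_column,
                                 fraction = 0.25) {
  stopifnot(fraction > 0, fraction <= 0.5)
  ok <- is.finite(table[[group_column]]) & is.finite(table[[value_column]])
  t2 <- table[ok, , drop = FALSE]
  ord <- order(t2[[group_column]], seq_len(nrow(t2)))  # stable in id order
  k <- floor(nrow(t2) * fraction)
  if (k < 3) stop_stapr("group_too_small", "tail groups have %d < 3 rows", k)
  low <- t2[ord[seq_len(k)], , drop = FALSE]
  high <- t2[ord[seq(nrow(t2) - k + 1L, nrow(t2))], , drop = FALSE]
  test <- wilcoxon_rank_sum(low[[value_column]], high[[value_column]])
  structure(list(low = low, high = high,
                 value_column = value_column, group_column = group_column,
                 fraction = fraction,
                 summary = rbind(low = .group_summary(low[[value_column]]),
                                 high = .group_summary(high[[value_column]])),
                 test = test,
                 curves = list(low = cumulative_curve(low[[value_column]]),
                               high = cumulative_curve(high[[value_column]])),
                 n_excluded = sum(!ok)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s by %s (fraction %.2f)\n",
              x$value_column, x$group_column, x$fraction))
  print(round(x$summary, 4))
  cat(sprintf("Wilcoxon rank-sum: W = %.1f, p = %.3g (%s)\n",
              x$test$statistic, x$test$p_value, x$test$method))
  invisible(x)
}

#' Within-operon dispersion of the structural score
#'
#' For every operon with at least `min_members` assigned proteins, the
#' sample SD (n-1 denominator) of the structural score; compared against
#' the global SD over all operon-assigned proteins.  Reports the fraction
#' of operons whose SD falls below the global SD, with a permutation
#' p-value obtained by shuffling operon labels among the operon-assigned
#' proteins.
#'
#' @param table proteome table with `average_score` and `operon_id`
#'   (NA = unassigned).
#' @param min_members minimum operon size entering the analysis (>= 2).
#' @param n_perm label permutations for the null.
#' @param seed RNG seed for the permutations.
#' @return List: `operon_sd` (data.frame operon_id, n, sd), `global_sd`,
#'   `fraction_below`, `perm_p`, `n_operons`, `n_proteins`.
#' @export
operon_dispersion <- function(table, min_members = 2L, n_perm = 1000L,
                              seed = 1L) {
  stopifnot(min_members >= 2)
  t2 <- table[!is.na(table$operon_id) & is.finite(table$average_score), ,
              drop = FALSE]
  sizes <- table(t2$operon_id)
  use <- names(sizes)[sizes >= min_members]
  if (!length(use)) stop_stapr("no_operons", "no operon with >= %d members",
                               min_members)
  global_sd <- stats::sd(t2$average_score)
  frac_below <- function(scores, labels) {
    sds <- tapply(scores, labels, stats::sd)
    mean(sds < global_sd)
  }
  lab <- factor(t2$operon_id[t2$operon_id %in% use])
  sc <- t2$average_score[t2$operon_id %in% use]
  sds <- tapply(sc, lab, stats::sd)
  observed <- mean(sds < global_sd)

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  perm <- replicate(n_perm, frac_below(sc, sample(lab)))
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)

  list(operon_sd = data.frame(operon_id = names(sds),
                              n = as.integer(table(lab)),
                              sd = as.numeric(sds)),
       global_sd = global_sd,
       fraction_below = observed,
       perm_p = (1 + sum(perm >= observed)) / (n_perm + 1),
       n_operons = length(sds), n_proteins = nrow(t2))
}

#' Split operons into low- and high-aggregation classes
#'
#' Classifies each operon by its mean structural score against the grand
#' mean of all operon-assigned proteins: LA (low aggregation) below the
#' grand mean, HA at or above it (equality goes to HA by convention).
#' Tallies essential vs non-essential proteins per class; proteins with
#' unknown essentiality are counted separately.
#'
#' @param table proteome table with `average_score`, `operon_id`,
#'   `essential` ("yes"/"no"/"unknown").
#' @param min_members minimum operon size.
#' @return List: `operons` (operon_id, n, mean_score, class), `grand_mean`,
#'   `counts` (class x essential matrix over annotated proteins),
#'   `n_unknown` per class.
#' @export
la_ha_split <- function(table, min_members = 2L) {
  t2 <- table[!is.na(table$operon_id) & is.finite(table$average_score), ,
              drop = FALSE]
  sizes <- table(t2$operon_id)
  t2 <- t2[t2$operon_id %in% names(sizes)[sizes >= min_members], ,
           drop = FALSE]
  grand_mean <- mean(t2$average_score)
  op_mean <- tapply(t2$average_score, t2$operon_id, mean)
  cls <- ifelse(op_mean < grand_mean, "LA", "HA")
  t2$class <- cls[t2$operon_id]
  ess <- factor(t2$essential, levels = c("yes", "no", "unknown"))
  counts <- table(class = factor(t2$class, c("LA", "HA")), essential = ess)
  list(operons = data.frame(operon_id = names(op_mean),
                            n = as.integer(table(t2$operon_id)[names(op_mean)]),
                            mean_score = as.numeric(op_mean),
                            class = unname(cls)),
       grand_mean = grand_mean,
       counts = counts[, c("yes", "no"), drop = FALSE],
       n_unknown = counts[, "unknown"])
}

#' Fold enrichment of a category in a selected list
#'
#' FE = (n_l / p_l) / (n_b / p_b): the category's hit rate in the list
#' relative to its rate in the background, with an upper-tail
#' hypergeometric p-value for observing at least `n_l` hits when drawing
#' `p_l` proteins from a background of `p_b` containing `n_b` category
#' members.
#'
#' @param n_l hits in the list; `p_l` list size; `n_b` hits in the
#'   background; `p_b` background size.
#' @param p_l,n_b,p_b see above.
#' @return List of class `enrichment_result`: counts, `fold_enrichment`,
#'   `p_value`.
#' @export
fold_enrichment <- function(n_l, p_l, n_b, p_b) {
  stopifnot(n_l >= 0, n_l <= p_l, n_b <= p_b, n_l <= n_b, p_l <= p_b)
  if (n_b == 0 || p_l == 0) {
    stop_stapr("undefined_enrichment",
               "fold enrichment undefined for n_b = 0 or p_l = 0")
  }
  structure(list(n_l = n_l, p_l = p_l, n_b = n_b, p_b = p_b,
                 fold_enrichment = (n_l * p_b) / (n_b * p_l),
                 p_value = stats::phyper(n_l - 1, n_b, p_b - n_b, p_l,
                                         lower.tail = FALSE)),
            class = "enrichment_result")
}

#' Surface amino-acid composition of two protein groups
#'
#' For each protein, the frequency of every amino acid among its surface
#' residues (RSA-based surface flags); per amino acid, the two protein
#' groups (canonically the bottom and top score deciles) are compared with
#' the Wilcoxon rank-sum test.  Raw p-values are reported together with
#' Benjamini-Hochberg FDR.
#'
#' @param group_low,group_high lists of `exposure_profile` objects (the
#'   low- and high-score groups).
#' @return data.frame: aa, mean_freq_low, mean_freq_high, direction
#'   ("low"/"high", group with the larger mean frequency, "none" on
#'   equality), p_value, fdr.
#' @export
surface_composition_compare <- function(group_low, group_high) {
  freqs <- function(group, label) {
    rows <- lapply(group, function(ep) {
      surf <- ep$aa[ep$is_surface]
      if (!length(surf)) return(NULL)
      as.numeric(table(factor(surf, amino_acids()))) / length(surf)
    })
    drop <- vapply(rows, is.null, logical(1))
    if (any(drop)) {
      warning(sprintf("%d protein(s) in %s group without surface residues excluded",
                      sum(drop), label), call. = FALSE)
    }
    do.call(rbind, rows[!drop])
  }
  f_low <- freqs(group_low, "low")
  f_high <- freqs(group_high, "high")
  res <- lapply(seq_along(amino_acids()), function(k) {
    t <- wilcoxon_rank_sum(f_low[, k], f_high[, k])
    ml <- mean(f_low[, k]); mh <- mean(f_high[, k])
    data.frame(aa = amino_acids()[k], mean_freq_low = ml,
               mean_freq_high = mh,
               direction = if (ml > mh) "low" else if (mh > ml) "high"
                           else "none",
               p_value = t$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' SSI by oligomeric state
#'
#' Compares the supersaturation index of monomers vs oligomer subunits and
#' reports, for each state, the percentage of its proteins falling in the
#' bottom and top SSI quantile groups (`floor(n * fraction)` rows per
#' tail, ties by stable id order).
#'
#' @param table proteome table with `id` and `oligomeric_state`
#'   ("monomer"/"oligomer").
#' @param ssi output of [compute_ssi()] on the same table.
#' @param fraction tail fraction (default 0.25: quartiles).
#' @return List: `test` (rank test monomers vs oligomers), `percentages`
#'   (state x low/high matrix, in percent), `n` per state.
#' @export
ssi_group_analysis <- function(table, ssi = compute_ssi(table),
                               fraction = 0.25) {
  m <- merge(ssi, table[, c("id", "oligomeric_state")], by = "id",
             sort = FALSE)
  states <- c("monomer", "oligomer")
  if (!all(states %in% m$oligomeric_state)) {
    stop_stapr("state_missing", "need both monomer and oligomer proteins")
  }
  test <- wilcoxon_rank_sum(m$ssi[m$oligomeric_state == "monomer"],
                            m$ssi[m$oligomeric_state == "oligomer"])
  ord <- order(m$ssi, seq_len(nrow(m)))
  k <- floor(nrow(m) * fraction)
  low_ids <- m$id[ord[seq_len(k)]]
  high_ids <- m$id[ord[seq(nrow(m) - k + 1L, nrow(m))]]
  pct <- sapply(states, function(s) {
    ids <- m$id[m$oligomeric_state == s]
    c(low = 100 * mean(ids %in% low_ids),
      high = 100 * mean(ids %in% high_ids))
  })
  list(test = test, percentages = t(pct),
       n = table(factor(m$oligomeric_state, states)))
}

#' Correlation between two proteome columns
#'
#' Pearson by default (on already log10-transformed abundance), Spearman
#' as a rank-based sensitivity option; two-sided p-value from
#' [stats::cor.test()].
#'
#' @param table data.frame.
#' @param col_a,col_b column names.
#' @param method "pearson" or "spearman".
#' @return List: `r`, `p_value`, `n`, `method`.
#' @export
correlation <- function(table, col_a, col_b, method = "pearson") {
  a <- table[[col_a]]; b <- table[[col_b]]
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 10) stop_stapr("empty_input", "need >= 10 paired finite values")
  if (length(unique(a[ok])) == 1L || length(unique(b[ok])) == 1L) {
    stop_stapr("undefined_correlation", "constant column")
  }
  ct <- suppressWarnings(stats::cor.test(a[ok], b[ok], method = method))
  list(r = unname(ct$estimate), p_value = ct$p.value, n = sum(ok),
       method = method)
}
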