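test_that("rank-sum test matches hand-enumerable cases", {
  r <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p_value, 0.1)               # 2/20 assignments as extreme
  expect_equal(r$method, "exact")
  expect_warning(r2 <- wilcoxon_rank_sum(c(2, 2, 2), c(2, 2, 2)), "identical")
  expect_equal(r2$p_value, 1)
  r3 <- wilcoxon_rank_sum(c(1, 3, 5), c(1, 3, 5))
  expect_gt(r3$p_value, 0.99)                # same multiset: no separation
  expect_error(wilcoxon_rank_sum(numeric(), 1:3), class = "stapr_empty_input")
})

test_that("rank-sum p agrees with exhaustive enumeration for tie-free small samples", {
  set.seed(29)
  for (k in 1:20) {
    n <- sample(2:5, 1); m <- sample(2:5, 1)
    v <- sample(1:50, n + m)                 # tie-free
    x <- v[seq_len(n)]; y <- v[-seq_len(n)]
    expect_equal(wilcoxon_rank_sum(x, y)$p_value, wilcox_enum_p(x, y),
                 tolerance = 1e-12)
  }
})

test_that("SSI arithmetic matches hand computation on a toy table", {
  t5 <- data.frame(id = paste0("p", 1:5),
                   abundance_log10 = c(0, 1, 2, 3, 4),
                   average_score = c(-1, -0.5, 0, 0.25, 1))
  ssi <- compute_ssi(t5)
  C <- (t5$abundance_log10 - 0) / 4
  A <- (t5$average_score + 1) / 2
  expect_equal(ssi$C, C)
  expect_equal(ssi$A, A)
  expect_equal(ssi$ssi, (C + A) / 2)
  # joint extremes pin SSI to 0 and 1
  expect_equal(ssi$ssi[1], 0)
  expect_equal(ssi$ssi[5], 1)
})

test_that("SSI is invariant under affine rescaling of either raw column", {
  set.seed(41)
  t0 <- data.frame(id = sprintf("p%02d", 1:30),
                   abundance_log10 = rnorm(30),
                   average_score = rnorm(30))
  base <- compute_ssi(t0)
  t1 <- t0
  t1$abundance_log10 <- 3.7 * t0$abundance_log10 - 11
  t1$average_score <- 0.2 * t0$average_score + 5
  expect_equal(compute_ssi(t1)$ssi, base$ssi)
  t2 <- t0
  t2$average_score <- 0  # constant score
  expect_error(compute_ssi(t2), class = "stapr_degenerate_normalization")
})

test_that("SSI excludes and counts rows without abundance", {
  t0 <- data.frame(id = paste0("p", 1:6),
                   abundance_log10 = c(1, 2, NA, 4, NA, 6),
                   average_score = c(-1, 0, 1, 2, 3, 4))
  ssi <- compute_ssi(t0)
  expect_equal(nrow(ssi), 4L)
  expect_equal(attr(ssi, "n_excluded"), 2L)
})

test_that("stratification partitions, detects a planted shift, and holds its size", {
  # fraction 0.5 splits all rows with distinct group values into two halves
  t0 <- data.frame(id = paste0("p", 1:10), v = rnorm(10), g = 1:10)
  gc <- stratify_and_compare(t0, "v", "g", fraction = 0.5)
  expect_equal(nrow(gc$low) + nrow(gc$high), 10L)
  expect_length(intersect(gc$low$id, gc$high$id), 0L)
  # planted shift: top-25% group's values shifted by -0.5 SD
  set.seed(71)
  n <- 400
  g <- rnorm(n)
  v <- rnorm(n) - 0.5 * (g > quantile(g, 0.75))
  tp <- data.frame(id = sprintf("p%03d", 1:n), v = v, g = g)
  gp <- stratify_and_compare(tp, "v", "g")
  expect_lt(gp$test$p_value, 0.01)
  expect_gt(gp$summary["low", "median"], gp$summary["high", "median"])
  expect_error(stratify_and_compare(t0[1:8, ], "v", "g", fraction = 0.25),
               class = "stapr_group_too_small")
})

test_that("stratified comparison type-I error is near nominal under the null", {
  set.seed(83)
  reps <- 2000
  hits <- 0L
  for (r in seq_len(reps)) {
    t0 <- data.frame(id = seq_len(400), v = rnorm(400), g = rnorm(400))
    if (stratify_and_compare(t0, "v", "g")$test$p_value < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.03)
  expect_lte(hits / reps, 0.07)
})

test_that("cumulative curves rise from 1/n to 1 over sorted values", {
  t0 <- data.frame(id = paste0("p", 1:20), v = rnorm(20), g = rnorm(20))
  gc <- stratify_and_compare(t0, "v", "g", fraction = 0.25)
  for (curve in gc$curves) {
    expect_equal(curve$cum_freq[length(curve$cum_freq)], 1)
    expect_true(!is.unsorted(curve$x))
    expect_true(!is.unsorted(curve$cum_freq))
  }
})

test_that("operon dispersion: hand-checkable SDs and degenerate operons", {
  t0 <- data.frame(id = paste0("p", 1:6),
                   average_score = c(-1, -0.8, 0.2, 0.6, -0.3, -0.3),
                   operon_id = rep(c("a", "b", "c"), each = 2))
  od <- operon_dispersion(t0, n_perm = 99, seed = 4)
  expect_equal(od$operon_sd$sd[od$operon_sd$operon_id == "a"],
               sd(c(-1, -0.8)))
  expect_equal(od$operon_sd$sd[od$operon_sd$operon_id == "c"], 0)
  expect_equal(od$global_sd, sd(t0$average_score))
  # identical scores within every operon: all SDs 0, fraction 1
  t1 <- data.frame(id = paste0("p", 1:8),
                   average_score = rep(c(-1, 0, 0.4, 1), each = 2),
                   operon_id = rep(letters[1:4], each = 2))
  expect_equal(operon_dispersion(t1, n_perm = 19, seed = 1)$fraction_below, 1)
  expect_error(operon_dispersion(data.frame(id = "x", average_score = 1,
                                            operon_id = "a"),
                                 min_members = 2),
               class = "stapr_no_operons")
})

test_that("random operon labels give a uniform permutation p", {
  set.seed(59)
  ps <- replicate(40, {
    t0 <- data.frame(id = seq_len(60), average_score = rnorm(60),
                     operon_id = sample(rep(sprintf("op%d", 1:12), each = 5)))
    operon_dispersion(t0, n_perm = 199, seed = sample.int(1e6, 1))$perm_p
  })
  # uniform p: roughly half below 0.5, none concentrated at the extreme
  expect_gt(mean(ps < 0.5), 0.2)
  expect_lt(mean(ps < 0.05), 0.35)
})

test_that("LA/HA split classifies operons against the grand mean", {
  t0 <- data.frame(id = paste0("p", 1:4),
                   average_score = c(-1, -1, 0, 0),
                   operon_id = rep(c("a", "b"), each = 2),
                   essential = c("yes", "yes", "no", "unknown"))
  out <- la_ha_split(t0)
  expect_equal(out$grand_mean, -0.5)
  expect_equal(out$operons$class[out$operons$operon_id == "a"], "LA")
  expect_equal(out$operons$class[out$operons$operon_id == "b"], "HA")
  expect_equal(unname(out$counts["LA", "yes"]), 2L)
  expect_equal(unname(out$counts["HA", "no"]), 1L)
  expect_equal(unname(out$n_unknown["HA"]), 1L)
  # boundary: every operon at the grand mean goes to HA by convention
  t1 <- data.frame(id = paste0("p", 1:4), average_score = rep(0.3, 4),
                   operon_id = rep(c("a", "b"), each = 2),
                   essential = "unknown")
  expect_true(all(la_ha_split(t1)$operons$class == "HA"))
})

test_that("fold enrichment follows its defining ratio and hypergeometric tail", {
  fe <- fold_enrichment(5, 10, 50, 1000)
  expect_equal(fe$fold_enrichment, 10)
  # equal rates force FE = 1 (property over a grid of valid counts)
  for (p_b in c(40, 100, 400)) {
    for (rate in c(0.1, 0.25, 0.5)) {
      n_b <- p_b * rate
      for (p_l in c(8, 20)) {
        n_l <- p_l * rate
        if (n_l == round(n_l) && n_b == round(n_b)) {
          expect_equal(fold_enrichment(n_l, p_l, n_b, p_b)$fold_enrichment, 1)
        }
      }
    }
  }
  # hypergeometric tail equals direct choose() arithmetic
  fe2 <- fold_enrichment(3, 8, 20, 100)
  expect_equal(fe2$p_value, hyper_tail(3, 8, 20, 100), tolerance = 1e-12)
  expect_error(fold_enrichment(0, 5, 0, 100),
               class = "stapr_undefined_enrichment")
})

test_that("surface composition: identical groups are null, planted bias is found", {
  g <- lapply(c(2, 3, 4, 5), function(s)
    generate_structure(30, 0.3, 0.2, seed = s)$exposure)
  out <- suppressWarnings(surface_composition_compare(g, g))
  expect_true(all(out$p_value > 0.99))
  expect_equal(nrow(out), 20L)
  # planted: charged low-group surfaces vs aromatic high-group surfaces
  low <- lapply(1:16, function(s)
    generate_structure(60, 0.5, 0.05, seed = 200 + s)$exposure)
  high <- lapply(1:16, function(s)
    generate_structure(60, 0.05, 0.5, seed = 300 + s)$exposure)
  cmp <- suppressWarnings(surface_composition_compare(low, high))
  ekr <- cmp[cmp$aa %in% c("E", "K", "R"), ]
  fyw <- cmp[cmp$aa %in% c("F", "Y", "W"), ]
  expect_true(all(ekr$direction == "low"))
  expect_true(all(fyw$direction == "high"))
  expect_true(all(ekr$p_value <= 0.01))
  expect_true(all(fyw$p_value <= 0.01))
  expect_true(all(cmp$fdr >= cmp$p_value))
})

test_that("SSI group analysis: toy quartiles and planted oligomer shift", {
  t4 <- data.frame(id = paste0("p", 1:4),
                   abundance_log10 = c(0, 1, 2, 3),
                   average_score = c(0, 1, 2, 3),
                   oligomeric_state = c("monomer", "monomer",
                                        "oligomer", "oligomer"))
  out <- suppressWarnings(ssi_group_analysis(t4))
  # floor(4 * 0.25) = 1 protein per tail: p1 lowest, p4 highest
  expect_equal(unname(out$percentages["monomer", "low"]), 50)
  expect_equal(unname(out$percentages["oligomer", "high"]), 50)
  expect_equal(unname(out$percentages["oligomer", "low"]), 0)
  expect_error(ssi_group_analysis(within(t4, oligomeric_state <- "monomer")),
               class = "stapr_state_missing")
  # planted shift recovered at scale
  set.seed(97)
  n <- 400
  olig <- rep(c(TRUE, FALSE), each = n / 2)
  tp <- data.frame(id = sprintf("p%03d", 1:n),
                   abundance_log10 = rnorm(n) + 0.6 * olig,
                   average_score = rnorm(n) + 0.6 * olig,
                   oligomeric_state = ifelse(olig, "oligomer", "monomer"))
  op <- ssi_group_analysis(tp)
  expect_lt(op$test$p_value, 0.01)
  expect_gt(op$percentages["oligomer", "high"],
            op$percentages["monomer", "high"])
})

test_that("correlation wrapper: exact line, arithmetic check, contract errors", {
  t0 <- data.frame(a = 1:12, b = 2 * (1:12))
  expect_equal(correlation(t0, "a", "b")$r, 1)
  t5 <- data.frame(a = c(1, 2, 4, 5, 7, 8, 10, 11, 13, 20),
                   b = c(2, 1, 5, 4, 9, 6, 11, 10, 12, 18))
  r_hand <- sum((t5$a - mean(t5$a)) * (t5$b - mean(t5$b))) /
    sqrt(sum((t5$a - mean(t5$a))^2) * sum((t5$b - mean(t5$b))^2))
  expect_equal(correlation(t5, "a", "b")$r, r_hand)
  expect_error(correlation(t0[1:5, ], "a", "b"), class = "stapr_empty_input")
  t0$c <- 3
  expect_error(correlation(t0, "a", "c"),
               class = "stapr_undefined_correlation")
  expect_equal(correlation(t5, "a", "b", method = "spearman")$method,
               "spearman")
})

test_that("null correlation distribution matches the analytic reference", {
  set.seed(13)
  n <- 600
  rs <- replicate(400, cor(rnorm(n), rnorm(n)))
  # 95th percentile of |r| under the null ~ qnorm(0.975)/sqrt(n)
  expect_equal(unname(quantile(abs(rs), 0.95)), qnorm(0.975) / sqrt(n),
               tolerance = 0.15)
  # p-values from the wrapper are uniform enough at alpha = 0.05
  ps <- replicate(400, correlation(data.frame(a = rnorm(50), b = rnorm(50)),
                                   "a", "b")$p_value)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.04)
})
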