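test_that("residue centers: Gly uses CA, Ala uses CB, Leu averages its side chain", {
  atoms <- data.frame(
    position = c(1L, 1L, 2L, 2L, rep(3L, 6)),
    aa = c("G", "G", "A", "A", rep("L", 6)),
    atom_name = c("N", "CA", "CA", "CB", "N", "CA", "CB", "CG", "CD1", "CD2"),
    element = c("N", "C", "C", "C", "N", "C", "C", "C", "C", "C"),
    x = c(0, 1, 5, 6, 10, 11, 12, 13, 14, 15),
    y = 0, z = 0, stringsAsFactors = FALSE)
  rec <- structure_record("ctr", atoms)
  ctr <- residue_centers(rec)
  expect_equal(unname(ctr[1, "x"]), 1)                  # glycine CA
  expect_equal(unname(ctr[2, "x"]), 6)                  # alanine CB
  expect_equal(unname(ctr[3, "x"]), mean(c(12, 13, 14, 15)))  # Leu side chain
})

test_that("single fully exposed residue scores its intrinsic propensity", {
  for (aa in c("I", "D")) {
    rec <- ca_record(cbind(0, 0, 0), aa)
    res <- stap(rec, manual_exposure(rec, 1))
    expect_equal(res$score, unname(a3v_scale()[aa]))
    expect_equal(res$average_score, unname(a3v_scale()[aa]))
  }
})

test_that("fully buried chains score exactly zero", {
  g <- generate_structure(10, 0.5, 0.2, seed = 3)
  res <- stap(g$record, manual_exposure(g$record, rep(0.01, 10)))
  expect_equal(res$score, rep(0, 10))
  expect_equal(res$average_score, 0)
})

test_that("spatial score equals the brute-force double loop on seeded globules", {
  for (seed in c(2, 9, 41)) {
    g <- generate_structure(12, 0.4, 0.2, seed = seed)
    res <- stap(g$record, g$exposure)
    ref <- brute_stap(g$record, g$exposure)
    expect_equal(res$score, ref$score, tolerance = 1e-12)
    expect_equal(res$average_score, ref$average_score, tolerance = 1e-12)
  }
})

test_that("scores are invariant under rigid motion", {
  g <- generate_structure(20, 0.4, 0.2, seed = 15)
  ep <- g$exposure
  res0 <- stap(g$record, ep)
  set.seed(27)
  rec2 <- rotate_record(g$record, random_rotation(), shift = c(12, -40, 7))
  res1 <- stap(rec2, manual_exposure(rec2, ep$relative_sasa))
  expect_equal(res1$score, res0$score, tolerance = 1e-6)
})

test_that("raising one exposed residue's propensity never lowers the average score", {
  set.seed(55)
  s <- a3v_scale()
  g <- generate_structure(15, 0.4, 0.2, seed = 8)
  ep <- g$exposure
  base <- stap(g$record, ep)$average_score
  exposed <- which(ep$relative_sasa >= 0.05)
  for (k in 1:5) {
    i <- sample(exposed, 1)
    aa_i <- record_sequence(g$record, FALSE)[i]
    higher <- names(s)[s > s[aa_i]]
    if (!length(higher)) next
    at <- g$record$atoms
    at$aa[at$position == i] <- sample(higher, 1)
    rec2 <- structure_record("mut", at)
    ep2 <- ep; ep2$aa <- record_sequence(rec2, FALSE)
    expect_gte(stap(rec2, ep2)$average_score, base)
  }
})

test_that("residues outside the sphere radius cannot affect a score", {
  # three residues on a line: 0, 5, 30 A; the far one is outside both spheres
  xyz <- rbind(c(0, 0, 0), c(5, 0, 0), c(30, 0, 0))
  rec <- ca_record(xyz, c("I", "D", "W"))
  ep <- manual_exposure(rec, c(1, 1, 1))
  res <- stap(rec, ep)
  # perturb the distant residue's identity and position
  xyz2 <- rbind(c(0, 0, 0), c(5, 0, 0), c(55, 3, -2))
  rec2 <- ca_record(xyz2, c("I", "D", "F"))
  res2 <- stap(rec2, manual_exposure(rec2, c(1, 1, 1)))
  expect_equal(res$score[1:2], res2$score[1:2])
  # a residue exactly at the boundary has weight zero
  xyz3 <- rbind(c(0, 0, 0), c(10, 0, 0))
  rec3 <- ca_record(xyz3, c("I", "W"))
  res3 <- stap(rec3, manual_exposure(rec3, c(1, 1)))
  expect_equal(res3$score[1], unname(a3v_scale()["I"]))
})

test_that("designed surfaces set the sign of the average score", {
  gq <- generate_structure(40, surface_charged_fraction = 1,
                           surface_aromatic_fraction = 0, seed = 61)
  expect_true(all(strsplit(gq$sequence, "")[[1]][gq$exposure$is_surface] %in%
                    c("D", "E", "K", "R")))
  expect_lt(stap(gq$record, gq$exposure)$average_score, 0)
  ga <- generate_structure(40, surface_charged_fraction = 0,
                           surface_aromatic_fraction = 1, seed = 61)
  expect_true(all(strsplit(ga$sequence, "")[[1]][ga$exposure$is_surface] %in%
                    c("F", "Y", "W")))
  expect_gt(stap(ga$record, ga$exposure)$average_score, 0)
})

test_that("naive point mutations relabel residues and enforce the wt contract", {
  g <- generate_structure(20, 0.6, 0.1, seed = 77)
  aa <- record_sequence(g$record, FALSE)
  m <- apply_mutations(g$record, data.frame(position = 4L, wt_aa = aa[4],
                                            new_aa = "L"))
  expect_equal(record_sequence(m, FALSE)[4], "L")
  expect_error(apply_mutations(g$record,
                               data.frame(position = 4L, wt_aa = aa[4],
                                          new_aa = "B")),
               class = "stapr_invalid_residue")
  wrong_wt <- setdiff(amino_acids(), aa[4])[1]
  expect_error(apply_mutations(g$record,
                               data.frame(position = 4L, wt_aa = wrong_wt,
                                          new_aa = "L")),
               class = "stapr_mutation_mismatch")
  expect_error(apply_mutations(g$record,
                               data.frame(position = 999L, wt_aa = "A",
                                          new_aa = "L")),
               class = "stapr_position_not_found")
})

test_that("charged-to-aliphatic surface mutations raise the average score", {
  g <- generate_structure(40, surface_charged_fraction = 0.8,
                          surface_aromatic_fraction = 0, seed = 91)
  ep <- g$exposure
  wt_score <- stap(g$record, ep)$average_score
  aa <- record_sequence(g$record, FALSE)
  targets <- which(ep$is_surface & aa %in% c("D", "E", "K"))[1:4]
  muts <- data.frame(position = targets, wt_aa = aa[targets], new_aa = "L")
  mrec <- apply_mutations(g$record, muts)
  mut_score <- stap(mrec, relative_exposure(mrec))$average_score
  expect_gt(mut_score, wt_score)
})
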