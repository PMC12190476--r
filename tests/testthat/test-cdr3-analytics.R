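test_that("cdr3Length counts residues and rejects illegal input", {
  expect_equal(cdr3Length("CALWYSNHWVF"), 11L)
  expect_equal(cdr3Length("CASSF"), 5L)
  expect_equal(cdr3Length(c("CAF", "CASSLGAYEQYF")), c(3L, 12L))
  expect_error(cdr3Length(""), "validation")
  expect_error(cdr3Length("CASS1F"), "validation")
})

test_that("length distributions are simplex-valued and match direct tallies", {
  rt <- make_rep(c("CALWYSNHWVF", "CALWYSNHWVA", "CQQSNEDPLTFGW",
                   "CASSLGAYEQYFGAG"))
  ld <- lengthDistribution(rt)
  expect_equal(ld$frequency[ld$length == 11], 0.5)
  expect_equal(ld$frequency[ld$length == 13], 0.25)
  expect_equal(ld$frequency[ld$length == 15], 0.25)

  one <- lengthDistribution(make_rep("CASSF"))
  expect_equal(one$frequency, 1)

  set.seed(11)
  lens <- sample(10:18, 1000, replace = TRUE)
  rt <- make_rep(vapply(lens, random_junction, character(1)),
                 cluster = sample(c("a", "b"), 1000, TRUE))
  ld <- lengthDistribution(rt, "cluster")
  for (g in unique(ld$group)) {
    sub <- ld[ld$group == g, ]
    expect_equal(sum(sub$frequency), 1, tolerance = 1e-9)
    manual <- table(lens[rt@clonotypes$cluster == g])
    expect_equal(sub$n[match(names(manual), sub$length)],
                 as.numeric(manual))
  }
  # count weighting with unit counts equals clonotype weighting
  expect_equal(lengthDistribution(rt, "cluster", weighting = "count"), ld)
})

test_that("V gene usage ranks by frequency with name-order tie breaks", {
  rt <- make_rep(c("CASSF", "CASSG", "CASSH"),
                 v_call = c("TRBV3", "TRBV3", "TRBV5"))
  u <- vGeneUsage(rt)
  expect_equal(u$usage$frequency[u$usage$v_call == "TRBV3"], 2 / 3)
  expect_equal(u$top$v_call[1], "TRBV3")

  rt <- make_rep(c("CASSF", "CASSG", "CASSH"),
                 v_call = c("TRBV9", "TRBV2", "TRBV11"))
  u <- vGeneUsage(rt, top_k = 2)
  expect_equal(u$top$v_call, c("TRBV11", "TRBV2"))  # uniform ties: name order

  sim <- simulateRepertoire(repertoireSimConfig(
    n_clusters = 4, clones_per_cluster = 250, seed = 3))
  top <- vGeneUsage(sim$table, "cluster", top_k = 5)$top
  for (g in unique(top$group))
    expect_true("TRBV3" %in% top$v_call[top$group == g], info = g)
})

test_that("position frequency matrices equal a brute-force tally", {
  rt <- make_rep(c("CAF", "CGF"))
  pfm <- positionFrequencyMatrix(rt, 3)
  expect_equal(pfm@freqs[2, c("A", "G")], c(A = 0.5, G = 0.5))
  expect_equal(unname(pfm@freqs[1, "C"]), 1)
  expect_equal(unname(pfm@freqs[3, "F"]), 1)

  one <- positionFrequencyMatrix(make_rep("CASSF"), 5)
  expect_true(all(apply(one@freqs, 1, max) == 1))

  set.seed(5)
  seqs <- vapply(rep(13, 200), random_junction, character(1))
  counts <- sample(1:5, 200, replace = TRUE)
  rt <- make_rep(seqs, count = counts)
  expect_equal(positionFrequencyMatrix(rt, 13)@freqs, oracle_pfm(seqs))
  expect_equal(positionFrequencyMatrix(rt, 13, weighting = "count")@freqs,
               oracle_pfm(seqs, counts))

  # clones containing X are excluded and reported
  rt <- make_rep(c("CAXSF", "CASSF"))
  pfm <- positionFrequencyMatrix(rt, 5)
  expect_equal(pfm@nExcluded, 1L)
  expect_equal(pfm@support, 1)
  expect_warning(positionFrequencyMatrix(make_rep("CAF"), 13), "empty")
})

test_that("chemistry class fractions aggregate the PFM and conserve mass", {
  pfm <- positionFrequencyMatrix(make_rep(c("CAF", "CDF")), 3)
  cc <- classifyPositionChemistry(pfm)
  p2 <- cc[cc$position == 2, ]
  expect_equal(p2$fraction[p2$class == "hydrophobic"], 0.5)
  expect_equal(p2$fraction[p2$class == "negatively_charged"], 0.5)
  expect_equal(cc$fraction[cc$position == 1 & cc$class == "special"], 1)
  agg <- tapply(cc$fraction, cc$position, sum)
  expect_true(all(abs(agg - 1) < 1e-9))
})

test_that("motif grammar matches its recursive oracle and flags bad patterns", {
  expect_true(motifMatch("CQQSNEDPLTF", "CQQ(4)PXTF"))
  expect_true(motifMatch("CASSLGAYEQYF", "CA*F"))
  expect_false(motifMatch("CASSLGAYEQYW", "CA*F"))
  expect_true(motifMatch("CAY", "C?Y"))
  expect_error(motifMatch("CASSF", "CA(x)F"), "position 4")
  expect_error(motifMatch("CASSF", "CA(3F"), "unclosed")

  set.seed(23)
  pats <- c("CA(3)F", "C*YW", "CQQ?PXTF", "CASS*", "C(2)S(2)F", "CA*Y*F")
  for (i in seq_len(2000)) {
    s <- random_junction(sample(6:14, 1))
    p <- sample(pats, 1)
    expect_identical(motifMatch(s, p), oracle_motif_match(s, p),
                     info = paste(s, p))
  }
})

test_that("motif conformity recovers an exactly planted template fraction", {
  sim <- simulateRepertoire(repertoireSimConfig(
    n_clusters = 1, clones_per_cluster = 100,
    n_shared = 0, n_treatment_unique = 0, n_cross_tissue = 0,
    motif_templates = list(list(pattern = "CQQ(4)PXTF", n = 30)),
    seed = 9))
  expect_equal(length(sim$truth$motif_sequence_ids), 30)
  expect_equal(motifConformity(sim$table, "CQQ(4)PXTF"), 0.30)
})

test_that("isotype usage normalises over assigned records per group", {
  rt <- make_rep(c("CARF", "CARG", "CARH"), chain = "IGH",
                 c_call = c("IGHM", "IGHM", "IGHD"))
  iso <- isotypeUsage(rt)
  expect_equal(iso$usage$frequency[iso$usage$c_call == "IGHM"], 2 / 3)
  expect_equal(sum(iso$usage$frequency), 1)

  rt <- make_rep(c("CARF", "CARG"), chain = "IGH", c_call = c("", ""))
  iso <- isotypeUsage(rt)
  expect_null(iso$usage)
  expect_equal(iso$unassigned$n, 2)

  probs <- c(IGHM = 0.5, IGHD = 0.2, IGHG1 = 0.15, IGHA = 0.15)
  sim <- simulateRepertoire(repertoireSimConfig(
    n_clusters = 1, clones_per_cluster = 800, chain = "IGH",
    length_distribution = c(`11` = 1), isotype_probs = probs,
    n_shared = 0, n_treatment_unique = 0, n_cross_tissue = 0, seed = 2))
  iso <- isotypeUsage(sim$table)$usage
  for (k in names(probs)) {
    got <- iso$frequency[iso$c_call == k]
    tol <- 3 * sqrt(probs[[k]] * (1 - probs[[k]]) / 800)
    expect_lt(abs(got - probs[[k]]), tol)
  }
})
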