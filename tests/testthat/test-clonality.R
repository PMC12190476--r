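test_that("clone keys follow the mode contract and include the chain", {
  df <- data.frame(chain = c("TRB", "TRB", "IGH"),
                   junction_aa = c("CASSF", "CASSF", "CASSF"),
                   v_call = c("TRBV3", "TRBV5", "IGHV1"))
  expect_equal(cloneKey(df, "cdr3_aa")[1], "TRB|CASSF")
  expect_equal(cloneKey(df, "cdr3_aa")[1], cloneKey(df, "cdr3_aa")[2])
  expect_false(cloneKey(df, "cdr3_aa+v")[1] == cloneKey(df, "cdr3_aa+v")[2])
  expect_false(cloneKey(df, "cdr3_aa")[1] == cloneKey(df, "cdr3_aa")[3])
})

test_that("expansion profiles bin counts and match the entropy oracle", {
  singletons <- make_rep(vapply(rep(12, 10), random_junction, character(1)))
  prof <- expansionProfile(singletons)
  expect_equal(prof$`1`, 10L)
  expect_equal(prof$clonality_index, 0)

  mono <- make_rep("CASSF", count = 50L)
  expect_equal(expansionProfile(mono)$clonality_index, 1)

  set.seed(13)
  counts <- sample(1:60, 30, replace = TRUE, prob = (1:60)^-2.5)
  rt <- make_rep(vapply(rep(13, 30), random_junction, character(1)),
                 count = counts)
  prof <- expansionProfile(rt)
  expect_equal(prof$clonality_index, oracle_clonality(counts),
               tolerance = 1e-12)
  expect_equal(prof$`1` + prof$`2-3` + prof$`4-9` + prof$`>=10`,
               prof$n_clonotypes)
  # invariance under uniform count rescaling
  rt10 <- make_rep(clonotypes(rt)$junction_aa, count = counts * 10L)
  expect_equal(expansionProfile(rt10)$clonality_index,
               prof$clonality_index, tolerance = 1e-12)
})

test_that("overlap partitions obey set algebra and match the oracle", {
  rt <- make_rep(c("CAD", "CAY", "CAY", "CAE"),
                 treatment = c("A", "A", "B", "B"))
  cmp <- overlapPartition(rt, "treatment")
  expect_equal(sharedKeys(cmp), "TRB|CAY")
  expect_equal(uniqueKeys(cmp, "A"), "TRB|CAD")
  expect_equal(uniqueKeys(cmp, "B"), "TRB|CAE")

  same <- make_rep(c("CAF", "CAG", "CAF", "CAG"),
                   treatment = c("A", "A", "B", "B"))
  cmp <- overlapPartition(same, "treatment")
  expect_equal(length(sharedKeys(cmp)), 2)
  expect_equal(length(uniqueKeys(cmp, "A")), 0)

  set.seed(19)
  for (i in 1:100) {
    n <- sample(6:30, 1)
    ks <- sprintf("CA%s", sample(c("A", "D", "E", "F", "G", "H", "K", "L"),
                                 n, replace = TRUE))
    gr <- sample(c("A", "B", "C"), n, replace = TRUE)
    if (length(unique(gr)) < 2) next
    rt <- make_rep(ks, treatment = gr)
    cmp <- overlapPartition(rt, "treatment")
    orc <- oracle_partition(paste0("TRB|", ks), gr)
    expect_setequal(sharedKeys(cmp), orc$shared)
    for (g in unique(gr))
      expect_setequal(uniqueKeys(cmp, g), orc$unique[[g]])
    # closure: |unique_A| + |shared_AB| = distinct keys of A (pairwise)
    gg <- colnames(membershipMatrix(cmp))
    for (a in gg) for (b in setdiff(gg, a)) {
      mem <- orc$membership[, c(a, b), drop = FALSE]
      pairkeys <- rownames(mem)[mem[, 1]]
      uA <- sum(mem[, 1] & !mem[, 2])
      expect_equal(uA + length(pairwiseShared(cmp, a, b)), length(pairkeys))
    }
  }
  expect_error(overlapPartition(make_rep("CAF", treatment = "A"),
                                "treatment"), "two groups")
})

test_that("planted shared and unique clones are recovered exactly", {
  sim <- simulateRepertoire(repertoireSimConfig(
    n_clusters = 2, clones_per_cluster = 150, n_shared = 6,
    n_treatment_unique = 7, n_cross_tissue = 0, seed = 21))
  cmp <- overlapPartition(sim$table, "treatment")
  expect_true(all(sim$truth$shared_keys %in% sharedKeys(cmp)))
  for (tr in names(sim$truth$unique_keys))
    expect_true(all(sim$truth$unique_keys[[tr]] %in% uniqueKeys(cmp, tr)))
  # partition closure over the whole lattice
  mm <- membershipMatrix(cmp)
  expect_true(all(rowSums(mm) >= 1))
  expect_equal(length(sharedKeys(cmp)) +
                 sum(vapply(colnames(mm), function(g)
                   length(uniqueKeys(cmp, g)), numeric(1))) +
                 sum(rowSums(mm) > 1 & rowSums(mm) < ncol(mm)),
               nrow(mm))
})

test_that("cross-tissue clone tracking flags exactly the planted clones", {
  sim <- simulateRepertoire(repertoireSimConfig(
    n_clusters = 2, clones_per_cluster = 120, n_shared = 0,
    n_treatment_unique = 0, n_cross_tissue = 9, seed = 5))
  tr <- trackClones(sim$table, "tissue")
  expect_setequal(tr$key[tr$dual_tissue], sim$truth$cross_tissue_keys)
  dual <- tr[tr$dual_tissue, ]
  expect_true(all(dual$count_muscle > 0 & dual$count_ILN > 0))
  expect_false(any(tr$dual_tissue[tr$count_ILN == 0]))
})

test_that("clone abundance and top clones follow count aggregation", {
  rt <- make_rep(c("CAF", "CAF", "CAG"), count = c(2L, 1L, 1L))
  ab <- cloneAbundance(rt, "TRB|CAF")
  expect_equal(ab$proportion, 0.75)
  expect_equal(ab$count, 3)
  expect_equal(cloneAbundance(rt, "TRB|CAW")$count, 0)
  expect_equal(cloneAbundance(rt, "TRB|CAW")$proportion, 0)
  # proportions over all keys sum to 1
  tc <- topClones(rt, k = 10)
  expect_equal(sum(tc$proportion), 1)

  ties <- make_rep(c("CAA", "CAD", "CAC"), count = c(5L, 5L, 1L))
  top2 <- topClones(ties, k = 2)
  expect_equal(top2$key, c("TRB|CAA", "TRB|CAD"))
  expect_equal(nrow(topClones(ties, k = 99)), 3)
})

test_that("group-unique expanded clones equal generator truth", {
  sim <- simulateRepertoire(repertoireSimConfig(
    n_clusters = 2, clones_per_cluster = 100,
    expansion = list(type = "singleton"),
    n_shared = 4, n_treatment_unique = 6, n_cross_tissue = 0, seed = 33))
  got <- uniqueExpandedClones(sim$table, "treatment", group = "PE",
                              min_count = 2)
  # background is all singletons, so only planted PE-unique clones qualify
  expect_setequal(got$key, sim$truth$unique_keys$PE)
  expect_true(all(got$count >= 2))
})
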