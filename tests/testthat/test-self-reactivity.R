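test_that("SRI tables load, reject gaps, and round-trip", {
  cfg <- loadSRITable(sri_toy_path(), threshold = 1.5)
  expect_s4_class(cfg, "SRIConfig")
  expect_equal(unname(cfg@weights["6", "Y"]), 1)
  expect_equal(unname(cfg@weights["7", "W"]), 1)
  expect_equal(sum(cfg@weights), 2)

  tf <- withr::local_tempfile(fileext = ".tsv")
  tab <- read.delim(sri_toy_path())
  write.table(tab[!(tab$position == 7 & tab$residue == "Q"), ], tf,
              sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(loadSRITable(tf), "P7:Q")

  writeSRITable(cfg, tf)
  back <- loadSRITable(tf, threshold = 1.5)
  expect_equal(back@weights, cfg@weights)

  # set-based load: residues define the promoting set
  prom <- loadSRITable(system.file("extdata", "sri_promoting_aromatic.tsv",
                                   package = "clonoSpat"),
                       combine = "both_promoting")
  expect_equal(prom@promotingSet, c("F", "W", "Y"))
})

test_that("sriScore follows the toy table and the 13-mer rule", {
  cfg <- toy_sri()
  expect_equal(sriScore("CASSLYWNTEVFF", cfg), 2)   # P6=Y, P7=W
  expect_true(is.na(sriScore("CALWYSNHWVF", cfg)))  # 11-mer: undefined
  expect_true(is.na(sriScore("CASSLXWNTEVFF", cfg)))  # X at P6

  set.seed(31)
  seqs <- vapply(rep(13, 500), random_junction, character(1))
  w <- matrix(rnorm(40), 2, 20, dimnames = list(c("6", "7"), AA))
  cfg <- SRIConfig(weights = w, threshold = 0)
  got <- sriScore(seqs, cfg)
  want <- vapply(seqs, function(s)
    w["6", substr(s, 6, 6)] + w["7", substr(s, 7, 7)], numeric(1),
    USE.NAMES = FALSE)
  expect_identical(got, want)
})

test_that("classification uses an inclusive threshold and honours NA", {
  cfg <- toy_sri(threshold = 1.5)
  expect_true(classifySelfReactive(2, cfg))
  expect_true(classifySelfReactive(1.5, cfg))   # boundary: >= convention
  expect_false(classifySelfReactive(1.49, cfg))
  expect_true(is.na(classifySelfReactive(NA_real_, cfg)))

  zero <- SRIConfig(list(`6` = c(), `7` = c()), threshold = 0.5)
  set.seed(1)
  seqs <- vapply(rep(13, 50), random_junction, character(1))
  expect_false(any(classifySelfReactive(sriScore(seqs, zero), zero)))
})

test_that("cluster fractions keep exclusion bookkeeping exact", {
  rt <- make_rep(c("CASSLYWNTEVFF", "CASSYYWNTEVFF", "CALWYSNHWVF"),
                 cluster = "c1")
  res <- clusterSelfReactivity(rt, toy_sri(), "cluster")
  expect_equal(res$n_scored, 2)
  expect_equal(res$n_excluded, 1)
  expect_equal(res$fraction, 1)  # every scored clone classifies positive
  expect_equal(res$n_scored + res$n_excluded, res$n_total)

  short <- make_rep(c("CALWYSNHWVF", "CASSF"))
  res <- clusterSelfReactivity(short, toy_sri())
  expect_equal(res$n_scored, 0)
  expect_true(is.na(res$fraction))
})

test_that("set-based both_promoting equals sum with 0/1 weights at threshold 2", {
  prom <- c("F", "W", "Y")
  set_cfg <- SRIConfig(combine = "both_promoting", promotingSet = prom)
  w <- matrix(0, 2, 20, dimnames = list(c("6", "7"), AA))
  w[, prom] <- 1
  sum_cfg <- SRIConfig(weights = w, threshold = 2)
  set.seed(17)
  seqs <- vapply(rep(13, 300), random_junction, character(1))
  expect_identical(
    classifySelfReactive(sriScore(seqs, set_cfg), set_cfg),
    classifySelfReactive(sriScore(seqs, sum_cfg), sum_cfg))
})

test_that("raising any single weight never lowers scores or fractions", {
  set.seed(41)
  seqs <- vapply(rep(13, 200), random_junction, character(1))
  rt <- make_rep(seqs)
  w <- matrix(rnorm(40), 2, 20, dimnames = list(c("6", "7"), AA))
  base_cfg <- SRIConfig(weights = w, threshold = 0.3)
  base_scores <- sriScore(seqs, base_cfg)
  base_frac <- clusterSelfReactivity(rt, base_cfg)$fraction
  for (k in 1:20) {
    w2 <- w
    pos <- sample(c("6", "7"), 1); res <- sample(AA, 1)
    w2[pos, res] <- w2[pos, res] + runif(1, 0, 2)
    cfg2 <- SRIConfig(weights = w2, threshold = 0.3)
    expect_true(all(sriScore(seqs, cfg2) >= base_scores))
    expect_gte(clusterSelfReactivity(rt, cfg2)$fraction, base_frac)
  }
})

test_that("aromatic P6/P7 fractions follow or/and semantics", {
  rt <- make_rep(c("CASSLYANTEVFF",   # P6=Y aromatic
                   "CASSLLLNTEVFF"))  # neither aromatic
  expect_equal(aromaticP67Fraction(rt)$fraction, 0.5)
  expect_equal(aromaticP67Fraction(rt, mode = "and")$fraction, 0)
  expect_equal(aromaticP67Fraction(rt, aromaticSet = character(0))$fraction, 0)
})
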