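test_that("module scores vanish when controls equal the signature", {
  # 40 genes in 4 identical-expression blocks: every control draw equals the
  # signature gene's own expression profile, so scores must be ~0
  set.seed(2)
  n_obs <- 30
  blocks <- lapply(1:4, function(b) {
    prof <- runif(n_obs, 0, 2) + b
    matrix(rep(prof, each = 10), 10, n_obs, byrow = FALSE)
  })
  m <- do.call(rbind, blocks)
  rownames(m) <- sprintf("g%02d", 1:40)
  colnames(m) <- sprintf("c%02d", seq_len(n_obs))
  sc <- moduleScore(m, c("g01", "g11", "g21"),
                    moduleScoreParams(n_bins = 4, n_ctrl = 5, seed = 1))
  expect_lt(max(abs(sc)), 1e-12)
})

test_that("module scores are gene-order invariant and seeded", {
  set.seed(3)
  m <- matrix(rnorm(200 * 40, mean = 5), 200, 40,
              dimnames = list(sprintf("g%03d", 1:200), sprintf("c%02d", 1:40)))
  gs <- c("g005", "g050", "g100")
  p <- moduleScoreParams(n_bins = 10, n_ctrl = 8, seed = 4)
  s1 <- moduleScore(m, gs, p)
  s2 <- moduleScore(m[sample(nrow(m)), ], gs, p)
  expect_equal(s1, s2)
  expect_equal(moduleScore(m, gs, p), s1)  # reproducible for fixed seed
  expect_warning(moduleScore(m, c(gs, "absent"), p), "absent")
  expect_error(suppressWarnings(moduleScore(m, "absent", p)),
               "empty gene set")
})

test_that("planted module-score offsets are recovered on spot maps", {
  sim <- simulateSpatial(spatialSimConfig(nrow = 30, ncol = 30,
                                          n_genes = 400, n_signature = 20,
                                          delta = 0.5, n_pairs = 0, seed = 8))
  sc <- moduleScore(sim$lattice, sim$truth$signature_genes,
                    moduleScoreParams(seed = 8))
  ms <- mapScoresToSpots(sc, sim$lattice)
  inj <- sim$truth$injury_mask[ms$map$barcode]
  d <- mean(ms$map$score[inj]) - mean(ms$map$score[!inj])
  expect_lt(abs(d - 0.5), 0.05)
})

test_that("score maps summarise in-tissue spots only", {
  m <- matrix(1, 2, 4, dimnames = list(c("g1", "g2"), sprintf("b%d", 1:4)))
  lat <- SpotLattice(m, data.frame(barcode = sprintf("b%d", 1:4), x = 1:4,
                                   y = 1, in_tissue = c(TRUE, TRUE, TRUE,
                                                        FALSE)))
  sc <- setNames(c(2, 2, 2, 99), sprintf("b%d", 1:4))
  ms <- mapScoresToSpots(sc, lat)
  expect_equal(ms$summary$mean, 2)
  expect_equal(ms$summary$median, 2)
  expect_error(mapScoresToSpots(unname(sc), lat), "alignment")
})

test_that("self- and anti-correlated genes give +1 / -1 maps", {
  set.seed(6)
  e <- runif(36, 1, 3)
  lat <- make_lattice(6, 6, list(gA = e, gB = e, gC = 10 - e))
  p <- coincidenceParams(bandwidth = 1.5, min_effective_neighbors = 2)
  self <- localCoincidence(lat, "gA", "gB", p)
  expect_true(all(self@values[self@valid] > 1 - 1e-9))
  expect_equal(coincidenceArea(self, 0.2), 1)
  expect_equal(coincidenceArea(self, 1), 0)  # strict inequality at the top
  anti <- localCoincidence(lat, "gA", "gC", p)
  expect_true(all(anti@values[anti@valid] < -1 + 1e-9))
  expect_error(localCoincidence(lat, "gA", "nope", p), "nope")
})

test_that("local coincidence equals the brute-force weighted-Pearson oracle", {
  set.seed(7)
  for (rep_i in 1:12) {
    a <- runif(49, 0, 4); b <- runif(49, 0, 4)
    lat <- make_lattice(7, 7, list(gA = a, gB = b))
    p <- coincidenceParams(bandwidth = runif(1, 0.8, 2.5),
                           min_effective_neighbors = runif(1, 1, 6))
    map <- localCoincidence(lat, "gA", "gB", p)
    co <- spotCoords(lat)
    orc <- oracle_local_coincidence(co$x, co$y, a, b, p$bandwidth,
                                    p$min_effective_neighbors)
    expect_equal(map@valid, orc$valid)
    expect_equal(map@values, orc$values, tolerance = 1e-10)
    # symmetry in gene order
    swapped <- localCoincidence(lat, "gB", "gA", p)
    expect_equal(swapped@values, map@values, tolerance = 1e-12)
    # bounds and monotone area
    v <- map@values[map@valid]
    expect_true(all(v >= -1 & v <= 1))
    if (any(map@valid)) {
      thr <- seq(-1, 1, by = 0.25)
      areas <- vapply(thr, function(t) coincidenceArea(map, t), numeric(1))
      expect_true(all(diff(areas) <= 0))
    }
  }
})

test_that("out-of-tissue spots and low-weight spots are invalid", {
  set.seed(9)
  m <- matrix(runif(2 * 9, 1, 2), 2, 9,
              dimnames = list(c("gA", "gB"), sprintf("b%d", 1:9)))
  co <- data.frame(barcode = sprintf("b%d", 1:9),
                   x = c(1:8, 50), y = 1, in_tissue = c(rep(TRUE, 8), TRUE))
  lat <- SpotLattice(m, co)
  map <- localCoincidence(lat, "gA", "gB",
                          coincidenceParams(bandwidth = 1,
                                            min_effective_neighbors = 1.5))
  expect_false(map@valid[9])  # isolated spot: effective weight ~1 < 1.5
  expect_true(is.na(map@values[9]))

  const <- make_lattice(3, 3, list(gA = rep(1, 9), gB = runif(9)))
  map <- localCoincidence(const, "gA", "gB",
                          coincidenceParams(min_effective_neighbors = 1))
  expect_true(all(!map@valid))  # zero variance everywhere
  expect_warning(a <- coincidenceArea(map), "no valid spots")
  expect_true(is.na(a))
})
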