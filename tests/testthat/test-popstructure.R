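test_that("VanRaden GRM has the expected exact and statistical properties", {
  # 1 marker, genotypes {0, 2}, p = 0.5: Z = (-1, 1), denom = 0.5 -> +/- 2...
  # entries are Z Z' / (2 p q) = {2, -2; -2, 2} / ... hand value: ZZ'/0.5
  g <- toy_geno(matrix(c(0L, 2L), 1, 2))
  K <- computeGRM(g)
  expect_equal(unname(K), matrix(c(2, -2, -2, 2), 2), tolerance = 1e-12)
  # duplicated sample: off-diagonal equals both diagonals
  sim <- small_sim(41, n_pop1 = 30, n_pop2 = 10)
  d <- dosages(sim$geno)
  d2 <- cbind(d, dup = d[, 1])
  si <- rbind(sampleInfo(sim$geno), sampleInfo(sim$geno)[1, ])
  si$sample_id[nrow(si)] <- "dup"
  K2 <- computeGRM(GenotypeData(d2, markerMap(sim$geno), si))
  id1 <- colnames(d)[1]
  expect_equal(K2[id1, "dup"], K2[id1, id1], tolerance = 1e-10)
  expect_equal(K2[id1, "dup"], K2["dup", "dup"], tolerance = 1e-10)
  # random-mating population: mean diagonal near 1
  cfg <- simConfig(n_pop1 = 100, n_pop2 = 2, n_chromosomes = 2,
                   markers_per_chromosome = 2500, chrom_length_bp = 1.6e8,
                   fst_background = 0.01, missing_rate = 0, seed = 42)
  gg <- simulateGenotypes(cfg)$geno
  g1 <- gg[, which(sampleInfo(gg)$origin == "mainland")]
  K3 <- computeGRM(g1)
  expect_lt(abs(mean(diag(K3)) - 1), 0.05)
  # invariant to marker order
  perm <- sample(nrow(d))
  gperm <- GenotypeData(d[perm, ], markerMap(sim$geno)[perm, ],
                        sampleInfo(sim$geno))
  expect_equal(computeGRM(gperm), computeGRM(sim$geno), tolerance = 1e-12)
  expect_error(computeGRM(toy_geno(matrix(2L, 3, 4))), "monomorphic")
})

test_that("PCA of the GRM matches a dense eigensolver and separates clusters", {
  # two diverged populations: PC1 separates them with opposite-sign scores
  sim <- small_sim(46, fst_background = 0.1)
  K0 <- computeGRM(sim$geno)
  p0 <- pcaGRM(K0, 2)
  org <- sampleInfo(sim$geno)$origin
  s1 <- p0$scores[org == "mainland", 1]
  s2 <- p0$scores[org == "island", 1]
  expect_true(all(s1 > 0) != all(s2 > 0))
  expect_true(all(s1 > 0) || all(s1 < 0))
  expect_equal(sum(pcaGRM(K0, nrow(K0))$pct_variance), 100, tolerance = 1e-8)
  expect_true(all(diff(p0$pct_variance) <= 1e-12))
  set.seed(43)
  for (i in 1:5) {
    A <- matrix(rnorm(400), 20)
    K <- crossprod(A); dimnames(K) <- list(letters[1:20], letters[1:20])
    p <- pcaGRM(K, 5)
    e <- eigen(K, symmetric = TRUE)
    ref <- e$vectors[, 1:5] %*% diag(sqrt(e$values[1:5]))
    for (j in 1:5) {
      agree <- min(max(abs(p$scores[, j] - ref[, j])),
                   max(abs(p$scores[, j] + ref[, j])))
      expect_lt(agree, 1e-8)
    }
  }
})

test_that("Reynolds distance recovers drift and is ratio-of-sums consistent", {
  # identical frequency vectors at large n
  set.seed(44)
  p <- runif(2000, 0.1, 0.9)
  expect_lt(abs(reynoldsDistance(p, p, 10000, 10000)), 1e-3)
  # Balding-Nichols c = 0.1: D estimates -ln(1 - 0.1)
  reps <- replicate(12, {
    bn <- bn_genotype_counts(4000, 0.1, 100)
    p1 <- (bn$c1[, 2] + 2 * bn$c1[, 3]) / (2 * rowSums(bn$c1))
    p2 <- (bn$c2[, 2] + 2 * bn$c2[, 3]) / (2 * rowSums(bn$c2))
    reynoldsDistance(p1, p2, 100, 100)
  })
  target <- -log(1 - 0.1)
  expect_lt(abs(mean(reps) - target), 3 * sd(reps) / sqrt(length(reps)) + 0.005)
  # doubling the marker set leaves the estimate unchanged (ratio of sums)
  bn <- bn_genotype_counts(1000, 0.05, 80)
  p1 <- (bn$c1[, 2] + 2 * bn$c1[, 3]) / (2 * rowSums(bn$c1))
  p2 <- (bn$c2[, 2] + 2 * bn$c2[, 3]) / (2 * rowSums(bn$c2))
  expect_equal(reynoldsDistance(c(p1, p1), c(p2, p2), 80, 80),
               reynoldsDistance(p1, p2, 80, 80), tolerance = 1e-12)
})

test_that("neighbor joining recovers additive trees and splits 2-pop edges", {
  D <- matrix(c(0, 0.08, 0.08, 0), 2,
              dimnames = list(c("A", "B"), c("A", "B")))
  pt <- popTreeNJ(D)
  expect_equal(unname(diag(driftMatrix(pt))), c(0.04, 0.04))
  expect_equal(unname(driftMatrix(pt)[1, 2]), 0)
  # additive 4-taxon metric from a known tree:
  # ((A:1,B:2):1,C:3,D:4) path distances
  tr <- ape::read.tree(text = "((A:1,B:2):1,C:3,D:4);")
  D4 <- cophenetic(tr)
  pt4 <- popTreeNJ(D4)
  rec <- cophenetic(pt4@tree)[rownames(D4), colnames(D4)]
  expect_equal(rec, D4, tolerance = 1e-10)
  # permuting labels permutes leaves, same topology
  perm <- c(3, 1, 4, 2)
  ptp <- popTreeNJ(D4[perm, perm])
  expect_equal(cophenetic(ptp@tree)[rownames(D4), colnames(D4)], D4,
               tolerance = 1e-10)
  # F is PSD with non-negative diagonal (validity) and matches shared paths
  expect_true(all(diag(driftMatrix(pt4)) >= 0))
  expect_error(popTreeNJ(matrix(0, 1, 1)))
})

test_that("population frequency and distance matrices line up by group", {
  sim <- small_sim(45)
  D <- reynoldsDistanceMatrix(sim$geno, "origin")
  expect_equal(rownames(D), c("island", "mainland"))
  expect_gt(D[1, 2], 0)
  pf <- populationFrequencies(sim$geno)
  expect_equal(rownames(pf), c("island", "mainland"))
  expect_true(all(pf >= 0 & pf <= 1))
})
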