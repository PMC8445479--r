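test_that("sample call-rate filter applies a strict lower bound", {
  d <- matrix(1L, 100, 3)
  d[1:6, 2] <- NA          # call rate 0.94
  d[1:5, 3] <- NA          # call rate 0.95 exactly
  g <- toy_geno(d)
  res <- sampleCallRateFilter(g, 0.95)
  expect_equal(res$excluded_ids, "s02")
  expect_equal(ncol(res$geno), 2)
  # vacuous threshold keeps everyone
  expect_equal(length(sampleCallRateFilter(g, 0)$excluded_ids), 0)
  dall <- matrix(NA_integer_, 10, 2)
  dall[1, ] <- 1L
  expect_error(sampleCallRateFilter(toy_geno(dall), 0.95), "threshold")
})

test_that("pi-hat recovers duplicates and unrelated pairs", {
  sim <- small_sim(21, n_pop1 = 50, n_pop2 = 10,
                   markers_per_chromosome = 2500)
  g <- sim$geno
  d <- dosages(g)
  id1 <- colnames(d)[1]
  # append a duplicate of sample 1
  d2 <- cbind(d, dup = d[, 1])
  si <- rbind(sampleInfo(g), sampleInfo(g)[1, ])
  si$sample_id[nrow(si)] <- "dup"
  g2 <- GenotypeData(d2, markerMap(g), si)
  ph <- estimatePihat(g2)
  expect_gte(ph[id1, "dup"][1], 0.95)
  # unrelated within-population pairs sit near zero
  within <- ph[2:20, 2:20][upper.tri(matrix(0, 19, 19))]
  expect_lt(max(abs(within)), 0.15)
  expect_lt(abs(median(within)), 0.05)
  expect_true(isSymmetric(ph))
  expect_error(estimatePihat(toy_geno(matrix(2L, 5, 3))), "polymorphic")
})

test_that("greedy relatedness pruning retains a maximal unrelated set", {
  ids <- c("a", "b", "c", "d")
  ph <- diag(1, 4); dimnames(ph) <- list(ids, ids)
  # single related pair, all ties: lexicographically smaller id removed
  ph2 <- ph; ph2["a", "b"] <- ph2["b", "a"] <- 0.5
  expect_setequal(pruneRelated(ph2, 0.25), c("b", "c", "d"))
  # star: hub 'a' related to b, c, d -> only the hub is removed
  ph3 <- ph
  ph3["a", c("b", "c", "d")] <- ph3[c("b", "c", "d"), "a"] <- 0.3
  expect_setequal(pruneRelated(ph3, 0.25), c("b", "c", "d"))
  # exhaustive check: removing any single leaf instead would leave offenders
  for (leaf in c("b", "c", "d")) {
    rest <- setdiff(ids, leaf)
    expect_true(any(ph3[rest, rest] > 0.25 & upper.tri(ph3[rest, rest])))
  }
  # call-rate tie-break: lower call rate removed first
  cr <- c(a = 0.99, b = 0.90, c = 1, d = 1)
  expect_setequal(pruneRelated(ph2, 0.25, cr), c("a", "c", "d"))
  # no pair above threshold -> identity
  expect_setequal(pruneRelated(ph, 0.25), ids)
})

test_that("pruning output never contains an offending pair", {
  set.seed(31)
  for (rep in 1:100) {
    n <- sample(4:12, 1)
    ph <- matrix(runif(n * n, 0, 0.6), n, n)
    ph <- (ph + t(ph)) / 2; diag(ph) <- 1
    ids <- sprintf("s%02d", seq_len(n))
    dimnames(ph) <- list(ids, ids)
    kept <- pruneRelated(ph, 0.25)
    sub <- ph[kept, kept, drop = FALSE]
    expect_true(all(sub[upper.tri(sub)] <= 0.25))
  }
})

test_that("exact HWE test matches enumeration and handles edge cases", {
  expect_gte(hweExactTest(25, 50, 25), 0.99)
  expect_equal(hweExactTest(100, 0, 0), 1)
  expect_lt(hweExactTest(50, 0, 50), 1e-5)
  set.seed(32)
  for (i in 1:50) {
    cnt <- as.vector(stats::rmultinom(1, sample(10:200, 1), runif(3, 0.05, 1)))
    expect_equal(hweExactTest(cnt[1], cnt[2], cnt[3]),
                 hwe_oracle(cnt[1], cnt[2], cnt[3]), tolerance = 1e-12)
  }
})

test_that("marker QC applies thresholds with fixed precedence", {
  set.seed(33)
  n <- 100
  d <- matrix(rbinom(n * 6, 2, 0.5), 6, n)
  d[1, sample(n, 6)] <- NA                          # call rate 0.94 -> drop
  d[2, ] <- c(rep(1L, 10), rep(0L, 90))             # MAF 0.05 -> kept
  d[3, ] <- c(rep(1L, 9), rep(0L, 91))              # MAF 0.045 -> drop
  d[4, ] <- c(rep(2L, 50), rep(0L, 50))             # HWE catastrophic -> drop
  d[5, ] <- c(rep(NA, 6), rep(1L, 8), rep(0L, 86))  # fails call rate AND maf
  g <- toy_geno(d, chrom = c(rep("1", 5), "30"))    # marker 6 non-autosomal
  res <- markerQC(g)
  kept <- rownames(res$geno)
  expect_true("m02" %in% kept)    # boundary: MAF exactly 0.05 is kept
  expect_setequal(kept, c("m02"))
  b <- res$report$breakdown
  expect_equal(unlist(b[c("non_autosomal", "call_rate", "maf", "hwe")]),
               c(non_autosomal = 1L, call_rate = 2L, maf = 1L, hwe = 1L))
  # marker 5 counted once, under call rate (precedence)
  expect_equal(res$report$n_markers_in - res$report$n_markers_excluded,
               res$report$n_markers_out)
})

test_that("LD pruning enforces the pairwise r2 bound within windows", {
  set.seed(34)
  n <- 60
  base <- rbinom(n, 2, 0.5)
  d <- rbind(base, base, matrix(rbinom(n * 10, 2, 0.4), 10, n))
  storage.mode(d) <- "integer"
  g <- toy_geno(d)
  kept <- ldPrune(g)
  expect_equal(sum(c("m01", "m02") %in% kept), 1)   # one duplicate survives
  # independent markers with low r2: nothing dropped
  d2 <- matrix(rbinom(40 * 200, 2, 0.5), 40, 200)
  g2 <- toy_geno(d2)
  expect_equal(length(ldPrune(g2)), 40)
  # brute-force post-check on a correlated 60-marker block
  sim <- small_sim(35, n_pop1 = 60, n_pop2 = 10, n_chromosomes = 1,
                   markers_per_chromosome = 60, chrom_length_bp = 3e6,
                   ld_beta = 0.02)
  g3 <- sim$geno
  kept3 <- ldPrune(g3, window_snps = 50, step_snps = 5, r2_max = 0.5)
  d3 <- dosages(g3)[kept3, ]
  mmp <- markerMap(g3)
  idx <- match(kept3, mmp$marker_id)
  for (a in seq_along(kept3)) for (b in seq_along(kept3)) {
    if (a < b && abs(idx[a] - idx[b]) < 46) {  # always share a 50-SNP window
      r2 <- suppressWarnings(cor(d3[a, ], d3[b, ],
                                 use = "pairwise.complete.obs"))^2
      if (is.finite(r2)) expect_lte(r2, 0.5 + 1e-12)
    }
  }
})
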