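test_that("per-SNP Weir-Cockerham estimates match the transcription oracle", {
  # a fixed arbitrary count table
  expect_equal(fstFromCounts(matrix(c(30, 40, 30), 1), matrix(c(60, 30, 10), 1)),
               wc84_oracle(30, 40, 30, 60, 30, 10), tolerance = 1e-12)
  set.seed(51)
  tabs <- random_count_tables(1000)
  got <- fstFromCounts(tabs$c1, tabs$c2)
  want <- vapply(seq_len(1000), function(i)
    wc84_oracle(tabs$c1[i, 1], tabs$c1[i, 2], tabs$c1[i, 3],
                tabs$c2[i, 1], tabs$c2[i, 2], tabs$c2[i, 3]), 0)
  ok <- is.finite(want)
  expect_true(all(abs(got[ok] - want[ok]) < 1e-12))
})

test_that("F_ST degenerate configurations behave as defined", {
  # identical genotype tables in both populations: non-positive, truncated
  d <- rbind(c(rep(0L, 10), rep(1L, 10), rep(2L, 10),
               rep(0L, 10), rep(1L, 10), rep(2L, 10)))
  g <- toy_geno(d, origin = rep(c("a", "b"), each = 30))
  r <- fstPerSnp(g)
  expect_lte(r$fst_signed, 0)
  expect_equal(r$fst, 0)
  # fixed difference, no heterozygotes
  d2 <- rbind(c(rep(2L, 20), rep(0L, 20)))
  g2 <- toy_geno(d2, origin = rep(c("a", "b"), each = 20))
  expect_equal(fstPerSnp(g2)$fst_signed, 1, tolerance = 1e-12)
  # truncation only changes negatives; signed value preserved
  sim <- small_sim(52)
  r3 <- fstPerSnp(sim$geno)
  neg <- !is.na(r3$fst_signed) & r3$fst_signed < 0
  expect_true(all(r3$fst[neg] == 0))
  expect_equal(r3$fst[!neg], r3$fst_signed[!neg])
  # marker genotyped in only one population is flagged
  d4 <- rbind(c(0L, 1L, 2L, NA, NA, NA))
  g4 <- toy_geno(d4, origin = rep(c("a", "b"), each = 3))
  expect_true(is.na(fstPerSnp(g4)$fst_signed))
})

test_that("empirical percentile uses interpolated order statistics", {
  v <- as.numeric(1:100000)
  # closed-form rank arithmetic: h = (n-1) p + 1 = 99999.00001
  expect_equal(empiricalPercentileThreshold(v, 99.999), 99999.00001,
               tolerance = 1e-9)
  expect_equal(empiricalPercentileThreshold(rep(3.3, 50), 99.999), 3.3)
  expect_equal(empiricalPercentileThreshold(v, 0), 1)
  expect_error(empiricalPercentileThreshold(numeric(0)), "finite")
  # constant vector: no value strictly exceeds the bound
  expect_equal(sum(rep(3.3, 50) > empiricalPercentileThreshold(rep(3.3, 50))), 0)
})

test_that("window smoothing tiles half-open 500kb windows and drops sparse ones", {
  map <- data.frame(marker_id = sprintf("m%d", 1:8),
                    chromosome = c(rep("1", 7), "2"),
                    position_bp = c(1e5, 2e5, 3e5, 4e5, 6e5, 7e5, 8e5, 1e5),
                    allele_a = "A", allele_b = "B")
  fst <- c(0, 0, 0, 0.4, 0.1, 0.2, 0.3, 0.5)
  w <- smoothFstWindows(fst, map, 500000, 4)
  # chr1 first window has 4 SNPs mean 0.1; second window 3 SNPs dropped;
  # chr2 has 1 SNP dropped
  expect_equal(nrow(w), 1)
  expect_equal(w$mean_fst, 0.1)
  expect_equal(w$n_snps, 4L)
  expect_equal(w$start_bp, 1)
  expect_equal(w$end_bp, 500001)
  # conservation: retained windows account for their SNPs exactly
  w2 <- smoothFstWindows(fst, map, 500000, 1)
  expect_equal(sum(w2$n_snps), 8L)
})

test_that("FLK is zero at equality, chi-squared calibrated and monotone", {
  F <- diag(c(0.05, 0.05))
  dimnames(F) <- list(c("a", "b"), c("a", "b"))
  pf <- rbind(a = c(0.3, 0.5), b = c(0.3, 0.5))
  r <- flkTest(pf, F)
  expect_equal(r$flk_stat, c(0, 0), tolerance = 1e-12)
  expect_equal(r$flk_p, c(1, 1))
  # strictly increasing in |p1 - p2| at fixed ancestral estimate
  ctr <- 0.45
  delta <- seq(0.01, 0.4, by = 0.01)
  pf2 <- rbind(a = ctr + delta / 2, b = ctr - delta / 2)
  st <- flkTest(pf2, F)$flk_stat
  expect_true(all(diff(st) > 0))
  # and a quadratic function of the contrast (R^2 of T on delta^2 = 1)
  fit <- lm(st ~ I(delta^2))
  expect_gt(suppressWarnings(summary(fit)$r.squared), 0.999)
  # degenerate ancestral frequency flagged, singular F rejected
  pf3 <- rbind(a = c(0, 0.5), b = c(0, 0.5))
  expect_true(is.na(flkTest(pf3, F)$flk_stat[1]))
  Fs <- matrix(c(0.1, 0.1, 0.1, 0.1), 2)
  expect_error(flkTest(pf, Fs), "singular")
})

test_that("FLK with a fitted two-population tree keeps null calibration", {
  set.seed(53)
  c0 <- 0.05
  m <- 4000
  p0 <- runif(m, 0.05, 0.95)
  p1 <- rbeta(m, p0 * (1 - c0) / c0, (1 - p0) * (1 - c0) / c0)
  p2 <- rbeta(m, p0 * (1 - c0) / c0, (1 - p0) * (1 - c0) / c0)
  r <- flkTest(rbind(pop1 = p1, pop2 = p2), diag(c0, 2))
  ks <- suppressWarnings(stats::ks.test(r$flk_p, "punif"))$statistic
  expect_lt(unname(ks), 0.035)
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(fdrBH(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdrBH(0.42), 0.42)
  expect_equal(fdrBH(rep(1, 5)), rep(1, 5))
  set.seed(54)
  p <- runif(100)
  adj <- fdrBH(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  expect_error(fdrBH(c(0.5, 1.2)), "0, 1")
})

test_that("outlier calling applies strict and inclusive bounds as published", {
  scan <- data.frame(marker_id = sprintf("m%d", 1:5),
                     fst = c(0.1, 0.2, 0.15, 0.05, 0.3),
                     flk_p_fdr = c(0.5, 0.100000, 0.3, 0.09, 0.2))
  out <- callOutliers(scan, fst_percentile = 50, flk_fdr_max = 0.1)
  # FLK boundary: FDR exactly 0.1 is significant ("below or equal")
  expect_true("m2" %in% out$flk_significant)
  expect_true("m4" %in% out$flk_significant)
  # F_ST rule is strict: values equal to the bound are not outliers
  expect_false(any(scan$fst[match(out$fst_outliers, scan$marker_id)] <=
                     out$fst_threshold))
  expect_setequal(out$intersection,
                  intersect(out$fst_outliers, out$flk_significant))
})
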