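test_that("fixtures are byte-deterministic in the seed", {
  cfg <- simConfig(n_pop1 = 10, n_pop2 = 12, n_chromosomes = 2,
                   markers_per_chromosome = 50, chrom_length_bp = 1e6,
                   missing_rate = 0.01, seed = 5)
  td1 <- withr::local_tempdir(); td2 <- withr::local_tempdir()
  writeFixture(cfg, td1)
  writeFixture(cfg, td2)
  expect_identical(readLines(file.path(td1, "sim.ped")),
                   readLines(file.path(td2, "sim.ped")))
  expect_identical(readBin(file.path(td1, "sim.bed"), "raw", 1e6),
                   readBin(file.path(td2, "sim.bed"), "raw", 1e6))
  cfg2 <- simConfig(n_pop1 = 10, n_pop2 = 12, n_chromosomes = 2,
                    markers_per_chromosome = 50, chrom_length_bp = 1e6,
                    missing_rate = 0.01, seed = 6)
  sim1 <- simulateGenotypes(cfg); sim2 <- simulateGenotypes(cfg2)
  expect_false(identical(dosages(sim1$geno), dosages(sim2$geno)))
  # read-back equals the in-memory matrix
  g <- readPlinkBinary(file.path(td1, "sim.bed"), file.path(td1, "sim.bim"),
                       file.path(td1, "sim.fam"))
  expect_identical(unname(dosages(g)), unname(dosages(sim1$geno)))
})

test_that("missingness and undifferentiated backgrounds match their targets", {
  cfg <- simConfig(n_pop1 = 30, n_pop2 = 30, n_chromosomes = 2,
                   markers_per_chromosome = 600, chrom_length_bp = 4e7,
                   fst_background = 0, missing_rate = 0.02, seed = 8)
  sim <- simulateGenotypes(cfg)
  d <- dosages(sim$geno)
  expect_gt(length(d), 50000)
  expect_lt(abs(mean(is.na(d)) - 0.02), 0.005)
  # no differentiation simulated: mean per-SNP WC estimate near 0
  fst <- fstPerSnp(sim$geno)
  expect_lt(abs(mean(fst$fst_signed, na.rm = TRUE)), 0.01)
})

test_that("Balding-Nichols drift parameter is recovered from the generator", {
  # multi-locus ratio-of-sums WC estimate across markers recovers c
  cfg <- simConfig(n_pop1 = 150, n_pop2 = 150, n_chromosomes = 2,
                   markers_per_chromosome = 2500, chrom_length_bp = 1.6e8,
                   fst_background = 0.05, missing_rate = 0, seed = 9)
  sim <- simulateGenotypes(cfg)
  d <- dosages(sim$geno)
  org <- sampleInfo(sim$geno)$origin
  cnt <- function(lab) {
    dd <- d[, org == lab, drop = FALSE]
    cbind(rowSums(dd == 0L), rowSums(dd == 1L), rowSums(dd == 2L))
  }
  est <- fstGlobal(cnt("mainland"), cnt("island"))
  expect_lt(abs(est - 0.05), 0.01)
})

test_that("planted relative pairs are recovered by the pi-hat estimator", {
  cfg <- simConfig(n_pop1 = 30, n_pop2 = 30, n_chromosomes = 2,
                   markers_per_chromosome = 1500, chrom_length_bp = 1e8,
                   fst_background = 0.05, missing_rate = 0,
                   n_planted_relative_pairs = 3, seed = 10)
  sim <- simulateGenotypes(cfg)
  ph <- estimatePihat(sim$geno)
  hi <- which(ph > 0.4 & upper.tri(ph), arr.ind = TRUE)
  expect_equal(nrow(hi), 3)
  found <- sort(unname(apply(hi, 1, function(ij)
    paste(sort(rownames(ph)[ij]), collapse = "+"))))
  truth <- sort(apply(sim$truth$relative_pairs, 1, function(r)
    paste(sort(unname(r)), collapse = "+")))
  expect_equal(found, truth)
  # planted pairs sit near the parent-offspring expectation
  expect_true(all(abs(ph[hi] - 0.5) < 0.1))
})

test_that("planted selected loci realize their target differentiation", {
  cfg <- simConfig(n_pop1 = 60, n_pop2 = 60, n_chromosomes = 2,
                   markers_per_chromosome = 500, chrom_length_bp = 3e7,
                   fst_background = 0.05,
                   selected_loci = data.frame(chromosome = "1",
                                              position_bp = 1.5e7,
                                              fst_selected = 0.4),
                   missing_rate = 0, seed = 11)
  sim <- simulateGenotypes(cfg)
  sel <- sim$truth$selected_loci$marker_id
  expect_true(sel %in% rownames(sim$geno))
  fst <- fstPerSnp(sim$geno)
  i <- match(sel, fst$marker_id)
  expect_lt(abs(fst$fst[i] - 0.4), 0.12)
  # far above the genome-wide median
  expect_gt(fst$fst[i], quantile(fst$fst, 0.99, na.rm = TRUE))
  # a strongly selected locus is the genome-wide top hit
  cfg2 <- simConfig(n_pop1 = 60, n_pop2 = 60, n_chromosomes = 2,
                    markers_per_chromosome = 500, chrom_length_bp = 3e7,
                    fst_background = 0.05,
                    selected_loci = data.frame(chromosome = "2",
                                               position_bp = 2e7,
                                               fst_selected = 0.8),
                    missing_rate = 0, seed = 12)
  sim2 <- simulateGenotypes(cfg2)
  fst2 <- fstPerSnp(sim2$geno)
  expect_equal(fst2$marker_id[which.max(fst2$fst)],
               sim2$truth$selected_loci$marker_id)
})

test_that("invalid configurations are rejected", {
  expect_error(simConfig(selected_loci = data.frame(
    chromosome = "1", position_bp = 2e9, fst_selected = 0.4)), "outside")
  expect_error(simConfig(selected_loci = data.frame(
    chromosome = "99", position_bp = 100, fst_selected = 0.4)), "chromosome")
  expect_error(simConfig(fst_background = 0.2, selected_loci = data.frame(
    chromosome = "1", position_bp = 100, fst_selected = 0.1)), "fst_selected")
  expect_error(simConfig(n_pop1 = 4, n_planted_relative_pairs = 3), "pairs")
})

test_that("simulated LD decays at the configured Sved rate", {
  cfg <- simConfig(n_pop1 = 200, n_pop2 = 10, n_chromosomes = 1,
                   markers_per_chromosome = 2500, chrom_length_bp = 6e6,
                   fst_background = 0.02, ld_beta = 0.10,
                   missing_rate = 0, seed = 13)
  sim <- simulateGenotypes(cfg)
  org <- sampleInfo(sim$geno)$origin
  g1 <- sim$geno[, which(org == "mainland")]
  pairs <- ldPairs(g1, max_distance_kb = 2500)
  fit <- fitLdDecay(pairs, origin = "mainland")
  expect_lt(abs(fit@beta - 0.10) / 0.10, 0.25)
})
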