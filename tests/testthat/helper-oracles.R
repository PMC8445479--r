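# Independent oracles, written directly from the published formulas and kept
# free of any package internals.

# Weir & Cockerham (1984) theta for two populations, one marker, scalar
# transcription of the a / (a + b + c) component formulas.
wc84_oracle <- function(n0_1, n1_1, n2_1, n0_2, n1_2, n2_2) {
  n_i <- c(n0_1 + n1_1 + n2_1, n0_2 + n1_2 + n2_2)
  p_i <- c((n1_1 + 2 * n2_1) / (2 * n_i[1]), (n1_2 + 2 * n2_2) / (2 * n_i[2]))
  h_i <- c(n1_1 / n_i[1], n1_2 / n_i[2])
  r <- 2
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  a / (a + b + cc)
}

# Exact HWE p-value by brute-force enumeration of genotype configurations
# with the observed allele counts; probabilities from the unnormalized
# product of binomial coefficients, normalized by total.
hwe_oracle <- function(naa, nab, nbb) {
  n <- naa + nab + nbb
  nA <- 2 * naa + nab
  nB <- 2 * nbb + nab
  if (nA == 0 || nB == 0) return(1)
  ks <- seq(min(nA, nB) %% 2, min(nA, nB), by = 2)
  wt <- vapply(ks, function(k) {
    aa <- (nA - k) / 2   # remaining bb genotypes are forced
    exp(lchoose(n, aa) + lchoose(n - aa, k) + k * log(2) - lchoose(2 * n, nA))
  }, 0)
  pr <- wt / sum(wt)
  obs <- pr[match(nab, ks)]
  min(1, sum(pr[pr <= obs * (1 + 1e-10)]))
}

# random genotype count tables for two populations
random_count_tables <- function(n_tables, n1 = 50, n2 = 70) {
  t1 <- t(vapply(seq_len(n_tables), function(i) {
    as.vector(stats::rmultinom(1, n1, prob = runif(3, 0.05, 1)))
  }, numeric(3)))
  t2 <- t(vapply(seq_len(n_tables), function(i) {
    as.vector(stats::rmultinom(1, n2, prob = runif(3, 0.05, 1)))
  }, numeric(3)))
  list(c1 = t1, c2 = t2)
}

# genotype counts sampled under HWE from Balding-Nichols population freqs
bn_genotype_counts <- function(m, c0, n, p0_range = c(0.05, 0.95)) {
  p0 <- runif(m, p0_range[1], p0_range[2])
  draw <- function() rbeta(m, p0 * (1 - c0) / c0, (1 - p0) * (1 - c0) / c0)
  p1 <- draw(); p2 <- draw()
  cnt <- function(p) {
    n0 <- rbinom(m, n, (1 - p)^2)
    nh <- rbinom(m, n - n0, pmin(2 * p * (1 - p) / pmax(1 - (1 - p)^2, 1e-12), 1))
    cbind(n0 = n0, n1 = nh, n2 = n - n0 - nh)
  }
  list(c1 = cnt(p1), c2 = cnt(p2), p1 = p1, p2 = p2, p0 = p0)
}

# small simulated dataset shared by several tests
small_sim <- function(seed = 42, ...) {
  args <- list(n_pop1 = 40, n_pop2 = 50, n_chromosomes = 2,
               markers_per_chromosome = 300, chrom_length_bp = 2e7,
               fst_background = 0.05, ld_beta = 0.11,
               missing_rate = 0.01, seed = seed)
  args <- utils::modifyList(args, list(...))
  simulateGenotypes(do.call(simConfig, args))
}

# hand-built GenotypeData
toy_geno <- function(dosage, chrom = NULL, pos = NULL, origin = NULL) {
  m <- nrow(dosage)
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  mm <- data.frame(marker_id = sprintf("m%02d", seq_len(m)),
                   chromosome = chrom, position_bp = pos,
                   allele_a = "A", allele_b = "B")
  si <- data.frame(sample_id = sprintf("s%02d", seq_len(ncol(dosage))))
  if (!is.null(origin)) si$origin <- origin
  GenotypeData(dosage, mm, si)
}
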