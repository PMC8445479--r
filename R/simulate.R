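#' Simulation configuration for two-population SNP-array data
#'
#' Defines the study conditions emulated by [simulateGenotypes()]: a
#' 50k-style array on the ovine autosomes for two diverged populations
#' (mainland and island). Defaults mirror the sampled study design: 90
#' mainland and 147 island animals, 26 autosomes, about 39k markers in total
#' and a background differentiation typical of within-species breed
#' divergence.
#'
#' @param n_pop1 mainland sample count (default 90).
#' @param n_pop2 island sample count (default 147).
#' @param n_chromosomes number of autosomes (default 26).
#' @param markers_per_chromosome markers per autosome (default 1500, giving
#'   39,000 markers genome-wide).
#' @param chrom_length_bp autosome length in bp (default 1e8, close to the
#'   ovine autosome average).
#' @param fst_background Balding-Nichols drift parameter `c` shared by both
#'   populations (default 0.05).
#' @param selected_loci data.frame with columns `chromosome`, `position_bp`,
#'   `fst_selected`: loci planted with elevated differentiation. A marker is
#'   inserted at each requested position.
#' @param ld_beta target decline rate (per kb) of the Sved-type r-squared
#'   curve `1/(1 + 4*beta*d)` within each population (default 0.11, matching
#'   LD decay observed on local sheep breeds).
#' @param missing_rate fraction of genotypes masked missing (default 0.005).
#' @param sweep_halfwidth_kb hitchhiking footprint of planted loci: the
#'   differentiation boost of linked neighbours halves every this many kb
#'   (default 150; the boost is Gaussian-shaped in distance, halving at this distance — a compact post-sweep footprint of a few hundred kb).
#' @param n_planted_relative_pairs number of parent-offspring-like pairs
#'   planted by copying one haplotype (default 0).
#' @param coord_centers 2x2 matrix of cluster centers (rows: pop1, pop2) for
#'   sample coordinates; default 10 units apart on the x axis.
#' @param coord_jitter_sd Gaussian jitter around each center (default 0.5).
#' @param seed integer RNG seed.
#' @return a validated list of class `"SimConfig"`.
#' @export
simConfig <- function(n_pop1 = 90, n_pop2 = 147, n_chromosomes = 26,
                      markers_per_chromosome = 1500, chrom_length_bp = 1e8,
                      fst_background = 0.05, selected_loci = NULL,
                      ld_beta = 0.11, missing_rate = 0.005,
                      sweep_halfwidth_kb = 150,
                      n_planted_relative_pairs = 0,
                      coord_centers = rbind(c(0, 0), c(10, 0)),
                      coord_jitter_sd = 0.5, seed = 1L) {
  if (!is.matrix(coord_centers))
    coord_centers <- matrix(unlist(coord_centers), 2, 2, byrow = TRUE)
  if (!is.null(selected_loci) && !is.data.frame(selected_loci))
    selected_loci <- as.data.frame(selected_loci)
  cfg <- list(n_pop1 = as.integer(n_pop1), n_pop2 = as.integer(n_pop2),
              n_chromosomes = as.integer(n_chromosomes),
              markers_per_chromosome = as.integer(markers_per_chromosome),
              chrom_length_bp = as.numeric(chrom_length_bp),
              fst_background = fst_background,
              selected_loci = selected_loci, ld_beta = ld_beta,
              missing_rate = missing_rate,
              sweep_halfwidth_kb = sweep_halfwidth_kb,
              n_planted_relative_pairs = as.integer(n_planted_relative_pairs),
              coord_centers = coord_centers,
              coord_jitter_sd = coord_jitter_sd, seed = as.integer(seed))
  stopifnot(cfg$n_pop1 >= 1, cfg$n_pop2 >= 1, cfg$n_chromosomes >= 1,
            cfg$markers_per_chromosome >= 1, cfg$chrom_length_bp >= 1,
            cfg$fst_background >= 0, cfg$fst_background < 1,
            cfg$ld_beta > 0, cfg$missing_rate >= 0, cfg$missing_rate < 1,
            cfg$n_planted_relative_pairs >= 0)
  if (!is.null(cfg$selected_loci)) {
    sl <- cfg$selected_loci
    stopifnot(all(c("chromosome", "position_bp", "fst_selected") %in% colnames(sl)))
    if (any(sl$position_bp < 1 | sl$position_bp > cfg$chrom_length_bp))
      stop("selected locus outside chromosome bounds")
    if (any(!as.character(sl$chromosome) %in% as.character(seq_len(cfg$n_chromosomes))))
      stop("selected locus on a chromosome not simulated")
    if (any(sl$fst_selected < cfg$fst_background))
      stop("fst_selected must be >= fst_background")
  }
  if (2 * cfg$n_planted_relative_pairs > cfg$n_pop1)
    stop("too many planted relative pairs for pop1 size")
  class(cfg) <- "SimConfig"
  cfg
}

# Latent-Gaussian AR(1) haplotypes: alleles are thresholded at qnorm(p).
# The latent autocorrelation over distance d kb is exp(-lambda d); the
# calibration constant maps the target Sved decline rate beta onto lambda so
# that a nonlinear LS fit of 1/(1+4 beta d) to the model's equilibrium
# r-squared profile (marker frequencies uniform on the simulated range)
# returns beta.
.LD_CALIBRATION <- 33.7

.simHaplotypes <- function(nhap, p, pos_kb, lambda) {
  m <- length(p)
  Z <- matrix(0, nhap, m)
  Z[, 1] <- rnorm(nhap)
  if (m > 1) for (j in 2:m) {
    a <- exp(-lambda * (pos_kb[j] - pos_kb[j - 1]))
    Z[, j] <- a * Z[, j - 1] + sqrt(1 - a^2) * rnorm(nhap)
  }
  (sweep(Z, 2, qnorm(p), "<")) * 1L
}

#' Simulate a two-population genotype dataset with known truth
#'
#' Per marker an ancestral frequency `p0 ~ Uniform(0.05, 0.95)` is drawn and
#' population frequencies follow the Balding-Nichols model:
#' `p_i ~ Beta(p0 (1-c)/c, (1-p0)(1-c)/c)` with `c = fst_background`.
#' Planted selected loci override the draw with the long-term
#' local-adaptation geometry: the selected allele near fixation in
#' population 1 and at the intermediate frequency in population 2 that
#' realizes pairwise theta = `fst_selected` exactly, plus a hitchhiking
#' footprint dragging linked neighbours' population-1 alleles toward
#' fixation with weight Gaussian in distance (halving at
#' `sweep_halfwidth_kb`). Haplotypes are
#' generated per population by a first-order latent-Gaussian copying process
#' along each chromosome whose autocorrelation per kb is calibrated so that
#' the expected r-squared between markers at distance `d` kb approximates
#' `1/(1 + 4 * ld_beta * d)`. Genotypes are sums of two haplotypes. Planted
#' relative pairs replace one haplotype of a pop1 sample with a copy from its
#' partner (parent-offspring-like, expected pi-hat near 0.5). Genotypes are
#' masked missing at `missing_rate`, and samples receive coordinates from
#' two spatially separated Gaussian clusters.
#'
#' @param config a [simConfig()] object.
#' @return list with elements `geno` (a [GenotypeData-class]; pop1 samples
#'   carry `origin = "mainland"`, pop2 `"island"`) and `truth`, a list
#'   recording planted selected loci (with marker ids), planted relative
#'   pairs and the per-marker ancestral/population frequencies.
#' @export
simulateGenotypes <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  nchr <- config$n_chromosomes
  mpc <- config$markers_per_chromosome
  len_kb <- config$chrom_length_bp / 1000
  lambda <- 4 * config$ld_beta / .LD_CALIBRATION
  n1 <- config$n_pop1; n2 <- config$n_pop2
  sl <- config$selected_loci
  maps <- vector("list", nchr)
  dos <- vector("list", nchr)
  p0_all <- p1_all <- p2_all <- c_all <- numeric(0)
  sel_ids <- character(0)
  for (ch in seq_len(nchr)) {
    pos_bp <- sort(sample.int(config$chrom_length_bp, mpc))
    sel_here <- NULL
    if (!is.null(sl)) {
      sel_here <- sl[as.character(sl$chromosome) == as.character(ch), , drop = FALSE]
      if (nrow(sel_here)) {
        pos_bp <- sort(unique(c(pos_bp, as.integer(sel_here$position_bp))))
      }
    }
    m <- length(pos_bp)
    cvec <- rep(config$fst_background, m)
    if (!is.null(sel_here) && nrow(sel_here)) {
      idx <- match(as.integer(sel_here$position_bp), pos_bp)
      cvec[idx] <- sel_here$fst_selected
    }
    p0 <- runif(m, 0.05, 0.95)
    drawP <- function(p0, cvec) {
      p <- ifelse(cvec > 0,
                  rbeta(m, p0 * (1 - cvec) / pmax(cvec, 1e-12),
                        (1 - p0) * (1 - cvec) / pmax(cvec, 1e-12)),
                  p0)
      # degenerate draws (numerically 0 or 1) are redrawn toward validity
      bad <- which(p <= 0 | p >= 1 | !is.finite(p))
      for (k in bad) {
        pk <- p0[k]
        repeat {
          pp <- if (cvec[k] > 0)
            rbeta(1, pk * (1 - cvec[k]) / cvec[k],
                  (1 - pk) * (1 - cvec[k]) / cvec[k]) else pk
          if (is.finite(pp) && pp > 0 && pp < 1) { p[k] <- pp; break }
        }
      }
      p
    }
    p1 <- drawP(p0, cvec)
    p2 <- drawP(p0, cvec)
    # planted loci realize their requested differentiation exactly:
    # population 1 is pushed from p0 toward fixation until the population
    # level theta (p1-p2)^2/((p1-p2)^2 + p1 q1 + p2 q2) equals fst_selected,
    # population 2 stays at p0 (divergent selection acting in one
    # population; yields the Ho-dip / dHo-peak local-adaptation pattern)
    if (!is.null(sel_here) && nrow(sel_here)) {
      idx <- match(as.integer(sel_here$position_bp), pos_bp)
      solvePush <- function(pb, tgt) {
        # frequency in population 1 realizing pairwise theta = tgt against
        # a population 2 fixed at pb; pushed toward the farther boundary
        thetaOf <- function(pa) {
          num <- (pa - pb)^2
          num / (num + pa * (1 - pa) + pb * (1 - pb))
        }
        up <- (1 - pb) >= pb
        lim <- if (up) 1 - pb else pb     # supremum of attainable theta
        tgt <- min(tgt, lim - 1e-6)
        iv <- if (up) c(pb + 1e-9, 1 - 1e-9) else c(1e-9, pb - 1e-9)
        stats::uniroot(function(pa) thetaOf(pa) - tgt, iv)$root
      }
      for (k in seq_along(idx)) {
        tgt <- sel_here$fst_selected[k]
        if (tgt <= config$fst_background) next
        # long-term local-adaptation geometry: the selected allele is near
        # fixation in population 1 (Ho collapse there), and population 2
        # keeps it at the intermediate frequency that realizes the requested
        # pairwise theta exactly (theta(1, p2) = 1 - p2)
        p1s <- 1 - min(0.005, (1 - tgt) / 20)
        thetaPair <- function(pa, pb) {
          num <- (pa - pb)^2
          num / (num + pa * (1 - pa) + pb * (1 - pb))
        }
        pk0 <- stats::uniroot(function(pb) thetaPair(p1s, pb) - tgt,
                              c(0.01, p1s - 0.02))$root
        p2[idx[k]] <- pk0
        p0[idx[k]] <- pk0
        p1[idx[k]] <- p1s
        # hitchhiking footprint: linked neighbours share the divergence.
        # Gaussian-shaped in distance (compact, like a post-sweep profile):
        # the boost halves at sweep_halfwidth_kb and is negligible beyond
        # twice that
        d_kb <- abs(pos_bp - pos_bp[idx[k]]) / 1000
        w <- 2^(-(d_kb / config$sweep_halfwidth_kb)^2)
        nb <- which(w >= 0.05 & seq_along(pos_bp) != idx[k])
        for (j in nb) {
          # the allele on the swept haplotype (B with probability p1_j) is
          # dragged toward fixation in population 1, in proportion to the
          # footprint weight; heterozygosity collapses under strong linkage
          if (runif(1) < p1[j]) p1[j] <- p1[j] + w[j] * (1 - p1[j])
          else p1[j] <- p1[j] * (1 - w[j])
        }
      }
    }
    pos_kb <- pos_bp / 1000
    H1 <- .simHaplotypes(2 * n1, p1, pos_kb, lambda)
    H2 <- .simHaplotypes(2 * n2, p2, pos_kb, lambda)
    G1 <- H1[seq(1, 2 * n1, 2), , drop = FALSE] + H1[seq(2, 2 * n1, 2), , drop = FALSE]
    G2 <- H2[seq(1, 2 * n2, 2), , drop = FALSE] + H2[seq(2, 2 * n2, 2), , drop = FALSE]
    # planted relatives: sample 2k-1 lends one haplotype to sample 2k (pop1)
    if (config$n_planted_relative_pairs > 0) {
      for (pr in seq_len(config$n_planted_relative_pairs)) {
        i <- 2 * pr - 1; jj <- 2 * pr
        G1[jj, ] <- H1[2 * i - 1, ] + H1[2 * jj, ]
      }
    }
    ids <- sprintf("snp_%d_%d", ch, pos_bp)
    maps[[ch]] <- data.frame(marker_id = ids, chromosome = as.character(ch),
                             position_bp = pos_bp,
                             allele_a = "A", allele_b = "B")
    dos[[ch]] <- t(rbind(G1, G2))
    p0_all <- c(p0_all, p0); p1_all <- c(p1_all, p1); p2_all <- c(p2_all, p2)
    c_all <- c(c_all, cvec)
    if (!is.null(sel_here) && nrow(sel_here))
      sel_ids <- c(sel_ids, ids[match(as.integer(sel_here$position_bp), pos_bp)])
  }
  dosage <- do.call(rbind, dos)
  mm <- do.call(rbind, maps)
  if (config$missing_rate > 0) {
    mask <- runif(length(dosage)) < config$missing_rate
    dosage[mask] <- NA_integer_
  }
  sid <- c(sprintf("m%03d", seq_len(n1)), sprintf("i%03d", seq_len(n2)))
  origin <- c(rep("mainland", n1), rep("island", n2))
  ctr <- config$coord_centers
  coords <- rbind(
    cbind(rnorm(n1, ctr[1, 1], config$coord_jitter_sd),
          rnorm(n1, ctr[1, 2], config$coord_jitter_sd)),
    cbind(rnorm(n2, ctr[2, 1], config$coord_jitter_sd),
          rnorm(n2, ctr[2, 2], config$coord_jitter_sd)))
  samp <- data.frame(sample_id = sid, origin = origin,
                     region = ifelse(origin == "mainland", "region_m", "region_i"),
                     herd = NA_character_,
                     coord_x = coords[, 1], coord_y = coords[, 2])
  geno <- GenotypeData(dosage, mm, samp)
  rel <- NULL
  if (config$n_planted_relative_pairs > 0)
    rel <- data.frame(sample_1 = sid[2 * seq_len(config$n_planted_relative_pairs) - 1],
                      sample_2 = sid[2 * seq_len(config$n_planted_relative_pairs)])
  sel_truth <- NULL
  if (!is.null(sl))
    sel_truth <- cbind(sl, marker_id = sel_ids)
  ord <- match(rownames(geno), mm$marker_id)
  truth <- list(selected_loci = sel_truth, relative_pairs = rel,
                p0 = p0_all[ord], p1 = p1_all[ord], p2 = p2_all[ord],
                fst_param = c_all[ord], seed = config$seed)
  list(geno = geno, truth = truth)
}

#' Write a simulated dataset as a fixture on disk
#'
#' Writes PED/MAP, BED/BIM/FAM, a sample table TSV and the truth record as
#' JSON under `out_dir`. Byte-identical output for identical seeds.
#'
#' @param config a [simConfig()] object.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the simulated object from [simulateGenotypes()].
#' @export
writeFixture <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulateGenotypes(config)
  writePlinkText(sim$geno, file.path(out_dir, "sim"))
  writePlinkBinary(sim$geno, file.path(out_dir, "sim"))
  writeSampleTable(sampleInfo(sim$geno), file.path(out_dir, "samples.tsv"))
  tr <- sim$truth
  tr$p0 <- round(tr$p0, 8); tr$p1 <- round(tr$p1, 8); tr$p2 <- round(tr$p2, 8)
  jsonlite::write_json(tr, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(sim)
}
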