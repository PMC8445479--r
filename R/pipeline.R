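#' Pipeline configuration
#'
#' Aggregates every stage threshold with the workflow's standard defaults:
#' sample/marker call rate 0.95, MAF 0.05, HWE 1e-5, LD prune r2 0.5 in
#' 50-SNP windows stepping by 5, pi-hat 0.25, F_ST percentile 99.999, 500-kb
#' windows with a minimum of 4 SNPs, FLK FDR 0.1, GWAS FDR 0.05, LD-score
#' windows 500/1000 kb, maximum pair distance 2500 kb, candidate flank
#' 500 kb, diagnostic flank 1 Mb, loess span 0.21. `sim` holds the
#' [simConfig()] used when no genotypes are supplied. The configuration
#' round-trips unchanged through the YAML serialization.
#'
#' @param sim a [simConfig()] (used when `runPipeline()` gets no `geno`).
#' @param seed master seed; per-stage seeds are derived from it.
#' @param sample_callrate_min,marker_callrate_min,maf_min,hwe_alpha,
#'   pihat_max,ld_prune_r2,ld_prune_window_snps,ld_prune_step_snps,
#'   fst_percentile,window_bp,window_min_snps,flk_fdr_max,gwas_fdr_max,
#'   ld_score_window_bp,ld_max_pair_kb,annotation_flank_bp,
#'   diagnostic_flank_bp,loess_span stage thresholds (see Description).
#' @return list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(sim = simConfig(), seed = 1L,
                           sample_callrate_min = 0.95,
                           marker_callrate_min = 0.95,
                           maf_min = 0.05, hwe_alpha = 1e-5,
                           pihat_max = 0.25, ld_prune_r2 = 0.5,
                           ld_prune_window_snps = 50, ld_prune_step_snps = 5,
                           fst_percentile = 99.999, window_bp = 500000,
                           window_min_snps = 4, flk_fdr_max = 0.1,
                           gwas_fdr_max = 0.05,
                           ld_score_window_bp = c(500000, 1000000),
                           ld_max_pair_kb = 2500,
                           annotation_flank_bp = 500000,
                           diagnostic_flank_bp = 1000000, loess_span = 0.21) {
  cfg <- list(sim = sim, seed = as.integer(seed),
              sample_callrate_min = sample_callrate_min,
              marker_callrate_min = marker_callrate_min,
              maf_min = maf_min, hwe_alpha = hwe_alpha,
              pihat_max = pihat_max, ld_prune_r2 = ld_prune_r2,
              ld_prune_window_snps = as.integer(ld_prune_window_snps),
              ld_prune_step_snps = as.integer(ld_prune_step_snps),
              fst_percentile = fst_percentile, window_bp = window_bp,
              window_min_snps = as.integer(window_min_snps),
              flk_fdr_max = flk_fdr_max, gwas_fdr_max = gwas_fdr_max,
              ld_score_window_bp = ld_score_window_bp,
              ld_max_pair_kb = ld_max_pair_kb,
              annotation_flank_bp = annotation_flank_bp,
              diagnostic_flank_bp = diagnostic_flank_bp,
              loess_span = loess_span)
  stopifnot(cfg$sample_callrate_min > 0, cfg$sample_callrate_min <= 1,
            cfg$maf_min >= 0, cfg$maf_min < 0.5,
            cfg$hwe_alpha > 0, cfg$hwe_alpha < 1,
            cfg$pihat_max > 0, cfg$pihat_max < 1,
            cfg$fst_percentile > 0, cfg$fst_percentile <= 100,
            cfg$flk_fdr_max > 0, cfg$flk_fdr_max <= 1,
            cfg$loess_span > 0, cfg$loess_span <= 1)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read/write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return for `readPipelineConfig`, a `"PipelineConfig"`; the writer
#'   returns `path` invisibly.
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  sim <- do.call(simConfig, raw$sim)
  raw$sim <- NULL
  do.call(pipelineConfig, c(list(sim = sim), raw))
}

#' @rdname readPipelineConfig
#' @param config a `"PipelineConfig"`.
#' @export
writePipelineConfig <- function(config, path) {
  out <- unclass(config)
  out$sim <- unclass(out$sim)
  out$sim$coord_centers <- as.vector(t(out$sim$coord_centers))
  yaml::write_yaml(out, path)
  invisible(path)
}

.stageSeed <- function(seed, stage) {
  offsets <- c(simulate = 11L, pihat = 23L, scan = 31L, gwas = 41L,
               spatial = 53L, ld = 61L)
  (seed * 97L + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the full mainland-island scan workflow
#'
#' Executes simulate (unless genotypes are supplied), sample and marker QC,
#' relatedness pruning, population structure (GRM, PCA, Reynolds/NJ tree),
#' the F_ST and FLK selection scans, LD scores and decay fits per origin,
#' the mixed-model association scan of origin, Moran's I on PC1, the
#' diagnostic profile around the top outlier (or planted locus) and,
#' optionally, positional candidate annotation. All tables are written as
#' TSV under `out_dir` together with a machine-readable `summary.json`;
#' outputs are identical for identical config and seed.
#'
#' @param config a [pipelineConfig()].
#' @param out_dir output directory.
#' @param geno optional [GenotypeData-class]; when NULL, data are simulated
#'   from `config$sim` (with the pipeline's derived seed).
#' @param features optional feature table for the annotation stage.
#' @return invisibly, the summary list.
#' @export
runPipeline <- function(config, out_dir, geno = NULL, features = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(seed = config$seed)
  truth <- NULL
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }
  if (is.null(geno)) {
    sim <- stage("simulate", {
      cfg <- config$sim
      cfg$seed <- .stageSeed(config$seed, "simulate")
      simulateGenotypes(cfg)
    })
    geno <- sim$geno
    truth <- sim$truth
  }
  summary$n_samples_in <- ncol(geno)
  summary$n_markers_in <- nrow(geno)

  qc <- stage("qc", {
    scr <- sampleCallRateFilter(geno, config$sample_callrate_min)
    g <- scr$geno
    mq <- markerQC(g, config$marker_callrate_min, config$maf_min,
                   config$hwe_alpha)
    g <- mq$geno
    ph <- estimatePihat(g)
    kept <- pruneRelated(ph, config$pihat_max, sampleCallRates(g))
    ibd_removed <- setdiff(colnames(dosages(g)), kept)
    g <- g[, kept]
    pruned_ids <- ldPrune(g, config$ld_prune_window_snps,
                          config$ld_prune_step_snps, config$ld_prune_r2)
    ld_removed <- nrow(g) - length(pruned_ids)
    g <- g[pruned_ids, ]
    list(geno = g, excluded_callrate = scr$excluded_ids,
         excluded_ibd = ibd_removed, marker_report = mq$report,
         ld_removed = ld_removed)
  })
  g <- qc$geno
  summary$qc <- list(
    n_samples_excluded_callrate = length(qc$excluded_callrate),
    n_samples_excluded_ibd = length(qc$excluded_ibd),
    n_samples_out = ncol(g),
    n_markers_excluded = qc$marker_report$n_markers_excluded + qc$ld_removed,
    marker_breakdown = c(qc$marker_report$breakdown,
                         list(ld_prune = qc$ld_removed)),
    n_markers_out = nrow(g))

  st <- stage("structure", {
    K <- computeGRM(g)
    pca <- pcaGRM(K, k = min(10, ncol(g)))
    D <- reynoldsDistanceMatrix(g, "origin")
    tree <- popTreeNJ(D)
    write.table(data.frame(sample_id = rownames(pca$scores), pca$scores),
                file.path(out_dir, "pca_scores.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(D, file.path(out_dir, "reynolds_distances.tsv"), sep = "\t",
                quote = FALSE)
    ape::write.tree(tree@tree, file.path(out_dir, "population_tree.nwk"))
    list(K = K, pca = pca, D = D, tree = tree)
  })
  summary$structure <- list(
    pc1_pct_variance = st$pca$pct_variance[1],
    pc2_pct_variance = st$pca$pct_variance[2],
    reynolds_distance = st$D[1, 2])

  scan <- stage("scan", {
    fst <- fstPerSnp(g)
    pf <- populationFrequencies(g, "origin")
    flk <- flkTest(pf, st$tree)
    tab <- cbind(markerMap(g)[, c("marker_id", "chromosome", "position_bp")],
                 fst_signed = fst$fst_signed, fst = fst$fst,
                 flk_stat = flk$flk_stat, flk_p = flk$flk_p,
                 flk_p_fdr = fdrBH(flk$flk_p))
    win <- smoothFstWindows(tab$fst, markerMap(g), config$window_bp,
                            config$window_min_snps)
    out <- callOutliers(tab, win, config$fst_percentile, config$flk_fdr_max)
    writeScanTable(tab, file.path(out_dir, "scan.tsv"))
    if (nrow(win)) writeScanTable(win, file.path(out_dir, "fst_windows.tsv"))
    list(tab = tab, win = win, outliers = out)
  })
  summary$scan <- list(
    fst_mean = mean(scan$tab$fst, na.rm = TRUE),
    fst_threshold = scan$outliers$fst_threshold,
    fst_outliers = as.list(scan$outliers$fst_outliers),
    n_windows = nrow(scan$win),
    flk_significant = as.list(scan$outliers$flk_significant),
    intersection = as.list(scan$outliers$intersection))

  ld <- stage("ld", {
    res <- list()
    origin <- sampleInfo(g)$origin
    for (org in sort(unique(origin[!is.na(origin)]))) {
      go <- g[, which(origin == org)]
      sc <- lapply(config$ld_score_window_bp, function(w) ldScores(go, w))
      names(sc) <- paste0("w", config$ld_score_window_bp)
      pr <- ldPairs(go, config$ld_max_pair_kb)
      fit <- tryCatch(fitLdDecay(pr, config$ld_max_pair_kb, origin = org),
                      error = function(e) NULL)
      res[[org]] <- list(scores = sc, fit = fit)
    }
    w1 <- config$ld_score_window_bp[1]
    cmp <- wilcoxonRankSum(res[[1]]$scores[[1]]$score,
                           res[[2]]$scores[[1]]$score)
    sc_tab <- do.call(rbind, lapply(names(res), function(org)
      data.frame(origin = org, window_bp = w1,
                 marker_id = res[[org]]$scores[[1]]$marker_id,
                 score = res[[org]]$scores[[1]]$score)))
    writeScanTable(sc_tab, file.path(out_dir, "ld_scores.tsv"))
    list(res = res, cmp = cmp)
  })
  summary$ld <- lapply(ld$res, function(r) {
    out <- list(median_score_500kb = median(r$scores[[1]]$score))
    if (!is.null(r$fit))
      out <- c(out, list(beta = r$fit@beta, beta_se = r$fit@se_beta,
                         n_pairs = r$fit@n_pairs))
    out
  })
  summary$ld$wilcoxon_p <- ld$cmp$p_value

  gw <- stage("gwas", {
    y <- ifelse(sampleInfo(g)$origin == "mainland", 1, 0)
    null <- fitNullMixedModel(y, st$K)
    res <- emmaxScan(g, y, null)
    writeScanTable(cbind(markerMap(g)[, c("marker_id", "chromosome",
                                          "position_bp")],
                         res[, -1]), file.path(out_dir, "gwas.tsv"))
    list(null = null, res = res)
  })
  summary$gwas <- list(lambda = attr(gw$res, "lambda"),
                       h2 = gw$null$h2,
                       n_significant = sum(gw$res$significant, na.rm = TRUE),
                       top_marker = gw$res$marker_id[which.min(gw$res$p_value)])

  sp <- stage("spatial", {
    si <- sampleInfo(g)
    moranI(st$pca$scores[, 1], cbind(si$coord_x, si$coord_y),
           seed = .stageSeed(config$seed, "spatial"))
  })
  summary$spatial <- list(moran_i = sp$moran_i, z_score = sp$z_score,
                          p_value = sp$p_value)

  diag_label <- NULL
  top <- scan$outliers$fst_outliers
  if (!length(top))
    top <- scan$tab$marker_id[which.max(scan$tab$fst)]
  dg <- stage("diagnose", {
    lapply(top, function(mk) {
      prof <- tryCatch(diagnosticProfile(g, mk, config$diagnostic_flank_bp,
                                         config$loess_span),
                       error = function(e) NULL)
      if (is.null(prof)) return(list(marker = mk, label = "inconclusive"))
      writeScanTable(prof, file.path(out_dir, sprintf("profile_%s.tsv", mk)))
      cl <- classifySelectiveProcess(prof)
      list(marker = mk, label = cl$label, metrics = cl$metrics)
    })
  })
  summary$diagnostics <- lapply(dg, function(z) list(marker = z$marker,
                                                     label = z$label))

  if (!is.null(features)) {
    ann <- stage("annotate", {
      mm <- markerMap(g)
      do.call(rbind, lapply(top, function(mk) {
        i <- match(mk, mm$marker_id)
        featuresNearMarker(mm$chromosome[i], mm$position_bp[i], features,
                           config$annotation_flank_bp, marker_id = mk)
      }))
    })
    if (!is.null(ann) && nrow(ann))
      writeScanTable(ann, file.path(out_dir, "candidate_features.tsv"))
    summary$annotation <- list(n_hits = if (is.null(ann)) 0L else nrow(ann))
  }
  if (!is.null(truth) && !is.null(truth$selected_loci))
    summary$truth_planted <- as.list(truth$selected_loci$marker_id)

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(summary)
}
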