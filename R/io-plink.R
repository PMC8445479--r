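#' Read PLINK text genotypes (PED/MAP)
#'
#' Parses a PED/MAP pair into a [GenotypeData-class] object. Dosages count
#' the B allele; the `"0 0"` genotype becomes missing. When both alleles of a
#' marker are observed, the ASCII-smaller allele is assigned to `allele_a`
#' and the larger to `allele_b`; a marker where only one allele is ever seen
#' is stored monomorphic for `allele_a` (dosage 0 everywhere) - the text
#' format cannot distinguish the two monomorphic states, the binary format
#' can. Markers are re-sorted by (chromosome, position) and markers whose
#' chromosome label is outside `autosomes` are dropped.
#'
#' The PED phenotype column is mapped to `origin` with the case/control
#' convention 1 = island, 2 = mainland (anything else = missing); the family
#' id column is kept as `region`.
#'
#' @param ped_path,map_path paths to the .ped and .map files.
#' @param autosomes chromosome labels to retain (default `"1".."26"`).
#' @param verbose emit a conservation audit line (non-missing genotype count).
#' @return a [GenotypeData-class] object.
#' @export
readPlinkText <- function(ped_path, map_path, autosomes = as.character(1:26),
                          verbose = FALSE) {
  stopifnot(file.exists(ped_path), file.exists(map_path))
  mp <- read.table(map_path, header = FALSE, colClasses = "character")
  if (ncol(mp) == 3) mp <- cbind(mp[, 1:2], cm = "0", mp[, 3])
  colnames(mp) <- c("chromosome", "marker_id", "cm", "position_bp")
  m <- nrow(mp)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(lines)]
  n <- length(lines)
  toks <- strsplit(trimws(lines), "[ \t]+")
  len <- lengths(toks)
  bad <- which(len != 6 + 2 * m)
  if (length(bad))
    stop(sprintf("PED line %d has %d tokens, expected %d",
                 bad[1], len[bad[1]], 6 + 2 * m))
  tok <- matrix(unlist(toks), nrow = n, byrow = TRUE)
  fam <- tok[, 1]; iid <- tok[, 2]; pheno <- tok[, 6]
  a1 <- tok[, 6 + 2 * seq_len(m) - 1, drop = FALSE]
  a2 <- tok[, 6 + 2 * seq_len(m), drop = FALSE]
  dosage <- matrix(NA_integer_, m, n)
  allele_a <- allele_b <- character(m)
  for (j in seq_len(m)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    miss <- x1 == "0" | x2 == "0"
    obs <- sort(unique(c(x1[!miss], x2[!miss])))
    if (length(obs) > 2)
      stop(sprintf("marker %s has >2 alleles: %s", mp$marker_id[j],
                   paste(obs, collapse = ",")))
    if (length(obs) == 0) { allele_a[j] <- allele_b[j] <- NA_character_; next }
    allele_a[j] <- obs[1]
    allele_b[j] <- if (length(obs) == 2) obs[2] else NA_character_
    b <- allele_b[j]
    d <- (x1 == b) + (x2 == b)
    if (is.na(b)) d <- rep(0L, n)
    d[miss] <- NA_integer_
    dosage[j, ] <- as.integer(d)
  }
  origin <- ifelse(pheno == "2", "mainland", ifelse(pheno == "1", "island", NA))
  samp <- data.frame(sample_id = iid, origin = origin, region = fam)
  mm <- data.frame(marker_id = mp$marker_id, chromosome = mp$chromosome,
                   position_bp = as.integer(mp$position_bp),
                   allele_a = allele_a, allele_b = allele_b)
  keep <- mm$chromosome %in% autosomes
  g <- GenotypeData(dosage[keep, , drop = FALSE], mm[keep, , drop = FALSE], samp)
  if (verbose)
    message(sprintf("readPlinkText: %d non-missing genotypes loaded",
                    sum(!is.na(dosages(g)))))
  g
}

#' Write PLINK text genotypes (PED/MAP)
#'
#' @param x a [GenotypeData-class] object.
#' @param prefix output path prefix; `<prefix>.ped` and `<prefix>.map` are
#'   written.
#' @return invisibly, the two file paths.
#' @export
writePlinkText <- function(x, prefix) {
  mm <- markerMap(x)
  si <- sampleInfo(x)
  d <- dosages(x)
  write.table(data.frame(mm$chromosome, mm$marker_id, 0L, mm$position_bp),
              paste0(prefix, ".map"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  pheno <- rep("-9", ncol(d))
  if (!is.null(si$origin))
    pheno <- ifelse(is.na(si$origin), "-9",
                    ifelse(si$origin == "mainland", "2", "1"))
  region <- if (!is.null(si$region)) as.character(si$region) else rep("0", ncol(d))
  region[is.na(region)] <- "0"
  aa <- ifelse(is.na(mm$allele_a), "A", mm$allele_a)
  ab <- ifelse(is.na(mm$allele_b), "B", mm$allele_b)
  con <- file(paste0(prefix, ".ped"), "w")
  on.exit(close(con))
  for (i in seq_len(ncol(d))) {
    di <- d[, i]
    gt <- ifelse(is.na(di), "0 0",
                 ifelse(di == 0L, paste(aa, aa),
                        ifelse(di == 1L, paste(aa, ab), paste(ab, ab))))
    writeLines(paste(region[i], si$sample_id[i], "0", "0", "0", pheno[i],
                     paste(gt, collapse = " ")), con)
  }
  invisible(paste0(prefix, c(".ped", ".map")))
}

#' Read PLINK binary genotypes (BED/BIM/FAM)
#'
#' SNP-major .bed files only (magic bytes `6c 1b 01`). The 2-bit codes map
#' as: `00` = homozygous for the first BIM allele (dosage 0 of the counted B
#' allele), `01` = missing, `10` = heterozygous, `11` = homozygous for the
#' second BIM allele (dosage 2). The counted B allele is the second allele
#' column of the BIM record.
#'
#' @inheritParams readPlinkText
#' @param bed_path,bim_path,fam_path paths to the three files.
#' @return a [GenotypeData-class] object.
#' @export
readPlinkBinary <- function(bed_path, bim_path, fam_path,
                            autosomes = as.character(1:26), verbose = FALSE) {
  stopifnot(file.exists(bed_path), file.exists(bim_path), file.exists(fam_path))
  bim <- read.table(bim_path, header = FALSE, colClasses = "character")
  colnames(bim) <- c("chromosome", "marker_id", "cm", "position_bp",
                     "allele_1", "allele_2")
  fam <- read.table(fam_path, header = FALSE, colClasses = "character")
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK .bed file (bad magic bytes)")
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major .bed files are supported (mode byte != 0x01)")
  nb <- ceiling(n / 4)
  body <- as.integer(raw[-(1:3)])
  if (length(body) != nb * m)
    stop(sprintf(".bed payload is %d bytes, expected %d", length(body), nb * m))
  bmat <- matrix(body, nrow = nb, ncol = m)
  codes <- matrix(0L, 4 * nb, m)
  for (s in 0:3)
    codes[seq(s + 1, 4 * nb, by = 4), ] <- (bmat %/% 4L^s) %% 4L
  codes <- codes[seq_len(n), , drop = FALSE]
  dosage <- t(codes)  # markers x samples
  dosage[] <- c(0L, NA_integer_, 1L, 2L)[dosage + 1L]
  origin <- ifelse(fam[, 6] == "2", "mainland",
                   ifelse(fam[, 6] == "1", "island", NA))
  samp <- data.frame(sample_id = fam[, 2], origin = origin, region = fam[, 1])
  mm <- data.frame(marker_id = bim$marker_id, chromosome = bim$chromosome,
                   position_bp = as.integer(bim$position_bp),
                   allele_a = bim$allele_1, allele_b = bim$allele_2)
  keep <- mm$chromosome %in% autosomes
  g <- GenotypeData(dosage[keep, , drop = FALSE], mm[keep, , drop = FALSE], samp)
  if (verbose)
    message(sprintf("readPlinkBinary: %d non-missing genotypes loaded",
                    sum(!is.na(dosages(g)))))
  g
}

#' Write PLINK binary genotypes (BED/BIM/FAM)
#'
#' @param x a [GenotypeData-class] object.
#' @param prefix output path prefix; `<prefix>.bed/.bim/.fam` are written.
#' @return invisibly, the three file paths.
#' @export
writePlinkBinary <- function(x, prefix) {
  mm <- markerMap(x)
  si <- sampleInfo(x)
  d <- dosages(x)
  n <- ncol(d); m <- nrow(d)
  aa <- ifelse(is.na(mm$allele_a), "A", mm$allele_a)
  ab <- ifelse(is.na(mm$allele_b), "B", mm$allele_b)
  write.table(data.frame(mm$chromosome, mm$marker_id, 0L, mm$position_bp, aa, ab),
              paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  pheno <- rep("-9", n)
  if (!is.null(si$origin))
    pheno <- ifelse(is.na(si$origin), "-9",
                    ifelse(si$origin == "mainland", "2", "1"))
  region <- if (!is.null(si$region)) as.character(si$region) else rep("0", n)
  region[is.na(region)] <- "0"
  write.table(data.frame(region, si$sample_id, 0L, 0L, 0L, pheno),
              paste0(prefix, ".fam"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  codes <- d
  codes[] <- ifelse(is.na(d), 1L, c(0L, 2L, 3L)[d + 1L])
  nb <- ceiling(n / 4)
  pad <- 4 * nb - n
  if (pad > 0) codes <- cbind(codes, matrix(0L, m, pad))
  # pack: per marker, sum of code * 4^(pos within byte) grouped in fours
  shift <- rep(4L^(0:3), nb)
  grp <- rep(seq_len(nb), each = 4)
  weighted <- sweep(codes, 2, shift, "*")
  bytes <- t(rowsum(t(weighted), grp))  # m x nb
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(t(bytes)), con)
  invisible(paste0(prefix, c(".bed", ".bim", ".fam")))
}

#' Read a gene/QTL feature table from BED or GFF3
#'
#' BED input (0-based half-open) is converted to the package's 1-based
#' inclusive convention; GFF3 is already 1-based inclusive.
#'
#' @param path input file.
#' @param format `"bed"` or `"gff3"`.
#' @param kind feature kind label to record (`"gene"` or `"qtl"`).
#' @return data.frame with columns `feature_id`, `chromosome`, `start_bp`,
#'   `end_bp` (1-based inclusive), `kind`, `name`.
#' @export
readFeatureTable <- function(path, format = c("bed", "gff3"), kind = "gene") {
  format <- match.arg(format)
  if (format == "bed") {
    tb <- read.table(path, header = FALSE, sep = "\t", colClasses = "character")
    name <- if (ncol(tb) >= 4) tb[, 4] else sprintf("feature_%d", seq_len(nrow(tb)))
    out <- data.frame(feature_id = name,
                      chromosome = tb[, 1],
                      start_bp = as.integer(tb[, 2]) + 1L,
                      end_bp = as.integer(tb[, 3]),
                      kind = kind, name = name)
  } else {
    ln <- readLines(path)
    ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
    tb <- do.call(rbind, strsplit(ln, "\t"))
    attr_name <- function(s, key) {
      m <- regmatches(s, regexec(paste0(key, "=([^;]+)"), s))
      vapply(m, function(z) if (length(z) == 2) z[2] else NA_character_, "")
    }
    nm <- attr_name(tb[, 9], "Name")
    id <- attr_name(tb[, 9], "ID")
    nm[is.na(nm)] <- id[is.na(nm)]
    out <- data.frame(feature_id = ifelse(is.na(id), nm, id),
                      chromosome = tb[, 1],
                      start_bp = as.integer(tb[, 4]),
                      end_bp = as.integer(tb[, 5]),
                      kind = kind, name = nm)
  }
  stopifnot(all(out$start_bp <= out$end_bp))
  out
}

#' Write a per-marker scan table as TSV
#'
#' Tab-separated, one row per marker, stable column order, full-precision
#' deterministic float formatting.
#'
#' @param table data.frame, one row per marker.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeScanTable <- function(table, path) {
  stopifnot(nrow(table) > 0)
  num <- vapply(table, is.numeric, TRUE) & !vapply(table, is.integer, TRUE)
  table[num] <- lapply(table[num], function(x) sprintf("%.10g", x))
  write.table(table, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' Read a scan table written by [writeScanTable()]
#'
#' @param path input path.
#' @return data.frame.
#' @export
readScanTable <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Read/write the sample table (TSV)
#'
#' @param path file path.
#' @return data.frame with `sample_id`, `origin`, `region`, `herd`,
#'   `coord_x`, `coord_y` (whichever are present).
#' @export
readSampleTable <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname readSampleTable
#' @param table data.frame to write.
#' @export
writeSampleTable <- function(table, path) {
  write.table(table, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}
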