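## On-disk formats: VCFv4.2 (read via vcfR, written by a small
## formatter), counts TSV, phenotype/population-map CSV, annotation TSV.
## Internal coordinates are the VCF's own 1-based positions; missing
## values serialize as "NA" in CSV/TSV and "./." in VCF.

.gtCode <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")

#' Write genotype calls as VCFv4.2
#'
#' Biallelic SNP records with per-sample GT (and DP when supplied), site
#' QUAL, and INFO field NS (samples without data).
#'
#' @param geno a [GenotypeData-class].
#' @param path output file.
#' @param dp optional sample x variant integer depth matrix.
#' @return `path`, invisibly.
#' @export
writeGenotypeVcf <- function(geno, path, dp = NULL) {
  d <- dosages(geno)
  vt <- variantInfo(geno)
  samples <- rownames(d)
  gt <- matrix(.gtCode[as.character(t(d))], ncol(d), nrow(d))
  gt[is.na(gt)] <- "./."
  if (!is.null(dp)) {
    dpv <- t(dp[samples, colnames(d), drop = FALSE])
    gt <- matrix(paste0(gt, ":", ifelse(is.na(dpv), ".", dpv)),
                 nrow(gt), ncol(gt))
    fmt <- "GT:DP"
  } else fmt <- "GT"
  qual <- if (!is.null(vt$QUAL)) sprintf("%.2f", vt$QUAL) else "."
  ns <- if (!is.null(vt$NS)) vt$NS else colSums(is.na(d))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=rilgp",
           paste0("##INFO=<ID=NS,Number=1,Type=Integer,",
                  "Description=\"Number of samples without data\">"),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           if (!is.null(dp))
             "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- cbind(vt$chrom, vt$pos, rownames(vt), vt$ref, vt$alt, qual,
                "PASS", paste0("NS=", ns), fmt, gt)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(body, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read genotype calls from a VCF file
#'
#' Parses biallelic SNP records (others are skipped and counted) into a
#' dosage matrix: GT 0/0 -> 0, 0/1 -> 1, 1/1 -> 2, ./. -> missing.
#' Per-sample DP, site QUAL and INFO NS are captured when present; MAF
#' is computed from the observed calls.
#'
#' @param path VCF file (may be bgzipped).
#' @param popmap the [PopulationMap-class] the lines belong to.
#' @return list with `geno` ([GenotypeData-class]), `dp` (sample x
#'   variant depth matrix or NULL) and `skipped` (non-biallelic record
#'   count).
#' @export
readGenotypeVcf <- function(path, popmap) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  bi <- vcfR::is.biallelic(vcf)
  skipped <- sum(!bi)
  if (skipped) message(skipped, " non-biallelic record(s) skipped")
  vcf <- vcf[bi, ]
  if (nrow(vcf@fix) == 0) stop("no biallelic SNP records in ", path)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gsub("|", "/", gt, fixed = TRUE)
  dos <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  dos[gt %in% c("0/0")] <- 0
  dos[gt %in% c("0/1", "1/0")] <- 1
  dos[gt %in% c("1/1")] <- 2
  fixed <- vcfR::getFIX(vcf)
  if (is.null(dim(fixed)))
    fixed <- matrix(fixed, nrow = 1, dimnames = list(NULL, names(fixed)))
  ids <- unname(fixed[, "ID"])
  noId <- is.na(ids) | ids == "."
  ids[noId] <- paste0(fixed[noId, "CHROM"], "_", fixed[noId, "POS"])
  rownames(dos) <- ids
  dp <- NULL
  if ("DP" %in% vcfR::vcf_field_names(vcf, tag = "FORMAT")$ID) {
    dp <- t(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
    colnames(dp) <- ids
  }
  ns <- suppressWarnings(as.integer(vcfR::extract.info(vcf, "NS")))
  d <- t(dos)
  vt <- data.frame(chrom = fixed[, "CHROM"],
                   pos = as.integer(fixed[, "POS"]),
                   ref = fixed[, "REF"], alt = fixed[, "ALT"],
                   QUAL = suppressWarnings(as.numeric(fixed[, "QUAL"])),
                   NS = if (all(is.na(ns))) colSums(is.na(d)) else ns,
                   DP = if (is.null(dp)) NA_real_ else colMeans(dp, na.rm = TRUE),
                   MAF = .maf(d),
                   row.names = ids, stringsAsFactors = FALSE)
  list(geno = GenotypeData(d, vt, popmap, provenance = "rnaseq"),
       dp = dp, skipped = skipped)
}

#' Write / read a transcript counts table (TSV)
#'
#' Transcripts x samples, tab-separated, with a header line of sample
#' ids and the transcript id in the first column.
#'
#' @param expr an [ExpressionCounts-class].
#' @param path file path.
#' @param countsPath,samplesPath paths of the counts and sample tables.
#' @return `path` invisibly / an [ExpressionCounts-class].
#' @export
writeCountsTsv <- function(expr, path) {
  cm <- countsMatrix(expr)
  df <- data.frame(transcript = rownames(cm), cm, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCountsTsv
#' @export
readCountsTsv <- function(countsPath, samplesPath = NULL) {
  df <- read.table(countsPath, header = TRUE, sep = "\t",
                   check.names = FALSE, stringsAsFactors = FALSE)
  cm <- as.matrix(df[, -1, drop = FALSE])
  rownames(cm) <- df[[1]]
  samples <- if (!is.null(samplesPath)) {
    s <- read.table(samplesPath, header = TRUE, sep = ",",
                    stringsAsFactors = FALSE)
    rownames(s) <- s$sample
    s[colnames(cm), c("line", "block"), drop = FALSE]
  } else {
    data.frame(line = colnames(cm), block = 1L, row.names = colnames(cm))
  }
  ExpressionCounts(cm, samples)
}

#' Write / read a long-format phenotype table (CSV)
#'
#' Columns: line, env, trait, value (missing as NA).
#'
#' @param phenos long data.frame.
#' @param path file path.
#' @return `path` invisibly / a data.frame.
#' @export
writePhenotypesCsv <- function(phenos, path) {
  write.table(phenos, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePhenotypesCsv
#' @export
readPhenotypesCsv <- function(path) {
  read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
}

#' Write / read a population map (CSV)
#'
#' Long format: line, population, parent1, parent2 (parents of the
#' line's population; parent lines carry population "parent").
#'
#' @param popmap a [PopulationMap-class].
#' @param path file path.
#' @return `path` invisibly / a [PopulationMap-class].
#' @export
writePopmapCsv <- function(popmap, path) {
  pop <- populationOf(popmap)
  p1 <- p2 <- rep(NA_character_, length(pop))
  for (p in populationNames(popmap)) {
    pr <- parentsOf(popmap, p)
    p1[pop == p] <- pr[1]; p2[pop == p] <- pr[2]
  }
  write.table(data.frame(line = names(pop), population = unname(pop),
                         parent1 = p1, parent2 = p2),
              path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePopmapCsv
#' @export
readPopmapCsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = ",",
                   stringsAsFactors = FALSE, na.strings = "NA")
  pops <- unique(df$population[df$population != "parent"])
  parents <- lapply(pops, function(p) {
    r <- df[df$population == p, ][1, ]
    c(r$parent1, r$parent2)
  })
  PopulationMap(setNames(df$population, df$line),
                setNames(parents, pops))
}

#' Write the variant annotation table (TSV)
#'
#' Columns: variant, effect (annotation class), distance (bp to the
#' coding region).
#'
#' @param variants variant metadata data.frame with `effect`, `distance`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeAnnotationTsv <- function(variants, path) {
  write.table(data.frame(variant = rownames(variants),
                         effect = variants$effect,
                         distance = variants$distance),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
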