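## Synthetic multi-parent RIL data with the statistical structure the
## downstream analysis assumes: three homozygous parents, three biparental
## RIL populations (F7 by default), negative-binomial transcript counts in
## randomized incomplete blocks of 24 (21 RILs + the three parental
## checks), expression-coupled variant-call observations, and multi-
## environment phenotypes with a target broad-sense heritability.

#' Simulation parameter set
#'
#' Defaults emulate the study design: 3 RIL populations of 65/92/80 F7
#' lines from pairwise crosses of 3 inbreds, blocks of 24 samples
#' (21 RILs + 3 parental checks), 8 traits in 4-7 environments with
#' broad-sense heritabilities in 0.74-0.89. Genome scale (variants,
#' transcripts, library size) defaults to a desk-scale reduction of the
#' study's RNA-Seq dimensions.
#'
#' @slot nChromosomes,mapLength chromosome count and genetic length per
#'   chromosome in Morgans.
#' @slot nVariants,nTranscripts genome scale.
#' @slot popSizes RIL count per population.
#' @slot selfingGenerations selfing generations after the F1 (6 = F7).
#' @slot nTraits number of traits.
#' @slot nEnvironments environments per trait (recycled to `nTraits`).
#' @slot targetH2 target broad-sense heritability per trait, in (0, 1].
#' @slot nQtlPerTrait QTL count per trait.
#' @slot nbDispersion negative-binomial dispersion of counts (0 = Poisson).
#' @slot meanLibrarySize mean reads per sample.
#' @slot blockSize samples per cultivation block.
#' @slot genotypingErrorRate,missingRate per-call error/missing probability.
#' @slot hetErrorShare share of genotyping errors that create a spurious
#'   heterozygote (the rest flip the homozygous class).
#' @slot eqtlFraction fraction of transcripts carrying a cis eQTL.
#' @slot blockSd standard deviation of log multiplicative block effects.
#' @slot dpRate expected variant read depth per host-transcript read.
#' @slot arraySize number of array-genotyped variants.
#' @slot parentRepsPerEnv phenotypic check replicates per environment.
#' @slot seed integer seed.
#' @export
setClass("SimParams",
  representation(nChromosomes = "numeric", mapLength = "numeric",
    nVariants = "numeric", nTranscripts = "numeric", popSizes = "numeric",
    selfingGenerations = "numeric", nTraits = "numeric",
    nEnvironments = "numeric", targetH2 = "numeric",
    nQtlPerTrait = "numeric", nbDispersion = "numeric",
    meanLibrarySize = "numeric", blockSize = "numeric",
    genotypingErrorRate = "numeric", missingRate = "numeric",
    hetErrorShare = "numeric", eqtlFraction = "numeric", blockSd = "numeric",
    dpRate = "numeric", arraySize = "numeric", parentRepsPerEnv = "numeric",
    seed = "numeric"))

setValidity("SimParams", function(object) {
  msg <- character()
  pr <- c(object@genotypingErrorRate, object@missingRate,
          object@hetErrorShare, object@eqtlFraction)
  if (any(pr < 0 | pr > 1)) msg <- c(msg, "probabilities must lie in [0,1]")
  if (any(object@popSizes <= 0)) msg <- c(msg, "popSizes must be positive")
  if (any(object@targetH2 <= 0 | object@targetH2 > 1))
    msg <- c(msg, "targetH2 must lie in (0,1]")
  if (object@nVariants < 1) msg <- c(msg, "nVariants must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Create a simulation parameter set
#'
#' @param nChromosomes,mapLength,nVariants,nTranscripts,popSizes,selfingGenerations,nTraits,nEnvironments,targetH2,nQtlPerTrait,nbDispersion,meanLibrarySize,blockSize,genotypingErrorRate,missingRate,hetErrorShare,eqtlFraction,blockSd,dpRate,arraySize,parentRepsPerEnv,seed
#'   see [SimParams-class].
#' @return A validated [SimParams-class] object.
#' @export
simParams <- function(nChromosomes = 3, mapLength = 1, nVariants = 5000,
                      nTranscripts = 2000, popSizes = c(65, 92, 80),
                      selfingGenerations = 6, nTraits = 8,
                      nEnvironments = c(5, 5, 7, 5, 4, 4, 4, 4),
                      targetH2 = c(0.88, 0.74, 0.86, 0.76, 0.84, 0.85,
                                   0.89, 0.84),
                      nQtlPerTrait = 30, nbDispersion = 0.05,
                      meanLibrarySize = 6e5, blockSize = 24,
                      genotypingErrorRate = 0.02, missingRate = 0.1,
                      hetErrorShare = 0.5, eqtlFraction = 0.2,
                      blockSd = 0.15, dpRate = 0.02, arraySize = 1000,
                      parentRepsPerEnv = 3, seed = 1) {
  nEnvironments <- rep_len(nEnvironments, nTraits)
  targetH2 <- rep_len(targetH2, nTraits)
  new("SimParams", nChromosomes = nChromosomes, mapLength = mapLength,
      nVariants = nVariants, nTranscripts = nTranscripts,
      popSizes = popSizes, selfingGenerations = selfingGenerations,
      nTraits = nTraits, nEnvironments = nEnvironments,
      targetH2 = targetH2, nQtlPerTrait = nQtlPerTrait,
      nbDispersion = nbDispersion, meanLibrarySize = meanLibrarySize,
      blockSize = blockSize, genotypingErrorRate = genotypingErrorRate,
      missingRate = missingRate, hetErrorShare = hetErrorShare,
      eqtlFraction = eqtlFraction, blockSd = blockSd, dpRate = dpRate,
      arraySize = arraySize, parentRepsPerEnv = parentRepsPerEnv,
      seed = seed)
}

setMethod("show", "SimParams", function(object) {
  cat(sprintf(
    "SimParams: %d chrom x %.1f M, %d variants, %d transcripts, pops %s, F%d\n",
    object@nChromosomes, object@mapLength, object@nVariants,
    object@nTranscripts, paste(object@popSizes, collapse = "/"),
    object@selfingGenerations + 1))
})

#' Simulate the three parental inbred genomes
#'
#' Places transcripts and (within-transcript) variants on a genetic map
#' and draws fully homozygous biallelic parent genotypes. Every variant is
#' guaranteed polymorphic between at least one parent pair. Variants carry
#' a functional-annotation class and a distance to the coding region, as a
#' variant-effect predictor would report them.
#'
#' @param params a [SimParams-class].
#' @return list with `map` (per-variant data.frame: `variant`, `chrom`,
#'   `pos` in bp, `posM` in Morgans, `transcript`, `ref`, `alt`, `effect`,
#'   `distance`), `parents` (3 x variants dosage matrix in \{0,2\}), and
#'   `transcripts` (id, chrom, pos).
#' @export
simulateParents <- function(params) {
  stopifnot(is(params, "SimParams"))
  set.seed(params@seed)
  nc <- params@nChromosomes
  L <- params@mapLength
  span <- round(L * 1e6)                      # 1 Mb per Morgan
  ntr <- params@nTranscripts
  nv <- params@nVariants

  trChrom <- sort(rep_len(seq_len(nc), ntr))
  trPos <- unlist(lapply(tabulate(trChrom, nc), function(k)
    sort(sample.int(span - 3000L, k))))
  transcripts <- data.frame(
    transcript = sprintf("tr%05d", seq_len(ntr)),
    chrom = paste0("chr", trChrom), pos = trPos,
    stringsAsFactors = FALSE)

  host <- sample.int(ntr, nv, replace = TRUE)
  pos <- trPos[host] + sample.int(2000L, nv, replace = TRUE)
  chrom <- trChrom[host]
  ord <- order(chrom, pos)
  host <- host[ord]; pos <- pos[ord]; chrom <- chrom[ord]

  nuc <- c("A", "C", "G", "T")
  ref <- sample(nuc, nv, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(nuc, r), 1), "")
  effect <- sample(c("missense_variant", "synonymous_variant",
                     "upstream_gene_variant", "downstream_gene_variant"),
                   nv, replace = TRUE)
  distance <- ifelse(grepl("stream", effect),
                     sample.int(8000L, nv, replace = TRUE), 0L)

  map <- data.frame(
    variant = sprintf("var%06d", seq_len(nv)),
    chrom = paste0("chr", chrom), pos = pos, posM = pos / 1e6,
    transcript = transcripts$transcript[host],
    ref = ref, alt = alt, effect = effect, distance = distance,
    stringsAsFactors = FALSE)

  par <- matrix(2L * rbinom(3L * nv, 1L, 0.5), nrow = 3,
                dimnames = list(c("ParentA", "ParentB", "ParentC"),
                                map$variant))
  mono <- which(par[1, ] == par[2, ] & par[2, ] == par[3, ])
  if (length(mono)) {
    flip <- sample.int(3L, length(mono), replace = TRUE)
    par[cbind(flip, mono)] <- 2L - par[cbind(flip, mono)]
  }
  list(map = map, parents = par, transcripts = transcripts)
}

## One meiotic gamete from a haplotype pair on one chromosome.
## h1/h2 are parental-origin vectors over loci sorted by posM; crossover
## count is Poisson with mean = map length (Haldane, no interference).
.simGamete <- function(h1, h2, posM, len) {
  k <- rpois(1L, len)
  start <- rbinom(1L, 1L, 0.5)
  if (k == 0L) {
    g <- if (start == 0L) h1 else h2
  } else {
    cuts <- sort(runif(k, 0, len))
    seg <- (start + findInterval(posM, cuts)) %% 2L
    g <- ifelse(seg == 0L, h1, h2)
  }
  attr(g, "ncross") <- k
  g
}

#' Simulate one biparental RIL population by single-seed descent
#'
#' F1 from two homozygous parents, then `selfingGenerations` rounds of
#' selfing with Haldane (Poisson, no interference) meioses. Residual
#' heterozygosity halves each generation, so F7 lines retain about
#' \eqn{(1/2)^6} heterozygous loci.
#'
#' @param parentA,parentB homozygous dosage vectors in \{0,2\} over the
#'   same variants (named).
#' @param nRils number of lines.
#' @param selfingGenerations selfing rounds after the F1.
#' @param map per-variant map with columns `chrom` and `posM` in the
#'   order of the parent vectors.
#' @param seed integer seed.
#' @param prefix line-id prefix.
#' @return nRils x variants dosage matrix in \{0,1,2\}.
#' @export
simulateRilPopulation <- function(parentA, parentB, nRils,
                                  selfingGenerations, map, seed,
                                  prefix = "RIL") {
  if (any(parentA == 1, na.rm = TRUE) || any(parentB == 1, na.rm = TRUE))
    stop("parents must be fully homozygous")
  set.seed(seed)
  chroms <- unique(map$chrom)
  idx <- lapply(chroms, function(ch) which(map$chrom == ch))
  lens <- vapply(idx, function(i) max(map$posM[i]) - min(map$posM[i]) +
                   .Machine$double.eps, 0)
  nv <- nrow(map)

  doss <- matrix(0L, nRils, nv,
                 dimnames = list(sprintf("%s%03d", prefix, seq_len(nRils)),
                                 map$variant))
  aA <- as.integer(parentA / 2)               # per-haplotype alt allele
  aB <- as.integer(parentB / 2)
  for (r in seq_len(nRils)) {
    h1 <- rep(0L, nv); h2 <- rep(1L, nv)      # F1: one haplotype per parent
    for (g in seq_len(selfingGenerations)) {
      n1 <- integer(nv); n2 <- integer(nv)
      for (ci in seq_along(idx)) {
        i <- idx[[ci]]
        pm <- map$posM[i]
        n1[i] <- .simGamete(h1[i], h2[i], pm, lens[ci])
        n2[i] <- .simGamete(h1[i], h2[i], pm, lens[ci])
      }
      h1 <- n1; h2 <- n2
    }
    doss[r, ] <- ifelse(h1 == 0L, aA, aB) + ifelse(h2 == 0L, aA, aB)
  }
  doss
}

## Block design: blocks of `blockSize` samples = (blockSize-3) RILs + the
## three parental checks. RIL slots left over in the last block are filled
## by re-replicating randomly chosen RILs (augmented design).
.blockDesign <- function(rils, parents, blockSize, seed) {
  set.seed(seed)
  perBlock <- blockSize - length(parents)
  nBlocks <- ceiling(length(rils) / perBlock)
  slots <- nBlocks * perBlock
  filler <- if (slots > length(rils))
    sample(rils, slots - length(rils)) else character()
  assigned <- sample(c(rils, filler))
  data.frame(
    line = c(assigned, rep(parents, times = nBlocks)),
    block = c(rep(seq_len(nBlocks), each = perBlock),
              rep(seq_len(nBlocks), each = length(parents))),
    stringsAsFactors = FALSE)
}

#' Simulate transcript read counts in an incomplete-block design
#'
#' Counts are negative binomial with mean = library size x relative
#' transcript abundance; a configurable fraction of transcripts carry a
#' cis eQTL (multiplicative genotype-dependent shift driven by a variant
#' hosted in the transcript); multiplicative per-block, per-transcript
#' effects; each block contains all three parental checks once.
#'
#' @param genotypes line x variant dosage matrix (all lines incl. parents).
#' @param sim output of [simulateParents()] (for the variant-transcript map).
#' @param popmap a [PopulationMap-class].
#' @param params a [SimParams-class].
#' @param seed integer seed.
#' @return list with `expr` ([ExpressionCounts-class]) and `truth`
#'   (eQTL assignment: transcript, variant, log2 fold per alt allele).
#' @export
simulateExpression <- function(genotypes, sim, popmap, params, seed) {
  design <- .blockDesign(rilLines(popmap), parentLines(popmap),
                         params@blockSize, seed)
  set.seed(seed + 1L)
  ntr <- nrow(sim$transcripts)
  trIds <- sim$transcripts$transcript
  base <- stats::rlnorm(ntr, 0, 1.2)

  nEqtl <- round(params@eqtlFraction * ntr)
  eqtlTr <- sample.int(ntr, nEqtl)
  hosted <- split(sim$map$variant, sim$map$transcript)
  eqtlVar <- vapply(trIds[eqtlTr], function(tr) {
    h <- hosted[[tr]]
    if (is.null(h)) sample(sim$map$variant, 1) else h[sample.int(length(h), 1)]
  }, "")
  eqtlFold <- rnorm(nEqtl, 0, 0.6)            # log2 fold per alt haplotype

  nS <- nrow(design)
  sampleId <- sprintf("%s_b%02d", design$line, design$block)
  ## re-replicated RILs within a block get unique suffixes
  sampleId <- make.unique(sampleId, sep = "r")
  lib <- round(stats::rlnorm(nS, log(params@meanLibrarySize), 0.2))

  relMat <- matrix(base, ntr, nS)
  dos <- genotypes[design$line, , drop = FALSE]
  for (k in seq_len(nEqtl)) {
    d <- dos[, eqtlVar[k]] / 2                # 0/0.5/1 alt haplotype share
    relMat[eqtlTr[k], ] <- relMat[eqtlTr[k], ] * 2^(eqtlFold[k] * d)
  }
  nBlocks <- max(design$block)
  blockEff <- matrix(stats::rlnorm(ntr * nBlocks, 0, params@blockSd),
                     ntr, nBlocks)
  relMat <- relMat * blockEff[, design$block]
  relMat <- sweep(relMat, 2, colSums(relMat), "/")
  mu <- sweep(relMat, 2, lib, "*")
  counts <- if (params@nbDispersion > 0) {
    matrix(rnbinom(ntr * nS, size = 1 / params@nbDispersion, mu = mu),
           ntr, nS)
  } else {
    matrix(rpois(ntr * nS, mu), ntr, nS)
  }
  dimnames(counts) <- list(trIds, sampleId)
  samples <- data.frame(line = design$line, block = design$block,
                        row.names = sampleId, stringsAsFactors = FALSE)
  list(expr = ExpressionCounts(counts, samples),
       truth = data.frame(transcript = trIds[eqtlTr], variant = eqtlVar,
                          log2fold = eqtlFold, stringsAsFactors = FALSE))
}

#' Simulate noisy RNA-Seq variant-call observations
#'
#' Per-sample read depth at a variant is Poisson with mean proportional
#' to the host transcript's read count, so callability follows
#' expression. Calls are missing at zero depth or with `missingRate`;
#' genotyping errors occur at `genotypingErrorRate` (a `hetErrorShare`
#' fraction produce spurious heterozygotes). Site QUAL increases
#' monotonically in total depth (plus noise); NS counts samples without a
#' call; MAF is computed from observed calls.
#'
#' @param genotypes line x variant true dosage matrix.
#' @param expr [ExpressionCounts-class] from [simulateExpression()].
#' @param sim output of [simulateParents()].
#' @param params a [SimParams-class].
#' @param seed integer seed.
#' @return list with `obs` (sample x variant observed dosage matrix),
#'   `variants` (data.frame: DP, QUAL, NS, MAF and map columns),
#'   `sampleLine` (named character sample -> line), and `dp`
#'   (sample x variant depth matrix).
#' @export
simulateVariantObservation <- function(genotypes, expr, sim, params, seed) {
  set.seed(seed)
  cm <- countsMatrix(expr)
  sampleLine <- setNames(sampleInfo(expr)$line, colnames(cm))
  host <- match(sim$map$transcript, rownames(cm))
  nv <- nrow(sim$map); nS <- ncol(cm)

  lam <- t(cm[host, , drop = FALSE]) * params@dpRate   # samples x variants
  dp <- matrix(rpois(length(lam), lam), nS, nv,
               dimnames = list(colnames(cm), sim$map$variant))

  true <- genotypes[sampleLine, , drop = FALSE][, sim$map$variant,
                                                drop = FALSE]
  obs <- true
  miss <- dp == 0 | matrix(runif(nS * nv) < params@missingRate, nS, nv)
  err <- !miss & matrix(runif(nS * nv) < params@genotypingErrorRate, nS, nv)
  isHetErr <- matrix(runif(nS * nv) < params@hetErrorShare, nS, nv)
  obs[err & isHetErr] <- 1
  flip <- err & !isHetErr
  obs[flip] <- 2 - obs[flip]                   # 0<->2, 1 stays 1
  obs[miss] <- NA
  rownames(obs) <- colnames(cm)

  totDP <- colSums(dp)
  qual <- 10 * log10(1 + totDP) * exp(rnorm(nv, 0, 0.05))
  ns <- colSums(is.na(obs))
  p <- colMeans(obs, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- NA
  variants <- cbind(sim$map,
                    data.frame(DP = colMeans(dp), QUAL = qual, NS = ns,
                               MAF = maf))
  rownames(variants) <- sim$map$variant
  list(obs = obs, variants = variants, sampleLine = sampleLine, dp = dp)
}

#' Derive parental WGS variants and an array genotype subset
#'
#' The WGS table covers all simulated variant positions for the three
#' parents, error-free (a superset of what RNA-Seq can observe). The
#' array is a fixed sparse subset of variants typed on every line with
#' low missingness and no genotyping error.
#'
#' @param sim output of [simulateParents()].
#' @param genotypes line x variant true dosage matrix.
#' @param popmap a [PopulationMap-class].
#' @param params a [SimParams-class].
#' @param seed integer seed.
#' @param arrayMissingRate missingness of array calls.
#' @return list with `wgs` (parent x variant dosage matrix + `map`) and
#'   `array` ([GenotypeData-class], provenance `"array"`).
#' @export
deriveWgsAndArray <- function(sim, genotypes, popmap, params, seed,
                              arrayMissingRate = 0.01) {
  if (params@arraySize > nrow(sim$map))
    stop("requested array size exceeds available variants")
  set.seed(seed)
  wgs <- list(genotypes = sim$parents, map = sim$map)
  keep <- sort(sample.int(nrow(sim$map), params@arraySize))
  arr <- genotypes[, sim$map$variant[keep], drop = FALSE]
  arr[matrix(runif(length(arr)) < arrayMissingRate, nrow(arr))] <- NA
  vt <- sim$map[keep, c("chrom", "pos", "ref", "alt")]
  rownames(vt) <- sim$map$variant[keep]
  list(wgs = wgs,
       array = GenotypeData(arr, vt, popmap, provenance = "array"))
}

#' Binomially thin read counts to emulate reduced sequencing depth
#'
#' Each count is thinned at the given fraction, preserving relative
#' composition in expectation. Samples falling below `minReads` total
#' reads are excluded, mirroring the rule that under-sequenced samples
#' are dropped and the same sample set is used across compared datasets.
#'
#' @param expr an [ExpressionCounts-class].
#' @param fraction retention probability in (0, 1].
#' @param seed integer seed.
#' @param minReads minimum total reads to keep a sample.
#' @return An [ExpressionCounts-class] with thinned counts (possibly
#'   fewer samples).
#' @export
thinReads <- function(expr, fraction, seed, minReads = 0) {
  if (fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]")
  cm <- countsMatrix(expr)
  if (fraction < 1) {
    set.seed(seed)
    cm <- matrix(rbinom(length(cm), size = cm, prob = fraction),
                 nrow(cm), dimnames = dimnames(cm))
  }
  keep <- colSums(cm) >= minReads
  if (!all(keep))
    message(sum(!keep), " sample(s) below ", minReads,
            " reads excluded after thinning")
  ExpressionCounts(cm[, keep, drop = FALSE],
                   sampleInfo(expr)[keep, , drop = FALSE])
}

## Scale QTL effects so that noise-free entry means hit the target
## broad-sense heritability in expectation: with single-replicate lines in
## J environments, vbar = 2(sigma_GxE^2 + sigma_e^2)/J, and
## H2 = sigmaG2 / (sigmaG2 + vbar/2). Setting sigma_GxE^2 = sigma_e^2 = s
## gives s = J * sigmaG2 * (1 - h2) / (2 * h2).
#' Simulate multi-environment phenotypes with target heritability
#'
#' Generates y = mu + G + E + GxE + error per trait. RILs carry a single
#' replicate per environment; the three parents are replicated checks.
#' Genotypic values are sums of QTL effects over the line's dosages;
#' interaction and residual variances are scaled so the Piepho-Moehring
#' heritability of the entry means matches `targetH2` in expectation
#' (`targetH2 = 1` gives noise-free data).
#'
#' @param genotypes line x variant dosage matrix (all lines incl. parents).
#' @param popmap a [PopulationMap-class].
#' @param params a [SimParams-class].
#' @param seed integer seed.
#' @return list with `phenos` (long data.frame: line, env, trait, value,
#'   rep) and `truth` (per-trait QTL table, true breeding values, variance
#'   components).
#' @export
simulatePhenotypes <- function(genotypes, popmap, params, seed) {
  set.seed(seed)
  lines <- rownames(genotypes)
  recs <- list(); qtlTab <- list(); bvTab <- list(); vcTab <- list()
  for (tr in seq_len(params@nTraits)) {
    trait <- sprintf("trait%d", tr)
    h2 <- params@targetH2[tr]
    J <- params@nEnvironments[tr]
    if (params@nQtlPerTrait == 0) {
      warning("trait ", trait, " has no QTL; all breeding values equal - ",
              "trait excluded")
      next
    }
    qtl <- sample.int(ncol(genotypes), params@nQtlPerTrait)
    eff <- rnorm(params@nQtlPerTrait)
    bv <- drop(genotypes[, qtl, drop = FALSE] %*% eff)
    bv <- bv - mean(bv)
    sigmaG2 <- var(bv)
    s <- if (h2 < 1) J * sigmaG2 * (1 - h2) / (2 * h2) else 0
    envEff <- rnorm(J, 0, sqrt(sigmaG2))
    reps <- ifelse(lines %in% parentLines(popmap),
                   params@parentRepsPerEnv, 1L)
    li <- rep(rep(lines, reps), times = J)
    ei <- rep(seq_len(J), each = sum(reps))
    gxe <- matrix(rnorm(length(lines) * J, 0, sqrt(s)), length(lines), J)
    val <- 50 + bv[match(li, lines)] + envEff[ei] +
      gxe[cbind(match(li, lines), ei)] + rnorm(length(li), 0, sqrt(s))
    recs[[trait]] <- data.frame(
      line = li, env = sprintf("%s_env%d", trait, ei), trait = trait,
      value = val,
      rep = stats::ave(seq_along(li), li, ei, FUN = seq_along),
      stringsAsFactors = FALSE)
    qtlTab[[trait]] <- data.frame(trait = trait,
                                  variant = colnames(genotypes)[qtl],
                                  effect = eff, stringsAsFactors = FALSE)
    bvTab[[trait]] <- bv
    vcTab[[trait]] <- c(sigmaG2 = sigmaG2, sigmaGxE2 = s, sigmaE2 = s)
  }
  bvs <- if (length(bvTab)) do.call(cbind, bvTab) else NULL
  if (!is.null(bvs)) rownames(bvs) <- lines
  bindRows <- function(x) if (length(x))
    do.call(rbind, c(x, make.row.names = FALSE)) else NULL
  list(phenos = bindRows(recs),
       truth = list(qtl = bindRows(qtlTab),
                    breedingValues = bvs, varComponents = vcTab))
}

#' Simulate a complete synthetic study
#'
#' Runs the full generator: parents, the three RIL populations,
#' block-design expression, variant-call observations, parental WGS and
#' array datasets, and phenotypes. All sub-seeds derive from
#' `params@seed`, so a fixed seed reproduces the bundle bit-exactly.
#'
#' @param params a [SimParams-class].
#' @return list with elements `params`, `sim` (map/parents/transcripts),
#'   `popmap`, `genotypes` (true line-level [GenotypeData-class]),
#'   `expr`, `exprTruth`, `obs` (variant-call observation list), `wgs`,
#'   `array`, `phenos`, `truth`.
#' @export
simulateStudy <- function(params = simParams()) {
  sim <- simulateParents(params)
  pops <- sprintf("pop%d", seq_along(params@popSizes))
  pairs <- list(c("ParentA", "ParentB"), c("ParentA", "ParentC"),
                c("ParentB", "ParentC"))
  dosL <- list()
  popLab <- character()
  for (k in seq_along(params@popSizes)) {
    pr <- pairs[[((k - 1) %% 3) + 1]]
    d <- simulateRilPopulation(sim$parents[pr[1], ], sim$parents[pr[2], ],
                               params@popSizes[k],
                               params@selfingGenerations, sim$map,
                               seed = params@seed + 100 + k,
                               prefix = sprintf("P%d_", k))
    dosL[[k]] <- d
    popLab <- c(popLab, setNames(rep(pops[k], nrow(d)), rownames(d)))
  }
  popmap <- PopulationMap(
    population = c(popLab,
                   setNames(rep("parent", 3), rownames(sim$parents))),
    parents = setNames(pairs[seq_along(params@popSizes)], pops))
  geno <- rbind(do.call(rbind, dosL), sim$parents)
  vt <- sim$map[, c("chrom", "pos", "ref", "alt", "transcript", "effect",
                    "distance")]
  rownames(vt) <- sim$map$variant
  genotypes <- GenotypeData(geno, vt, popmap, provenance = "true")

  ex <- simulateExpression(geno, sim, popmap, params,
                           seed = params@seed + 200)
  obs <- simulateVariantObservation(geno, ex$expr, sim, params,
                                    seed = params@seed + 300)
  wa <- deriveWgsAndArray(sim, geno, popmap, params,
                          seed = params@seed + 400)
  ph <- simulatePhenotypes(geno, popmap, params, seed = params@seed + 500)
  list(params = params, sim = sim, popmap = popmap, genotypes = genotypes,
       expr = ex$expr, exprTruth = ex$truth, obs = obs, wgs = wa$wgs,
       array = wa$array, phenos = ph$phenos, truth = ph$truth)
}
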