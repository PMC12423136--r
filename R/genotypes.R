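## Variant-call cleaning and filtering for homozygous RIL populations.
## The chain mirrors an RNA-Seq variant workflow: collapse duplicated
## observations by major allele, exclude variants with missing parental
## information, mask heterozygous and parent-inconsistent calls, impute
## per-population medians, optionally restrict to parental-WGS-confirmed
## positions with two-founder haplotype imputation, and filter by
## functional annotation or empirical quality criteria.

## Low median: for even counts the lower middle element, so a {0,2} tie
## resolves deterministically to 0.
.lowMedian <- function(v) {
  v <- v[!is.na(v)]
  if (!length(v)) return(NA_real_)
  sort(v)[ceiling(length(v) / 2)]
}

## MAF from allele counts (minor count / total), so exact-fraction
## boundaries like 1/20 compare exactly against literal thresholds
.maf <- function(mat) {
  alt <- colSums(mat, na.rm = TRUE)
  tot <- 2 * colSums(!is.na(mat))
  ifelse(tot == 0, NA_real_, pmin(alt, tot - alt) / tot)
}

.dropMonomorphic <- function(geno) {
  d <- dosages(geno)
  nClasses <- (colSums(d == 0, na.rm = TRUE) > 0) +
    (colSums(d == 1, na.rm = TRUE) > 0) +
    (colSums(d == 2, na.rm = TRUE) > 0)
  geno[, nClasses >= 2]
}

#' Consensus call from repeated observations of one line
#'
#' Repeated genotype observations of the same line at one variant (e.g.
#' the replicated parental checks) are united using the major allele;
#' ties and all-missing inputs give a missing call.
#'
#' @param calls numeric vector of dosage observations (may contain NA).
#' @return a single dosage value or NA.
#' @export
consensusDuplicates <- function(calls) {
  stopifnot(length(calls) >= 1)
  calls <- calls[!is.na(calls)]
  if (!length(calls)) return(NA_real_)
  tab <- table(calls)
  top <- tab[tab == max(tab)]
  if (length(top) > 1) return(NA_real_)
  as.numeric(names(top))
}

#' Collapse a sample-level call matrix to line level
#'
#' Applies [consensusDuplicates()] per line and variant. Lines with a
#' single sample are copied through.
#'
#' @param obs sample x variant dosage matrix.
#' @param sampleLine named character vector sample id -> line id.
#' @return line x variant dosage matrix.
#' @export
collapseDuplicates <- function(obs, sampleLine) {
  sampleLine <- sampleLine[rownames(obs)]
  lines <- unique(sampleLine)
  out <- matrix(NA_real_, length(lines), ncol(obs),
                dimnames = list(lines, colnames(obs)))
  counts <- table(sampleLine)
  singles <- names(counts)[counts == 1]
  if (length(singles)) {
    sidx <- match(singles, sampleLine)
    out[singles, ] <- obs[sidx, , drop = FALSE]
  }
  for (ln in names(counts)[counts > 1]) {
    sub <- obs[sampleLine == ln, , drop = FALSE]
    out[ln, ] <- apply(sub, 2, consensusDuplicates)
  }
  out
}

#' Clean RIL variant calls using homozygosity and parental information
#'
#' Removes variants with any missing parental call, masks heterozygous
#' calls (the lines are near-fully homozygous inbreds, so heterozygotes
#' are treated as call errors), and masks RIL calls inconsistent with the
#' alleles of the line's two parents. Parent calls are untouched
#' otherwise. With `raw = TRUE` all three steps are skipped, emulating an
#' uncleaned dataset for quality-filter benchmarking.
#'
#' @param geno a [GenotypeData-class] whose rows cover all lines of its
#'   population map (parents included).
#' @param raw skip cleaning (default FALSE).
#' @return A cleaned [GenotypeData-class].
#' @export
cleanCalls <- function(geno, raw = FALSE) {
  pm <- popMap(geno)
  d <- dosages(geno)
  need <- c(rilLines(pm), parentLines(pm))
  missing <- setdiff(need, rownames(d))
  if (length(missing))
    stop("lines in the population map absent from the matrix: ",
         paste(missing, collapse = ", "))
  if (raw) return(geno)

  d[d == 1] <- NA
  par <- d[parentLines(pm), , drop = FALSE]
  keep <- colSums(is.na(par)) == 0
  d <- d[, keep, drop = FALSE]
  par <- par[, keep, drop = FALSE]

  pops <- populationOf(pm)
  for (pop in populationNames(pm)) {
    rl <- intersect(names(pops)[pops == pop], rownames(d))
    pp <- parentsOf(pm, pop)
    pa <- par[pp[1], ]; pb <- par[pp[2], ]
    sub <- d[rl, , drop = FALSE]
    bad <- sweep(sub != 0, 2, pa == 0 & pb == 0, "&") |
           sweep(sub != 2, 2, pa == 2 & pb == 2, "&")
    sub[bad & !is.na(bad)] <- NA
    d[rl, ] <- sub
  }
  initialize(geno, dosage = d,
             variants = variantInfo(geno)[colnames(d), , drop = FALSE])
}

## column-wise low median of a dosage submatrix; count-based fast path
## for {0,2} data, element-wise fallback otherwise
.colLowMedian <- function(sub) {
  if (!any(sub == 1, na.rm = TRUE)) {
    n0 <- colSums(sub == 0, na.rm = TRUE)
    n2 <- colSums(sub == 2, na.rm = TRUE)
    ifelse(n0 + n2 == 0, NA_real_, ifelse(n2 > n0, 2, 0))
  } else {
    apply(sub, 2, .lowMedian)
  }
}

#' Median-impute missing calls per RIL population
#'
#' Each missing value is replaced by the per-population, per-variant low
#' median of the observed dosages ({0,2} ties resolve to 0). Populations
#' with no observed call at a variant fall back to the cross-population
#' median; variants with no observed call anywhere are dropped, as are
#' variants monomorphic after imputation.
#'
#' @param geno a cleaned [GenotypeData-class].
#' @return An imputed [GenotypeData-class] with no missing values.
#' @export
medianImpute <- function(geno) {
  pm <- popMap(geno)
  d <- dosages(geno)
  anyObs <- colSums(!is.na(d)) > 0
  if (!all(anyObs)) d <- d[, anyObs, drop = FALSE]
  globalMed <- .colLowMedian(d)

  groups <- split(rownames(d), populationOf(pm)[rownames(d)])
  for (g in groups) {
    sub <- d[g, , drop = FALSE]
    na <- is.na(sub)
    cols <- which(colSums(na) > 0)
    if (!length(cols)) next
    med <- .colLowMedian(sub[, cols, drop = FALSE])
    med[is.na(med)] <- globalMed[cols][is.na(med)]
    sub[, cols] <- ifelse(na[, cols, drop = FALSE],
                          matrix(med, nrow(sub), length(cols), byrow = TRUE),
                          sub[, cols, drop = FALSE])
    d[g, ] <- sub
  }
  out <- initialize(geno, dosage = d,
                    variants = variantInfo(geno)[colnames(d), , drop = FALSE])
  .dropMonomorphic(out)
}

#' Intersect RNA-Seq variants with parental WGS variants
#'
#' Retains exactly the variants present at the same chromosome, position
#' and alleles in both datasets; parental genotypes are replaced by the
#' (error-free) WGS calls. Sites where ref and alt are swapped between
#' the datasets are harmonized by flipping the RNA-Seq dosages; other
#' allele mismatches are excluded and counted.
#'
#' @param geno RNA-Seq [GenotypeData-class] (variant table must carry
#'   `chrom`, `pos`, `ref`, `alt`).
#' @param wgs list with `genotypes` (parent x variant dosage matrix) and
#'   `map` (data.frame with `variant`, `chrom`, `pos`, `ref`, `alt`).
#' @return A consensus-skeleton [GenotypeData-class] (provenance
#'   `"wgs_consensus"`), possibly still containing missing RIL calls.
#' @export
intersectWgs <- function(geno, wgs) {
  vt <- variantInfo(geno)
  keyR <- paste(vt$chrom, vt$pos)
  keyW <- paste(wgs$map$chrom, wgs$map$pos)
  hit <- match(keyR, keyW)
  shared <- which(!is.na(hit))
  if (!length(shared)) {
    warning("no shared variant positions between RNA-Seq and WGS sets")
    return(initialize(geno, dosage = dosages(geno)[, 0, drop = FALSE],
                      variants = vt[0, , drop = FALSE],
                      provenance = "wgs_consensus"))
  }
  w <- hit[shared]
  same <- vt$ref[shared] == wgs$map$ref[w] & vt$alt[shared] == wgs$map$alt[w]
  swap <- vt$ref[shared] == wgs$map$alt[w] & vt$alt[shared] == wgs$map$ref[w]
  bad <- !(same | swap)
  if (any(bad))
    message(sum(bad), " shared position(s) excluded for allele mismatch")
  shared <- shared[!bad]; w <- w[!bad]; swap <- swap[!bad]

  d <- dosages(geno)[, shared, drop = FALSE]
  if (any(swap)) d[, swap] <- 2 - d[, swap]
  vt2 <- vt[shared, , drop = FALSE]
  vt2$ref <- wgs$map$ref[w]; vt2$alt <- wgs$map$alt[w]
  parents <- intersect(rownames(wgs$genotypes), rownames(d))
  d[parents, ] <- wgs$genotypes[parents, wgs$map$variant[w], drop = FALSE]
  initialize(geno, dosage = d, variants = vt2,
             provenance = "wgs_consensus")
}

#' Impute missing RIL calls from the two founder haplotypes
#'
#' RIL genomes are mosaics of the two parental haplotypes, so a missing
#' call is assigned the allele of the parent whose haplotype is supported
#' by the nearest informative (parent-discriminating, observed) markers
#' on both sides. Sites where the parents share an allele take that
#' allele directly. Conflicting or absent flanks fall back to the
#' per-population median; chromosomes without any informative marker for
#' a line fall back entirely to the median (logged).
#'
#' @param geno consensus [GenotypeData-class] with parent rows present
#'   and complete (e.g. from [intersectWgs()]).
#' @return An imputed [GenotypeData-class] with no missing values,
#'   monomorphic variants removed.
#' @export
imputeFromParents <- function(geno) {
  pm <- popMap(geno)
  d <- dosages(geno)
  vt <- variantInfo(geno)
  ord <- order(vt$chrom, vt$pos)
  d <- d[, ord, drop = FALSE]
  vt <- vt[ord, , drop = FALSE]
  chroms <- vt$chrom
  pops <- populationOf(pm)

  ## per-population median fallback from observed calls
  fallback <- matrix(NA_real_, length(populationNames(pm)), ncol(d),
                     dimnames = list(populationNames(pm), colnames(d)))
  for (pop in populationNames(pm)) {
    rl <- intersect(names(pops)[pops == pop], rownames(d))
    fallback[pop, ] <- apply(d[rl, , drop = FALSE], 2, .lowMedian)
  }
  globalMed <- apply(d, 2, .lowMedian)
  fallback[is.na(fallback)] <- matrix(globalMed, nrow(fallback),
                                      ncol(d), byrow = TRUE)[is.na(fallback)]
  nFellBack <- 0L
  for (pop in populationNames(pm)) {
    pp <- parentsOf(pm, pop)
    pa <- d[pp[1], ]; pb <- d[pp[2], ]
    inf <- !is.na(pa) & !is.na(pb) & pa != pb
    rl <- intersect(names(pops)[pops == pop], rownames(d))
    for (ln in rl) {
      v <- d[ln, ]
      mis <- which(is.na(v))
      if (!length(mis)) next
      sameAllele <- !is.na(pa) & pa == pb
      fillSame <- mis[sameAllele[mis]]
      v[fillSame] <- pa[fillSame]
      mis <- setdiff(mis, fillSame)
      if (length(mis)) {
        obsInf <- which(inf & !is.na(v))
        origin <- integer(ncol(d))               # 0 = parent A, 1 = parent B
        origin[obsInf] <- as.integer(v[obsInf] == pb[obsInf])
        for (ch in unique(chroms[mis])) {
          onCh <- which(chroms == ch)
          oi <- intersect(obsInf, onCh)
          mCh <- intersect(mis, onCh)
          if (!length(oi)) {
            nFellBack <- nFellBack + length(mCh)
            v[mCh] <- fallback[pop, mCh]
            next
          }
          li <- findInterval(mCh, oi)            # last observed index <= site
          ri <- li + 1L                          # first observed index > site
          lo <- ifelse(li >= 1L, origin[oi[pmax(li, 1L)]], NA)
          hi <- ifelse(ri <= length(oi), origin[oi[pmin(ri, length(oi))]], NA)
          agree <- !is.na(lo) & !is.na(hi) & lo == hi
          pick <- ifelse(lo == 0, pa[mCh], pb[mCh])
          v[mCh] <- ifelse(agree, pick, fallback[pop, mCh])
          nFellBack <- nFellBack + sum(!agree)
        }
      }
      d[ln, ] <- v
    }
  }
  if (nFellBack)
    message(nFellBack, " missing call(s) filled by median fallback")
  out <- initialize(geno, dosage = d, variants = vt)
  .dropMonomorphic(out)
}

#' Filter variants by functional-annotation class
#'
#' `"Reg"` keeps upstream/downstream gene variants within 5 kb of the
#' coding region (regulatory UTR-proximal set); `"CDS"` keeps missense
#' variants only (synonymous variants are excluded). Monomorphic
#' variants are then removed.
#'
#' @param geno a [GenotypeData-class] whose variant table carries
#'   `effect` and `distance`.
#' @param class `"Reg"` or `"CDS"`.
#' @param maxDistance distance cutoff for the regulatory set (bp).
#' @return A filtered [GenotypeData-class].
#' @export
functionalFilter <- function(geno, class = c("Reg", "CDS"),
                             maxDistance = 5000) {
  class <- match.arg(class)
  vt <- variantInfo(geno)
  keep <- if (class == "Reg") {
    vt$effect %in% c("upstream_gene_variant", "downstream_gene_variant") &
      vt$distance <= maxDistance
  } else {
    vt$effect == "missense_variant"
  }
  .dropMonomorphic(geno[, keep])
}

#' Filter variants by one quality criterion at a relative strength
#'
#' The threshold is interpolated linearly between the criterion's
#' observed minimum and maximum. For DP, MAF and QUAL, variants with
#' values >= threshold(min -> max) are kept; for NS (samples without
#' data) the interpolation runs max -> min and variants <= threshold are
#' kept. Strength 0 keeps every variant; strength 1 keeps only the
#' extreme.
#'
#' @param geno a [GenotypeData-class] with the criterion column populated.
#' @param criterion one of `"DP"`, `"MAF"`, `"QUAL"`, `"NS"`.
#' @param strength relative filtering strength in \[0, 1\].
#' @return A filtered [GenotypeData-class]; attribute `"report"` records
#'   criterion, strength, threshold and before/after counts.
#' @export
qualityFilter <- function(geno, criterion = c("DP", "MAF", "QUAL", "NS"),
                          strength) {
  criterion <- match.arg(criterion)
  stopifnot(strength >= 0, strength <= 1)
  x <- variantInfo(geno)[[criterion]]
  stopifnot(!is.null(x), all(is.finite(x)))
  lo <- min(x); hi <- max(x)
  if (lo == hi)
    warning("all ", criterion, " values identical; strength has no effect")
  if (criterion == "NS") {
    thr <- hi - strength * (hi - lo)
    keep <- x <= thr
  } else {
    thr <- lo + strength * (hi - lo)
    keep <- x >= thr
  }
  out <- geno[, keep]
  attr(out, "report") <- list(criterion = criterion, strength = strength,
                              threshold = thr, nBefore = length(x),
                              nAfter = sum(keep))
  out
}

#' Inclusive intersection of filtered variant subsets
#'
#' Retains the variants present in every member subset (a marker must
#' pass all combined filters).
#'
#' @param geno the [GenotypeData-class] the subsets were drawn from.
#' @param sets list (>= 2) of variant-id character vectors.
#' @return A [GenotypeData-class] restricted to the intersection.
#' @export
combineFilters <- function(geno, sets) {
  stopifnot(length(sets) >= 2)
  ids <- Reduce(intersect, sets)
  ids <- intersect(colnames(dosages(geno)), ids)
  if (!length(ids)) warning("filter combination retains no variants")
  geno[, ids]
}

#' Standard variant quality filter
#'
#' Keeps variants with per-variant missing rate < 20% and minor allele
#' frequency > 0.05 (both strict), the conventional filter used as the
#' benchmark for the empirical quality-filter grid. Both statistics are
#' computed from the (pre-imputation) call matrix.
#'
#' @param geno a [GenotypeData-class].
#' @param maxMissing missing-rate bound (strict `<`).
#' @param minMaf minor-allele-frequency bound (strict `>`).
#' @return A filtered [GenotypeData-class].
#' @export
standardFilter <- function(geno, maxMissing = 0.20, minMaf = 0.05) {
  d <- dosages(geno)
  missRate <- colMeans(is.na(d))
  maf <- .maf(d)
  keep <- missRate < maxMissing & !is.na(maf) & maf > minMaf
  geno[, keep]
}

#' Nei's coefficient of genetic differentiation
#'
#' Per variant, \eqn{G_{st} = (H_T - H_S)/H_T} where \eqn{H_S} is the
#' mean within-population expected heterozygosity and \eqn{H_T} the
#' expected heterozygosity at the (unweighted) mean allele frequency
#' across populations. The multilocus summary is the ratio of
#' locus-averaged \eqn{H_T - H_S} to locus-averaged \eqn{H_T}.
#' Monomorphic sites (\eqn{H_T = 0}) are undefined and excluded from the
#' summary.
#'
#' @param geno a [GenotypeData-class] (only RIL populations enter; the
#'   parental checks are ignored).
#' @return list with `perVariant` (named numeric, NA where undefined)
#'   and `multilocus` (scalar).
#' @export
gst <- function(geno) {
  pm <- popMap(geno)
  d <- dosages(geno)
  pops <- populationNames(pm)
  popOf <- populationOf(pm)
  freqs <- vapply(pops, function(pop) {
    rl <- intersect(names(popOf)[popOf == pop], rownames(d))
    colMeans(d[rl, , drop = FALSE], na.rm = TRUE) / 2
  }, numeric(ncol(d)))
  if (is.null(dim(freqs))) freqs <- matrix(freqs, nrow = 1)
  typed <- rowSums(!is.na(freqs)) >= 2
  if (!any(typed)) stop("need >= 2 populations with typed lines")
  hs <- rowMeans(2 * freqs * (1 - freqs), na.rm = TRUE)
  pbar <- rowMeans(freqs, na.rm = TRUE)
  ht <- 2 * pbar * (1 - pbar)
  g <- ifelse(typed & ht > 0, (ht - hs) / ht, NA_real_)
  names(g) <- colnames(d)
  ok <- !is.na(g)
  list(perVariant = g,
       multilocus = sum(ht[ok] - hs[ok]) / sum(ht[ok]))
}
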