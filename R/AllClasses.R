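#' @import methods
#' @importFrom stats median cor sd var quantile rbinom rpois rnorm runif
#'   rnbinom optimize pchisq p.adjust t.test setNames complete.cases
#' @importFrom utils read.table write.table head
NULL

## Central containers. Dosage coding throughout: count of the alternate
## allele in {0, 1, 2}; NA = missing call. After cleaning only {0, 2, NA}
## remain (homozygous RILs).

#' Population structure of a connected RIL experiment
#'
#' Maps every line to its sub-population and every sub-population to its
#' ordered parent pair. The three parental inbreds are lines themselves
#' (they carry genotype and expression observations as replicated checks).
#'
#' @slot population named character vector: line id -> population label.
#'   Parent lines carry the label `"parent"`.
#' @slot parents named list: population label -> character(2) parent ids.
#' @slot parentLines character vector of parental line ids.
#' @export
setClass("PopulationMap",
  representation(population = "character", parents = "list",
                 parentLines = "character"))

setValidity("PopulationMap", function(object) {
  msg <- character()
  if (is.null(names(object@population)) || anyDuplicated(names(object@population)))
    msg <- c(msg, "line ids must be unique and named")
  if (!all(lengths(object@parents) == 2L))
    msg <- c(msg, "each population must have exactly 2 parents")
  bad <- !unlist(object@parents) %in% object@parentLines
  if (any(bad))
    msg <- c(msg, "population parents must be listed in parentLines")
  if (length(msg)) msg else TRUE
})

#' Construct a PopulationMap
#'
#' @param population named character vector mapping line id to population
#'   label; parents must carry the label `"parent"`.
#' @param parents named list mapping population label to a character(2)
#'   ordered parent pair.
#' @return A [PopulationMap-class] object.
#' @export
PopulationMap <- function(population, parents) {
  new("PopulationMap", population = population, parents = parents,
      parentLines = unique(unlist(parents, use.names = FALSE)))
}

#' @describeIn PopulationMap-class line ids of the RILs (non-parents)
#' @param object,x a `PopulationMap`
#' @export
setGeneric("rilLines", function(object) standardGeneric("rilLines"))
setMethod("rilLines", "PopulationMap", function(object)
  names(object@population)[object@population != "parent"])

#' @describeIn PopulationMap-class parental line ids
#' @export
setGeneric("parentLines", function(object) standardGeneric("parentLines"))
setMethod("parentLines", "PopulationMap", function(object) object@parentLines)

#' @describeIn PopulationMap-class population labels (excluding "parent")
#' @export
setGeneric("populationNames", function(object) standardGeneric("populationNames"))
setMethod("populationNames", "PopulationMap", function(object) names(object@parents))

#' @describeIn PopulationMap-class population label per line (named vector)
#' @export
setGeneric("populationOf", function(object) standardGeneric("populationOf"))
setMethod("populationOf", "PopulationMap", function(object) object@population)

#' @describeIn PopulationMap-class ordered parent pair of one population
#' @param pop population label
#' @export
setGeneric("parentsOf", function(object, pop) standardGeneric("parentsOf"))
setMethod("parentsOf", "PopulationMap", function(object, pop) object@parents[[pop]])

setMethod("show", "PopulationMap", function(object) {
  tab <- table(object@population[object@population != "parent"])
  cat("PopulationMap:", length(object@parents), "populations,",
      sum(tab), "RILs,", length(object@parentLines), "parents\n")
  for (p in names(object@parents))
    cat(sprintf("  %s: %d RILs (%s x %s)\n", p, tab[[p]],
                object@parents[[p]][1], object@parents[[p]][2]))
})

#' Genotype matrix with variant metadata
#'
#' Lines x variants allele-dosage matrix (0/1/2, NA missing) with a
#' per-variant metadata table and the population structure it belongs to.
#'
#' @slot dosage numeric matrix, rows = lines, columns = variants.
#' @slot variants data.frame keyed by variant id (rownames) with columns
#'   `chrom`, `pos` (1-based), `ref`, `alt`, `DP` (mean read depth),
#'   `QUAL`, `NS` (samples without data), `MAF`, and optionally
#'   `effect` (annotation class) and `distance` (bp to coding region).
#' @slot popmap the [PopulationMap-class].
#' @slot provenance character scalar: `"rnaseq"`, `"wgs_consensus"`,
#'   `"array"` or `"true"`.
#' @export
setClass("GenotypeData",
  representation(dosage = "matrix", variants = "data.frame",
                 popmap = "PopulationMap", provenance = "character"))

setValidity("GenotypeData", function(object) {
  msg <- character()
  if (anyDuplicated(rownames(object@dosage)))
    msg <- c(msg, "line ids must be unique")
  if (anyDuplicated(colnames(object@dosage)))
    msg <- c(msg, "variant ids must be unique")
  if (!identical(as.character(colnames(object@dosage)),
                 as.character(rownames(object@variants))))
    msg <- c(msg, "variant table rows must match dosage columns")
  v <- object@dosage[!is.na(object@dosage)]
  if (length(v) && !all(v %in% c(0, 1, 2)))
    msg <- c(msg, "dosages must be in {0,1,2} or NA")
  if (!is.null(object@variants$MAF)) {
    maf <- object@variants$MAF
    if (any(!is.na(maf) & (maf < 0 | maf > 0.5)))
      msg <- c(msg, "MAF must lie in [0, 0.5]")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeData object
#'
#' @param dosage lines x variants numeric matrix with dimnames.
#' @param variants per-variant metadata data.frame (rownames = variant ids).
#' @param popmap a [PopulationMap-class].
#' @param provenance one of `"rnaseq"`, `"wgs_consensus"`, `"array"`, `"true"`.
#' @return A [GenotypeData-class] object.
#' @export
GenotypeData <- function(dosage, variants = NULL, popmap, provenance = "rnaseq") {
  if (is.null(variants))
    variants <- data.frame(row.names = colnames(dosage))
  variants <- variants[colnames(dosage), , drop = FALSE]
  rownames(variants) <- colnames(dosage)
  new("GenotypeData", dosage = dosage, variants = variants,
      popmap = popmap, provenance = provenance)
}

#' @describeIn GenotypeData-class the lines x variants dosage matrix
#' @param object,x a `GenotypeData`
#' @export
setGeneric("dosages", function(object) standardGeneric("dosages"))
setMethod("dosages", "GenotypeData", function(object) object@dosage)

#' @describeIn GenotypeData-class per-variant metadata table
#' @export
setGeneric("variantInfo", function(object) standardGeneric("variantInfo"))
setMethod("variantInfo", "GenotypeData", function(object) object@variants)

#' @describeIn GenotypeData-class the population map
#' @export
setGeneric("popMap", function(object) standardGeneric("popMap"))
setMethod("popMap", "GenotypeData", function(object) object@popmap)

#' @describeIn GenotypeData-class dataset provenance tag
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))
setMethod("provenance", "GenotypeData", function(object) object@provenance)

#' @describeIn GenotypeData-class subset by line and/or variant
#' @param i,j line / variant index
#' @param drop ignored
#' @param ... ignored
#' @export
setMethod("[", "GenotypeData", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@dosage))
  if (missing(j)) j <- seq_len(ncol(x@dosage))
  dm <- x@dosage[i, j, drop = FALSE]
  v <- x@variants[j, , drop = FALSE]
  rownames(v) <- colnames(dm)        # zero-column frames drop row names
  initialize(x, dosage = dm, variants = v)
})

setMethod("show", "GenotypeData", function(object) {
  cat(sprintf("GenotypeData [%s]: %d lines x %d variants, %.1f%% missing\n",
              object@provenance, nrow(object@dosage), ncol(object@dosage),
              100 * mean(is.na(object@dosage))))
})

#' Transcript read-count matrix with experimental design
#'
#' Raw transcript x sample counts together with the incomplete-block
#' design (block id per sample) and the line each sample was taken from.
#' Parental checks appear as one sample per block, so a line can own
#' several samples.
#'
#' @slot counts integer-valued matrix, transcripts x samples.
#' @slot samples data.frame keyed by sample id with columns `line`, `block`.
#' @slot libSize named numeric, per-sample library size (defaults to the
#'   column sums).
#' @export
setClass("ExpressionCounts",
  representation(counts = "matrix", samples = "data.frame",
                 libSize = "numeric"))

setValidity("ExpressionCounts", function(object) {
  msg <- character()
  if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
  if (!identical(colnames(object@counts), rownames(object@samples)))
    msg <- c(msg, "sample table rows must match count columns")
  if (!identical(names(object@libSize), colnames(object@counts)))
    msg <- c(msg, "library sizes must be named by sample")
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionCounts object
#'
#' @param counts transcripts x samples matrix of raw counts (dimnames set).
#' @param samples data.frame with one row per sample (rownames = sample
#'   ids) and columns `line` and `block`.
#' @param libSize optional per-sample library sizes; defaults to column sums.
#' @return An [ExpressionCounts-class] object.
#' @export
ExpressionCounts <- function(counts, samples, libSize = NULL) {
  samples <- samples[colnames(counts), , drop = FALSE]
  if (is.null(libSize)) libSize <- colSums(counts)
  libSize <- libSize[colnames(counts)]
  new("ExpressionCounts", counts = counts, samples = samples,
      libSize = libSize)
}

#' @describeIn ExpressionCounts-class raw count matrix
#' @param object,x an `ExpressionCounts`
#' @export
setGeneric("countsMatrix", function(object) standardGeneric("countsMatrix"))
setMethod("countsMatrix", "ExpressionCounts", function(object) object@counts)

#' @describeIn ExpressionCounts-class sample annotation (line, block)
#' @export
setGeneric("sampleInfo", function(object) standardGeneric("sampleInfo"))
setMethod("sampleInfo", "ExpressionCounts", function(object) object@samples)

#' @describeIn ExpressionCounts-class per-sample library sizes
#' @export
setGeneric("libSizes", function(object) standardGeneric("libSizes"))
setMethod("libSizes", "ExpressionCounts", function(object) object@libSize)

#' @describeIn ExpressionCounts-class subset by transcript and/or sample
#' @param i,j transcript / sample index
#' @param drop ignored
#' @param ... ignored
#' @export
setMethod("[", "ExpressionCounts", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@counts))
  if (missing(j)) j <- seq_len(ncol(x@counts))
  cm <- x@counts[i, j, drop = FALSE]
  initialize(x, counts = cm, samples = x@samples[j, , drop = FALSE],
             libSize = x@libSize[j])
})

setMethod("show", "ExpressionCounts", function(object) {
  cat(sprintf("ExpressionCounts: %d transcripts x %d samples, %d blocks\n",
              nrow(object@counts), ncol(object@counts),
              length(unique(object@samples$block))))
})

#' Line x line relationship kernel
#'
#' Symmetric genomic (or transcriptomic) relationship matrix with a
#' provenance record of the source datasets and their weights.
#'
#' @slot K symmetric numeric matrix with line ids as dimnames.
#' @slot provenance list with elements `sources` (character) and
#'   `weights` (numeric).
#' @export
setClass("Kernel", representation(K = "matrix", provenance = "list"))

setValidity("Kernel", function(object) {
  msg <- character()
  K <- object@K
  if (!identical(rownames(K), colnames(K)))
    msg <- c(msg, "kernel dimnames must agree")
  if (max(abs(K - t(K))) > 1e-10)
    msg <- c(msg, "kernel must be symmetric within 1e-10")
  if (length(msg)) msg else TRUE
})

#' @describeIn Kernel-class the relationship matrix
#' @param object a `Kernel`
#' @export
setGeneric("relMatrix", function(object) standardGeneric("relMatrix"))
setMethod("relMatrix", "Kernel", function(object) object@K)

#' @describeIn Kernel-class line ids covered by the kernel
#' @export
setGeneric("kernelLines", function(object) standardGeneric("kernelLines"))
setMethod("kernelLines", "Kernel", function(object) rownames(object@K))

setMethod("show", "Kernel", function(object) {
  cat(sprintf("Kernel: %d lines [%s], mean diag %.4f\n", nrow(object@K),
              paste(object@provenance$sources, collapse = "+"),
              mean(diag(object@K))))
})

#' Fitted GBLUP model
#'
#' Result of a single-kernel REML fit of y = mu + u + e with
#' u ~ N(0, sigma2u * K) and e ~ N(0, sigma2e * I).
#'
#' @slot mu estimated general mean.
#' @slot sigma2u,sigma2e estimated variance components.
#' @slot u named vector of genotypic-effect BLUPs for the training lines.
#' @slot logLik restricted log-likelihood at the optimum.
#' @slot y named training phenotype vector (kept for prediction).
#' @export
setClass("GBLUPFit",
  representation(mu = "numeric", sigma2u = "numeric", sigma2e = "numeric",
                 u = "numeric", logLik = "numeric", y = "numeric"))

setValidity("GBLUPFit", function(object) {
  if (object@sigma2u < 0 || object@sigma2e < 0)
    "variance components must be non-negative" else TRUE
})

setMethod("show", "GBLUPFit", function(object) {
  cat(sprintf(
    "GBLUPFit: n=%d, mu=%.4g, sigma2u=%.4g, sigma2e=%.4g, h2=%.3f\n",
    length(object@u), object@mu, object@sigma2u, object@sigma2e,
    object@sigma2u / (object@sigma2u + object@sigma2e)))
})

#' Validation-scheme description
#'
#' @slot kind one of `"fivefold"`, `"cross"`, `"intra"`, `"inter"`.
#' @slot nFolds folds for `"fivefold"`.
#' @slot reps repetitions.
#' @slot tsSize,vsSize training-/validation-set sizes for subset schemes.
#' @slot tsPop,vsPop population labels for intra/inter schemes ("" = pooled).
#' @slot seed integer seed.
#' @export
setClass("ValidationScheme",
  representation(kind = "character", nFolds = "numeric", reps = "numeric",
                 tsSize = "numeric", vsSize = "numeric", tsPop = "character",
                 vsPop = "character", seed = "numeric"))

#' Construct a validation scheme
#'
#' Defaults follow the study design: 5-fold cross-validation with 50
#' repetitions; fixed-size subset validation with 200 repetitions,
#' training size 50, validation size 65 (inter/cross) or 15 (intra).
#'
#' @param kind `"fivefold"`, `"cross"`, `"intra"` or `"inter"`.
#' @param nFolds folds (fivefold only).
#' @param reps repetitions.
#' @param tsSize,vsSize subset sizes (ignored for fivefold).
#' @param tsPop,vsPop population labels (intra: same; inter: different).
#' @param seed integer seed.
#' @return A [ValidationScheme-class] object.
#' @export
validationScheme <- function(kind = c("fivefold", "cross", "intra", "inter"),
                             nFolds = 5, reps = NULL, tsSize = 50,
                             vsSize = NULL, tsPop = "", vsPop = "",
                             seed = 1) {
  kind <- match.arg(kind)
  if (is.null(reps)) reps <- if (kind == "fivefold") 50 else 200
  if (is.null(vsSize)) vsSize <- if (kind == "intra") 15 else 65
  new("ValidationScheme", kind = kind, nFolds = nFolds, reps = reps,
      tsSize = tsSize, vsSize = vsSize, tsPop = tsPop, vsPop = vsPop,
      seed = seed)
}

#' Evaluation result
#'
#' Per-repetition prediction abilities for one validation scheme, stored
#' at full resolution (never only aggregates).
#'
#' @slot scheme the scheme kind.
#' @slot results long data.frame with columns `dataset`, `trait`, `rep`,
#'   `fold` (or subset index), `ability`, plus scheme-specific columns
#'   (e.g. `tsSize`, `weight`, `depth`).
#' @slot params list of scheme parameters.
#' @export
setClass("EvalResult",
  representation(scheme = "character", results = "data.frame",
                 params = "list"))

#' @describeIn EvalResult-class per-repetition results table
#' @param object an `EvalResult`
#' @export
setGeneric("abilities", function(object) standardGeneric("abilities"))
setMethod("abilities", "EvalResult", function(object) object@results)

#' @describeIn EvalResult-class mean ability per dataset and trait
#' @export
setGeneric("abilitySummary", function(object) standardGeneric("abilitySummary"))
setMethod("abilitySummary", "EvalResult", function(object) {
  res <- object@results
  extras <- intersect(c("tsSize", "weight", "depth"), names(res))
  keys <- c("dataset", "trait", extras)
  agg <- aggregate(res["ability"], res[keys],
                   function(a) mean(a, na.rm = TRUE))
  sds <- aggregate(res["ability"], res[keys],
                   function(a) sd(a, na.rm = TRUE))
  agg$sd <- sds$ability
  names(agg)[names(agg) == "ability"] <- "mean"
  agg
})

setMethod("show", "EvalResult", function(object) {
  cat(sprintf("EvalResult [%s]: %d records\n", object@scheme,
              nrow(object@results)))
  print(head(abilitySummary(object), 10))
})

#' @importFrom stats aggregate
NULL
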