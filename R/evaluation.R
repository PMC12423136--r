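## Validation designs: fivefold cross-validation (50 repetitions),
## fixed-size cross/intra/inter-population subset validation (200
## repetitions), the training-set-size sweep (20..170 step 15), the
## empirical quality-filter grid (21 strengths x 4 criteria + 11
## combinations), the two-kernel weight sweep, and the sequencing-depth
## sweep. Fold/subset draws depend only on (seed, repetition, line set),
## so different datasets are compared on identical partitions (paired).

.asKernelList <- function(kernels) {
  if (is(kernels, "Kernel")) kernels <- list(dataset = kernels)
  if (is.null(names(kernels)))
    names(kernels) <- paste0("dataset", seq_along(kernels))
  kernels
}

.asEmMatrix <- function(entryMeans) {
  if (is.matrix(entryMeans)) return(entryMeans)
  stopifnot(!is.null(names(entryMeans)))
  matrix(entryMeans, ncol = 1,
         dimnames = list(names(entryMeans), "trait1"))
}

## prediction ability of one train/test split for one kernel and trait
.splitAbility <- function(kernel, em, trait, train, test) {
  y <- em[train, trait]
  y <- y[!is.na(y)]
  obs <- em[test, trait]
  obs <- obs[!is.na(obs)]
  if (length(y) < 5 || length(obs) < 3) return(NA_real_)
  fit <- remlFit(y, kernel)
  pred <- gblupPredict(fit, kernel, names(obs))
  suppressWarnings(predictionAbility(pred, obs))
}

#' Fivefold cross-validation of prediction ability
#'
#' Per repetition, the lines are randomly partitioned into `nFolds`
#' folds; each fold is predicted from the remaining ones; prediction
#' ability is recorded per fold. Fold assignments depend only on the
#' seed, repetition and line set, so several datasets evaluated with the
#' same arguments are compared on identical partitions.
#'
#' @param kernels a [Kernel-class] or named list of kernels (datasets).
#' @param entryMeans lines x traits matrix (or named vector for one
#'   trait) of adjusted entry means.
#' @param reps repetitions (default 50).
#' @param nFolds folds (default 5).
#' @param seed integer seed.
#' @return An [EvalResult-class] (scheme `"fivefold"`).
#' @export
cvFivefold <- function(kernels, entryMeans, reps = 50, nFolds = 5,
                       seed = 1) {
  kernels <- .asKernelList(kernels)
  em <- .asEmMatrix(entryMeans)
  lines <- sort(Reduce(intersect, c(lapply(kernels, kernelLines),
                                    list(rownames(em)[rowSums(!is.na(em)) > 0]))))
  n <- length(lines)
  if (n < 10) stop("need at least 10 lines for cross-validation")
  if (floor(n / nFolds) < 3) stop("folds would contain fewer than 3 lines")
  res <- list()
  for (r in seq_len(reps)) {
    set.seed(seed + r)
    foldOf <- setNames(rep_len(seq_len(nFolds), n)[sample.int(n)], lines)
    for (ds in names(kernels)) for (tr in colnames(em)) {
      for (f in seq_len(nFolds)) {
        test <- lines[foldOf == f]
        train <- lines[foldOf != f]
        res[[length(res) + 1]] <- data.frame(
          dataset = ds, trait = tr, rep = r, fold = f,
          ability = .splitAbility(kernels[[ds]], em, tr, train, test))
      }
    }
  }
  new("EvalResult", scheme = "fivefold",
      results = do.call(rbind, c(res, make.row.names = FALSE)),
      params = list(reps = reps, nFolds = nFolds, seed = seed, n = n))
}

#' Fixed-size subset validation (cross-, intra- or inter-population)
#'
#' Per repetition, draws disjoint training and validation sets of fixed
#' size: `"cross"` samples both from the pooled lines, `"intra"` from
#' one population, `"inter"` the training set from one population and
#' the validation set from another. Infeasible sizes are rejected with
#' the limiting population named; an inter-population validation size
#' exceeding the population is capped (without replacement, reported).
#'
#' @param kernels a [Kernel-class] or named list.
#' @param entryMeans lines x traits matrix of adjusted entry means.
#' @param popmap a [PopulationMap-class].
#' @param scheme a [ValidationScheme-class] of kind `"cross"`, `"intra"`
#'   or `"inter"`.
#' @return An [EvalResult-class].
#' @export
subsetValidation <- function(kernels, entryMeans, popmap, scheme) {
  stopifnot(is(scheme, "ValidationScheme"),
            scheme@kind %in% c("cross", "intra", "inter"))
  kernels <- .asKernelList(kernels)
  em <- .asEmMatrix(entryMeans)
  avail <- sort(Reduce(intersect, c(lapply(kernels, kernelLines),
                                    list(rownames(em)[rowSums(!is.na(em)) > 0]))))
  popOf <- populationOf(popmap)[avail]
  ts <- scheme@tsSize; vs <- scheme@vsSize
  kind <- scheme@kind
  if (kind == "cross") {
    pool <- avail
    if (ts + vs > length(pool))
      stop("pooled line count (", length(pool),
           ") too small for ts+vs = ", ts + vs)
  } else if (kind == "intra") {
    pop <- if (nzchar(scheme@tsPop)) scheme@tsPop else
      names(which.max(table(popOf[popOf != "parent"])))
    pool <- avail[popOf == pop]
    if (ts + vs > length(pool))
      stop("population ", pop, " has ", length(pool),
           " lines; infeasible for ts+vs = ", ts + vs)
  } else {
    stopifnot(nzchar(scheme@tsPop), nzchar(scheme@vsPop),
              scheme@tsPop != scheme@vsPop)
    tsPool <- avail[popOf == scheme@tsPop]
    vsPool <- avail[popOf == scheme@vsPop]
    if (ts > length(tsPool))
      stop("population ", scheme@tsPop, " has only ", length(tsPool),
           " lines for the training set")
    if (vs > length(vsPool)) {
      message("validation size capped at ", length(vsPool),
              " (population ", scheme@vsPop, ")")
      vs <- length(vsPool)
    }
  }
  res <- list()
  draws <- vector("list", scheme@reps)
  for (r in seq_len(scheme@reps)) {
    set.seed(scheme@seed + r)
    if (kind == "inter") {
      train <- sample(tsPool, ts)
      test <- sample(vsPool, vs)
    } else {
      s <- sample(pool, ts + vs)
      train <- s[seq_len(ts)]
      test <- s[ts + seq_len(vs)]
    }
    draws[[r]] <- list(train = train, test = test)
    for (ds in names(kernels)) for (tr in colnames(em)) {
      res[[length(res) + 1]] <- data.frame(
        dataset = ds, trait = tr, rep = r,
        tsSize = ts, vsSize = vs,
        tsPop = scheme@tsPop, vsPop = scheme@vsPop,
        ability = .splitAbility(kernels[[ds]], em, tr, train, test))
    }
  }
  new("EvalResult", scheme = kind,
      results = do.call(rbind, c(res, make.row.names = FALSE)),
      params = list(scheme = scheme, draws = draws))
}

#' Training-set-size sweep (cross-population)
#'
#' One cross-population subset validation per training-set size
#' (default 20 to 170 in steps of 15, validation size 65).
#'
#' @param kernels a [Kernel-class] or named list.
#' @param entryMeans lines x traits matrix.
#' @param popmap a [PopulationMap-class].
#' @param sizes training-set sizes.
#' @param vsSize validation-set size.
#' @param reps repetitions per size.
#' @param seed integer seed.
#' @return An [EvalResult-class] (scheme `"ts_sweep"`); results carry
#'   their `tsSize`.
#' @export
tsSizeSweep <- function(kernels, entryMeans, popmap,
                        sizes = seq(20, 170, by = 15), vsSize = 65,
                        reps = 200, seed = 1) {
  res <- lapply(sizes, function(s) {
    sv <- subsetValidation(kernels, entryMeans, popmap,
                           validationScheme("cross", reps = reps,
                                            tsSize = s, vsSize = vsSize,
                                            seed = seed))
    abilities(sv)
  })
  new("EvalResult", scheme = "ts_sweep",
      results = do.call(rbind, c(res, make.row.names = FALSE)),
      params = list(sizes = sizes, vsSize = vsSize, reps = reps,
                    seed = seed))
}

#' Empirical quality-filter grid search
#'
#' Evaluates each quality criterion (DP, MAF, QUAL, NS) at `steps`
#' relative strengths (default 21: 0 to 100% in 5% steps) by median
#' imputation, kernel construction and paired fivefold cross-validation;
#' picks the best strength per criterion (argmax mean ability, ties to
#' the smaller strength); then enumerates all multi-criterion
#' combinations of the four single-best subsets (6 pairs + 4 triples +
#' 1 quadruple = 11) via inclusive intersection and evaluates them the
#' same way. The objective is the mean ability across all traits.
#'
#' @param geno a cleaned, un-imputed [GenotypeData-class] with DP, MAF,
#'   QUAL, NS populated.
#' @param entryMeans lines x traits matrix of adjusted entry means.
#' @param criteria criteria to scan.
#' @param steps strength-grid size (21 = 5% steps).
#' @param reps,nFolds,seed cross-validation settings (paired across
#'   subsets).
#' @param minVariants subsets below this size are skipped (logged).
#' @return list with `singles` (criterion, strength, threshold,
#'   nVariants, ability), `best` (per-criterion best rows), `combos`
#'   (combo, nVariants, ability), `bestCombo` (name), and
#'   `bestComboGeno` (imputed [GenotypeData-class] of the winner).
#' @export
filterGridSearch <- function(geno, entryMeans,
                             criteria = c("DP", "MAF", "QUAL", "NS"),
                             steps = 21, reps = 3, nFolds = 5, seed = 1,
                             minVariants = 10) {
  strengths <- seq(0, 1, length.out = steps)
  em <- .asEmMatrix(entryMeans)
  evalGeno <- function(g) {
    if (ncol(dosages(g)) < minVariants) return(NA_real_)
    imp <- medianImpute(g)
    if (ncol(dosages(imp)) < 2) return(NA_real_)
    K <- vanradenKernel(dosages(imp), source = "subset")
    cv <- cvFivefold(K, em, reps = reps, nFolds = nFolds, seed = seed)
    mean(abilities(cv)$ability, na.rm = TRUE)
  }
  singles <- list()
  subsetsIds <- list()
  for (cr in criteria) {
    for (s in strengths) {
      sub <- qualityFilter(geno, cr, s)
      rep_ <- attr(sub, "report")
      ab <- evalGeno(sub)
      if (is.na(ab) && ncol(dosages(sub)) < minVariants)
        message("criterion ", cr, " strength ", s,
                ": subset below ", minVariants, " variants; skipped")
      singles[[length(singles) + 1]] <- data.frame(
        criterion = cr, strength = s, threshold = rep_$threshold,
        nVariants = rep_$nAfter, ability = ab)
      subsetsIds[[paste(cr, s)]] <- colnames(dosages(sub))
    }
  }
  singles <- do.call(rbind, c(singles, make.row.names = FALSE))
  best <- do.call(rbind, lapply(criteria, function(cr) {
    d <- singles[singles$criterion == cr & !is.na(singles$ability), ]
    d[order(-d$ability, d$strength), ][1, ]
  }))
  bestSets <- lapply(seq_len(nrow(best)), function(i)
    subsetsIds[[paste(best$criterion[i], best$strength[i])]])
  names(bestSets) <- best$criterion

  combos <- list()
  comboGenos <- list()
  for (k in 2:length(bestSets)) {
    for (sel in utils::combn(names(bestSets), k, simplify = FALSE)) {
      nm <- paste(sel, collapse = "+")
      g <- suppressWarnings(combineFilters(geno, bestSets[sel]))
      comboGenos[[nm]] <- g
      combos[[length(combos) + 1]] <- data.frame(
        combo = nm, nVariants = ncol(dosages(g)), ability = evalGeno(g))
    }
  }
  combos <- do.call(rbind, c(combos, make.row.names = FALSE))
  ok <- !is.na(combos$ability)
  bestCombo <- if (any(ok))
    combos$combo[ok][which.max(combos$ability[ok])] else NA_character_
  list(singles = singles, best = best, combos = combos,
       bestCombo = bestCombo,
       bestComboGeno = if (!is.na(bestCombo))
         medianImpute(comboGenos[[bestCombo]]) else NULL,
       grid = strengths)
}

#' Two-kernel weight sweep
#'
#' Evaluates the weighted combination (1-w, w) for w = 0, `step`, ...,
#' 1 by fivefold cross-validation (paired folds across weights). The
#' endpoints reproduce the single-dataset results exactly.
#'
#' @param kernelA,kernelB [Kernel-class] objects on identical lines.
#' @param entryMeans lines x traits matrix.
#' @param step weight step (default 0.10, 11 evaluations).
#' @param reps,nFolds,seed cross-validation settings.
#' @return An [EvalResult-class] (scheme `"weight_sweep"`); results
#'   carry the weight of `kernelB`.
#' @export
weightSweep <- function(kernelA, kernelB, entryMeans, step = 0.10,
                        reps = 50, nFolds = 5, seed = 1) {
  ws <- seq(0, 1, by = step)
  res <- lapply(ws, function(w) {
    K <- combineKernels(list(kernelA, kernelB), c(1 - w, w))
    cv <- cvFivefold(K, entryMeans, reps = reps, nFolds = nFolds,
                     seed = seed)
    cbind(abilities(cv), weight = w)
  })
  new("EvalResult", scheme = "weight_sweep",
      results = do.call(rbind, c(res, make.row.names = FALSE)),
      params = list(step = step, reps = reps, seed = seed))
}

#' Sequencing-depth sweep
#'
#' For each depth fraction, thins the read counts, re-derives the
#' variant-call observations, rebuilds the SNP datasets (total and
#' standard-filtered) and the expression datasets (total,
#' cpm-threshold-filtered, DEG), and records the cross-validated
#' prediction ability and feature count of each. The same sample set
#' (those above `minReads` at every depth) is enforced across all
#' datasets and depths. Datasets with fewer than 10 features at a depth
#' are recorded as missing.
#'
#' @param bundle a [simulateStudy()] bundle.
#' @param fractions depth fractions in (0, 1]; include 1 for the
#'   full-depth reference.
#' @param entryMeans lines x traits matrix (defaults to adjusted entry
#'   means computed from the bundle's phenotypes).
#' @param reps,nFolds,seed cross-validation settings.
#' @param minReads minimum total reads per sample.
#' @return An [EvalResult-class] (scheme `"depth_sweep"`); results carry
#'   `depth` and `nFeatures`.
#' @export
depthSweep <- function(bundle, fractions, entryMeans = NULL, reps = 3,
                       nFolds = 5, seed = 1, minReads = 1000) {
  stopifnot(all(fractions > 0), all(fractions <= 1))
  fractions <- sort(fractions)
  if (is.null(entryMeans))
    entryMeans <- entryMeansMatrix(adjustedEntryMeans(bundle$phenos))
  em <- .asEmMatrix(entryMeans)
  geno <- dosages(bundle$genotypes)

  thinned <- lapply(seq_along(fractions), function(i)
    thinReads(bundle$expr, fractions[i], seed = seed + i,
              minReads = minReads))
  common <- Reduce(intersect, lapply(thinned, function(e)
    colnames(countsMatrix(e))))
  res <- list()
  for (i in seq_along(fractions)) {
    f <- fractions[i]
    ex <- thinned[[i]][, common]
    obs <- simulateVariantObservation(geno, ex, bundle$sim,
                                      bundle$params, seed = seed + 999)
    lineMat <- collapseDuplicates(obs$obs, obs$sampleLine)
    gd <- GenotypeData(lineMat, obs$variants, bundle$popmap, "rnaseq")
    cleaned <- cleanCalls(gd)
    feats <- list()
    snpTotal <- medianImpute(cleaned)
    feats$SNP_total <- dosages(snpTotal)
    snpStd <- standardFilter(cleaned)
    feats$SNP_std <- if (ncol(dosages(snpStd)))
      dosages(medianImpute(snpStd)) else NULL

    det <- detectionFilter(ex)
    feats$GE_total <- expressionFeatures(det, "cpm")
    scan <- cpmThresholdScan(det)
    keepF <- rowMeans(countsPerMillion(det)) > scan$threshold
    feats$GE_filtered <- feats$GE_total[, keepF, drop = FALSE]
    sig <- scan$deg$transcript[scan$deg$significant]
    feats$GE_deg <- feats$GE_total[, colnames(feats$GE_total) %in% sig,
                                   drop = FALSE]
    for (ds in names(feats)) {
      X <- feats[[ds]]
      nf <- if (is.null(X)) 0L else ncol(X)
      ab <- NA_real_
      if (nf >= 10) {
        K <- suppressMessages(vanradenKernel(X, source = ds))
        cv <- cvFivefold(K, em, reps = reps, nFolds = nFolds, seed = seed)
        ab <- mean(abilities(cv)$ability, na.rm = TRUE)
      }
      res[[length(res) + 1]] <- data.frame(
        dataset = ds, trait = "all", rep = NA_integer_, depth = f,
        nFeatures = nf, ability = ab)
    }
  }
  new("EvalResult", scheme = "depth_sweep",
      results = do.call(rbind, c(res, make.row.names = FALSE)),
      params = list(fractions = fractions, reps = reps, seed = seed,
                    minReads = minReads, nSamples = length(common)))
}

#' Paired t-test on matched ability vectors
#'
#' Utility mirroring pairwise dataset comparisons on identical
#' fold/subset draws.
#'
#' @param x,y ability vectors of equal length (matched repetitions).
#' @return An object of class `htest`.
#' @export
pairedAbilityTest <- function(x, y) {
  stopifnot(length(x) == length(y))
  t.test(x, y, paired = TRUE)
}
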