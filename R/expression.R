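## Expression processing: detection filtering, counts-per-million,
## between-sample TMM normalization, per-transcript block adjustment
## (EMM), negative-binomial likelihood-ratio DEG calling with dispersion
## anchored on the replicated parental checks, and the cpm-threshold scan
## that maximizes the number of significant DEG.

#' Keep transcripts detected in a minimum share of samples
#'
#' A transcript is retained when its share of samples with nonzero read
#' counts is at least `fraction` (default 2%, boundary inclusive).
#'
#' @param expr an [ExpressionCounts-class].
#' @param fraction minimum nonzero-sample share in (0, 1].
#' @return A filtered [ExpressionCounts-class].
#' @export
detectionFilter <- function(expr, fraction = 0.02) {
  stopifnot(fraction > 0, fraction <= 1)
  cm <- countsMatrix(expr)
  expr[rowMeans(cm > 0) >= fraction, ]
}

#' Counts per million
#'
#' value = count / library size x 1e6, so each column sums to 1e6 when
#' library sizes are the column sums. Samples with zero library size are
#' excluded with a warning.
#'
#' @param expr an [ExpressionCounts-class] (or a plain counts matrix).
#' @param libSize optional library sizes (defaults to the object's).
#' @return A transcripts x samples cpm matrix.
#' @export
countsPerMillion <- function(expr, libSize = NULL) {
  cm <- if (is(expr, "ExpressionCounts")) countsMatrix(expr) else expr
  if (is.null(libSize))
    libSize <- if (is(expr, "ExpressionCounts")) libSizes(expr) else
      colSums(cm)
  zero <- libSize == 0
  if (any(zero)) {
    warning(sum(zero), " sample(s) with zero library size excluded")
    cm <- cm[, !zero, drop = FALSE]
    libSize <- libSize[!zero]
  }
  sweep(cm, 2, libSize, "/") * 1e6
}

#' Trimmed-mean-of-M-values normalization factors
#'
#' Between-sample scaling factors: for each sample, the weighted mean of
#' log2 expression ratios (M-values) against a reference sample after
#' two-sided trimming on M (default 30%) and on average log intensity A
#' (default 5%), with inverse asymptotic-variance weights; factors are
#' rescaled to geometric mean 1. The reference is the sample whose 75th
#' percentile of cpm is closest to the mean across samples.
#'
#' @param expr an [ExpressionCounts-class].
#' @param trimM,trimA two-sided trim fractions for M and A.
#' @param ref optional reference sample id.
#' @return Named numeric vector of normalization factors.
#' @export
tmmFactors <- function(expr, trimM = 0.30, trimA = 0.05, ref = NULL) {
  cm <- countsMatrix(expr)
  lib <- libSizes(expr)
  if (ncol(cm) < 2) stop("TMM needs at least 2 samples")
  cpm <- sweep(cm, 2, lib, "/") * 1e6
  if (is.null(ref)) {
    uq <- apply(cpm, 2, quantile, probs = 0.75)
    ref <- colnames(cm)[which.min(abs(uq - mean(uq)))]
  }
  yr <- cm[, ref]; nr <- lib[ref]
  f <- vapply(colnames(cm), function(s) {
    yk <- cm[, s]; nk <- lib[s]
    use <- yk > 0 & yr > 0
    if (!any(use)) {
      warning("sample ", s, " shares no expressed transcripts with the ",
              "reference; factor set to 1")
      return(1)
    }
    m <- log2((yk[use] / nk) / (yr[use] / nr))
    a <- 0.5 * log2((yk[use] / nk) * (yr[use] / nr))
    w <- 1 / ((nk - yk[use]) / (nk * yk[use]) +
                (nr - yr[use]) / (nr * yr[use]))
    n <- length(m)
    loM <- floor(n * trimM) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trimA) + 1; hiA <- n + 1 - loA
    keep <- rank(m) >= loM & rank(m) <= hiM &
            rank(a) >= loA & rank(a) <= hiA
    if (!any(keep)) return(1)
    val <- 2^(sum(w[keep] * m[keep]) / sum(w[keep]))
    if (!is.finite(val)) 1 else val
  }, 0)
  f / exp(mean(log(f)))
}

## REML profile for y = X beta + Z b + e with one random factor,
## V = sigma_e^2 (I + lambda Z Z'). Returns GLS coefficient estimates at
## the profiled-REML optimum over log(lambda) in [-12, 12].
.remlOneRandom <- function(y, X, Z, tol = 1e-8) {
  n <- length(y); p <- ncol(X)
  XtX <- crossprod(X); XtZ <- crossprod(X, Z); ZtZ <- crossprod(Z)
  Xty <- crossprod(X, y); Zty <- crossprod(Z, y); yty <- sum(y^2)
  crit <- function(loglam) {
    lam <- exp(loglam)
    A <- diag(1 / lam, ncol(Z)) + ZtZ
    Ai <- solve(A)
    Cxx <- XtX - XtZ %*% Ai %*% t(XtZ)
    cxy <- Xty - XtZ %*% Ai %*% Zty
    q <- yty - drop(crossprod(Zty, Ai %*% Zty))
    beta <- solve(Cxx, cxy)
    rss <- q - drop(crossprod(cxy, beta))
    s2 <- max(rss, 1e-300) / (n - p)
    ldV <- determinant(diag(ncol(Z)) + lam * ZtZ, logarithm = TRUE)$modulus
    ldC <- determinant(Cxx, logarithm = TRUE)$modulus
    0.5 * ((n - p) * log(s2) + ldV + ldC)
  }
  opt <- optimize(crit, c(-12, 12), tol = tol)
  lam <- exp(opt$minimum)
  A <- diag(1 / lam, ncol(Z)) + ZtZ
  Ai <- solve(A)
  Cxx <- XtX - XtZ %*% Ai %*% t(XtZ)
  cxy <- Xty - XtZ %*% Ai %*% Zty
  beta <- drop(solve(Cxx, cxy))
  list(beta = beta, lambda = lam, vcovScaled = solve(Cxx))
}

#' Block-adjusted genotype means of expression (EMM normalization)
#'
#' Per transcript, fits y = mu + genotype (fixed) + block (random) +
#' error by profiled REML on the block-to-residual variance ratio and
#' returns generalized-least-squares genotype means. With fewer than two
#' blocks the raw genotype means are returned with a warning.
#'
#' @param expr an [ExpressionCounts-class].
#' @param response `"cpm"` (default) or `"counts"`.
#' @return A transcripts x genotypes matrix of adjusted means.
#' @export
emmAdjust <- function(expr, response = c("cpm", "counts")) {
  response <- match.arg(response)
  y <- if (response == "cpm") countsPerMillion(expr) else countsMatrix(expr)
  si <- sampleInfo(expr)
  gf <- factor(si$line)
  bf <- factor(si$block)
  if (nlevels(bf) < 2) {
    warning("fewer than 2 blocks; returning raw genotype means")
    out <- t(apply(y, 1, function(v) tapply(v, gf, mean)))
    return(out)
  }
  X <- stats::model.matrix(~ 0 + gf)
  Z <- stats::model.matrix(~ 0 + bf)
  out <- matrix(NA_real_, nrow(y), nlevels(gf),
                dimnames = list(rownames(y), levels(gf)))
  for (t in seq_len(nrow(y)))
    out[t, ] <- .remlOneRandom(y[t, ], X, Z)$beta
  out
}

## Per-transcript method-of-moments NB dispersion from replicated
## groups, with library-size factors c_s:
## E[var(y/c)] = m * mean(1/c) + phi * m^2.
.momDispersion <- function(cm, groups, cfac, floor = 1e-4) {
  numT <- rep(0, nrow(cm)); denT <- rep(0, nrow(cm))
  for (g in groups) {
    if (length(g) < 2) next
    adj <- sweep(cm[, g, drop = FALSE], 2, cfac[g], "/")
    m <- rowMeans(adj)
    v <- apply(adj, 1, var)
    w <- length(g) - 1
    numT <- numT + w * (v - m * mean(1 / cfac[g]))
    denT <- denT + w * m^2
  }
  pmax(ifelse(denT > 0, numT / denT, floor), floor)
}

## Common NB dispersion by Cox-Reid adjusted profile likelihood over the
## replicated groups, pooled across transcripts. The adjustment
## (-0.5 * log Fisher information of the group mean) corrects the
## downward bias of plain profile ML when every group's mean is
## estimated from few replicates.
.crCommonDispersion <- function(cm, groups, cfac, floor = 1e-4) {
  apl <- function(logphi) {
    phi <- rep(exp(logphi), nrow(cm))
    tot <- 0
    for (g in groups) {
      ym <- cm[, g, drop = FALSE]
      m <- .nbGroupMean(ym, cfac[g], phi)
      ll <- .nbLogLik(ym, outer(m, cfac[g]), phi)
      ## I(m) = sum_s c_s / (m * (1 + phi * m * c_s))
      info <- rowSums(sweep(1 / (1 + outer(exp(logphi) * m, cfac[g])),
                            2, cfac[g], "*")) / pmax(m, 1e-8)
      ok <- m > 0
      tot <- tot + sum(ll[ok] - 0.5 * log(info[ok]))
    }
    -tot
  }
  max(exp(optimize(apl, c(log(floor), 2))$minimum), floor)
}

## NB mean MLE for one group of samples with known dispersion phi and
## library factors c: iterate the stationarity condition
## m = sum(y) / sum((y + 1/phi) * phi * c / (1 + phi * m * c)).
## Vectorized over transcripts (rows of ym).
.nbGroupMean <- function(ym, cfac, phi, iter = 8) {
  if (ncol(ym) == 1) return(ym[, 1] / cfac[1])
  m <- rowSums(ym) / sum(cfac)
  k <- 1 / phi
  for (i in seq_len(iter)) {
    denom <- rowSums(sweep((ym + k) * phi, 2, cfac, "*") /
                       (1 + outer(phi * m, cfac)))
    m <- ifelse(denom > 0, rowSums(ym) / denom, 0)
  }
  m
}

.nbLogLik <- function(ym, mu, phi) {
  sz <- matrix(1 / phi, nrow(ym), ncol(ym))
  mu <- pmax(mu, 1e-12)
  rowSums(stats::dnbinom(ym, size = sz, mu = mu, log = TRUE))
}

#' Differential-expression test by negative-binomial likelihood ratio
#'
#' Per transcript, compares a full model with one mean per genotype
#' against a reduced model with a single grand mean, both negative
#' binomial with a fixed dispersion estimated from the replicated
#' parental checks: one common value by Cox-Reid adjusted profile
#' likelihood (default) or per-transcript method-of-moments
#' (`"tagwise"`), either floored at 1e-4.
#' Library-size differences enter as multiplicative offsets. The
#' statistic 2*deltaLogLik is referred to chi-square with
#' (number of genotypes - 1) degrees of freedom; p-values are BH
#' adjusted and flagged at `alpha`. All-zero transcripts get p = 1.
#'
#' @param expr an [ExpressionCounts-class] with replicated parental
#'   checks among the samples.
#' @param parents line ids of the replicated checks; defaults to all
#'   lines observed in more than one sample.
#' @param dispersion `"common"` (one pooled value, default) or
#'   `"tagwise"` (per transcript).
#' @param alpha adjusted-p significance threshold.
#' @return data.frame with columns `transcript`, `stat`, `df`, `p`,
#'   `fdr`, `significant`, plus the dispersion used as attribute
#'   `"dispersion"`.
#' @export
degLrt <- function(expr, parents = NULL,
                   dispersion = c("common", "tagwise"), alpha = 0.05) {
  dispersion <- match.arg(dispersion)
  cm <- countsMatrix(expr)
  si <- sampleInfo(expr)
  lib <- libSizes(expr)
  cfac <- lib / mean(lib)
  gf <- factor(si$line)
  if (is.null(parents)) {
    tab <- table(si$line)
    parents <- names(tab)[tab > 1]
  }
  if (!length(parents)) stop("no replicated lines to estimate dispersion")
  groups <- lapply(parents, function(p) which(si$line == p))
  phi <- if (dispersion == "common")
    rep(.crCommonDispersion(cm, groups, cfac), nrow(cm)) else
    .momDispersion(cm, groups, cfac)

  ## full model: one mean per genotype
  llFull <- rep(0, nrow(cm))
  for (lev in levels(gf)) {
    idx <- which(gf == lev)
    ym <- cm[, idx, drop = FALSE]
    m <- .nbGroupMean(ym, cfac[idx], phi)
    llFull <- llFull + .nbLogLik(ym, outer(m, cfac[idx]), phi)
  }
  mAll <- .nbGroupMean(cm, cfac, phi)
  llRed <- .nbLogLik(cm, outer(mAll, cfac), phi)

  stat <- pmax(2 * (llFull - llRed), 0)
  df <- nlevels(gf) - 1
  p <- pchisq(stat, df, lower.tail = FALSE)
  p[rowSums(cm) == 0] <- 1
  fdr <- p.adjust(p, "BH")
  out <- data.frame(transcript = rownames(cm), stat = stat, df = df,
                    p = p, fdr = fdr, significant = fdr < alpha,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "dispersion") <- phi
  out
}

#' Scan cpm thresholds for the one maximizing significant DEG
#'
#' Evaluates a grid of mean-cpm thresholds (by default 40 evenly spaced
#' quantiles of the per-transcript mean cpm between 0 and its 90th
#' percentile, plus threshold 0). For each threshold, transcripts with
#' mean cpm above it are retained, the BH adjustment is recomputed
#' within the retained set, and significant DEG are counted. Returns the
#' threshold with the maximum count (ties resolve to the smallest
#' threshold). The likelihood-ratio statistics do not depend on the
#' filtering, so they are computed once.
#'
#' @param expr an [ExpressionCounts-class].
#' @param grid optional numeric vector of thresholds.
#' @param gridSize,maxQuantile grid construction parameters.
#' @param alpha adjusted-p significance threshold.
#' @param ... passed to [degLrt()].
#' @return list with `threshold` (chosen), `table` (data.frame:
#'   threshold, nTranscripts, nDeg) and `deg` (the full [degLrt()]
#'   result).
#' @export
cpmThresholdScan <- function(expr, grid = NULL, gridSize = 40,
                             maxQuantile = 0.9, alpha = 0.05, ...) {
  meanCpm <- rowMeans(countsPerMillion(expr))
  if (is.null(grid)) {
    grid <- unique(c(0, unname(
      quantile(meanCpm, seq(0, maxQuantile, length.out = gridSize)))))
  }
  if (!length(grid)) stop("empty threshold grid")
  grid <- sort(grid)
  deg <- degLrt(expr, alpha = alpha, ...)
  nDeg <- integer(length(grid)); nKept <- integer(length(grid))
  for (i in seq_along(grid)) {
    keep <- meanCpm > grid[i]
    nKept[i] <- sum(keep)
    nDeg[i] <- sum(p.adjust(deg$p[keep], "BH") < alpha)
  }
  best <- grid[which.max(nDeg)]             # which.max takes the first tie
  list(threshold = best,
       table = data.frame(threshold = grid, nTranscripts = nKept,
                          nDeg = nDeg),
       deg = deg)
}

#' Sum transcript counts within genes
#'
#' @param expr an [ExpressionCounts-class].
#' @param geneOf named character vector transcript id -> gene id.
#' @return An [ExpressionCounts-class] at gene level (counts conserved).
#' @export
aggregateToGenes <- function(expr, geneOf) {
  cm <- countsMatrix(expr)
  g <- geneOf[rownames(cm)]
  agg <- rowsum(cm, group = g)
  ExpressionCounts(agg, sampleInfo(expr), libSizes(expr))
}

#' Line-level expression features for genomic prediction
#'
#' Collapses the sample x transcript expression to one value per line:
#' un-normalized cpm averaged over a line's samples (default), TMM-scaled
#' cpm, log2(cpm + 1), or EMM block-adjusted genotype means.
#'
#' @param expr an [ExpressionCounts-class].
#' @param method `"cpm"`, `"tmm"`, `"log2cpm"` or `"emm"`.
#' @return A lines x transcripts feature matrix.
#' @export
expressionFeatures <- function(expr,
                               method = c("cpm", "tmm", "log2cpm", "emm")) {
  method <- match.arg(method)
  if (method == "emm") return(t(emmAdjust(expr, response = "cpm")))
  v <- switch(method,
    cpm = countsPerMillion(expr),
    tmm = countsPerMillion(expr,
            libSize = libSizes(expr) * tmmFactors(expr)),
    log2cpm = log2(countsPerMillion(expr) + 1))
  lines <- sampleInfo(expr)$line
  sums <- rowsum(t(v), group = lines)
  sums / as.vector(table(lines)[rownames(sums)])
}
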