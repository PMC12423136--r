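## Kernel-based genomic prediction: z-scored feature matrices, the
## additive relationship kernel G = W* W*' / m, weighted multi-kernel
## averaging, single-kernel REML by spectral decomposition, GBLUP
## prediction for unphenotyped lines, and prediction ability.

#' Z-score a feature matrix column-wise
#'
#' Each feature (column) is centered and scaled to unit variance using
#' the population denominator n, so that for the resulting matrix
#' \eqn{\sum_i w_{ij}^2 = n} per column. Zero-variance columns are
#' dropped (count reported via message).
#'
#' @param features lines x features numeric matrix.
#' @return The z-scored matrix (possibly fewer columns).
#' @export
zscoreFeatures <- function(features) {
  stopifnot(nrow(features) >= 2)
  m <- colMeans(features)
  ctr <- sweep(features, 2, m)
  s <- sqrt(colMeans(ctr^2))
  keep <- s > 0
  if (!any(keep)) stop("all feature columns are constant")
  if (any(!keep))
    message(sum(!keep), " zero-variance feature column(s) dropped")
  sweep(ctr[, keep, drop = FALSE], 2, s[keep], "/")
}

#' Additive relationship kernel from z-scored features
#'
#' \eqn{G = W^* W^{*T} / m} with \eqn{W^*} the z-score matrix and m the
#' feature count. With population-denominator z-scores the mean of the
#' diagonal equals 1 exactly.
#'
#' @param features lines x features matrix (dosages or expression).
#' @param zscore standardize first (default TRUE; set FALSE if
#'   `features` is already z-scored).
#' @param source provenance label.
#' @return A [Kernel-class].
#' @export
vanradenKernel <- function(features, zscore = TRUE, source = "features") {
  W <- if (zscore) zscoreFeatures(features) else features
  m <- ncol(W)
  if (m == 0) stop("no features left after dropping constant columns")
  K <- tcrossprod(W) / m
  K <- (K + t(K)) / 2
  new("Kernel", K = K,
      provenance = list(sources = source, weights = 1))
}

#' Weighted average of relationship kernels
#'
#' Elementwise weighted average of kernels on the identical line set and
#' ordering. Default weights are equal.
#'
#' @param kernels list of [Kernel-class] objects.
#' @param weights non-negative weights summing to 1 (default equal).
#' @return The combined [Kernel-class] with provenance recording sources
#'   and weights.
#' @export
combineKernels <- function(kernels, weights = NULL) {
  stopifnot(length(kernels) >= 1)
  ids <- kernelLines(kernels[[1]])
  kernels <- lapply(kernels, function(k) {
    if (identical(kernelLines(k), ids)) return(k)
    d <- c(setdiff(ids, kernelLines(k)), setdiff(kernelLines(k), ids))
    if (length(d))
      stop("kernels cover different line sets: ",
           paste(head(d, 5), collapse = ", "),
           if (length(d) > 5) " ..." else "")
    initialize(k, K = relMatrix(k)[ids, ids])   # same set, align order
  })
  if (is.null(weights)) weights <- rep(1 / length(kernels), length(kernels))
  stopifnot(length(weights) == length(kernels), all(weights >= 0))
  stopifnot(abs(sum(weights) - 1) < 1e-8)
  K <- Reduce(`+`, Map(function(k, w) w * relMatrix(k), kernels, weights))
  new("Kernel", K = K,
      provenance = list(
        sources = unlist(lapply(kernels, function(k) k@provenance$sources)),
        weights = weights))
}

#' REML fit of the single-kernel GBLUP model
#'
#' Maximizes the restricted likelihood of y = mu + u + e with
#' u ~ N(0, sigma2u K) and e ~ N(0, sigma2e I) over the variance ratio
#' lambda = sigma2e/sigma2u, using one spectral decomposition of the
#' kernel and a bounded scalar search on log(lambda) in \[-12, 12\]
#' (tolerance 1e-8). Exact for one random effect. A kernel with
#' eigenvalues below -1e-8 is ridge-stabilized (1e-8 on the diagonal,
#' reported via message).
#'
#' @param y named phenotype vector (adjusted entry means) for the
#'   training lines; names must appear in the kernel.
#' @param kernel a [Kernel-class] covering at least the training lines.
#' @return A [GBLUPFit-class].
#' @export
remlFit <- function(y, kernel) {
  if (any(!is.finite(y))) stop("non-finite phenotypes")
  n <- length(y)
  if (n < 5) stop("need at least 5 training lines")
  stopifnot(!is.null(names(y)), all(names(y) %in% kernelLines(kernel)))
  K <- relMatrix(kernel)[names(y), names(y)]
  eig <- eigen(K, symmetric = TRUE)
  d <- eig$values
  if (min(d) < -1e-8) {
    message("kernel not PSD; ridge-stabilizing with 1e-8")
    d <- d - min(d) + 1e-8
  }
  d <- pmax(d, 0)
  U <- eig$vectors
  yt <- drop(crossprod(U, y))
  xt <- drop(crossprod(U, rep(1, n)))

  remlNegLL <- function(loglam) {
    w <- d + exp(loglam)
    sxx <- sum(xt^2 / w)
    mu <- sum(xt * yt / w) / sxx
    r <- yt - mu * xt
    s2u <- sum(r^2 / w) / (n - 1)
    0.5 * ((n - 1) * log(s2u) + sum(log(w)) + log(sxx))
  }
  opt <- optimize(remlNegLL, c(-12, 12), tol = 1e-8)
  lam <- exp(opt$minimum)
  w <- d + lam
  sxx <- sum(xt^2 / w)
  mu <- sum(xt * yt / w) / sxx
  r <- yt - mu * xt
  s2u <- sum(r^2 / w) / (n - 1)
  u <- drop(U %*% (d / w * r))
  names(u) <- names(y)
  new("GBLUPFit", mu = mu, sigma2u = s2u, sigma2e = lam * s2u, u = u,
      logLik = -(opt$objective + 0.5 * (n - 1) * (1 + log(2 * pi))),
      y = y)
}

#' Predict genotypic values of unphenotyped lines
#'
#' Conditional-mean GBLUP:
#' \eqn{\hat u_{test} = G_{test,train} (G_{train,train} + \lambda I)^{-1}
#' (y_{train} - \hat\mu)} with \eqn{\lambda = \hat\sigma^2_e /
#' \hat\sigma^2_u}; the predicted value is \eqn{\hat\mu + \hat u_{test}}.
#' Equivalent to solving the joint Henderson mixed-model equations with
#' the test phenotypes masked. When \eqn{\hat\sigma^2_u = 0} all
#' predictions equal \eqn{\hat\mu} (with a warning).
#'
#' @param fit a [GBLUPFit-class] obtained on the training lines.
#' @param kernel the full [Kernel-class] covering training and test lines.
#' @param testLines character ids (or integer indices into the kernel)
#'   of the lines to predict.
#' @return Named numeric vector of predicted genotypic values.
#' @export
gblupPredict <- function(fit, kernel, testLines) {
  K <- relMatrix(kernel)
  if (is.numeric(testLines)) testLines <- rownames(K)[testLines]
  train <- names(fit@y)
  stopifnot(all(testLines %in% rownames(K)), all(train %in% rownames(K)))
  if (fit@sigma2u <= 0) {
    warning("sigma2u is zero; predictions equal the general mean")
    return(setNames(rep(fit@mu, length(testLines)), testLines))
  }
  lam <- fit@sigma2e / fit@sigma2u
  Ktt <- K[train, train]
  alpha <- solve(Ktt + diag(lam, length(train)), fit@y - fit@mu)
  pred <- drop(K[testLines, train, drop = FALSE] %*% alpha) + fit@mu
  setNames(pred, testLines)
}

#' Prediction ability
#'
#' Pearson correlation between predicted genotypic values and observed
#' adjusted entry means. Undefined (NA, with a warning) when either
#' vector has zero variance.
#'
#' @param predicted,observed numeric vectors (>= 3 pairs; matched by
#'   names when both are named).
#' @return Scalar correlation or NA.
#' @export
predictionAbility <- function(predicted, observed) {
  if (!is.null(names(predicted)) && !is.null(names(observed)))
    observed <- observed[names(predicted)]
  ok <- is.finite(predicted) & is.finite(observed)
  predicted <- predicted[ok]; observed <- observed[ok]
  if (length(predicted) < 3) stop("need at least 3 pairs")
  if (sd(predicted) == 0 || sd(observed) == 0) {
    warning("zero variance; prediction ability undefined")
    return(NA_real_)
  }
  cor(predicted, observed)
}
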