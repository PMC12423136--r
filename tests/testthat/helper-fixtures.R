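# Shared fixtures, built in code. A small three-population study bundle
# is memoised so several test files can reuse it.

.fixtures <- new.env()

tinyParams <- function(...) {
  args <- list(popSizes = c(20, 20, 20), nVariants = 600,
               nTranscripts = 300, nTraits = 2, nEnvironments = c(4, 5),
               targetH2 = c(0.85, 0.8), meanLibrarySize = 1e5,
               arraySize = 150, seed = 42)
  do.call(simParams, utils::modifyList(args, list(...)))
}

tinyStudy <- function() {
  if (is.null(.fixtures$tiny)) .fixtures$tiny <- simulateStudy(tinyParams())
  .fixtures$tiny
}

# single biparental population map over generic line names
onePopMap <- function(rils = sprintf("L%02d", 1:6),
                      parents = c("PA", "PB")) {
  PopulationMap(
    population = c(setNames(rep("pop1", length(rils)), rils),
                   setNames(rep("parent", 2), parents)),
    parents = list(pop1 = parents))
}

# hand-built GenotypeData: rows = c(rils, parents); dosage given row-wise
handGeno <- function(dosage, popmap, variants = NULL,
                     provenance = "rnaseq") {
  GenotypeData(dosage, variants, popmap, provenance)
}

# Henderson mixed-model-equation GBLUP oracle: builds the joint MME over
# all lines with the test phenotypes masked and solves it directly.
#   [ 1'1   1'Z          ] [mu]   [1'y]
#   [ Z'1   Z'Z + lam*Ginv] [u ] = [Z'y]
hendersonGblup <- function(K, y, trainIds, testIds, sigma2u, sigma2e,
                           ridge = 0) {
  all <- rownames(K)
  Ginv <- solve(K + diag(ridge, nrow(K)))
  Z <- matrix(0, length(trainIds), length(all),
              dimnames = list(trainIds, all))
  Z[cbind(trainIds, trainIds)] <- 1
  lam <- sigma2e / sigma2u
  one <- rep(1, length(trainIds))
  C <- rbind(cbind(sum(one), t(one) %*% Z),
             cbind(t(Z) %*% one, crossprod(Z) + lam * Ginv))
  rhs <- c(sum(y[trainIds]), drop(t(Z) %*% y[trainIds]))
  sol <- solve(C, rhs)
  mu <- unname(sol[1])
  u <- sol[-1]
  names(u) <- all
  list(mu = mu, u = u, pred = mu + u[testIds])
}

# restricted log-likelihood of y = 1*mu + u + e at given variance
# components (independent evaluation, no profiling)
remlLogLik <- function(y, K, s2u, s2e) {
  n <- length(y)
  V <- s2u * K + s2e * diag(n)
  Vi <- solve(V)
  X <- matrix(1, n, 1)
  XtViX <- drop(t(X) %*% Vi %*% X)
  P <- Vi - Vi %*% X %*% t(X) %*% Vi / XtViX
  as.numeric(-0.5 * (determinant(V, logarithm = TRUE)$modulus +
                       log(XtViX) + drop(t(y) %*% P %*% y) +
                       (n - 1) * log(2 * pi)))
}
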