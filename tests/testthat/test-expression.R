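# Expression processing: detection filter, cpm, TMM (with a brute-force
# oracle and an edgeR cross-check), EMM block adjustment (GLS oracle),
# the NB likelihood-ratio DEG test, and the cpm-threshold scan.

.exprFixture <- function(counts, lines = NULL, blocks = NULL) {
  if (is.null(lines)) lines <- colnames(counts)
  if (is.null(blocks)) blocks <- rep(1L, ncol(counts))
  ExpressionCounts(counts, data.frame(line = lines, block = blocks,
                                      row.names = colnames(counts)))
}

test_that("detection filter keeps transcripts at the 2% boundary inclusively", {
  cm <- matrix(0L, 3, 100, dimnames = list(paste0("t", 1:3),
                                           paste0("s", 1:100)))
  cm[1, 1:2] <- 5L      # 2% of samples: kept
  cm[2, 1] <- 5L        # 1%: dropped
  out <- detectionFilter(.exprFixture(cm + 0), fraction = 0.02)
  expect_identical(rownames(countsMatrix(out)), "t1")
})

test_that("cpm is the library-scaled count with unit column sums", {
  cm <- matrix(c(4, 1999996, 10, 999990), 2,
               dimnames = list(c("t1", "t2"), c("a", "b")))
  v <- countsPerMillion(.exprFixture(cm))
  expect_equal(v["t1", "a"], 2)
  expect_equal(unname(colSums(v)), c(1e6, 1e6))
  # scale invariance: doubling all counts of a sample leaves cpm unchanged
  cm2 <- cm; cm2[, "a"] <- 2 * cm2[, "a"]
  expect_equal(countsPerMillion(.exprFixture(cm2))[, "a"], v[, "a"])
})

test_that("detection filter and cpm commute with sample reordering", {
  b <- tinyStudy()
  ex <- b$expr
  perm <- rev(seq_len(ncol(countsMatrix(ex))))
  exP <- ex[, perm]
  expect_equal(countsPerMillion(exP),
               countsPerMillion(ex)[, perm])
  expect_identical(rownames(countsMatrix(detectionFilter(exP))),
                   rownames(countsMatrix(detectionFilter(ex))))
})

test_that("TMM factors are 1 for identical or proportional samples", {
  cm <- matrix(rpois(600, 50) + 1, 100)
  colnames(cm) <- paste0("s", 1:6); rownames(cm) <- paste0("t", 1:100)
  same <- cm[, c(1, 1, 1)]
  colnames(same) <- paste0("s", 1:3)
  expect_equal(unname(tmmFactors(.exprFixture(same))), rep(1, 3))
  prop <- cbind(a = cm[, 1], b = 2L * cm[, 1])
  expect_equal(unname(tmmFactors(.exprFixture(prop))), c(1, 1),
               tolerance = 1e-12)
})

test_that("TMM matches a brute-force trimmed weighted mean oracle", {
  # oracle: direct enumeration of M/A values, rank trimming, weighting
  tmmOracle <- function(cm, lib, refIdx, trimM = 0.3, trimA = 0.05) {
    f <- vapply(seq_len(ncol(cm)), function(k) {
      use <- cm[, k] > 0 & cm[, refIdx] > 0
      yk <- cm[use, k]; yr <- cm[use, refIdx]
      nk <- lib[k]; nr <- lib[refIdx]
      M <- log2((yk / nk) / (yr / nr))
      A <- 0.5 * log2((yk / nk) * (yr / nr))
      w <- 1 / ((nk - yk) / (nk * yk) + (nr - yr) / (nr * yr))
      n <- length(M)
      lo <- floor(n * trimM) + 1; hi <- n + 1 - lo
      loA <- floor(n * trimA) + 1; hiA <- n + 1 - loA
      keep <- rank(M) >= lo & rank(M) <= hi &
              rank(A) >= loA & rank(A) <= hiA
      2^(sum(w[keep] * M[keep]) / sum(w[keep]))
    }, 0)
    f / exp(mean(log(f)))
  }
  set.seed(5)
  cm <- matrix(rnbinom(6 * 40, size = 5, mu = 60) + 1, 40)
  dimnames(cm) <- list(paste0("t", 1:40), paste0("s", 1:6))
  ex <- .exprFixture(cm)
  got <- tmmFactors(ex, ref = "s1")
  expect_equal(unname(got),
               tmmOracle(cm, colSums(cm), 1), tolerance = 1e-10)
  expect_lt(abs(exp(mean(log(got))) - 1), 1e-12)
})

test_that("TMM agrees with the edgeR reference implementation", {
  skip_if_not_installed("edgeR")
  set.seed(9)
  cm <- matrix(rnbinom(8 * 500, size = 2, mu = 40) + 1, 500)
  dimnames(cm) <- list(paste0("t", 1:500), paste0("s", 1:8))
  ours <- tmmFactors(.exprFixture(cm), ref = "s3")
  theirs <- edgeR::calcNormFactors(cm, method = "TMM", refColumn = 3)
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-6)
})

test_that("EMM adjustment equals raw genotype means on balanced designs", {
  set.seed(2)
  lines <- rep(c("A", "B", "C"), each = 3)
  blocks <- rep(1:3, times = 3)
  cm <- matrix(rpois(5 * 9, 100), 5,
               dimnames = list(paste0("t", 1:5), paste0("s", 1:9)))
  ex <- .exprFixture(cm, lines, blocks)
  adj <- emmAdjust(ex, response = "counts")
  raw <- t(apply(cm, 1, function(v) tapply(v, lines, mean)))
  expect_equal(adj, raw[, colnames(adj)], tolerance = 1e-6)
})

test_that("EMM removes strong block effects that bias raw genotype means", {
  set.seed(3)
  # unbalanced design: genotype means are confounded with blocks
  lines <- rep(c("A", "B", "C", "D"), times = 5)
  blocks <- rep(1:5, each = 4)
  gEff <- c(A = 0, B = 4, C = -3, D = 1)
  bEff <- rnorm(5, 0, 25)
  y <- 100 + gEff[lines] + bEff[blocks] + rnorm(20, 0, 1)
  # delete cells so blocks no longer cancel in raw means
  keep <- -c(2, 7, 12, 17, 20)
  cm <- matrix(y[keep], 1, dimnames = list("t1", paste0("s", seq_along(y[keep]))))
  ex <- .exprFixture(cm, lines[keep], blocks[keep])
  adj <- emmAdjust(ex, response = "counts")["t1", ]
  raw <- tapply(cm[1, ], lines[keep], mean)
  errAdj <- max(abs((adj - adj["A"]) - gEff[names(adj)]))
  errRaw <- max(abs((raw - raw["A"]) - gEff[names(raw)]))
  expect_lt(errAdj, errRaw)
  expect_lt(errAdj, 2)
})

test_that("EMM reproduces a direct GLS solve at the profiled variance ratio", {
  set.seed(4)
  lines <- c("A", "A", "B", "C", "A", "B", "B", "C", "C")
  blocks <- c(1, 1, 1, 2, 2, 2, 3, 3, 3)
  y <- rnorm(9, 50, 5)
  cm <- matrix(y, 1, dimnames = list("t1", paste0("s", 1:9)))
  ex <- .exprFixture(cm, lines, blocks)
  got <- emmAdjust(ex, response = "counts")
  fit <- rilgp:::.remlOneRandom(y, stats::model.matrix(~ 0 + factor(lines)),
                                stats::model.matrix(~ 0 + factor(blocks)))
  # independent GLS at the same ratio: full-V solve
  V <- diag(9) + fit$lambda * tcrossprod(stats::model.matrix(~ 0 + factor(blocks)))
  X <- stats::model.matrix(~ 0 + factor(lines))
  beta <- solve(t(X) %*% solve(V, X), t(X) %*% solve(V, y))
  expect_equal(unname(got["t1", ]), unname(drop(beta)), tolerance = 1e-6)
  # and against lme4's fit of the same model
  df <- data.frame(y = y, g = factor(lines), b = factor(blocks))
  lfit <- suppressMessages(lme4::lmer(y ~ 0 + g + (1 | b), data = df))
  expect_equal(unname(got["t1", ]), unname(lme4::fixef(lfit)),
               tolerance = 1e-4)
})

test_that("EMM falls back to raw means with fewer than two blocks", {
  cm <- matrix(rpois(6, 30), 2,
               dimnames = list(c("t1", "t2"), c("a", "b", "c")))
  expect_warning(out <- emmAdjust(.exprFixture(cm, c("A", "A", "B")),
                                  response = "counts"),
                 "blocks")
  expect_equal(unname(out["t1", "A"]), mean(cm[1, 1:2]))
})

.degFixture <- function(seed, fold = 1, nNull = 150, nDe = 20,
                        dispersion = 0.05) {
  set.seed(seed)
  lines <- c(sprintf("L%02d", 1:40), rep(c("PA", "PB", "PC"), each = 4))
  nS <- length(lines)
  nT <- nNull + nDe
  mu <- matrix(60, nT, nS)
  grp <- as.integer(factor(lines)) %% 2
  if (nDe > 0)
    mu[nNull + seq_len(nDe), ] <- 60 * matrix(rep(fold^grp, each = nDe),
                                              nDe, nS)
  cm <- matrix(rnbinom(length(mu), size = 1 / dispersion, mu = mu), nT,
               dimnames = list(sprintf("t%03d", seq_len(nT)),
                               sprintf("s%03d", seq_len(nS))))
  .exprFixture(cm, lines)
}

test_that("DEG statistics are non-negative, all-zero transcripts get p = 1, and strong shifts are detected", {
  ex <- .degFixture(1, fold = 10, nNull = 100, nDe = 10)
  cm <- countsMatrix(ex)
  cm <- rbind(cm, tzero = 0)
  ex2 <- .exprFixture(cm, sampleInfo(ex)$line)
  deg <- degLrt(ex2)
  expect_true(all(deg$stat >= 0))
  expect_equal(deg$p[deg$transcript == "tzero"], 1)
  expect_false(deg$significant[deg$transcript == "tzero"])
  expect_true(all(deg$fdr >= deg$p))
  # 10-fold genotype-specific shift: overwhelming evidence
  expect_true(all(deg$fdr[101:110] < 1e-4))
  # p monotone decreasing in the statistic at fixed df
  ord <- order(deg$stat)
  expect_true(all(diff(deg$p[ord]) <= 1e-12))
})

test_that("cpm-threshold scan returns a grid member maximizing DEG count", {
  ex <- .degFixture(7, fold = 1.8)
  scan <- cpmThresholdScan(ex)
  expect_true(scan$threshold %in% scan$table$threshold)
  at0 <- scan$table$nDeg[scan$table$threshold == 0]
  expect_gte(max(scan$table$nDeg), at0)
  expect_equal(max(scan$table$nDeg),
               scan$table$nDeg[scan$table$threshold == scan$threshold])
  expect_error(cpmThresholdScan(ex, grid = numeric()), "grid")
})

test_that("the scan picks a positive threshold when DEGs sit in high-expression transcripts", {
  mkExpr <- function(seed) {
    set.seed(seed)
    lines <- c(sprintf("L%02d", 1:60), rep(c("PA", "PB", "PC"), each = 4))
    nS <- length(lines)
    mu <- matrix(rep(c(rep(2, 300), rep(200, 100)), nS), 400, nS)
    grp <- as.integer(factor(lines)) %% 2
    mu[301:350, ] <- mu[301:350, ] * matrix(rep(1.5^grp, each = 50), 50, nS)
    cm <- matrix(rnbinom(length(mu), size = 20, mu = mu), 400,
                 dimnames = list(sprintf("t%03d", 1:400),
                                 sprintf("s%03d", 1:nS)))
    .exprFixture(cm, lines)
  }
  hits <- vapply(1:20, function(s) cpmThresholdScan(mkExpr(s))$threshold > 0,
                 NA)
  expect_gte(mean(hits), 0.8)
})

test_that("gene-level aggregation conserves counts", {
  b <- tinyStudy()
  trs <- rownames(countsMatrix(b$expr))
  geneOf <- setNames(paste0("g", (seq_along(trs) - 1) %/% 3), trs)
  agg <- aggregateToGenes(b$expr, geneOf)
  expect_equal(sum(countsMatrix(agg)), sum(countsMatrix(b$expr)))
  expect_equal(unname(colSums(countsMatrix(agg))),
               unname(colSums(countsMatrix(b$expr))))
})

test_that("expression features are per line, with replicated checks averaged", {
  b <- tinyStudy()
  X <- expressionFeatures(b$expr, "cpm")
  expect_setequal(rownames(X),
                  unique(sampleInfo(b$expr)$line))
  cpm <- countsPerMillion(b$expr)
  pa <- sampleInfo(b$expr)$line == "ParentA"
  expect_equal(unname(X["ParentA", 1]), mean(cpm[1, pa]))
})
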