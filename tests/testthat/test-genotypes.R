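# Variant cleaning, imputation, consensus, filtering and Gst.

test_that("consensus of duplicated observations follows the major allele", {
  expect_equal(consensusDuplicates(c(0, 0, 2)), 0)
  expect_equal(consensusDuplicates(c(2, 2)), 2)
  expect_true(is.na(consensusDuplicates(c(0, 2))))
  expect_true(is.na(consensusDuplicates(c(NA, NA))))
  expect_equal(consensusDuplicates(c(NA, 2, 2, 0)), 2)
})

test_that("collapseDuplicates copies singles and unites replicates", {
  obs <- rbind(s1 = c(0, 2, NA), s2 = c(0, 0, 2), s3 = c(2, NA, 2),
               s4 = c(1, NA, 0))
  colnames(obs) <- paste0("v", 1:3)
  out <- collapseDuplicates(obs, c(s1 = "A", s2 = "A", s3 = "A", s4 = "B"))
  expect_equal(unname(out["A", ]), c(0, NA, 2))   # majority / tie / majority
  expect_equal(unname(out["B", ]), c(1, NA, 0))
})

.cleanFixture <- function() {
  pm <- onePopMap(rils = c("R1", "R2"))
  d <- rbind(
    R1 = c(1, 2, 0, 0),
    R2 = c(0, 0, 2, NA),
    PA = c(0, 0, 0, NA),
    PB = c(2, 0, 2, 0))
  colnames(d) <- paste0("v", 1:4)
  handGeno(d, pm)
}

test_that("cleaning masks heterozygotes and parent-inconsistent calls and drops variants with missing parental data", {
  cl <- cleanCalls(.cleanFixture())
  d <- dosages(cl)
  expect_equal(colnames(d), c("v1", "v2", "v3"))  # v4: parent PA missing
  expect_true(is.na(d["R1", "v1"]))               # heterozygote masked
  expect_true(is.na(d["R1", "v2"]))               # both parents 0, call 2
  expect_equal(d["R2", "v3"], 2)                  # consistent call kept
  expect_equal(d["PA", "v2"], 0)                  # parents untouched
  # raw mode performs none of the three steps
  expect_identical(dosages(cleanCalls(.cleanFixture(), raw = TRUE)),
                   dosages(.cleanFixture()))
})

test_that("cleaning rejects a population map with absent lines", {
  pm <- onePopMap(rils = c("R1", "R2", "Rmissing"))
  d <- rbind(R1 = c(0, 2), R2 = c(2, 2), PA = c(0, 0), PB = c(2, 2))
  colnames(d) <- c("v1", "v2")
  expect_error(cleanCalls(handGeno(d, pm)), "Rmissing")
})

test_that("cleaning never unmasks and never increases observed calls", {
  b <- tinyStudy()
  lineMat <- collapseDuplicates(b$obs$obs, b$obs$sampleLine)
  gd <- GenotypeData(lineMat, b$obs$variants, b$popmap, "rnaseq")
  cl <- cleanCalls(gd)
  before <- dosages(gd)[, colnames(dosages(cl))]
  after <- dosages(cl)
  expect_true(all(is.na(after[is.na(before)])))
  expect_lte(sum(!is.na(after)), sum(!is.na(before)))
})

test_that("median imputation fills per-population low medians and drops monomorphic variants", {
  pm <- onePopMap(rils = paste0("R", 1:5))
  d <- rbind(R1 = c(0,  2, 0,  0),
             R2 = c(0,  2, 2,  0),
             R3 = c(2,  NA, NA, 0),
             R4 = c(NA, 0, NA, 0),
             R5 = c(NA, 2, 2,  NA),
             PA = c(0,  0, 0,  0),
             PB = c(2,  2, 2,  0))
  colnames(d) <- paste0("v", 1:4)
  out <- dosages(medianImpute(handGeno(d, pm)))
  expect_false(anyNA(out))
  expect_true(all(out %in% c(0, 2)))
  expect_equal(unname(out[c("R4", "R5"), "v1"]), c(0, 0))  # median of {0,0,2}
  expect_equal(unname(out["R3", "v2"]), 2)                 # median of {2,2,0,2}
  expect_false("v4" %in% colnames(out))                    # monomorphic
})

test_that("even-count median ties resolve to the lower dosage", {
  pm <- onePopMap(rils = paste0("R", 1:4))
  d <- rbind(R1 = 0, R2 = 2, R3 = NA, R4 = NA, PA = 0, PB = 2)
  colnames(d) <- "v1"
  out <- dosages(medianImpute(handGeno(d, pm)))
  expect_equal(unname(out[c("R3", "R4"), "v1"]), c(0, 0))
})

test_that("WGS intersection keeps shared positions and harmonizes allele swaps", {
  pm <- onePopMap(rils = c("R1", "R2"), parents = c("ParentA", "ParentB"))
  d <- rbind(R1 = c(0, 2, 2), R2 = c(2, 0, 0),
             ParentA = c(0, 0, 2), ParentB = c(2, 2, 0))
  colnames(d) <- c("v1", "v2", "v3")
  vt <- data.frame(chrom = "chr1", pos = c(1, 5, 9),
                   ref = c("A", "C", "G"), alt = c("T", "G", "A"),
                   row.names = colnames(d))
  wgs <- list(
    genotypes = rbind(ParentA = c(0, 0, 2), ParentB = c(2, 2, 0)),
    map = data.frame(variant = c("w1", "w2", "w3"), chrom = "chr1",
                     pos = c(5, 9, 12), ref = c("C", "A", "T"),
                     alt = c("G", "G", "C")))
  colnames(wgs$genotypes) <- wgs$map$variant
  cons <- intersectWgs(handGeno(d, pm, vt), wgs)
  out <- dosages(cons)
  expect_equal(colnames(out), c("v2", "v3"))
  expect_equal(provenance(cons), "wgs_consensus")
  expect_equal(unname(out["R1", "v2"]), 2)       # same alleles: unchanged
  expect_equal(unname(out["R1", "v3"]), 0)       # ref/alt swap: flipped
  expect_equal(unname(out["ParentA", "v3"]), 0)  # parents from WGS
  # empty intersection warns and returns an empty matrix
  wgsFar <- list(genotypes = wgs$genotypes,
                 map = transform(wgs$map, pos = pos + 1000))
  expect_warning(empty <- intersectWgs(handGeno(d, pm, vt), wgsFar),
                 "no shared")
  expect_equal(ncol(dosages(empty)), 0)
})

test_that("parental-haplotype imputation follows the nearest informative flanks", {
  pm <- onePopMap(rils = c("R1", "R2"), parents = c("PA", "PB"))
  d <- rbind(R1 = c(0, 0, NA, 0, 2),
             R2 = c(0, NA, NA, NA, 2),
             PA = c(0, 0, 0, 0, 0),
             PB = c(2, 2, 2, 2, 2))
  colnames(d) <- paste0("v", 1:5)
  vt <- data.frame(chrom = "chr1", pos = 1:5, ref = "A", alt = "G",
                   row.names = colnames(d))
  out <- dosages(imputeFromParents(handGeno(d, pm, vt)))
  expect_false(anyNA(out))
  expect_equal(unname(out["R1", "v3"]), 0)   # flanks both parent A
  # R2 v3: flanks disagree (v1 from A, v5 from B) -> median fallback (0)
  expect_equal(unname(out["R2", "v3"]), 0)
})

test_that("two-founder imputation recovers masked truth on clean synthetic data", {
  p <- simParams(nChromosomes = 3, nVariants = 5000, nTranscripts = 500,
                 seed = 21)
  sim <- simulateParents(p)
  rils <- simulateRilPopulation(sim$parents[1, ], sim$parents[2, ], 40, 6,
                                sim$map, seed = 22, prefix = "L")
  rils[rils == 1] <- 0                     # residual hets out of the way
  pm <- PopulationMap(
    c(setNames(rep("pop1", 40), rownames(rils)),
      setNames(rep("parent", 2), c("ParentA", "ParentB"))),
    list(pop1 = c("ParentA", "ParentB")))
  d <- rbind(rils, sim$parents[c("ParentA", "ParentB"), ])
  set.seed(23)
  mask <- matrix(runif(length(rils)) < 0.1, nrow(rils))
  dMasked <- d
  dMasked[seq_len(nrow(rils)), ][mask] <- NA
  vt <- data.frame(chrom = sim$map$chrom, pos = sim$map$pos,
                   ref = sim$map$ref, alt = sim$map$alt,
                   row.names = sim$map$variant)
  out <- suppressMessages(
    imputeFromParents(handGeno(dMasked, pm, vt)))
  imp <- dosages(out)
  truth <- d[rownames(imp), colnames(imp)]
  maskKept <- mask[, colnames(d) %in% colnames(imp)]
  acc <- mean(imp[seq_len(nrow(rils)), ][maskKept] ==
                truth[seq_len(nrow(rils)), ][maskKept])
  expect_gte(acc, 0.95)
})

test_that("functional filtering selects annotation classes with the 5 kb rule", {
  pm <- onePopMap(rils = c("R1", "R2"))
  d <- rbind(R1 = c(0, 0, 0, 0), R2 = c(2, 2, 2, 2),
             PA = c(0, 0, 0, 0), PB = c(2, 2, 2, 2))
  colnames(d) <- paste0("v", 1:4)
  vt <- data.frame(
    effect = c("missense_variant", "synonymous_variant",
               "upstream_gene_variant", "upstream_gene_variant"),
    distance = c(0, 0, 3000, 6000), row.names = colnames(d))
  g <- handGeno(d, pm, vt)
  expect_equal(colnames(dosages(functionalFilter(g, "CDS"))), "v1")
  expect_equal(colnames(dosages(functionalFilter(g, "Reg"))), "v3")
  expect_error(functionalFilter(g, "UTR"))
})

test_that("quality filtering interpolates thresholds between min and max", {
  pm <- onePopMap(rils = c("R1", "R2"))
  d <- rbind(R1 = c(0, 0, 0), R2 = c(2, 2, 2),
             PA = c(0, 0, 0), PB = c(2, 2, 2))
  colnames(d) <- paste0("v", 1:3)
  vt <- data.frame(MAF = c(0.01, 0.10, 0.40), NS = c(0, 3, 10),
                   DP = c(5, 5, 5), QUAL = c(10, 20, 30),
                   row.names = colnames(d))
  g <- handGeno(d, pm, vt)
  expect_equal(ncol(dosages(qualityFilter(g, "MAF", 0))), 3)
  at05 <- qualityFilter(g, "MAF", 0.5)
  expect_equal(attr(at05, "report")$threshold, 0.205)
  expect_equal(colnames(dosages(at05)), "v3")
  atNs <- qualityFilter(g, "NS", 1)
  expect_equal(attr(atNs, "report")$threshold, 0)
  expect_equal(colnames(dosages(atNs)), "v1")
  expect_warning(qualityFilter(g, "DP", 0.5), "identical")
})

test_that("retained counts are monotone non-increasing in filter strength", {
  b <- tinyStudy()
  lineMat <- collapseDuplicates(b$obs$obs, b$obs$sampleLine)
  gd <- GenotypeData(lineMat, b$obs$variants, b$popmap, "rnaseq")
  for (cr in c("DP", "MAF", "QUAL", "NS")) {
    counts <- vapply(seq(0, 1, by = 0.1), function(s)
      attr(qualityFilter(gd, cr, s), "report")$nAfter, 0)
    expect_true(all(diff(counts) <= 0), info = cr)
    expect_equal(counts[1], ncol(dosages(gd)))
  }
})

test_that("filter combinations are set intersections bounded by their members", {
  b <- tinyStudy()
  g <- b$array
  ids <- colnames(dosages(g))
  A <- ids[1:80]; B <- ids[41:120]
  comb <- combineFilters(g, list(A = A, B = B))
  expect_setequal(colnames(dosages(comb)), ids[41:80])
  expect_identical(colnames(dosages(combineFilters(g, list(A, A)))), A)
  expect_lte(ncol(dosages(comb)), min(length(A), length(B)))
  expect_error(combineFilters(g, list(A)))
  expect_warning(combineFilters(g, list(ids[1:3], ids[10:12])), "no variants")
})

test_that("boundary cases of the standard filter are excluded strictly", {
  pm <- onePopMap(rils = paste0("R", 1:18))
  # 20 lines total (18 RILs + 2 parents); v1 missing in exactly 4 (20%)
  d <- matrix(2, 20, 3, dimnames = list(c(paste0("R", 1:18), "PA", "PB"),
                                        c("v1", "v2", "v3")))
  d[1:10, ] <- 0
  d[1:4, "v1"] <- NA
  d[, "v2"] <- c(rep(0, 1), rep(2, 19))    # MAF = 0.05 exactly
  out <- standardFilter(handGeno(d, pm))
  expect_false("v1" %in% colnames(dosages(out)))
  expect_false("v2" %in% colnames(dosages(out)))
  expect_true("v3" %in% colnames(dosages(out)))
})

test_that("Gst matches Nei's formula on hand-evaluated cases", {
  mkGeno <- function(p1dos, p2dos) {
    pm <- PopulationMap(
      c(setNames(rep("pop1", length(p1dos)), paste0("A", seq_along(p1dos))),
        setNames(rep("pop2", length(p2dos)), paste0("B", seq_along(p2dos))),
        PA = "parent", PB = "parent", PC = "parent"),
      list(pop1 = c("PA", "PB"), pop2 = c("PA", "PC")))
    d <- matrix(c(p1dos, p2dos, 0, 2, 2), ncol = 1,
                dimnames = list(c(paste0("A", seq_along(p1dos)),
                                  paste0("B", seq_along(p2dos)),
                                  "PA", "PB", "PC"), "v1"))
    handGeno(d, pm)
  }
  # p1 = 0.5, p2 = 1.0: Hs = 0.25, Ht = 0.375, Gst = 1/3
  g <- gst(mkGeno(c(0, 2, 0, 2), c(2, 2, 2, 2)))
  expect_equal(unname(g$perVariant["v1"]), 1 / 3)
  expect_equal(g$multilocus, 1 / 3)
  # fixed difference: Gst = 1
  expect_equal(unname(gst(mkGeno(c(0, 0), c(2, 2)))$perVariant["v1"]), 1)
  # equal frequencies: Gst = 0
  expect_equal(unname(gst(mkGeno(c(0, 2), c(0, 2)))$perVariant["v1"]), 0)
})

test_that("Gst lies in [0, 1] wherever defined on simulated data", {
  b <- tinyStudy()
  g <- gst(medianImpute(cleanCalls(GenotypeData(
    collapseDuplicates(b$obs$obs, b$obs$sampleLine),
    b$obs$variants, b$popmap, "rnaseq"))))
  v <- g$perVariant[!is.na(g$perVariant)]
  expect_true(all(v >= 0 & v <= 1 + 1e-12))
  expect_gte(g$multilocus, 0)
  expect_lte(g$multilocus, 1)
})
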