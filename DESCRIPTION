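Package: rilgp
Title: Multi-Omic Genomic Prediction for Multi-Parent RIL Populations
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for genomic prediction in connected recombinant inbred
    line (RIL) populations from RNA-Seq derived predictors. Implements the
    full analysis chain: simulation of multi-parent RIL genotypes,
    negative-binomial transcript counts and noisy RNA-Seq variant calls;
    homozygosity-based variant cleaning, per-population median imputation,
    parental whole-genome-sequencing consensus construction and
    two-founder haplotype imputation; functional-annotation and empirical
    quality filtering of variants (21-level relative-strength grid with
    inclusive intersections); counts-per-million, trimmed-mean-of-M-values
    and block-adjusted expression normalization with a negative-binomial
    likelihood-ratio test for differential expression; adjusted entry
    means and Piepho-Moehring broad-sense heritability; VanRaden genomic
    relationship kernels from z-scored features, weighted multi-kernel
    combination, spectral REML and GBLUP; and the validation designs used
    to assess them (fivefold cross-validation, fixed-size intra-, inter-
    and cross-population validation, training-set-size, kernel-weight and
    sequencing-depth sweeps, empirical filter-grid optimization).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    vcfR,
    jsonlite,
    lme4
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
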