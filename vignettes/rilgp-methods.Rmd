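---
title: "Models and methods behind rilgp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rilgp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`rilgp` implements a complete genomic-prediction workflow for connected
biparental RIL populations whose predictors come from RNA-Seq: the
sequence variants segregating in the transcribed genome, the transcript
expression levels, and their combinations with parental whole-genome
sequencing (WGS) and array genotypes. This vignette describes the
models, the defaults and why they were chosen, the synthetic-data
generator the test suite runs on, and the numerical and design
decisions a maintainer should know about.

## The prediction model

Phenotypes enter as adjusted entry means. For every relationship kernel
$G$ the model is GBLUP,

$$y = \mu + Zu + \varepsilon,\qquad
u \sim N(0, G\,\sigma^2_u),\qquad
\varepsilon \sim N(0, I\,\sigma^2_e),$$

with $G = W^{*}W^{*T}/m$ computed from the column-wise z-scored feature
matrix $W^*$ ($m$ features; population denominator $n$ in the standard
deviation, so $\mathrm{mean}(\mathrm{diag}(G)) = 1$ identically).
Zero-variance features are dropped before scaling. Several predictor
datasets are integrated by an elementwise weighted average of their
kernels; weights are equal unless a sweep varies them.

`remlFit()` maximizes the restricted likelihood over the single
variance ratio $\lambda = \sigma^2_e/\sigma^2_u$ using one spectral
decomposition of the training kernel and a bounded golden-section
search on $\log\lambda \in [-12, 12]$ with tolerance $10^{-8}$. For one
random effect this profiling is exact, needs no iterative solver, and
cannot diverge; the bounds correspond to heritabilities between about
$6\times10^{-6}$ and $1-6\times10^{-6}$, which is beyond anything the
data can support. Kernels with eigenvalues below $-10^{-8}$ are
ridge-stabilized by $10^{-8}$ on the diagonal (reported via message).
Predictions for unphenotyped lines use the conditional mean
$\hat u_{\text{test}} = G_{\text{test,train}}
(G_{\text{train,train}} + \lambda I)^{-1}(y - \hat\mu)$, which is
algebraically the masked-phenotype Henderson system; the equivalence is
itself verified in the test suite against an explicit joint solve.
Variance components are re-estimated inside every training fold rather
than fixed globally: refitting is cheap here and avoids leaking
validation information into the fit.

Prediction ability is the Pearson correlation between predicted values
and observed adjusted entry means of the validation set — the field's
standard reading; it is undefined (and excluded from averages, with a
count) when either vector is constant.

## Variant cleaning and imputation

The lines are F7-generation inbreds, so residual heterozygosity is
$\approx (1/2)^6 \approx 1.6\%$ and observed heterozygous calls are far
more often call errors than genuine. Cleaning therefore (1) removes
variants with any missing parental call, (2) masks heterozygous calls,
and (3) masks RIL calls that match neither parent of the line's
population. Duplicated observations of one line (the replicated
parental checks) are united by the major allele beforehand; a tie gives
a missing call — deterministic and conservative, rather than a random
pick.

Missing calls are median-imputed per RIL population. On cleaned
$\{0,2\}$ data the median of an even split is 1, which is not a legal
homozygous dosage; the implementation uses the *low* median, so ties
resolve to dosage 0. This is an arbitrary but deterministic choice; the
alternative (ties to 2) relabels a handful of calls and does not affect
any kernel noticeably. A population with no observed call at a variant
falls back to the cross-population median; variants observed nowhere,
or monomorphic after imputation, are dropped.

The WGS consensus dataset keeps exactly the variants present at the
same chromosome, position and alleles in the RNA-Seq and parental WGS
sets (ref/alt swaps are harmonized by flipping dosages; other
mismatches are excluded and counted), replaces parental genotypes by
the error-free WGS calls, and imputes missing RIL calls from the two
founder haplotypes: a missing site takes the allele of the parent
supported by the nearest informative flanking markers on both sides.
This replaces a general phased-imputation model on purpose — a
biparental RIL has exactly two founder haplotypes, so nearest-flank
assignment is the maximum-likelihood rule everywhere except inside a
recombination interval, where the method deliberately falls back to the
population median instead of guessing the breakpoint. With 10% missing
calls on clean synthetic data the imputation recovers well over 95% of
the masked genotypes (tested); its weakness is chromosome ends and
sparse regions, where one flank is missing.

G<sub>st</sub> follows Nei: per variant,
$(H_T - H_S)/H_T$ with $H_S$ the unweighted mean within-population
expected heterozygosity and $H_T$ the expected heterozygosity at the
mean allele frequency; the multilocus summary is the ratio of the
locus-averaged numerator to the locus-averaged $H_T$. Monomorphic sites
are undefined and excluded.

## Variant filtering

Functional subsets keep missense variants (CDS set) or
upstream/downstream gene variants within 5 kb of the coding region
(regulatory set). The standard filter keeps variants with missing rate
strictly below 20% and MAF strictly above 0.05, computed from allele
*counts* so that exact-fraction boundary cases (a variant missing in
exactly 20% of lines, MAF of exactly 1/20) compare exactly.

The empirical quality filter scans each of DP (mean site depth), MAF,
QUAL and NS (samples without data) over 21 relative strengths — 0 to
100% in 5% steps — with the threshold interpolated linearly between the
criterion's observed minimum and maximum (NS runs max→min since
smaller is better). Strength 0 keeps everything. Per criterion the
strength with the best cross-validated mean ability wins (ties to the
weaker filter), and all $\binom{4}{2}+\binom{4}{3}+\binom{4}{4}=11$
combinations of the four winners are evaluated as *inclusive
intersections*: a marker must pass every combined filter. The
intersection reading (rather than a union) is what makes combined
subsets smaller than their members, which matches how combined marker
counts behave; a union variant would only ever grow the set and never
needs the enumeration. All subsets are compared on identical fold
assignments (the fold draw depends only on seed, repetition and line
set), so subset rankings are not confounded by partition noise — this
pairing is also what justifies paired t-tests between datasets. DP
filtering uses the per-site mean depth; the minimum would be an
alternative, but the mean is what a VCF's site DP reports.

## Expression processing

Transcripts are kept when at least 2% of samples have a nonzero count
(boundary inclusive). Downstream features are un-normalized cpm by
default; TMM-scaled cpm, $\log_2(\text{cpm}+1)$, and block-adjusted
genotype means are selectable. Log scaling is offered because expression
variance grows with the mean, and homoscedastic features mix better
with dosage features in a combined kernel.

TMM is implemented directly: M- and A-values against a reference sample
(the one whose 75th cpm percentile is closest to the mean), two-sided
trims of 30% on M and 5% on A, inverse-asymptotic-variance weights, and
factors rescaled to geometric mean 1. These are the conventional trim
constants; the implementation is cross-checked in the tests against
both a brute-force enumeration oracle and the edgeR reference.

The block adjustment (EMM) fits, per transcript,
$y = \mu + G_i + B_j + \varepsilon$ with genotype fixed and block
random, by profiled REML on the block-to-residual variance ratio
(bounded search on the log ratio, same tolerance as above), returning
GLS genotype means. Because the block effect is *random*, strong block
offsets are shrunken, not eliminated: an additive offset to one block
is absorbed only in the limit of a large estimated block variance, so
the adjustment is tested against an exact GLS oracle at the profiled
ratio and for recovery under strong block effects, not for exact
offset invariance. With fewer than two blocks the function returns raw
genotype means with a warning.

## Differential expression

The DEG test compares, per transcript, a negative-binomial model with
one mean per genotype against a single grand mean, with library-size
factors as multiplicative offsets and a *fixed* dispersion estimated
from the replicated parental check groups. The statistic
$2\Delta\log L$ is referred to $\chi^2$ with (number of genotypes − 1)
degrees of freedom; p-values are BH-adjusted and flagged at 0.05 (the
threshold is a parameter).

The dispersion estimator matters more than it looks. A pooled
method-of-moments estimate over three groups of a few replicates is
heavy-tailed: its sampling error of several percent shifts the whole
LRT distribution because the degrees of freedom are large, and the null
type-I rate then swings far outside its nominal neighbourhood from one
dataset to the next. The default common dispersion is therefore
estimated by Cox–Reid adjusted profile likelihood over the parental
groups (the adjustment corrects the downward bias of plain profile ML
when every group mean is estimated from few replicates); per-transcript
method-of-moments remains available as `dispersion = "tagwise"`. Both
are floored at $10^{-4}$. All-zero transcripts get $p = 1$ by
convention.

The cpm-threshold scan evaluates mean-cpm thresholds on a grid of 40
evenly spaced quantiles between 0 and the 90th percentile (plus 0
itself — bounded and data-adaptive; nothing in the method fixes a
grid), re-running the BH adjustment within each retained set. The LRT
statistics themselves do not depend on the filter, so they are computed
once. The returned threshold maximizes the significant-DEG count, ties
resolving to the smallest threshold; by construction its count is never
below the unfiltered one. Filtering helps exactly when differential
expression concentrates in well-measured, higher-expression
transcripts, so the multiplicity burden of the uninformative tail can
be shed.

## Phenotypes and heritability

Adjusted entry means come from
$y_{ijk} = \mu + G_i + E_j + (G\times E)_{ij} + \varepsilon_{ijk}$ with
genotype fixed and environment and interaction random. The fits use
lme4's REML — a deliberate build-on-standard-tools decision: this is an
ordinary linear mixed model, and a bespoke optimizer would add risk
without adding capability. The tests verify the returned means against
an explicit GLS solve at the fitted components. When no genotype has
within-environment replication the interaction is not separable from
the residual and the two are pooled into one term automatically (the
single-replicate situation for the non-check lines); with replicated
checks present the full model is identifiable and used. Traits seen in
one environment fall back to raw means with a warning.

$\bar\nu$ is the mean variance of a difference between two adjusted
means, computed from the fixed-effect covariance matrix; $\sigma^2_G$
comes from a companion fit with genotype random (the standard
two-stage entry-mean convention), and
$H^2 = \sigma^2_G/(\sigma^2_G + \bar\nu/2)$. Degenerate (noise-free)
data make the genotype-random fit singular; the implementation then
takes $\sigma^2_G$ from the variance of the adjusted means.

## The synthetic-data generator

The generator reproduces the statistical structure the analysis
assumes, as study defaults: three fully homozygous parents; three RIL
populations of 65/92/80 F7 lines from the pairwise crosses; meiosis
under the Haldane model (Poisson crossovers, mean = map length, no
interference — the simplest defensible model when no interference
information is available); residual heterozygosity halving per selfing
generation; a randomized incomplete block design of 24 samples per
block (21 RILs plus the three parental checks, left-over slots filled
by re-replicated RILs); negative-binomial counts with per-block
multiplicative effects and a configurable cis-eQTL fraction; variant
read depth Poisson-proportional to the host transcript's counts, so
callability tracks expression; genotyping errors with a configurable
spurious-heterozygote share; site QUAL increasing monotonically in
total depth plus noise (only the ordering matters to the filter grid);
an error-free parental WGS superset and a sparse array subset; and
phenotypes whose interaction and residual variances are scaled from the
target $H^2$ by inverting the balanced-case entry-mean relation
($\sigma^2_{G\times E} = \sigma^2_e = J\sigma^2_G(1-h^2)/(2h^2)$ for
$J$ environments), so the target is recovered in expectation.
Eight traits in 4–7 environments with $H^2$ targets between 0.74 and
0.89 mirror the trait panel of the motivating study design.

What the generator does *not* emulate: linkage-disequilibrium decay
beyond the biparental recombination process, multiallelic sites and
indels, splice isoforms, read-level errors, spatial field trends, and
any misspecification of the NB count model. Passing tests therefore
show that the chain is correct and well-calibrated under its assumed
model, not that those assumptions hold for any particular real dataset.

Desk-scale defaults for the test suite are 3 chromosomes × 1 Morgan,
a few hundred to 5 000 variants, 300–2 000 transcripts and populations
of 20–30 lines; the acceptance checks that concern population-level
behaviour (training-set sweeps, intra/inter-population contrasts,
H² recovery at 237 lines) run at the full 65/92/80 design. Genome scale
(variants, transcripts, mean library size) is a proportional reduction
of the study's RNA-Seq dimensions so that per-transcript counts stay
realistic.

## Validation designs

All schemes draw training and validation sets disjointly, store
per-repetition results (never only aggregates), and derive every draw
from (seed, repetition, line set) so that datasets share partitions.
The fivefold scheme defaults to 50 repetitions; subset schemes to 200
repetitions with training size 50 and validation size 65 (cross/inter)
or 15 (intra); the training-size sweep runs 20 to 170 in steps of 15
with validation size 65. An inter-population validation set larger than
the source population is capped (sampling stays without replacement)
and reported. The depth sweep thins counts binomially, re-derives the
variant observations at each depth, rebuilds all datasets, and keeps
only samples above the read minimum at *every* depth so comparisons
share a sample set. Feature counts of the detection-driven datasets
grow with depth by construction; the adaptively thresholded subsets
(cpm-filtered, DEG) need not, because their thresholds move with depth.

## Known limitations

* The DEG test's $\chi^2$ reference is asymptotic; with near-saturated
  genotype models its calibration relies on moderate counts and an
  accurate common dispersion. Tagwise dispersions at three small check
  groups are noisy and are not the default for this reason.
* The two-founder imputation does not model the breakpoint position
  inside a recombination interval; the median fallback there is
  deliberately crude.
* The phenotype model omits row–column field-design effects; only
  environment and interaction terms are removed.
* Kernel averaging assumes the datasets are exchangeable up to their
  weights; no attempt is made to estimate optimal weights beyond the
  grid sweep.
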