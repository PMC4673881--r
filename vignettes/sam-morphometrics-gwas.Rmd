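---
title: "From SAM images to genotype-phenotype associations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From SAM images to genotype-phenotype associations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(samgwas)
```

## The problem

The maize shoot apical meristem (SAM) is a microscopic dome of stem cells
whose size and shape vary across inbred lines and predict agronomically
relevant adult traits. `samgwas` implements the full quantitative chain
from a traced SAM outline to genome-wide association: parabolic shape
morphometrics, BLUP phenotypes across replicated plantings, construction
of a homozygous SNP matrix from sequencing reads, a unified mixed linear
model scan with kinship and principal-component covariates, candidate-gene
window mapping and ALT-allele burden analysis, and nuclei-lattice
cytometry for cell number and cell size. A seeded synthetic-data module
generates every input the pipeline consumes, with the statistical
structure the analyses assume, so the whole chain is testable end to end.

## The parabolic SAM model

A median longitudinal SAM profile is modeled as the downward-opening
parabola

$$y = h - \frac{h}{r^2} x^2,$$

with apex height $h$ and base radius $r$ (micrometres); the base is the
P1-notch level. `fit_parabola()` spline-resamples the traced contour at
evenly spaced stations (51 by default; the regression is insensitive to
this count once it exceeds a few dozen) and fits the full quadratic
$y = c_0 + c_1 x + c_2 x^2$ rather than a symmetric form, so imperfect
centering of the trace is absorbed by the vertex. The shape coefficient is
$a = -c_2$, with the consistency identity $a r^2 = h$.

Two numerical choices matter here. First, the base level is read from the
*fitted* curve at the contour endpoints, not from the raw endpoint
points: raw endpoints carry measurement noise, and the minimum of two
noisy values is biased downward, which would bias $h$ (and every derived
volume) upward. Second, when the two fitted ends are statistically
indistinguishable — the symmetric-trace case — their average is used
instead of their minimum, for the same reason; the minimum is kept for
genuinely asymmetric traces, where the lower end is the P1 notch.

From $(h, r)$, `microphenotypes()` derives the full phenotype set:
ratio $h/r$, diameter $2r$, midsection (parabolic-segment) area
$\tfrac{4}{3} h r$, paraboloid-of-revolution volume
$\tfrac{\pi}{2} r^2 h$, coefficient $a = h/r^2$, lateral surface area
$\frac{\pi r}{6 h^2}\left[(r^2 + 4h^2)^{3/2} - r^3\right]$, and profile
arc length $\sqrt{r^2 + 4h^2} + \frac{r^2}{2h}\operatorname{asinh}(2h/r)$.
Surface area is lateral only (no base disc). Each closed form is tested
against adaptive numeric integration to a relative $10^{-8}$ over a
5 × 5 grid of $(h, r)$; scaling laws (volume $\sim s^3$, areas
$\sim s^2$, lengths $\sim s$) are asserted as properties.

`area_estimated_vs_measured()` compares the model estimate
$\tfrac{4}{3} h r$ with the shoelace-polygon area of the trace closed
along its base chord. On exact parabolas the two agree by the
parabolic-segment theorem up to discretization; on noisy traces the
paired difference is centered (no measurement-technique bias), which the
test suite checks with a paired t test over 100 simulated domes.

## BLUP phenotypes and repeatability

Replicated plantings are modeled as
$y_{ij} = \mu + \rho_j + g_i + e_{ij}$ with replicate (growth batch)
$\rho_j$ fixed and genotype $g_i$ random; `fit_blup()` fits this by REML
through `lme4`, using sum-to-zero replicate contrasts so the intercept is
the grand replicate-level mean. Replicate is fixed rather than random
because four levels cannot support a stable variance component; the
assumption is exposed in the model formula. Phenotypes are reported in
BLUP + intercept form. The entry-mean repeatability is

$$H^2 = \frac{\sigma^2_g}{\sigma^2_g + \sigma^2_e / \bar n},$$

with $\bar n$ the harmonic mean of per-genotype replicate counts, which
handles cells lost to failed germination. Negative variance estimates are
clamped at $10^{-12}$. Tests verify the fit against a dense
mixed-model-equation solve, the closed-form balanced-case shrinkage, and
parameter recovery when the true $H^2$ is 0.84 at $\bar n = 4$.

## The SNP matrix

Reads are quality-trimmed in two phases with PHRED threshold 15: ends are
stripped base by base, then overlapping 10-bp windows are scanned 5' to
3' and the read is truncated at the first window whose mean quality falls
below the threshold. The truncation wording admits two readings; the
package truncates at the first failing window (the alternative — keep
through the last passing window — is available as `mode = "last_pass"`).
The two phases are iterated to a fixpoint so that trimming is idempotent.
Alignments are kept when unique, with at most 2 mismatches per 36 bp and
fewer than 5 unaligned tail bases per 75 bp (allowances prorated with a
ceiling on the length ratio; "two or less" is inclusive, "fewer than
five" strict). Homozygous calls require base quality at least 20, at
least 5 unique supporting reads after masking the first and last 3
aligned bases of each read, and a supporting fraction of at least 0.9 —
the purity fraction is a parameter, since only "putative homozygous" is
specified by the calling design. Repeated runs are consensus-merged
(agreement kept, conflict scored missing), and sites with minor allele
frequency below 1% or missingness above 60% are excluded; both
boundaries are encoded strictly (exactly 60% missing is kept). All
boundary semantics are tested against brute-force re-filtering oracles.
Coordinates are 1-based in all file formats (VCF v4.2, minimal SAM,
FASTQ PHRED+33).

## Mixed-model association

The scan fits $y = X\beta + s\alpha + u + e$ with
$u \sim N(0, \sigma^2_g K)$, where $K$ is the VanRaden centered-genotype
kinship matrix, $K = WW' / 2\sum_k p_k(1-p_k)$ (the kinship method is a
flag; VanRaden is the default). With the inbred $\{0, 2\}$ coding the
diagonal of $K$ sits near 2 rather than the outbred 1 — centering does
not remove inbreeding — and the centered off-diagonal mean is
$-\overline{\mathrm{diag}}/(n-1)$, which tests account for. $K$ is
eigendecomposed once; $\delta = \sigma^2_e/\sigma^2_g$ is estimated by a
1-D REML profile on $\log\delta \in [-10, 10]$; with P3D (the default)
these null components are reused for every SNP, and each marker test is a
weighted (generalized least squares) regression on the rotated data with
a Wald t on $n - \mathrm{rank}(X) - 1$ degrees of freedom. Exact per-SNP
REML is available with `p3d = FALSE`; on simulated panels the two differ
by well under one -log10 unit and the difference is bounded in a sanity
test, not asserted as equality. Missing genotypes are mean-imputed per
site for testing only and never written back.

Principal-component covariates are chosen by BIC over 0..3 PCs on the
null model. The BIC uses the *maximum-likelihood* log-likelihood, not the
REML one: REML likelihoods are not comparable across different
fixed-effect matrices, and using them reliably overselects PCs.

Trait-associated SNPs (TAS) are those exceeding the Bonferroni threshold
$T = -\log_{10}(\alpha / M)$ with $M$ the number of SNPs actually tested
after filtering. Candidate genes are assigned within a 100-kb window;
distance is the gap convention (bases strictly between SNP and gene
boundary, 0 inside the gene), which is what makes a SNP 50 kb from a gene
boundary assigned at distance exactly 50,000. The ALT burden per
individual is the count of ALT-homozygous calls over the TAS sites
(missing skipped), correlated with phenotype via the Fisher
transformation: $z = \operatorname{atanh}(r)$, $\mathrm{se} =
1/\sqrt{n-3}$, two-sided normal p. `cor.test`'s t approximation is not
used because the Fisher z test is the study's stated procedure.

## Cytometry

Nuclei in a stained median section are segmented by Gaussian smoothing,
median-background subtraction, an Otsu threshold computed on the masked
pixel histogram (a whole-image threshold would be biased by out-of-mask
background), and a watershed split on the distance transform; objects
below a minimum area are discarded and centroids are intensity-weighted
(unbiased for blob-like nuclei). The SAM mask is then partitioned by
nearest centroid (Euclidean; ties to the lowest centroid index, for
bit-exact reproducibility) into a Voronoi cell lattice. SAM cell number
(SCN) is the centroid count and average SAM cell size (ASCS) is mask
area / SCN; cell areas sum to the mask area exactly at pixel resolution,
asserted as an invariant. Cell size is defined on the 2-D median section,
not in 3-D. Watershed breaks intensity ties by pixel index, so
translation equivariance holds exactly for counts and to a fraction of a
pixel for centroids; the test encodes that distinction. SCN and ASCS are
related to genotype class and SAM volume by a sequential (Type-I)
two-way ANOVA, `response ~ genotype + volume + genotype:volume`; with
sequential sums of squares the genotype term absorbs any volume imbalance
between classes, which is why the sampling design balances volumes
across classes.

## What the synthetic data emulates

`sim_config()` defaults are the study conditions: 369 genotypes in 4
biological replicates; rare ALT alleles with per-site frequency drawn
uniformly from (0.01, 0.09), so the common allele exceeds 91%; three
subpopulations; 20% genotype missingness; 5% of genotype × replicate
cells lost to germination failure; contour measurement noise of 2 um.
Sizes follow a log-normal aspect ratio ($h/r$, meanlog $\log 2$, sdlog
0.1) around a mean volume of 390,000 um^3 — the across-panel size
distribution is not specified beyond its range, so the log-normal is a
documented modeling choice.

ALT carriers at each site are allocated as an exact quota
$\mathrm{round}(p \cdot n)$ of individuals, drawn with
subpopulation-biased Dirichlet weights. This has two deliberate
consequences: realized allele frequencies equal their drawn values (so
the COM > 91% property holds at the site level, not just in
expectation), and rare alleles tend to be private to one subpopulation —
which is also what makes population structure detectable from the
genotypes alone.

The genetic architecture is rare-allele/large-effect: 12 causal SNPs of
+65,000 um^3 per ALT genotype plus a polygenic term built from the
realized genomic relationship with plot-level heritability 0.45 and a
residual sd of 70,000 um^3. These three numbers are derived jointly, not
independently tunable: with $c$ the causal variance, $g$ the polygenic
variance and $E = \sigma^2_e/\bar n$ the entry-mean error variance,
requiring an entry-mean repeatability of 0.84 and an observed ALT-burden
correlation of 0.5 (after the $\sqrt{0.8}$ attenuation from 20%
missingness in the burden counts) fixes $c : g : E$, and the defaults are
the solution at $\sigma_e = 70{,}000$. Simulations at the default
conditions reproduce both statistics to within sampling error.

Nuclei images place approximately (segment area / mean cell area)
centroids by hard-core dart throwing (minimum spacing
$0.72\sqrt{\text{mean cell area}}$, which keeps Voronoi cells well
conditioned), with a boundary margin of twice the blob sigma so rendered
nuclei are never clipped by the tissue mask; each nucleus is a Gaussian
blob (sigma $0.18\sqrt{\text{mean cell area}}$) plus optional background
noise. Reads are drawn uniformly over a reference with ALT substitutions
at designated sites and constant or tail-degraded quality profiles.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: optical artifacts of DIC imaging,
realistic maize linkage-disequilibrium structure (sites are exchangeable
given the subpopulation weights), heterozygosity, indels, spliced
alignment, and 3-D confocal stacks. Results on synthetic data validate
the computational chain, not the biology.

## Problem sizes and reproducibility

Every generator consumes a single master seed expanded into fixed
per-module substreams, so identical configurations give byte-identical
outputs and each stage can be re-run independently; the pipeline manifest
records thresholds and per-file checksums. The test suite runs its
heavier simulations at deliberately chosen sizes: mixed-model calibration
on 400 individuals × 5,000 SNPs over 200 null replicates, power at
400 × 1,000 over 100 replicates, repeatability recovery on 100 genotypes
× 4 replicates over 200 seeds, and the demo pipeline at 40-50 genotypes
× a few hundred SNPs. The `scripts/acceptance.R` report averages eight
369-genotype simulations, whose per-simulation sampling sd for the burden
correlation is about 0.05.

## Known limitations

The compressed mixed model is run at full rank (every individual its own
group); kinship-clustered compression changes nothing at these panel
sizes and is out of scope. MAF filtering is applied to the merged matrix;
per-source counts are logged but the order (filter-then-merge vs
merge-then-filter) is a documented choice. The Wald t with P3D slightly
understates small-sample uncertainty relative to exact per-SNP REML; the
calibration test bounds the practical consequence. Voronoi cell areas
are a proxy for cell size wherever true cell walls deviate from
nearest-nucleus geometry.
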