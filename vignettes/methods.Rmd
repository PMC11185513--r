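---
title: "Models and methods: selection and regulatory architecture of gene expression under salinity stress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

riceqx analyses how natural selection acts on transcript abundance in a
structured crop population grown in two field environments — a normal wet
paddy and a moderately saline field — and how the genetic architecture of
expression (cis and trans eQTLs) shapes that response. This vignette is
the package's account of its models, the choices behind them, and what
the synthetic-data tests do and do not demonstrate.

## Study design and data model

The unit of observation is a single plant: an accession (inbred genotype)
grown as one of `r` replicates per environment, one replicate per block.
Expression is a samples-by-transcripts matrix of log2(normalized TPM + 1)
values; fitness is the plant's fecundity (total filled grain count);
genotypes are accession-by-SNP alternate-allele dosages for a
near-fully-homozygous (inbred) population. All per-record results are
tibbles keyed by `transcript_id` / `snp_id`, so stages chain with the
pipe; the matrix-valued containers (expression, dosages, kinship, G)
remain plain matrices.

## Variance partitioning and heritability

`partition_variance()` fits, per transcript, the two-way mixed ANOVA with
environment fixed and genotype and genotype-by-environment random. Sums
of squares come from accession-by-environment cell means; F-ratios follow
the classic expected-mean-squares scheme for a random interaction
(`F_G = MS_G/MS_GxE`, `F_E = MS_E/MS_GxE`, `F_GxE = MS_GxE/MS_res`), and
method-of-moments components are read off the expected mean squares, with
negative estimates truncated to zero and flagged — standard
method-of-moments practice. Unbalanced (non-empty) cells are handled by
an unweighted-means analysis with the harmonic-mean replicate count and a
warning; the package targets balanced or near-balanced field designs and
makes no claim beyond them.

Broad-sense heritability is
`H2 = s2_G / (s2_G + s2_GxE / e + s2_E / (r e))` with `e` environments
and `r` replicates per environment. The `s2_E` in this denominator is the
*within-genotype environmental variance* — the ANOVA residual — as in the
classical quantitative-genetics definition; the fixed macro-environment
effect is reported separately as a quasi-component and does not belong in
the denominator (it would otherwise make `H2` depend on how different the
two fields happen to be).

## Univariate selection analysis

Relative fitness `w` is fecundity divided by the mean fecundity of the
environment, after dropping zero-fecundity plants — so `mean(w) = 1` per
environment by construction. The linear selection differential `S` is the
slope of `w` on expression with block as a categorical fixed covariate;
the quadratic differential `C` is *twice* the squared-term coefficient of
the quadratic regression (linear term retained), the Lande–Arnold
convention. Variance- and mean-standardized variants are `S·sd`, `C·sd²`,
`S·mean`, `C·mean²`, equivalent to rerunning the regression on scaled
traits (asserted in tests to 1e-8).

Design choices worth stating:

* **Block as a fixed OLS covariate.** A mixed-model fit with an
  unspecified random structure is not reproducible; with balanced blocks
  the OLS point estimate of `S` is identical in expectation, and a
  deterministic fit keeps every downstream count stable under a seed.
* **Outlier trimming** (|expression − mean| > 3 SD) happens per
  transcript per environment *before* the regression, and the trimmed
  samples are also excluded from the mean/SD used for standardization.
* **Inclusion rule:** a transcript must be expressed (> 0) in at least 20
  retained individuals; the Bonferroni family is all transcripts tested
  in that environment.
* **Pseudo-replication caveat.** Replicate plants of one accession share
  genetic expression effects. When fitness itself depends on expression
  (i.e., under true selection), residuals are correlated within
  accession and naive OLS p-values on *other* transcripts are mildly
  anti-conservative. The null-calibration tests therefore use a
  no-selection simulation, which is also the regime in which the 5%
  type-I level is a meaningful claim.

Cross-environment classification uses asymmetric thresholds to offset the
detection bias that favours conditional neutrality: CN requires
`p < 0.025` in exactly one environment and `p > 0.05` in the other,
antagonistic pleiotropy requires `p < 0.05` in both with opposite signs
of `S`.

For GO biological-process terms, the term statistic is the median |S| of
its annotated, tested transcripts (≥ 20 of them), with a percentile
bootstrap CI over transcripts; a term is called only when the
transcriptome-wide median strength falls below the CI lower bound.
Whether "selection strength" should be signed is genuinely open; the
package takes the absolute value (strength) as the ranking statistic and
reports the signed median alongside, so either reading is available.

## Multivariate selection, G, and the response to selection

PCA (column-centered SVD, deterministic sign convention: the
largest-magnitude loading of each PC is positive) summarizes correlated
transcripts; PCs explaining > 0.5% of variance enter one joint multiple
regression of `w` on the scores (`beta`), with `gamma` as twice the
squared-term coefficients of the quadratic extension. Each PC's direction
is assigned by majority vote of its top-1%-|loading| transcripts,
comparing the loading sign with the sign of the univariate `S`.

The G-matrix is estimated on "eigengenes" — accession means of PC scores
— because PCs are uncorrelated at the plant level by construction and
only reveal genetic covariance once replicates are averaged within
genotype. Additive variance per PC comes from a single-component REML
(kinship + identity residual) solved on the spectral decomposition of the
kinship matrix and profiled over heritability on (0, 1) with explicit
comparison of the zero boundary; covariances use the polarization
identity `Cov(x, y) = [VarA(x+y) − VarA(x) − VarA(y)] / 2` with the same
REML on sums. The result is symmetrized and clipped to the PSD cone
(negative eigenvalues set to zero, flagged). One practical caveat: in a
panel of unrelated accessions the kinship matrix is near-proportional to
the identity and the additive/residual split is weakly identified; the
REML tests therefore use structured (family) kinships, and on real panels
the estimates inherit whatever relatedness structure the population has.

Kinship itself is the VanRaden genomic relationship matrix
`(X − 2p)(X − 2p)' / (2 Σ p(1−p))`; for fully inbred material the mean
diagonal approaches 1 + f = 2.

The predicted response is the multivariate breeder's equation
`Δz = G β`, decomposed as direct (`G_ii β_i`) and indirect
(`Σ_{j≠i} G_ij β_j`) responses; PCs whose direct and indirect parts
oppose each other are flagged as evolutionarily constrained.

## Decoherence (CILP)

The correlation-by-individual-level-product test asks whether the
correlation between two transcripts differs between environments.
Individuals are accession means per environment (matching the eQTL
stage); each transcript is z-scored *within* environment using the
population (n) denominator, so the mean of the per-individual products
equals that environment's Pearson correlation exactly — an identity the
tests assert. The per-pair product is regressed on the environment
indicator (optional covariates supported; none by default, since no
specific covariates are prescribed), with BH q-values across all tested
pairs. Transcripts enter the pair universe when |S| > 0.1 in at least one
environment and expression > 0 in at least half the individuals.

## eQTL architecture

The association scan is ordinary least squares of accession-mean
expression on dosage plus the top five kinship eigenvectors, implemented
as residualize-then-correlate, which is algebraically identical to
per-pair OLS (asserted to 1e-8 in tests) and fast enough to scan every
SNP-transcript pair. BH q-values form one family per environment across
all pairs; q < 0.001 is retained. Missing dosages fall back to a per-SNP
complete-case path rather than imputation.

Classification: cis means same chromosome and SNP-to-TSS distance
< 100 kb; trans means a different chromosome or ≥ 1 Mb; the
same-chromosome 100 kb–1 Mb band is left unclassified and excluded from
both summaries, since long homozygous tracts make that band ambiguous in
inbred rice. Distances anchor at the annotated TSS for determinism.
Environment overlap percentages are computed against the union of the
two environments' significant sets. G×eQTLs are mapped on the
per-accession expression difference (normal − saline) at FDR 0.05, so a
saline-specific positive effect appears with a negative sign.

Lead SNPs are the most significant association per transcript per 100-kb
window (ties to the lower position); hotspot windows are those whose lead
SNPs trans-regulate strictly more than 30 distinct transcripts.

Compensation/reinforcement: for genes with both a lead cis and lead trans
eQTLs, each accession's cis contribution is `beta_cis (x − mean x)` and
its trans contribution the mean of the analogous lead-trans terms; the
fraction of accessions whose contributions agree in sign (zero products
excluded from the denominator) drives the 60% rule. Two properties of
this statistic matter for interpretation and shaped the generator:
with *independent* cis and trans dosages the fraction concentrates at
0.5 and calls are rightly "unclassified" — informative configurations
require cis-trans LD, which is why the generator plants architecture
genes with trans dosages largely fixed with the cis allele (copy with a
flip rate tuned to r² ≈ 0.3, the regime where such calls are typically
made); and under that LD the *marginal* scan effect of a compensating
gene's cis SNP shrinks by about `r |beta_trans|`, so strongly unequal
planted magnitudes would push one class below the detection threshold.

The LD test compares mean r² (squared dosage correlation) over focal
cis-trans pairs against 1,000 permuted pair sets matched on the focal
distance profile — same-chromosome pairs by log10-distance bin (widened
with a warning when a bin is too sparse), different-chromosome pairs by
chromosome-pair category — with the two-tailed add-one p-value computed
around the null median. Matching on distance is what makes the test
specific to *excess* LD rather than proximity.

SFS/diversity: folded MAF per SNP (heterozygous dosages count half an
alternate allele), Welch t-tests of each eQTL SNP set against all other
SNPs, per-site `pi = 2p(1−p) n/(n−1)`, averaged over 50-kb flanks around
each focal SNP and compared against tiling 100-kb background blocks that
exclude the flank regions.

## The synthetic-data generator

`sim_config()` fixes the study conditions: two environments, three
replicates in three blocks, inbred genotypes with folded MAF ≥ 0.05 drawn
from a Beta(0.5, 0.5) frequency distribution, and default variance
components `s2_G = 1`, `s2_GxE = 1.4`, `s2_res = 1`, `s2_E = 0.1` chosen
so that the default heritability sits near the observed median for field
expression data (`H2 ≈ 0.54`) with pervasive G×E and only a weak fixed
environment shift. Gene means are uniform on log2 scale over (4, 9) —
widely expressed transcripts — and expression is floored at zero, which
is why variance-recovery tests use high-mean genes where flooring is
negligible. Fecundity is `round(max(0, 1000 w))` with Gaussian noise on
`w` and a 2% structural-zero rate; fecundity generation is the package's
own model (a measured quantity in the field, so some generative choice
is unavoidable) and integer grain counts with occasional zeros are the
realistic shape. Planted structure — selection coefficients on
standardized expression, cis/trans/GxE eQTLs, a hotspot SNP,
environment-specific pair correlations, cis-trans-linked architecture
genes — is recorded in a `TruthSet` for recovery testing. LD blocks, when
enabled, use a founder-copy-with-mutation scheme whose founders stay
polymorphic at every SNP, giving controllable within-block r².

What the generator does *not* emulate: read-level noise and library-size
artefacts, invariant-set normalization, linkage between causal and
neighbouring markers (outside the explicit LD options), population
structure beyond what random genotypes induce, and selection acting
through anything but the planted fitness surface. Passing recovery tests
therefore demonstrates the correctness and calibration of the estimators
under the stated generative model, not robustness to every artefact of
field transcriptomics.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale chosen as the
smallest sizes at which the statistical claims are meaningful: 20–200
accessions, 40–300 transcripts, 60–500 SNPs, 1,000 permutations or
bootstrap draws, 20 replicate simulations for power estimates. REML
optimization uses `optimize()` on the heritability scale to 1e-6 with an
explicit boundary check at zero. All randomness flows from a single
integer seed through small derived offsets (kept below 2^31), and every
generator and resampling routine is byte-reproducible under a fixed
configuration.

## Known limitations

* Selection regressions treat plants as exchangeable given block; within-
  accession correlation under strong true selection mildly inflates
  nominal significance on correlated transcripts (see above).
* The REML G-matrix needs genuine relatedness structure to separate
  additive from residual variance.
* The unclassified 100 kb–1 Mb band means cis and trans counts do not
  partition all significant associations.
* The hypergeometric enrichment helper is a plain over-representation
  test without annotation-graph weighting.
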