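---
title: "Methods: quantitative genetics of liver fat in a farmed salmon population"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative genetics of liver fat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(salmofat)
```

# Scope and population

`salmofat` analyses individual variation in liver fat content (% lipid by
weight) in a single year-class of farmed Atlantic salmon: 634 phenotyped
fish descending from 39 sires and 48 dams, 610 of them genotyped on a SNP
array, and 48 with liver RNA-seq and fatty-acid profiles.  The package
covers the statistical chain only — genotype QC, relationship matrices,
variance components, association testing, expression modelling, enrichment —
plus a simulator that reproduces the population's statistical structure.
Wet-lab steps (lipid chemistry, read alignment, transcript quantification)
and visual scoring are out of scope; the simulator emulates their outputs.

# The synthetic-data generator

The generator is first-class, tested code: its defaults *are* the study
conditions, and the downstream stages are validated by recovering the
generating parameters.

**Pedigree.**  Each dam is mated to one sire (round-robin, so some sires
serve two dams); a sire×dam pair is a full-sib family (≤ 48 families).
Offspring are assigned to families uniformly; sex is male with probability
0.55.  Exactly 610 fish are flagged genotyped and 48 of those flagged for
expression.  The real study chose its 48 RNA-seq fish inside a narrow
body-weight window; that selection step is not emulated (the expression
subset here is a random subset of genotyped fish), so the 48-fish
descriptive statistics of the real data are not a calibration target.

**Genotypes.**  Gene dropping: founder haplotypes are drawn per SNP in
Hardy-Weinberg proportions with second-allele frequency uniform on
[0.05, 0.5]; offspring receive one random allele per parent per SNP.  This
produces the family co-segregation ("family LD") the GRM and LOCO-GWAS
stages rely on; population-level linkage disequilibrium beyond family
structure, selection and epistasis are deliberately not modelled.  5,000
SNPs on 29 chromosomes stand in for the ~52,925-SNP post-QC array — GRM and
REML behaviour depends on n and family structure far more than on marker
count, and this keeps the full test suite and acceptance runs inside a
couple of minutes.  1% of dosages are set missing.  Optional "spike" SNPs
carry guaranteed QC violations (>10% missingness; MAF = 1/(2n); an
all-heterozygote column) with their violation type recorded, giving the QC
stage truth labels.

**Phenotypes.**  Six traits (liver fat, muscle fat, body weight, liver
score, HSI, viscera score) with means/SDs and heritabilities from the
study's descriptive and genetic-parameter tables (liver fat: σ²_g = 2.59,
σ²_e = 4.19, mean 7.6%).  Additive genetic values are built from per-SNP
effects — raw scores `Z B` with i.i.d. normal effect rows, the
infinitesimal architecture GREML assumes — then recoloured so the *realised*
genetic covariance equals the target `diag(σ_g) R diag(σ_g)` exactly
(trait 1's values reduce to a pure rescaling of its `Z b` score, so they
remain a valid SNP-effect model).  Exact recolouring pins the generating
truth, which is what parameter-recovery tests must compare against.
Residuals are independent Gaussians per trait (the source reports only
genetic correlations; residual cross-correlations default to zero and are
configurable).  The genetic correlation matrix sets liver fat against
muscle fat 0.37, body weight 0.31, liver score 0.70, HSI 0.25, viscera
score 0.28, other pairs 0 — that vector has norm < 1, so the matrix is
positive semidefinite.

Liver fat passes through a softplus rectification with a soft floor at 4%
(scale 0.5% fat): real livers show a physiological minimum near 4% and a
long right tail.  The floor raises the mean by ≈ 0.1 over the Gaussian
core, well inside the calibration band.  Because rectification biases
variance-component recovery, `liver_fat_floor = NA` switches to a pure
Gaussian trait; recovery studies use that switch.  Scores are latent
Gaussian traits (mean 3, SD 1) discretised by rounding onto 1–5, already on
the "reversed" presentation scale where higher = fattier;
`reverse_liver_score()` implements the 6 − s involution for data recorded
on the original colour scale.  Discretisation attenuates the realised
genetic correlation slightly; bivariate recovery tests therefore use the
continuous latent scores (`discretize_scores = FALSE`).  HSI is realised by
turning the latent HSI trait into a liver weight given body weight, then
recomputing liver weight / body weight × 100; body weight is clamped at
0.2 kg so the ratio is always defined (a >4 SD left-tail event otherwise).

**Expression.**  For a configured 10% of genes, log2 expression couples
linearly to standardised liver fat with coefficient ~N(0, 0.8²); all genes
get a gene baseline ~N(4, 1.5²), a small sex effect, a full-sib family
intercept with variance 10% of the residual variance (its magnitude is not
reported; with 48 fish from ~48 families it is weakly identified anyway),
and Gaussian noise (SD 0.5).  Counts are Poisson at rate
FPKM × length/10³ × library/10⁶ with library sizes ~U(4–6 M), so the
normalisation stage can reconstruct FPKM.  Truth labels (which genes are
coupled, with what sign) drive the signal-recovery and
enrichment-of-truth tests.

**Fatty acids.**  Nine fatty acids with the study's means/SDs; each couples
to standardised liver fat with the observed signs (positive: 16:1n-7,
18:1n-9, 18:2n-6; negative: 16:0, EPA, DPA, DHA — DHA strongest, |r| = 0.9)
and closes to exactly 100% through an "other" pool.  Rows are truncated at
zero and rescaled only in the (never observed at defaults) case the named
acids exceed 99.5%.

**Seeds.**  One master seed; every stage derives a deterministic 32-bit
child seed, so `simulate_dataset()` is byte-reproducible and stages can be
re-run independently.

# Quality control

Per SNP: call rate (non-missing fraction), MAF = min(p̄, 1−p̄) on
non-missing calls, and a Hardy-Weinberg p-value from the 1-df Pearson χ²
of observed vs expected genotype counts — the conventional deterministic
array-QC test; missing dosages are excluded from the denominators, not
imputed.  A SNP passes only if it *strictly* exceeds all thresholds
(defaults 0.9 / 0.02 / 0.001, matching the printed ">" criteria).  SNPs
with fewer than two calls fail with undefined metrics; monomorphic SNPs
get HWE p = 1 and fail on MAF.  A SNP failing several filters counts once
per filter and once overall.  Note that in a 48-family population genotype
frequencies genuinely deviate from Hardy-Weinberg proportions, so the HWE
filter removes a few hundred clean SNPs at defaults — the same mechanism
that trims a real sib-structured panel.

# GRM, PCA and REML

The VanRaden GRM uses allele frequencies computed from the analysed sample
(no external reference panel exists for this population) and mean-imputes
missing dosages to 2p, which contributes zero after centring.  Principal
components come from the GRM itself (the analysis computes nothing
upstream of it), scaled by √eigenvalue with the largest-magnitude loading
made positive for determinism.

Univariate GREML eigendecomposes the GRM once and iterates in the rotated
basis: one EM-REML step, then average-information updates with
step-halving, so accepted steps never decrease the restricted likelihood.
Convergence is a relative log-likelihood change below 1e-8 (cap 100
iterations; non-convergence is flagged, not thrown).  Components are
clamped at 1e-8 × phenotypic variance and flagged at the boundary, so null
simulations run unattended.  SEs come from the inverse AI matrix, SE(h²)
by the delta method.  A `log_transform` option refits log(y) — the
sensitivity analysis used for skewed traits.

The bivariate fit estimates full 2×2 genetic and residual covariance
matrices (residual covariance unconstrained, as both traits are measured
on the same fish).  With complete data the likelihood factorises through
the same eigenbasis into n 2×2 blocks; records missing one trait fall back
to a dense-likelihood path on observed records (the two paths agree to
numerical precision on complete data, which is itself a test).  Implied
correlations are clamped at ±0.999 to keep the covariance matrices inside
the PSD cone; clamping is flagged.  The first iteration uses an
EM-flavoured scaled-score step (the matrix analogue of the univariate EM
update) rather than a literal bivariate EM — with step-halving the
optimiser is monotone either way, and the univariate fitter implements the
literal EM first step.  One caveat found while testing: the *free* joint
fit's marginal components differ from the univariate fit by O(1e-3) at
n ≈ 600, because information flows through the sampled cross-covariances;
the exact identity — the bivariate likelihood factorising into the two
univariate likelihoods at zero cross-covariances — is what the test suite
asserts tightly.

# GWAS

Variance components are estimated once genome-wide and reused for every
leave-one-chromosome-out chromosome (the convention of the standard MLMA
implementation; per-chromosome re-estimation sits behind `per_chrom_vc`).
Per SNP, the allele-substitution effect and SE are exact GLS under
`V(−c) = G(−c)σ̂²_g + Iσ̂²_e`, computed via the eigenbasis of `G(−c)` with
the fixed effects projected out — verified against an explicit
full-matrix-inverse GLS oracle to 1e-8.  P-values are 1-df Wald χ² (no
score test in this version).  SNPs without a genome placement are tested
against the full GRM and reported as a separate stratum, mirroring the
"unknown placement" column of array annotations.  Bonferroni thresholds
divide α = 0.05 by the total and the average per-chromosome SNP count;
λ = median(χ²)/0.455.  The candidate-gene scan takes the top-10 SNPs
(ties: ascending p, chromosome, position, id) and intersects the closed
interval ±200 kb (clipped at 1) with gene intervals on the same
chromosome, via `GenomicRanges::findOverlaps`.

# Expression association and enrichment

Size factors are median-of-ratios over genes expressed in every sample;
the "normalised library size" is the size factor times the geometric-mean
depth, so doubling a sample's counts doubles its size factor and leaves
FPKM unchanged while a 10⁶-fragment library with a 1-kb, 100-count gene
still gives FPKM 100.  log2(FPKM + 1) is modelled (a pseudocount of 1, as
zero handling is otherwise unspecified).  Genes must show FPKM > 0 in at
least half the samples (the real pipeline's 1,872 → 1,781 QC step is
unspecified, so the filter is configurable and logged in the result).

The per-gene model profiles the family-to-residual variance ratio by REML
in the eigenbasis of the family incidence crossproduct — one 48×48
eigendecomposition shared across genes.  At ratio zero the fit *is*
ordinary least squares, bit-for-bit in β, SE and p; with 48 fish from ~48
families that boundary is the typical case, so it is a contracted, tested
path (and the profiled fit is cross-checked against `lme4::lmer` on a
family-signal fixture).  The default Wald reference is the standard normal
(large-sample χ²); `reference = "t"` uses the residual-df t distribution,
which is the calibrated choice at n = 48 and is what the null-uniformity
test uses.  Significance is raw p < 0.05 — no multiple-testing correction,
reproducing the published convention, which the user should keep in mind
when interpreting gene counts.

Enrichment tests each term's 2×2 table (in-term × significant) over the
background of all retained genes — the conventional reading of testing the
trait-associated set against its analysis background.  Terms with fewer
than five *background* genes are skipped before any p-value is computed
(the size rule is applied to the background, the less ambiguous reading).
Yates' correction is clamped at zero when it exceeds |ad − bc|; the
statistic can never exceed the uncorrected Pearson χ² (property-tested).

# Numerical choices and problem sizes

Tolerances: REML relative log-likelihood 1e-8; PSD checks at −1e-8;
GRM symmetry enforced by averaging; float32 on-disk GRM triangle
(round-trip tested to 1e-6).  The test suite runs the recovery studies at
the sizes the analyses are about: 20 replicates of 600 fish × 5,000 SNPs
for univariate (±0.05 band around h² = 0.38) and bivariate (±0.10 around
r_G = 0.70) recovery, ten 400-fish null-GWAS replicates for λ and type-I
calibration, and small instances (n ≤ 50) wherever an exact oracle
(double-loop GRM, full-inverse GLS, 50×50 likelihood grid, OLS limit,
hand-evaluated Yates formula) is compared to machine precision.

# Known limitations

- No population LD beyond family co-segregation; marker density effects on
  GWAS resolution are therefore not represented.
- The GWAS stage is validated for calibration and signal recovery on
  synthetic data; the real study's specific SNP hits cannot be reproduced
  without the original genotypes.
- The expression generator's Poisson counts have no extra-Poisson
  dispersion; the association stage models log2 FPKM, not counts, so this
  mainly understates low-count noise.
- Bivariate REML supports two traits; multi-trait (>2) models, dominance
  and epistatic components, and Bayesian estimation are out of scope.
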