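---
title: "Mapping genotype-by-watering-regime QTLs in structured tomato panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping genotype-by-watering-regime QTLs in structured tomato panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gxwqtl)
```

## The problem

Greenhouse panels of small-fruited tomato (wild *S. pimpinellifolium*,
*S. lycopersicum* var. *cerasiforme*, and admixed cherry types) respond to
deficit irrigation with trait changes that differ strongly between
accessions: fruit quality often improves while yield components decline,
and the balance is genotype-dependent. The standard design grows each
accession under a control (C) and a reduced-watering (D) regime with a
small number of replicate plants, and asks three questions:

1. how much of the phenotypic variation is genetic, and how much of the
   genotype-by-watering (G×W) interaction is re-ranking of accessions
   rather than a change of scale;
2. which markers tag QTLs for each trait, correcting for the strong
   genetic structure of such panels; and
3. how each QTL behaves across regimes — *constitutive* (same effect),
   *specific* to one regime, or *interactive*, the latter split into
   *differential* (intensity change) and *antagonist* (sign change).

`gxwqtl` implements this workflow end to end, plus a simulator that
generates panels with known QTL architecture so every stage can be
validated against ground truth.

## Phenotype dissection

Replicate-level values for one trait at one location are dissected with
the fixed-effects model

$$Y_{ijkl} = \mu + Gr_i + Gr_i(G_j) + W_k + Gr_i{\times}W_k +
Gr_i(G_j){\times}W_k + e_{ijkl},$$

where $Gr$ is the genetic group, $G$ the accession nested in its group and
$W$ the watering regime. `anova_partition()` reports Type I (sequential)
sums of squares in exactly this term order, as fractions of the total sum
of squares, with F-tests against the residual. Sequential SS in the
stated order is what the per-term "share of variation" framing requires;
locations are always analysed separately because trait sets differ
between trials.

Broad-sense heritability per regime comes from the REML fit of
`value ~ group + (1 | accession)` (`lme4`), with

$$H^2 = \frac{\sigma^2_G}{\sigma^2_G + \sigma^2_e / n},$$

where $n$ is the mean number of replicates per accession for that trait
(replication varies between plant traits and pooled fruit assays).
Plasticity is the relative accession-mean change
$\Delta_{ki} = (D_{ki} - C_{ki}) / C_{ki}$, computed on raw (untransformed)
means so that it keeps its interpretation as a relative change. The G×W
interaction is partitioned with genotypic standard deviations $s_C, s_D$
and the cross-regime correlation $r$ of accession means into a scale part
$(s_C - s_D)^2$ and a re-ranking part $2 s_C s_D (1 - r)$, normalized by
their sum; when both parts are numerically zero (relative to the
genotypic variances, tolerance $10^{-10}$) the fractions are reported as
$(0, 0)$ with a degeneracy flag rather than as $0/0$.

Skewed traits are transformed before modelling by a Box–Cox power chosen
from the grid $\lambda \in \{-2, -1.75, \ldots, 2\}$ to minimize the
absolute sample skewness — a "least skewed distribution" criterion rather
than maximum likelihood. One transformation is chosen per trait and
location on the pooled C+D data and shared by both regimes, so regime
means stay comparable.

## Genotype quality control and structure

Array genotypes are filtered in a fixed order: accessions with more than
25% missing calls, then markers with more than 10% missing calls, then
markers with minor allele frequency below 0.04 (computed on non-missing
calls after the accession filter). Remaining missing calls are imputed by
the marker mean dosage — twice the major-allele frequency on the major
coding — which is the imputation consistent with downstream linear
models. Markers are named `S<chrom>_<pos>` with two- and eight-digit
zero-padding (`S01_58000085`).

Kinship is identity-by-state allele sharing,
$K_{ij} = 1 - \overline{|x_i - x_j|} / 2$, a natural similarity for a
nearly homozygous panel; it is bent to positive semi-definiteness by
flooring eigenvalues at $10^{-6}$ before REML, since IBS matrices can be
slightly indefinite. Structure covariates are the first three principal
co-ordinates of the dissimilarity $1 - K$ (classical metric MDS via
`cmdscale`); three axes resolve the three-group structure of the default
panel.

LD between markers is the squared Pearson correlation of dosages
(composite LD). For near-inbred material this is numerically close to the
haplotype-frequency estimator, and it is what the interval machinery
needs; the approximation is the package's deliberate choice. The
*critical LD threshold* is the 95th percentile of $r^2$ over (by default)
100 000 random pairs of markers on different chromosomes — the level of
apparent LD generated by drift, sampling and structure alone. On an
unstructured panel this percentile approaches the asymptotic null
$\chi^2_1(0.95)/n = 3.84/n$; population structure pushes it up, which is
exactly why it is estimated from the panel itself.

## The univariate scan (multi-locus mixed model)

Accession means $y$ are modelled as

$$y = X\beta + g\,b + u + e, \qquad u \sim N(0, \sigma^2_g K), \quad
e \sim N(0, \sigma^2_e I),$$

with $X$ the intercept plus PCoA axes and $g$ one marker dosage at a
time. REML estimation uses a single eigendecomposition of $K$ and a
one-dimensional search over $\delta = \sigma^2_e/\sigma^2_g$ (100-point
log-grid on $[10^{-5}, 10^5]$ plus local refinement), after which every
marker test is a generalized-least-squares partial F-test in the rotated
(whitened) coordinates with residual degrees of freedom
$n - n_{\text{fixed}}$. The F form (rather than a $\chi^2$) matters at
$n \approx 141$. With $K = I$ the whitening is a rescaling and every
p-value equals the textbook OLS F-test — the closed-form oracle used in
the test suite.

The multi-locus scan (`mlmm_select()`) adds markers as fixed cofactors by
forward selection: at each step the most significant marker enters (ties
broken by lower chromosome, then position) and the variance components
are re-estimated. The path stops after five cofactors or when the
pseudo-heritability $1/(1+\delta)$ falls below 0.01. The retained
("optimal") model is the largest model along the path whose cofactors
*all* have drop-one partial p-values below $10^{-4}$ — a deliberately
permissive threshold that trades a few false positives for power in a
small panel, while the five-cofactor cap prevents overfitting. Drop-one
tests (rather than entry-order p-values) are used because the rule is a
property of the retained model. Forward-only selection is used; a
backward pass would rarely change the retained model under the all-
cofactors-significant rule and is not part of the selection criterion.
The scan is run per trait under C, under D, and on the plasticity values
$\Delta$, all with the same kinship and structure correction.

The global PVE of a trait's retained markers is the variance of their
jointly fitted (GLS) fixed component divided by the variance of the
covariate-adjusted phenotype, clamped to $[0, 1]$.

## The bivariate scan (multi-trait mixed model)

The same trait under C and D is treated as two correlated traits in a
stacked $2n$ model with genetic covariance $V_g \otimes K$, where

$$V_g = \begin{pmatrix} \sigma^2_{g,C} & \rho_g \sigma_{g,C}\sigma_{g,D} \\
\rho_g \sigma_{g,C}\sigma_{g,D} & \sigma^2_{g,D} \end{pmatrix},$$

and residual covariance $\mathrm{diag}(\sigma^2_{e,C},
\sigma^2_{e,D}) \otimes I$. The residual cross-regime covariance is fixed
at zero: the two regime phenotypes come from different plants, so a
shared residual is structurally absent (and unidentifiable here). The
five parameters are estimated once by REML under the no-SNP model (BFGS
on log-variance / $\tanh^{-1}\rho$ scale after rotating both trait
vectors into the eigenbasis of $K$, started from the univariate fits).

Per marker, three nested fixed-effect GLS models are compared under the
fixed fitted covariance: no SNP, one common effect, and separate
per-regime effects. The **global test** (common vs null, 1 df) detects
shared-effect markers; the **G×W test** (full vs common, 1 df) detects
regime-dependent effects. Both are partial F-tests with residual df
$2n - n_{\text{fixed}}$, the same convention as the univariate engine —
with the consequence, exploited by the tests, that when $\rho_g = 0$ and
the parameters are equal the stacked model factorizes and the global test
is *identical* to the univariate engine run on the stacked system.
Per-marker PVE is the partial $R^2$ of the added term in the whitened
model. This two-step scheme (variance components fixed from the null
model) keeps the scan $O(\text{markers})$.

**Degenerate input.** If the two trait vectors are numerically identical,
the bivariate REML is unbounded: the difference subspace has exactly zero
variance, which drives the residual variances to zero. `fit_mtmm_null()`
detects this and collapses exactly to the univariate model on the shared
trait ($\rho_g = 1$ boundary); `mtmm_tests()` then reports the univariate
p-values as the global test and $p_{G\times W} = 1$. This is the exact
limit of the model, not an approximation.

Markers significant in either MTMM test on the same chromosome with
pairwise $r^2$ above the critical threshold are merged into one QTL by
single linkage, represented by the most significant member. Single
linkage is the direct transitive application of the "two markers in LD
are one QTL" rule; a chain a–b–c merges even if a and c themselves fall
below the threshold.

## QTL intervals, effects and classification

The confidence interval of a significant marker extends to the *last*
marker on the chromosome, in each direction, whose LD with the peak is at
least the critical threshold — gaps of unlinked markers do not stop the
extension, matching long-range LD in strongly structured inbred panels.
With no linked marker in a direction the bound is the peak position.
Intervals are 1-based inclusive; gene counts over a GFF3 annotation use
any-overlap (a gene abutting the interval end counts). Lowering the
threshold can only widen an interval (a tested monotonicity property).

Allelic effects per regime are `(minor mean − major mean)/2` on raw
accession means, with carriers defined by rounded dosage on the
minor-allele coding; the few heterozygotes in a near-inbred panel are
counted on the carrier side (a documented, configurable-by-construction
convention — the field formula does not specify it).

Classification combines the five test outcomes: a marker significant on
the $\Delta$ scan and/or the G×W test is `interactive` — this takes
precedence, so the type assignment is mutually exclusive — with subtype
`antagonist` when the allelic effect changes sign between regimes and
`differential` otherwise; a marker significant under both regime scans or
under the MTMM global test is `constitutive` (MTMM-global detections are
absorbed here even when absent from the per-regime scans, since the
global test is precisely a shared-effect test); significance in exactly
one regime scan gives `control_specific` or `drought_specific`. For
cross-population comparison, pH and the organic-acid contents are grouped
as "acids", SSC and the sugar contents as "sugars", and two QTL sets
share a QTL when trait group and chromosome match and the intervals
overlap by at least one base pair, regardless of QTL type or trial
location.

## The simulator

`simulate_genotypes()` builds a panel that reproduces the statistical
features the pipeline is sensitive to:

* **Structure.** Three groups (default sizes 10/110/21 of 141) with
  Balding–Nichols group allele frequencies around ancestral frequencies
  $U(0.1, 0.9)$ at divergence `fst` (default 0.20) — enough for clear
  PCoA separation, as in real panels mixing a wild relative with
  cultivated groups.
* **LD.** Haplotypes follow a latent Gaussian AR(1) copula along each
  chromosome with correlation $\exp(-d/L)$, $L$ = `ld_block_length`
  (default 2 Mb on 65 Mb chromosomes). This realizes the intended
  "blocks of expected length $L$" as a smooth distance-decay, which is
  what the interval machinery actually probes; markers on different
  chromosomes are independent.
* **Inbreeding.** Each locus is forced homozygous with probability
  $F = 0.95$, reflecting near-inbred accessions and keeping dosage
  $r^2$ close to haplotype $r^2$.
* **Scale.** Twelve chromosomes with 508 markers each (~6100 genome-wide)
  at the default; tests use smaller maps since power depends on panel
  size and LD, not marker count.

`simulate_phenotypes()` adds, per regime, planted marker effects, a
polygenic term with covariance proportional to the *realized* kinship of
the simulated panel and cross-regime correlation `genetic_correlation`,
and replicate noise (2 plants per accession per regime). Defaults are
deliberate:

* `polygenic_h2 = 0.6` — mid-range of the broad-sense heritabilities
  (0.30–0.92) such trials report. Noise is scaled so the *realized* H²
  matches: because the heritability model fits the genetic group as a
  fixed effect, the polygenic draw is calibrated on its within-group
  variance (the between-group part of a kinship-structured draw would
  otherwise be absorbed by the group effect and the realized H² would
  undershoot).
* `genetic_correlation = 0.9` — high but imperfect. Trait re-ranking
  dominates the reported G×W interaction in such trials (interaction
  variance 1–19% of total), which requires a cross-regime genetic
  correlation clearly below 1; near-unity correlations of per-trait
  genetic *variances* across regimes are a different, weaker statement.
* **QTL classes.** `constitutive` plants equal effects, the `*_specific`
  classes one-regime effects, `antagonist` opposite signs of equal
  magnitude. Effects are calibrated in two passes against realized
  genotypic variances so each marker's realized PVE hits its target
  (±0.02) in the regime(s) where the class gives it a full-size effect.
  `differential` multiplies the calibrated control effect by 3 under
  drought: an intensity change must be of the order of the main effect
  to be a *detectable* interaction at $n = 141$, and the ratio is a fixed
  design constant. Its drought-regime realized PVE therefore exceeds the
  target; the truth table records both realized values.
* **Trait scale.** A baseline mean of 20 units (coefficient of variation
  ≈ 5%) and a −10% drought shift keep the plasticity denominator away
  from zero and give $\Delta$ values of realistic magnitude.

The same seed reproduces panels and phenotypes bit for bit.

### What the simulator does not emulate

Tomato demographic history, sequence-level mutation/recombination
processes, location effects (one location is simulated), trait networks
(each trait is generated independently), non-Gaussian trait
distributions, and genotyping error beyond simple random missingness.
Passing tests therefore show that the *statistical machinery* is correct
and calibrated under the stated generative model — not that real data
meet its assumptions (real traits may need the Box–Cox step, and real
panels have more complex relatedness than Balding–Nichols plus AR(1)
LD).

## Numerical choices

* $\delta$ search: 100-point log10 grid on $[10^{-5}, 10^5]$ plus
  `optimize()` refinement between the best grid neighbours; REML, not ML.
* Kinship bending: eigenvalue floor $10^{-6}$.
* Collinearity: a marker whose residualized whitened norm falls below
  $10^{-8}$ of scale (e.g. a duplicate of a cofactor) is reported as
  `NA` and flagged, never silently dropped.
* Ties in the forward step break by (chromosome, position), making the
  path deterministic.
* The MTMM optimizer rejects non-finite or runaway parameter values
  (|log-variance| > 40) with a large penalty, and its degenerate branch
  (identical traits) bypasses optimization entirely.
* Fractions (PVE, H²) are clamped to their defining ranges only at the
  reporting boundary, never inside the estimators.

## Validation strategy and problem sizes

The test suite validates each stage against an independent route: OLS as
the closed-form special case of the scan (141 accessions × ~500 markers);
exhaustive single-addition search as the forward-selection oracle (100
panels of ≤ 30 accessions × ≤ 12 markers); an explicit dense-GLS
`lm()` oracle for the stacked bivariate tests; hand-enumerated fixtures
for filtering, kinship, intervals, gene counts and classification (all
32 source combinations); and simulation-based calibration checks —
permutation type-I error and genomic-control $\lambda$ over 20 seeds, and
detection/typing of all four planted QTL classes at per-regime PVE 15%
over 50 seeds, with realized-H² recovery. These sizes keep the whole
suite at a few minutes on one core while leaving the power checks at the
study's own sample size.

One boundary is worth stating plainly: at PVE 15% and $n = 141$, a QTL
whose effect exists in only one regime *is* a strong G×W signal — the
effect difference equals the whole effect, while the correlated polygenic
background cancels from the contrast. The plasticity scan and G×W test
therefore fire for most such QTLs, and the precedence rule types them
`interactive` rather than `*_specific`. The regime-specific label is, in
this framework, the label of a QTL whose interaction evidence is *below*
the detection threshold; with well-powered planted effects the
interactive label is the statistically faithful outcome. The acceptance
checks report this boundary honestly rather than relaxing the
classification rule.

## Known limitations

* Composite (dosage) $r^2$ slightly underestimates haplotype LD when
  heterozygosity is appreciable; the panel model (F = 0.95) makes this
  negligible here but the approximation is load-bearing for outbred data.
* The two-step MTMM (variance components from the no-SNP model) is the
  standard fast approximation; exact per-marker REML would change
  p-values marginally near the significance boundary.
* PVE estimators (partial $R^2$ in the whitened model; global PVE on the
  covariate-adjusted scale) are conventions — the literature rarely
  defines them precisely — and are documented rather than claimed
  canonical.
* `run_pipeline()` analyses locations independently and does not fit
  multi-location joint models.
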