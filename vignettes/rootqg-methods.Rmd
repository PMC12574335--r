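---
title: "Root shape quantitative genetics with rootqg: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Root shape quantitative genetics with rootqg: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootqg)
```

`rootqg` implements the full analysis chain used in image-based
quantitative genetics of storage-root shape: silhouette phenotyping,
multi-environment mixed-model trait decomposition, population-structure
inference, kinship-corrected genome-wide association, and genomic
prediction, with a synthetic-data generator that gives every stage a
ground-truth recovery test. This vignette documents the models, the
numerical choices, and the limits of what the synthetic tests demonstrate.

## The synthetic panel generator

`generate_population()` draws a structured diploid panel under the
Balding–Nichols model. Ancestral allele frequencies are uniform on
[0.1, 0.9]; each of the $K$ populations receives frequencies
$f_{kj} \sim \mathrm{Beta}\!\big(p_j\tfrac{1-F}{F},\,(1-p_j)\tfrac{1-F}{F}\big)$,
whose variance is $F\,p_j(1-p_j)$, so the parameter $F$ is the expected
fixation index among the ancestral populations. Ancestry proportions are
Dirichlet($\alpha$) — small $\alpha$ gives near-pure individuals, large
$\alpha$ heavy admixture — and dosages are
$g_{ij} \sim \mathrm{Binomial}(2, \sum_k q_{ik} f_{kj})$. Marker positions
are uniform within chromosomes. Markers are therefore exchangeable and
*unlinked* given the population structure: linkage-disequilibrium machinery
(pruning, decay) is exercised on structure-induced and explicitly
constructed correlation, not on recombination-generated haplotype
structure.

`simulate_phenotypes()` generates long-format observations from the
additive multi-environment model described below, with independent normal
draws at configurable variances for environment, genotype-by-environment,
block-within-environment, plot, and residual, and a genetic value equal to
the causal-dosage sum plus an optional polygenic normal term. The default
design — 4 environments (two locations in two years), 3 randomized
complete blocks, one plot per accession per block — mirrors a typical
multi-environment diversity-panel trial of this kind. With one root per
plot the plot effect is not identifiable and is dropped from model fits
with a logged message.

### Root silhouettes

Silhouettes are defined by four parameters: length, maximum width, bulge
position, and a taper exponent, in one of four profile families for the
half-width $w(t)$ at fractional depth $t$ from the crown:

* **globose** — a parabolic-power bulge $(4m(1-m))^e$ where the depth warp
  $m(t)$ peaks at the bulge position. With exponent $e = 0.5$ (default) and
  the bulge at 0.5 this is an exact circle, which makes closed-form checks
  (sphere: log length-to-width ratio 0, width at 50% = diameter) exact
  rather than approximate. A raised-cosine bulge was considered and
  rejected for that reason.
* **cylindrical** — constant width with a flat bottom by default. A
  rounded elliptical tip cap is available (`cap_fraction`), but the flat
  bottom is the default because it preserves the analytic area $W \cdot L$
  and the closed-form tip angle $2\arctan\!\big(\tfrac{W/2}{0.1L}\big)$.
* **conical** — linear taper $(1-t)$ (exponent configurable).
* **taproot** — a sharper power taper (default exponent 2.5) with the
  constraint $W/L < 0.15$, representing unswollen wild-type roots.

`render_root_mask()` rasterizes with midpoint sampling: a pixel is
foreground when its center lies strictly inside the analytic half-width of
its row, with the silhouette centered between two pixel columns so fills
are symmetric. Rows whose analytic width is positive but below one pixel
are painted as a two-pixel center line; this preserves the rendered length
of thin power-law tips (on which the length-to-width ratio depends) at the
cost of a small area overestimate confined to sub-pixel regions. The 2%
area-fidelity guarantee therefore applies where the local width exceeds
the pixel size — true for the globose, cylindrical, and conical test
solids at 0.5 mm/px — and the overall mask area still converges to the
analytic profile integral as the pixel scale shrinks.

## Shape phenotyping

`extract_contour()` keeps the largest connected component (a tie between
equal-size components is an error), fills interior holes (the digital
biomass is the area of the filled silhouette), and anchors the crown and
tip at the midpoints of the topmost and bottommost foreground row spans.
Images are assumed axis-aligned with the crown up; no reorientation is
attempted, matching a fixed imaging rig.

The six traits are: digital biomass (foreground area, mm²), length
(vertical crown-to-tip anchor distance, mm), maximum width (largest
horizontal foreground extent over all rows, mm), width at 50% length,
$\ln(\mathrm{length}/\mathrm{max\ width})$, and tip angle. Width at a
station is the horizontal *extent* (rightmost minus leftmost column plus
one pixel), i.e. a diameter, not a sum of runs. Profiles are sampled at
$S = 101$ stations ($t = 0, 0.01, \dots, 1$), enough to resolve typical
root heights without oversampling.

The tip angle is the interior angle at the tip anchor subtended by the
left and right contour points 10% of the length above the tip. The flank
points are placed on the outer pixel *edge* (half a pixel beyond the
outermost foreground center): the mask boundary, not the last pixel
center, is the silhouette outline, and this convention makes the
flat-bottomed cylinder give exactly 90° and a 40-mm-wide, 100-mm cone
exactly $2\arctan(2/10) = 22.62°$.

The contour score is PC1 of the station-wise width profiles after each
profile is normalized by its own maximum width (a size-independent
descriptor). The sign is fixed so positive scores track crown-ward mass
(widths at $t < 0.5$ minus $t > 0.5$); per-root scores can be obtained by
projecting onto loadings fitted once at the dataset level, so all roots
live in a single population-level shape space. Whether the original
score used PC1 alone or a combination of components is not restated in the
source material; PC1 is used here and the variance share is reported
alongside.

`outlier_filter()` removes observations whose absolute z-score strictly
exceeds 3 (configurable), with the mean and the *population* standard
deviation (divisor $n$) computed in a single pass over the unfiltered
data; a value exactly at the threshold is kept, and a zero-variance trait
removes nothing.

## Trait modeling

For each trait the model is

$$y_{ijkl} = \mu + g_i + e_j + (g{\times}e)_{ij} + b_{k(j)} + p_{l(jk)} + \varepsilon_{ijkl},$$

with environment ($e_j$), interaction, block-within-environment, plot, and
residual random. Two fits are made per trait, because the analysis needs
both faces of the genotype term: **fixed** genotype for BLUEs (the GWAS
phenotypes), and **random** genotype for the genetic variance, BLUPs, and
heritability. REML estimation is performed by `lme4` — the standard,
heavily validated fitter for exactly this model class. What `lme4` does
not expose is the full prediction-error *covariance* of the genotype
BLUPs, so `rootqg` rebuilds Henderson's mixed-model equations at the
converged variance components and inverts the genotype block:
$\mathrm{PEC} = \hat\sigma^2_\varepsilon\, C^{gg}$. The Cullis broad-sense
heritability is then

$$H^2 = 1 - \frac{\mathrm{PEV}}{\hat\sigma^2_g}, \qquad
\mathrm{PEV} = \tfrac12\,\overline{\mathrm{Var}(\hat u_i - \hat u_j)},$$

the average taken over all accession pairs, clamped to [0, 1], with
$H^2 = 0$ by convention when $\hat\sigma^2_g = 0$. Using the pairwise
definition (not just the diagonal of the PEC) is what makes the statistic
exact under unbalanced designs.

Per-environment BLUEs refit
$y = \mu + g_i + b_k + p_l + \varepsilon$ within each environment
(genotype fixed, block/plot random; single-block environments fall back to
accession means; missing accession-environment cells are left missing).
Finlay–Wilkinson stability regresses each accession's per-environment
value on the environment mean — by default over the complete-replication
subset, mirroring the practice of restricting to accessions present in
every environment — so a slope of 1 is average environmental sensitivity.
Environment-pair trait correlations are Pearson over shared accessions.

## Population structure

Marker QC follows the panel rules: biallelic/polymorphic, at least five
individuals per homozygous class, and modal genotype frequency at most
$1 - 5/N$; read-depth and genotype-quality minima apply when those tags
are present. LD pruning scans markers in position order and drops a marker
whose squared dosage correlation (composite LD — phase is unknown in
dosage data) with any retained marker within the window exceeds the
cutoff; this marker-anchored scan is the dense limit of a sliding window
and is verified against a brute-force oracle.

`admixture_em()` maximizes the binomial admixture likelihood
$\sum_{ij} \big[g_{ij}\ln(\textstyle\sum_k q_{ik}f_{kj}) + (2-g_{ij})\ln(1-\sum_k q_{ik}f_{kj})\big]$
by the classical multiplicative EM updates, which are monotone in the
log-likelihood at every iteration; three random restarts (Dirichlet(1)
starts for $Q$, jittered observed frequencies for $F$) guard against local
optima. The number of populations is chosen by entry-level
cross-validation: random folds of accession-by-marker *cells* are masked
out of the likelihood, and held-out cells are scored by binomial deviance
against the predicted dose $2\sum_k q_{ik}f_{kj}$; the $k$ with the
smallest mean deviance is selected. CV refits use a single restart and a
looser tolerance — model ranking, not parameter precision, is what the CV
needs.

Nei's (1972) standard distance is
$D = -\ln\!\big(J_{xy}/\sqrt{J_xJ_y}\big)$ over biallelic gene
identities; pairs sharing no alleles have infinite distance and are capped
at $-\ln(\epsilon_{\mathrm{machine}})$ with a warning, since
neighbor-joining needs finite input. Trees are built with the Saitou–Nei
algorithm (`ape::nj`, the canonical implementation); negative branch
lengths, which NJ can produce on non-additive input, are clamped to zero
with the deficit transferred to the adjacent branch so path lengths
through the node are preserved. Additive matrices are recovered exactly.

### The Fst estimator

Two estimators are provided. The default (`method = "nei87"`) is the
sample-size-corrected estimator in the lineage of Nei (1987) used by the
standard pairwise-Fst implementations: per locus,
$H_S = \tfrac{2\tilde n}{2\tilde n - 1}\,\overline{2p_kq_k}$ with
$\tilde n$ the harmonic mean sample size,
$H_T = 2\bar p\bar q + H_S/(4\tilde n)$,
$D'_{ST} = \tfrac{k}{k-1}(H_T - H_S)$ (the two-population correction), and
$F_{ST} = \sum_l D'_{ST}/\sum_l (H_S + D'_{ST})$ as a ratio of sums.
The $k/(k-1)$ correction matters: for two demes the uncorrected Nei (1973)
$G_{ST}$ has expectation $F/(2-F)$ under the Balding–Nichols model
(about 0.11 at $F = 0.2$), while the corrected estimator's expectation is
$F$ itself — which is why the generator's recovery tests return the
simulation parameter. The uncorrected $G_{ST}$
(`method = "gst"`) is retained for hand-checkable arithmetic
(e.g. $p_1 = 0.2, p_2 = 0.8$: $H_T = 0.5$, $H_S = 0.32$,
$G_{ST} = 0.36$). Estimates are clamped to [0, 1].

## Genome-wide association

Kinship is VanRaden's $K = WW^{\top} / (2\sum_j p_j(1-p_j))$ on
frequency-centered dosages, with monomorphic markers skipped;
leave-one-chromosome-out kinship (`K-LOCO`) excludes the tested marker's
chromosome, avoiding proximal contamination. The scan is EMMA-style: the
null model $y = X_0\beta + u + \varepsilon$,
$\mathrm{Var} = \sigma^2_g K + \sigma^2_e I$, is fitted once per trait
(per chromosome for LOCO) by REML on the spectral decomposition of $K$,
with the variance ratio optimized by bounded scalar search over
$\log\delta \in [-25, 25]$ at tolerance $10^{-8}$ — a range wide enough
that data without genetic covariance collapse numerically to ordinary
least squares. Each marker is then tested by generalized least squares in
the rotated space with a Wald $t$-test (single-pass speed, the standard
choice in this scan family); the residual scale is re-estimated per
marker. Markers collinear with the covariates are skipped and logged. The
scan is verified against a dense-matrix GLS oracle to $10^{-6}$ and
calibrated on structured nulls (inflation $\lambda \approx 1$, type-I
error at the nominal 5%).

Supporting statistics: the Bonferroni threshold $-\log_{10}(\alpha/m)$;
the inflation factor $\lambda$ as the no-intercept regression slope of
sorted observed on expected $-\log_{10}p$ (uniform order-statistic
quantiles $(i-0.5)/n$); and per-marker variance explained
$\mathrm{PVE} = 100\,\hat\beta^2\mathrm{Var}(x)/\mathrm{Var}(y)$, capped
at 100 — a deliberately simple single-marker formula, since the internal
PVE computations of the upstream GWAS tools it stands in for are not
published.

Consensus QTL calling implements the two-model/two-panel rule: a marker is
called when it reaches its panel's threshold in at least two models within
a panel, or in at least one model of each of two panels. Passing markers
within 100 kb (default) on a chromosome merge into one call — the default
radius motivated by treating associated markers some 80 kb apart as a
single locus — and reported scores and PVE are means over the supporting
significant entries. Output is invariant to table order. LD decay bins
pairwise $r^2$ by distance, smooths the bin means with an isotonic
non-increasing fit, and reports the first bin midpoint below the
$r^2 = 0.1$ target as the block size.

## Genomic prediction and annotation

RR-BLUP solves $y = \mu + Wu + \varepsilon$ with
$u \sim N(0, \sigma^2_uI)$ on column-centered dosages. The ridge parameter
$\lambda = \sigma^2_e/\sigma^2_u$ is estimated by REML through the
eigendecomposition of $WW^{\top}$ (the kinship form), after which
$\hat u = W^{\top}(WW^{\top} + \lambda I)^{-1}(y - \hat\mu)$ and
$\mathrm{GEBV} = W\hat u$ — algebraically identical to GBLUP, an identity
the tests verify to $10^{-8}$. Cross-validation uses random 80/20
train/test splits; accuracy is the mean Pearson correlation between
predicted and observed test values over replicates, and $r^2$ its square.
The replicate count defaults to 50 (the source analysis does not state
one); pipeline demonstrations use 10 for speed and report the standard
error of the mean alongside.

Candidate genes are those whose bodies intersect the closed window
±500 kb around a QTL position (gene-body intersection, not gene start;
marker-anchored, since anchoring at an LD-block edge is not specified
anywhere and the window size is configurable). Target designation is an
input — an expert-curated id list — not something the package infers. GO
enrichment is a one-sided Fisher exact test per term on the
target/background × annotated/not table over the gene universe, ranked by
p-value; no topology weighting and no multiple-testing correction are
applied, matching the reporting of raw Fisher p-values (the
topology-aware weighting of specialized GO tools is deliberately out of
scope and results are labeled plain-Fisher).

## The pipeline and its demonstration run

`run_pipeline()` executes simulate → phenotype → model → structure → GWAS
→ predict → annotate from a single validated `run_config()`, writing each
stage's artifacts to fresh files (no stage mutates another's inputs) and
returning a report with per-stage summaries and an md5-checksummed
manifest; identical configurations and seeds give byte-identical outputs.
All stage seeds derive deterministically from the single global seed. The
GWAS stage runs two panels — the full panel and the largest inferred
population as a subset, each re-filtered and with its own Bonferroni
threshold — times two models (K, K-LOCO), feeding the consensus rule.

In the built-in synthetic demonstration, two latent genetic traits (log
length and log width) carry the causal markers; each observation's latent
values become `shape_params` (family assigned per accession from its
expected length-to-width ratio), masks are rendered and measured, and the
measured traits drive all downstream stages. Because digital biomass is
the *product* of length and width, its observation noise compounds
multiplicatively, and its cross-validated prediction accuracy falls below
that of the log length-to-width ratio — the qualitative contrast the
demonstration is designed to show. Default demonstration sizes (100
accessions, 1200 markers on 5 chromosomes, 2 environments × 2 blocks × 2
roots) keep a full run under a minute; recovery studies in the test suite
use 200 accessions × 4 environments × 3 blocks for variance components,
10 seeds for calibration loops, and 5000 markers × 20 replicates for Fst
— sizes chosen so each estimate's sampling error is comfortably inside
the tolerance it is checked against.

## Known limitations

* The generator produces unlinked markers given ancestry; recombination
  LD, allele-frequency spectra from real demography, and GBS artifacts
  (depth-dependent missingness, genotyping error) are not emulated, so
  passing recovery tests demonstrates correctness of the estimators, not
  robustness to those data pathologies.
* Masks are clean binary silhouettes: segmentation noise, lateral roots,
  soil residue, and perspective distortion are out of scope (inputs are
  assumed pre-cleaned, as with a fixed imaging rig).
* The mixed model assumes homogeneous residual variance across
  environments and no spatial field trend.
* PVE is the single-marker regression formula; exact reproduction of
  tool-internal PVE values from external GWAS software is not attempted.
* The taproot family's sub-pixel tail makes its rendered area biased high
  by a few percent at coarse scales (see the renderer notes above).
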