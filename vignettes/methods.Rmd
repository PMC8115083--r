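---
title: "Models and methods behind ricegq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ricegq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the places where
the design was genuinely open and a choice had to be made.

## 1. Starch hydrolysis kinetics and predicted GI

Cooked rice starch digested by amylases releases glucose that is sampled at
30, 60, 90, 120 and 180 minutes. Glucose mass is converted to anhydrous
starch equivalents by the stoichiometric factor 0.9 (162/180: one water per
glycosidic bond), and the percent of total starch hydrolyzed is assumed to
follow first-order kinetics toward a plateau,

$$C(t) = C_\alpha\,(1 - e^{-kt}),$$

with $C_\alpha$ the equilibrium percent hydrolyzed (unitless %, bounded
[0, 110] to absorb assay noise above 100) and $k$ the kinetic constant
(min$^{-1}$, bounded (0, 1]). The model assumes a single exponential pool —
adequate for milled rice flour, not for intact kernels with multi-phase
digestion.

**Fitting.** Least squares, but not a generic 2-D optimizer: for fixed $k$
the model is linear in $C_\alpha$, so $C_\alpha$ is profiled out
analytically and the search is one-dimensional in $k$ (80-point log-spaced
grid bracket + golden-section refinement, tolerance 1e-12). This recovers
noiseless curves to better than 1e-6 relative error and cannot be trapped
by a bad 2-D start. An all-zero curve returns $C_\alpha = 0$ with the rate
flagged unidentifiable; a $k$ pinned at a search boundary also clears the
`identifiable` flag. The source protocol defines $C_\alpha$ once as the
180-min value and once via the 120-min reading — a contradiction we do not
try to resolve: the default is the *fitted asymptote*, and
`fit_first_order(..., calpha = "plugin")` exposes the observed-end-point
alternative.

**AUC, HI, PGI.** The area under $C(t)$ on $[t_0, t_f] = [0, 180]$ min has
the closed form $C_\alpha(t_f-t_0) - (C_\alpha/k)(1-e^{-k(t_f-t_0)})$
(checked against quadrature to 1e-6 relative in the tests). The hydrolysis
index is the sample AUC as a **percent** of a white-bread reference AUC.
The percent convention is forced by arithmetic: with PGI = 39.7 + 0.548·HI
and observed panel PGIs up to ~100, HI must reach ~110 — impossible for a
bare ratio ≤ ~1. The reference can be a flagged curve (fitted with the same
machinery) or a precomputed AUC; the simulator's convention for a bread
reference is $C_\alpha = 100$, $k = 0.025$. GI classes band at < 55 (low)
and > 70 (high); only the low bound is printed in the source protocol, 70
is the conventional upper bound.

**RS assay.** GOPOD absorbance minus blank, times the glucose-per-
absorbance calibration factor and the assay dilution, gives glucose
micrograms; times 0.9, over sample mass, gives RS%. The kit's exact
volumetric factors are not published for the down-scaled assay, so they are
explicit parameters rather than baked-in constants. Negative net
absorbances clamp to zero with a warning.

## 2. Trait statistics

LBR = KL/KB and LER = KLAC/KL are the standard rice-quality definitions
(the source names but never defines them). Gel-consistency banding has
printed gaps (40–41, 60–61) and a floor at 25 mm while panel minima go
lower; we band half-open at 41 and 61 and classify below-25 values as hard
with a below-scale warning, so every positive gel length classifies.
Correlations are pairwise-complete Pearson with two-sided t-tests and
stars at 0.05/0.01; missing-data handling is unstated in the source, and
pairwise deletion is the least-surprising default. Constant columns yield
`NA` rather than an error.

## 3. Genotype QC and IO

Calls are alt-allele dosage {0, 1, 2, NA}; the panel is inbred, so
heterozygotes are legal but rare. The QC filter keeps markers with
**alternative**-allele frequency ≥ 0.01 (taken literally — not minor; a
`freq = "minor"` option exists) and missingness ≤ 0.2, frequency computed
over non-missing calls; a marker failing both is attributed to the
frequency rule. The filter is idempotent. VCF parsing is delegated to
VariantAnnotation (phased ≡ unphased; multi-allelic records dropped and
counted), GFF3 to rtracklayer; the package's own writers emit minimal
VCF 4.2 / GFF3 text and are round-trip-tested against those readers.
Annotation (exonic, nonsynonymous, indel, containing gene) travels in VCF
INFO flags. All coordinates are 1-based inclusive throughout.

## 4. Mixed-model GWAS

The phenotype model is $y = Q\beta + u + e$ with $u \sim N(0, \sigma_g^2
K)$, $e \sim N(0, \sigma_e^2 I)$; $K$ is the VanRaden genomic relationship
matrix and $Q$ an intercept plus top genotype principal components (the
standard stand-in for a STRUCTURE Q-matrix, whose source data do not
exist). REML is profiled onto $\delta = \sigma_e^2/\sigma_g^2$ through the
eigendecomposition of $K$ and maximized over $\log\delta \in [-5, 5]\ln 10$
by a 41-point grid plus Brent refinement — the returned likelihood is
checked in the tests against a dense-matrix oracle and against random
$\delta$ draws.

**Scan.** Variance parameters stay fixed at the null fit (P3D), the data
are whitened by the null covariance, and each marker gets an OLS t-test
(df = n − q − 1). Exact per-marker REML is available via `p3d = FALSE`.
Missing calls are mean-imputed, monomorphic markers skipped, and a marker
collinear with the covariates is reported with β = 0, p = 1 (documented
contract, not an error). By default the *pipeline* scan is
leave-one-chromosome-out: the kinship used to test chromosome $c$ is
rebuilt from all other chromosomes. Including the tested marker's own
chromosome lets the polygenic term absorb part of its effect (proximal
contamination); in our power measurements this cost real detections, and
LOCO is the field-standard remedy. The plain full-kinship scan remains
exported and is the operation pinned by the GLS-whitening oracle tests.

**Thresholds.** Suggestive associations at −log10(p) strictly > 5;
multi-locus confirmation at LOD strictly > 3. The multi-locus stage is a
documented stand-in for the mrMLM family: forward selection on the
whitened data (entry at partial-F p < 0.01, capped at n/2 terms), then per
candidate LOD = $\tfrac{n}{2}\log_{10}(\mathrm{RSS_{reduced}} /
\mathrm{RSS_{full}})$ — the Gaussian likelihood-ratio in LOD units —
dropping retained markers from, or adding unselected ones to, the joint
model. Optional peak grouping keeps the smallest-p record per 1 Mb window.

**Effects.** PVE = 100·β̂²·Var(g)/Var(y) (one of several GAPIT-era
conventions; outputs are labeled, and the quantity is invariant to affine
rescaling of y). The per-allele effect is the carrier mean minus the grand
mean — the cited formula is not printed, and this choice reproduces the
published sign semantics (a favorable allele "decreases PGI by −2.91").
Favorable directions: up for AC, KL, LBR, ASV, KLAC, LER, GC, RS; down for
KB, KBAC, PGI. Candidate genes: containment wins; intergenic markers get
both flanking genes with distances.

## 5. Haplo-pheno analysis

Gene haplotypes are exact joint patterns over the gene's exonic
nonsynonymous/indel variants. Accessions with a missing call in the gene
are excluded rather than pattern-matched — missing-as-state would mint
phantom haplotypes, and post-QC missingness in an inbred panel is low.
Labels H1, H2, … follow descending carrier count (ties by first
occurrence), so label identity is structural, not nominal: published
SNP-seek labels will not match, only counts/frequencies/superiority are
comparable. The SNP-seek Calinski k-grouping step is deliberately not
emulated; exact-pattern grouping is a documented divergence.

Haplotypes carried by ≥ 2 lines enter a one-way ANOVA; Duncan's multiple
range test then assigns letters. For a span of $p$ ordered means the
shortest significant range is $R_p = q(1-\alpha_p, p, \nu)\sqrt{MSE/n_h}$
with protection level $\alpha_p = 1-(1-\alpha)^{p-1}$ and $n_h$ the
harmonic mean of the group sizes in the span (Kramer adjustment — the
source is silent on unequal n). A span inside a non-significant span is
never declared significant; maximal homogeneous spans become letters. The
superior haplotype is the best tested mean in the trait's favorable
direction, ties broken by larger n then lower label index, flagged "not
separated" when it shares a letter with every rival.

## 6. The synthetic panel: what it emulates, what it does not

The generator states a world once and the tests live in it:

* 150 inbred accessions in the panel's 8 named subpopulations, split as
  evenly as possible; dosages drawn per subpopulation from Balding–Nichols
  frequencies (Beta with mean $p$ and variance $F\,p(1-p)$). Divergence
  default **F = 0.15** — subspecies-level differentiation in rice — chosen
  a priori; neither source states a generative model.
* Ancestral frequencies uniform on [0.05, 0.5]; missingness uniform at
  2%; heterozygosity 0 by default.
* Traits are standardized liabilities — planted QTL terms at
  $\sqrt{\mathrm{PVE}/100}$ times the standardized dosage, a polygenic
  term with covariance proportional to the realized kinship at fraction
  h² = 0.4, iid noise for the rest — affine-mapped so the mean sits at the
  published range midpoint and 3 SD span the half-range, then clamped to
  the published ranges (ASV rounded to its 1–7 score). Only ranges are
  published, so realism is nominal: no skew, no season effects, no
  QTL-by-environment interaction, and clamping slightly compresses tails.
* Hydrolysis curves: exact first-order glucose values on the 5-point grid
  plus additive Gaussian noise truncated at zero (default SD 1
  glucose-percent unit; the error model is unstated in the source).
* Gene models: non-overlapping single-exon blocks of consecutive markers
  with a 100 bp margin; in-gene markers flagged nonsynonymous-exonic at a
  configurable rate. No introns, no strand-dependent coordinates, no LD —
  markers are exchangeable given subpopulation frequencies (stated
  non-goal).

A green test therefore establishes that the *pipeline arithmetic and
inference behave as specified under this stated world* — it does not
certify performance on real 3K-RGP data, whose LD, allele-frequency
spectrum and trait distributions are richer.

## 7. Numerical choices and degenerate inputs

* Kinetics: 1-D profiled search, k-grid 1e-6…1, `optimize` tol 1e-12.
* REML: log-δ grid of 41 points over ±5 decades, Brent tol 1e-8; eigenvalues
  clipped at 0; falls back to the best grid point if refinement ties.
* Scan: p-values floored at `.Machine$double.xmin` before −log10.
* Duncan: letter construction from maximal homogeneous spans; identical
  means always share a letter; MSE ≤ 0 or df < 1 is an error upstream and
  a "letters omitted" notice in the table wrapper.
* Haplotype calling: empty variant set → everyone H1; all-missing
  accession → excluded with reason.
* Config: JSON (jsonlite) rather than YAML/TOML — the only key-value
  format guaranteed in the deployment environment; thresholds echo into
  every run manifest with per-file MD5s.
* Seeds: every simulator takes an explicit integer seed; pipeline stages
  derive offsets (+1 phenotypes, +2 gene models, +3 curves) from the run
  seed, keeping all derived seeds well under 2³¹.

## 8. Known limitations

* The mrMLM stand-in shares thresholds and intent with the published
  multi-locus models, not their empirical-Bayes machinery; LOD values are
  comparable in spirit only.
* PVE conventions differ across GWAS tools; ours is one defensible choice
  and labeled as such, so published PVE ranges are structural anchors, not
  reproduction targets.
* Published headline numbers (41 MTAs, specific haplotype means and
  letters) require the unreleased panel data and are out of scope by
  design.
* `scan_mlm` assumes a complete phenotype vector; drop or impute missing
  trait values before scanning.
* The RS stage implements assay arithmetic only; enzymatic chemistry,
  wet-lab QC and instrument drift are out of scope.
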