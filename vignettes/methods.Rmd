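---
title: "Models and methods behind introshell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind introshell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(introshell)
```

`introshell` quantifies *Mytilus trossulus* (MT) introgression in cultivated
blue-mussel stocks and links it to cultivation depth and shell phenotypes.
This vignette documents the models, the tunable parameters and their
defaults, the numerical conventions, and what the synthetic-data generator
does and does not emulate.

## Introgression statistics

Genotypes at taxon-diagnostic biallelic loci are stored as the dosage of the
MT-diagnostic allele within the genotype, 0 / 0.5 / 1 (or `NA`), mirroring
how such matrices are displayed as heatmaps so that statistics and graphics
share one representation. For an individual genotyped at $M$ retained loci,
with $n_{XY}$ heterozygous and $n_{XX}$ homozygous loci for the MT allele,

$$H_O = \frac{n_{XY}}{M}, \qquad
  HI = \frac{n_{XY} + n_{XX}}{M}, \qquad
  MT_{AF} = \frac{n_{XY} + 2\,n_{XX}}{2M},$$

so $MT_{AF} = HI - H_O/2$ holds identically; the package asserts this
identity per individual and per stratum mean. $M$ counts only non-missing
retained loci, which makes $MT_{AF}$ robust to per-individual missingness at
the price of varying denominators. Carriers are binned on $MT_{AF}$ with
half-open intervals $(0, 0.10)$, $[0.10, 0.50)$, $[0.50, 0.75)$,
$[0.75, 1]$; published tables of this kind leave edge membership undefined,
so the edges here were fixed once for determinism. An individual is flagged
`f1_like` when $0.35 \le MT_{AF} \le 0.5$ and at least 80% of its
MT-carrying loci are heterozygous — an operationalisation of the qualitative
"predominantly heterozygous, intermediate allele frequency" signature of
first-generation hybrids.

**QC order.** Loci are filtered before individuals: assay flags first
(cluster failure, false calls, ambiguous genotypes), then the missing-data
threshold (default 0.2) computed over all individuals; individual missing
fractions are then computed over the *retained* panel. The order matters
when a failing locus drives individuals over the threshold; filtering loci
first is the choice here because locus failures are assay properties, not
sample properties. The filter is idempotent: re-running it on its own output
changes nothing. Ambiguous-genotype loci are an input flag, not inferred —
detecting them requires the underlying fluorescence data, which the package
does not model.

**Heatmap ordering** uses agglomerative hierarchical clustering with
Euclidean distance and complete linkage on rows and columns, with missing
dosages imputed as 0 *for the distance computation only*. The linkage and
metric are a fixed convention (the displays this mirrors do not document
theirs); ties resolve by input order, so the leaf order is deterministic.

## Depth models

The odds of carrying MT alleles are modelled by a grouped binomial logistic
regression on depth, treated as a continuous covariate in metres. The slope
is reported as a multiplicative odds factor per metre with a Wald 95% CI —
Wald rather than profile intervals because the reported quantity is
symmetric on the log-odds scale, and for these group sizes the two coincide
to three decimals. Complete separation aborts with an explicit error rather
than returning runaway coefficients. The quasibinomial variant shares the
mean model (hence identical point estimates) and estimates the dispersion
$\phi$ as Pearson $\chi^2 / (n_{\text{groups}} - k)$, scaling standard
errors by $\sqrt{\phi}$.

Class-by-depth contingency tables are tested Fisher-style: exact
hypergeometric for 2×2; for larger tables a Monte-Carlo estimate with fixed
margins (sampled by `r2dtable`), default 100 000 tables, seeded, reported
with its binomial Monte-Carlo standard error. Network-algorithm enumeration
was deliberately not implemented; at these table sizes the MC error
(≈ 0.0014 at p ≈ 0.27) is far below any interpretive threshold.

Shell strength is normalized per cm of shell length
(`force_kg / (SL_mm / 10)`, kg cm⁻¹ SL) and modelled by OLS; candidate
models (e.g. `MT_AF * depth` vs `MT_AF + depth`) are ranked by Gaussian AIC
in which the residual variance counts as a parameter, exactly as
`stats::AIC()` counts it. With a true additive model the superfluous
interaction term wins AIC only when its likelihood-ratio statistic exceeds
its 2-point penalty, an event of probability $P(\chi^2_1 > 2) = 0.157$; the
test suite checks the additive win rate against that theoretical 84.3%
rather than against an arbitrary higher figure. Collinearity among shell
traits is screened by pairwise correlation (flag threshold $|r| > 0.8$,
configurable) plus PCA variance shares. The practical weak-shell rule flags
`strength < 2` kg cm⁻¹ SL **and** `SL:SH > 2`, both strictly, so boundary
shells are not flagged.

## Outline morphometrics

Binary masks are traced with Moore-neighbourhood boundary following.
Termination uses state-repetition detection — the walk is a deterministic
map on (pixel, backtrack) states, so the recurring segment is exactly the
boundary cycle; this is robust where the classic "revisit the start with the
same entry direction" criterion can fail to fire. Coordinates are
pixel-center based, 0-based, y-axis up; outlines are closed with the first
point not repeated, and preprocessing (uniform arc-length resampling to 300
points by default, centering, counterclockwise orientation) fixes all
remaining conventions. 300 points is comfortably above the Nyquist
requirement for the ≤ 32 harmonics used anywhere in the package.

Elliptic Fourier decomposition follows the Kuhl–Giardina chain formulation.
The contour parameter is the cumulative chord length by default
(`parametrization = "chord"`, appropriate for raw pixel chains); a
`"uniform"` option treats the sample index as the parameter, appropriate for
points sampled uniformly in an underlying curve parameter. The two coincide
after arc-length resampling. The distinction matters for exactness
statements: an ellipse sampled uniformly in its angular parameter is
*exactly* harmonic 1 under `"uniform"` (residual power below 1e-10), whereas
re-parametrising the same curve by arc length genuinely spreads ≈ 0.6% of
the power into higher harmonics — that is a property of the curve, not an
implementation error.

Normalization is the standard first-harmonic procedure: rotate the starting
point to the first-harmonic semi-major axis, rotate the plane so that axis
lies along x, divide by the semi-major length. Afterwards $a_1 = 1$,
$b_1 = c_1 = 0$, and $d_1$ is the signed aspect of the first-harmonic
ellipse. The residual two-fold ambiguity (which end of the major axis the
parameter starts from) flips the sign of every even harmonic; it is resolved
deterministically by requiring the first even-harmonic coefficient larger
than 1e-7 in magnitude to be positive. When all even harmonics vanish the
two candidates are identical and the choice is moot. Normalized coefficients
are invariant to rotation, translation, isotropic scaling and starting point
of the input (verified to 1e-6 in the tests); the alignment convention is
recorded in the object because alternative conventions change coefficient
signs.

Shape PCA is centred and unscaled on the normalized coefficients. Columns
constant by construction after normalization ($a_1, b_1, c_1$) carry no
information and are dropped automatically — equivalently, the PCA runs on
$d_1$ plus harmonics 2..N, which is the set the first-harmonic convention
leaves free. Components are retained up to the smallest set exceeding 95%
cumulative variance (configurable). MANOVA reports Wilks' Λ with Rao's F
approximation, supporting both factor groupings and continuous covariates;
with a single response variable Λ reduces algebraically to
$RSS_{\text{full}}/RSS_{\text{null}}$ and the exact ANOVA F is returned.
Pairwise MANOVA reports raw per-pair statistics, with a Bonferroni column
available but not applied by default, matching how such pairwise comparisons
are conventionally reported in this literature.

## The synthetic-cohort generator

The generator exists so that every analysis stage has data with known truth.
Its defaults describe a depth-structured cultivated stock:

- **Design**: four depth strata at 1/3/5/7 m with 116/118/118/83
  individuals; a stock dominated by pure ME with ME×MG hybrids (~9–17% by
  depth), and a small pure-MT / F1 / first-backcross ME×MT component that
  declines with depth so the stratum mean $MT_{AF}$ falls from ≈ 0.04 at 1 m
  to below 0.01 at 7 m. Ancestry classes stop at the first backcross:
  multi-locus dosage patterns distinguish "predominantly heterozygous" from
  "predominantly homozygous" individuals, but deeper pedigrees are not
  identifiable from a 33-locus panel and are out of scope.
- **Panel**: 33 loci, 28 strictly diagnostic and 5 leaking the diagnostic
  allele into ME/MG at frequency 0.014 — the detection floor $1/72$ of a
  discovery sample of 72 ME/MG chromosomes, and the mechanism by which a
  minority of loci produce rare false MT signals concentrated at the same
  few markers.
- **Genotype law**: each individual draws two alleles per locus from the
  gamete pools of its class (pure: both from one species; F1: one from each;
  backcross: one allele from an F1 gamete — a fair per-locus coin flip
  between the parental pools — and one from the recurrent parent). On
  strictly diagnostic loci this forces the Mendelian patterns exactly: F1s
  all-heterozygous, pure classes all-homozygous, for every seed. A simulated
  Me15/16 locus is inherited under the same law and emits the
  species-specific fragments (ME 180 bp, MT 168 bp, MG 126 bp).
- **Shell traits**: normalized strength is linear —
  `2.03 + 0.135·(depth − 1) − 1.37·MT_AF + N(0, 0.65)` in kg cm⁻¹ SL — with
  Gaussian noise on the normalized scale (the simplest noise model
  compatible with a linear analysis of normalized strength). The SL:SH
  elongation ratio is `1.50 + 0.75·MT_AF − 0.02·(depth − 1) + N(0, 0.07)`:
  the MT effect is set so heavily introgressed shells exceed the practical
  `SL:SH > 2` threshold by a clear margin while MT-free shells stay near
  1.5, and the small depth slope reproduces the dorso-ventral compression
  gradient. Raw puncture force is back-computed as `strength × SL(cm)` so
  normalization round-trips. With `residual_sd → 0`, refitting the linear
  model recovers the generating coefficients to at least four significant
  digits (tested).
- **Outlines**: a fixed mussel-like polar template
  ($r(\theta) = 1 + 0.18\cos\theta + 0.06\cos 2\theta - 0.04\sin\theta$)
  perturbed by smooth random harmonics (orders 3–8) at a relative amplitude
  `noise_sd`, then anisotropically scaled, which makes the bounding-box
  length:height ratio match the requested elongation exactly.
- **Salinity**: i.i.d. Gaussian around per-depth means, truncated at zero;
  shallow depths get lower means and higher variances when so configured.
- **Seeds**: one integer seed per design feeds per-operation substreams (a
  deterministic hash of seed and stage name), so stages can be re-run
  independently and whole cohorts are bit-reproducible.

What the generator does **not** emulate: linkage between loci, genotyping
error beyond missingness, wild-larval settlement dynamics, Fluidigm
fluorescence intensities, RAD reads, within-stratum depth variation
(depth is the nominal 1/3/5/7 m), photographic calibration, or left/right
valve asymmetry. Passing tests therefore demonstrate the correctness of the
statistics and the internal consistency of the pipeline under a clean
generative model — not robustness to assay artefacts absent from that model.
The mixture proportions that shape the depth decline are a modelling choice
pinned once in `default_cohort_design()`, not published values.

## Problem sizes and numerical tolerances

The test suite runs cohorts of 435–8 700 individuals, 10 000-individual
calibration checks for binomial expectations (asserted within 3 binomial
SEs), 200-replicate simulate-and-refit experiments at n = 430 for the
strength model, and 100 000-table Monte-Carlo draws for the Fisher test —
sizes chosen so the whole suite completes in well under a minute while
keeping Monte-Carlo error an order of magnitude below every asserted
tolerance. Exact identities (the $MT_{AF}$ identity, Mendelian forcing,
PCA variance shares) are asserted at 1e-10–1e-12; EFA invariances at 1e-6,
which is the discretization level of 300-point outlines.

## Known limitations

- The quasibinomial "weighted proportions" analysis of class proportions and
  the per-metre allele-frequency decline depend on response/weight choices
  that published descriptions leave ambiguous; the fitting operations exist,
  but no numeric values for those particular analyses are asserted.
- `enumerate_class_counts()` can return multiple integer solutions for a
  single printed table row; uniqueness generally requires a pooled
  constraint across rows (the tests resolve a four-row table that way).
- Boundary tracing assumes a single well-filled foreground component;
  one-pixel-wide filaments are traversed but can yield degenerate polygons.
- The first-harmonic normalization is unstable for nearly circular outlines
  (the semi-major axis is then ill-defined); mussel valves are far from this
  regime.
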