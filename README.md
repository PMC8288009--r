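# introshell

Blue mussels (*Mytilus edulis*, ME) grown in suspended longline culture can
hybridize with *M. galloprovincialis* (MG) and, more consequentially for the
farmer, with *M. trossulus* (MT), whose introgressed offspring build thin,
weak, elongated shells. `introshell` implements the quantitative toolkit for
studying this problem: species classification from the Me15/16 PCR marker,
quality control of taxon-diagnostic SNP panels, per-individual introgression
statistics, depth-stratified regression models, shell-strength analysis, and
elliptic Fourier outline morphometrics — together with a synthetic-cohort
generator that reproduces the statistical structure of a depth-structured
mussel stock so every stage can be exercised without field data.

The package is written for population geneticists and shellfish-aquaculture
researchers working with diagnostic marker panels and shell phenotypes.

## The statistics at the core

For each individual genotyped at *M* retained diagnostic loci, with *nXY*
loci heterozygous and *nXX* homozygous for the MT-diagnostic allele:

- observed heterozygosity `H_O = nXY / M`
- hybrid index `HI = (nXY + nXX) / M`
- MT allele frequency `MT_AF = (nXY + 2 nXX) / (2M)`, so that
  `MT_AF = HI − H_O / 2` identically.

`MT_AF` runs from 0 (no introgression) to 1 (pure MT); an F1 hybrid on a
strictly diagnostic panel has `MT_AF = 0.5` with `H_O = 1`. The odds of
carrying MT alleles are modelled against cultivation depth by grouped
binomial logistic regression (with a quasibinomial variant whose dispersion
is Pearson χ²/df), shell strength normalized per cm of shell length
(kg cm⁻¹ SL) is modelled linearly on `MT_AF` and depth with AIC model
selection, and valve shape is decomposed into Kuhl–Giardina elliptic Fourier
coefficients, normalized to the first harmonic, and analysed by PCA and
MANOVA (Wilks' Λ).

## Worked example

```r
library(introshell)
library(dplyr)

co   <- simulate_cohort(default_cohort_design(seed = 1), default_panel(seed = 1))
qc   <- qc_filter(co$genotypes)                  # 20% missing-data threshold
prof <- introgression_profile(qc$genotypes)
summarize_introgression(prof, co$meta)
#> # A tibble: 5 × 10
#>   depth      n pct_mt_positive n_lt10 n_10_50 n_50_75 n_gt75 mean_mt_af mean_ho
#> 1 1        116            25       13       4       5      7    0.0918  0.0624
#> 2 3        118            14.4     10       2       3      2    0.0342  0.0339
#> 3 5        118            22.0     19       1       2      4    0.0470  0.0262
#> 4 7         83            10.8      8       1       0      0    0.00438 0.00876
#> 5 pooled   435            18.6     50       8      10     13    0.0473  0.0346
```

Each row is a depth stratum: `pct_mt_positive` is the share of individuals
carrying at least one MT-diagnostic allele, the `n_*` columns bin carriers by
their `MT_AF`, and the means satisfy `mean_mt_af = mean_hi − mean_ho / 2`
exactly. Introgression is concentrated in the shallow strata and fades by 7 m.

The depth trend in the odds of carrying MT alleles, fitted on grouped counts
(here the depth-stratified carrier counts 21/116, 22/118, 22/118, 11/83):

```r
fit <- fit_logistic_grouped(c(21, 22, 22, 11), c(116, 118, 118, 83), c(1, 3, 5, 7))
fit
#> <grouped_glm_fit: binomial> n = 4 groups (435 individuals)
#>   odds factor per unit x: 0.957 (95% CI 0.852, 1.074)
```

The odds of encountering an MT-introgressed mussel shrink by a factor of
about 0.96 per metre of depth, with a CI spanning 1 (no significant overall
depth effect). Shell strength against introgression and depth, with AIC
selection between the interaction and additive models:

```r
sh  <- simulate_shell_traits(co, seed = 1)
sel <- fit_linear(sh, list(strength_norm ~ mt_af * depth_m,
                           strength_norm ~ mt_af + depth_m,
                           strength_norm ~ depth_m))
tidy(sel)
#> # A tibble: 3 × 6
#>   term        estimate std_error  ci_low ci_high  p_value
#> 1 (Intercept)    1.96     0.0697  1.82     2.09   1.63e-99
#> 2 mt_af         -1.34     0.182  -1.70    -0.982  9.55e-13
#> 3 depth_m        0.110    0.0157  0.0790   0.141  1.07e-11
```

The additive model wins (ΔAIC = 1.9 over the interaction model): shells
strengthen by ≈ 0.11 kg cm⁻¹ SL per metre of depth and weaken by
≈ 1.3 kg cm⁻¹ SL per unit of MT ancestry in this realisation. A practical
field rule flags the weak, elongated shells typical of heavy introgression:

```r
weak_shell_flag(strength_norm = 1.8, SL_mm = 66, SH_mm = 30)   # TRUE
```

Morphometrics runs from binary masks or coordinate lists through
`trace_outline()`, `preprocess_outline()`, `efa_decompose()`,
`efa_normalize()`, `shape_pca()` and `manova_wilks()`; `run_pipeline()`
chains every stage and writes tidy CSV artifacts plus a run report.

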