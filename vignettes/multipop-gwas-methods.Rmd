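---
title: "Mega- versus meta-analysis for multi-population GWAS: models, simulation design and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mega- versus meta-analysis for multi-population GWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(salmeta)
```

## The problem

When several related breeding populations have been phenotyped and genotyped,
there are two ways to combine them for genome-wide association. A
*mega-analysis* pools the individual-level records into one mixed-model scan
with a population fixed effect; a *meta-analysis* combines only per-population
summary statistics (p-values or allele substitution effects). Meta-analysis is
attractive when individual records cannot be shared, but its estimators assume
the component studies are independent. Aquaculture breeding populations are
not independent: they share founders, exchange broodstock and carry strong
family structure, so cryptic relatedness links samples *across* population
boundaries. Each within-population mixed model corrects its own relatedness,
yet the correlation between populations' test statistics survives into the
combined statistic and inflates it. The pooled mega-analysis models the full
relationship matrix and stays calibrated. This package implements both
routes, the diagnostics that expose the contrast, and the three
secondary-signal procedures used to count independent QTL, together with a
synthetic data generator so the whole phenomenon is reproducible at desk
scale without any proprietary data.

## Models

### Within-population association

Each population is analysed with the mixed linear model

$$y = 1\mu + x b + Z u + e, \qquad
u \sim N(0, G\sigma^2_u), \quad e \sim N(0, I\sigma^2_e),$$

where $y$ is the (ordinal, treated as linear) score, $x$ the SNP dosage
coded 0/1/2, $b$ the allele substitution effect and $G$ the genomic
relationship matrix built by VanRaden's first method,
$G = WW' / (2\sum_k p_k(1-p_k))$ with $W$ the dosage matrix centered at twice
the pooled allele frequencies. Variance components are estimated once by
REML under the null (no SNP) per scan; after rotating by the eigenbasis of
$G$ the restricted likelihood is a one-dimensional profile in
$\gamma = \sigma^2_u/\sigma^2_e$, optimized on the log scale with the
boundary $\gamma = 0$ checked explicitly. Each SNP is then tested by
generalized least squares with $V = G\hat\sigma^2_u + I\hat\sigma^2_e$ held
fixed, a Wald $\chi^2(1)$ on $(b/\mathrm{SE})^2$. The SE carries an estimated
residual scale (so the test is invariant to rescaling $V$ by a constant; at
the REML optimum the scale is $\approx 1$ and the test matches the usual
fixed-$V$ Wald test). The candidate SNP's chromosome is *not* excluded from
the GRM — the scan mirrors the single-GRM convention, which is slightly
conservative (within-population inflation factors come out just below 1,
matching the study design this emulates).

### Mega-analysis

The pooled panel is scanned with the same model plus population indicator
columns in the fixed-effect design, and a GRM built on the pooled panel.

### Meta-analysis

Three estimators combine the per-population tables after allele
harmonization (effects flipped onto a shared effect allele; irreconcilable
allele pairs dropped and counted):

* **Stouffer/sample-size Z-score**:
  $Z_{ij} = \Phi^{-1}(1 - p_{ij}/2)\,\mathrm{sign}(b_{ij})$,
  $Z = \sum_j Z_{ij} w_{ij} / \sqrt{\sum_j w_{ij}^2}$ with
  $w_{ij} = \sqrt{n_{ij}}$.
* **Inverse-variance weighting**: $\beta_j = \sum \beta_{ij} w_{ij} / \sum
  w_{ij}$, $w_{ij} = V_{ij}^{-1}$, with Cochran's
  $Q = \sum w_{ij}(\beta_{ij} - \beta_j)^2$ (flagged at the 0.10 level
  against $\chi^2(N-1)$) and $I^2 = (Q - (N-1))/Q \times 100$, truncated to
  $[0, 100]$ and banded at 25/50/75.
* **Han–Eskin random effects**: the statistic decomposes as
  $S_\mathrm{rand} = S_\mathrm{FE} + S_\mathrm{Het}$, where $S_\mathrm{FE}$
  equals the IVW $\chi^2$ and $S_\mathrm{Het}$ collects the heterogeneity
  likelihood terms evaluated at the DerSimonian–Laird
  $\tau^2 = (Q - (N-1)) / (\sum w - \sum w^2 / \sum w)$ (truncated at 0),
  with $\beta^*_j$ the $\tau^2$-reweighted mean. $S_\mathrm{Het}$ is
  truncated at zero (the plug-in $\tau^2$ is not the restricted MLE, so the
  raw expression can go marginally negative). The default null for
  $S_\mathrm{rand}$ is the boundary-LRT mixture
  $\tfrac12\chi^2(1) + \tfrac12\chi^2(2)$; `han_eskin_null()` provides a
  seeded Monte-Carlo null for small study counts where tabulated small-sample
  corrections would otherwise be needed.

Z-score results carry no effect size; `z_to_beta_se()` converts them via
$b = z/\sqrt{2p(1-p)(n+z^2)}$, $\mathrm{SE} = 1/\sqrt{2p(1-p)(n+z^2)}$,
exact in the ratio $b/\mathrm{SE} = z$.

### Diagnostics and multiple testing

The genomic inflation factor is the median observed $\chi^2$ over the
$\chi^2(1)$ median (0.4549, reported at the conventional 3 decimals as
0.455); $\lambda > 1.1$ (strict) is flagged as evidence of confounding. For
the random-effects scan a decomposed mode reports the sum of the
$S_\mathrm{FE}$ and $S_\mathrm{Het}$ component inflations, which is the
convention under which a heterogeneity-powered statistic shows its combined
inflation. FDR control is Benjamini–Hochberg step-up; because downstream
procedures need a working p-value *threshold* rather than adjusted p-values,
the threshold is taken as the largest BH-significant p-value (the rejection
set is identical). An alternative threshold derivation based on the
estimated-FDR formula $\mathrm{FDR}(t) = t(1-k/m)/((k/m)(1-t))$ is exposed
as a labelled diagnostic; both are provided because the literature uses
either, and on realistic p-value mixtures they reject nearly identical sets.

### Secondary signals

* **Conditional association** (gold standard): refit the scan with the lead
  significant SNP as a fixed covariate (REML refitted each round), repeat
  until nothing passes the threshold; each round's QTL region spans that
  round's significant SNPs on the lead's chromosome. Because the multi-round
  interval arithmetic is ambiguous when several rounds fire, regions are
  reported per round (plus their union implicitly via the table) rather than
  differenced.
* **COJO-style selection** from summary statistics: $X'X$ blocks are
  reconstructed from reference-panel correlations and per-SNP variances
  ($D_j = n_j \mathrm{var}_\mathrm{ref}(x_j)$), $X'y$ from $D_j b_j$, and
  the phenotypic sum of squares from the median per-SNP implied value.
  Candidates beyond the window (default 100 Mb, reflecting long-range LD in
  aquaculture populations) are treated as uncorrelated; a candidate whose
  squared correlation with any selected SNP reaches the collinearity bound
  (default 0.05, deliberately strict) has its conditional p-value set to 1.
  Stepwise add/drop iterates to a fixed point and the selected set is
  reported with joint estimates.
* **Clumping**: greedy grouping of significant SNPs around leads by p-value
  ($\le p_1$), squared dosage correlation ($\ge 0.05$) and distance
  ($\le 5000$ kb, boundary inclusive, measured lead-to-member on the
  association map). Significant SNPs are partitioned.

Ties everywhere break deterministically: smallest p, then largest $|b|$,
then lowest (chromosome, position).

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
not salmon biology:

* **Population differentiation**: ancestral allele frequencies uniform on
  [0.05, 0.95]; per-population frequencies from the Balding–Nichols
  distribution with drift 0.03 — small genetic distances, as between
  year-classes of one breeding program.
* **Cryptic relatedness and LD phase**: each population owns a finite pool
  of 24 haplotypes; founder haplotypes copy blocks of 1 Mb from pools chosen
  by an admixture matrix (default: 0.55 own / 0.15 each other population).
  The small pool induces haplotype sharing (within-block LD, family-like
  relatedness); cross-population copying makes that sharing cross
  population boundaries — the cryptic relatedness that drives the headline
  phenomenon. Identity admixture switches it off.
* **Families**: founders are paired into distinct couples; full-sib
  offspring are produced with Poisson(1) crossovers per chromosome at
  uniform positions.
* **Phenotype**: liability = population shift + centered QTL dosage effect
  + polygenic term + Gaussian noise. The polygenic term uses one shared
  vector of i.i.d. per-SNP effects over the whole panel (so populations
  share their genetic architecture), scaled to `h2_poly` (default 0.5) of
  the unit-variance residual liability. The ordinal score 0–5 counts
  thresholds exceeded; the preset thresholds (−0.95, −0.05, 0.85, 1.75,
  2.65) with population shifts (0.75, 0.35, 0, 0) give closed-form mean
  scores of about 2.39 / 1.97 / 1.61 / 1.61 and SDs near 1.2, matching the
  descriptive geometry of four gill-scored populations with one
  higher-scoring outbreak cohort.
* **The major QTL**: one marker on chromosome 3 at 15 Mb with an allele
  substitution effect of 0.4 liability SD. Its ancestral frequency is
  anchored at Uniform(0.3, 0.7): a mapped major QTL is by construction
  common, and at desk-scale sample sizes a rare variant would simply vanish
  rather than test the machinery.
* **Missingness**: uniform at 1% so quality control has work to do. No
  genotyping-error model, no sex chromosomes, no selection, no
  coalescent-grade LD decay — passing tests show the pipeline's statistical
  behaviour under the assumed covariance structure, not performance on real
  genotype data.

The preset sizes scale the study geometry (2006/640/2911/2949 samples) by a
`scale` factor; the replicated benchmarks in the tests and the acceptance
script use scale 0.10–0.14 with 3,000–5,000 SNPs (roughly 850–1,200 samples),
chosen so the full replicated study runs on one CPU in minutes while keeping
the mixed-model scans at realistic sample-to-marker ratios.

### What calibration shows

On the admixed *null* preset (no QTL, polygenic liability), the
within-population and mega-analysis inflation factors average ~1.0 while
every meta-analysis estimator averages ~1.1 and exceeds the mega-analysis
λ in essentially all replicates — the central contrast this package exists
to demonstrate. On the *homogeneous* single-QTL preset, meta and mega
−log₁₀ p rank-correlate strongly, and the secondary-signal counts order as
clumping ≥ COJO ≥ conditional. The admixture proportions and polygenic
heritability of the preset were calibrated once to reproduce the direction
and rough magnitude of this contrast and then frozen; they are not fitted to
any dataset.

## Numerical choices

* GRM diagonal jitter $10^{-6}$ before eigendecomposition (documented,
  configurable); eigenvalues clipped at 0.
* REML search over $\log\gamma \in [\log 10^{-8}, \log 10^{8}]$, tolerance
  $10^{-8}$, explicit boundary comparison at $\gamma = 0$; variances are
  nonnegative by construction.
* SNPs collinear with the fixed effects (weighted residual sum of squares
  below $10^{-10} n$) return NA rows rather than spurious estimates.
* Meta-analysis p-values of exactly 0 are clamped to the smallest positive
  normal double before the normal-quantile transform.
* Monomorphic SNPs are an error in `compute_grm()` (named in the message)
  and are filtered defensively in the pipeline wrapper.
* Exact Hardy–Weinberg p-values use log-factorial enumeration with the
  conventional $(1 + 10^{-9})$ slack when summing tables no more probable
  than the observed one.
* Within-population HWE testing removes a SNP that fails in *any*
  population (the pooled variant is available via `qc_config(hwe_scope =
  "pooled")`); which scope the emulated study used is not recoverable, so
  both are first-class.
* Sporadic missing genotypes are imputed to the within-population modal
  genotype, ties toward the genotype carrying the locally more frequent
  allele — a deliberate, deterministic stand-in for the study's unnamed
  imputer.

## Known limitations

* The ordinal score is analysed as a linear trait (as the emulated design
  does); no threshold/ordinal mixed model is provided.
* The between-population block means of a pooled-centered VanRaden GRM sum
  against the within-population blocks (the grand mean of $G$ is exactly 0),
  so "cryptic relatedness" is read from the *contrast* between admixed and
  unadmixed presets, not from the absolute sign of the between-block mean.
* COJO's summary-statistic algebra assumes the reference panel is the
  analysed panel (true here); with an external reference its approximations
  degrade long before the window rule matters.
* The Monte-Carlo random-effects null is provided but not tabulated;
  at $N = 4$ studies the mixture asymptotics are adequate for ranking but
  p-values near machine precision should not be over-interpreted.
* LD-score regression and sample-overlap corrections are out of scope.
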