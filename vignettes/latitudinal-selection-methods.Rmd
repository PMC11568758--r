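---
title: "Methods: latitudinal selection scans and trans-expression analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: latitudinal selection scans and trans-expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What this package computes

`clinesel` is a pipeline for a recurring question in human population
genomics: has a focal biallelic variant been under recent positive selection
along an environmental (here, latitudinal) cline, and does its risk allele
have downstream *trans* effects on cell-type gene expression? The package
implements the four statistical layers of that question —

1. **Differentiation**: per-site Weir–Cockerham F~ST~ between a focal
   population and comparison populations, with significance from an
   allele-frequency-matched empirical null rather than a parametric
   distribution.
2. **Haplotype-based selection**: extended haplotype homozygosity (EHH)
   curves, their integrals (iHH) over genetic distance, and the iHS
   statistic standardized within derived-allele-frequency bins.
3. **Cline modeling**: phylogenetic generalized least squares (PGLS)
   regression of population allele frequencies on latitude and temperature,
   with a Brownian-motion covariance from a neighbor-joining population
   tree, likelihood-ratio testing, and Akaike-weight multi-model inference.
4. **Trans expression**: single-nucleus marker identification, risk-allele
   differential expression with replication, binned-control module scores
   with a donor-level permutation null, and pseudobulk TMM / inverse-normal
   correlation analyses down to adipocyte-size phenotypes.

Because the cohort data this kind of study uses (large genotyped cohorts,
biobanks, single-nucleus atlases) are controlled-access, every layer is
exercised end-to-end on synthetic data from the package's own generators.
The generators are first-class, tested code: their statistical structure is
what the analyses assume, so recovery of planted signals is evidence the
analysis code does what it claims — on data with that structure.

# The models and their assumptions

## Forward Wright–Fisher simulator

`simulate_haplotype_panel()` evolves phased haplotype panels forward in
discrete generations: each offspring haplotype is a recombinant gamete of a
parent diploid drawn with probability proportional to fitness, which is
`1, 1+s, 1+2s` by derived-allele dosage at one focal site (additive
selection). Crossovers occur independently per adjacent-site interval with
probability `recombination_rate × bp`.

The initial panel is drawn from a finite pool of `n_founders` unrelated
founder haplotypes. This is a deliberate emulation of a bottlenecked,
founder-effect population — the demographic setting in which this kind of
selection scan is typically run — and it is what gives the panel long-range
haplotype sharing at time scales deeper than the simulated horizon: two
sampled haplotypes either coalesce inside the simulated generations, or
they trace to founders, which are unrelated and therefore break extended
homozygosity immediately. No claim of demographic realism for any specific
population is made (bottleneck timing, growth, and mutation are out of
scope).

**Scaled-down population sizes.** Simulating thousands of diploids is
unnecessary for calibration; instead population sizes are scaled down and
the per-bp recombination rate scaled up to preserve the population-scaled
recombination rate ρ = 4Nr per bp at roughly the human value of 4 × 10⁻⁴
(N = 10⁴, r = 10⁻⁸). The two canonical panels are:

* **Neutral calibration panel** (`neutral_panel_config()`): N = 100
  diploids, 20,000 sites over 10 Mb, r = 10⁻⁶, 150 generations, 40
  founders. More than 10,000 sites pass the MAF ≥ 0.05 filter.
* **Sweep panel** (`sweep_panel_config()`): N = 300 diploids, 3,000 sites
  over 3 Mb, r = 3 × 10⁻⁷, 130 generations. The derived focal allele is
  introduced as a **single copy at generation 0** and the post-introduction
  phase is re-run from the same checkpoint until the allele is still
  segregating with MAF ≥ 0.05 at sampling (`introduce_focal = TRUE`). This
  is the standard conditioning on an *established, ongoing* hard sweep:
  iHS is a statistic about sweeps in progress, and a lost or fixed allele
  has no defined iHS. N = 300 was chosen so that with the spec-level
  s = 0.05 the sweep is strong in scaled terms (2Ns = 30, sweep duration
  ≪ panel depth); at much smaller N the same s gives a weak sweep that no
  statistic could reliably detect, which is a property of the scaled
  scenario rather than of the estimator.

An island-model `migration_rate` (per-haplotype replacement probability per
generation) is available for multi-population runs; F~ST~ decreases
monotonically in it, which the tests assert.

## EHH, iHH, iHS

EHH at site *x* for carriers of a core allele is the probability that two
randomly chosen carrier haplotypes are identical over the entire stretch
from the core to *x*: carriers are partitioned into identical extended
haplotypes and `EHH(x) = Σ_h C(n_h, 2) / C(n_c, 2)`. The implementation
(Rcpp) refines the partition one site at a time, so a curve costs
O(carriers) per site; tests compare it against an exhaustive
pairwise-comparison oracle on small panels at 10⁻¹² tolerance.

iHH is the trapezoidal integral of EHH over genetic distance (cM), summed
over both directions, each truncated at the **last site with EHH ≥ 0.05**
— no interpolation of the crossing point. This truncation rule is simple,
deterministic, and identical for the numerator and denominator of iHS, so
the ratio is not biased by the stopping rule. Unstandardized
iHS = ln(iHH_ancestral / iHH_derived); long derived haplotypes therefore
give negative values, matching the convention in which a negative score
indicates selection for the derived allele. Standardization subtracts the
bin mean and divides by the bin sample SD within 50 equal-width
derived-allele-frequency bins over [0.05, 0.95]; bins with fewer than two
values yield missing standardized scores. Percentile ranking of a focal
score against a background uses strict comparison of magnitudes
(`100 × #(|background| < |focal|) / #background`), so an extreme negative
score ranks high without interpolation.

Decay distances report how far EHH stays ≥ 0.05 in each direction; a curve
still above threshold at the panel edge returns the edge distance flagged
censored. Genetic distances are cM throughout, with bp reported alongside.
Missing genotypes are out of scope for the synthetic panels; VCF input with
an allele other than REF/ALT phases is rejected upstream.

## Weir–Cockerham F~ST~ and the matched empirical null

`weir_cockerham_fst()` computes the per-site 1984 estimator
θ̂ = a / (a + b + c) from the among-population (a),
among-individual-within-population (b) and within-individual (c) variance
components, using diploid genotypes and observed heterozygote frequencies.
Raw values can be negative for undifferentiated sites; both the raw value
and the [0, 1]-clipped value are reported, and the multi-site ratio of sums
Σa / Σ(a+b+c) is available separately. Monomorphic or under-sampled sites
are missing, not zero.

The empirical null for a focal site ranks candidate sites by
|candidate frequency − focal frequency| (ties broken by candidate order,
so the procedure is deterministic), keeps the k = 10,000 closest, and
reports the proportion with F~ST~ **strictly** greater than the focal
value. The p value may be exactly 0; an add-one variant
`(r + 1)/(k + 1)` sits behind a flag. Under exchangeability this p is
uniform on its grid, which the calibration tests verify by
Kolmogorov–Smirnov.

## NJ, Brownian covariance, PGLS

The population tree comes from Saitou–Nei neighbor joining on an F~ST~
distance matrix (backed by the standard implementation in `ape`, with
negative branch lengths clamped to zero and the deficit moved to the
sister branch). The Brownian-motion covariance over tips — shared
root-to-tip branch length — is built after midpoint rooting when the tree
is unrooted, since NJ output is unrooted and the covariance needs a root.

`pgls_fit()` is closed-form GLS with the scalar rate σ² profiled by maximum
likelihood: β̂ = (XᵀV⁻¹X)⁻¹XᵀV⁻¹y, σ̂² = RSS_V/n, with the Gaussian
log-likelihood and AIC = 2k − 2ℓ (k counts coefficients plus the variance
parameter). Standard errors use the unbiased residual variance
RSS_V/(n − p), so the identity-covariance case reproduces OLS exactly
(asserted at 10⁻¹⁰). A Shapiro–Wilk p on the whitened residuals reports
the residual-normality check. Pagel's λ is fixed at 1 (no transformation
estimation); V is jittered by 10⁻¹⁰ × mean diagonal only if the Cholesky
fails. Tests cross-check coefficients, SEs and log-likelihoods against
`nlme::gls` with a Brownian correlation structure on ultrametric trees,
where the covariance and correlation parameterizations coincide.

Model scale: the response can be the raw frequency or its logit
(`response = "logit"`, the default in `fit_cline_models()`), since the
cline generator works on the logit scale; the raw-scale option is exposed
because the choice is not identifiable from the downstream contracts and
residual normality is checked either way. AIC (not AICc) is used for the
Akaike weights `w_i = exp(−Δ_i/2)/Σ exp(−Δ_j/2)`; predictor weights sum
the weights of models containing the predictor. Leave-one-out stability
refits the full model dropping one population (and pruning its tip) at a
time.

**LRT calibration and sample size.** The likelihood-ratio test uses the
asymptotic χ² reference. At n ≈ 22 populations this reference is
anti-conservative for ML-profiled Gaussian models (the exact F-based
calculation gives a rejection rate near 0.086 at nominal 0.05 with two
extra predictors), which is a property of the χ² approximation, not of the
implementation. The type-I calibration experiment therefore runs at
n = 200 tips, where the analytic rejection rate is ≈ 0.053; the
small-sample behaviour is worth keeping in mind when interpreting LRT p
values on 22 populations.

## Cline generator

`simulate_cline()` draws per-population derived-allele frequencies as
inverse-logit(intercept + slope·latitude + b), with b a Brownian-motion
draw on the tree (variance `bm_sigma2` per unit branch length). The
logistic link keeps frequencies strictly inside (0, 1). The calibrated
recovery experiment uses slope 0.08 per degree on the logit scale,
`bm_sigma2 = 0.1`, and 22 populations — the scale of a continental
population panel. Temperatures default to a deterministic lapse of
latitude (24 − 0.5·|lat| °C), making latitude and temperature strongly
collinear, as they are in real panels; this is why multi-model Akaike
weights, not single-predictor p values, are the headline summary.

## Single-nucleus layer

Counts are log-normalized per cell as ln(1 + 10⁴·count/total). Marker
identification is one-vs-rest Wilcoxon on normalized values, screened at
logFC ≥ 0.25 (log2 of expm1-means with pseudocount 1 — the base-2
convention is pinned; the natural-log alternative exists in the field and
would only rescale the threshold), positive-only by default, Bonferroni
over the genes tested for that type. Unique markers subtract the union of
all other types' marker sets.

Risk-allele differential expression pools cells of the target type by
donor carrier status (carrier = at least one risk allele, per the
Hardy–Weinberg generator) and tests each gene across cells with a
Wilcoxon rank-sum test at logFC threshold 0; Bonferroni is over the genes
actually tested in the run — 722-scale marker sets at discovery, only the
carried-forward genes at replication — never genome-wide. Replication
requires adjusted p < 0.05 **and** the discovery sign. Cell-level testing
mirrors the standard single-cell workflow and is anti-conservative under
donor structure (cells are not independent); the package therefore keeps
all donor-level machinery — pseudobulk construction and the donor-level
permutation null — alongside, and the null-cohort test asserts only that
discovery counts stay at module scale, not at zero.

Module scores bin all genes into 24 equal-count bins of average normalized
expression and draw 100 seeded control genes per module gene from the same
bin (without replacement when the bin allows, excluding module genes so a
planted shift is not absorbed into its own control set); the score is the
per-cell mean module value minus mean control value. The permutation null
shuffles carrier labels **at the donor level** — cells keep their donor,
so within-donor correlation is preserved; a cell-level shuffle would be
anti-conservative. The permutation p is (r + 1)/(B + 1) by default with
the raw proportion r/B alongside, because both estimators are in use in
the literature and the add-one form is never 0. B is capped at the number
of distinct label assignments. Inside the permutation loop the Wilcoxon p
is computed from precomputed pooled ranks with tie and continuity
correction — scores are fixed, only labels move — which makes 10⁴
permutations cheap and is the same approximation `wilcox.test` uses at
these sample sizes.

## Pseudobulk, TMM, INT, correlations

Pseudobulk sums counts per donor over cells of one type, recording nuclei
count, age and sex as covariates; donors with zero cells of the type are
dropped and listed. TMM normalization follows the canonical published
defaults exactly: reference = sample whose upper-quartile expression is
closest to the mean upper quartile; per-sample factor = precision-weighted
mean of log2 ratios after double trimming (30% on M, 5% on A); factors
renormalized to geometric mean 1. The test suite requires agreement with
`edgeR::calcNormFactors` within 5% on a spiked matrix (the observed
agreement is exact). Covariate adjustment regresses each gene on the
covariates and maps residuals through the Blom inverse normal transform
(rank − 3/8)/(n + 1/4), ties averaged; affine transforms of the input
leave the result unchanged.

Regional correlations take all pairwise Spearman correlations among genes
overlapping [anchor start − 1 Mb, anchor stop + 1 Mb] (gene-body overlap
with the window, 1-based inclusive — the window could also be anchored on
the neighbours' TSS only; overlap-of-window is the broader, documented
choice) and flag pairs not nominally significant. Size correlations
inverse-normal transform the diameters within each BMI group, then
correlate each gene with diameter per group, Bonferroni over all
gene × group tests of the invocation.

## Twin generator

`simulate_twin_cohort()` builds BMI-discordant pairs (one higher-, one
lower-BMI member each) and ties one designated gene to adipocyte diameter
through a Gaussian copula. The copula parameter is 2·sin(π·ρ_s/6) so that
the **Spearman** correlation, which is what the analysis estimates, hits
the requested target; group-specific targets allow planting the
association in one BMI group only. At n ≈ 44 pairs the sampling SD of
Spearman's ρ̂ around 0.55 is ≈ 0.13 (Fisher z), so calibration tests check
the mean across seeds and a wide-interval coverage rather than demanding
individual estimates land in a narrow band.

# What the tests do and do not show

The suite has three tiers. Exact tiers (combinatorial EHH values, WC84
transcription, NJ additivity, OLS identity, Akaike arithmetic, permutation
floor) verify the estimators against independent oracles. Calibration
tiers verify distributional behaviour under the generators' nulls:
standardized iHS pooled mean within ±0.05, SD in [0.95, 1.05], |iHS| ≥ 2
fraction in [0.03, 0.06] on ≥ 10,000 informative neutral sites; uniformity
of the matched-null and permutation p values; LRT type-I error in
[0.035, 0.065]. Power tiers verify planted-signal recovery: PGLS slope
mean within 10% of 0.08 over 500 replicates; the full 12-gene trans module
recovered and replicated with zero sign-flipped replications; an s = 0.05
sweep ranking above the 90th |iHS| percentile with negative sign in ≥ 80%
of conditioned runs.

Passing these shows the estimators are correct and calibrated **for data
with the generators' structure**. Real cohort data differ in ways the
generators deliberately omit: mutation, gene conversion and genotyping
error; realistic demographic history (growth, bottleneck timing,
migration surfaces); ambient RNA, doublets and batch structure in
single-nucleus counts; and LD-driven non-exchangeability of the
matched-SNP null. Results on real data inherit those caveats.

# Numerical choices and degenerate inputs

* EHH requires ≥ 2 carriers per allele class; iHS is missing when either
  iHH integral is 0; sites failing the MAF filter are missing.
* Raw EHH decay distances separate the derived from the ancestral allele
  only while a sweep is mid-rise: once the derived allele is near
  fixation, the shrunken ancestral remnant class also coalesces recently
  and can carry long haplotypes. This is why iHS — integrals standardized
  within frequency bins — is the detection statistic, and why the
  decay-distance calibration conditions on a final derived frequency in
  [0.08, 0.55] (`establish_range`).
* Wilcoxon tests on expression use `stats::wilcox.test` defaults: exact
  only for small, tie-free samples, otherwise the normal approximation
  with tie and continuity correction — expression values are massively
  tied, where no exact distribution exists.
* F~ST~ is missing for pooled-monomorphic or under-sampled sites;
  clipping to [0, 1] never overwrites the retained raw value.
* NJ rejects asymmetric or negative distance input; identical taxa give a
  zero-length cherry.
* PGLS rejects singular XᵀV⁻¹X with a condition-number report; the
  likelihood is invariant to V → cV (profiled σ²), which is tested.
* The expression generator redraws degenerate genotype vectors (all
  donors in one carrier group) up to a bounded retry count, then errors —
  pipelines stay deterministic and non-hanging.
* Module-score bins that cannot supply controls fall back (with a
  warning) to sampling with replacement, or to the global non-module pool.
* All generators are seed-deterministic; identical seeds give identical
  output byte-for-byte.

# Problem sizes

The calibration and power experiments are sized to run on a single CPU in
minutes: the neutral calibration panel is one 20,000-site simulation and
scan (~20 s); the sweep power experiment runs 6 conditioned sweeps (~30 s
each); PGLS recovery uses 500 refits on 22 tips and the LRT calibration
2,000 refits on 200 tips (seconds each); the trans experiments simulate
60-donor × 200-cell cohorts (~7 s per seed triplet). These sizes are the
package's calibration conditions, chosen once; rerunning at larger sizes
only narrows the Monte-Carlo error around the same targets.
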