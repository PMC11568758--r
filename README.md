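# clinesel

An R package and analysis workflow for a recurring question in human
population genomics: **has a focal biallelic variant been selected along a
latitudinal cline, and does its risk allele have downstream *trans* effects
on cell-type gene expression?**

The package implements the four statistical layers of that question and a
set of synthetic-data generators that exercise every layer end-to-end, so
the whole pipeline is testable without controlled-access cohort data.

## What it computes

**Differentiation.** Per-site Weir–Cockerham (1984) F<sub>ST</sub> between
two populations, θ̂ = a/(a+b+c) from the among-population (a),
among-individual (b) and within-individual (c) variance components, with
raw and [0,1]-clipped values. Significance comes from an
allele-frequency-matched empirical null: candidate SNPs are ranked by
|frequency − focal frequency|, the k = 10,000 closest retained, and
p = (# matched SNPs with F<sub>ST</sub> strictly greater)/k.

**Haplotype-based selection.** Extended haplotype homozygosity
EHH(x) = Σ<sub>h</sub> C(n<sub>h</sub>,2)/C(n<sub>c</sub>,2) over carriers
partitioned into identical extended haplotypes from the core to x; iHH as
the trapezoidal integral of EHH over genetic distance truncated at
EHH < 0.05; iHS = ln(iHH<sub>A</sub>/iHH<sub>D</sub>) standardized within
50 derived-allele-frequency bins (negative values ⇒ long derived
haplotypes ⇒ selection for the derived allele); percentile ranking of a
focal score against a chromosome-wide background by strict magnitude
comparison.

**Cline modeling.** Neighbor-joining population trees from F<sub>ST</sub>
distances, Brownian-motion tip covariance, PGLS
β̂ = (XᵀV⁻¹X)⁻¹XᵀV⁻¹y with σ² profiled by ML, likelihood-ratio tests,
Akaike weights w<sub>i</sub> = exp(−Δ<sub>i</sub>/2)/Σexp(−Δ<sub>j</sub>/2)
over the {latitude, temperature} model set, and leave-one-out stability.

**Trans expression.** Log-normalization (scale 10⁴), one-vs-rest Wilcoxon
cell-type markers (logFC ≥ 0.25, Bonferroni), unique-marker subtraction,
risk-allele differential expression across cells with replication
(adjusted p < 0.05 *and* concordant direction), module scores against
binned expression-matched controls (24 bins × 100 controls), a
donor-level permutation null (p = (r+1)/(B+1), raw proportion alongside),
sex-stratified tests, pseudobulk TMM normalization, covariate adjustment +
Blom inverse-normal transform, regional (±1 Mb) Spearman correlation hubs
and adipocyte-size correlations in BMI-discordant twin groups.

**Generators.** Forward Wright–Fisher simulation with recombination,
additive selection at a focal site, founder-pool initialization, island
migration, population splits, and ongoing-sweep conditioning; Brownian
clines on trees with a latitude effect; negative-binomial single-nucleus
cohorts with planted trans modules under Hardy–Weinberg risk genotypes;
Gaussian-copula twin cohorts. All seed-deterministic.

## Worked example

```r
library(clinesel)

# an ongoing hard sweep: derived allele enters as a single copy, s = 0.05
sim <- simulate_haplotype_panel(population_spec("pop", 300),
                                sweep_panel_config(seed = 1))
sim$focal_freq
#>   pop
#> 0.747

scan <- standardize_ihs(ihs_scan(sim$panels$pop))
scan$ihs_std[sim$focal_site]
#> [1] -2.205
ihs_percentile(scan$ihs_std[sim$focal_site], scan$ihs_std[-sim$focal_site])
#> [1] 97.6
```

The derived allele rose to frequency 0.75 and carries an unusually long
haplotype: its standardized iHS of −2.21 (negative = selection **for** the
derived allele) sits in the 97.6th percentile of the panel's |iHS|
distribution — the signature the selection scan is built to detect.

```r
# does latitude predict allele frequency beyond shared ancestry?
set.seed(2)
tree <- ape::rcoal(22)
lat <- setNames(runif(22, -40, 65), tree$tip.label)
cline <- simulate_cline(tree, lat, slope = 0.08, bm_sigma2 = 0.1, seed = 2)
fit <- fit_cline_models(cline, tree)
round(fit$fits$full$coefficients["latitude"], 4); signif(fit$lrt$p, 3)
#> latitude
#>   0.0783
#> [1] 6.12e-39
round(fit$akaike$predictor_weights, 3)
#> latitude temperature
#>    1.000       0.629
```

The fitted latitude slope (0.078 logit per degree, true value 0.08) is
strongly supported by the likelihood-ratio test against the ancestry-only
model, and latitude carries essentially all the Akaike weight.

## The analysis workflow

`analysis/` holds numbered drivers that run the pipeline end-to-end on
synthetic cohorts and write tables under `results/`:

1. `01_simulate_cohorts.R` — generate all inputs (phased VCF panels,
   MTX single-nucleus cohorts, cline TSV + newick tree, twin tables).
2. `02_fst_and_ld.R` — F<sub>ST</sub>, matched empirical p, regional LD
   contrast.
3. `03_selection_scan.R` — EHH decay, iHS scan, focal percentile.
4. `04_latitudinal_cline.R` — PGLS, LRT, Akaike weights, leave-one-out.
5. `05_trans_expression.R` — markers → unique markers → risk-allele DE →
   replication → module scores → permutation null → sex stratification.
6. `06_adipose_correlation.R` — pseudobulk TMM/INT, regional correlation
   hub, adipocyte-size correlations.

Run them in order from the repository root
(`Rscript analysis/01_simulate_cohorts.R`, …). Bulky intermediates go to
`scratch/`, summaries to `results/`.

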