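#!/usr/bin/env Rscript
# Step 1: generate every synthetic input the downstream analyses consume.
#
# Two haplotype panels ("north" and "south", split with drift) written as
# phased VCF + sample map + genetic map; a single-nucleus discovery and
# replication cohort with a planted 12-gene trans module (written as
# MTX + TSVs); a latitudinal cline dataset on a 22-population tree; and a
# BMI-discordant twin cohort. Bulky intermediates go under scratch/ (not
# part of the deliverable); small summary tables under results/.

library(clinesel)

data_dir <- "scratch/analysis_data"
res_dir <- "results"
dir.create(data_dir, showWarnings = FALSE, recursive = TRUE)
dir.create(res_dir, showWarnings = FALSE, recursive = TRUE)

## a split into a cold northern and a warmer southern environment: the
## derived focal allele (single founder origin) is selected in the north
## only (s_factor 0 keeps the south neutral)
## ascertainment: the workflow studies a variant chosen for its frequency
## difference between environments (as such variants are ascertained from
## GWAS in practice), so retry seeds until the sweep is ongoing in the
## north (both alleles segregating) and clearly differentiated from the
## neutral south
for (seed in 101:150) {
  cfg <- sim_config(n_sites = 1500, s = 0.05, generations = 50, seed = seed,
                    region_bp = 1.5e6, recombination_rate = 3e-7,
                    cM_per_Mb = 30, init_focal_freq = 0.15, focal_founders = 1)
  sim <- simulate_haplotype_panel(
    list(population_spec("north", 150, latitude = 62),
         population_spec("south", 150, latitude = 40, split_parent = "north",
                         split_generation = 0, s_factor = 0)),
    cfg)
  fn <- sim$focal_freq["north"]; fs <- sim$focal_freq["south"]
  if (min(fn, 1 - fn) >= 0.05 && min(fs, 1 - fs) >= 0.05 &&
      fn - fs >= 0.3) break
}
message(sprintf("focal derived frequency: north %.2f, south %.2f",
                sim$focal_freq["north"], sim$focal_freq["south"]))
for (nm in names(sim$panels))
  write_panel_vcf(sim$panels[[nm]], data_dir, prefix = nm)
writeLines(as.character(sim$focal_site), file.path(data_dir, "focal_site.txt"))

## single-nucleus cohorts: discovery (8-donor scale) and replication (68)
disc <- simulate_expression_cohort(n_donors = 8, cells_per_donor = 400,
                                   n_genes = 300, trans_set = 12, effect = 2,
                                   seed = 102)
repl <- simulate_expression_cohort(n_donors = 68, cells_per_donor = 150,
                                   n_genes = 300, trans_set = 12, effect = 2,
                                   seed = 103)
write_cohort_mtx(disc, file.path(data_dir, "discovery"))
write_cohort_mtx(repl, file.path(data_dir, "replication"))
writeLines(attr(disc, "trans_genes"), file.path(data_dir, "planted_trans_genes.txt"))

## latitudinal cline on a 22-population tree
set.seed(104)
tree <- ape::rcoal(22)
tree$tip.label <- sprintf("pop%02d", 1:22)
lat <- stats::setNames(runif(22, -40, 65), tree$tip.label)
cline <- simulate_cline(tree, lat, slope = 0.08, bm_sigma2 = 0.1, seed = 105)
ape::write.tree(tree, file.path(data_dir, "populations.nwk"))
write.table(cline, file.path(data_dir, "cline.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

## BMI-discordant twin cohort with a planted size correlation
tw <- simulate_twin_cohort(n_pairs = 44, target_rho = c(0.55, 0.2),
                           seed = 106)
write.table(tw$samples, file.path(data_dir, "twin_samples.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(gene = rownames(tw$expression), tw$expression,
                       check.names = FALSE),
            file.path(data_dir, "twin_expression.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

message("inputs written under ", data_dir)
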