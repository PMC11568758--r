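#!/usr/bin/env Rscript
# Step 2: differentiation at the focal site. Per-site Weir-Cockerham FST
# between the two populations, the focal site's frequency-matched empirical
# p value, and the regional LD (r2) contrast between populations.

library(clinesel)

data_dir <- "scratch/analysis_data"
res_dir <- "results"
if (!dir.exists(data_dir)) stop("run analysis/01_simulate_cohorts.R first")

north <- read_panel_vcf(file.path(data_dir, "north.vcf"),
                        map = file.path(data_dir, "north_map.tsv"),
                        population = "north")
south <- read_panel_vcf(file.path(data_dir, "south.vcf"),
                        map = file.path(data_dir, "south_map.tsv"),
                        population = "south")
focal <- as.integer(readLines(file.path(data_dir, "focal_site.txt")))

fst <- weir_cockerham_fst(panel_genotypes(north), panel_genotypes(south),
                          site_ids = north$site_ids)
message(sprintf("multi-site FST %.3f; focal-site FST %.3f",
                fst_ratio_of_sums(fst), fst$fst[focal]))

freq_north <- panel_freqs(north)
emp <- matched_empirical_p(fst$fst[focal], freq_north[focal],
                           fst$fst[-focal], freq_north[-focal], k = 1000)
message(sprintf("matched empirical p (k = %d): %.4g", emp$k, emp$p))

ld_n <- ld_profile(north, focal, window_bp = 5e5)
ld_s <- ld_profile(south, focal, window_bp = 5e5)
cmp <- compare_regional_ld(ld_n$r2, ld_s$r2)
message(sprintf("regional LD: median r2 north %.3f vs south %.3f (Wilcoxon p %.3g)",
                cmp$median_a, cmp$median_b, cmp$p))

per_site <- fst[, c("site", "fst_raw", "fst", "freq1", "freq2")]
per_site[-1] <- lapply(per_site[-1], round, 4)
write.table(per_site, file.path(res_dir, "02_fst_per_site.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(statistic = c("fst_multisite", "fst_focal",
                                     "matched_empirical_p", "ld_wilcoxon_p",
                                     "median_r2_north", "median_r2_south"),
                       value = c(fst_ratio_of_sums(fst), fst$fst[focal],
                                 emp$p, cmp$p, cmp$median_a, cmp$median_b)),
            file.path(res_dir, "02_fst_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
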