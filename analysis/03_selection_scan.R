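#!/usr/bin/env Rscript
# Step 3: haplotype-based selection statistics in the northern population.
# EHH decay around the focal site for both alleles, the iHS scan with
# frequency-bin standardization, and the focal site's percentile rank.

library(clinesel)

data_dir <- "scratch/analysis_data"
res_dir <- "results"
if (!dir.exists(data_dir)) stop("run analysis/01_simulate_cohorts.R first")

north <- read_panel_vcf(file.path(data_dir, "north.vcf"),
                        map = file.path(data_dir, "north_map.tsv"),
                        population = "north")
focal <- as.integer(readLines(file.path(data_dir, "focal_site.txt")))

curve_d <- ehh(north, focal, "derived")
curve_a <- ehh(north, focal, "ancestral")
dec_d <- ehh_decay_distance(curve_d)
dec_a <- ehh_decay_distance(curve_a)
message(sprintf("EHH decay (bp, L+R): derived %.0f, ancestral %.0f",
                sum(dec_d$distance_bp), sum(dec_a$distance_bp)))

scan <- standardize_ihs(ihs_scan(north))
foc_ihs <- scan$ihs_std[focal]
pct <- ihs_percentile(foc_ihs, scan$ihs_std[-focal])
message(sprintf("focal standardized iHS %.2f (unstd %.2f), percentile %.1f",
                foc_ihs, scan$ihs_unstd[focal], pct))

informative <- scan[!is.na(scan$ihs_unstd),
                    c("site", "freq_derived", "ihs_unstd", "ihs_std")]
num <- vapply(informative, is.numeric, TRUE)
informative[num] <- lapply(informative[num], round, 4)
write.table(informative, file.path(res_dir, "03_ihs_scan.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(rbind(cbind(allele = "derived", dec_d),
                  cbind(allele = "ancestral", dec_a)),
            file.path(res_dir, "03_ehh_decay.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(statistic = c("focal_ihs_std", "focal_ihs_unstd",
                                     "focal_percentile"),
                       value = c(foc_ihs, scan$ihs_unstd[focal], pct)),
            file.path(res_dir, "03_selection_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
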