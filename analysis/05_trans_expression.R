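#!/usr/bin/env Rscript
# Step 5: trans effects of the risk allele on adipocyte expression.
# Unique adipocyte markers in the discovery cohort, risk-allele DE on those
# markers, replication in the independent cohort with direction filtering,
# module scores of the upregulated trans genes, a 10,000-permutation donor
# null, and sex-stratified tests.

library(clinesel)

data_dir <- "scratch/analysis_data"
res_dir <- "results"
if (!dir.exists(data_dir)) stop("run analysis/01_simulate_cohorts.R first")

disc <- log_normalize(read_cohort_mtx(file.path(data_dir, "discovery")))
repl <- log_normalize(read_cohort_mtx(file.path(data_dir, "replication")))
planted <- readLines(file.path(data_dir, "planted_trans_genes.txt"))

markers <- find_cell_type_markers(disc)
uniq <- unique_markers(markers, "adipocyte")
message(sprintf("unique adipocyte markers in discovery: %d (planted trans genes among them: %d)",
                length(uniq), sum(planted %in% uniq)))

de <- risk_allele_de(disc, "adipocyte", uniq)
sig <- de$results[!is.na(de$results$p_adj) & de$results$p_adj < 0.05, ]
message(sprintf("risk-allele-associated markers in discovery: %d", nrow(sig)))

rep_out <- replicate_de(de, repl)
trans_genes <- rep_out$replicated
message(sprintf("replicated trans genes: %d (planted recovered: %d/%d)",
                length(trans_genes), sum(planted %in% trans_genes),
                length(planted)))

up <- rep_out$results$gene[rep_out$results$replicated &
                             rep_out$results$direction == "up"]
sc <- suppressWarnings(module_score(repl, up, seed = 1))
gt <- module_group_test(sc, repl)
message(sprintf("module score carrier-vs-noncarrier Wilcoxon p = %.3g", gt$p))

perm <- suppressWarnings(permutation_module_test(repl, up, B = 10000, seed = 2))
message(sprintf("permutation p: add-one %.3g, raw proportion %.3g (B = %d)",
                perm$perm_p, perm$perm_p_raw, perm$B))

strat <- sex_stratified_de(repl, "adipocyte", trans_genes)
for (sx in names(strat))
  message(sprintf("sex %s: %d/%d trans genes with adjusted p < 0.05", sx,
                  sum(strat[[sx]]$results$p_adj < 0.05, na.rm = TRUE),
                  length(trans_genes)))

write.table(de$results, file.path(res_dir, "05_discovery_de.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(rep_out$results, file.path(res_dir, "05_replication.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(statistic = c("n_unique_markers", "n_discovery_sig",
                                     "n_replicated", "module_p",
                                     "perm_p_add_one", "perm_p_raw"),
                       value = c(length(uniq), nrow(sig), length(trans_genes),
                                 gt$p, perm$perm_p, perm$perm_p_raw)),
            file.path(res_dir, "05_trans_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
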