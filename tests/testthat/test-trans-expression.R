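make_cohort <- function(...) log_normalize(simulate_expression_cohort(...))

test_that("log normalization follows its definition and invariances", {
  counts <- matrix(c(1, 0, 9999, 0, 0, 0), nrow = 3,
                   dimnames = list(paste0("g", 1:3), c("c1", "c2")))
  counts[1, 2] <- 5; counts[3, 2] <- 5
  norm <- log_normalize(counts)
  expect_equal(norm["g1", "c1"], log(2))     # count 1 of total 10000
  expect_equal(norm["g2", ], c(c1 = 0, c2 = 0))  # all-zero gene
  doubled <- log_normalize(counts * 2)
  expect_equal(doubled, norm)                # per-cell scale invariance
  zero <- cbind(counts, c3 = c(0, 0, 0))
  expect_error(log_normalize(zero), "zero total")
})

test_that("planted cell-type markers are recovered and only them", {
  coh <- make_cohort(n_donors = 20, cells_per_donor = 150, n_genes = 90,
                     trans_set = 5, effect = 1, seed = 6,
                     cell_types = c("adipocyte", "immune", "endothelial"),
                     markers_per_type = 10, marker_lfc = 6)
  mk <- find_cell_type_markers(coh)
  planted <- attr(coh, "marker_genes")
  for (ct in names(planted)) {
    found <- mk[[ct]]$gene[mk[[ct]]$marker]
    expect_setequal(found, planted[[ct]])
  }
  # flat gene is never a marker (logFC 0 < 0.25)
  flat <- mk$adipocyte[mk$adipocyte$gene == "gene_40", ]
  expect_false(flat$marker)
  # a type with too few cells is skipped with a warning
  coh2 <- coh
  drop <- which(coh2$cells$cell_type == "immune")[-(1:2)]
  coh2$cells$cell_type[drop] <- "adipocyte"
  expect_warning(find_cell_type_markers(coh2), "fewer than")
})

test_that("unique marker sets are the target set minus all other types", {
  mk <- list(
    adipocyte = data.frame(gene = c("A", "B", "C"), marker = TRUE),
    tcell = data.frame(gene = "B", marker = TRUE))
  expect_setequal(unique_markers(mk, "adipocyte"), c("A", "C"))
  mk$tcell$gene <- "Z"
  expect_setequal(unique_markers(mk, "adipocyte"), c("A", "B", "C"))
  mk$tcell <- data.frame(gene = c("A", "B", "C"), marker = TRUE)
  expect_warning(u <- unique_markers(mk, "adipocyte"), "shared")
  expect_length(u, 0)
  expect_error(unique_markers(mk, "nope"), "no marker results")
})

test_that("risk-allele DE recovers a planted trans module with directions", {
  coh <- make_cohort(seed = 3)   # 60 donors x 200 cells, 12-gene 2x module
  genes <- attr(coh, "trans_genes")
  de <- risk_allele_de(coh, "adipocyte", genes)
  expect_true(all(de$results$p_adj < 0.05))
  expect_true(all(de$results$direction == "up"))
  # absent genes are reported, not tested
  de2 <- risk_allele_de(coh, "adipocyte", c(genes, "ghost_gene"))
  expect_equal(de2$skipped, "ghost_gene")
  expect_false("ghost_gene" %in% de2$results$gene)
})

test_that("null risk-allele DE keeps Bonferroni discoveries at the nominal
           level", {
  hits <- vapply(1:8, function(sd) {
    coh <- make_cohort(n_donors = 24, cells_per_donor = 40, n_genes = 80,
                       trans_set = 8, effect = 1, seed = sd,
                       cell_types = c("adipocyte", "immune"),
                       markers_per_type = 10)
    de <- risk_allele_de(coh, "adipocyte", rownames(coh$counts))
    sum(de$results$p_adj < 0.05, na.rm = TRUE)
  }, 0)
  # cell-level tests are anti-conservative under donor structure, but a
  # null effect should not produce module-scale discovery counts
  expect_lte(mean(hits), 3)
})

test_that("replication requires significance and direction concordance", {
  disc_coh <- make_cohort(seed = 4)
  genes <- attr(disc_coh, "trans_genes")
  de <- risk_allele_de(disc_coh, "adipocyte", genes)
  same <- replicate_de(de, make_cohort(seed = 104))
  expect_setequal(same$replicated, genes)
  flipped <- replicate_de(de, make_cohort(effect = 0.5, seed = 204))
  expect_length(flipped$replicated, 0)
  empty <- replicate_de(list(results = de$results[0, ]), disc_coh)
  expect_length(empty$replicated, 0)
  expect_null(empty$results)
})

test_that("module scores vanish for constant input and ignore global shifts", {
  coh <- make_cohort(n_donors = 8, cells_per_donor = 20, n_genes = 50,
                     trans_set = 5, effect = 1, seed = 7,
                     cell_types = c("adipocyte", "immune"),
                     markers_per_type = 5)
  const <- coh
  const$normalized[] <- 1.7
  s0 <- suppressWarnings(module_score(const, attr(coh, "trans_genes"), seed = 2))
  expect_equal(unname(s0), rep(0, ncol(coh$counts)), ignore_attr = TRUE)
  s1 <- suppressWarnings(module_score(coh, attr(coh, "trans_genes"), seed = 2))
  shifted <- coh
  shifted$normalized <- coh$normalized + 3
  s2 <- suppressWarnings(module_score(shifted, attr(coh, "trans_genes"), seed = 2))
  expect_equal(s1, s2)
  expect_identical(
    s1, suppressWarnings(module_score(coh, attr(coh, "trans_genes"), seed = 2)))
  expect_error(module_score(coh, "ghost"), "absent")
})

test_that("a +c shift of the module relative to matched controls gives mean
           score near c", {
  set.seed(8)
  n_genes <- 60; n_cells <- 100
  norm <- matrix(rnorm(n_genes * n_cells, 1, 0.2), n_genes, n_cells,
                 dimnames = list(paste0("g", 1:n_genes), paste0("c", 1:n_cells)))
  set_genes <- paste0("g", 1:6)
  norm[set_genes, ] <- norm[set_genes, ] + 0.8
  coh <- structure(list(
    counts = matrix(1, n_genes, n_cells, dimnames = dimnames(norm)),
    cells = data.frame(cell_id = colnames(norm), cell_type = "adipocyte",
                       donor_id = rep(c("d1", "d2"), 50)),
    donors = data.frame(donor_id = c("d1", "d2"),
                        risk_carrier = c(TRUE, FALSE), sex = "F", age = 50),
    normalized = norm), class = "cell_cohort")
  sc <- module_score(coh, set_genes, n_bins = 1, n_ctrl = 40, seed = 3)
  expect_equal(mean(sc), 0.8, tolerance = 0.1)
})

test_that("module group test separates separated groups and errors when a
           group is empty", {
  coh <- make_cohort(n_donors = 10, cells_per_donor = 20, n_genes = 40,
                     trans_set = 4, effect = 1, seed = 10,
                     cell_types = c("adipocyte", "immune"),
                     markers_per_type = 5)
  carriers <- coh$donors$donor_id[coh$donors$risk_carrier]
  sc <- rep(0, ncol(coh$counts))
  names(sc) <- coh$cells$cell_id
  sc[coh$cells$donor_id %in% carriers] <- 1   # complete separation
  gt <- module_group_test(sc, coh)
  expect_lt(gt$p, 1e-25)
  expect_equal(gt$median_carrier, 1)
  bad <- coh
  bad$donors$risk_carrier <- FALSE
  expect_error(module_group_test(sc, bad), "empty")
})

test_that("planted module effects strengthen the group separation
           monotonically", {
  pvals <- vapply(c(1.2, 1.6, 2.2), function(eff) {
    coh <- make_cohort(n_donors = 30, cells_per_donor = 50, n_genes = 60,
                       trans_set = 6, effect = eff, seed = 11,
                       cell_types = c("adipocyte", "immune"),
                       markers_per_type = 8)
    sc <- suppressWarnings(module_score(coh, attr(coh, "trans_genes"),
                                        n_bins = 10, n_ctrl = 20, seed = 1))
    log10(module_group_test(sc, coh)$p)
  }, 0)
  expect_true(all(diff(pvals) < 0))
})

test_that("donor-level permutation p has the add-one floor and caps B", {
  coh <- make_cohort(n_donors = 60, cells_per_donor = 50, n_genes = 60,
                     trans_set = 8, effect = 3, seed = 12,
                     cell_types = c("adipocyte", "immune"),
                     markers_per_type = 10)
  pt <- suppressWarnings(
    permutation_module_test(coh, attr(coh, "trans_genes"), B = 10000,
                            seed = 5, n_bins = 10, n_ctrl = 15))
  expect_equal(pt$perm_p, 1 / 10001)
  expect_equal(pt$perm_p_raw, 0)
  expect_gte(pt$perm_p, 1 / (pt$B + 1))
  # B capped at the number of distinct assignments
  tiny <- make_cohort(n_donors = 6, cells_per_donor = 10, n_genes = 30,
                      trans_set = 3, effect = 1, seed = 13, risk_maf = 0.5,
                      cell_types = c("adipocyte", "immune"),
                      markers_per_type = 5)
  expect_message(
    ptt <- suppressWarnings(
      permutation_module_test(tiny, attr(tiny, "trans_genes"), B = 1e6,
                              seed = 1, n_bins = 5, n_ctrl = 5)),
    "capped")
  expect_equal(ptt$B, choose(6, sum(tiny$donors$risk_carrier)))
})

test_that("sex-stratified DE localizes an effect planted in one sex", {
  coh <- simulate_expression_cohort(n_donors = 40, cells_per_donor = 80,
                                    n_genes = 60, trans_set = 6, effect = 1,
                                    seed = 14, p_female = 0.5,
                                    cell_types = c("adipocyte", "immune"),
                                    markers_per_type = 8)
  # balanced sex x carrier design, assigned deterministically
  coh$donors$sex <- rep(c("F", "M"), 20)
  coh$donors$risk_carrier <- rep(c(TRUE, TRUE, FALSE, FALSE), 10)
  genes <- attr(coh, "trans_genes")
  f_carrier <- with(coh$donors, donor_id[sex == "F" & risk_carrier])
  cells_f <- coh$cells$donor_id %in% f_carrier
  coh$counts[genes, cells_f] <- coh$counts[genes, cells_f] * 3
  coh <- log_normalize(coh)
  strat <- sex_stratified_de(coh, "adipocyte", genes)
  expect_true(all(strat$F$results$p_adj < 0.05))
  expect_gt(min(strat$M$results$p_adj), 0.05)
  expect_true(all(strat$F$results$tier[strat$F$results$p_adj < 1e-4] == "****"))
  # a sex without both carrier groups is skipped
  coh$donors$risk_carrier[coh$donors$sex == "M"] <- FALSE
  expect_message(s2 <- sex_stratified_de(coh, "adipocyte", genes), "skipped")
  expect_null(s2$M)
})
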