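test_that("neutral drift keeps the focal frequency near its starting value", {
  # 2N = 2000, 5 generations: drift SD per run is sqrt(p(1-p)t/2N)
  drift_sd <- sqrt(0.3 * 0.7 * 5 / 2000)
  n_ok <- sum(vapply(1:40, function(sd) {
    sim <- simulate_haplotype_panel(
      population_spec("A", 1000),
      sim_config(n_sites = 20, s = 0, generations = 5, seed = sd,
                 init_focal_freq = 0.3))
    abs(sim$focal_freq - 0.3) <= 3 * drift_sd
  }, TRUE))
  expect_gte(n_ok, 39)
})

test_that("selection raises the mean final derived frequency over neutrality", {
  fin <- vapply(1:25, function(sd) {
    sel <- simulate_haplotype_panel(
      population_spec("A", 100),
      sim_config(n_sites = 30, s = 0.05, generations = 200, seed = sd,
                 init_focal_freq = 0.05))$focal_freq
    neu <- simulate_haplotype_panel(
      population_spec("A", 100),
      sim_config(n_sites = 30, s = 0, generations = 200, seed = sd,
                 init_focal_freq = 0.05))$focal_freq
    c(sel, neu)
  }, c(0, 0))
  expect_gt(mean(fin[1, ]), mean(fin[2, ]))
})

test_that("drift after a clean split matches the 1 - exp(-t/2N) expectation", {
  fsts <- vapply(1:5, function(sd) {
    sim <- simulate_haplotype_panel(
      list(population_spec("A", 50),
           population_spec("B", 50, split_parent = "A", split_generation = 0)),
      sim_config(n_sites = 500, s = 0, generations = 100, seed = sd,
                 recombination_rate = 0, init_freq_range = c(0.2, 0.8)))
    fst_ratio_of_sums(
      weir_cockerham_fst(panel_genotypes(sim$panels$A),
                         panel_genotypes(sim$panels$B)))
  }, 0)
  expect_lt(abs(mean(fsts) / (1 - exp(-1)) - 1), 0.2)
})

test_that("the simulator is deterministic and conserves allele counts", {
  cfg <- sim_config(n_sites = 80, s = 0.02, generations = 25, seed = 7)
  a <- simulate_haplotype_panel(population_spec("A", 40), cfg)
  b <- simulate_haplotype_panel(population_spec("A", 40), cfg)
  expect_identical(a$panels$A$haps, b$panels$A$haps)
  cnt <- colSums(a$panels$A$haps)
  expect_true(all(cnt >= 0 & cnt <= 80))
  expect_true(all(a$panels$A$haps %in% c(0L, 1L)))
})

test_that("without recombination every offspring haplotype is parental", {
  cfg <- sim_config(n_sites = 60, s = 0, generations = 1, seed = 3,
                    recombination_rate = 0)
  set.seed(cfg$seed)
  pos <- sort(sample.int(cfg$region_bp, cfg$n_sites))
  sim <- simulate_haplotype_panel(population_spec("A", 30), cfg)
  # rebuild generation 0 under the same seed, then compare haplotype sets
  cfg0 <- sim_config(n_sites = 60, s = 0, generations = 0, seed = 3,
                     recombination_rate = 0)
  gen0 <- simulate_haplotype_panel(population_spec("A", 30), cfg0)
  parents <- apply(gen0$panels$A$haps, 1, paste, collapse = "")
  offspring <- apply(sim$panels$A$haps, 1, paste, collapse = "")
  expect_true(all(offspring %in% parents))
})

test_that("island-model FST decreases as migration increases", {
  mean_fst <- vapply(c(0, 0.02, 0.1), function(m) {
    mean(vapply(1:3, function(sd) {
      sim <- simulate_haplotype_panel(
        list(population_spec("A", 50),
             population_spec("B", 50, split_parent = "A", split_generation = 0)),
        sim_config(n_sites = 300, s = 0, generations = 80, seed = sd,
                   recombination_rate = 0, migration_rate = m,
                   init_freq_range = c(0.2, 0.8)))
      fst_ratio_of_sums(
        weir_cockerham_fst(panel_genotypes(sim$panels$A),
                           panel_genotypes(sim$panels$B)))
    }, 0))
  }, 0)
  expect_true(all(diff(mean_fst) < 0))
})

test_that("invalid simulator inputs are rejected", {
  expect_error(sim_config(10, recombination_rate = -1), "recombination")
  expect_error(sim_config(10, focal_site_index = 11), "out of range")
  expect_error(population_spec("A", 1), "diploid_size")
  expect_error(population_spec("A", 10, latitude = 100), "latitude")
  expect_error(simulate_haplotype_panel(list(), sim_config(10)),
               "at least one population")
})

test_that("the cline generator honours its degenerate and monotone limits", {
  tree <- ape::rcoal(8)
  lat <- stats::setNames(seq(-35, 35, length.out = 8), tree$tip.label)
  flat <- simulate_cline(tree, lat, slope = 0, bm_sigma2 = 0, intercept = 0.5)
  expect_equal(flat$frequency, rep(1 / (1 + exp(-0.5)), 8))
  up <- simulate_cline(tree, lat, slope = 0.1, bm_sigma2 = 0, intercept = 0)
  expect_true(all(diff(up$frequency[order(up$latitude_deg)]) > 0))
  noisy <- simulate_cline(tree, lat, slope = 0.05, bm_sigma2 = 0.4, seed = 5)
  expect_true(all(noisy$frequency > 0 & noisy$frequency < 1))
  expect_identical(noisy, simulate_cline(tree, lat, slope = 0.05,
                                         bm_sigma2 = 0.4, seed = 5))
  expect_error(simulate_cline(tree, lat[-1]), "must match")
})

test_that("expression cohort genotypes follow Hardy-Weinberg and the planted
           effect shifts only the trans genes", {
  coh <- simulate_expression_cohort(n_donors = 1000, cells_per_donor = 2,
                                    n_genes = 40, trans_set = 4, effect = 1,
                                    risk_maf = 0.4, seed = 2)
  geno <- coh$donors$genotype
  expect_equal(mean(geno) / 2, 0.4, tolerance = 0.1)
  hw <- c(0.36, 0.48, 0.16)
  obs <- unname(table(factor(geno, 0:2))) / 1000
  expect_lt(max(abs(obs - hw)), 0.05)

  coh2 <- simulate_expression_cohort(n_donors = 40, cells_per_donor = 100,
                                     n_genes = 60, trans_set = 5, effect = 3,
                                     seed = 4, cell_types = c("adipocyte", "immune"),
                                     markers_per_type = 10)
  carrier_cells <- coh2$cells$donor_id %in%
    coh2$donors$donor_id[coh2$donors$risk_carrier]
  tg <- attr(coh2, "trans_genes")
  ratio <- rowMeans(coh2$counts[, carrier_cells]) /
    rowMeans(coh2$counts[, !carrier_cells])
  expect_true(all(ratio[tg] > 2))
  other <- setdiff(rownames(coh2$counts), tg)
  expect_lt(median(ratio[other]), 1.3)

  expect_identical(
    simulate_expression_cohort(n_donors = 10, cells_per_donor = 5,
                               n_genes = 20, trans_set = 2, seed = 9)$counts,
    simulate_expression_cohort(n_donors = 10, cells_per_donor = 5,
                               n_genes = 20, trans_set = 2, seed = 9)$counts)
  expect_error(simulate_expression_cohort(effect = 0), "effect")
  expect_error(simulate_expression_cohort(risk_maf = 1.2), "risk_maf")
  # all donors in one carrier group within the retry budget -> error
  expect_error(simulate_expression_cohort(n_donors = 2, risk_maf = 0.999,
                                          cells_per_donor = 2, n_genes = 10,
                                          trans_set = 1, seed = 1,
                                          max_retries = 3),
               "carrier")
})

test_that("twin cohort copula is calibrated and deterministic", {
  rh <- vapply(1:60, function(sd) {
    tw <- simulate_twin_cohort(n_pairs = 45, target_rho = 0.55, seed = sd)
    low <- tw$samples$bmi_group == "lower"
    cor(tw$expression[1, low], tw$samples$diameter_um[low],
        method = "spearman")
  }, 0)
  expect_gt(mean(rh), 0.48)
  expect_lt(mean(rh), 0.60)
  expect_gte(mean(rh >= 0.30 & rh <= 0.75), 0.9)

  null_rho <- vapply(1:30, function(sd) {
    tw <- simulate_twin_cohort(n_pairs = 40, target_rho = 0, seed = sd)
    low <- tw$samples$bmi_group == "lower"
    cor(tw$expression[1, low], tw$samples$diameter_um[low],
        method = "spearman")
  }, 0)
  expect_lt(abs(mean(null_rho)), 2 / sqrt(40))

  expect_identical(simulate_twin_cohort(seed = 3),
                   simulate_twin_cohort(seed = 3))
  expect_error(simulate_twin_cohort(n_pairs = 2), "n_pairs")
  expect_error(simulate_twin_cohort(target_rho = 1.5), "target_rho")
})

test_that("panel VCF round-trip preserves alleles, positions and map", {
  sim <- simulate_haplotype_panel(
    population_spec("FIN", 15),
    sim_config(n_sites = 40, seed = 21, cM_per_Mb = 2))
  pan <- sim$panels$FIN
  dir <- withr::local_tempdir()
  files <- write_panel_vcf(pan, dir, prefix = "t")
  back <- read_panel_vcf(files["vcf"], map = files["map"], population = "FIN")
  expect_identical(back$haps, pan$haps)
  expect_equal(back$pos_bp, pan$pos_bp)
  expect_equal(back$pos_cM, pan$pos_cM, tolerance = 1e-8)
})

test_that("cohort MTX round-trip preserves counts and annotations", {
  coh <- simulate_expression_cohort(n_donors = 6, cells_per_donor = 8,
                                    n_genes = 25, trans_set = 3, seed = 5)
  dir <- withr::local_tempdir()
  write_cohort_mtx(coh, dir)
  back <- read_cohort_mtx(dir)
  expect_equal(as.matrix(back$counts), as.matrix(coh$counts),
               ignore_attr = TRUE)
  expect_equal(back$cells$donor_id, coh$cells$donor_id)
  expect_equal(back$donors$risk_carrier, coh$donors$risk_carrier)
})
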