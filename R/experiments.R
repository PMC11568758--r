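#' Study conditions for the neutral iHS calibration panel
#'
#' A single population of 100 diploids sampled after 150 generations of
#' neutral Wright-Fisher evolution from a 40-founder pool; 20,000 sites
#' over 10 Mb with a per-bp recombination rate of 1e-6, chosen so the
#' population-scaled rate rho = 4Nr per bp matches human-scale data
#' (4 x 1e4 x 1e-8) at the scaled-down N. More than 10,000 sites pass the
#' MAF >= 0.05 filter under these conditions.
#'
#' @param seed integer RNG seed.
#' @return a [sim_config()].
#' @export
neutral_panel_config <- function(seed = 1L) {
  sim_config(n_sites = 20000, s = 0, generations = 150, seed = seed,
             region_bp = 1e7, recombination_rate = 1e-6, n_founders = 40,
             cM_per_Mb = 100)
}

#' Neutral calibration of the standardized iHS distribution
#'
#' Simulates the [neutral_panel_config()] panel, scans iHS at every site
#' passing the MAF filter, standardizes in frequency bins, and summarizes
#' the pooled standardized distribution.
#'
#' @param seed integer RNG seed.
#' @return list with `records` (the standardized scan), `n` (sites with a
#'   defined standardized iHS), `mean`, `sd`, and `tail_frac`
#'   (fraction with |iHS| >= 2).
#' @export
neutral_ihs_calibration <- function(seed = 1L) {
  sim <- simulate_haplotype_panel(population_spec("pop", 100),
                                  neutral_panel_config(seed))
  rec <- standardize_ihs(ihs_scan(sim$panels$pop))
  v <- rec$ihs_std[!is.na(rec$ihs_std)]
  list(records = rec, n = length(v), mean = mean(v), sd = stats::sd(v),
       tail_frac = mean(abs(v) >= 2))
}

#' Study conditions for the ongoing-hard-sweep panel
#'
#' A single population of 300 diploids, 3,000 sites over 3 Mb,
#' recombination 3e-7 per bp (again preserving rho = 4Nr at the scaled-down
#' N), evolved for 130 generations. The derived focal allele enters as a
#' single copy at generation 0 with additive advantage `s` and the run is
#' conditioned on the sweep still segregating (MAF >= 0.05) at sampling.
#'
#' @param seed integer RNG seed.
#' @param s selection coefficient (default 0.05).
#' @return a [sim_config()].
#' @export
sweep_panel_config <- function(seed = 1L, s = 0.05) {
  sim_config(n_sites = 3000, s = s, generations = 130, seed = seed,
             region_bp = 3e6, recombination_rate = 3e-7, n_founders = 40,
             cM_per_Mb = 30, selection_start = 0L, introduce_focal = TRUE,
             max_establish_retries = 500L)
}

#' Selection-detection power experiment
#'
#' For each seed, simulates an ongoing hard sweep under
#' [sweep_panel_config()], scans and standardizes iHS over the whole panel,
#' and records the focal site's standardized iHS, its percentile among the
#' neutral background, the focal frequency, and the EHH decay distances of
#' the two focal alleles.
#'
#' @param seeds integer vector of seeds, one sweep per seed.
#' @param s selection coefficient (default 0.05).
#' @return data.frame with one row per seed: `seed`, `focal_ihs`,
#'   `percentile`, `focal_freq`, `decay_derived_bp`, `decay_ancestral_bp`.
#' @export
sweep_power_experiment <- function(seeds = 1:6, s = 0.05) {
  do.call(rbind, lapply(seeds, function(sd) {
    sim <- simulate_haplotype_panel(population_spec("pop", 300),
                                    sweep_panel_config(sd, s))
    pan <- sim$panels$pop
    rec <- standardize_ihs(ihs_scan(pan))
    foc <- rec$ihs_std[sim$focal_site]
    pct <- if (is.na(foc)) NA_real_ else
      ihs_percentile(foc, rec$ihs_std[-sim$focal_site])
    dd <- sum(ehh_decay_distance(ehh(pan, sim$focal_site, "derived"))$distance_bp)
    da <- sum(ehh_decay_distance(ehh(pan, sim$focal_site, "ancestral"))$distance_bp)
    data.frame(seed = sd, focal_ihs = foc, percentile = pct,
               focal_freq = sim$focal_freq, decay_derived_bp = dd,
               decay_ancestral_bp = da, row.names = NULL)
  }))
}

#' Type-I error of the PGLS likelihood-ratio test
#'
#' Simulates null clines (latitude slope 0) on a fixed coalescent tree of
#' `n_tips` populations and records the rejection rate of the full-vs-null
#' likelihood-ratio test at `alpha`. The tree size defaults to 200 tips,
#' the asymptotic regime of the chi-square reference.
#'
#' @param n_reps number of null replicates.
#' @param n_tips tree size.
#' @param alpha nominal level.
#' @param seed integer RNG seed.
#' @return list with `rejection_rate`, `n_reps`, `n_tips`.
#' @export
lrt_type1_experiment <- function(n_reps = 2000, n_tips = 200, alpha = 0.05,
                                 seed = 1L) {
  set.seed(seed)
  tree <- ape::rcoal(n_tips)
  lat <- stats::setNames(stats::runif(n_tips, -60, 60), tree$tip.label)
  rej <- vapply(seq_len(n_reps), function(b) {
    cl <- simulate_cline(tree, lat, slope = 0, bm_sigma2 = 0.3,
                         intercept = -0.5, seed = seed * 1000L + b)
    fit_cline_models(cl, tree)$lrt$p < alpha
  }, TRUE)
  list(rejection_rate = mean(rej), n_reps = n_reps, n_tips = n_tips)
}

#' Latitude-slope recovery of the PGLS cline model
#'
#' Simulates clines with a known latitude slope on a fixed 22-population
#' coalescent tree and refits the full model (logit response, matching the
#' generator's link) for each replicate.
#'
#' @param n_reps number of replicates.
#' @param slope true latitude slope on the logit scale (default 0.08).
#' @param bm_sigma2 Brownian rate of the generator.
#' @param n_tips number of populations (default 22).
#' @param seed integer RNG seed.
#' @return list with `slopes` (vector), `mean_slope`, `true_slope`.
#' @export
cline_recovery_experiment <- function(n_reps = 500, slope = 0.08,
                                      bm_sigma2 = 0.1, n_tips = 22,
                                      seed = 1L) {
  set.seed(seed)
  tree <- ape::rcoal(n_tips)
  lat <- stats::setNames(stats::runif(n_tips, -60, 60), tree$tip.label)
  sl <- vapply(seq_len(n_reps), function(b) {
    cl <- simulate_cline(tree, lat, slope = slope, bm_sigma2 = bm_sigma2,
                         seed = seed * 1000L + b)
    unname(fit_cline_models(cl, tree)$fits$full$coefficients["latitude"])
  }, 0)
  list(slopes = sl, mean_slope = mean(sl), true_slope = slope)
}

#' Uniformity of the matched-SNP empirical p under exchangeability
#'
#' Draws the focal statistic from the same distribution as the candidates
#' (so the matched-null p should be uniform on its grid) and returns the
#' replicate p values with a Kolmogorov-Smirnov comparison to U(0, 1).
#'
#' @param n_reps replicates.
#' @param k matched candidates per replicate.
#' @param seed integer RNG seed.
#' @return list with `p_values`, `ks_stat`, `ks_p`.
#' @export
matched_p_uniformity_experiment <- function(n_reps = 2000, k = 2000,
                                            seed = 1L) {
  set.seed(seed)
  ps <- vapply(seq_len(n_reps), function(i) {
    fst <- stats::rchisq(k + 1, 1) / 50
    fr <- stats::runif(k + 1, 0.2, 0.4)
    matched_empirical_p(fst[1], fr[1], fst[-1], fr[-1], k = k)$p
  }, 0)
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  list(p_values = ps, ks_stat = unname(ks$statistic), ks_p = ks$p.value)
}

#' Uniformity of the donor-permutation module p under the null
#'
#' Simulates label-invariant cohorts (no trans effect) and runs the
#' donor-level permutation module test on each; the permutation p should be
#' approximately uniform.
#'
#' @param n_reps replicates (one cohort each).
#' @param B permutations per cohort.
#' @param seed integer RNG seed.
#' @return list with `p_values`, `ks_stat`, `ks_p`.
#' @export
permutation_p_uniformity_experiment <- function(n_reps = 150, B = 99,
                                                seed = 1L) {
  ps <- vapply(seq_len(n_reps), function(i) {
    coh <- simulate_expression_cohort(
      n_donors = 20, cells_per_donor = 30, n_genes = 60, trans_set = 6,
      effect = 1, seed = seed * 1000L + i,
      cell_types = c("adipocyte", "immune"), markers_per_type = 10)
    coh <- log_normalize(coh)
    suppressWarnings(
      permutation_module_test(coh, attr(coh, "trans_genes"), B = B,
                              seed = seed * 1000L + i, n_bins = 10,
                              n_ctrl = 10)$perm_p)
  }, 0)
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  list(p_values = ps, ks_stat = unname(ks$statistic), ks_p = ks$p.value)
}

#' Planted trans-module recovery and replication experiment
#'
#' For each seed, simulates a discovery cohort with a 2-fold planted trans
#' module (12 genes, 60 donors x 200 cells), tests the module genes for
#' risk-allele effects, replicates in an independently seeded cohort with
#' the same effect, and in a cohort with the effect sign flipped.
#'
#' @param seeds integer vector of seeds.
#' @param effect planted multiplicative effect (default 2).
#' @return data.frame per seed: `n_recovered` (of 12, discovery),
#'   `n_replicated` (same-effect replication), `n_flipped_replicated`
#'   (sign-flipped replication; should be 0).
#' @export
trans_recovery_experiment <- function(seeds = 1:6, effect = 2) {
  do.call(rbind, lapply(seeds, function(sd) {
    disc <- log_normalize(simulate_expression_cohort(effect = effect,
                                                     seed = sd))
    genes <- attr(disc, "trans_genes")
    de <- risk_allele_de(disc, "adipocyte", genes)
    rep_same <- log_normalize(simulate_expression_cohort(effect = effect,
                                                         seed = sd + 500L))
    rep_flip <- log_normalize(simulate_expression_cohort(effect = 1 / effect,
                                                         seed = sd + 900L))
    r1 <- replicate_de(de, rep_same)
    r2 <- replicate_de(de, rep_flip)
    data.frame(seed = sd,
               n_recovered = sum(de$results$p_adj < 0.05 &
                                   de$results$logfc > 0, na.rm = TRUE),
               n_replicated = length(r1$replicated),
               n_flipped_replicated = length(r2$replicated),
               row.names = NULL)
  }))
}
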