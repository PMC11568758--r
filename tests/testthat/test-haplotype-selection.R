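test_that("EHH equals the combinatorial value for hand-built panels", {
  # 4 carriers splitting into two groups of 2 -> (1 + 1) / C(4,2) = 1/3
  haps <- rbind(c(1, 1, 0), c(1, 1, 0), c(0, 1, 1), c(0, 1, 1),
                c(0, 0, 0), c(1, 0, 1))
  pan <- toy_panel(haps)
  cv <- ehh(pan, 2, "derived")
  expect_equal(cv$left$ehh, 1 / 3)
  expect_equal(cv$right$ehh, 1 / 3)
  # all carriers identical out to the edge -> EHH stays 1
  ident <- toy_panel(rbind(c(1, 1, 1), c(1, 1, 1), c(0, 0, 1), c(0, 1, 0)))
  expect_equal(ehh(ident, 1, "derived")$right$ehh, c(1, 1))
  # fewer than two carriers -> error with the count
  expect_error(ehh(toy_panel(rbind(c(1, 0), c(0, 0), c(0, 1), c(0, 0))), 1,
                   "derived"), "1 carrier")
})

test_that("EHH matches the exhaustive pairwise oracle on random small panels", {
  for (sd in 1:6) {
    set.seed(sd)
    haps <- matrix(rbinom(16 * 12, 1, 0.5), 16, 12)
    core <- sample(2:11, 1)
    for (al in 0:1) {
      if (sum(haps[, core] == al) < 2) next
      curve <- ehh(toy_panel(haps), core,
                   if (al == 1) "derived" else "ancestral")
      for (j in seq_len(nrow(curve$right)))
        expect_equal(curve$right$ehh[j],
                     oracle_ehh(haps, core, al, core + j), tolerance = 1e-12)
      for (j in seq_len(nrow(curve$left)))
        expect_equal(curve$left$ehh[j],
                     oracle_ehh(haps, core, al, core - j), tolerance = 1e-12)
    }
  }
})

test_that("EHH curves are non-increasing and invariant to row permutation and
           non-core relabeling", {
  set.seed(9)
  haps <- matrix(rbinom(20 * 15, 1, 0.5), 20, 15)
  pan <- toy_panel(haps)
  cv <- ehh(pan, 8, "derived")
  expect_true(all(diff(c(1, cv$right$ehh)) <= 1e-12))
  expect_true(all(diff(c(1, cv$left$ehh)) <= 1e-12))
  perm <- toy_panel(haps[sample(20), ])
  cvp <- ehh(perm, 8, "derived")
  expect_equal(cvp$right$ehh, cv$right$ehh)
  expect_equal(cvp$left$ehh, cv$left$ehh)
  flip <- haps
  flip[, -8] <- 1L - flip[, -8]
  cvf <- ehh(toy_panel(flip), 8, "derived")
  expect_equal(cvf$right$ehh, cv$right$ehh)
  expect_equal(cvf$left$ehh, cv$left$ehh)
})

test_that("decay distance reads the curve correctly, with edge censoring", {
  fake <- structure(list(
    core_site = "s", core_allele = "derived", n_carriers = 4,
    left = data.frame(site = character(0), distance_bp = numeric(0),
                      distance_cM = numeric(0), ehh = numeric(0)),
    right = data.frame(site = c("a", "b"), distance_bp = c(1e4, 2e4),
                       distance_cM = c(0.01, 0.02), ehh = c(0.6, 0.04))),
    class = "ehh_curve")
  d <- ehh_decay_distance(fake, threshold = 0.05)
  expect_equal(d$distance_bp[d$direction == "right"], 1e4)
  expect_false(d$censored[d$direction == "right"])
  fake$right$ehh <- c(0.6, 0.5)   # never below threshold -> censored at edge
  d2 <- ehh_decay_distance(fake, threshold = 0.05)
  expect_equal(d2$distance_bp[d2$direction == "right"], 2e4)
  expect_true(d2$censored[d2$direction == "right"])
})

test_that("integrated EHH is the truncated trapezoid over genetic distance", {
  fake <- structure(list(
    core_site = "s", core_allele = "derived", n_carriers = 4,
    left = data.frame(site = character(0), distance_bp = numeric(0),
                      distance_cM = numeric(0), ehh = numeric(0)),
    right = data.frame(site = c("a", "b"), distance_bp = c(1e6, 2e6),
                       distance_cM = c(1, 2), ehh = c(0.5, 0.01))),
    class = "ehh_curve")
  # (1 + 0.5)/2 * 1 = 0.75, second site below threshold -> truncated
  expect_equal(integrated_ehh(fake), 0.75)
  # EHH == 1 over [0, 2 cM] -> rectangle of area 2
  fake$right <- data.frame(site = c("a", "b"), distance_bp = c(1e6, 2e6),
                           distance_cM = c(1, 2), ehh = c(1, 1))
  expect_equal(integrated_ehh(fake), 2)
  # symmetric two-direction curve doubles the one-direction integral
  fake$left <- fake$right
  expect_equal(integrated_ehh(fake), 4)
  # degenerate curve warns and returns 0
  fake$left$ehh <- fake$right$ehh <- c(0.01, 0.01)
  expect_warning(expect_equal(integrated_ehh(fake), 0), "iHH = 0")
})

test_that("iHH and unstandardized iHS match the exhaustive oracle exactly", {
  for (sd in 1:4) {
    set.seed(sd + 20)
    haps <- matrix(rbinom(8 * 10, 1, 0.5), 8, 10)
    core <- 5
    if (min(sum(haps[, core]), sum(1 - haps[, core])) < 2) next
    pan <- toy_panel(haps, cM_per_Mb = 100)
    rec <- unstandardized_ihs(pan, core, maf_min = 0)
    oa <- oracle_ihh(haps, pan$pos_cM, core, 0)
    od <- oracle_ihh(haps, pan$pos_cM, core, 1)
    expect_equal(rec$ihh_ancestral, oa, tolerance = 1e-12)
    expect_equal(rec$ihh_derived, od, tolerance = 1e-12)
    if (oa > 0 && od > 0)
      expect_equal(rec$ihs_unstd, log(oa / od), tolerance = 1e-12)
  }
})

test_that("iHS sign convention and antisymmetry hold", {
  # derived carriers identical everywhere, ancestral maximally diverse
  derived <- matrix(1L, 6, 9)
  set.seed(31)
  anc <- matrix(rbinom(6 * 9, 1, 0.5), 6, 9)
  anc[, 5] <- 0L
  haps <- rbind(derived, anc)
  pan <- toy_panel(haps, cM_per_Mb = 100)
  rec <- unstandardized_ihs(pan, 5, maf_min = 0)
  expect_lt(rec$ihs_unstd, 0)
  # swapping ancestral/derived labels at the core negates iHS
  swapped <- haps
  swapped[, 5] <- 1L - swapped[, 5]
  rec2 <- unstandardized_ihs(toy_panel(swapped, cM_per_Mb = 100), 5,
                             maf_min = 0)
  expect_equal(rec2$ihs_unstd, -rec$ihs_unstd, tolerance = 1e-12)
  # mirror-image structure between the classes -> iHS = 0
  mirror <- rbind(cbind(anc[, 1:4], 1L, anc[, 6:9]),
                  cbind(anc[, 1:4], 0L, anc[, 6:9]))
  rec3 <- unstandardized_ihs(toy_panel(mirror, cM_per_Mb = 100), 5,
                             maf_min = 0)
  expect_equal(rec3$ihs_unstd, 0, tolerance = 1e-12)
})

test_that("a mid-rise sweep stretches the derived allele's EHH decay span
           beyond the ancestral allele's", {
  res <- vapply(1:4, function(sd) {
    cfg <- sim_config(n_sites = 1500, s = 0.05, generations = 110, seed = sd,
                      region_bp = 1.5e6, recombination_rate = 3e-7,
                      cM_per_Mb = 30, introduce_focal = TRUE,
                      establish_range = c(0.08, 0.55),
                      max_establish_retries = 800)
    sim <- simulate_haplotype_panel(population_spec("pop", 200), cfg)
    pan <- sim$panels$pop
    dd <- sum(ehh_decay_distance(ehh(pan, sim$focal_site, "derived"))$distance_bp)
    da <- sum(ehh_decay_distance(ehh(pan, sim$focal_site, "ancestral"))$distance_bp)
    dd > da
  }, TRUE)
  expect_gte(mean(res), 0.75)
})

test_that("standardization centers bins and is idempotent", {
  rec <- data.frame(freq_derived = c(0.2, 0.2, 0.2), ihs_unstd = c(1, 2, 3))
  std <- standardize_ihs(rec, n_bins = 1)
  expect_equal(std$ihs_std, c(-1, 0, 1))
  # re-standardizing already standardized values leaves them unchanged
  rec2 <- std
  rec2$ihs_unstd <- rec2$ihs_std
  expect_equal(standardize_ihs(rec2, n_bins = 1)$ihs_std, std$ihs_std)
  # constant bin -> missing
  recc <- data.frame(freq_derived = rep(0.4, 3), ihs_unstd = rep(1.5, 3))
  expect_true(all(is.na(standardize_ihs(recc, n_bins = 1)$ihs_std)))
  # sites outside [maf_min, 1 - maf_min] get no bin
  reco <- data.frame(freq_derived = c(0.01, 0.5, 0.5, 0.5),
                     ihs_unstd = c(5, 1, 2, 3))
  so <- standardize_ihs(reco)
  expect_true(is.na(so$ihs_std[1]))
  expect_error(standardize_ihs(data.frame()), "no records")
})

test_that("percentile ranking uses strict magnitude comparison", {
  bg <- c(seq(0.01, 0.96, length.out = 96), -seq(1.2, 1.8, length.out = 4))
  expect_equal(ihs_percentile(-1, bg), 96)
  expect_equal(ihs_percentile(0.001, bg), 0)
  expect_equal(ihs_percentile(-5, bg), 100)
  expect_error(ihs_percentile(NA, bg), "missing")
  expect_error(ihs_percentile(1, NA_real_), "empty")
})

test_that("ihs_scan agrees with the single-site path and respects the MAF
           filter", {
  set.seed(40)
  haps <- matrix(rbinom(30 * 20, 1, 0.4), 30, 20)
  pan <- toy_panel(haps, cM_per_Mb = 100)
  sc <- ihs_scan(pan, min_maf = 0.1)
  f <- panel_freqs(pan)
  expect_true(all(is.na(sc$ihs_unstd[pmin(f, 1 - f) < 0.1])))
  ok <- which(!is.na(sc$ihs_unstd))
  for (i in ok[1:min(4, length(ok))]) {
    one <- unstandardized_ihs(pan, i, maf_min = 0.1)
    expect_equal(sc$ihs_unstd[i], one$ihs_unstd, tolerance = 1e-12)
  }
})
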