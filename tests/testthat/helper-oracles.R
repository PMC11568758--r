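# Independent oracles used across tests. These deliberately use brute-force
# pairwise enumeration / scalar arithmetic, not the package's refinement and
# matrix code paths.

# EHH at site x by exhaustive pairwise comparison of carrier haplotypes over
# the full stretch core..x
oracle_ehh <- function(haps, core, allele, x) {
  carriers <- which(haps[, core] == allele)
  stopifnot(length(carriers) >= 2)
  prs <- utils::combn(carriers, 2)
  rng <- min(core, x):max(core, x)
  hits <- sum(apply(prs, 2, function(pr)
    all(haps[pr[1], rng] == haps[pr[2], rng])))
  hits / ncol(prs)
}

# iHH by trapezoid over the exhaustive EHH values, truncated at the last
# site with EHH >= threshold per direction, core point (0, 1) included
oracle_ihh <- function(haps, gpos, core, allele, threshold = 0.05) {
  one_dir <- function(idx) {
    if (!length(idx)) return(0)
    e <- vapply(idx, function(x) oracle_ehh(haps, core, allele, x), 0)
    below <- which(e < threshold)
    stop_at <- if (length(below)) below[1] - 1L else length(e)
    if (stop_at < 1L) return(0)
    d <- abs(gpos[idx[seq_len(stop_at)]] - gpos[core])
    xx <- c(0, d); yy <- c(1, e[seq_len(stop_at)])
    sum((yy[-1] + yy[-length(yy)]) / 2 * diff(xx))
  }
  left <- rev(seq_len(core - 1))
  right <- seq(core + 1, length.out = ncol(haps) - core)
  one_dir(left) + one_dir(right)
}

# Weir-Cockerham (1984) theta for one biallelic site, two populations,
# written out as scalar arithmetic from the published variance components
oracle_wc84 <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a / (a + b + cc)
}

# small phased panel with the given allele matrix and unit-spaced positions
toy_panel <- function(haps, bp = NULL, cM_per_Mb = 1) {
  haps <- as.matrix(haps)
  if (is.null(bp)) bp <- seq_len(ncol(haps)) * 1000
  haplotype_panel(haps, bp, cM_per_Mb = cM_per_Mb)
}

# genotype matrix (n diploids x 1 site) realizing allele frequency p with a
# given number of heterozygotes
geno_config <- function(n, p, n_het) {
  n_alt <- round(2 * n * p)
  n_hom <- (n_alt - n_het) / 2
  stopifnot(n_het >= 0, n_hom >= 0, n_hom == floor(n_hom),
            n_het + n_hom <= n)
  matrix(c(rep(2L, n_hom), rep(1L, n_het), rep(0L, n - n_hom - n_het)),
         ncol = 1)
}
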