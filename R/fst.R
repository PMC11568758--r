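#' Per-site Weir-Cockerham (1984) F_ST between two populations
#'
#' Computes the per-site theta-hat = a / (a + b + c) from the among-population
#' (a), among-individuals-within-population (b) and within-individual (c)
#' variance components, using diploid genotype data (the estimator behind the
#' usual per-site pairwise VCF workflow). Raw estimates can be negative for
#' undifferentiated sites; both the raw and the [0,1]-clipped value are
#' returned.
#'
#' @param geno1,geno2 genotype matrices (individuals x sites) of alternate-
#'   allele dosages 0/1/2; `NA` allowed.
#' @param site_ids optional site identifiers.
#' @return data.frame with `site`, `fst_raw`, `fst` (clipped), and the
#'   per-population allele frequencies. Sites monomorphic in the pooled
#'   sample (or with < 2 genotyped individuals in either population) have
#'   missing estimates.
#' @export
weir_cockerham_fst <- function(geno1, geno2, site_ids = NULL) {
  geno1 <- as.matrix(geno1); geno2 <- as.matrix(geno2)
  if (ncol(geno1) != ncol(geno2)) stop("both populations must cover the same sites")
  if (is.null(site_ids)) site_ids <- colnames(geno1)
  if (is.null(site_ids)) site_ids <- paste0("site_", seq_len(ncol(geno1)))
  r <- 2   # number of populations
  comp <- function(g) {
    n <- colSums(!is.na(g))
    p <- colMeans(g, na.rm = TRUE) / 2
    h <- colMeans(g == 1L, na.rm = TRUE)    # observed heterozygote frequency
    list(n = n, p = p, h = h)
  }
  c1 <- comp(geno1); c2 <- comp(geno2)
  nbar <- (c1$n + c2$n) / 2
  nc <- (r * nbar - (c1$n^2 + c2$n^2) / (r * nbar)) / (r - 1)
  pbar <- (c1$n * c1$p + c2$n * c2$p) / (r * nbar)
  s2 <- (c1$n * (c1$p - pbar)^2 + c2$n * (c2$p - pbar)^2) / ((r - 1) * nbar)
  hbar <- (c1$n * c1$h + c2$n * c2$h) / (r * nbar)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                      (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  theta <- a / (a + b + cc)
  bad <- pbar <= 0 | pbar >= 1 | c1$n < 2 | c2$n < 2
  theta[bad] <- NA_real_
  a[bad] <- NA_real_; b[bad] <- NA_real_; cc[bad] <- NA_real_
  data.frame(site = site_ids, fst_raw = theta,
             fst = pmin(1, pmax(0, theta)),
             a = a, b = b, c = cc,
             freq1 = c1$p, freq2 = c2$p, row.names = NULL)
}

#' Multi-site Weir-Cockerham F_ST (ratio of sums)
#'
#' The standard weighted combination `sum(a) / sum(a + b + c)` over sites
#' with defined components.
#'
#' @param fst_table output of [weir_cockerham_fst()].
#' @return a single F_ST estimate.
#' @export
fst_ratio_of_sums <- function(fst_table) {
  ok <- !is.na(fst_table$a)
  sum(fst_table$a[ok]) / sum((fst_table$a + fst_table$b + fst_table$c)[ok])
}

#' Allele-frequency-matched empirical p value for a focal F_ST
#'
#' Ranks candidate sites by the absolute difference between their allele
#' frequency and the focal site's frequency (ties broken by candidate
#' order), keeps the `k` closest, and reports the proportion of matched
#' sites whose F_ST is strictly greater than the focal value.
#'
#' @param focal_fst F_ST of the focal site.
#' @param focal_freq allele frequency of the focal site in the reference
#'   (matching) population.
#' @param candidate_fst,candidate_freq F_ST values and matching-population
#'   frequencies of the candidate sites (the focal site must be excluded).
#' @param k number of matched sites (default 10000; all candidates when
#'   fewer are available).
#' @param add_one when TRUE, uses the add-one estimator
#'   `(r + 1) / (k + 1)` instead of the raw proportion `r / k`.
#' @return list with `p`, `k` (matched count actually used), `matched_idx`
#'   (indices of matched candidates) and `n_greater`.
#' @export
matched_empirical_p <- function(focal_fst, focal_freq, candidate_fst,
                                candidate_freq, k = 10000, add_one = FALSE) {
  ok <- !is.na(candidate_fst) & !is.na(candidate_freq)
  if (!any(ok)) stop("no usable candidate sites")
  idx <- which(ok)
  d <- abs(candidate_freq[idx] - focal_freq)
  ord <- idx[order(d, idx)]           # deterministic tie-break by site order
  k_use <- min(k, length(ord))
  matched <- ord[seq_len(k_use)]
  r <- sum(candidate_fst[matched] > focal_fst)
  p <- if (add_one) (r + 1) / (k_use + 1) else r / k_use
  list(p = p, k = k_use, matched_idx = matched, n_greater = r)
}
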