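#' Pairwise haplotype r-squared between two sites
#'
#' With phase known, r2 = (p_AB - p_A p_B)^2 / (p_A(1-p_A) p_B(1-p_B)) is
#' computed directly from haplotype counts (no EM).
#'
#' @param panel a [haplotype_panel()].
#' @param site_a,site_b site indices (or site ids).
#' @return r-squared in [0, 1]; `NA` when either site is monomorphic.
#' @export
haplotype_r2 <- function(panel, site_a, site_b) {
  if (is.character(site_a)) site_a <- match(site_a, panel$site_ids)
  if (is.character(site_b)) site_b <- match(site_b, panel$site_ids)
  a <- panel$haps[, site_a]
  b <- panel$haps[, site_b]
  pa <- mean(a); pb <- mean(b)
  if (pa %in% c(0, 1) || pb %in% c(0, 1)) return(NA_real_)
  d <- mean(a * b) - pa * pb
  d^2 / (pa * (1 - pa) * pb * (1 - pb))
}

#' r-squared profile between a focal site and all sites in a window
#'
#' Applies a per-population MAF filter before computing LD, mirroring the
#' usual regional LD visualization workflow.
#'
#' @param panel a [haplotype_panel()].
#' @param focal_site focal site index (or id).
#' @param window_bp half-width of the window on each side of the focal site.
#' @param maf minimum minor-allele frequency for included sites.
#' @return data.frame with `site`, `pos_bp`, `distance_bp`, `r2`.
#' @export
ld_profile <- function(panel, focal_site, window_bp = 1e6, maf = 0.05) {
  if (is.character(focal_site)) focal_site <- match(focal_site, panel$site_ids)
  freqs <- panel_freqs(panel)
  pos0 <- panel$pos_bp[focal_site]
  keep <- which(abs(panel$pos_bp - pos0) <= window_bp &
                  pmin(freqs, 1 - freqs) >= maf)
  keep <- setdiff(keep, focal_site)
  r2 <- vapply(keep, function(j) haplotype_r2(panel, focal_site, j), 0)
  data.frame(site = panel$site_ids[keep], pos_bp = panel$pos_bp[keep],
             distance_bp = panel$pos_bp[keep] - pos0, r2 = r2,
             row.names = NULL)
}

#' Compare regional LD between two populations
#'
#' Two-sided Wilcoxon rank-sum test on the r-squared values between a focal
#' site and its neighbours in each population.
#'
#' @param r2_a,r2_b numeric vectors of r-squared values (NAs dropped).
#' @return list with `statistic` (rank-sum W), `p`, `median_a`, `median_b`,
#'   and `higher_ld` (which set has the larger median).
#' @export
compare_regional_ld <- function(r2_a, r2_b) {
  r2_a <- r2_a[!is.na(r2_a)]; r2_b <- r2_b[!is.na(r2_b)]
  if (!length(r2_a) || !length(r2_b)) stop("both r2 sets must be non-empty")
  wt <- suppressWarnings(stats::wilcox.test(r2_a, r2_b))
  ma <- stats::median(r2_a); mb <- stats::median(r2_b)
  list(statistic = unname(wt$statistic), p = wt$p.value,
       median_a = ma, median_b = mb,
       higher_ld = if (ma >= mb) "a" else "b")
}
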