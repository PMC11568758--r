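#' Extended haplotype homozygosity curve around a core site
#'
#' EHH at a site x is the probability that two randomly chosen haplotypes
#' carrying the core allele are identical over the whole stretch from the
#' core to x: carriers are partitioned into identical extended haplotypes
#' and EHH(x) = sum_h C(n_h, 2) / C(n_c, 2). The curve starts at 1 at the
#' core and is non-increasing outward in each direction.
#'
#' @param panel a [haplotype_panel()].
#' @param core_site site index (or id) of the core.
#' @param core_allele `"derived"` (1) or `"ancestral"` (0).
#' @return an `ehh_curve`: list with `core_site`, `core_allele`,
#'   `n_carriers`, and `left` / `right` data.frames
#'   (`site`, `distance_bp`, `distance_cM`, `ehh`).
#' @export
ehh <- function(panel, core_site, core_allele = c("derived", "ancestral")) {
  core_allele <- match.arg(core_allele)
  if (is.character(core_site)) core_site <- match(core_site, panel$site_ids)
  allele <- if (core_allele == "derived") 1L else 0L
  cv <- .ehh_curve_cpp(panel$haps, core_site, allele, 0)
  mk <- function(vals, idx) {
    idx <- idx[seq_along(vals)]
    data.frame(site = panel$site_ids[idx],
               distance_bp = abs(panel$pos_bp[idx] - panel$pos_bp[core_site]),
               distance_cM = abs(panel$pos_cM[idx] - panel$pos_cM[core_site]),
               ehh = vals, row.names = NULL)
  }
  left_idx <- rev(seq_len(core_site - 1L))
  right_idx <- seq(core_site + 1L, length.out = ncol(panel$haps) - core_site)
  structure(list(core_site = panel$site_ids[core_site],
                 core_allele = core_allele, n_carriers = cv$n_carriers,
                 left = mk(cv$left, left_idx), right = mk(cv$right, right_idx)),
            class = "ehh_curve")
}

#' @export
print.ehh_curve <- function(x, ...) {
  cat(sprintf("ehh_curve: core %s (%s allele), %d carriers; %d left / %d right sites\n",
              x$core_site, x$core_allele, x$n_carriers, nrow(x$left), nrow(x$right)))
  invisible(x)
}

#' Distance over which EHH stays above a threshold
#'
#' Distance from the core to the most distant site with EHH >= `threshold`
#' in each direction. When the curve never drops below the threshold before
#' the panel edge the edge distance is returned with `censored = TRUE`.
#'
#' @param curve an [ehh()] curve.
#' @param threshold EHH decay threshold (default 0.05).
#' @return data.frame with one row per direction: `direction`,
#'   `distance_bp`, `distance_cM`, `censored`.
#' @export
ehh_decay_distance <- function(curve, threshold = 0.05) {
  one <- function(df, dir) {
    keep <- which(df$ehh >= threshold)
    if (!length(keep))
      return(data.frame(direction = dir, distance_bp = 0, distance_cM = 0,
                        censored = FALSE))
    last <- max(keep)
    data.frame(direction = dir, distance_bp = df$distance_bp[last],
               distance_cM = df$distance_cM[last],
               censored = last == nrow(df))
  }
  rbind(one(curve$left, "left"), one(curve$right, "right"))
}

#' Integrated EHH (iHH)
#'
#' Trapezoidal integral of the EHH curve over genetic distance (cM), summed
#' over both directions, each truncated at the last site with
#' EHH >= `threshold` (no interpolation of the crossing point). The core
#' contributes the point (0 cM, EHH = 1).
#'
#' @param curve an [ehh()] curve.
#' @param threshold truncation threshold (default 0.05).
#' @return iHH in centimorgans.
#' @export
integrated_ehh <- function(curve, threshold = 0.05) {
  one <- function(df) {
    below <- which(df$ehh < threshold)
    stop_at <- if (length(below)) below[1] - 1L else nrow(df)
    if (stop_at < 1L) return(0)
    x <- c(0, df$distance_cM[seq_len(stop_at)])
    y <- c(1, df$ehh[seq_len(stop_at)])
    sum((y[-1] + y[-length(y)]) / 2 * diff(x))
  }
  tot <- one(curve$left) + one(curve$right)
  if (tot == 0) warning("iHH = 0: EHH fell below the threshold immediately in both directions")
  tot
}

#' Unstandardized iHS at a core site
#'
#' `ln(iHH_ancestral / iHH_derived)`: unusually long derived-allele
#' haplotypes (recent positive selection on the derived allele) give
#' negative values.
#'
#' @param panel a [haplotype_panel()].
#' @param core_site site index (or id).
#' @param maf_min minimum minor-allele frequency (default 0.05).
#' @param threshold EHH truncation threshold for the integrals.
#' @return a one-row data.frame: `site`, `freq_derived`, `ihh_ancestral`,
#'   `ihh_derived`, `ihs_unstd` (NA when either integral is 0).
#' @export
unstandardized_ihs <- function(panel, core_site, maf_min = 0.05,
                               threshold = 0.05) {
  idx <- if (is.character(core_site)) match(core_site, panel$site_ids) else core_site
  f <- mean(panel$haps[, idx])
  if (min(f, 1 - f) < maf_min)
    stop(sprintf("site MAF %.3f below maf_min = %.3f", min(f, 1 - f), maf_min))
  ia <- sum(.ihh_cpp(panel$haps, panel$pos_cM, idx, 0L, threshold))
  id <- sum(.ihh_cpp(panel$haps, panel$pos_cM, idx, 1L, threshold))
  data.frame(site = panel$site_ids[idx], freq_derived = f,
             ihh_ancestral = ia, ihh_derived = id,
             ihs_unstd = if (ia > 0 && id > 0) log(ia / id) else NA_real_,
             row.names = NULL)
}

#' iHS scan over all sites of a panel
#'
#' Computes iHH for the ancestral and derived allele classes and the
#' unstandardized iHS at every site passing the MAF filter.
#'
#' @param panel a [haplotype_panel()].
#' @param min_maf minimum minor-allele frequency (default 0.05).
#' @param threshold EHH truncation threshold.
#' @return data.frame with `site`, `pos_bp`, `freq_derived`,
#'   `ihh_ancestral`, `ihh_derived`, `ihs_unstd`.
#' @export
ihs_scan <- function(panel, min_maf = 0.05, threshold = 0.05) {
  sc <- .ihs_scan_cpp(panel$haps, panel$pos_cM, min_maf, threshold)
  data.frame(site = panel$site_ids, pos_bp = panel$pos_bp,
             freq_derived = sc$freq_derived, ihh_ancestral = sc$ihh_ancestral,
             ihh_derived = sc$ihh_derived, ihs_unstd = sc$ihs_unstd,
             row.names = NULL)
}

#' Standardize iHS within derived-allele-frequency bins
#'
#' Bins partition `[maf_min, 1 - maf_min]` into `n_bins` equal-width
#' intervals of derived-allele frequency. Within each bin, the standardized
#' value is `(x - bin mean) / bin SD` (sample SD); bins with fewer than two
#' defined values yield missing standardized values.
#'
#' @param records data.frame with `freq_derived` and `ihs_unstd` columns
#'   (e.g. from [ihs_scan()]).
#' @param n_bins number of frequency bins (default 50).
#' @param maf_min lower frequency bound (default 0.05).
#' @return the input with `freq_bin` and `ihs_std` columns added.
#' @export
standardize_ihs <- function(records, n_bins = 50, maf_min = 0.05) {
  if (!nrow(records)) stop("no records to standardize")
  breaks <- seq(maf_min, 1 - maf_min, length.out = n_bins + 1)
  bin <- findInterval(records$freq_derived, breaks, rightmost.closed = TRUE)
  bin[bin < 1 | bin > n_bins] <- NA_integer_
  std <- rep(NA_real_, nrow(records))
  for (b in unique(bin[!is.na(bin)])) {
    i <- which(bin == b & !is.na(records$ihs_unstd))
    if (length(i) >= 2) {
      s <- stats::sd(records$ihs_unstd[i])
      if (s > 0) std[i] <- (records$ihs_unstd[i] - mean(records$ihs_unstd[i])) / s
    }
  }
  records$freq_bin <- bin
  records$ihs_std <- std
  records
}

#' Percentile rank of a focal iHS among a background
#'
#' Percentile = 100 x (number of background values whose magnitude is
#' strictly smaller than the focal magnitude) / (background size). Absolute
#' values are used, so extreme negative iHS ranks high.
#'
#' @param focal standardized iHS of the focal site.
#' @param background standardized iHS values of the background (NAs dropped).
#' @return percentile in [0, 100].
#' @export
ihs_percentile <- function(focal, background) {
  if (is.na(focal)) stop("focal iHS is missing")
  background <- background[!is.na(background)]
  if (!length(background)) stop("background is empty")
  100 * sum(abs(background) < abs(focal)) / length(background)
}
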