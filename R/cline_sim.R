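#' Simulate a latitudinal allele-frequency cline on a population tree
#'
#' Generates per-population derived-allele frequencies as
#' `inverse-logit(intercept + slope * latitude + b)` where `b` is a Brownian
#' motion draw on the tree: multivariate normal with covariance
#' `bm_sigma2 * shared-branch-length` between tips. Frequencies are strictly
#' inside (0, 1) by the logistic link.
#'
#' @param tree a rooted `phylo` whose tip labels name the populations.
#' @param latitudes named numeric vector of latitudes (degrees), names
#'   matching the tip labels.
#' @param slope latitude effect on the logit-frequency scale (per degree).
#' @param bm_sigma2 Brownian-motion rate (logit variance per unit branch
#'   length); 0 gives a deterministic cline.
#' @param intercept logit-scale intercept.
#' @param temperatures optional named vector of mean annual temperatures; by
#'   default a deterministic lapse of latitude, `24 - 0.5 * |latitude|`.
#' @param seed integer RNG seed.
#' @return a `data.frame` (one row per population): `population`, `frequency`,
#'   `latitude_deg`, `temp_c`.
#' @export
simulate_cline <- function(tree, latitudes, slope = 0.08, bm_sigma2 = 0.1,
                           intercept = -1, temperatures = NULL, seed = 1L) {
  if (bm_sigma2 < 0) stop("bm_sigma2 must be >= 0")
  tips <- tree$tip.label
  if (!all(tips %in% names(latitudes)) || !all(names(latitudes) %in% tips))
    stop("tree tip labels and latitude names must match")
  lat <- latitudes[tips]
  set.seed(seed)
  b <- rep(0, length(tips))
  if (bm_sigma2 > 0) {
    V <- bm_covariance(tree)[tips, tips]
    b <- drop(crossprod(chol(bm_sigma2 * V + 1e-12 * diag(length(tips))),
                        stats::rnorm(length(tips))))
  }
  eta <- intercept + slope * lat + b
  temp <- if (is.null(temperatures)) 24 - 0.5 * abs(lat) else temperatures[tips]
  data.frame(population = tips, frequency = inv_logit(eta),
             latitude_deg = unname(lat), temp_c = unname(temp),
             row.names = NULL)
}
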