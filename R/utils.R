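#' @keywords internal
logit <- function(p) log(p / (1 - p))

#' @keywords internal
inv_logit <- function(x) 1 / (1 + exp(-x))

#' Bonferroni adjustment over the tests actually run
#'
#' @param p numeric vector of raw p values.
#' @param n family size; defaults to the number of non-missing p values.
#' @return adjusted p values, capped at 1.
#' @keywords internal
bonferroni <- function(p, n = sum(!is.na(p))) pmin(1, p * n)

#' Two-sided Wilcoxon rank-sum p value from precomputed ranks
#'
#' Normal approximation with tie correction and continuity correction,
#' suitable for repeated tests (permutations) where the pooled ranks are
#' fixed and only group membership changes.
#'
#' @param ranks ranks of the pooled sample (with average ties).
#' @param in_group logical vector marking group 1.
#' @param tie_term precomputed \code{sum(t^3 - t)} over tie groups.
#' @keywords internal
ranksum_p <- function(ranks, in_group, tie_term = 0) {
  n1 <- sum(in_group)
  n2 <- length(ranks) - n1
  if (n1 == 0L || n2 == 0L) stop("both groups must be non-empty")
  n <- n1 + n2
  w <- sum(ranks[in_group]) - n1 * (n1 + 1) / 2   # Mann-Whitney U
  mu <- n1 * n2 / 2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (abs(w - mu) - 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
}

#' @keywords internal
tie_correction_term <- function(ranks) {
  tt <- table(ranks)
  sum(tt^3 - tt)
}
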