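#' Per-cell module score with expression-matched control genes
#'
#' All genes are binned by average normalized expression across cells into
#' `n_bins` equal-count bins; for each gene-set gene, `n_ctrl` control genes
#' are drawn (seeded; without replacement within the bin, falling back to
#' sampling with replacement when the bin is too small) from the same bin,
#' excluding the gene-set genes themselves. The score is
#' `mean(gene-set values) - mean(control values)` per cell.
#'
#' @param cohort a log-normalized [cell_cohort()].
#' @param gene_set genes scored as a module.
#' @param n_bins number of average-expression bins (default 24).
#' @param n_ctrl control genes drawn per gene-set gene (default 100).
#' @param seed RNG seed for the control draw.
#' @return named numeric vector of per-cell scores, with the sampled control
#'   genes in `attr(, "control_genes")`.
#' @export
module_score <- function(cohort, gene_set, n_bins = 24, n_ctrl = 100,
                         seed = 1L) {
  if (is.null(cohort$normalized)) cohort <- log_normalize(cohort)
  norm <- cohort$normalized
  missing <- setdiff(gene_set, rownames(norm))
  if (length(missing)) stop("gene set genes absent from the matrix: ",
                            paste(missing, collapse = ", "))
  avg <- rowMeans(norm)
  n_bins_eff <- min(n_bins, length(unique(avg)))
  br <- unique(stats::quantile(avg, probs = seq(0, 1, length.out = n_bins_eff + 1)))
  bin <- if (length(br) < 2) rep(1L, length(avg))
         else cut(avg, breaks = br, include.lowest = TRUE, labels = FALSE)
  names(bin) <- rownames(norm)
  set.seed(seed)
  controls <- unlist(lapply(gene_set, function(g) {
    pool <- setdiff(names(bin)[bin == bin[g]], gene_set)
    if (!length(pool)) {
      warning("bin of gene '", g, "' contains no control candidates; ",
              "sampling from all non-module genes")
      pool <- setdiff(rownames(norm), gene_set)
    }
    if (length(pool) >= n_ctrl) sample(pool, n_ctrl)
    else {
      warning("bin of gene '", g, "' smaller than n_ctrl; sampling with replacement")
      sample(pool, n_ctrl, replace = TRUE)
    }
  }))
  score <- colMeans(norm[gene_set, , drop = FALSE]) -
    colMeans(norm[controls, , drop = FALSE])
  attr(score, "control_genes") <- controls
  score
}

#' Compare module scores between risk-carrier and non-carrier cells
#'
#' Two-sided (non-paired) Wilcoxon rank-sum test on cell-level scores.
#'
#' @param scores per-cell scores from [module_score()].
#' @param cohort the [cell_cohort()] the scores were computed on.
#' @param cells optional subset of cell ids (default: all scored cells).
#' @return list with `p`, `statistic`, group medians and sizes.
#' @export
module_group_test <- function(scores, cohort, cells = names(scores)) {
  keep <- cohort$cells$cell_id %in% cells
  donor <- cohort$cells$donor_id[keep]
  carrier <- donor %in% cohort$donors$donor_id[cohort$donors$risk_carrier]
  s <- scores[cohort$cells$cell_id[keep]]
  if (!any(carrier) || !any(!carrier)) stop("one carrier group is empty")
  wt <- suppressWarnings(stats::wilcox.test(s[carrier], s[!carrier]))
  list(p = wt$p.value, statistic = unname(wt$statistic),
       median_carrier = stats::median(s[carrier]),
       median_noncarrier = stats::median(s[!carrier]),
       n_carrier = sum(carrier), n_noncarrier = sum(!carrier))
}

#' Donor-level permutation null for the module-score group test
#'
#' Carrier labels are permuted at the donor level (cells keep their donor),
#' preserving within-donor correlation; the Wilcoxon rank-sum p of the
#' module-score comparison is recorded for each permutation. The
#' permutation p is `(# null p <= observed p + 1) / (B + 1)` (add-one
#' estimator); the raw proportion is also returned.
#'
#' @param cohort a log-normalized [cell_cohort()].
#' @param gene_set module genes.
#' @param B number of permutations (default 10000); capped (with a message)
#'   at the number of distinct carrier-label assignments.
#' @param seed RNG seed (controls the control-gene draw and permutations).
#' @param cell_type cell type whose cells are scored (default all cells).
#' @param n_bins,n_ctrl forwarded to [module_score()].
#' @return list with `observed_p`, `perm_p` (add-one), `perm_p_raw`,
#'   `null_p` (vector of permutation p values) and `B`.
#' @export
permutation_module_test <- function(cohort, gene_set, B = 10000, seed = 1L,
                                    cell_type = NULL, n_bins = 24,
                                    n_ctrl = 100) {
  if (is.null(cohort$normalized)) cohort <- log_normalize(cohort)
  if (B < 1) stop("B must be >= 1")
  scores <- module_score(cohort, gene_set, n_bins, n_ctrl, seed)
  keep <- rep(TRUE, nrow(cohort$cells))
  if (!is.null(cell_type)) keep <- cohort$cells$cell_type == cell_type
  donor <- cohort$cells$donor_id[keep]
  s <- scores[cohort$cells$cell_id[keep]]
  donors <- cohort$donors
  n_carrier <- sum(donors$risk_carrier)
  if (n_carrier < 2 || nrow(donors) - n_carrier < 2)
    stop("need at least 2 donors per carrier group")
  n_assign <- choose(nrow(donors), n_carrier)
  if (B > n_assign) {
    message("B capped at the ", n_assign, " distinct label assignments")
    B <- n_assign
  }
  r <- rank(s)
  tt <- tie_correction_term(r)
  obs_in <- donor %in% donors$donor_id[donors$risk_carrier]
  observed_p <- ranksum_p(r, obs_in, tt)
  set.seed(seed + 1L)
  null_p <- vapply(seq_len(B), function(b) {
    lab <- sample(donors$risk_carrier)
    ranksum_p(r, donor %in% donors$donor_id[lab], tt)
  }, 0)
  hits <- sum(null_p <= observed_p)
  list(observed_p = observed_p, perm_p = (hits + 1) / (B + 1),
       perm_p_raw = hits / B, null_p = null_p, B = B)
}
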