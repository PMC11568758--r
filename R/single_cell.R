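#' Log-normalize cell-level counts
#'
#' Per cell: `value = ln(1 + scale_factor * count / cell_total)`.
#'
#' @param x a [cell_cohort()] or a gene x cell count matrix.
#' @param scale_factor library-size scaling (default 10000).
#' @return for a cohort, the cohort with `$normalized` filled; for a matrix,
#'   the normalized matrix. Cells with zero total counts are an error.
#' @export
log_normalize <- function(x, scale_factor = 10000) {
  counts <- if (inherits(x, "cell_cohort")) x$counts else x
  totals <- Matrix::colSums(counts)
  if (any(totals == 0))
    stop("cells with zero total counts: ",
         paste(utils::head(colnames(counts)[totals == 0], 5), collapse = ", "))
  norm <- log1p(sweep(as.matrix(counts), 2, totals / scale_factor, "/"))
  if (inherits(x, "cell_cohort")) {
    x$normalized <- norm
    x
  } else norm
}

# Wilcoxon rank-sum p for every row of a matrix, group vs rest.
# Normal approximation with tie and continuity correction (the regime these
# cell-level tests run in: thousands of observations, many ties).
rowwise_ranksum_p <- function(mat, in_group) {
  n1 <- sum(in_group); n2 <- sum(!in_group); n <- n1 + n2
  vapply(seq_len(nrow(mat)), function(i) {
    r <- rank(mat[i, ])
    ranksum_p(r, in_group, tie_correction_term(r))
  }, 0)
}

# log2 fold change on expm1 means with pseudocount 1 (pinned convention)
lfc_expm1 <- function(norm_in, norm_out) {
  log2((mean(expm1(norm_in)) + 1) / (mean(expm1(norm_out)) + 1))
}

#' One-vs-rest cell-type marker genes
#'
#' For each cell type, genes are screened by log fold-change
#' (`log2` of expm1-means with pseudocount 1, in-type vs all other cells)
#' and the survivors tested with a Wilcoxon rank-sum test across cells.
#' Bonferroni correction is over the genes tested for that type; markers
#' are genes with adjusted p < 0.05.
#'
#' @param cohort a log-normalized [cell_cohort()].
#' @param logfc_threshold minimum logFC to test (default 0.25).
#' @param only_pos keep positive-logFC genes only (default TRUE).
#' @param min_cells cell types with fewer cells are skipped with a warning.
#' @return named list (one per cell type) of data.frames: `gene`, `logfc`,
#'   `p`, `p_adj`, `pct_in`, `pct_out`, `marker`.
#' @export
find_cell_type_markers <- function(cohort, logfc_threshold = 0.25,
                                   only_pos = TRUE, min_cells = 3) {
  if (is.null(cohort$normalized)) cohort <- log_normalize(cohort)
  types <- unique(cohort$cells$cell_type)
  if (length(types) < 2) stop("need at least 2 cell types")
  norm <- cohort$normalized
  out <- list()
  for (ct in types) {
    in_ct <- cohort$cells$cell_type == ct
    if (sum(in_ct) < min_cells) {
      warning("cell type '", ct, "' has fewer than ", min_cells, " cells; skipped")
      next
    }
    em <- expm1(norm)
    lfc <- log2((rowMeans(em[, in_ct, drop = FALSE]) + 1) /
                  (rowMeans(em[, !in_ct, drop = FALSE]) + 1))
    pass <- if (only_pos) lfc >= logfc_threshold else abs(lfc) >= logfc_threshold
    tested <- which(pass)
    p <- rep(NA_real_, nrow(norm))
    if (length(tested))
      p[tested] <- rowwise_ranksum_p(norm[tested, , drop = FALSE], in_ct)
    p_adj <- bonferroni(p, length(tested))
    out[[ct]] <- data.frame(
      gene = rownames(norm), cell_type = ct, logfc = lfc, p = p, p_adj = p_adj,
      pct_in = rowMeans(norm[, in_ct, drop = FALSE] > 0),
      pct_out = rowMeans(norm[, !in_ct, drop = FALSE] > 0),
      marker = !is.na(p_adj) & p_adj < 0.05, row.names = NULL)
  }
  out
}

#' Unique markers of a target cell type
#'
#' Target-type markers minus the union of every other type's marker set.
#'
#' @param markers_by_type output of [find_cell_type_markers()].
#' @param target_type cell type of interest.
#' @return character vector of unique marker genes.
#' @export
unique_markers <- function(markers_by_type, target_type) {
  if (!target_type %in% names(markers_by_type))
    stop("no marker results for type '", target_type, "'")
  own <- with(markers_by_type[[target_type]], gene[marker])
  others <- unlist(lapply(markers_by_type[setdiff(names(markers_by_type), target_type)],
                          function(m) m$gene[m$marker]))
  res <- setdiff(own, others)
  if (!length(res)) warning("all markers of '", target_type,
                            "' are shared with other cell types")
  res
}

#' Risk-allele-status differential expression within a cell type
#'
#' Cells of the stated type are pooled by donor carrier status (carrier =
#' at least one risk allele) and each gene in `gene_set` is tested with a
#' Wilcoxon rank-sum test across cells. Bonferroni correction is over the
#' genes tested in this run.
#'
#' @param cohort a log-normalized [cell_cohort()].
#' @param cell_type cell type analyzed.
#' @param gene_set genes to test; genes absent from the matrix are reported
#'   in `skipped` and not tested.
#' @param logfc_threshold minimum |logFC| (carriers vs non-carriers) for a
#'   gene to be tested (default 0: test all).
#' @param donors_subset optional donor ids restricting the analysis (used by
#'   [sex_stratified_de()]).
#' @return list with `results` (data.frame: gene, logfc, p, p_adj,
#'   direction) and `skipped` (missing genes).
#' @export
risk_allele_de <- function(cohort, cell_type = "adipocyte", gene_set,
                           logfc_threshold = 0, donors_subset = NULL) {
  if (is.null(cohort$normalized)) cohort <- log_normalize(cohort)
  skipped <- setdiff(gene_set, rownames(cohort$counts))
  gene_set <- intersect(gene_set, rownames(cohort$counts))
  donors <- cohort$donors
  if (!is.null(donors_subset)) donors <- donors[donors$donor_id %in% donors_subset, ]
  carriers <- donors$donor_id[donors$risk_carrier]
  noncarr <- donors$donor_id[!donors$risk_carrier]
  keep <- cohort$cells$cell_type == cell_type &
    cohort$cells$donor_id %in% donors$donor_id
  cells <- cohort$cells[keep, ]
  if (!any(cells$donor_id %in% carriers) || !any(cells$donor_id %in% noncarr))
    stop("both carrier and non-carrier cells are required")
  norm <- cohort$normalized[gene_set, keep, drop = FALSE]
  in_carrier <- cells$donor_id %in% carriers
  lfc <- vapply(seq_along(gene_set), function(i)
    lfc_expm1(norm[i, in_carrier], norm[i, !in_carrier]), 0)
  tested <- which(abs(lfc) >= logfc_threshold)
  p <- rep(NA_real_, length(gene_set))
  if (length(tested))
    p[tested] <- rowwise_ranksum_p(norm[tested, , drop = FALSE], in_carrier)
  list(results = data.frame(
         gene = gene_set, logfc = lfc, p = p,
         p_adj = bonferroni(p, length(tested)),
         direction = ifelse(lfc >= 0, "up", "down"), row.names = NULL),
       skipped = skipped,
       n_carrier_cells = sum(in_carrier),
       n_noncarrier_cells = sum(!in_carrier))
}

#' Replication of discovery risk-allele associations
#'
#' Reruns [risk_allele_de()] on the replication cohort restricted to the
#' discovery-significant genes (Bonferroni denominator = genes carried
#' forward). A gene replicates when its adjusted p < 0.05 and its logFC has
#' the discovery sign.
#'
#' @param discovery output of [risk_allele_de()] on the discovery cohort.
#' @param replication_cohort a log-normalized [cell_cohort()].
#' @param cell_type cell type analyzed.
#' @param alpha significance level (default 0.05).
#' @return list with `replicated` (gene set), `results` (replication table
#'   with `replicated` flag), and `carried_forward`.
#' @export
replicate_de <- function(discovery, replication_cohort,
                         cell_type = "adipocyte", alpha = 0.05) {
  disc <- discovery$results
  sig <- disc[!is.na(disc$p_adj) & disc$p_adj < alpha, ]
  if (!nrow(sig))
    return(list(replicated = character(0), results = NULL,
                carried_forward = character(0)))
  rep_de <- risk_allele_de(replication_cohort, cell_type, sig$gene)
  res <- rep_de$results
  res$discovery_direction <- sig$direction[match(res$gene, sig$gene)]
  res$replicated <- !is.na(res$p_adj) & res$p_adj < alpha &
    res$direction == res$discovery_direction
  list(replicated = res$gene[res$replicated], results = res,
       carried_forward = sig$gene)
}

#' Sex-stratified risk-allele differential expression
#'
#' Runs [risk_allele_de()] separately within each sex. A sex with only one
#' carrier group (or no donors) is skipped with a message. Significance
#' tiers at adjusted p < 0.05 / 0.01 / 0.001 / 0.0001 are annotated.
#'
#' @inheritParams risk_allele_de
#' @return named list per sex of [risk_allele_de()] results with a `tier`
#'   column (`""`, `"*"`, `"**"`, `"***"`, `"****"`).
#' @export
sex_stratified_de <- function(cohort, cell_type = "adipocyte", gene_set,
                              logfc_threshold = 0) {
  out <- list()
  for (sx in unique(cohort$donors$sex)) {
    d <- cohort$donors[cohort$donors$sex == sx, ]
    if (!nrow(d) || length(unique(d$risk_carrier)) < 2) {
      message("sex '", sx, "' lacks both carrier groups; skipped")
      next
    }
    res <- risk_allele_de(cohort, cell_type, gene_set, logfc_threshold,
                          donors_subset = d$donor_id)
    res$results$tier <- cut(res$results$p_adj,
                            breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
                            labels = c("****", "***", "**", "*", ""))
    out[[sx]] <- res
  }
  out
}
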