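#' Donor-level pseudobulk within a cell type
#'
#' Sums counts over each donor's cells of the stated type; donors with zero
#' such cells are dropped and listed. The nuclei count per donor is kept as
#' a covariate alongside donor age and sex.
#'
#' @param cohort a [cell_cohort()].
#' @param cell_type cell type to aggregate.
#' @return list with `counts` (gene x donor summed counts), `covariates`
#'   (data.frame: donor_id, n_nuclei, age, sex), `dropped` (donor ids with
#'   no cells of the type).
#' @export
pseudobulk <- function(cohort, cell_type = "adipocyte") {
  keep <- cohort$cells$cell_type == cell_type
  if (!any(keep)) stop("no cells of type '", cell_type, "'")
  cells <- cohort$cells[keep, ]
  counts <- as.matrix(cohort$counts[, keep, drop = FALSE])
  donor <- factor(cells$donor_id, levels = unique(cells$donor_id))
  agg <- counts %*% stats::model.matrix(~ 0 + donor)
  colnames(agg) <- levels(donor)
  dropped <- setdiff(cohort$donors$donor_id, levels(donor))
  cov <- data.frame(donor_id = levels(donor),
                    n_nuclei = as.integer(table(donor)[levels(donor)]))
  cov <- merge(cov, cohort$donors[, c("donor_id", "age", "sex")],
               by = "donor_id", sort = FALSE)
  list(counts = agg, covariates = cov, dropped = dropped)
}

#' TMM normalization factors (trimmed mean of M-values)
#'
#' Reference sample = the one whose upper-quartile expression (of
#' library-size-scaled counts) is closest to the mean upper quartile. For
#' each sample, the factor is the precision-weighted mean of log2 count
#' ratios vs the reference after double trimming (30% on M, 5% on A);
#' factors are renormalized to geometric mean 1. Normalized values are
#' `scale * count / (library size x factor)`.
#'
#' @param counts gene x sample count matrix; samples with all-zero counts
#'   are rejected.
#' @param trim_m,trim_a trim fractions for the log-ratios and average
#'   log-expression (defaults 0.30 and 0.05).
#' @param scale multiplier for the normalized values (default 1e6, i.e.
#'   TMM-scaled counts per million).
#' @return list with `factors` (named), `normalized` (matrix), `ref`
#'   (reference sample).
#' @export
tmm_normalize <- function(counts, trim_m = 0.30, trim_a = 0.05, scale = 1e6) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("need at least 2 samples")
  lib <- colSums(counts)
  if (any(lib == 0)) stop("samples with all-zero counts: ",
                          paste(colnames(counts)[lib == 0], collapse = ", "))
  uq <- vapply(seq_len(ncol(counts)), function(j)
    stats::quantile(counts[, j] / lib[j], 0.75, names = FALSE), 0)
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) return(1)
    x <- counts[, j]; xr <- counts[, ref]
    ok <- x > 0 & xr > 0
    if (!any(ok)) return(1)
    m <- log2((x[ok] / lib[j]) / (xr[ok] / lib[ref]))
    a <- 0.5 * log2((x[ok] / lib[j]) * (xr[ok] / lib[ref]))
    v <- (lib[j] - x[ok]) / (lib[j] * x[ok]) +
      (lib[ref] - xr[ok]) / (lib[ref] * xr[ok])
    if (max(abs(m)) < 1e-6) return(1)
    n <- length(m)
    lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
    lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
    rm_ <- rank(m); ra <- rank(a)
    keep <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
    if (!any(keep)) return(1)
    2^(sum(m[keep] / v[keep]) / sum(1 / v[keep]))   # precision-weighted mean
  }, 0)
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  normalized <- sweep(counts, 2, lib * f / scale, "/")
  list(factors = f, normalized = normalized,
       ref = colnames(counts)[ref] %||% ref)
}

#' Covariate adjustment followed by rank-based inverse normal transform
#'
#' Per gene: residuals from a linear fit on the covariates, then the Blom
#' inverse normal transform `qnorm((rank - 3/8) / (n + 1/4))` with average
#' ranks for ties.
#'
#' @param mat gene x sample matrix of normalized expression.
#' @param covariates data.frame of covariates (factors allowed), one row
#'   per sample in column order of `mat`.
#' @return transformed gene x sample matrix.
#' @export
adjust_and_int <- function(mat, covariates) {
  mat <- as.matrix(mat)
  n <- ncol(mat)
  covariates <- as.data.frame(covariates)
  if (n < ncol(covariates) + 2)
    stop("too few samples for the covariate adjustment")
  X <- stats::model.matrix(~ ., data = covariates)
  if (n < ncol(X) + 2) stop("too few samples for the covariate adjustment")
  res <- t(stats::residuals(stats::lm.fit(X, t(mat))))
  out <- t(apply(res, 1, function(v)
    stats::qnorm((rank(v) - 3 / 8) / (n + 1 / 4))))
  dimnames(out) <- dimnames(mat)
  out
}

#' Genes overlapping a window around an anchor gene
#'
#' Members are genes whose body overlaps
#' `[anchor start - half_width, anchor stop + half_width]` (1-based,
#' inclusive coordinates).
#'
#' @param coords data.frame with `gene`, `start`, `stop` (1-based inclusive).
#' @param anchor anchor gene name.
#' @param half_width window half-width in bp (default 1e6).
#' @return character vector of member genes (anchor included).
#' @export
region_genes <- function(coords, anchor, half_width = 1e6) {
  a <- coords[coords$gene == anchor, ]
  if (!nrow(a)) stop("anchor gene '", anchor, "' not in the coordinate table")
  lo <- a$start[1] - half_width
  hi <- a$stop[1] + half_width
  coords$gene[coords$stop >= lo & coords$start <= hi]
}

#' Pairwise Spearman correlations among region genes
#'
#' All pairwise Spearman correlations (two-sided p) among the given genes;
#' pairs with p > 0.05 are flagged as not nominally significant. Constant
#' genes give missing correlations for their pairs.
#'
#' @param mat gene x sample matrix (e.g. from [adjust_and_int()]).
#' @param genes genes to correlate (>= 2, present in `mat`).
#' @return data.frame with `gene_a`, `gene_b`, `rho`, `p`, `nominal`
#'   (p <= 0.05).
#' @export
regional_correlations <- function(mat, genes) {
  genes <- intersect(genes, rownames(mat))
  if (length(genes) < 2) stop("need at least 2 region genes present in the matrix")
  if (ncol(mat) < 3) stop("need at least 3 samples")
  pairs <- utils::combn(genes, 2)
  res <- apply(pairs, 2, function(gg) {
    x <- mat[gg[1], ]; y <- mat[gg[2], ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      return(c(NA_real_, NA_real_))
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                           exact = FALSE))
    c(ct$estimate, ct$p.value)
  })
  data.frame(gene_a = pairs[1, ], gene_b = pairs[2, ],
             rho = res[1, ], p = res[2, ],
             nominal = !is.na(res[2, ]) & res[2, ] <= 0.05, row.names = NULL)
}

#' Spearman correlation of gene expression with adipocyte size per BMI group
#'
#' Diameters are inverse-normal transformed (Blom) within each group before
#' correlating. Bonferroni correction is over all gene x group tests of the
#' run.
#'
#' @param expression gene x sample matrix (TPM-like).
#' @param samples data.frame with `sample_id`, `bmi_group`, `diameter_um`
#'   (as produced by [simulate_twin_cohort()]).
#' @param genes genes to test (default all rows).
#' @param min_group groups with fewer members are skipped.
#' @return data.frame with `gene`, `group`, `rho`, `p`, `p_adj`.
#' @export
size_correlations <- function(expression, samples, genes = rownames(expression),
                              min_group = 3) {
  genes <- intersect(genes, rownames(expression))
  out <- list()
  for (grp in unique(samples$bmi_group)) {
    sel <- samples$bmi_group == grp
    if (sum(sel) < min_group) {
      message("group '", grp, "' has fewer than ", min_group, " members; skipped")
      next
    }
    d <- samples$diameter_um[sel]
    d_int <- stats::qnorm((rank(d) - 3 / 8) / (length(d) + 1 / 4))
    ids <- samples$sample_id[sel]
    res <- t(vapply(genes, function(g) {
      ct <- suppressWarnings(stats::cor.test(expression[g, ids], d_int,
                                             method = "spearman", exact = FALSE))
      c(ct$estimate, ct$p.value)
    }, c(0, 0)))
    out[[grp]] <- data.frame(gene = genes, group = grp,
                             rho = res[, 1], p = res[, 2], row.names = NULL)
  }
  res <- do.call(rbind, out)
  res$p_adj <- bonferroni(res$p, nrow(res))
  rownames(res) <- NULL
  res
}
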