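#' Cell-level expression cohort container
#'
#' Counts are stored genes x cells (the field convention). `cells` maps each
#' cell to a cell type and donor; `donors` carries risk-carrier status, sex
#' and age.
#'
#' @param counts gene x cell matrix of non-negative integer counts
#'   (dense or `Matrix` sparse).
#' @param cells data.frame with columns `cell_id`, `cell_type`, `donor_id`.
#' @param donors data.frame with columns `donor_id`, `risk_carrier`
#'   (logical), `sex`, `age`.
#' @return a `cell_cohort` object.
#' @export
cell_cohort <- function(counts, cells, donors) {
  stopifnot(ncol(counts) == nrow(cells),
            all(c("cell_id", "cell_type", "donor_id") %in% names(cells)),
            all(c("donor_id", "risk_carrier", "sex") %in% names(donors)))
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!all(cells$donor_id %in% donors$donor_id))
    stop("every cell must map to a known donor")
  colnames(counts) <- cells$cell_id
  structure(list(counts = counts, cells = cells, donors = donors,
                 normalized = NULL), class = "cell_cohort")
}

#' @export
print.cell_cohort <- function(x, ...) {
  cat(sprintf("cell_cohort: %d genes x %d cells, %d donors (%d risk carriers)\n",
              nrow(x$counts), ncol(x$counts), nrow(x$donors),
              sum(x$donors$risk_carrier)))
  invisible(x)
}

#' Simulate a single-nucleus expression cohort with planted trans effects
#'
#' Donor genotypes at the risk variant are drawn under Hardy-Weinberg at
#' `risk_maf`; a donor carrying at least one risk allele is a carrier. Counts
#' are negative binomial with gene-specific means; for genes in `trans_set`
#' the mean is multiplied by `effect` in carrier donors. Cell types are
#' assigned with type-specific marker genes (a planted `marker_lfc`-fold
#' elevation), so marker identification is testable on the same cohort.
#'
#' @param n_donors number of donors.
#' @param cells_per_donor cells per donor.
#' @param n_genes number of genes.
#' @param trans_set character labels (subset of `gene_1..n_genes`) of the
#'   planted trans genes, or an integer count (first genes of the adipocyte
#'   markers are used).
#' @param effect multiplicative mean shift of `trans_set` genes in carriers
#'   (> 0; 1 = null).
#' @param risk_maf risk-allele frequency, in (0, 1).
#' @param dispersion negative-binomial size parameter (smaller = noisier).
#' @param cell_types character vector of cell types; cells are split evenly.
#' @param markers_per_type planted markers per cell type.
#' @param marker_lfc fold elevation of a marker gene in its own type.
#' @param base_mean_range range of gene base means (log-uniform).
#' @param p_female probability a donor is female.
#' @param seed integer RNG seed.
#' @param max_retries genotype redraws allowed when all donors land in one
#'   carrier group.
#' @return a [cell_cohort()] with attributes `trans_genes` (planted set) and
#'   `marker_genes` (list per cell type).
#' @export
simulate_expression_cohort <- function(n_donors = 60, cells_per_donor = 200,
                                       n_genes = 300, trans_set = 12,
                                       effect = 2, risk_maf = 0.4,
                                       dispersion = 2,
                                       cell_types = c("adipocyte", "immune", "endothelial"),
                                       markers_per_type = 25, marker_lfc = 4,
                                       base_mean_range = c(0.05, 5),
                                       p_female = 0.6, seed = 1L,
                                       max_retries = 50L) {
  if (effect <= 0) stop("effect must be > 0")
  if (risk_maf <= 0 || risk_maf >= 1) stop("risk_maf must be in (0, 1)")
  set.seed(seed)
  genes <- paste0("gene_", seq_len(n_genes))
  n_types <- length(cell_types)
  idx_all <- seq_len(min(n_genes, markers_per_type * n_types))
  marker_idx <- lapply(seq_len(n_types), function(t)
    idx_all[idx_all > (t - 1) * markers_per_type &
              idx_all <= t * markers_per_type])
  marker_genes <- lapply(marker_idx, function(i) genes[i])
  names(marker_genes) <- cell_types
  if (is.numeric(trans_set) && length(trans_set) == 1L) {
    trans_set <- marker_genes[[1]][seq_len(trans_set)]
  }
  if (!all(trans_set %in% genes)) stop("trans_set genes missing from the gene universe")

  # Hardy-Weinberg genotypes, redrawn (bounded) if one carrier group is empty
  geno <- NULL
  for (try in seq_len(max_retries)) {
    geno <- stats::rbinom(n_donors, 2L, risk_maf)
    if (any(geno > 0) && any(geno == 0)) break
    geno <- NULL
  }
  if (is.null(geno)) stop("could not draw both carrier and non-carrier donors in ",
                          max_retries, " attempts")
  donors <- data.frame(
    donor_id = sprintf("donor_%02d", seq_len(n_donors)),
    genotype = geno, risk_carrier = geno > 0,
    sex = sample(c("F", "M"), n_donors, replace = TRUE, prob = c(p_female, 1 - p_female)),
    age = round(stats::runif(n_donors, 30, 65)))

  n_cells <- n_donors * cells_per_donor
  cells <- data.frame(
    cell_id = sprintf("cell_%05d", seq_len(n_cells)),
    donor_id = rep(donors$donor_id, each = cells_per_donor),
    cell_type = sample(cell_types, n_cells, replace = TRUE))

  base_mu <- exp(stats::runif(n_genes, log(base_mean_range[1]), log(base_mean_range[2])))
  mu <- matrix(base_mu, n_genes, n_cells)
  for (ct in cell_types) {
    idx <- marker_idx[[match(ct, cell_types)]]
    mu[idx, cells$cell_type == ct] <- mu[idx, cells$cell_type == ct] * marker_lfc
  }
  carrier_cells <- cells$donor_id %in% donors$donor_id[donors$risk_carrier]
  tr <- match(trans_set, genes)
  mu[tr, carrier_cells] <- mu[tr, carrier_cells] * effect
  counts <- matrix(stats::rnbinom(n_genes * n_cells, mu = mu, size = dispersion),
                   n_genes, n_cells, dimnames = list(genes, cells$cell_id))
  out <- cell_cohort(counts, cells, donors)
  attr(out, "trans_genes") <- trans_set
  attr(out, "marker_genes") <- marker_genes
  out
}

#' Simulate a BMI-discordant twin cohort with a planted size correlation
#'
#' Each twin pair contributes one higher-BMI and one lower-BMI member. A
#' Gaussian copula ties the designated target gene's expression to adipocyte
#' diameter with rank correlation about `target_rho` (optionally different
#' per BMI group); all other genes are independent of diameter.
#'
#' @param n_pairs number of twin pairs (>= 3).
#' @param n_genes genes in the TPM-like expression table.
#' @param target_gene index of the gene tied to diameter.
#' @param target_rho copula correlation; length 1 (both groups) or 2
#'   (`lower`, `higher` BMI group).
#' @param seed integer RNG seed.
#' @return list with `expression` (gene x individual TPM-like matrix),
#'   `samples` (data.frame: `sample_id`, `pair_id`, `bmi_group`,
#'   `diameter_um`).
#' @export
simulate_twin_cohort <- function(n_pairs = 44, n_genes = 10, target_gene = 1,
                                 target_rho = 0.55, seed = 1L) {
  if (n_pairs < 3) stop("n_pairs must be >= 3")
  if (any(abs(target_rho) >= 1)) stop("target_rho must be in (-1, 1)")
  if (length(target_rho) == 1L) target_rho <- rep(target_rho, 2)
  set.seed(seed)
  n <- 2L * n_pairs
  grp <- rep(c("lower", "higher"), n_pairs)
  samples <- data.frame(
    sample_id = sprintf("twin_%03d", seq_len(n)),
    pair_id = rep(sprintf("pair_%02d", seq_len(n_pairs)), each = 2),
    bmi_group = grp)
  # Gaussian-copula parameter giving the requested Spearman correlation
  rho_g <- 2 * sin(pi * target_rho / 6)
  rho <- ifelse(grp == "lower", rho_g[1], rho_g[2])
  z_diam <- stats::rnorm(n)
  z_gene <- rho * z_diam + sqrt(1 - rho^2) * stats::rnorm(n)
  expr <- matrix(exp(stats::rnorm(n_genes * n, mean = 3, sd = 1)), n_genes, n,
                 dimnames = list(paste0("gene_", seq_len(n_genes)), samples$sample_id))
  expr[target_gene, ] <- exp(3 + z_gene)           # monotone in the copula draw
  diam <- 90 + 12 * z_diam + ifelse(grp == "higher", 10, 0)
  samples$diameter_um <- diam
  list(expression = expr, samples = samples)
}

#' Write a cell cohort as MatrixMarket + annotation TSVs
#'
#' @param cohort a [cell_cohort()].
#' @param dir output directory.
#' @return invisibly, the file paths.
#' @export
write_cohort_mtx <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- Matrix::Matrix(as.matrix(cohort$counts), sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "counts.mtx"))
  utils::write.table(data.frame(gene = rownames(cohort$counts)),
                     file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$cells, file.path(dir, "cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$donors, file.path(dir, "donors.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file.path(dir, c("counts.mtx", "genes.tsv", "cells.tsv", "donors.tsv")))
}

#' Read a cell cohort from MatrixMarket + annotation TSVs
#'
#' @param dir directory produced by [write_cohort_mtx()].
#' @return a [cell_cohort()].
#' @export
read_cohort_mtx <- function(dir) {
  counts <- as.matrix(Matrix::readMM(file.path(dir, "counts.mtx")))
  genes <- utils::read.delim(file.path(dir, "genes.tsv"))
  cells <- utils::read.delim(file.path(dir, "cells.tsv"))
  donors <- utils::read.delim(file.path(dir, "donors.tsv"))
  rownames(counts) <- genes$gene
  cell_cohort(counts, cells, donors)
}
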