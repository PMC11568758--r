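#' Phased haplotype panel
#'
#' Container for a phased biallelic panel: a haplotype x site allele matrix
#' coded 0 = ancestral, 1 = derived, with physical (bp) and genetic (cM)
#' positions. Two consecutive rows form one diploid individual.
#'
#' @param haps integer matrix (haplotypes x sites), values in {0, 1}.
#' @param pos_bp strictly increasing physical positions (1-based bp).
#' @param pos_cM non-decreasing genetic-map positions (cM). If `NULL`, a
#'   uniform map of `cM_per_Mb` centimorgans per megabase is applied.
#' @param site_ids site identifiers; defaults to `site_<bp>`.
#' @param population optional population label.
#' @param cM_per_Mb uniform map density used when `pos_cM` is `NULL`.
#' @return an object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(haps, pos_bp, pos_cM = NULL, site_ids = NULL,
                            population = NA_character_, cM_per_Mb = 1) {
  haps <- as.matrix(haps)
  storage.mode(haps) <- "integer"
  if (!all(haps %in% c(0L, 1L))) stop("alleles must be coded 0 (ancestral) / 1 (derived)")
  if (nrow(haps) %% 2L != 0L) stop("phased panel needs an even number of haplotypes")
  if (length(pos_bp) != ncol(haps)) stop("pos_bp length must match the number of sites")
  if (is.unsorted(pos_bp, strictly = TRUE)) stop("pos_bp must be strictly increasing")
  if (is.null(pos_cM)) pos_cM <- (pos_bp - pos_bp[1]) * cM_per_Mb / 1e6
  if (length(pos_cM) != ncol(haps)) stop("pos_cM length must match the number of sites")
  if (is.unsorted(pos_cM)) stop("pos_cM must be non-decreasing")
  if (is.null(site_ids)) site_ids <- paste0("site_", pos_bp)
  structure(
    list(haps = haps, pos_bp = as.numeric(pos_bp), pos_cM = as.numeric(pos_cM),
         site_ids = as.character(site_ids), population = population),
    class = "haplotype_panel"
  )
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("haplotype_panel: %d haplotypes x %d sites", nrow(x$haps), ncol(x$haps)))
  if (!is.na(x$population)) cat(sprintf(" [%s]", x$population))
  cat(sprintf("\n  span: %.0f-%.0f bp, %.3f cM\n",
              x$pos_bp[1], x$pos_bp[length(x$pos_bp)],
              x$pos_cM[length(x$pos_cM)] - x$pos_cM[1]))
  invisible(x)
}

#' Diploid genotype matrix from a phased panel
#'
#' @param panel a [haplotype_panel()].
#' @return integer matrix (individuals x sites) of derived-allele dosages 0/1/2.
#' @export
panel_genotypes <- function(panel) {
  h <- panel$haps
  g <- h[seq(1, nrow(h), by = 2), , drop = FALSE] +
    h[seq(2, nrow(h), by = 2), , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Derived-allele frequencies of a panel
#' @param panel a [haplotype_panel()].
#' @return numeric vector of per-site derived-allele frequencies.
#' @export
panel_freqs <- function(panel) colMeans(panel$haps)

#' Per-site, per-population allele frequency table
#'
#' @param panels named list of [haplotype_panel()] objects sharing a site set.
#' @return a `data.frame` with one row per site x population: diploid sample
#'   size, derived-allele count, frequency, and MAF.
#' @export
site_frequency_table <- function(panels) {
  if (is.null(names(panels)) || any(!nzchar(names(panels))))
    names(panels) <- paste0("pop", seq_along(panels))
  do.call(rbind, lapply(names(panels), function(nm) {
    p <- panels[[nm]]
    cnt <- colSums(p$haps)
    n <- nrow(p$haps) / 2
    freq <- cnt / (2 * n)
    data.frame(site = p$site_ids, pos_bp = p$pos_bp, population = nm,
               n_diploid = n, derived_count = cnt, freq = freq,
               maf = pmin(freq, 1 - freq), row.names = NULL)
  }))
}

#' Write a phased panel as VCF plus sample-map and genetic-map files
#'
#' Writes an uncompressed VCFv4.2 with phased `GT` and the ancestral allele in
#' the `AA` INFO key (REF is the ancestral allele by construction here), a
#' sample-to-population TSV, and a genetic map TSV (`position_bp`, `cM`).
#'
#' @param panel a [haplotype_panel()].
#' @param dir output directory (created if needed).
#' @param prefix file name stem.
#' @param chrom chromosome label used in the VCF.
#' @return invisibly, the three file paths.
#' @export
write_panel_vcf <- function(panel, dir, prefix = "panel", chrom = "1") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  h <- panel$haps
  n_ind <- nrow(h) / 2
  samples <- sprintf("%s_ind%03d", ifelse(is.na(panel$population), "pop", panel$population), seq_len(n_ind))
  a1 <- h[seq(1, nrow(h), 2), , drop = FALSE]
  a2 <- h[seq(2, nrow(h), 2), , drop = FALSE]
  gt <- matrix(paste0(a1, "|", a2), nrow = n_ind)
  body <- cbind(chrom, format(panel$pos_bp, scientific = FALSE, trim = TRUE),
                panel$site_ids, "A", "T", ".", "PASS", "AA=A", "GT", t(gt))
  vcf <- file.path(dir, paste0(prefix, ".vcf"))
  con <- file(vcf, "w")
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Phased genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t")), con)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  close(con)
  pops <- file.path(dir, paste0(prefix, "_samples.tsv"))
  utils::write.table(data.frame(sample = samples, population = panel$population),
                     pops, sep = "\t", quote = FALSE, row.names = FALSE)
  gmap <- file.path(dir, paste0(prefix, "_map.tsv"))
  utils::write.table(data.frame(position_bp = panel$pos_bp, cM = panel$pos_cM),
                     gmap, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(vcf = vcf, samples = pops, map = gmap))
}

#' Read a phased VCF back into a haplotype panel
#'
#' The ancestral allele is taken from the INFO `AA` key; where absent, REF is
#' assumed ancestral with a warning. Sites whose ancestral allele matches ALT
#' are flipped so that 1 always codes the derived allele.
#'
#' @param vcf path to an uncompressed VCF with phased GT.
#' @param map optional genetic map TSV (`position_bp`, `cM`).
#' @param population population label to attach.
#' @return a [haplotype_panel()].
#' @export
read_panel_vcf <- function(vcf, map = NULL, population = NA_character_) {
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v)
  if (any(!grepl("|", gt[1, ], fixed = TRUE))) stop("genotypes must be phased ('|')")
  split1 <- matrix(as.integer(substr(gt, 1, 1)), nrow = nrow(gt))
  split2 <- matrix(as.integer(substr(gt, 3, 3)), nrow = nrow(gt))
  aa <- sub(".*AA=([^;]+).*", "\\1", fix$INFO)
  no_aa <- !grepl("AA=", fix$INFO)
  if (any(no_aa)) {
    warning("INFO/AA missing for ", sum(no_aa), " site(s); REF assumed ancestral")
    aa[no_aa] <- fix$REF[no_aa]
  }
  flip <- aa == fix$ALT
  split1[flip, ] <- 1L - split1[flip, ]
  split2[flip, ] <- 1L - split2[flip, ]
  haps <- matrix(0L, nrow = 2 * ncol(gt), ncol = nrow(gt))
  haps[seq(1, nrow(haps), 2), ] <- t(split1)
  haps[seq(2, nrow(haps), 2), ] <- t(split2)
  pos <- as.numeric(fix$POS)
  pos_cM <- NULL
  if (!is.null(map)) {
    m <- utils::read.delim(map)
    pos_cM <- stats::approx(m$position_bp, m$cM, xout = pos, rule = 2)$y
  }
  haplotype_panel(haps, pos, pos_cM = pos_cM, site_ids = fix$ID,
                  population = population)
}
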