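#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via the standard Q-criterion implementation in
#' \pkg{ape}) with post-processing for negative branch lengths: a negative
#' edge is clamped to zero and its deficit transferred to the sister edge at
#' the same node, preserving path lengths between the subtended tips as far
#' as possible. The returned tree is unrooted.
#'
#' @param dist symmetric non-negative distance matrix with labelled rows and
#'   zero diagonal (a `matrix` or `dist`).
#' @return an unrooted `phylo`.
#' @export
neighbor_joining <- function(dist) {
  d <- as.matrix(dist)
  if (nrow(d) < 3) stop("need at least 3 taxa")
  if (any(d < 0)) stop("distances must be non-negative")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("diagonal must be zero")
  tr <- ape::nj(stats::as.dist(d))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    deficit <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    parent <- tr$edge[e, 1]
    sisters <- which(tr$edge[, 1] == parent & seq_along(tr$edge.length) != e)
    if (length(sisters))
      tr$edge.length[sisters[1]] <- max(0, tr$edge.length[sisters[1]] + deficit)
  }
  tr
}

#' Brownian-motion covariance matrix over the tips of a tree
#'
#' Entry (i, j) is the branch length shared on the root-to-tip paths of tips
#' i and j; the diagonal is the root-to-tip depth. Unrooted input is
#' midpoint-rooted first (with a message).
#'
#' @param tree a `phylo`.
#' @return positive semi-definite matrix with tip labels as dimnames.
#' @export
bm_covariance <- function(tree) {
  if (!ape::is.rooted(tree)) {
    message("unrooted tree: midpoint rooting for the Brownian covariance")
    tree <- phangorn::midpoint(tree)
  }
  if (any(tree$edge.length < 0)) stop("branch lengths must be non-negative")
  ape::vcv(tree)
}
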