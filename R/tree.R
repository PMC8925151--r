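#' Neighbour-joining / BIONJ tree from a repeat distance matrix
#'
#' Builds an unrooted tree by classic Saitou–Nei neighbour joining or by
#' BIONJ (variance-weighted branch updates), the default being BIONJ.
#' Negative branch-length estimates, which NJ can produce on non-additive
#' input, are clamped to zero with a warning; the pre-clamp values are kept
#' in the `preclamp` attribute.
#'
#' @param m labelled symmetric distance matrix (or `dist`) with at least 3
#'   taxa and finite entries.
#' @param method `"bionj"` (default) or `"nj"`.
#' @return An [ape::phylo] tree over the matrix labels.
#' @export
nj_tree <- function(m, method = c("bionj", "nj")) {
  method <- match.arg(method)
  m <- as.matrix(m)
  if (nrow(m) < 3L) stop("need at least 3 taxa for neighbour joining")
  if (any(!is.finite(m))) stop("distance matrix has non-finite entries")
  if (max(abs(m - t(m))) > 1e-9) stop("distance matrix is not symmetric")
  if (is.null(rownames(m))) rownames(m) <- colnames(m) <- paste0("t", seq_len(nrow(m)))
  d <- as.dist(m)
  tr <- if (method == "bionj") ape::bionj(d) else ape::nj(d)
  if (any(tr$edge.length < 0)) {
    pre <- tr$edge.length
    tr$edge.length[tr$edge.length < 0] <- 0
    attr(tr, "preclamp") <- pre
    warning(sum(pre < 0), " negative branch length(s) clamped to 0")
  }
  tr
}

#' Root a tree on the branch leading to an outgroup
#'
#' Inserts the root on the outgroup's pendant branch, by default at its
#' midpoint; path lengths between all other leaves are unchanged (rooting
#' only adds a degree-2 node).
#'
#' @param tree an [ape::phylo] tree.
#' @param outgroup a tip label present in the tree.
#' @param fraction where on the pendant branch to place the root, as the
#'   fraction of branch length on the outgroup side (default 0.5).
#' @return A rooted [ape::phylo] tree with the outgroup as a child of the
#'   root.
#' @export
root_tree <- function(tree, outgroup, fraction = 0.5) {
  if (!outgroup %in% tree$tip.label)
    stop("outgroup '", outgroup, "' is not a tip of the tree")
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  tip <- which(tree$tip.label == outgroup)
  pend <- tree$edge.length[which(tree$edge[, 2L] == tip)]
  phytools::reroot(tree, tip, position = fraction * pend)
}

#' Write a tree as Newick
#'
#' Branch lengths are printed with 6 significant decimals; labels
#' containing spaces are quoted (ape convention).
#'
#' @param tree an [ape::phylo] tree.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 6)
  invisible(path)
}
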