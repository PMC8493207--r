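#' Phylogenetic covariance matrix
#'
#' Builds the Brownian-motion expected covariance among tips: `C[i, j]` is
#' the branch length shared by the root-to-tip paths of taxa i and j, and
#' `C[i, i]` the root-to-tip distance of taxon i. This matrix carries all
#' covariance structure used by the regression models.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param taxa_order optional character vector: the subset and order of taxa
#'   wanted in the rows/columns. Must be a subset of the tree's tips.
#' @return a symmetric positive-semidefinite matrix with taxa as dimnames.
#' @export
phylo_covariance <- function(tree, taxa_order = NULL) {
  stem <- tree$root.edge %||% 0      # set by prune_to_taxa: path shared by
  tree <- .validate_phylo(tree)      # all tips back to the original root
  C <- ape::vcv.phylo(tree) + stem
  if (!is.null(taxa_order)) {
    taxa_order <- normalize_taxa(taxa_order)
    missing <- setdiff(taxa_order, rownames(C))
    if (length(missing))
      stop("taxa absent from tree: ", paste(missing, collapse = ", "),
           call. = FALSE)
    C <- C[taxa_order, taxa_order, drop = FALSE]
  }
  if (all(diag(C) <= 0))
    stop("phylogenetic covariance is singular: all root-to-tip distances ",
         "are zero", call. = FALSE)
  C
}

#' Pagel's lambda transformation of a phylogenetic covariance
#'
#' Multiplies the off-diagonal elements of `C` by `lam`, leaving the
#' diagonal untouched. `lam = 1` is the full Brownian expectation,
#' `lam = 0` removes all phylogenetic covariance (independent tips with
#' their original variances). The transform is restricted to `[0, 1]`,
#' where the result is guaranteed positive semidefinite.
#'
#' @param C phylogenetic covariance matrix.
#' @param lam numeric scalar in `[0, 1]`.
#' @return the transformed covariance matrix.
#' @export
lambda_transform <- function(C, lam) {
  if (!is.numeric(lam) || length(lam) != 1L || is.na(lam) ||
      lam < 0 || lam > 1)
    stop("lambda must be a single value in [0, 1]; got ", format(lam),
         call. = FALSE)
  Cl <- C * lam
  diag(Cl) <- diag(C)
  Cl
}

#' Prune a tree to a taxon subset
#'
#' Returns the induced subtree on `keep`: path lengths between retained
#' tips are preserved, and internal nodes left with a single child are
#' suppressed with their edge lengths summed. At least 3 taxa must be kept
#' (fewer leaves no fittable comparative model).
#'
#' @param tree a `phylo`.
#' @param keep character vector of tip labels to retain.
#' @return the pruned `phylo`.
#' @export
prune_to_taxa <- function(tree, keep) {
  tree <- .validate_phylo(tree)
  keep <- normalize_taxa(keep)
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing))
    stop("taxa absent from tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (length(keep) < 3L)
    stop("cannot prune to fewer than 3 taxa (model unfittable); got ",
         length(keep), call. = FALSE)
  if (setequal(keep, tree$tip.label)) return(tree)
  stem0 <- tree$root.edge %||% 0
  sub <- ape::keep.tip(tree, keep)
  ## keep.tip reroots at the MRCA of `keep`; carry the dropped stem as a
  ## root edge so covariances still refer to the original root
  ref <- keep[1]
  d_full <- ape::node.depth.edgelength(tree)[match(ref, tree$tip.label)]
  d_sub <- ape::node.depth.edgelength(sub)[match(ref, sub$tip.label)]
  stem <- stem0 + d_full - d_sub
  if (stem > 1e-12) sub$root.edge <- stem
  sub
}
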