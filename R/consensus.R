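## One row per (non-root) edge of the tree: the clade of tip labels below
## the edge, keyed canonically, with its branch length.
.clade_lengths <- function(tr) {
  ntip <- length(tr$tip.label)
  pp <- ape::prop.part(tr)
  labels <- tr$tip.label
  child <- tr$edge[, 2]
  keys <- character(length(child))
  for (i in seq_along(child)) {
    node <- child[i]
    set <- if (node <= ntip) labels[node] else labels[pp[[node - ntip]]]
    keys[i] <- paste(sort(set), collapse = "\t")
  }
  data.frame(key = keys, length = tr$edge.length, stringsAsFactors = FALSE)
}

#' Majority-rule consensus tree with averaged branch lengths
#'
#' Builds the majority-rule consensus of a tree block: a clade is retained
#' when it occurs in strictly more than `p` of the trees (default: more
#' than half). Each retained edge's length is the mean of that edge's
#' lengths over the trees that contain it; terminal edges, present in every
#' tree, are averaged over the whole block. Summarizes a distribution of
#' equally plausible phylogenies into the single tree used for
#' consensus-tree model fits.
#'
#' @param block a `multiPhylo` (or list of `phylo`) over an identical taxon
#'   set.
#' @param p retention threshold as a fraction of trees; clades with
#'   frequency strictly greater than `p` are kept. Default 0.5
#'   (majority rule).
#' @return a `phylo`.
#' @export
consensus_tree <- function(block, p = 0.5) {
  if (inherits(block, "phylo")) block <- list(block)
  if (length(block) < 1L) stop("tree block is empty")
  block <- lapply(block, .validate_phylo)
  taxa <- sort(block[[1]]$tip.label)
  for (k in seq_along(block)) {
    if (!setequal(block[[k]]$tip.label, taxa))
      stop("taxon-set mismatch: tree ", k, " does not match tree 1 (",
           paste(union(setdiff(block[[k]]$tip.label, taxa),
                       setdiff(taxa, block[[k]]$tip.label)), collapse = ", "),
           ")", call. = FALSE)
  }
  k <- length(block)
  tabs <- lapply(block, .clade_lengths)
  all_keys <- unlist(lapply(tabs, `[[`, "key"))
  all_len <- unlist(lapply(tabs, `[[`, "length"))
  count <- table(all_keys)
  len_sum <- tapply(all_len, all_keys, sum)
  keys <- names(count)
  sizes <- vapply(strsplit(keys, "\t", fixed = TRUE), length, integer(1))
  keep <- sizes == 1L | as.vector(count) > p * k
  keys <- keys[keep]
  mean_len <- as.vector(len_sum[keys] / count[keys])
  names(mean_len) <- keys
  sets <- strsplit(keys, "\t", fixed = TRUE)
  ord <- order(-vapply(sets, length, integer(1)))
  sets <- sets[ord]
  keys <- keys[ord]

  build <- function(S) {
    ## maximal retained clades strictly inside S become the children
    inside <- which(vapply(sets, function(x)
      length(x) < length(S) && all(x %in% S), logical(1)))
    kids <- list()
    covered <- character(0)
    for (i in inside) {   # already sorted largest-first => maximal kept first
      x <- sets[[i]]
      if (!any(x %in% covered)) {
        kids <- c(kids, list(x))
        covered <- c(covered, x)
      }
    }
    parts <- vapply(kids, function(x) {
      key <- paste(sort(x), collapse = "\t")
      body <- if (length(x) == 1L) x else build(x)
      paste0(body, ":", sprintf("%.10g", mean_len[[key]]))
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  read_newick(text = paste0(build(taxa), ";"))
}
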