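#' Normalize taxon labels
#'
#' Unifies spaces and underscores in taxon names (spaces become underscores)
#' and trims surrounding whitespace. Comparison stays case-sensitive
#' otherwise. Applied uniformly to tree tip labels and to the `species`
#' column of trait tables so that the two sources key on the same strings.
#'
#' @param x character vector of taxon labels.
#' @return character vector of normalized labels.
#' @export
normalize_taxa <- function(x) {
  gsub("[ ]+", "_", trimws(as.character(x)))
}

## Pre-scan a Newick string so parse failures carry a character position,
## which ape's reader does not report.
.check_newick_syntax <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  depth <- 0L
  in_quote <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") in_quote <- !in_quote
    if (in_quote) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("malformed Newick: unmatched ')' at character ", i, call. = FALSE)
    }
  }
  if (in_quote)
    stop("malformed Newick: unterminated quoted label", call. = FALSE)
  if (depth > 0L)
    stop("malformed Newick: ", depth, " unclosed '(' at character ",
         nchar(s), call. = FALSE)
  if (!grepl(";\\s*$", s))
    stop("malformed Newick: missing terminal ';' at character ",
         nchar(s), call. = FALSE)
  invisible(TRUE)
}

.validate_phylo <- function(tr, where = "tree") {
  if (is.null(tr$edge.length))
    stop(where, ": branch lengths are required but absent", call. = FALSE)
  if (anyNA(tr$edge.length))
    stop(where, ": one or more branch lengths are missing (no silent default)",
         call. = FALSE)
  if (any(tr$edge.length < 0))
    stop(where, ": negative branch length(s) found", call. = FALSE)
  tr$tip.label <- normalize_taxa(tr$tip.label)
  if (anyDuplicated(tr$tip.label))
    stop(where, ": duplicated tip labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "),
         call. = FALSE)
  ## internal node support labels are parsed by ape; discard them
  tr$node.label <- NULL
  tr
}

## Resolve quoted labels before handing the string to ape: spaces inside
## quotes become underscores, the quotes themselves are dropped.
.unquote_labels <- function(s) {
  m <- gregexpr("'[^']*'", s)[[1]]
  if (m[1] == -1) return(s)
  parts <- regmatches(s, gregexpr("'[^']*'", s))[[1]]
  fixed <- gsub(" ", "_", gsub("'", "", parts))
  for (i in seq_along(parts))
    s <- sub(parts[i], fixed[i], s, fixed = TRUE)
  s
}

#' Read trees in Newick format
#'
#' Reads one or several rooted trees from a Newick string or file. Branch
#' lengths are mandatory on all non-root edges; the root edge, if present,
#' is ignored. Internal node support labels are parsed and discarded.
#' Quoted labels are supported; spaces in labels are normalized to
#' underscores.
#'
#' @param text Newick string, possibly containing several `;`-terminated
#'   trees.
#' @param file path to a Newick file (one tree per line or per `;`).
#' @return a `phylo` object, or a `multiPhylo` list if the input holds more
#'   than one tree.
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of 'text' or 'file'")
  if (!is.null(file)) {
    if (!file.exists(file)) stop("file not found: ", file)
    text <- paste(readLines(file, warn = FALSE), collapse = "\n")
  }
  pieces <- strsplit(text, "(?<=;)", perl = TRUE)[[1]]
  pieces <- pieces[nzchar(trimws(pieces))]
  if (length(pieces) == 0L) stop("no Newick tree found in input")
  trees <- vector("list", length(pieces))
  for (k in seq_along(pieces)) {
    s <- trimws(pieces[k])
    .check_newick_syntax(s)
    tr <- tryCatch(ape::read.tree(text = .unquote_labels(s)),
                   error = function(e) NULL, warning = function(w) NULL)
    if (is.null(tr))
      stop("malformed Newick: tree ", k, " could not be parsed", call. = FALSE)
    tr$root.edge <- NULL          # root edge optional in the dialect, ignored
    trees[[k]] <- .validate_phylo(tr, where = paste0("tree ", k))
  }
  if (length(trees) == 1L) return(trees[[1]])
  class(trees) <- "multiPhylo"
  trees
}

#' Write trees in Newick format
#'
#' Emits Newick with branch lengths at 10 significant digits, so that
#' write-then-read round-trips preserve topology and lengths to printed
#' precision.
#'
#' @param tree a `phylo` or `multiPhylo` object.
#' @param file optional output path; when `NULL` the string is returned.
#' @return the Newick string(s), invisibly when writing to file.
#' @export
write_newick <- function(tree, file = NULL) {
  out <- ape::write.tree(tree, digits = 10)
  if (is.null(file)) return(out)
  writeLines(out, file)
  invisible(out)
}

#' Assemble a tree block
#'
#' Bundles an ordered set of trees over a shared taxon set, the carrier of
#' phylogenetic uncertainty. Trees whose tip sets extend beyond the shared
#' set are pruned down to it; a tree missing any shared taxon is an error.
#'
#' @param trees a `multiPhylo` or list of `phylo` objects.
#' @param taxa optional character vector giving the shared taxon set;
#'   defaults to the intersection of all tip sets, which must be non-trivial.
#' @return a `multiPhylo` with identical tip sets and attribute
#'   `shared_taxa`.
#' @export
tree_block <- function(trees, taxa = NULL) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- lapply(trees, .validate_phylo)
  if (length(trees) < 1L) stop("tree block must contain at least one tree")
  tipsets <- lapply(trees, function(t) t$tip.label)
  if (is.null(taxa)) taxa <- Reduce(intersect, tipsets)
  taxa <- normalize_taxa(taxa)
  for (k in seq_along(trees)) {
    missing <- setdiff(taxa, tipsets[[k]])
    if (length(missing))
      stop("tree ", k, " lacks shared taxa: ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  if (length(taxa) < 3L)
    stop("shared taxon set has fewer than 3 taxa")
  trees <- lapply(trees, function(t) {
    if (length(setdiff(t$tip.label, taxa))) ape::keep.tip(t, taxa) else t
  })
  class(trees) <- "multiPhylo"
  attr(trees, "shared_taxa") <- sort(taxa)
  trees
}
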