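# Reading, validation, pruning and Brownian covariance of time-calibrated
# trees. Trees are ape "phylo" objects throughout; branch lengths are in time
# units (Myr for the empirical chronogram).

#' Validate a time-calibrated phylogeny
#'
#' Checks the structural invariants every downstream analysis relies on:
#' rooted topology, unique tip labels, nonnegative branch lengths on every
#' edge, and positive tree height. Tip-label whitespace is normalized to
#' underscores. Trees that are not ultrametric within a relative tolerance
#' of 1e-6 raise a warning (floating-point Newick round-trips routinely
#' perturb the last digits), never an error: the covariance construction is
#' valid for non-ultrametric trees too.
#'
#' @param tree An object of class `phylo`.
#' @param warn_nonultrametric Emit the near-ultrametricity warning?
#' @return The validated (possibly relabelled) tree, invisibly classed `phylo`.
#' @export
validate_phylogeny <- function(tree, warn_nonultrametric = TRUE) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  if (is.null(tree$edge.length)) {
    stop("validation error: tree has no branch lengths")
  }
  if (anyNA(tree$edge.length)) {
    stop("validation error: missing branch length on ",
         sum(is.na(tree$edge.length)), " edge(s)")
  }
  if (any(tree$edge.length < 0)) {
    stop("validation error: negative branch lengths")
  }
  tree$tip.label <- gsub("['\"]", "", gsub("[[:space:]]+", "_",
                                           tree$tip.label))
  if (anyDuplicated(tree$tip.label)) {
    stop("validation error: duplicated tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  }
  # a designated root = exactly one node that is never a child; basal
  # polytomies (star trees) are acceptable
  nodes <- (ape::Ntip(tree) + 1L):(ape::Ntip(tree) + tree$Nnode)
  rootless <- setdiff(nodes, tree$edge[, 2])
  if (length(rootless) != 1L) {
    stop("validation error: tree does not have a single root")
  }
  depths <- .node_depths(tree)[seq_len(ape::Ntip(tree))]
  if (max(depths) <= 0) stop("validation error: tree height is not positive")
  if (warn_nonultrametric &&
      (max(depths) - min(depths)) > 1e-6 * max(depths)) {
    warning("tree is not ultrametric (relative tip-depth spread ",
            signif((max(depths) - min(depths)) / max(depths), 3), ")")
  }
  invisible(tree)
}

#' Read a rooted time-calibrated tree from a Newick file
#'
#' @param path Path to a file containing a single Newick tree with branch
#'   lengths.
#' @return A validated `phylo` object with whitespace in labels normalized to
#'   underscores.
#' @seealso [read_newick_set()] for posterior tree sets, [write_newick()].
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  depth <- 0L
  for (i in seq_len(nchar(txt))) {
    ch <- substr(txt, i, i)
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop("Newick parse error: unbalanced ')' at character offset ", i)
      }
    }
  }
  if (depth != 0L) {
    stop("Newick parse error: ", depth,
         " unclosed '(' by character offset ", nchar(txt))
  }
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) stop("Newick parse error: ",
                                            conditionMessage(e)))
  if (inherits(tree, "multiPhylo")) {
    if (length(tree) != 1L) stop("expected a single tree; found ", length(tree))
    tree <- tree[[1L]]
  }
  if (is.null(tree)) stop("Newick parse error: no tree found in ", path)
  tree <- validate_phylogeny(tree)
  tree
}

#' Read a multi-tree Newick file (e.g. a posterior sample of chronograms)
#'
#' @param path Path to a Newick file with one tree per line.
#' @return A `multiPhylo` list of validated trees.
#' @export
read_newick_set <- function(path) {
  trees <- ape::read.tree(path)
  if (inherits(trees, "phylo")) trees <- c(trees)
  trees <- lapply(trees, validate_phylogeny, warn_nonultrametric = FALSE)
  class(trees) <- "multiPhylo"
  trees
}

#' Write a tree to a Newick file
#'
#' @param tree A `phylo` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Prune a phylogeny to a set of taxa
#'
#' Drops all tips outside `keep`, collapsing the resulting degree-2 internal
#' nodes and summing their branch lengths, so root-to-tip distances of the
#' retained taxa are unchanged.
#'
#' @param tree A validated `phylo` object.
#' @param keep Character vector of tip labels to retain (at least 2).
#' @return The pruned `phylo` object.
#' @export
prune_to_taxa <- function(tree, keep) {
  keep <- unique(gsub("[[:space:]]+", "_", as.character(keep)))
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing) > 0) {
    stop("taxa not in tree: ", paste(missing, collapse = ", "))
  }
  if (length(keep) < 2) stop("need at least 2 taxa to keep")
  if (length(keep) == ape::Ntip(tree)) return(tree)
  ape::keep.tip(tree, keep)
}

#' Brownian-motion covariance implied by a phylogeny
#'
#' Under Brownian motion with unit rate, the covariance of trait values at
#' tips i and j is the shared path length from the root, i.e. the depth of
#' their most recent common ancestor; the variance at tip i is its
#' root-to-tip distance. This matrix (and its inverse square root) is the
#' workhorse behind every GLS-based statistic in the package.
#'
#' @param tree A validated `phylo` object.
#' @return An N x N symmetric matrix with tip labels as dimnames.
#' @export
phylo_covariance <- function(tree) {
  validate_phylogeny(tree, warn_nonultrametric = FALSE)
  ape::vcv.phylo(tree)
}
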