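# Phylomorphospace: principal-component ordination of species trait values
# with Brownian-motion (GLS) ancestral estimates projected onto the same
# axes, so tree branches can be drawn through morphospace.

#' Phylomorphospace projection
#'
#' Runs a centered (unscaled) PCA of the species trait matrix, estimates
#' ancestral values at every internal node by GLS under Brownian motion, and
#' projects those estimates onto the tip-defined axes.
#'
#' @param tree A validated `phylo` object.
#' @param traits Species x dimensions numeric matrix with species rownames.
#' @return List with `scores` (tips x axes), `anc_scores` (internal nodes x
#'   axes, rownames are ape node numbers), `variance_fraction` (per-axis
#'   fraction of total variance), `rotation`, `center`, and `tree` (pruned
#'   to the species analysed).
#' @export
phylomorphospace <- function(tree, traits) {
  traits <- as.matrix(traits)
  if (is.null(rownames(traits))) stop("traits must have species rownames")
  rownames(traits) <- gsub("[[:space:]]+", "_", rownames(traits))
  common <- intersect(tree$tip.label, rownames(traits))
  if (length(common) < 2) stop("fewer than 2 species shared by tree and traits")
  tree <- prune_to_taxa(tree, common)
  Y <- traits[tree$tip.label, , drop = FALSE]
  pc <- stats::prcomp(Y, center = TRUE, scale. = FALSE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  A <- .anc_operator(tree)
  anc <- A %*% Y
  anc_scores <- sweep(anc, 2, pc$center) %*% pc$rotation
  list(scores = pc$x, anc_scores = anc_scores,
       variance_fraction = vf, rotation = pc$rotation, center = pc$center,
       tree = tree)
}
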