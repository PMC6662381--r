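# Shared internal helpers: seeded evaluation and tree bookkeeping used by
# several modules. All functions here assume an ape "phylo" object that has
# already passed validate_phylogeny().

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` with the global random number generator seeded at `seed`, then
#' restores the previous RNG state, so that seeded package functions do not
#' clobber the caller's random stream. A `NULL` seed evaluates `code` on the
#' current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# edge matrix in postorder (children before parents)
.postorder <- function(tree) ape::reorder.phylo(tree, "postorder")

# root-to-node distance for every node (tips first, then internals)
.node_depths <- function(tree) ape::node.depth.edgelength(tree)

# parent of every node (NA at the root), indexed by node number
.parents <- function(tree) {
  out <- rep(NA_integer_, ape::Ntip(tree) + tree$Nnode)
  out[tree$edge[, 2]] <- tree$edge[, 1]
  out
}

# list over all nodes of the tip indices descending from each node
.tip_descendants <- function(tree) {
  n <- ape::Ntip(tree)
  desc <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) desc[[i]] <- i
  po <- .postorder(tree)
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1L]
    desc[[p]] <- c(desc[[p]], desc[[po$edge[e, 2L]]])
  }
  desc
}

# Shared path length (depth of the MRCA) between every internal node and
# every tip; rows are internal nodes in ape numbering order.
.node_tip_cov <- function(tree) {
  n <- ape::Ntip(tree)
  m <- tree$Nnode
  d <- .node_depths(tree)
  desc <- .tip_descendants(tree)
  parent <- .parents(tree)
  root <- n + 1L
  Cn <- matrix(0, m, n,
               dimnames = list(as.character((n + 1L):(n + m)), tree$tip.label))
  for (u in (n + 1L):(n + m)) {
    row <- numeric(n)
    assigned <- rep(FALSE, n)
    a <- u
    repeat {
      tips <- desc[[a]]
      fresh <- tips[!assigned[tips]]
      row[fresh] <- d[a]
      assigned[tips] <- TRUE
      if (a == root) break
      a <- parent[a]
    }
    Cn[u - n, ] <- row
  }
  Cn
}

# Linear operator A (Nnode x Ntip) with anc = A %*% Y giving the GLS (ML
# under Brownian motion) ancestral trait estimates at every internal node.
.anc_operator <- function(tree, C = NULL) {
  n <- ape::Ntip(tree)
  if (is.null(C)) C <- ape::vcv.phylo(tree)
  Ci <- solve(C)
  w <- rowSums(Ci) / sum(Ci)          # GLS weights for the phylogenetic mean
  Cn <- .node_tip_cov(tree)
  A <- matrix(w, nrow(Cn), n, byrow = TRUE) +
    Cn %*% Ci %*% (diag(n) - tcrossprod(rep(1, n), w))
  dimnames(A) <- dimnames(Cn)
  A
}

# Symmetric inverse square root of a covariance matrix via eigendecomposition.
.inv_sqrt <- function(C) {
  e <- eigen(C, symmetric = TRUE)
  if (any(e$values < max(e$values) * 1e-12)) {
    stop("covariance matrix is computationally singular")
  }
  e$vectors %*% (t(e$vectors) / sqrt(e$values))
}

# Lower-triangular factor L with L %*% t(L) = C, for simulating tip data.
.chol_lower <- function(C) t(chol(C))

# Symmetric square root of a trait covariance that may be rank deficient.
.psd_sqrt <- function(R) {
  e <- eigen((R + t(R)) / 2, symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% (t(e$vectors) * sqrt(v))
}

# permutation p-value under the (1 + exceedances) / (1 + draws) convention
.perm_p <- function(observed, draws) {
  (1 + sum(draws >= observed)) / (1 + length(draws))
}
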