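# Independent oracles used across the suite. These deliberately avoid the
# package's own algorithms: the likelihood oracle enumerates ancestral
# states, the path-sampling oracle is plain forward simulation with
# endpoint rejection, and the covariance oracle walks root-to-tip paths.

# matrix exponential by plain scaled Taylor summation (oracle-grade, for
# the small matrices used in these tests)
oracle_expm <- function(A) {
  s <- max(0L, ceiling(log2(max(1, max(abs(A))))))
  As <- A / 2^s
  P <- diag(nrow(A))
  term <- diag(nrow(A))
  for (k in 1:60) {
    term <- term %*% As / k
    P <- P + term
  }
  for (i in seq_len(s)) P <- P %*% P
  P
}

# Mk likelihood by explicit summation over all interior-state assignments.
enum_mk_loglik <- function(tree, states, Q, prior) {
  Q <- unclass(as.matrix(Q))
  K <- nrow(Q)
  labels <- rownames(Q)
  n <- ape::Ntip(tree)
  m <- tree$Nnode
  x <- match(states[tree$tip.label], labels)
  Pe <- lapply(seq_len(nrow(tree$edge)), function(e) {
    oracle_expm(Q * tree$edge.length[e])
  })
  combs <- as.matrix(expand.grid(rep(list(seq_len(K)), m)))
  tot <- 0
  for (r in seq_len(nrow(combs))) {
    st <- c(x, combs[r, ])
    pr <- prior[st[n + 1]]
    for (e in seq_len(nrow(tree$edge))) {
      pr <- pr * Pe[[e]][st[tree$edge[e, 1]], st[tree$edge[e, 2]]]
    }
    tot <- tot + pr
  }
  log(tot)
}

# Marginal node probabilities by the same enumeration.
enum_marginals <- function(tree, states, Q, prior) {
  Q <- unclass(as.matrix(Q))
  K <- nrow(Q)
  labels <- rownames(Q)
  n <- ape::Ntip(tree)
  m <- tree$Nnode
  x <- match(states[tree$tip.label], labels)
  Pe <- lapply(seq_len(nrow(tree$edge)), function(e) {
    oracle_expm(Q * tree$edge.length[e])
  })
  combs <- as.matrix(expand.grid(rep(list(seq_len(K)), m)))
  marg <- matrix(0, m, K)
  for (r in seq_len(nrow(combs))) {
    st <- c(x, combs[r, ])
    pr <- prior[st[n + 1]]
    for (e in seq_len(nrow(tree$edge))) {
      pr <- pr * Pe[[e]][st[tree$edge[e, 1]], st[tree$edge[e, 2]]]
    }
    for (u in seq_len(m)) marg[u, combs[r, u]] <- marg[u, combs[r, u]] + pr
  }
  sweep(marg, 1, rowSums(marg), "/")
}

# Shared-path covariance by explicit per-pair traversal to the root.
bruteforce_vcv <- function(tree) {
  n <- ape::Ntip(tree)
  parent <- rep(NA_integer_, n + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen <- rep(0, n + tree$Nnode)
  elen[tree$edge[, 2]] <- tree$edge.length
  anc_path <- function(i) {
    out <- i
    while (!is.na(parent[i])) {
      i <- parent[i]
      out <- c(out, i)
    }
    out
  }
  depth <- function(i) sum(elen[anc_path(i)])
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      common <- intersect(anc_path(i), anc_path(j))
      mrca <- common[1]
      C[i, j] <- depth(mrca)
    }
  }
  C
}

# small fixed Q-matrices used in several files
q2 <- function(a = 0.8, b = 0.5) {
  q_matrix(matrix(c(0, a, b, 0), 2, 2, byrow = TRUE), c("A", "B"))
}
q3 <- function() {
  q_matrix(matrix(c(0, 0.3, 0.6,
                    0.2, 0, 0.1,
                    0.5, 0.4, 0), 3, 3, byrow = TRUE), c("a", "b", "c"))
}

# paint a clade with one state and the rest of the tree with another,
# returning a deterministic single-segment-per-edge character history
paint_clade_history <- function(tree, node, inside = "fast",
                                outside = "slow") {
  clade_tips <- ape::extract.clade(tree, node)$tip.label
  desc <- habshape:::.tip_descendants(tree)
  focal_idx <- match(clade_tips, tree$tip.label)
  st <- vapply(seq_len(nrow(tree$edge)), function(e) {
    tips <- desc[[tree$edge[e, 2]]]
    if (all(tips %in% focal_idx)) inside else outside
  }, character(1))
  paths <- lapply(seq_len(nrow(tree$edge)), function(e) {
    data.frame(state = st[e], dwell = tree$edge.length[e],
               stringsAsFactors = FALSE)
  })
  ns <- rep(outside, ape::Ntip(tree) + tree$Nnode)
  for (e in seq_len(nrow(tree$edge))) ns[tree$edge[e, 2]] <- st[e]
  h <- list(tree = tree, node_states = ns, paths = paths,
            states = sort(unique(c(inside, outside))))
  class(h) <- "character_history"
  h
}

# internal node with a descendant-tip count nearest the target fraction
clade_node_near <- function(tree, fraction = 0.5) {
  n <- ape::Ntip(tree)
  desc <- habshape:::.tip_descendants(tree)
  sizes <- vapply(desc, length, integer(1))
  cand <- (n + 2L):(n + tree$Nnode)   # exclude the root
  cand[which.min(abs(sizes[cand] - fraction * n))]
}
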