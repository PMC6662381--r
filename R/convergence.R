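# Phenotypic convergence statistics: C1 (proportional reduction of current
# distance between focal taxa relative to the maximal distance among their
# ancestral values), C5 (number of lineages whose evolutionary path enters
# the morphospace region delimited by the focal taxa), and the allometric
# convergence permutation test (do two groups' predicted shapes approach
# each other as size increases?). Null distributions come from Brownian
# motion simulation on the tree with the trait covariance estimated from
# the data.

# node numbers (ape indexing) on the path tip -> ... -> stop_node, inclusive
.path_to <- function(parent, node, stop_node) {
  out <- node
  while (node != stop_node) {
    node <- parent[node]
    out <- c(out, node)
  }
  out
}

# precomputed geometry for C1: per focal pair, the node numbers on both
# root-ward paths to the MRCA (tips included)
.c1_structure <- function(tree, focal) {
  parent <- .parents(tree)
  tips <- match(focal, tree$tip.label)
  pairs <- utils::combn(tips, 2)
  lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]
    i2 <- pairs[2, j]
    mrca <- ape::getMRCA(tree, c(i1, i2))
    list(t1 = i1, t2 = i2,
         nodes = unique(c(.path_to(parent, i1, mrca),
                          .path_to(parent, i2, mrca))))
  })
}

# C1 given tip values Y (ordered as tree tips) and ancestral values anc
# (rownames = node numbers); struct from .c1_structure()
.c1_value <- function(Y, anc, struct, warn = FALSE) {
  n <- nrow(Y)
  all_vals <- rbind(Y, anc)     # rows 1..n tips, then internal nodes
  vals <- numeric(length(struct))
  for (j in seq_along(struct)) {
    s <- struct[[j]]
    V <- all_vals[s$nodes, , drop = FALSE]
    dmax <- max(stats::dist(V))
    dtip <- sqrt(sum((Y[s$t1, ] - Y[s$t2, ])^2))
    if (dmax == 0) {
      if (warn) warning("all node values identical for a focal pair; C1 = 0")
      vals[j] <- 0
    } else {
      vals[j] <- 1 - dtip / dmax
    }
  }
  vals
}

#' C1 convergence statistic for a focal set of taxa
#'
#' For each pair of focal tips, C1 = 1 - Dtip / Dmax, where Dtip is the
#' Euclidean distance between the two tips' trait values and Dmax the
#' maximum distance between any two node values (GLS ancestral estimates,
#' tips included) along the two root-ward paths to the pair's most recent
#' common ancestor. The statistic is the mean over focal pairs; its p-value
#' is the fraction of Brownian-motion simulations (trait covariance
#' estimated from the data) with simulated C1 at least as large.
#'
#' @param tree A validated `phylo` object.
#' @param Y Species x dimensions trait matrix with species rownames.
#' @param focal Character vector of focal tip labels (>= 2).
#' @param n_sim Number of null simulations.
#' @param seed RNG seed.
#' @return Object of class `convergence_result` with `C1`, `C1_pairs`,
#'   `p`, `n_sim`.
#' @export
convergence_c1 <- function(tree, Y, focal, n_sim = 999, seed = 1) {
  m <- .match_comparative(tree, Y)
  focal <- gsub("[[:space:]]+", "_", focal)
  missing <- setdiff(focal, m$tree$tip.label)
  if (length(missing) > 0) {
    stop("focal taxa not present: ", paste(missing, collapse = ", "))
  }
  if (length(focal) < 2) stop("need at least 2 focal taxa")
  struct <- .c1_structure(m$tree, focal)
  C <- phylo_covariance(m$tree)
  A <- .anc_operator(m$tree, C)
  n <- nrow(m$Y)
  p <- ncol(m$Y)
  # row indexing of rbind(Y, anc): internal node u sits at row u
  obs_pairs <- .c1_value(m$Y, A %*% m$Y, struct, warn = TRUE)
  obs <- mean(obs_pairs)
  Lc <- .chol_lower(C)
  Rsq <- .psd_sqrt(crossprod(.phylo_residuals(m$tree, m$Y)) / n)
  sims <- with_seed(seed, {
    vapply(seq_len(n_sim), function(i) {
      Ysim <- Lc %*% matrix(stats::rnorm(n * p), n, p) %*% Rsq
      mean(.c1_value(Ysim, A %*% Ysim, struct))
    }, numeric(1))
  })
  out <- list(C1 = obs, C1_pairs = obs_pairs, p = .perm_p(obs, sims),
              n_sim = n_sim, focal = focal)
  class(out) <- "convergence_result"
  out
}

## 2-D convex-hull helpers --------------------------------------------------

# hull as ordered vertex matrix (closed: first vertex repeated at the end)
.hull_polygon <- function(pts) {
  h <- grDevices::chull(pts)
  if (length(h) < 3) {
    stop("degenerate convex hull; need non-collinear focal points")
  }
  poly <- rbind(pts[h, , drop = FALSE], pts[h[1], , drop = FALSE])
  # shoelace area: collinear focal points give a zero-area hull
  area <- abs(sum(poly[-nrow(poly), 1] * poly[-1, 2] -
                    poly[-1, 1] * poly[-nrow(poly), 2])) / 2
  if (area < 1e-10 * max(1, max(abs(pts)))^2) {
    stop("degenerate convex hull; need non-collinear focal points")
  }
  poly
}

.cross2 <- function(o, a, b) {
  (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
}

# point inside (or on the boundary of) a convex polygon
.in_hull <- function(pt, poly) {
  k <- nrow(poly) - 1
  signs <- vapply(seq_len(k), function(i) {
    .cross2(poly[i, ], poly[i + 1, ], pt)
  }, numeric(1))
  tol <- 1e-12 * max(1, max(abs(poly)))
  all(signs >= -tol) || all(signs <= tol)
}

# do segments ab and cd properly intersect (shared endpoints count)?
.seg_intersect <- function(a, b, c, d) {
  d1 <- .cross2(c, d, a)
  d2 <- .cross2(c, d, b)
  d3 <- .cross2(a, b, c)
  d4 <- .cross2(a, b, d)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  on_seg <- function(p, q, r) {
    min(p[1], q[1]) - 1e-12 <= r[1] && r[1] <= max(p[1], q[1]) + 1e-12 &&
      min(p[2], q[2]) - 1e-12 <= r[2] && r[2] <= max(p[2], q[2]) + 1e-12
  }
  (d1 == 0 && on_seg(c, d, a)) || (d2 == 0 && on_seg(c, d, b)) ||
    (d3 == 0 && on_seg(a, b, c)) || (d4 == 0 && on_seg(a, b, d))
}

# does the path (matrix of points, root first) enter the hull?
.path_enters <- function(path, poly) {
  inside <- apply(path, 1, .in_hull, poly = poly)
  if (inside[1]) return(TRUE)            # lineage starts within the region
  for (i in seq_len(nrow(path) - 1)) {
    if (!inside[i] && inside[i + 1]) return(TRUE)
    if (!inside[i] && !inside[i + 1]) {
      # pass-through: segment crossing a hull edge without an inside endpoint
      for (j in seq_len(nrow(poly) - 1)) {
        if (.seg_intersect(path[i, ], path[i + 1, ], poly[j, ],
                           poly[j + 1, ])) return(TRUE)
      }
    }
  }
  FALSE
}

# C5 for one dataset: ordinate, build focal hull, count entering lineages;
# A is the precomputed GLS ancestral operator
.c5_value <- function(Y, focal_idx, parent, root, A) {
  pc <- stats::prcomp(Y, center = TRUE, scale. = FALSE)
  S <- pc$x[, 1:2, drop = FALSE]
  anc <- sweep(A %*% Y, 2, pc$center) %*% pc$rotation[, 1:2, drop = FALSE]
  all_pts <- rbind(S, anc)               # row u = node u
  poly <- .hull_polygon(S[focal_idx, , drop = FALSE])
  entered <- 0L
  for (tip in seq_len(nrow(S))) {
    nodes <- rev(.path_to(parent, tip, root))   # root first
    if (.path_enters(all_pts[nodes, , drop = FALSE], poly)) {
      entered <- entered + 1L
    }
  }
  entered
}

#' C5 convergence statistic: lineages entering the focal morphospace region
#'
#' Tips and GLS ancestral estimates are ordinated onto the first two
#' principal axes; the focal region is the convex hull of the focal tips'
#' scores. C5 counts the root-to-tip lineages whose path enters the hull
#' (each lineage at most once; a lineage already inside at the root counts).
#' The p-value is the fraction of Brownian-motion simulations with C5 at
#' least as large, each simulation re-ordinated from scratch.
#'
#' @inheritParams convergence_c1
#' @param dims Ordination dimensionality for the hull; only 2 is supported
#'   (planar convex hulls).
#' @return Object of class `convergence_result` with `C5`, `p`, `n_sim`.
#' @export
convergence_c5 <- function(tree, Y, focal, dims = 2, n_sim = 999, seed = 1) {
  if (dims != 2) {
    stop("only 2-D morphospace hulls are supported (dims = 2)")
  }
  m <- .match_comparative(tree, Y)
  focal <- gsub("[[:space:]]+", "_", focal)
  missing <- setdiff(focal, m$tree$tip.label)
  if (length(missing) > 0) {
    stop("focal taxa not present: ", paste(missing, collapse = ", "))
  }
  if (length(focal) < dims + 1) stop("need at least dims + 1 focal taxa")
  focal_idx <- match(focal, m$tree$tip.label)
  parent <- .parents(m$tree)
  root <- ape::Ntip(m$tree) + 1L
  n <- nrow(m$Y)
  p <- ncol(m$Y)
  C <- phylo_covariance(m$tree)
  A <- .anc_operator(m$tree, C)
  obs <- .c5_value(m$Y, focal_idx, parent, root, A)
  Lc <- .chol_lower(C)
  Rsq <- .psd_sqrt(crossprod(.phylo_residuals(m$tree, m$Y)) / n)
  sims <- with_seed(seed, {
    vapply(seq_len(n_sim), function(i) {
      Ysim <- Lc %*% matrix(stats::rnorm(n * p), n, p) %*% Rsq
      .c5_value(Ysim, focal_idx, parent, root, A)
    }, numeric(1))
  })
  out <- list(C5 = obs, p = .perm_p(obs, sims), n_sim = n_sim,
              focal = focal)
  class(out) <- "convergence_result"
  out
}

#' @export
print.convergence_result <- function(x, ...) {
  if (!is.null(x$C1)) {
    cat(sprintf("C1 = %.4f (mean over %d focal pairs), p = %.4g [%d sims]\n",
                x$C1, length(x$C1_pairs), x$p, x$n_sim))
  }
  if (!is.null(x$C5)) {
    cat(sprintf("C5 = %d lineages entering the focal region, p = %.4g [%d sims]\n",
                x$C5, x$p, x$n_sim))
  }
  invisible(x)
}

#' Allometric convergence between two groups
#'
#' Tests whether two groups' shapes converge as size increases: shape is
#' regressed on log size within each group, predicted shapes are compared
#' at the shared minimum and maximum observed sizes, and the statistic
#' D_small - D_large (positive when the groups are closer at large size) is
#' evaluated against random reassignments of species to groups (each
#' species keeps its own size and shape).
#'
#' @param Y Species x dimensions shape matrix with species rownames.
#' @param group Named vector with exactly two group levels after matching.
#' @param size Named numeric vector of log centroid sizes (or any log size
#'   measure) per species.
#' @param n_perm Number of label permutations.
#' @param seed RNG seed.
#' @return Object of class `allometry_convergence`: `D_small`, `D_large`,
#'   `statistic`, `p`, `n_perm`, `size_range`.
#' @export
allometric_convergence <- function(Y, group, size, n_perm = 999, seed = 1) {
  Y <- as.matrix(Y)
  if (is.null(rownames(Y))) stop("Y must have species rownames")
  gv <- .states_vector(group)
  common <- Reduce(intersect, list(rownames(Y), names(gv), names(size)))
  if (length(common) < 6) stop("fewer than 6 species after matching")
  Y <- Y[common, , drop = FALSE]
  g <- factor(gv[common])
  s <- as.numeric(size[common])
  if (nlevels(g) != 2) stop("exactly two groups are required")
  if (any(table(g) < 3)) stop("each group needs at least 3 species")
  r1 <- range(s[g == levels(g)[1]])
  r2 <- range(s[g == levels(g)[2]])
  if (r1[2] < r2[1] || r2[2] < r1[1]) {
    warning("group size ranges do not overlap; predictions are extrapolated")
  }
  s_min <- min(s)
  s_max <- max(s)
  stat_of <- function(gg) {
    preds <- lapply(levels(gg), function(lv) {
      ix <- gg == lv
      fit <- stats::lm.fit(cbind(1, s[ix]), Y[ix, , drop = FALSE])
      b <- fit$coefficients
      list(small = b[1, ] + s_min * b[2, ],
           large = b[1, ] + s_max * b[2, ])
    })
    d_small <- sqrt(sum((preds[[1]]$small - preds[[2]]$small)^2))
    d_large <- sqrt(sum((preds[[1]]$large - preds[[2]]$large)^2))
    c(D_small = d_small, D_large = d_large,
      statistic = d_small - d_large)
  }
  obs <- stat_of(g)
  perms <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      stat_of(factor(sample(as.character(g))))[["statistic"]]
    }, numeric(1))
  })
  out <- list(D_small = obs[["D_small"]], D_large = obs[["D_large"]],
              statistic = obs[["statistic"]],
              p = .perm_p(obs[["statistic"]], perms), n_perm = n_perm,
              size_range = c(s_min, s_max), groups = levels(g))
  class(out) <- "allometry_convergence"
  out
}

#' @export
print.allometry_convergence <- function(x, ...) {
  cat(sprintf(
    "Allometric convergence (%s vs %s): D_small - D_large = %.4f, p = %.4g\n",
    x$groups[1], x$groups[2], x$statistic, x$p))
  invisible(x)
}
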