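# Phylogenetic ANOVA by generalized least squares with residual
# randomization (RRPP): trait and design matrices are whitened by the
# inverse square root of the Brownian covariance, sums of squares are traced
# over dimensions, and the null distribution comes from permuting
# reduced-model (intercept-only) residuals.

# Align tree, trait matrix and per-species labels; prunes per-analysis to
# the intersection, per the pipeline's matching convention.
.match_comparative <- function(tree, Y, group = NULL) {
  Y <- as.matrix(Y)
  if (is.null(rownames(Y))) stop("trait matrix must have species rownames")
  rownames(Y) <- gsub("[[:space:]]+", "_", rownames(Y))
  common <- intersect(tree$tip.label, rownames(Y))
  if (!is.null(group)) {
    gv <- .states_vector(group)
    common <- intersect(common, names(gv))
  }
  if (length(common) < 3) stop("fewer than 3 species after matching")
  tree <- prune_to_taxa(tree, common)
  Y <- Y[tree$tip.label, , drop = FALSE]
  if (!all(is.finite(Y))) stop("trait values must be finite")
  out <- list(tree = tree, Y = Y)
  if (!is.null(group)) {
    out$group <- factor(gv[tree$tip.label])
    if (nlevels(droplevels(out$group)) < 2) {
      stop("need at least 2 groups after matching")
    }
    out$group <- droplevels(out$group)
  }
  out
}

# trace sums of squares for transformed data vs full/reduced hat matrices
.rrpp_stats <- function(Yt, Hf, Hr, df1, df2) {
  ss_tot <- sum((Yt - Hr %*% Yt)^2)
  resid_f <- Yt - Hf %*% Yt
  ss_err <- sum(resid_f^2)
  ss_mod <- ss_tot - ss_err
  R2 <- ss_mod / ss_tot
  F <- (ss_mod / df1) / (ss_err / df2)
  c(R2 = R2, F = F)
}

.hat <- function(X) {
  qx <- qr(X)
  Q <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
  tcrossprod(Q)
}

#' Phylogenetic ANOVA with residual randomization (RRPP)
#'
#' Tests whether group mean trait values differ, accounting for phylogenetic
#' non-independence under Brownian motion. Data and design are transformed
#' by the inverse square root of the tree covariance; R-squared and F are
#' computed from traced sums of squares and cross-products; significance
#' comes from `n_perm` randomizations of the reduced-model (intercept-only)
#' residuals. The effect size Z is the standard deviate of log(F) against
#' the permutation distribution (observed value included).
#'
#' On a star phylogeny with equal tip depths the transformation is a scalar
#' and the statistics equal their ordinary (non-phylogenetic) MANOVA-trace
#' counterparts.
#'
#' @param tree A validated `phylo` object.
#' @param Y Species x dimensions trait matrix (rownames are species).
#' @param group Named character vector or `scheme_assignment` mapping
#'   species to groups.
#' @param n_perm Number of residual randomizations.
#' @param seed RNG seed.
#' @return Object of class `anova_result`: `R2`, `F`, `Z`, `p`, `n_perm`,
#'   `df`, `groups` (group sizes).
#' @export
phylogenetic_anova <- function(tree, Y, group, n_perm = 999, seed = 1) {
  m <- .match_comparative(tree, Y, group)
  n <- nrow(m$Y)
  g <- nlevels(m$group)
  Tm <- .inv_sqrt(phylo_covariance(m$tree))
  Yt <- Tm %*% m$Y
  Xf <- Tm %*% stats::model.matrix(~ m$group)
  Xr <- Tm %*% matrix(1, n, 1)
  Hf <- .hat(Xf)
  Hr <- .hat(Xr)
  df1 <- g - 1
  df2 <- n - g
  obs <- .rrpp_stats(Yt, Hf, Hr, df1, df2)
  fit_r <- Hr %*% Yt
  res_r <- Yt - fit_r
  Fs <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      Yp <- fit_r + res_r[sample.int(n), , drop = FALSE]
      .rrpp_stats(Yp, Hf, Hr, df1, df2)[["F"]]
    }, numeric(1))
  })
  p <- .perm_p(obs[["F"]], Fs)
  logF <- log(c(obs[["F"]], Fs))
  Z <- (logF[1] - mean(logF)) / stats::sd(logF)
  out <- list(R2 = obs[["R2"]], F = obs[["F"]], Z = Z, p = p,
              n_perm = n_perm, df = c(df1, df2),
              groups = table(m$group))
  class(out) <- "anova_result"
  out
}

#' @export
print.anova_result <- function(x, ...) {
  cat("Phylogenetic ANOVA (RRPP, ", x$n_perm, " permutations)\n", sep = "")
  cat(sprintf("  R2 = %.4f, F = %.4f, Z = %.4f, p = %.4g\n",
              x$R2, x$F, x$Z, x$p))
  invisible(x)
}

#' Pairwise distances between phylogenetic group means
#'
#' GLS group means are estimated under the tree covariance; Euclidean
#' distances between all pairs of means are evaluated against the same
#' residual-randomization null as [phylogenetic_anova()].
#'
#' @inheritParams phylogenetic_anova
#' @return List with `distances` (g x g matrix), `p` (g x g matrix of
#'   permutation p-values), `means` (GLS group means), `n_perm`.
#' @export
pairwise_group_distances <- function(tree, Y, group, n_perm = 999,
                                     seed = 1) {
  m <- .match_comparative(tree, Y, group)
  n <- nrow(m$Y)
  lev <- levels(m$group)
  Tm <- .inv_sqrt(phylo_covariance(m$tree))
  Yt <- Tm %*% m$Y
  Xg <- Tm %*% stats::model.matrix(~ 0 + m$group)
  Xr <- Tm %*% matrix(1, n, 1)
  Hr <- .hat(Xr)
  gls_means <- function(Ym) {
    B <- qr.coef(qr(Xg), Ym)
    rownames(B) <- lev
    B
  }
  dist_of <- function(B) as.matrix(stats::dist(B))
  obs_means <- gls_means(Yt)
  obs_d <- dist_of(obs_means)
  fit_r <- Hr %*% Yt
  res_r <- Yt - fit_r
  exceed <- matrix(0, length(lev), length(lev),
                   dimnames = dimnames(obs_d))
  with_seed(seed, {
    for (i in seq_len(n_perm)) {
      Yp <- fit_r + res_r[sample.int(n), , drop = FALSE]
      dp <- dist_of(gls_means(Yp))
      exceed <- exceed + (dp >= obs_d)
    }
  })
  p <- (1 + exceed) / (1 + n_perm)
  diag(p) <- NA
  list(distances = obs_d, p = p, means = obs_means, n_perm = n_perm)
}
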