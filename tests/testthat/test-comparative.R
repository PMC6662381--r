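star_tree <- function(n, depth = 1) {
  tr <- ape::stree(n, "star")
  tr$edge.length <- rep(depth, n)
  tr$tip.label <- paste0("t", seq_len(n))
  tr
}

test_that("phylogenetic ANOVA equals ordinary MANOVA-trace stats on a star
           tree", {
  tr <- star_tree(30)
  Y <- with_seed(3, matrix(rnorm(30 * 4), 30, 4,
                           dimnames = list(tr$tip.label, NULL)))
  grp <- setNames(rep(c("a", "b", "c"), each = 10), tr$tip.label)
  res <- phylogenetic_anova(tr, Y, grp, n_perm = 49, seed = 1)
  fit <- lm(Y ~ factor(grp))
  ss_tot <- sum(scale(Y, scale = FALSE)^2)
  ss_err <- sum(residuals(fit)^2)
  ss_mod <- ss_tot - ss_err
  expect_equal(res$F, (ss_mod / 2) / (ss_err / 27), tolerance = 1e-9)
  expect_equal(res$R2, ss_mod / ss_tot, tolerance = 1e-9)
  expect_true(res$R2 >= 0 && res$R2 <= 1)
  expect_true(res$p > 0 && res$p <= 1)
})

test_that("RRPP p-values use the (1 + exceedances)/(1 + draws) convention
           and are seed-reproducible", {
  tr <- simulate_yule_tree(40, seed = 31)
  Y <- simulate_multivariate_bm(tr, 1, p = 3, seed = 5)
  grp <- setNames(rep(c("x", "y"), 20), tr$tip.label)
  a1 <- phylogenetic_anova(tr, Y, grp, n_perm = 99, seed = 7)
  a2 <- phylogenetic_anova(tr, Y, grp, n_perm = 99, seed = 7)
  expect_identical(a1$p, a2$p)
  expect_identical(a1$Z, a2$Z)
  expect_true(a1$p >= 1 / 100 && a1$p <= 1)
  # p is a multiple of 1/(1 + n_perm)
  expect_equal(a1$p * 100, round(a1$p * 100), tolerance = 1e-9)
})

test_that("pairwise group distances are metric and calibrated under
           random labels", {
  tr <- simulate_yule_tree(45, seed = 13)
  Y <- simulate_multivariate_bm(tr, 1, p = 4, seed = 3)
  grp <- setNames(rep(c("a", "b", "c"), 15), tr$tip.label)
  pw <- pairwise_group_distances(tr, Y, grp, n_perm = 99, seed = 2)
  d <- pw$distances
  expect_true(all(d >= 0))
  expect_equal(d, t(d))
  # triangle inequality over the three group means
  expect_lte(d["a", "b"], d["a", "c"] + d["c", "b"] + 1e-12)
  expect_lte(d["a", "c"], d["a", "b"] + d["b", "c"] + 1e-12)
  expect_lte(d["b", "c"], d["b", "a"] + d["a", "c"] + 1e-12)
  # identical group means -> zero distance
  Ydup <- Y
  Ydup[grp == "b", ] <- Ydup[grp == "a", ]
  pw2 <- pairwise_group_distances(star_tree(45), Ydup,
                                  grp, n_perm = 19, seed = 1)
  expect_lt(pw2$distances["a", "b"], 1e-9)
})

test_that("sigma_mult satisfies its closed forms and invariances", {
  tr <- simulate_yule_tree(40, seed = 7)
  Y <- simulate_multivariate_bm(tr, 0.5, p = 4, seed = 3)
  s <- sigma_mult(tr, Y)
  # orthogonal rotation of trait columns leaves the rate unchanged
  R <- with_seed(5, qr.Q(qr(matrix(rnorm(16), 4, 4))))
  expect_equal(sigma_mult(tr, Y %*% R), s, tolerance = 1e-10)
  # constant traits give rate zero
  Y0 <- matrix(2, 40, 3, dimnames = list(tr$tip.label, NULL))
  expect_lt(sigma_mult(tr, Y0), 1e-18)
  # p = 1 reduces to the univariate GLS estimator
  C <- phylo_covariance(tr)
  Ci <- solve(C)
  y <- Y[, 1, drop = FALSE]
  mu <- sum(Ci %*% y) / sum(Ci)
  expect_equal(sigma_mult(tr, y),
               as.numeric(t(y - mu) %*% Ci %*% (y - mu)) / 40,
               tolerance = 1e-10)
})

test_that("sigma_mult recovers a known generating rate", {
  ests <- vapply(1:40, function(i) {
    tr <- simulate_yule_tree(150, seed = 400 + i)
    Y <- simulate_multivariate_bm(tr, 0.5, p = 4, seed = 500 + i)
    sigma_mult(tr, Y)
  }, numeric(1))
  expect_lt(abs(mean(ests) / 0.5 - 1), 0.05)     # near-unbiased
  expect_gt(mean(abs(ests / 0.5 - 1) < 0.25), 0.9)
})

test_that("rate comparison recovers painted clade rates and respects
           group exclusions", {
  tr <- simulate_yule_tree(200, seed = 61)
  node <- clade_node_near(tr, 0.5)
  h <- paint_clade_history(tr, node)
  Y <- simulate_multivariate_bm(tr, c(fast = 4, slow = 1), p = 6,
                                seed = 62, history = h)
  grp <- setNames(h$node_states[1:200], tr$tip.label)
  r <- compare_rates_by_group(tr, Y, grp, n_sim = 99, seed = 1)
  expect_gt(r$pairwise_ratios["fast", "slow"], 2)
  expect_gte(r$ratio, 1)
  expect_true(all(r$sigma2_by_group > 0))
  expect_lt(r$p, 0.05)
  # singleton groups are excluded with a warning
  grp2 <- grp
  grp2[1] <- "lonely"
  expect_warning(compare_rates_by_group(tr, Y, grp2, n_sim = 9, seed = 1),
                 "lonely")
})

test_that("C1 hits its boundary cases", {
  tr <- ape::read.tree(text =
    "(((f1:1,a:1):1,(f2:1,b:1):1):1,(c:2,d:2):1);")
  base <- with_seed(8, matrix(rnorm(12), 6, 2))
  rownames(base) <- tr$tip.label
  Y <- base
  # identical focal tips with divergent relatives: C1 = 1
  Y["f2", ] <- Y["f1", ]
  r <- convergence_c1(tr, Y, c("f1", "f2"), n_sim = 19, seed = 1)
  expect_equal(r$C1, 1, tolerance = 1e-12)
  expect_true(r$p >= 1 / 20 && r$p <= 1)
  # tip distance equal to the maximal node distance: C1 = 0
  tr2 <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  Y2 <- matrix(0, 4, 2, dimnames = list(c("a", "b", "c", "d"), NULL))
  Y2["a", ] <- c(10, 0)
  Y2["b", ] <- c(-10, 0)
  # ancestors shrink toward the mean, so the tips are the extremes
  r2 <- convergence_c1(tr2, Y2, c("a", "b"), n_sim = 19, seed = 1)
  expect_equal(r2$C1, 0, tolerance = 1e-9)
  # degenerate all-identical data: C1 defined as 0, with warning
  Y3 <- matrix(1, 4, 2, dimnames = list(c("a", "b", "c", "d"), NULL))
  expect_warning(r3 <- convergence_c1(tr2, Y3, c("a", "b"), n_sim = 9,
                                      seed = 1), "identical")
  expect_equal(r3$C1, 0)
})

test_that("C1 is invariant to global rotation and translation of trait
           space", {
  tr <- simulate_yule_tree(30, seed = 17)
  Y <- simulate_multivariate_bm(tr, 1, p = 4, seed = 19)
  focal <- tr$tip.label[c(2, 9, 20)]
  r1 <- convergence_c1(tr, Y, focal, n_sim = 9, seed = 2)
  R <- with_seed(21, qr.Q(qr(matrix(rnorm(16), 4, 4))))
  Yt <- sweep(Y %*% R, 2, c(3, -1, 2, 7), "+")
  r2 <- convergence_c1(tr, Yt, focal, n_sim = 9, seed = 2)
  expect_equal(r1$C1, r2$C1, tolerance = 1e-9)
})

test_that("C5 equals the hand-counted crossings on a worked example", {
  # ten tips: five focal tips clustered far from everything else, so only
  # the five focal lineages enter their hull
  tr <- star_tree(10)
  focal <- paste0("t", 1:5)
  ang <- seq(0, 2 * pi, length.out = 6)[-6]
  Y <- rbind(cbind(10 + 0.6 * cos(ang), 0.6 * sin(ang)),
             cbind(-4 + 0.3 * cos(ang), 6 * sin(ang) - 3))
  rownames(Y) <- tr$tip.label
  r <- convergence_c5(tr, Y, focal, n_sim = 19, seed = 1)
  expect_equal(r$C5, 5L)
  # hull containing the grand mean of a star tree catches every lineage:
  # all root-to-tip paths start at the ancestral estimate inside the hull
  Yc <- rbind(cbind(cos(ang), sin(ang)),
              cbind(3 * cos(ang), 3 * sin(ang)))
  rownames(Yc) <- tr$tip.label
  r2 <- convergence_c5(tr, Yc, paste0("t", 6:10), n_sim = 9, seed = 1)
  expect_equal(r2$C5, 10L)
  expect_error(convergence_c5(tr, Y, focal, dims = 4), "2-D")
  # degenerate hull (collinear focal scores) is refused
  Yd <- Y
  Yd[1:5, ] <- cbind(10 + (1:5) * 0.1, (1:5) * 0.1 - 10)
  expect_error(suppressWarnings(convergence_c5(tr, Yd, focal, n_sim = 9,
                                               seed = 1)),
               "degenerate|collinear")
})

test_that("allometric convergence finds constructed convergence and
           nothing in duplicated groups", {
  # identical groups: distances and statistic are exactly zero
  sp <- sprintf("s%02d", 1:20)
  Y <- with_seed(3, matrix(rnorm(40), 20, 2, dimnames = list(sp, NULL)))
  size <- setNames(rep(seq(1, 3, length.out = 10), 2), sp)
  grp <- setNames(rep(c("g1", "g2"), each = 10), sp)
  Y[11:20, ] <- Y[1:10, ]
  size[11:20] <- size[1:10]
  r0 <- allometric_convergence(Y, grp, size, n_perm = 49, seed = 1)
  expect_equal(r0$D_small, 0, tolerance = 1e-12)
  expect_equal(r0$D_large, 0, tolerance = 1e-12)
  expect_equal(r0$statistic, 0, tolerance = 1e-12)

  # trajectories built to intersect at large size from distinct
  # small-size shapes
  sp2 <- sprintf("s%02d", 1:60)
  s2 <- setNames(rep(seq(0, 1, length.out = 30), 2), sp2)
  g2 <- setNames(rep(c("g1", "g2"), each = 30), sp2)
  shape <- with_seed(11, {
    base <- cbind(s2[1:30] * 1, 2 - 2 * s2[1:30])      # group 1
    conv <- cbind(s2[31:60] * 1, -2 + 2 * s2[31:60])   # group 2, meets at 1
    rbind(base, conv) + matrix(rnorm(120, 0, 0.1), 60, 2)
  })
  rownames(shape) <- sp2
  r1 <- allometric_convergence(shape, g2, s2, n_perm = 199, seed = 5)
  expect_gt(r1$statistic, 0)
  expect_lt(r1$p, 0.05)
  # non-overlapping size ranges trigger the extrapolation warning
  s3 <- s2
  s3[31:60] <- s3[31:60] + 10
  expect_warning(allometric_convergence(shape, g2, s3, n_perm = 9,
                                        seed = 1), "overlap")
})
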