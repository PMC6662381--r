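test_that("imputation is the identity on complete tables and recovers
           exact allometry", {
  tab <- generate_measurement_table(n_species = 10, n_per_species = 4,
                                    noise = 0.05, seed = 3)
  out <- impute_missing_measurements(tab)
  mv <- c("SVL", "TL", "HL", "BW", "SE", "FLL", "HLL")
  expect_identical(out[, mv], tab[, mv])
  expect_equal(attr(out, "n_imputed"), 0L)

  # exact allometry TL = 1.2 SVL, one masked value: recovered to 1e-6
  exact <- generate_measurement_table(
    n_species = 6, n_per_species = 5,
    allometry = list(coef = c(TL = 1.2, HL = 0.25, BW = 0.15, SE = 0.08,
                              FLL = 0.28, HLL = 0.32),
                     exponent = c(TL = 1, HL = 1, BW = 1, SE = 1,
                                  FLL = 1, HLL = 1)),
    noise = 0, seed = 5)
  truth <- exact$TL[4]
  exact$TL[4] <- NA
  fixed <- impute_missing_measurements(exact)
  expect_equal(fixed$TL[4], truth, tolerance = 1e-6)
  expect_equal(attr(fixed, "n_imputed"), 1L)
  # observed entries bit-identical
  expect_identical(fixed$SVL, exact$SVL)
  expect_identical(fixed$TL[-4], exact$TL[-4])
  # deterministic
  expect_identical(impute_missing_measurements(exact)$TL[4], fixed$TL[4])
})

test_that("imputation recovers noisily masked entries and rejects empty
           specimens", {
  tab <- generate_measurement_table(n_species = 12, n_per_species = 6,
                                    noise = 0.05, missing_fraction = 0.05,
                                    seed = 11)
  full <- generate_measurement_table(n_species = 12, n_per_species = 6,
                                     noise = 0.05, missing_fraction = 0,
                                     seed = 11)
  fixed <- impute_missing_measurements(tab)
  mask <- which(is.na(as.matrix(tab[, c("TL", "HL", "BW", "SE", "FLL",
                                        "HLL")])))
  rel_err <- abs(as.matrix(fixed[, c("TL", "HL", "BW", "SE", "FLL",
                                     "HLL")])[mask] /
                   as.matrix(full[, c("TL", "HL", "BW", "SE", "FLL",
                                      "HLL")])[mask] - 1)
  expect_lt(median(rel_err), 0.15)   # within the table's noise scale
  bad <- tab
  bad[1, c("SVL", "TL", "HL", "BW", "SE", "FLL", "HLL")] <- NA
  expect_error(impute_missing_measurements(bad), "all measurements missing")
})

test_that("shape ratios are log Mosimann ratios of species means", {
  tab <- data.frame(specimen = c("s1", "s2", "s3"),
                    species = c("sp1", "sp1", "sp2"),
                    SVL = c(10, 20, 30), TL = c(20, 40, 30),
                    HL = c(10, 20, 30), BW = c(10, 20, 30),
                    SE = c(10, 20, 30), FLL = c(10, 20, 30),
                    HLL = c(10, 20, 30))
  r <- shape_ratios(tab)
  expect_equal(unname(r["sp1", "TL"]), log(2))
  expect_equal(unname(r["sp2", ]), rep(0, 6))     # all equal to SVL
  # scale invariance: doubling all of a species' measurements changes nothing
  tab2 <- tab
  tab2[tab2$species == "sp1", 3:9] <- tab2[tab2$species == "sp1", 3:9] * 2
  expect_equal(shape_ratios(tab2), shape_ratios(tab), ignore_attr = TRUE)
})

test_that("thin-plate splines reproduce similarity transforms and warps", {
  tm <- foot_template()$coords
  # identity: masked point recovered exactly
  cfg <- tm
  cfg[7, ] <- NA
  out <- interpolate_missing_landmarks(cfg, tm)
  expect_lt(max(abs(out - tm)), 1e-9)
  expect_equal(attr(out, "interpolated"), 7L)
  # rotation + scale: still exact (the affine term carries it)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  warped <- 1.7 * tm %*% R
  cfg2 <- warped
  cfg2[c(3, 15), ] <- NA
  out2 <- interpolate_missing_landmarks(cfg2, tm)
  expect_lt(max(abs(out2 - warped)), 1e-9)
  # known quadratic warp: interpolant agrees with a dense-grid spline fit
  quad <- cbind(tm[, 1] + 0.1 * tm[, 2]^2, tm[, 2] - 0.08 * tm[, 1]^2)
  cfg3 <- quad
  cfg3[5, ] <- NA
  out3 <- interpolate_missing_landmarks(cfg3, tm)
  sp_full <- tps_spline(tm[-5, ], quad[-5, ])
  expect_lt(max(abs(out3[5, ] - tps_evaluate(sp_full, tm[5, , drop = FALSE]))),
            1e-9)
  # and lands within the warp's own bending scale of the true point
  expect_lt(sqrt(sum((out3[5, ] - quad[5, ])^2)), 0.1)
  # degenerate shared sets are refused
  colin <- cbind(1:21, 2 * (1:21))
  expect_error(tps_spline(colin, colin), "collinear")
})

test_that("GPA removes similarity transforms to machine precision", {
  tm <- foot_template()$coords
  copies <- with_seed(6, lapply(1:8, function(i) {
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    sweep(exp(rnorm(1)) * tm %*% R, 2, rnorm(2, 0, 3), "+")
  }))
  g <- gpa(copies)
  for (i in 2:8) {
    expect_lt(procrustes_distance(g$coords[, , 1], g$coords[, , i]), 1e-9)
  }
  # invariants: centroid at the origin, unit centroid size, consensus = mean
  expect_lt(max(abs(apply(g$coords, 3, colMeans))), 1e-9)
  expect_lt(max(abs(apply(g$coords, 3, function(X) sqrt(sum(X^2))) - 1)),
            1e-9)
  cons <- apply(g$coords, c(1, 2), mean)
  cons <- cons / sqrt(sum(cons^2))
  expect_lt(max(abs(cons - g$consensus)), 1e-6)
})

test_that("pairwise Procrustes distance matches the closed-form two-shape
           solution", {
  X <- matrix(c(0, 0, 1, 0, 0, 1), 3, 2, byrow = TRUE)
  Y <- matrix(c(0.1, 0, 1.2, 0.1, -0.1, 0.9), 3, 2, byrow = TRUE)
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  Xc <- Xc / sqrt(sum(Xc^2))
  Yc <- Yc / sqrt(sum(Yc^2))
  # full orthogonal alignment: min distance^2 = 2 - 2 * sum of singular
  # values of the cross-product
  d_closed <- sqrt(2 - 2 * sum(svd(crossprod(Xc, Yc))$d))
  expect_equal(procrustes_distance(X, Y), d_closed, tolerance = 1e-12)
})

test_that("GPA output is invariant to pre-applied similarity transforms", {
  lms <- generate_landmark_dataset(n_species = 5, n_per_species = 3,
                                   noise = 0.02, seed = 14)
  g1 <- gpa(lms$coords)
  jittered <- with_seed(3, lapply(lms$coords, function(X) {
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    sweep(exp(rnorm(1, 0, 0.4)) * X %*% R, 2, rnorm(2), "+")
  }))
  g2 <- gpa(jittered)
  for (i in seq_len(dim(g1$coords)[3])) {
    expect_lt(procrustes_distance(g1$coords[, , i], g2$coords[, , i]), 1e-7)
  }
})

test_that("semilandmark sliding never increases bending energy in a pass", {
  lms <- generate_landmark_dataset(n_species = 6, n_per_species = 3,
                                   noise = 0.02, seed = 9)
  g <- gpa(lms$coords, slide = TRUE, curves = lms$curves)
  expect_true(all(g$bending_trace[, "after"] <=
                    g$bending_trace[, "before"] + 1e-10))
  # sliding with no curves is refused
  expect_error(gpa(lms$coords, slide = TRUE), "curves")
})

test_that("species mean shapes: duplicates give the member shape and
           balanced noise-free data match single-stage GPA", {
  tm <- foot_template()$coords
  coords <- with_seed(4, lapply(1:6, function(i) {
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    sweep(2 * tm %*% R, 2, rnorm(2), "+")
  }))
  sm <- species_mean_shapes(coords, rep(c("sp1", "sp2"), each = 3))
  expect_lt(procrustes_distance(sm$coords[, , "sp1"],
                                habshape:::.center_scale(tm)), 1e-8)
  expect_lt(procrustes_distance(sm$coords[, , "sp1"],
                                sm$coords[, , "sp2"]), 1e-8)
  expect_equal(unname(sm$mean_centroid_size["sp1"]),
               2 * habshape:::.centroid_size(tm), tolerance = 1e-9)
  # one specimen per species: stage 1 is center-and-scale only
  sm1 <- species_mean_shapes(coords[1:3], c("a", "b", "c"))
  expect_equal(dim(sm1$coords)[3], 3)
})

test_that("phylomorphospace variance fractions behave at the extremes", {
  tr <- simulate_yule_tree(40, seed = 21)
  # rank-1 data: first axis carries everything
  v <- with_seed(2, rnorm(40))
  Y1 <- outer(v, c(1, 2, 3))
  rownames(Y1) <- tr$tip.label
  pm <- phylomorphospace(tr, Y1)
  expect_equal(pm$variance_fraction[1], 1, tolerance = 1e-12)
  # fractions always sum to one
  Y2 <- with_seed(3, matrix(rnorm(40 * 5), 40, 5,
                            dimnames = list(tr$tip.label, NULL)))
  pm2 <- phylomorphospace(tr, Y2)
  expect_equal(sum(pm2$variance_fraction), 1, tolerance = 1e-12)
  # circularly symmetric 2-D data: fractions near one half each
  ang <- seq(0, 2 * pi, length.out = 41)[-41]
  Y3 <- cbind(cos(ang), sin(ang))
  rownames(Y3) <- tr$tip.label
  pm3 <- phylomorphospace(tr, Y3)
  expect_equal(unname(pm3$variance_fraction), c(0.5, 0.5), tolerance = 1e-9)
  # ancestral projections exist for every internal node
  expect_equal(nrow(pm3$anc_scores), tr$Nnode)
})

test_that("TPS files round-trip coordinates, ids and missing points", {
  lms <- generate_landmark_dataset(n_species = 3, n_per_species = 2,
                                   missing_fraction = 0.1, seed = 8)
  f <- withr::local_tempfile(fileext = ".tps")
  write_tps(lms$coords, f, id = lms$specimen)
  back <- read_tps(f)
  expect_equal(length(back$coords), length(lms$coords))
  expect_identical(back$id, lms$specimen)
  for (i in seq_along(lms$coords)) {
    expect_equal(back$coords[[i]], unname(lms$coords[[i]]),
                 tolerance = 1e-12)
  }
  # SCALE records are honored
  f2 <- withr::local_tempfile(lines = c("LM=3", "0 0", "1 0", "0 1",
                                        "IMAGE=x.jpg", "ID=7",
                                        "SCALE=0.5"))
  sc <- read_tps(f2)
  expect_equal(sc$coords[[1]][2, 1], 0.5)
  expect_identical(sc$id, "7")
})
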