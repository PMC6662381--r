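test_that("every generator is a pure function of its seed", {
  expect_identical(simulate_yule_tree(20, seed = 5),
                   simulate_yule_tree(20, seed = 5))
  tr <- simulate_yule_tree(20, seed = 5)
  Q <- q2(0.4, 0.2)
  s1 <- simulate_discrete_character(tr, Q, root = "A", seed = 9)
  s2 <- simulate_discrete_character(tr, Q, root = "A", seed = 9)
  expect_identical(s1$tip_states, s2$tip_states)
  expect_identical(s1$history$paths, s2$history$paths)
  expect_identical(simulate_multivariate_bm(tr, 1, p = 3, seed = 2),
                   simulate_multivariate_bm(tr, 1, p = 3, seed = 2))
  expect_identical(
    generate_landmark_dataset(n_species = 4, n_per_species = 2, seed = 3),
    generate_landmark_dataset(n_species = 4, n_per_species = 2, seed = 3))
  expect_identical(
    generate_measurement_table(n_species = 5, n_per_species = 3, seed = 4),
    generate_measurement_table(n_species = 5, n_per_species = 3, seed = 4))
  # generators do not disturb the caller's RNG stream
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(simulate_yule_tree(10, seed = 7))
  expect_identical(runif(1), before)
})

test_that("Yule trees are valid ultrametric chronograms of the right size", {
  tr2 <- simulate_yule_tree(2, seed = 1)
  expect_equal(ape::Ntip(tr2), 2)          # the smallest case: one cherry
  for (s in 1:3) {
    tr <- simulate_yule_tree(30, seed = s, height = 7)
    expect_equal(ape::Ntip(tr), 30)
    d <- ape::node.depth.edgelength(tr)[1:30]
    expect_lt(max(d) - min(d), 1e-9 * max(d))
    expect_equal(max(d), 7, tolerance = 1e-9)
    expect_silent(validate_phylogeny(tr))
  }
  # lineage-through-time growth is roughly exponential: log-lineage counts
  # against time are close to linear on average
  ltt_r2 <- mean(vapply(1:40, function(s) {
    tr <- simulate_yule_tree(60, seed = 100 + s)
    times <- sort(ape::branching.times(tr), decreasing = TRUE)
    k <- seq_along(times) + 1
    summary(lm(log(k) ~ times))$r.squared
  }, numeric(1)))
  expect_gt(ltt_r2, 0.9)
})

test_that("discrete forward simulation matches the binary closed form", {
  # single branch of length t: P(end != start) = 0.5 - 0.5 exp(-2qt)
  tr <- ape::read.tree(text = "(A:1,B:1);")
  q <- 0.6
  Q <- q2(q, q)
  flips <- vapply(1:4000, function(i) {
    s <- simulate_discrete_character(tr, Q, root = "A", seed = i)
    unname(s$tip_states["A"] != "A")
  }, logical(1))
  p_hat <- mean(flips)
  p_true <- 0.5 - 0.5 * exp(-2 * q)
  expect_lt(abs(p_hat - p_true), 3 * sqrt(p_true * (1 - p_true) / 4000))
  # zero Q: everything stays in the root state
  s0 <- simulate_discrete_character(tr, q_matrix(matrix(0, 2, 2)),
                                    root = "A", seed = 1)
  expect_true(all(s0$tip_states == "A"))
  expect_equal(sum(count_transitions(s0$history)), 0)
})

test_that("true transition counts round-trip through stochastic mapping", {
  tr <- simulate_yule_tree(60, seed = 77, height = 2)
  Q <- q2(0.5, 0.3)
  true_counts <- 0
  mapped_counts <- 0
  n_syn <- 120
  for (i in seq_len(n_syn)) {
    sim <- simulate_discrete_character(tr, Q, root = "A", seed = 3000 + i)
    true_counts <- true_counts + sum(count_transitions(sim$history))
    h <- sample_history(tr, sim$tip_states, Q, seed = 4000 + i)
    mapped_counts <- mapped_counts + sum(count_transitions(h))
  }
  expect_lt(abs(mapped_counts / true_counts - 1), 0.1)
})

test_that("Brownian moments on a cherry match theory", {
  tr <- ape::read.tree(text = "(A:2,B:2);")
  vals <- vapply(1:2000, function(i) {
    simulate_multivariate_bm(tr, 0.7, p = 1, seed = i)[, 1]
  }, numeric(2))
  v <- apply(vals, 1, var)
  expect_lt(max(abs(v / (2 * 0.7) - 1)), 0.15)   # var = T * sigma^2
  expect_lt(abs(cov(vals[1, ], vals[2, ])), 0.1) # no shared history
  # zero-rate segments contribute nothing
  h <- paint_clade_history(tr, 3, inside = "on", outside = "on")
  h$paths[[1]]$state <- "off"
  Y <- simulate_multivariate_bm(tr, c(on = 1, off = 0), p = 1, seed = 5,
                                history = h)
  expect_equal(unname(Y["A", 1]), 0)
})

test_that("state-dependent BM variance follows the painted history", {
  tr <- simulate_yule_tree(150, seed = 55)
  node <- clade_node_near(tr, 0.45)
  h <- paint_clade_history(tr, node)
  Y <- simulate_multivariate_bm(tr, c(fast = 9, slow = 1), p = 4,
                                seed = 56, history = h)
  grp <- setNames(h$node_states[1:150], tr$tip.label)
  r <- compare_rates_by_group(tr, Y, grp, n_sim = 0)
  expect_gt(r$pairwise_ratios["fast", "slow"], 3)
})

test_that("convergent attraction reduces to BM at strength zero and
           collapses focal tips at high strength", {
  tr <- simulate_yule_tree(40, seed = 23)
  focal <- ape::extract.clade(tr, clade_node_near(tr, 0.2))$tip.label
  y0 <- simulate_convergent_traits(tr, focal, attractor = rep(0, 3),
                                   strength = 0, base_rate = 1, seed = 31)
  ybm <- simulate_multivariate_bm(tr, 1, p = 3, seed = 31)
  # strength 0 follows the plain BM code path; distributions must agree
  ks <- suppressWarnings(stats::ks.test(as.vector(y0), as.vector(ybm)))
  expect_gt(ks$p.value, 1e-4)
  # strong attraction: focal tips collapse onto the attractor
  yc <- simulate_convergent_traits(tr, focal, attractor = c(5, 5, 5),
                                   strength = 200, base_rate = 0.5,
                                   seed = 33)
  focal_spread <- max(dist(yc[focal, ]))
  expect_lt(focal_spread, max(dist(yc)) / 5)
  expect_lt(max(abs(yc[focal[1], ] - c(5, 5, 5))), 1.5)
})

test_that("landmark datasets respect their masking contract and complete
           cleanly", {
  lms <- generate_landmark_dataset(n_species = 10, n_per_species = 4,
                                   noise = 0.01, missing_fraction = 0.08,
                                   seed = 6)
  n_missing <- vapply(lms$coords, function(X) sum(is.na(X[, 1])),
                      integer(1))
  expect_true(all(n_missing <= 6))
  expect_gt(sum(n_missing), 0)
  # masked points are recovered near the truth by TPS completion: the
  # completed specimen deviates from its species mean shape only at the
  # digitizing-noise scale
  i <- which(n_missing > 0)[1]
  ref <- lms$species_means[[lms$species[i]]]
  completed <- interpolate_missing_landmarks(lms$coords[[i]], ref)
  expect_lt(procrustes_distance(completed, ref), 0.05)

  # noise 0, missing 0: GPA recovers the template exactly up to similarity
  clean <- generate_landmark_dataset(n_species = 1, n_per_species = 5,
                                     species_sd = 0, noise = 0,
                                     seed = 2)
  g <- gpa(clean$coords)
  expect_lt(procrustes_distance(g$consensus, clean$template$coords), 1e-8)
})

test_that("measurement tables follow their allometry and masking contract", {
  # noise 0, exponent 1: identical shape-ratio vectors across species
  exact <- generate_measurement_table(n_species = 8, n_per_species = 3,
                                      noise = 0, seed = 9)
  r <- shape_ratios(exact)
  expect_lt(max(apply(r, 2, function(col) diff(range(col)))), 1e-12)
  # masked fraction tracks the requested rate
  tab <- generate_measurement_table(n_species = 40, n_per_species = 10,
                                    missing_fraction = 0.1, seed = 10)
  cells <- as.matrix(tab[, c("TL", "HL", "BW", "SE", "FLL", "HLL")])
  frac <- mean(is.na(cells))
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / length(cells)))
  expect_false(anyNA(tab$SVL))
})
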