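# Synthetic-data generators emulating the structure of the empirical study
# inputs: Yule chronograms, discrete microhabitat characters under a
# Q-matrix, multivariate traits under (state-dependent or convergent)
# Brownian motion, landmark datasets around a template foot shape, and
# linear measurement tables with allometric structure and missing cells.
# Every generator is a pure function of its seed.

#' Simulate a pure-birth (Yule) chronogram
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth_rate Speciation rate of the pure-birth process.
#' @param seed Integer seed.
#' @param height Rescale the tree to this root-to-tip height (default 1);
#'   `NULL` keeps the simulated depth.
#' @return An ultrametric `phylo` object with tips `t1..tn`.
#' @export
simulate_yule_tree <- function(n_tips, birth_rate = 1, seed = 1,
                               height = 1) {
  if (n_tips < 2) stop("n_tips must be >= 2")
  tree <- with_seed(seed, ape::rphylo(n_tips, birth = birth_rate, death = 0))
  if (!is.null(height)) {
    h <- max(.node_depths(tree))
    tree$edge.length <- tree$edge.length * (height / h)
  }
  validate_phylogeny(tree, warn_nonultrametric = FALSE)
  tree
}

#' Forward-simulate a discrete character along a tree
#'
#' Exact continuous-time Markov simulation: the state waits an exponential
#' time at its total leave-rate and jumps proportionally to its row of Q.
#' Returns both the tip states and the complete true history, so inference
#' can be checked by round trip.
#'
#' @param tree A validated `phylo` object.
#' @param q Q-matrix ([q_matrix()]).
#' @param root Root state label, or `NULL` to draw from `root_prior`.
#' @param seed Integer seed.
#' @param root_prior Per-state probabilities for a random root state.
#' @return List with `tip_states` (named character vector) and `history`
#'   (a `character_history`).
#' @export
simulate_discrete_character <- function(tree, q, root = NULL, seed = 1,
                                        root_prior = "flat") {
  Q <- .check_q(q)
  labels <- rownames(Q)
  K <- nrow(Q)
  with_seed(seed, {
    n <- ape::Ntip(tree)
    node_state <- integer(n + tree$Nnode)
    rt <- n + 1L
    if (is.null(root)) {
      pi <- .resolve_root_prior(root_prior, Q)
      node_state[rt] <- sample.int(K, 1L, prob = pi)
    } else {
      node_state[rt] <- match(root, labels)
      if (is.na(node_state[rt])) stop("unknown root state: ", root)
    }
    po <- .postorder(tree)
    ord <- match(
      paste(po$edge[, 1], po$edge[, 2]),
      paste(tree$edge[, 1], tree$edge[, 2])
    )
    paths <- vector("list", nrow(tree$edge))
    for (e in rev(seq_len(nrow(po$edge)))) {
      ei <- ord[e]
      par <- tree$edge[ei, 1L]
      ch <- tree$edge[ei, 2L]
      t_total <- tree$edge.length[ei]
      s <- node_state[par]
      tm <- 0
      st <- integer(0)
      dw <- numeric(0)
      repeat {
        rate <- -Q[s, s]
        w <- if (rate > 0) stats::rexp(1, rate) else Inf
        d <- min(w, t_total - tm)
        st <- c(st, s)
        dw <- c(dw, d)
        tm <- tm + d
        if (tm >= t_total) break
        pr <- Q[s, ]
        pr[s] <- 0
        s <- sample.int(K, 1L, prob = pr)
      }
      paths[[ei]] <- data.frame(state = labels[st], dwell = dw,
                                stringsAsFactors = FALSE)
      node_state[ch] <- s
    }
    history <- list(tree = tree, node_states = labels[node_state],
                    paths = paths, states = labels)
    class(history) <- "character_history"
    tips <- stats::setNames(labels[node_state[seq_len(n)]], tree$tip.label)
    list(tip_states = tips, history = history)
  })
}

#' Simulate multivariate Brownian motion, optionally with state-dependent
#' rates
#'
#' Trait values accumulate independent Gaussian increments along each branch
#' with variance = segment duration x the rate of the segment's state, per
#' dimension. With a single-state (scalar) regime this is plain BM.
#'
#' @param tree A validated `phylo` object.
#' @param rate_by_state Named per-state rates (used with `history`), or a
#'   single rate.
#' @param p Number of trait dimensions.
#' @param seed Integer seed.
#' @param history Optional `character_history` painting states on the tree.
#' @return Species x p trait matrix with tip-label rownames.
#' @export
simulate_multivariate_bm <- function(tree, rate_by_state, p = 6, seed = 1,
                                     history = NULL) {
  if (!is.null(history)) {
    if (!isTRUE(all.equal(sort(history$tree$tip.label),
                          sort(tree$tip.label))) ||
        abs(sum(history$tree$edge.length) - sum(tree$edge.length)) >
          1e-9 * max(1, sum(tree$edge.length))) {
      stop("history was simulated on a different tree")
    }
  }
  if (any(rate_by_state < 0)) stop("rates must be nonnegative")
  with_seed(seed, {
    n <- ape::Ntip(tree)
    vals <- matrix(0, n + tree$Nnode, p)
    po <- .postorder(tree)
    ord <- match(
      paste(po$edge[, 1], po$edge[, 2]),
      paste(tree$edge[, 1], tree$edge[, 2])
    )
    for (e in rev(seq_len(nrow(po$edge)))) {
      ei <- ord[e]
      par <- tree$edge[ei, 1L]
      ch <- tree$edge[ei, 2L]
      v <- if (is.null(history)) {
        rate_by_state[1] * tree$edge.length[ei]
      } else {
        path <- history$paths[[ei]]
        sum(rate_by_state[path$state] * path$dwell)
      }
      vals[ch, ] <- vals[par, ] + stats::rnorm(p, 0, sqrt(v))
    }
    out <- vals[seq_len(n), , drop = FALSE]
    rownames(out) <- tree$tip.label
    out
  })
}

# edges all of whose descendant tips are focal
.focal_edges <- function(tree, focal) {
  desc <- .tip_descendants(tree)
  focal_idx <- match(focal, tree$tip.label)
  vapply(seq_len(nrow(tree$edge)), function(ei) {
    tips <- desc[[tree$edge[ei, 2L]]]
    all(tips %in% focal_idx)
  }, logical(1))
}

#' Simulate traits with convergent attraction for focal lineages
#'
#' Brownian motion everywhere, with an added Ornstein-Uhlenbeck-style
#' attraction toward a common attractor point on branches whose descendant
#' tips are all focal, integrated by Euler discretization with steps of at
#' most 1% of tree height. Strength 0 reduces to pure Brownian motion.
#'
#' @param tree A validated `phylo` object.
#' @param focal Labels of the focal (convergent) tips.
#' @param attractor Length-p attractor point in trait space.
#' @param strength Attraction strength (per unit time; >= 0).
#' @param base_rate BM rate per dimension.
#' @param seed Integer seed.
#' @return Species x p trait matrix.
#' @export
simulate_convergent_traits <- function(tree, focal, attractor,
                                       strength = 1, base_rate = 1,
                                       seed = 1) {
  if (strength < 0) stop("strength must be >= 0")
  p <- length(attractor)
  focal <- gsub("[[:space:]]+", "_", focal)
  is_focal_edge <- .focal_edges(tree, focal)
  hmax <- max(.node_depths(tree)) * 0.01
  with_seed(seed, {
    n <- ape::Ntip(tree)
    vals <- matrix(0, n + tree$Nnode, p)
    po <- .postorder(tree)
    ord <- match(
      paste(po$edge[, 1], po$edge[, 2]),
      paste(tree$edge[, 1], tree$edge[, 2])
    )
    for (e in rev(seq_len(nrow(po$edge)))) {
      ei <- ord[e]
      par <- tree$edge[ei, 1L]
      ch <- tree$edge[ei, 2L]
      t_total <- tree$edge.length[ei]
      x <- vals[par, ]
      if (!is_focal_edge[ei] || strength == 0) {
        x <- x + stats::rnorm(p, 0, sqrt(base_rate * t_total))
      } else if (t_total > 0) {
        n_steps <- max(1L, ceiling(t_total / hmax))
        dt <- t_total / n_steps
        for (s in seq_len(n_steps)) {
          x <- x + strength * (attractor - x) * dt +
            stats::rnorm(p, 0, sqrt(base_rate * dt))
        }
      }
      vals[ch, ] <- x
    }
    out <- vals[seq_len(n), , drop = FALSE]
    rownames(out) <- tree$tip.label
    out
  })
}

#' Template foot shape for landmark simulations
#'
#' A stylized five-toed right hind foot: 11 fixed landmarks (five toe tips,
#' four webbing minima between adjacent toes, two foot-base corners) and 10
#' semilandmarks (two per toe, flanking each tip along the toe margin).
#'
#' @return List with `coords` (21 x 2 template), `landmarks` (fixed indices),
#'   `semilandmarks`, and `curves` (semilandmark sliding matrix: anterior
#'   neighbour, semilandmark, posterior neighbour).
#' @export
foot_template <- function() {
  ang <- seq(130, 50, length.out = 5) * pi / 180   # toe directions
  tip_r <- c(1.6, 1.9, 2.1, 1.9, 1.6)              # toe lengths
  tips <- cbind(tip_r * cos(ang), tip_r * sin(ang))
  web_ang <- (ang[-5] + ang[-1]) / 2
  webs <- cbind(0.85 * cos(web_ang), 0.85 * sin(web_ang))
  base <- rbind(c(-0.55, -0.35), c(0.55, -0.35))
  fixed <- rbind(tips, webs, base)                 # 5 + 4 + 2 = 11
  # two semilandmarks per toe, on the toe margin just lateral to each tip
  semis <- NULL
  curves <- NULL
  left_nb <- c(10, 6, 7, 8, 9)    # landmark bracketing each toe on the left
  right_nb <- c(6, 7, 8, 9, 11)   # ... and on the right
  for (i in seq_len(5)) {
    a <- ang[i] + 0.09
    b <- ang[i] - 0.09
    r <- tip_r[i] * 0.93
    s1 <- c(r * cos(a), r * sin(a))
    s2 <- c(r * cos(b), r * sin(b))
    semis <- rbind(semis, s1, s2)
    curves <- rbind(curves,
                    c(left_nb[i], 11 + 2 * i - 1, i),
                    c(i, 11 + 2 * i, right_nb[i]))
  }
  coords <- rbind(fixed, semis)
  rownames(coords) <- NULL
  list(coords = coords, landmarks = 1:11, semilandmarks = 12:21,
       curves = curves)
}

#' Generate a synthetic landmark dataset around a template shape
#'
#' Species mean shapes are the template plus independent Gaussian deviations
#' (or Brownian deviations on a supplied tree); specimens add isotropic
#' digitizing noise and a random similarity transform (rotation, scale,
#' translation); a fraction of points is masked as missing (at most 6 per
#' specimen, so thin-plate spline completion stays well-posed).
#'
#' @param template Template list from [foot_template()] (or compatible).
#' @param n_species,n_per_species Dataset dimensions.
#' @param species_sd Standard deviation of species-level shape deviations
#'   (ignored when `tree` is supplied; then `bm_rate` scales Brownian
#'   deviations).
#' @param noise Specimen-level digitizing noise standard deviation.
#' @param missing_fraction Fraction of landmark points masked at random.
#' @param seed Integer seed.
#' @param tree Optional `phylo` with `n_species` tips for phylogenetically
#'   structured species means.
#' @param bm_rate Brownian rate per coordinate when `tree` is given.
#' @return List with `coords` (list of 21 x 2 matrices, NA rows where
#'   masked), `species`, `specimen`, `species_means`, `template`, `curves`.
#' @export
generate_landmark_dataset <- function(template = foot_template(),
                                      n_species = 20, n_per_species = 5,
                                      species_sd = 0.05, noise = 0.01,
                                      missing_fraction = 0, seed = 1,
                                      tree = NULL, bm_rate = 0.002) {
  X0 <- template$coords
  k <- nrow(X0)
  with_seed(seed, {
    if (!is.null(tree)) {
      if (ape::Ntip(tree) != n_species) stop("tree tip count != n_species")
      dev <- simulate_multivariate_bm(tree, bm_rate, p = 2 * k,
                                      seed = sample.int(1e6, 1))
      species_names <- tree$tip.label
    } else {
      dev <- matrix(stats::rnorm(n_species * 2 * k, 0, species_sd),
                    n_species, 2 * k)
      species_names <- sprintf("sp%02d", seq_len(n_species))
      rownames(dev) <- species_names
    }
    means <- lapply(seq_len(n_species), function(i) {
      X0 + matrix(dev[i, ], k, 2)
    })
    names(means) <- species_names
    coords <- list()
    species <- character(0)
    specimen <- character(0)
    for (i in seq_len(n_species)) {
      for (j in seq_len(n_per_species)) {
        X <- means[[i]] + matrix(stats::rnorm(2 * k, 0, noise), k, 2)
        th <- stats::runif(1, 0, 2 * pi)
        R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
        sc <- exp(stats::rnorm(1, 0, 0.2))
        tr <- stats::rnorm(2, 0, 0.5)
        X <- sweep(sc * X %*% R, 2, tr, "+")
        if (missing_fraction > 0) {
          mask <- which(stats::runif(k) < missing_fraction)
          if (length(mask) > 6) mask <- mask[1:6]
          X[mask, ] <- NA_real_
        }
        coords[[length(coords) + 1L]] <- X
        species <- c(species, species_names[i])
        specimen <- c(specimen, sprintf("%s_%02d", species_names[i], j))
      }
    }
    list(coords = coords, species = species, specimen = specimen,
         species_means = means, template = template,
         curves = template$curves)
  })
}

#' Generate a synthetic linear-measurement table
#'
#' Species mean snout-vent lengths are lognormal; the other six variables
#' follow power-law allometries `coef * SVL^exponent` with lognormal noise;
#' a fraction of non-SVL cells is masked as missing (SVL is never masked:
#' it anchors both size and imputation).
#'
#' @param n_species,n_per_species Table dimensions.
#' @param allometry List with named numeric vectors `coef` and `exponent`
#'   for `TL`, `HL`, `BW`, `SE`, `FLL`, `HLL`.
#' @param noise Lognormal noise sdlog on each measurement (0 = exact
#'   allometry).
#' @param missing_fraction Fraction of maskable cells set to NA.
#' @param seed Integer seed.
#' @return Data frame in the [impute_missing_measurements()] layout.
#' @export
generate_measurement_table <- function(n_species = 30, n_per_species = 8,
                                       allometry = list(
                                         coef = c(TL = 0.9, HL = 0.25,
                                                  BW = 0.15, SE = 0.08,
                                                  FLL = 0.28, HLL = 0.32),
                                         exponent = c(TL = 1, HL = 1,
                                                      BW = 1, SE = 1,
                                                      FLL = 1, HLL = 1)),
                                       noise = 0.05, missing_fraction = 0,
                                       seed = 1) {
  if (any(allometry$coef <= 0)) stop("allometry coefficients must be positive")
  vars <- setdiff(MEASUREMENT_VARS, "SVL")
  with_seed(seed, {
    sp_names <- sprintf("genus%02d_sp%02d",
                        rep(seq_len(max(1, n_species %/% 4)),
                            length.out = n_species),
                        seq_len(n_species))
    sp_svl <- stats::rlnorm(n_species, log(50), 0.4)
    rows <- list()
    for (i in seq_len(n_species)) {
      for (j in seq_len(n_per_species)) {
        svl <- sp_svl[i] * stats::rlnorm(1, 0, noise)
        vals <- allometry$coef[vars] * svl^allometry$exponent[vars] *
          stats::rlnorm(length(vars), 0, noise)
        rows[[length(rows) + 1L]] <- data.frame(
          specimen = sprintf("%s_%02d", sp_names[i], j),
          species = sp_names[i], SVL = svl,
          t(vals), stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    if (missing_fraction > 0) {
      for (v in vars) {
        mask <- stats::runif(nrow(out)) < missing_fraction
        out[[v]][mask] <- NA_real_
      }
    }
    rownames(out) <- NULL
    out
  })
}
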