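# Bayesian stochastic character mapping: joint node states are drawn from
# their conditional distribution given the tips, then each branch path is
# sampled conditioned on its endpoint states by uniformization. Histories
# are piecewise-constant state paths on every edge.

# Endpoint-conditioned CTMC bridge on one branch via uniformization.
# Returns data.frame(state, dwell) whose dwell times sum to t.
.sample_bridge <- function(Q, state_labels, a, b, t, Pt) {
  K <- nrow(Q)
  omega <- max(-diag(Q))
  if (omega <= 0 || t == 0) {
    if (a != b) stop("impossible endpoint pair with zero rates")
    return(data.frame(state = state_labels[a], dwell = t,
                      stringsAsFactors = FALSE))
  }
  p_ab <- Pt[a, b]
  if (p_ab <= 0) stop("endpoint pair has zero transition probability")
  R <- diag(K) + Q / omega
  mu <- omega * t
  # number of dominating-process jumps
  u <- stats::runif(1)
  Rpow <- list(diag(K))
  nj <- -1L
  cum <- 0
  repeat {
    nj <- nj + 1L
    if (nj > 0) Rpow[[nj + 1L]] <- Rpow[[nj]] %*% R
    cum <- cum + stats::dpois(nj, mu) * Rpow[[nj + 1L]][a, b] / p_ab
    if (u <= cum) break
    if (nj > 1e5) stop("uniformization failed to terminate")
  }
  states <- integer(nj + 1L)
  states[1L] <- a
  states[nj + 1L] <- b
  if (nj >= 2L) {
    for (j in 2:nj) {
      w <- R[states[j - 1L], ] * Rpow[[nj - j + 2L]][, b]
      states[j] <- sample.int(K, 1L, prob = w)
    }
  }
  times <- c(0, sort(stats::runif(nj)) * t, t)
  dwell <- diff(times)
  # merge virtual jumps (state unchanged)
  keep_state <- states[1L]
  out_state <- integer(0)
  out_dwell <- numeric(0)
  acc <- 0
  for (j in seq_len(nj + 1L)) {
    if (j > 1L && states[j] != keep_state) {
      out_state <- c(out_state, keep_state)
      out_dwell <- c(out_dwell, acc)
      keep_state <- states[j]
      acc <- 0
    }
    acc <- acc + dwell[j]
  }
  out_state <- c(out_state, keep_state)
  out_dwell <- c(out_dwell, acc)
  data.frame(state = state_labels[out_state], dwell = out_dwell,
             stringsAsFactors = FALSE)
}

# rejection-sampling bridge: forward simulation with endpoint rejection;
# kept as an independent oracle for the uniformization sampler
.sample_bridge_rejection <- function(Q, state_labels, a, b, t,
                                     max_tries = 1e6) {
  K <- nrow(Q)
  for (i in seq_len(max_tries)) {
    s <- a
    tm <- 0
    path_state <- integer(0)
    path_dwell <- numeric(0)
    repeat {
      rate <- -Q[s, s]
      w <- if (rate > 0) stats::rexp(1, rate) else Inf
      d <- min(w, t - tm)
      path_state <- c(path_state, s)
      path_dwell <- c(path_dwell, d)
      tm <- tm + d
      if (tm >= t) break
      pr <- Q[s, ]
      pr[s] <- 0
      s <- sample.int(K, 1L, prob = pr)
    }
    if (s == b) {
      return(data.frame(state = state_labels[path_state], dwell = path_dwell,
                        stringsAsFactors = FALSE))
    }
  }
  stop("rejection sampler exhausted its tries")
}

#' Sample one stochastic character map
#'
#' Draws a complete character history conditioned on the observed tip states
#' and a Q-matrix: internal node states are sampled root-to-tips from their
#' joint conditional distribution, then each branch path is sampled given
#' its endpoint states by uniformization (a dominating Poisson process at
#' the maximum total leave-rate, with virtual jumps removed).
#'
#' @inheritParams mk_log_likelihood
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return An object of class `character_history`: list with `tree`,
#'   `node_states` (state label per node, tips included),
#'   `paths` (per-edge data frames of `(state, dwell)` segments, in
#'   `tree$edge` order, running parent to child), and `states` (labels).
#' @export
sample_history <- function(tree, states, q, root_prior = "flat",
                           seed = NULL) {
  Q <- .check_q(q)
  K <- nrow(Q)
  labels <- rownames(Q)
  x <- .tip_state_ints(tree, states, labels)
  pi <- .resolve_root_prior(root_prior, Q)
  cl <- .mk_conditionals(tree, x, Q)
  if (!is.finite(cl$logscale)) stop("data have zero likelihood under this Q")
  n <- ape::Ntip(tree)
  root <- n + 1L
  with_seed(seed, {
    node_state <- integer(n + tree$Nnode)
    node_state[seq_len(n)] <- x
    w <- pi * cl$cond[root, ]
    if (sum(w) <= 0) stop("data have zero likelihood under this Q")
    node_state[root] <- sample.int(K, 1L, prob = w)
    po <- .postorder(tree)
    ord <- match(
      paste(po$edge[, 1], po$edge[, 2]),
      paste(tree$edge[, 1], tree$edge[, 2])
    )
    # parents before children
    for (e in rev(seq_len(nrow(po$edge)))) {
      ei <- ord[e]
      par <- tree$edge[ei, 1L]
      ch <- tree$edge[ei, 2L]
      if (ch > n) {
        w <- cl$P[[ei]][node_state[par], ] * cl$cond[ch, ]
        node_state[ch] <- sample.int(K, 1L, prob = w)
      }
    }
    paths <- vector("list", nrow(tree$edge))
    for (ei in seq_len(nrow(tree$edge))) {
      par <- tree$edge[ei, 1L]
      ch <- tree$edge[ei, 2L]
      paths[[ei]] <- tryCatch(
        .sample_bridge(Q, labels, node_state[par], node_state[ch],
                       tree$edge.length[ei], cl$P[[ei]]),
        error = function(e) {
          stop("path sampling failed on edge ", par, "->", ch, ": ",
               conditionMessage(e))
        }
      )
    }
    out <- list(tree = tree, node_states = labels[node_state],
                paths = paths, states = labels)
    class(out) <- "character_history"
    out
  })
}

#' Sample many stochastic maps
#'
#' @inheritParams sample_history
#' @param n_maps Number of maps (the study default is 1,000).
#' @param seed Integer seed; map i uses stream `seed + i - 1`.
#' @return List of [sample_history()] results.
#' @export
sample_histories <- function(tree, states, q, n_maps = 1000,
                             root_prior = "flat", seed = 1) {
  lapply(seq_len(n_maps), function(i) {
    sample_history(tree, states, q, root_prior, seed = seed + i - 1L)
  })
}

.check_history <- function(history) {
  if (!inherits(history, "character_history")) {
    stop("not a character_history")
  }
  history
}

#' Count realized state transitions in a character history
#'
#' @param history A [sample_history()] result (or a forward-simulated true
#'   history).
#' @return K x K integer matrix; entry (i, j) is the number of i -> j
#'   changes summed over all edges; the diagonal is zero.
#' @export
count_transitions <- function(history) {
  .check_history(history)
  labels <- history$states
  K <- length(labels)
  counts <- matrix(0L, K, K, dimnames = list(labels, labels))
  for (path in history$paths) {
    s <- match(path$state, labels)
    if (length(s) > 1) {
      for (j in seq_len(length(s) - 1L)) {
        counts[s[j], s[j + 1L]] <- counts[s[j], s[j + 1L]] + 1L
      }
    }
  }
  counts
}

#' Count independent origins of a focal state in a history
#'
#' An origin is a realized change from any other state into the focal state
#' on an edge; gains nested inside an earlier focal clade after a loss count
#' again. A root already in the focal state contributes no origin.
#'
#' @param history A `character_history`.
#' @param focal Focal state label (e.g. `"A"` for arboreality).
#' @return Nonnegative integer count of gains.
#' @export
count_origins <- function(history, focal) {
  .check_history(history)
  if (!(focal %in% history$states)) stop("unknown focal state: ", focal)
  gains <- 0L
  for (path in history$paths) {
    s <- path$state
    if (length(s) > 1) {
      gains <- gains + sum(s[-1] == focal & s[-length(s)] != focal)
    }
  }
  gains
}

# per-edge gain indicator for a focal state, used for origin locations
.edge_gains <- function(history, focal) {
  vapply(history$paths, function(path) {
    s <- path$state
    length(s) > 1 && any(s[-1] == focal & s[-length(s)] != focal)
  }, logical(1))
}

#' Summarize a set of stochastic maps
#'
#' @param histories List of `character_history` objects sampled on the same
#'   tree.
#' @param origin_threshold Edges whose per-state gain frequency across maps
#'   is at least this value are reported as origin locations.
#' @return Object of class `map_summary`: `n_maps`, `node_state_freq`
#'   (nodes x K frequencies; tip rows are the observed indicator vectors),
#'   `mean_transition_counts` (K x K), `mean_origins` (named per-state mean
#'   number of gains), `origin_locations` (data frame of edge, state,
#'   frequency), and `mean_dwell` (per-state mean total dwell time).
#' @export
summarize_maps <- function(histories, origin_threshold = 0.1) {
  if (length(histories) < 1) stop("need at least one history")
  lapply(histories, .check_history)
  tr <- histories[[1]]$tree
  sig <- function(h) {
    paste(ape::Ntip(h$tree), signif(sum(h$tree$edge.length), 12),
          paste(sort(h$tree$tip.label), collapse = ","))
  }
  if (length(unique(vapply(histories, sig, character(1)))) != 1L) {
    stop("histories were sampled on different trees")
  }
  labels <- histories[[1]]$states
  K <- length(labels)
  nn <- ape::Ntip(tr) + tr$Nnode
  freq <- matrix(0, nn, K, dimnames = list(NULL, labels))
  trans <- matrix(0, K, K, dimnames = list(labels, labels))
  origins <- stats::setNames(numeric(K), labels)
  dwell <- stats::setNames(numeric(K), labels)
  gain_freq <- matrix(0, nrow(tr$edge), K, dimnames = list(NULL, labels))
  for (h in histories) {
    si <- match(h$node_states, labels)
    freq[cbind(seq_len(nn), si)] <- freq[cbind(seq_len(nn), si)] + 1
    trans <- trans + count_transitions(h)
    for (s in labels) {
      origins[s] <- origins[s] + count_origins(h, s)
      gain_freq[, s] <- gain_freq[, s] + .edge_gains(h, s)
    }
    for (path in h$paths) {
      agg <- tapply(path$dwell, factor(path$state, levels = labels), sum)
      agg[is.na(agg)] <- 0
      dwell <- dwell + agg
    }
  }
  nm <- length(histories)
  gain_freq <- gain_freq / nm
  loc <- which(gain_freq >= origin_threshold, arr.ind = TRUE)
  origin_locations <- data.frame(
    edge = loc[, 1],
    parent = tr$edge[loc[, 1], 1],
    child = tr$edge[loc[, 1], 2],
    state = labels[loc[, 2]],
    frequency = gain_freq[loc],
    stringsAsFactors = FALSE
  )
  origin_locations <-
    origin_locations[order(-origin_locations$frequency), , drop = FALSE]
  out <- list(n_maps = nm, node_state_freq = freq / nm,
              mean_transition_counts = trans / nm,
              mean_origins = origins / nm,
              origin_locations = origin_locations,
              mean_dwell = dwell / nm, states = labels, tree = tr)
  class(out) <- "map_summary"
  out
}

#' @export
print.map_summary <- function(x, ...) {
  cat("Stochastic mapping summary over", x$n_maps, "maps\n")
  cat("mean transition counts:\n")
  print(round(x$mean_transition_counts, 2))
  cat("mean origins per state:\n")
  print(round(x$mean_origins, 2))
  invisible(x)
}
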