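# Mk models of discrete character evolution: Q-matrix construction, matrix
# exponentials, the Felsenstein pruning likelihood, maximum-likelihood
# fitting under ER/SYM/ARD constraints, AIC model selection, and marginal
# ancestral-state estimation.

#' Construct an instantaneous rate matrix (Q-matrix)
#'
#' Off-diagonal entries q_ij are the instantaneous rates (per unit branch
#' length, Myr for the empirical chronogram) of moving from state i to state
#' j; each diagonal entry is minus its row's off-diagonal sum, so rows sum
#' to zero.
#'
#' @param rates K x K matrix of nonnegative off-diagonal rates (the diagonal
#'   is ignored and recomputed).
#' @param states Character vector of K state labels; defaults to existing
#'   dimnames or ABC labels.
#' @return A K x K matrix of class `q_matrix` with state labels as dimnames.
#' @export
q_matrix <- function(rates, states = NULL) {
  rates <- as.matrix(rates)
  K <- nrow(rates)
  if (ncol(rates) != K) stop("rates must be square")
  if (is.null(states)) {
    states <- if (!is.null(rownames(rates))) rownames(rates) else
      LETTERS[seq_len(K)]
  }
  off <- rates
  diag(off) <- 0
  if (any(off < 0)) stop("off-diagonal rates must be nonnegative")
  Q <- off
  diag(Q) <- -rowSums(off)
  dimnames(Q) <- list(states, states)
  class(Q) <- c("q_matrix", class(Q))
  Q
}

.check_q <- function(q) {
  q <- unclass(as.matrix(q))
  if (nrow(q) != ncol(q)) stop("Q must be square")
  if (max(abs(rowSums(q))) > 1e-8 * max(1, max(abs(q)))) {
    stop("Q rows must sum to zero")
  }
  off <- q
  diag(off) <- 0
  if (any(off < -1e-12)) stop("Q off-diagonals must be nonnegative")
  if (is.null(rownames(q))) {
    dimnames(q) <- list(LETTERS[seq_len(nrow(q))], LETTERS[seq_len(nrow(q))])
  }
  q
}

# scaling-and-squaring series exponential; robust fallback for defective Q
.expm_ss <- function(A) {
  K <- nrow(A)
  nrm <- max(abs(A))
  s <- if (nrm > 0) max(0L, ceiling(log2(nrm)) + 1L) else 0L
  As <- A / 2^s
  P <- diag(K)
  term <- diag(K)
  for (k in seq_len(40L)) {
    term <- term %*% As / k
    P <- P + term
    if (max(abs(term)) < 1e-17) break
  }
  for (i in seq_len(s)) P <- P %*% P
  P
}

# Returns function(t) -> P(t) = exp(Q t), precomputing the eigendecomposition
# once; falls back to series exponentials when Q is (nearly) defective.
.make_propagator <- function(Q) {
  Q <- unclass(as.matrix(Q))
  K <- nrow(Q)
  eg <- tryCatch(eigen(Q), error = function(e) NULL)
  Vi <- NULL
  if (!is.null(eg)) {
    Vi <- tryCatch(solve(eg$vectors), error = function(e) NULL)
    if (!is.null(Vi)) {
      err <- max(abs(Re(eg$vectors %*% (eg$values * Vi)) - Q))
      if (!is.finite(err) || err > 1e-9 * max(1, max(abs(Q)))) Vi <- NULL
    }
  }
  if (is.null(Vi)) {
    return(function(t) {
      if (t == 0) return(diag(K))
      P <- .expm_ss(Q * t)
      P[P < 0] <- 0
      P / rowSums(P)
    })
  }
  V <- eg$vectors
  lam <- eg$values
  function(t) {
    if (t == 0) return(diag(K))
    P <- Re(V %*% (exp(lam * t) * Vi))
    P[P < 0] <- 0
    P / rowSums(P)
  }
}

#' Transition probabilities of the Mk chain over a time interval
#'
#' Computes P(t) = exp(Qt), the matrix of probabilities of ending in state j
#' after time t given a start in state i.
#'
#' @param q A Q-matrix (see [q_matrix()]).
#' @param t Nonnegative duration.
#' @return A K x K row-stochastic matrix.
#' @export
transition_probability <- function(q, t) {
  if (t < 0) stop("t must be nonnegative")
  Q <- .check_q(q)
  P <- .make_propagator(Q)(t)
  dimnames(P) <- dimnames(Q)
  P
}

# Resolve tip states against the Q-matrix state set; returns integer vector
# ordered by tree tip.
.tip_state_ints <- function(tree, states, state_labels) {
  sv <- .states_vector(states)
  missing <- setdiff(tree$tip.label, names(sv))
  if (length(missing) > 0) {
    stop("tips missing from states table: ", paste(missing, collapse = ", "))
  }
  sv <- sv[tree$tip.label]
  unknown <- setdiff(unique(sv), state_labels)
  if (length(unknown) > 0) {
    stop("tip states not in Q state set: ", paste(unknown, collapse = ", "))
  }
  match(sv, state_labels)
}

.resolve_root_prior <- function(root_prior, Q) {
  K <- nrow(Q)
  if (is.character(root_prior)) {
    root_prior <- match.arg(root_prior, c("flat", "stationary"))
    if (root_prior == "flat") return(rep(1 / K, K))
    ns <- eigen(t(Q))
    i <- which.min(abs(ns$values))
    pi <- Re(ns$vectors[, i])
    pi <- abs(pi) / sum(abs(pi))
    return(pi)
  }
  if (length(root_prior) != K) stop("root prior has wrong length")
  if (any(root_prior < 0) || sum(root_prior) <= 0) stop("invalid root prior")
  root_prior / sum(root_prior)
}

# Post-order conditional likelihoods. Returns list(cond = (n+m) x K matrix of
# rescaled conditionals, logscale = accumulated log scaling constant,
# P = per-edge transition matrices in tree$edge order).
.mk_conditionals <- function(tree, x, Q) {
  n <- ape::Ntip(tree)
  K <- nrow(Q)
  prop <- .make_propagator(Q)
  cond <- matrix(1, n + tree$Nnode, K)
  cond[seq_len(n), ] <- 0
  cond[cbind(seq_len(n), x)] <- 1
  po <- .postorder(tree)
  ord <- match(
    paste(po$edge[, 1], po$edge[, 2]),
    paste(tree$edge[, 1], tree$edge[, 2])
  )
  P <- vector("list", nrow(tree$edge))
  logscale <- 0
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1L]
    ch <- po$edge[e, 2L]
    Pe <- prop(po$edge.length[e])
    P[[ord[e]]] <- Pe
    msg <- as.vector(Pe %*% cond[ch, ])
    sc <- max(msg)
    if (sc <= 0 || !is.finite(sc)) {
      return(list(cond = cond, logscale = -Inf, P = P))
    }
    cond[par, ] <- cond[par, ] * (msg / sc)
    logscale <- logscale + log(sc)
  }
  list(cond = cond, logscale = logscale, P = P)
}

#' Log-likelihood of tip states under an Mk model
#'
#' Felsenstein's pruning algorithm: post-order conditional likelihoods with
#' per-branch transition probabilities, weighted at the root by the root
#' state prior.
#'
#' @param tree A validated `phylo` object.
#' @param states A `scheme_assignment` or named character vector of tip
#'   states.
#' @param q Q-matrix whose state labels cover the observed states.
#' @param root_prior `"flat"` (default), `"stationary"`, or a length-K
#'   probability vector.
#' @return The log-likelihood (scalar).
#' @export
mk_log_likelihood <- function(tree, states, q, root_prior = "flat") {
  Q <- .check_q(q)
  x <- .tip_state_ints(tree, states, rownames(Q))
  pi <- .resolve_root_prior(root_prior, Q)
  cl <- .mk_conditionals(tree, x, Q)
  if (!is.finite(cl$logscale)) return(-Inf)
  root <- ape::Ntip(tree) + 1L
  lik <- sum(pi * cl$cond[root, ])
  if (lik <= 0) return(-Inf)
  log(lik) + cl$logscale
}

# Map of free-parameter indices for the off-diagonal of Q under each model.
.model_index <- function(K, model) {
  idx <- matrix(0L, K, K)
  if (model == "ER") {
    idx[row(idx) != col(idx)] <- 1L
  } else if (model == "SYM") {
    p <- 0L
    for (i in seq_len(K - 1)) {
      for (j in (i + 1):K) {
        p <- p + 1L
        idx[i, j] <- p
        idx[j, i] <- p
      }
    }
  } else if (model == "ARD") {
    p <- 0L
    for (i in seq_len(K)) {
      for (j in seq_len(K)) {
        if (i != j) {
          p <- p + 1L
          idx[i, j] <- p
        }
      }
    }
  } else {
    stop("unknown model: ", model)
  }
  idx
}

.q_from_pars <- function(rates, idx, states) {
  K <- nrow(idx)
  off <- matrix(0, K, K)
  off[idx > 0] <- rates[idx[idx > 0]]
  q_matrix(off, states)
}

# lightweight signature tying a fit to its data, for select_model()
.data_signature <- function(tree, sv) {
  paste(length(sv), signif(sum(tree$edge.length), 12),
        paste(sv[order(names(sv))], collapse = ""),
        sep = "|")
}

#' Fit an Mk model by maximum likelihood
#'
#' Maximizes the pruning log-likelihood over the free transition rates of
#' the chosen model (ER: one shared rate; SYM: one rate per unordered state
#' pair; ARD: all K(K-1) rates free) by bounded quasi-Newton optimization on
#' log-rates, with multiple random restarts drawn log-uniformly around a
#' parsimony-flavoured initial guess. Rates are bounded in
#' `rate_bounds` (default [1e-9, 1e3] per Myr); estimates at the lower bound
#' print as 0 at four decimals.
#'
#' @inheritParams mk_log_likelihood
#' @param model `"ER"`, `"SYM"` or `"ARD"`.
#' @param n_starts Number of optimization starts (first is deterministic).
#' @param seed Seed for the random restarts.
#' @param rate_bounds Length-2 vector of rate bounds.
#' @param tol Convergence tolerance on the log-likelihood.
#' @return An object of class `mk_fit`: list with `model`, `q` (the fitted
#'   [q_matrix()]), `lnL`, `k` (free parameters), `aic`, `root_prior`,
#'   `states`, `convergence` and `starts` diagnostics.
#' @export
fit_mk <- function(tree, states, model = c("ER", "SYM", "ARD"),
                   root_prior = "flat", n_starts = 10, seed = 1,
                   rate_bounds = c(1e-9, 1e3), tol = 1e-8) {
  model <- match.arg(model)
  validate_phylogeny(tree, warn_nonultrametric = FALSE)
  sv <- .states_vector(states)
  missing <- setdiff(tree$tip.label, names(sv))
  if (length(missing) > 0) {
    stop("tips missing from states table: ", paste(missing, collapse = ", "))
  }
  sv <- sv[tree$tip.label]
  state_set <- sort(unique(sv))
  if (length(state_set) < 2) {
    stop("need at least 2 observed states among tips")
  }
  K <- length(state_set)
  x <- match(sv, state_set)
  idx <- .model_index(K, model)
  npar <- max(idx)
  lb <- log(rate_bounds[1])
  ub <- log(rate_bounds[2])

  negll <- function(logr) {
    Q <- .q_from_pars(exp(logr), idx, state_set)
    pi <- .resolve_root_prior(root_prior, unclass(Q))
    cl <- .mk_conditionals(tree, x, unclass(Q))
    if (!is.finite(cl$logscale)) return(1e10)
    lik <- sum(pi * cl$cond[ape::Ntip(tree) + 1L, ])
    if (lik <= 0 || !is.finite(lik)) return(1e10)
    -(log(lik) + cl$logscale)
  }

  # initial guess: one expected change per edge carrying a state difference,
  # spread over the total tree length
  height <- max(.node_depths(tree))
  q0 <- max(rate_bounds[1] * 10, 0.5 / height)
  starts <- with_seed(seed, {
    s <- list(rep(log(q0), npar))
    if (n_starts > 1) {
      for (i in seq_len(n_starts - 1)) {
        s[[i + 1]] <- log(q0) + log(10) * stats::runif(npar, -2, 2)
      }
    }
    s
  })
  starts <- lapply(starts, function(p) pmin(pmax(p, lb), ub))

  # place each start at the best overall rate magnitude first: a coarse
  # line scan over a global scaling of Q avoids the flat saturated region
  # at high rates, where quasi-Newton steps stall
  scan <- log(10) * seq(-3, 3, by = 0.5)
  starts <- lapply(starts, function(p) {
    vals <- vapply(scan, function(s) negll(pmin(pmax(p + s, lb), ub)),
                   numeric(1))
    pmin(pmax(p + scan[which.min(vals)], lb), ub)
  })

  best <- NULL
  diag_tab <- data.frame(start = seq_along(starts), value = NA_real_,
                         convergence = NA_integer_)
  for (i in seq_along(starts)) {
    opt <- tryCatch(
      stats::optim(starts[[i]], negll, method = "L-BFGS-B",
                   lower = lb, upper = ub,
                   control = list(factr = tol / .Machine$double.eps,
                                  maxit = 500)),
      error = function(e) NULL
    )
    if (is.null(opt)) next
    diag_tab$value[i] <- opt$value
    diag_tab$convergence[i] <- opt$convergence
    if (is.null(best) || opt$value < best$value - 1e-12) best <- opt
  }
  if (is.null(best) || !any(diag_tab$convergence %in% 0L)) {
    cond <- simpleError("Mk optimization failed to converge in all restarts")
    cond$best <- best
    cond$diagnostics <- diag_tab
    stop(cond)
  }
  Q <- .q_from_pars(exp(best$par), idx, state_set)
  lnL <- -best$value
  pi <- .resolve_root_prior(root_prior, unclass(Q))
  fit <- list(model = model, q = Q, lnL = lnL, k = npar,
              aic = -2 * lnL + 2 * npar,
              root_prior = pi, states = state_set,
              convergence = best$convergence, starts = diag_tab,
              data_signature = .data_signature(tree, sv))
  class(fit) <- "mk_fit"
  fit
}

#' @export
print.mk_fit <- function(x, ...) {
  cat("Mk model fit (", x$model, "), K = ", length(x$states),
      " states\n", sep = "")
  cat("  lnL = ", format(x$lnL, digits = 6), ", k = ", x$k,
      ", AIC = ", format(x$aic, digits = 6), "\n", sep = "")
  cat("  rates (per unit branch length; lower-bound estimates shown as 0):\n")
  Qp <- round(unclass(x$q), 4)
  print(Qp)
  invisible(x)
}

#' Compare fitted Mk models by AIC
#'
#' @param fits List of [fit_mk()] results fitted to the same tree and tip
#'   states.
#' @return An object of class `model_comparison`: `fits`, `best` (the model
#'   name with minimal AIC, ties broken toward fewer parameters),
#'   `delta_aic` (named vector), and `table`.
#' @export
select_model <- function(fits) {
  if (length(fits) < 2) stop("need at least 2 fits")
  sigs <- vapply(fits, function(f) f$data_signature, character(1))
  if (length(unique(sigs)) != 1L) {
    stop("fits were made on different data")
  }
  aic <- vapply(fits, function(f) f$aic, numeric(1))
  k <- vapply(fits, function(f) f$k, numeric(1))
  models <- vapply(fits, function(f) f$model, character(1))
  ord <- order(aic, k)
  best <- ord[1]
  delta <- aic - aic[best]
  names(delta) <- models
  out <- list(fits = fits, best = models[best], delta_aic = delta,
              table = data.frame(model = models, k = k,
                                 lnL = vapply(fits, function(f) f$lnL,
                                              numeric(1)),
                                 aic = aic, delta_aic = delta))
  class(out) <- "model_comparison"
  out
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Mk model comparison (best: ", x$best, ")\n", sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Marginal ancestral-state probabilities under an Mk model
#'
#' For every internal node, the marginal posterior probability of each state
#' given all tip states, computed by combining post-order (below-node) and
#' pre-order (above-node) messages. At the root this is the normalized
#' product of the root conditional likelihoods and the root prior.
#'
#' @inheritParams mk_log_likelihood
#' @return Matrix (internal nodes x K) of probabilities, rows summing to 1;
#'   rownames are ape node numbers.
#' @export
marginal_ancestral_states <- function(tree, states, q, root_prior = "flat") {
  Q <- .check_q(q)
  K <- nrow(Q)
  x <- .tip_state_ints(tree, states, rownames(Q))
  pi <- .resolve_root_prior(root_prior, Q)
  cl <- .mk_conditionals(tree, x, Q)
  if (!is.finite(cl$logscale)) stop("data have zero likelihood under this Q")
  n <- ape::Ntip(tree)
  m <- tree$Nnode
  root <- n + 1L

  # children edges per internal node, in tree$edge indexing
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  above <- matrix(NA_real_, n + m, K)
  above[root, ] <- pi
  marg <- matrix(NA_real_, m, K,
                 dimnames = list(as.character((n + 1L):(n + m)),
                                 rownames(Q)))
  marg[1, ] <- pi * cl$cond[root, ]
  marg[1, ] <- marg[1, ] / sum(marg[1, ])

  # pre-order traversal: reverse postorder visits parents before children
  po <- .postorder(tree)
  ord <- match(
    paste(po$edge[, 1], po$edge[, 2]),
    paste(tree$edge[, 1], tree$edge[, 2])
  )
  for (e in rev(seq_len(nrow(po$edge)))) {
    ei <- ord[e]
    par <- tree$edge[ei, 1L]
    ch <- tree$edge[ei, 2L]
    sib_edges <- setdiff(kids[[as.character(par)]], ei)
    others <- rep(1, K)
    for (se in sib_edges) {
      others <- others * as.vector(cl$P[[se]] %*% cl$cond[tree$edge[se, 2L], ])
    }
    a <- as.vector(crossprod(cl$P[[ei]], above[par, ] * others))
    s <- sum(a)
    if (s > 0) a <- a / s
    above[ch, ] <- a
    if (ch > n) {
      v <- a * cl$cond[ch, ]
      marg[ch - n, ] <- v / sum(v)
    }
  }
  marg
}
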