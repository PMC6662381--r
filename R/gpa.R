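# Generalized Procrustes analysis with optional bending-energy sliding of
# semilandmarks, plus pairwise Procrustes distances and two-stage species
# mean shapes.

.centroid_size <- function(X) {
  c0 <- colMeans(X)
  sqrt(sum(sweep(X, 2, c0)^2))
}

.center_scale <- function(X) {
  X <- sweep(X, 2, colMeans(X))
  X / sqrt(sum(X^2))
}

# Orthogonal least-squares rotation (reflection allowed) of X onto C.
.opa_rotate <- function(X, C) {
  s <- svd(crossprod(X, C))
  X %*% (s$u %*% t(s$v))
}

.as_coord_array <- function(coords) {
  if (is.list(coords) && !is.array(coords)) {
    k <- nrow(coords[[1]])
    arr <- array(NA_real_, c(k, 2, length(coords)),
                 dimnames = list(NULL, NULL, names(coords)))
    for (i in seq_along(coords)) arr[, , i] <- as.matrix(coords[[i]])
    arr
  } else if (is.array(coords) && length(dim(coords)) == 3) {
    coords
  } else {
    stop("coords must be a k x 2 x n array or a list of k x 2 matrices")
  }
}

# One bending-energy sliding pass of a single configuration against the
# consensus. curves is an m x 3 matrix (anterior, semilandmark, posterior);
# B is the consensus bending-energy matrix. Returns the slid configuration.
.slide_one <- function(X, consensus, curves, B) {
  k <- nrow(X)
  m <- nrow(curves)
  Ux <- matrix(0, k, m)
  Uy <- matrix(0, k, m)
  for (j in seq_len(m)) {
    u <- X[curves[j, 3], ] - X[curves[j, 1], ]
    nu <- sqrt(sum(u^2))
    if (nu == 0) next
    u <- u / nu
    Ux[curves[j, 2], j] <- u[1]
    Uy[curves[j, 2], j] <- u[2]
  }
  vx <- X[, 1] - consensus[, 1]
  vy <- X[, 2] - consensus[, 2]
  M <- crossprod(Ux, B %*% Ux) + crossprod(Uy, B %*% Uy)
  rhs <- crossprod(Ux, B %*% vx) + crossprod(Uy, B %*% vy)
  tj <- tryCatch(-solve(M + diag(1e-12, m), rhs),
                 error = function(e) matrix(0, m, 1))
  X + cbind(Ux %*% tj, Uy %*% tj)
}

#' Generalized Procrustes analysis
#'
#' Iteratively centers each configuration, scales it to unit centroid size,
#' and rotates it onto the current consensus by orthogonal least squares
#' (reflections are allowed, which also corrects mirror-digitized
#' specimens). With `slide = TRUE`, a fixed number of sliding passes
#' follows the initial superimposition: each pass slides every semilandmark
#' along the chord between its bracketing neighbours so as to minimize the
#' thin-plate-spline bending energy against the current consensus (an exact
#' quadratic minimization, so energy never increases within a pass), then
#' re-superimposes to convergence. Alignment stops when the consensus moves
#' by less than `tol` (root summed squared change).
#'
#' @param coords k x 2 x n array or list of n complete k x 2 configurations.
#' @param slide Slide semilandmarks? Requires `curves`.
#' @param curves m x 3 integer matrix: each row (anterior neighbour,
#'   semilandmark, posterior neighbour) defines one sliding point and its
#'   tangent chord.
#' @param tol Convergence tolerance on the consensus.
#' @param max_iter Iteration cap per alignment; exceeding it is an error
#'   whose condition carries the convergence trace.
#' @param slide_passes Number of slide-then-realign passes when sliding.
#' @return Object of class `gpa_result`: `coords` (aligned k x 2 x n array,
#'   centroid at the origin and unit centroid size), `centroid_sizes`
#'   (original sizes), `consensus` (the coordinate-wise mean shape),
#'   `iterations`, and `bending_trace` (per-iteration total bending energy
#'   before and after sliding, when sliding).
#' @export
gpa <- function(coords, slide = FALSE, curves = NULL, tol = 1e-8,
                max_iter = 100, slide_passes = 3) {
  arr <- .as_coord_array(coords)
  if (anyNA(arr)) stop("configurations must be complete; interpolate first")
  n <- dim(arr)[3]
  if (n < 2) stop("need at least 2 configurations")
  if (slide && (is.null(curves) || nrow(curves) == 0)) {
    stop("slide = TRUE requires a curves matrix")
  }
  cs <- apply(arr, 3, .centroid_size)
  for (i in seq_len(n)) arr[, , i] <- .center_scale(arr[, , i])
  consensus <- .center_scale(arr[, , 1])

  # iterative superimposition against the running consensus
  align <- function(arr, consensus) {
    for (it in seq_len(max_iter)) {
      for (i in seq_len(n)) arr[, , i] <- .opa_rotate(arr[, , i], consensus)
      new_consensus <- .center_scale(apply(arr, c(1, 2), mean))
      delta <- sqrt(sum((new_consensus - consensus)^2))
      consensus <- new_consensus
      if (delta < tol) {
        return(list(arr = arr, consensus = consensus, iterations = it))
      }
    }
    cond <- simpleError(paste0("GPA did not converge in ", max_iter,
                               " iterations"))
    cond$trace <- consensus
    stop(cond)
  }

  st <- align(arr, consensus)
  iterations <- st$iterations
  bending_trace <- NULL
  if (slide) {
    for (pass in seq_len(slide_passes)) {
      B <- bending_energy_matrix(st$consensus)
      be <- function(a) {
        sum(vapply(seq_len(n), function(i) {
          v <- a[, , i] - st$consensus
          sum(diag(crossprod(v, B %*% v)))
        }, numeric(1)))
      }
      be_before <- be(st$arr)
      for (i in seq_len(n)) {
        st$arr[, , i] <- .slide_one(st$arr[, , i], st$consensus, curves, B)
      }
      be_after <- be(st$arr)
      bending_trace <- rbind(bending_trace,
                             c(pass = pass, before = be_before,
                               after = be_after))
      for (i in seq_len(n)) st$arr[, , i] <- .center_scale(st$arr[, , i])
      st <- align(st$arr, st$consensus)
      iterations <- iterations + st$iterations
    }
  }
  out <- list(coords = st$arr, centroid_sizes = cs,
              consensus = st$consensus, iterations = iterations,
              bending_trace = bending_trace)
  class(out) <- "gpa_result"
  out
}

#' Pairwise (partial) Procrustes distance between two configurations
#'
#' Both configurations are centered, scaled to unit centroid size, and one
#' is rotated onto the other; the distance is the square root of the summed
#' squared coordinate differences.
#'
#' @param X1,X2 k x 2 configurations.
#' @return Nonnegative scalar.
#' @export
procrustes_distance <- function(X1, X2) {
  A <- .center_scale(as.matrix(X1))
  Bm <- .center_scale(as.matrix(X2))
  A <- .opa_rotate(A, Bm)
  sqrt(sum((A - Bm)^2))
}

#' Species mean shapes by two-stage Procrustes alignment
#'
#' Specimens are first aligned within species (single specimens are simply
#' centered and scaled); the per-species consensus shapes are then aligned
#' across species with a second GPA. The per-species mean centroid size is
#' retained for allometric analyses.
#'
#' @param coords k x 2 x n array or list of specimen configurations.
#' @param species Character vector (length n) mapping specimens to species.
#' @param slide,curves Passed to the across-species [gpa()] (and to the
#'   within-species stage when a species has 2+ specimens).
#' @return List with `coords` (k x 2 x n_species aligned species means),
#'   `mean_centroid_size` (named vector), `species`, and `gpa` (the
#'   across-species `gpa_result`).
#' @export
species_mean_shapes <- function(coords, species, slide = FALSE,
                                curves = NULL) {
  arr <- .as_coord_array(coords)
  species <- as.character(species)
  if (length(species) != dim(arr)[3]) {
    stop("species vector length must match specimen count")
  }
  sp_levels <- sort(unique(species))
  k <- dim(arr)[1]
  means <- array(NA_real_, c(k, 2, length(sp_levels)),
                 dimnames = list(NULL, NULL, sp_levels))
  mcs <- stats::setNames(numeric(length(sp_levels)), sp_levels)
  for (s in sp_levels) {
    idx <- which(species == s)
    mcs[s] <- mean(apply(arr[, , idx, drop = FALSE], 3, .centroid_size))
    if (length(idx) == 1) {
      means[, , s] <- .center_scale(arr[, , idx])
    } else {
      g <- gpa(arr[, , idx, drop = FALSE], slide = slide, curves = curves)
      means[, , s] <- g$consensus
    }
  }
  g2 <- gpa(means, slide = slide, curves = curves)
  list(coords = g2$coords, mean_centroid_size = mcs, species = sp_levels,
       gpa = g2)
}

#' Flatten aligned configurations into a species-by-coordinates matrix
#'
#' @param coords k x 2 x n array of aligned configurations.
#' @return n x 2k matrix (x1, y1, x2, y2, ...) with specimen dimnames.
#' @export
flatten_shapes <- function(coords) {
  arr <- .as_coord_array(coords)
  n <- dim(arr)[3]
  k <- dim(arr)[1]
  out <- t(vapply(seq_len(n), function(i) as.vector(t(arr[, , i])),
                  numeric(2 * k)))
  rownames(out) <- dimnames(arr)[[3]]
  colnames(out) <- paste0(rep(c("x", "y"), k), rep(seq_len(k), each = 2))
  out
}
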