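# Thin-plate splines and the TPS landmark file dialect. The spline is the
# 2D biharmonic interpolant with kernel U(r) = r^2 log(r^2); its bending
# energy matrix (the upper-left block of the inverse TPS system) is also the
# quadratic form minimized when sliding semilandmarks.

.tps_kernel <- function(r2) {
  out <- numeric(length(r2))
  pos <- r2 > 0
  out[pos] <- r2[pos] * log(r2[pos])
  out
}

.tps_K <- function(P, Q2 = P) {
  # kernel matrix between point sets P (k x 2) and Q2 (m x 2)
  d2 <- outer(P[, 1], Q2[, 1], "-")^2 + outer(P[, 2], Q2[, 2], "-")^2
  matrix(.tps_kernel(d2), nrow(P), nrow(Q2))
}

# Full TPS system matrix L = [[K, P1],[t(P1), 0]] for reference points ref.
.tps_L <- function(ref) {
  k <- nrow(ref)
  K <- .tps_K(ref)
  P1 <- cbind(1, ref)
  rbind(cbind(K, P1), cbind(t(P1), matrix(0, 3, 3)))
}

#' Fit a thin-plate spline mapping one point set onto another
#'
#' @param ref k x 2 matrix of reference (source) points.
#' @param target k x 2 matrix of corresponding target points.
#' @return A spline object (list of coefficients) for [tps_evaluate()].
#' @export
tps_spline <- function(ref, target) {
  ref <- as.matrix(ref)
  target <- as.matrix(target)
  if (nrow(ref) != nrow(target)) stop("point counts differ")
  if (nrow(ref) < 3) stop("need at least 3 points")
  if (qr(scale(ref, scale = FALSE))$rank < 2) {
    stop("reference points are collinear")
  }
  L <- .tps_L(ref)
  rhs <- rbind(target, matrix(0, 3, 2))
  coef <- tryCatch(solve(L, rhs),
                   error = function(e) stop("degenerate TPS system: ",
                                            conditionMessage(e)))
  structure(list(ref = ref, coef = coef), class = "tps_spline")
}

#' Evaluate a thin-plate spline at new points
#'
#' @param spline A [tps_spline()] object.
#' @param points m x 2 matrix of points in the reference frame.
#' @return m x 2 matrix of mapped points.
#' @export
tps_evaluate <- function(spline, points) {
  points <- matrix(as.numeric(points), ncol = 2)
  k <- nrow(spline$ref)
  Kx <- .tps_K(points, spline$ref)
  cbind(Kx, 1, points) %*% spline$coef
}

#' Bending energy matrix of a reference configuration
#'
#' The upper-left k x k block of the inverse TPS system matrix; the bending
#' energy of a displacement field h at the reference landmarks is t(h) B h
#' per coordinate. Its null space is the affine transformations.
#'
#' @param ref k x 2 reference configuration.
#' @return k x k symmetric positive semi-definite matrix.
#' @export
bending_energy_matrix <- function(ref) {
  ref <- as.matrix(ref)
  Li <- solve(.tps_L(ref))
  B <- Li[seq_len(nrow(ref)), seq_len(nrow(ref)), drop = FALSE]
  (B + t(B)) / 2
}

#' Total bending energy of a configuration relative to a reference
#'
#' @param X k x 2 configuration.
#' @param ref k x 2 reference whose bending energy matrix is used.
#' @return Nonnegative scalar (x and y energies summed).
#' @export
bending_energy <- function(X, ref) {
  B <- bending_energy_matrix(ref)
  v <- as.matrix(X) - as.matrix(ref)
  sum(diag(t(v) %*% B %*% v))
}

#' Complete a landmark configuration by thin-plate spline interpolation
#'
#' Estimates missing landmarks from a complete reference configuration
#' (a conspecific consensus, or a sister-species consensus when no complete
#' conspecific exists): a spline is fitted from the reference to the target
#' on the shared (present) points and the missing points are the spline
#' images of the corresponding reference points. Present points are
#' untouched.
#'
#' @param config k x 2 matrix with NA rows at missing landmarks.
#' @param reference Complete k x 2 reference configuration.
#' @return The completed k x 2 matrix, with attribute `interpolated` giving
#'   the filled row indices.
#' @export
interpolate_missing_landmarks <- function(config, reference) {
  config <- as.matrix(config)
  reference <- as.matrix(reference)
  if (anyNA(reference)) stop("reference must be complete")
  if (nrow(config) != nrow(reference)) stop("landmark counts differ")
  mis <- which(apply(config, 1, anyNA))
  if (length(mis) == 0) {
    attr(config, "interpolated") <- integer(0)
    return(config)
  }
  shared <- setdiff(seq_len(nrow(config)), mis)
  if (length(shared) < 3) stop("fewer than 3 shared landmarks")
  sp <- tps_spline(reference[shared, , drop = FALSE],
                   config[shared, , drop = FALSE])
  config[mis, ] <- tps_evaluate(sp, reference[mis, , drop = FALSE])
  attr(config, "interpolated") <- mis
  config
}

#' Read landmark configurations from a TPS file
#'
#' Supports the standard `LM=`, `IMAGE=`, `ID=`, and `SCALE=` records
#' (coordinates are multiplied by SCALE when present). Missing landmarks may
#' be encoded as `NA NA` or with the `-999` sentinel; both become NA rows.
#'
#' @param path Path to a TPS file.
#' @return List with `coords` (list of k x 2 matrices), `id`, `image`
#'   (character vectors).
#' @export
read_tps <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  coords <- list()
  ids <- character(0)
  images <- character(0)
  i <- 1L
  while (i <= length(lines)) {
    if (!grepl("^LM=", lines[i], ignore.case = TRUE)) {
      stop("TPS parse error at line ", i, ": expected LM= record")
    }
    k <- as.integer(sub("^LM=", "", lines[i], ignore.case = TRUE))
    X <- matrix(NA_real_, k, 2)
    for (j in seq_len(k)) {
      parts <- strsplit(lines[i + j], "[[:space:]]+")[[1]]
      X[j, ] <- suppressWarnings(as.numeric(parts[1:2]))
    }
    i <- i + k + 1L
    id <- NA_character_
    image <- NA_character_
    scale <- 1
    while (i <= length(lines) && !grepl("^LM=", lines[i],
                                        ignore.case = TRUE)) {
      if (grepl("^IMAGE=", lines[i], ignore.case = TRUE)) {
        image <- sub("^IMAGE=", "", lines[i], ignore.case = TRUE)
      } else if (grepl("^ID=", lines[i], ignore.case = TRUE)) {
        id <- sub("^ID=", "", lines[i], ignore.case = TRUE)
      } else if (grepl("^SCALE=", lines[i], ignore.case = TRUE)) {
        scale <- as.numeric(sub("^SCALE=", "", lines[i], ignore.case = TRUE))
      }
      i <- i + 1L
    }
    X[X == -999] <- NA_real_
    X <- X * scale
    coords[[length(coords) + 1L]] <- X
    ids <- c(ids, id)
    images <- c(images, image)
  }
  list(coords = coords, id = ids, image = images)
}

#' Write landmark configurations to a TPS file
#'
#' @param coords List of k x 2 matrices (NA rows allowed for missing
#'   landmarks).
#' @param path Output path.
#' @param id,image Optional per-configuration identifier vectors.
#' @return `path`, invisibly.
#' @export
write_tps <- function(coords, path, id = NULL, image = NULL) {
  if (is.array(coords) && length(dim(coords)) == 3) {
    coords <- lapply(seq_len(dim(coords)[3]), function(i) coords[, , i])
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(coords)) {
    X <- coords[[i]]
    writeLines(paste0("LM=", nrow(X)), con)
    for (j in seq_len(nrow(X))) {
      writeLines(paste(format(X[j, 1], digits = 15),
                       format(X[j, 2], digits = 15)), con)
    }
    if (!is.null(image)) writeLines(paste0("IMAGE=", image[i]), con)
    writeLines(paste0("ID=", if (is.null(id)) i else id[i]), con)
  }
  invisible(path)
}
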