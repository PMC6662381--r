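# Linear body measurements: regression imputation of missing values and
# species-level log Mosimann shape ratios (each variable divided by
# snout-vent length, then natural-log transformed).

MEASUREMENT_VARS <- c("SVL", "TL", "HL", "BW", "SE", "FLL", "HLL")

.check_measurements <- function(specimens) {
  specimens <- as.data.frame(specimens)
  need <- c("specimen", "species", MEASUREMENT_VARS)
  miss <- setdiff(need, names(specimens))
  if (length(miss) > 0) {
    stop("measurement table is missing columns: ",
         paste(miss, collapse = ", "))
  }
  vals <- as.matrix(specimens[, MEASUREMENT_VARS])
  if (any(vals[!is.na(vals)] <= 0)) {
    stop("all present measurements must be positive")
  }
  specimens
}

.genus_of <- function(species) sub("_.*$", "", species)

# Pick the narrowest pool of complete-case rows sharing taxonomy with the
# target specimen: conspecifics, then congeners, then everything. A pool is
# usable once it has more complete rows than observed predictors + 1.
.imputation_pool <- function(specimens, complete, i, n_obs) {
  sp <- specimens$species[i]
  cand <- which(complete & specimens$species == sp)
  if (length(cand) > n_obs + 1) return(cand)
  gn <- .genus_of(sp)
  cand <- which(complete & .genus_of(specimens$species) == gn)
  if (length(cand) > n_obs + 1) return(cand)
  which(complete)
}

#' Impute missing linear measurements by multivariate regression
#'
#' Missing entries are predicted, on the natural-log scale, from a
#' least-squares regression of the missing variables on the specimen's
#' observed variables, fitted over complete cases drawn from the narrowest
#' available taxonomic pool (conspecifics, else congeners, else the whole
#' table). Observed values are never modified and the procedure is fully
#' deterministic.
#'
#' @param specimens Data frame with columns `specimen`, `species`, and the
#'   seven measurements `SVL`, `TL`, `HL`, `BW`, `SE`, `FLL`, `HLL` (mm; NA
#'   where missing).
#' @return The completed data frame, with attribute `n_imputed` giving the
#'   number of filled cells.
#' @export
impute_missing_measurements <- function(specimens) {
  specimens <- .check_measurements(specimens)
  vals <- as.matrix(specimens[, MEASUREMENT_VARS])
  all_missing <- rowSums(!is.na(vals)) == 0
  if (any(all_missing)) {
    stop("specimens with all measurements missing: ",
         paste(specimens$specimen[all_missing], collapse = ", "))
  }
  complete <- rowSums(is.na(vals)) == 0
  if (!any(complete)) stop("no complete-case specimens to regress on")
  logv <- log(vals)
  n_imputed <- 0L
  for (i in which(!complete)) {
    obs <- which(!is.na(vals[i, ]))
    mis <- which(is.na(vals[i, ]))
    pool <- .imputation_pool(specimens, complete, i, length(obs))
    X <- logv[pool, obs, drop = FALSE]
    Y <- logv[pool, mis, drop = FALSE]
    fit <- stats::lm.fit(cbind(1, X), Y)
    pred <- c(1, logv[i, obs]) %*% ifelse(is.na(fit$coefficients), 0,
                                          fit$coefficients)
    vals[i, mis] <- exp(pred)
    n_imputed <- n_imputed + length(mis)
  }
  specimens[, MEASUREMENT_VARS] <- vals
  attr(specimens, "n_imputed") <- n_imputed
  specimens
}

#' Species-level log Mosimann shape ratios
#'
#' Averages each measurement within species, divides the means by mean
#' snout-vent length (SVL), and natural-log transforms, yielding six
#' size-free body-proportion variables per species.
#'
#' @param specimens Completed measurement table (no NA), as returned by
#'   [impute_missing_measurements()].
#' @return Matrix (species x 6) of log shape ratios with columns
#'   `TL`, `HL`, `BW`, `SE`, `FLL`, `HLL`; attribute `mean_svl` holds the
#'   per-species mean SVL.
#' @export
shape_ratios <- function(specimens) {
  specimens <- .check_measurements(specimens)
  vals <- as.matrix(specimens[, MEASUREMENT_VARS])
  if (anyNA(vals)) stop("measurements contain NA; impute first")
  sp <- factor(specimens$species)
  means <- apply(vals, 2, function(v) tapply(v, sp, mean))
  means <- matrix(means, nrow = nlevels(sp),
                  dimnames = list(levels(sp), MEASUREMENT_VARS))
  if (any(means <= 0)) stop("nonpositive species mean measurement")
  ratios <- log(means[, setdiff(MEASUREMENT_VARS, "SVL"), drop = FALSE] /
                  means[, "SVL"])
  attr(ratios, "mean_svl") <- means[, "SVL"]
  ratios
}
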