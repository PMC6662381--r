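# End-to-end orchestration: microhabitat classification -> Mk model fitting
# and selection -> ancestral states and stochastic mapping -> morphometric
# processing -> comparative statistics, with sensitivity loops over
# classification schemes and posterior tree sets.

#' Build a pipeline configuration
#'
#' @param tree A validated `phylo` object (the summary chronogram).
#' @param microhabitat Data frame of microhabitat records
#'   (see [apply_scheme()]), or `NULL` if `states` is given.
#' @param states Optional precomputed named state vector (bypasses
#'   classification).
#' @param schemes Character vector of classification schemes to run.
#' @param measurements Optional specimen measurement table.
#' @param landmarks Optional list with `coords`, `species`, `curves` (as
#'   produced by [generate_landmark_dataset()] or read from TPS files).
#' @param models Mk models to fit and compare.
#' @param focal_state Focal state for origin counts and convergence (the
#'   study's focal state is arboreality, "A").
#' @param allometry_groups Two states compared by the allometric test
#'   (study: arboreal vs cave).
#' @param n_maps,n_perm,n_sim,n_starts Monte-Carlo sizes.
#' @param seed Master seed; stage seeds are derived deterministically.
#' @param outdir Optional directory for CSV/JSON reports.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(tree, microhabitat = NULL, states = NULL,
                            schemes = "6-M", measurements = NULL,
                            landmarks = NULL,
                            models = c("ER", "SYM", "ARD"),
                            focal_state = "A",
                            allometry_groups = c("A", "C"),
                            n_maps = 1000, n_perm = 999, n_sim = 999,
                            n_starts = 5, seed = 1, outdir = NULL) {
  if (is.null(microhabitat) && is.null(states)) {
    stop("either microhabitat records or precomputed states are required")
  }
  if (length(schemes) < 1) stop("at least one scheme is required")
  cfg <- list(tree = tree, microhabitat = microhabitat, states = states,
              schemes = schemes, measurements = measurements,
              landmarks = landmarks, models = models,
              focal_state = focal_state,
              allometry_groups = allometry_groups,
              n_maps = n_maps, n_perm = n_perm, n_sim = n_sim,
              n_starts = n_starts, seed = seed, outdir = outdir)
  class(cfg) <- "pipeline_config"
  cfg
}

# comparative battery shared by the body-ratio and foot-shape branches
.run_trait_battery <- function(tree, Y, states, focal_state, size = NULL,
                               allometry_groups = NULL, n_perm, n_sim,
                               seed) {
  out <- list()
  out$anova <- phylogenetic_anova(tree, Y, states, n_perm = n_perm,
                                  seed = seed)
  out$pairwise <- pairwise_group_distances(tree, Y, states,
                                           n_perm = n_perm, seed = seed + 1)
  out$rates <- tryCatch(
    compare_rates_by_group(tree, Y, states, n_sim = n_sim, seed = seed + 2),
    error = function(e) structure(list(error = conditionMessage(e)),
                                  class = "stage_error")
  )
  sv <- .states_vector(states)
  focal <- names(sv)[sv == focal_state]
  focal <- intersect(focal, rownames(Y))
  if (length(focal) >= 3) {
    out$C1 <- convergence_c1(tree, Y, focal, n_sim = n_sim, seed = seed + 3)
    out$C5 <- tryCatch(
      convergence_c5(tree, Y, focal, n_sim = n_sim, seed = seed + 4),
      error = function(e) structure(list(error = conditionMessage(e)),
                                    class = "stage_error")
    )
  }
  if (!is.null(size) && !is.null(allometry_groups)) {
    two <- sv[sv %in% allometry_groups]
    if (length(unique(two)) == 2 &&
        all(table(two[names(two) %in% rownames(Y)]) >= 3)) {
      out$allometry <- allometric_convergence(
        Y[intersect(rownames(Y), names(two)), , drop = FALSE],
        two, size, n_perm = n_perm, seed = seed + 5)
    }
  }
  out
}

#' Run the full analysis pipeline
#'
#' Per classification scheme: classify species, prune the tree to classified
#' species, fit the configured Mk models, select by AIC, estimate marginal
#' ancestral states, sample stochastic maps, and summarize transitions and
#' origins of the focal state. On morphology (when supplied): impute
#' measurements and form log shape ratios; complete, align (with
#' semilandmark sliding) and average landmark configurations; then run the
#' comparative battery (phylogenetic ANOVA, pairwise distances, rate
#' comparison, C1/C5 convergence, and the allometric test on foot shape).
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_report` list with one entry per scheme plus
#'   morphology blocks; written to `config$outdir` when set.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  tree <- validate_phylogeny(config$tree, warn_nonultrametric = FALSE)
  seed <- config$seed
  report <- list(seed = seed, schemes = list())

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  for (scheme in config$schemes) {
    sc <- list(scheme = scheme)
    states <- if (!is.null(config$states)) {
      config$states
    } else {
      run_stage("classification", apply_scheme(config$microhabitat, scheme))
    }
    sv <- .states_vector(states)
    sv <- sv[names(sv) %in% tree$tip.label]
    sc_tree <- run_stage("pruning", prune_to_taxa(tree, names(sv)))
    fits <- run_stage("mk_fit", lapply(config$models, function(mdl) {
      fit_mk(sc_tree, sv, model = mdl, n_starts = config$n_starts,
             seed = seed)
    }))
    sc$model_comparison <- run_stage("model_selection", select_model(fits))
    best_fit <- fits[[which(vapply(fits, function(f) f$model,
                                   character(1)) ==
                              sc$model_comparison$best)]]
    sc$fit <- best_fit
    sc$ancestral <- run_stage(
      "ancestral_states",
      marginal_ancestral_states(sc_tree, sv, best_fit$q,
                                root_prior = best_fit$root_prior))
    maps <- run_stage(
      "stochastic_mapping",
      sample_histories(sc_tree, sv, best_fit$q, n_maps = config$n_maps,
                       root_prior = best_fit$root_prior, seed = seed + 100))
    sc$map_summary <- run_stage("map_summary", summarize_maps(maps))
    sc$focal_origins <- mean(vapply(maps, count_origins, numeric(1),
                                    focal = config$focal_state))
    sc$focal_origins_modal <- as.integer(names(which.max(table(
      vapply(maps, count_origins, numeric(1), focal = config$focal_state)))))
    report$schemes[[scheme]] <- sc
  }

  primary_states <- if (!is.null(config$states)) config$states else
    apply_scheme(config$microhabitat, config$schemes[1])

  if (!is.null(config$measurements)) {
    imputed <- run_stage("imputation",
                         impute_missing_measurements(config$measurements))
    ratios <- run_stage("shape_ratios", shape_ratios(imputed))
    report$body <- run_stage(
      "body_battery",
      .run_trait_battery(tree, ratios, primary_states, config$focal_state,
                         n_perm = config$n_perm, n_sim = config$n_sim,
                         seed = seed + 200))
    report$body$n_imputed <- attr(imputed, "n_imputed")
    report$body$ratios <- ratios
  }

  if (!is.null(config$landmarks)) {
    lm <- config$landmarks
    coords <- lm$coords
    # complete missing landmarks against the conspecific consensus of
    # complete specimens (sister species fallback handled by the caller's
    # reference choice)
    complete_idx <- !vapply(coords, anyNA, logical(1))
    refs <- list()
    for (i in which(!complete_idx)) {
      sp <- lm$species[i]
      pool <- which(complete_idx & lm$species == sp)
      if (length(pool) == 0) pool <- which(complete_idx)
      ref <- Reduce(`+`, coords[pool]) / length(pool)
      coords[[i]] <- run_stage("landmark_interpolation",
                               interpolate_missing_landmarks(coords[[i]],
                                                             ref))
    }
    sms <- run_stage("species_means",
                     species_mean_shapes(coords, lm$species, slide = TRUE,
                                         curves = lm$curves))
    shapes <- flatten_shapes(sms$coords)
    rownames(shapes) <- sms$species
    report$foot <- run_stage(
      "foot_battery",
      .run_trait_battery(tree, shapes, primary_states, config$focal_state,
                         size = log(sms$mean_centroid_size),
                         allometry_groups = config$allometry_groups,
                         n_perm = config$n_perm, n_sim = config$n_sim,
                         seed = seed + 300))
    report$foot$mean_centroid_size <- sms$mean_centroid_size
    report$foot$shapes <- shapes
  }

  class(report) <- "pipeline_report"
  if (!is.null(config$outdir)) .write_report(report, config)
  report
}

# numeric summary rows extracted from a report, used by CSV output and the
# sensitivity loop
.report_stats <- function(report) {
  out <- list()
  for (scheme in names(report$schemes)) {
    sc <- report$schemes[[scheme]]
    pre <- paste0(scheme, ".")
    out[[paste0(pre, "best_model_aic")]] <-
      min(sc$model_comparison$table$aic)
    out[[paste0(pre, "delta_aic_runner_up")]] <-
      unname(sort(sc$model_comparison$delta_aic)[2])
    out[[paste0(pre, "mean_focal_origins")]] <- sc$focal_origins
    out[[paste0(pre, "max_mean_transitions")]] <-
      max(sc$map_summary$mean_transition_counts)
  }
  for (block in c("body", "foot")) {
    b <- report[[block]]
    if (is.null(b)) next
    pre <- paste0(block, ".")
    out[[paste0(pre, "anova_R2")]] <- b$anova$R2
    out[[paste0(pre, "anova_F")]] <- b$anova$F
    out[[paste0(pre, "anova_p")]] <- b$anova$p
    if (!inherits(b$rates, "stage_error")) {
      out[[paste0(pre, "rate_ratio")]] <- b$rates$ratio
      out[[paste0(pre, "rate_p")]] <- b$rates$p
    }
    if (!is.null(b$C1)) {
      out[[paste0(pre, "C1")]] <- b$C1$C1
      out[[paste0(pre, "C1_p")]] <- b$C1$p
    }
    if (!is.null(b$C5) && !inherits(b$C5, "stage_error")) {
      out[[paste0(pre, "C5")]] <- b$C5$C5
      out[[paste0(pre, "C5_p")]] <- b$C5$p
    }
    if (!is.null(b$allometry)) {
      out[[paste0(pre, "allometry_stat")]] <- b$allometry$statistic
      out[[paste0(pre, "allometry_p")]] <- b$allometry$p
    }
  }
  unlist(out)
}

.write_report <- function(report, config) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  stats <- .report_stats(report)
  utils::write.csv(data.frame(statistic = names(stats), value = stats,
                              row.names = NULL),
                   file.path(config$outdir, "summary_statistics.csv"),
                   row.names = FALSE)
  for (scheme in names(report$schemes)) {
    sc <- report$schemes[[scheme]]
    tag <- gsub("[^0-9A-Za-z]+", "_", scheme)
    utils::write.csv(unclass(sc$fit$q),
                     file.path(config$outdir,
                               paste0("qmatrix_", tag, ".csv")))
    utils::write.csv(sc$map_summary$mean_transition_counts,
                     file.path(config$outdir,
                               paste0("transitions_", tag, ".csv")))
    utils::write.csv(sc$ancestral,
                     file.path(config$outdir,
                               paste0("ancestral_states_", tag, ".csv")))
  }
  jsonlite::write_json(
    list(seed = config$seed, n_maps = config$n_maps,
         n_perm = config$n_perm, n_sim = config$n_sim,
         schemes = config$schemes,
         statistics = as.list(stats)),
    file.path(config$outdir, "report.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' Sensitivity analysis over a set of posterior chronograms
#'
#' Repeats the configured analyses on each tree of a posterior set and
#' summarizes every reported statistic by its 2.5% and 97.5% quantiles,
#' quantifying robustness to phylogenetic uncertainty. Trees whose tips do
#' not cover the classified species are skipped with a warning.
#'
#' @param config A [pipeline_config()] (its `tree` is the summary tree whose
#'   point estimates the intervals contextualize).
#' @param trees A `multiPhylo` set (>= 2 trees).
#' @return A `sensitivity_report`: `per_tree` (statistic x tree matrix),
#'   `intervals` (2.5%/50%/97.5% quantiles per statistic), `point`
#'   (summary-tree statistics), `n_skipped`.
#' @export
sensitivity_analysis <- function(config, trees) {
  stopifnot(inherits(config, "pipeline_config"))
  if (length(trees) < 2) stop("need at least 2 trees")
  point <- .report_stats(run_full_analysis(config))
  rows <- list()
  skipped <- 0L
  for (i in seq_along(trees)) {
    cfg_i <- config
    cfg_i$tree <- trees[[i]]
    cfg_i$outdir <- NULL
    res <- tryCatch(.report_stats(run_full_analysis(cfg_i)),
                    error = function(e) NULL)
    if (is.null(res)) {
      skipped <- skipped + 1L
      warning("tree ", i, " skipped")
      next
    }
    rows[[length(rows) + 1L]] <- res
  }
  if (length(rows) == 0) stop("all trees failed")
  common <- Reduce(intersect, lapply(rows, names))
  per_tree <- vapply(rows, function(r) r[common],
                     numeric(length(common)))
  per_tree <- matrix(per_tree, nrow = length(common),
                     dimnames = list(common, NULL))
  intervals <- t(apply(per_tree, 1, stats::quantile,
                       probs = c(0.025, 0.5, 0.975)))
  out <- list(per_tree = per_tree, intervals = intervals,
              point = point[common], n_skipped = skipped)
  class(out) <- "sensitivity_report"
  out
}
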