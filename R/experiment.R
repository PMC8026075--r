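# End-to-end study driver: simulate quadruples at every base-rate pair,
# evaluate the coefficient registry, correlate, cluster with K-median and
# compare the partitions across base-rate pairs.

#' Experiment configuration
#'
#' @param simulation A \code{\link{simulation_config}}.
#' @param k Number of clusters for the per-pair K-median partition.
#' @param restarts Multistart restarts per partition.
#' @param exemplar_pairs Coefficient pairs for the exemplar correlation
#'   table (see \code{\link{exemplar_correlation_table}}).
#' @param output_dir Optional directory; when given, all artifacts are
#'   written there as CSV/JSON with a manifest.
#' @return An object of class \code{"experiment_config"}.
#' @export
experiment_config <- function(simulation = simulation_config(),
                              k = 2L, restarts = 2000L,
                              exemplar_pairs = NULL, output_dir = NULL) {
  stopifnot(inherits(simulation, "simulation_config"), k >= 1L, restarts >= 1L)
  structure(list(simulation = simulation, k = as.integer(k),
                 restarts = as.integer(restarts),
                 exemplar_pairs = exemplar_pairs, output_dir = output_dir),
            class = "experiment_config")
}

#' Run the full base-rate study
#'
#' Executes every stage with seeds derived from the simulation master seed:
#' quadruple generation per base-rate pair, evaluation of all registered
#' coefficients, per-pair correlation matrices with the drop rule, global
#' exclusion of coefficients dropped at any pair, K-median partitioning of
#' each retained correlation matrix, and the cross-pair comparisons (ARI
#' matrix, co-membership stability at the all-pairs and all-but-one
#' thresholds, exemplar correlation table).
#'
#' @param config An \code{\link{experiment_config}}.
#' @return A result bundle (list) with elements \code{config},
#'   \code{correlations} (per-pair \code{coefficient_correlation}),
#'   \code{kept} (globally retained keys), \code{dropped_global},
#'   \code{partitions} (per-pair \code{kmedian_partition}),
#'   \code{ari_matrix}, \code{stability_full}, \code{stability_minus_one}
#'   and \code{exemplar_table}.
#' @export
run_experiment <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  sim <- config$simulation
  trials <- generate_trials(sim)
  correlations <- lapply(trials, function(q) correlation_matrix(evaluate_trials(q)))
  kept <- globally_kept(correlations)
  dropped_global <- setdiff(coefficient_keys(), kept)
  partitions <- vector("list", length(correlations))
  names(partitions) <- names(correlations)
  for (i in seq_along(correlations)) {
    S <- similarity_matrix(correlations[[i]]$matrix[kept, kept])
    partitions[[i]] <- multistart_kmedian(S, config$k, restarts = config$restarts,
                                          seed = pair_seed(sim$seed, 1000L + i))
  }
  am <- ari_matrix(partitions)
  stab_full <- co_membership_stability(partitions)
  stab_m1 <- if (length(partitions) > 1L) {
    co_membership_stability(partitions, threshold = length(partitions) - 1L)
  } else stab_full
  extab <- if (is.null(config$exemplar_pairs)) {
    exemplar_correlation_table(correlations)
  } else {
    exemplar_correlation_table(correlations, config$exemplar_pairs)
  }
  bundle <- list(config = config, correlations = correlations, kept = kept,
                 dropped_global = dropped_global, partitions = partitions,
                 ari_matrix = am, stability_full = stab_full,
                 stability_minus_one = stab_m1, exemplar_table = extab)
  if (!is.null(config$output_dir)) write_bundle(bundle, config$output_dir)
  bundle
}

write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(bundle$ari_matrix, file.path(dir, "ari_matrix.csv"))
  utils::write.csv(bundle$exemplar_table, file.path(dir, "exemplar_correlations.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$stability_full$counts,
                   file.path(dir, "co_membership_counts.csv"))
  parts <- do.call(rbind, lapply(names(bundle$partitions), function(lab) {
    p <- bundle$partitions[[lab]]
    data.frame(pair = lab, coefficient = names(p$cluster),
               cluster = as.integer(p$cluster), row.names = NULL)
  }))
  utils::write.csv(parts, file.path(dir, "partitions.csv"), row.names = FALSE)
  for (lab in names(bundle$correlations)) {
    f <- file.path(dir, sprintf("correlation_%s.csv", gsub("[^0-9.]+", "_", lab)))
    utils::write.csv(bundle$correlations[[lab]]$matrix, f)
  }
  dropped <- do.call(rbind, lapply(names(bundle$correlations), function(lab) {
    d <- bundle$correlations[[lab]]$dropped
    if (nrow(d)) cbind(pair = lab, d) else NULL
  }))
  sim <- bundle$config$simulation
  manifest <- list(
    package = "binsimco",
    version = as.character(utils::packageVersion("binsimco")),
    r_version = R.version.string,
    seed = sim$seed, trials = sim$trials, n = sim$n, sampler = sim$sampler,
    k = bundle$config$k, restarts = bundle$config$restarts,
    pairs = names(bundle$partitions),
    kept = bundle$kept, dropped_global = bundle$dropped_global,
    dropped_per_pair = dropped
  )
  jsonlite::write_json(manifest, file.path(dir, "MANIFEST.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Render the study's summary tables from a result bundle
#'
#' @param bundle Result of \code{\link{run_experiment}}.
#' @param fair_threshold ARI level flagged as at-least-fair agreement.
#' @return A list with \code{agreement} (ARI matrix plus a logical flag
#'   matrix of entries at or above \code{fair_threshold}), \code{subsets}
#'   (data frame of stable subsets at the all-pairs threshold, with members
#'   that attach at the all-but-one threshold marked) and \code{exemplars}
#'   (the exemplar correlation table).
#' @export
report_tables <- function(bundle, fair_threshold = 0.65) {
  need <- c("ari_matrix", "stability_full", "stability_minus_one", "exemplar_table")
  miss <- need[!vapply(need, function(nm) !is.null(bundle[[nm]]), TRUE)]
  if (length(miss)) {
    stop(sprintf("bundle is missing stage output '%s'", miss[1]), call. = FALSE)
  }
  subs <- bundle$stability_full$subsets
  if (!length(subs)) stop("bundle contains no stable subsets", call. = FALSE)
  rows <- lapply(seq_along(subs), function(i) {
    core <- subs[[i]]
    anchor <- core[1]
    wider <- stable_subset_of(bundle$stability_minus_one, anchor)
    attach <- setdiff(wider, core)
    data.frame(subset = i, size = length(core),
               members = paste(core, collapse = ", "),
               attach_at_minus_one = paste(attach, collapse = ", "),
               row.names = NULL)
  })
  list(agreement = list(ari = bundle$ari_matrix,
                        fair = bundle$ari_matrix >= fair_threshold),
       subsets = do.call(rbind, rows),
       exemplars = bundle$exemplar_table)
}
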