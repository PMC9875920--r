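# End-to-end experiment drivers: split-half reliability, overlapping vs
# nonoverlapping validity, and membership diversity. Every stage seed is
# derived from one master seed and recorded in the returned manifest.

#' Experiment configuration
#'
#' Defaults mirror the analysis conventions of the pipeline: retain the top
#' 10% of correlations at both thresholding stages, assign K = 7 networks,
#' 10,000 permutation iterations at a family-wise alpha of .05, and 100
#' k-means replicates.
#'
#' @param threshold_fraction retained edge fraction (default 0.10).
#' @param n_networks K (default 7).
#' @param n_permutations permutation iterations (default 10000).
#' @param alpha_fw family-wise significance level (default 0.05).
#' @param kmeans_replicates k-means restarts (default 100).
#' @param fit arguments passed on to [fit_config()] (list).
#' @param seed master seed; all stage seeds derive from it via
#'   [split_seed()].
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(threshold_fraction = 0.10, n_networks = 7L,
                              n_permutations = 10000L, alpha_fw = 0.05,
                              kmeans_replicates = 100L, fit = list(),
                              seed = 1L) {
  structure(list(threshold_fraction = threshold_fraction,
                 n_networks = as.integer(n_networks),
                 n_permutations = as.integer(n_permutations),
                 alpha_fw = alpha_fw,
                 kmeans_replicates = as.integer(kmeans_replicates),
                 fit = fit, seed = as.integer(seed)),
            class = "experiment_config")
}

#' @noRd
stage_fit_config <- function(config, seed) {
  do.call(fit_config, c(list(n_networks = config$n_networks, seed = seed),
                        config$fit))
}

#' Split-half reliability of overlapping network assignment
#'
#' Builds a group connectome per cohort, fits the mixed-membership model to
#' each, binarizes, and runs the Dice permutation comparison with homologue
#' matching between the two solutions.
#'
#' @param cohort_a,cohort_b lists of [subject_timeseries()] (two independent
#'   samples collected under one protocol).
#' @param config an [experiment_config()].
#' @return list: `connectomes`, `assignments`, `topographies`, `similarity`,
#'   `homologues`, `seeds`.
#' @export
run_reliability <- function(cohort_a, cohort_b, config = experiment_config()) {
  seeds <- split_seed(config$seed, 3L)
  ga <- build_group_connectome(cohort_a, config$threshold_fraction)
  gb <- build_group_connectome(cohort_b, config$threshold_fraction)
  match_labels(ga$region_labels, gb$region_labels,
               "region labels (cohort A vs B)")
  dd <- drop_disconnected(ga, gb)
  ga <- dd$connectomes[[1]]
  gb <- dd$connectomes[[2]]
  fa <- fit_ammsb(ga, stage_fit_config(config, seeds[1]))
  fb <- fit_ammsb(gb, stage_fit_config(config, seeds[2]))
  ta <- binarize_assignment(fa)
  tb <- binarize_assignment(fb)
  sim <- permutation_test(ta, tb, n_iter = config$n_permutations,
                          seed = seeds[3], alpha_fw = config$alpha_fw)
  hom <- match_homologues(sim)
  list(connectomes = list(a = ga, b = gb),
       assignments = list(a = fa, b = fb),
       topographies = list(a = ta, b = tb),
       similarity = sim, homologues = hom,
       excluded = dd$excluded,
       seeds = list(fit_a = seeds[1], fit_b = seeds[2], permutation = seeds[3]))
}

#' Overlapping vs nonoverlapping network validity
#'
#' On one (combined) cohort: build the group connectome, fit the overlapping
#' model, derive K nonoverlapping networks by k-means on the group weight
#' matrix, and compare the two solutions with the Dice permutation test in
#' both orientations (the k-means topographies are the shuffled set, per the
#' convention for comparisons against a fixed reference).
#'
#' @param cohort list of [subject_timeseries()].
#' @param config an [experiment_config()].
#' @return list: `connectome`, `group_weights`, `assignment`, `overlapping`,
#'   `partition`, `nonoverlapping`, `comparison` (similarity rows =
#'   overlapping networks, plus homologues), `seeds`.
#' @export
run_validity <- function(cohort, config = experiment_config()) {
  seeds <- split_seed(config$seed, 3L)
  px <- propagate_exclusions(cohort)
  per_subject <- lapply(px$cohort, function(ts) {
    proportional_threshold(remove_negatives(fisher_z_correlation(ts)),
                           config$threshold_fraction)
  })
  w <- group_average(per_subject)
  g <- proportional_threshold(w, config$threshold_fraction)
  dd <- drop_disconnected(g)
  g <- dd$connectomes[[1]]
  keep <- w$region_labels %in% g$region_labels
  w <- structure(list(values = w$values[keep, keep, drop = FALSE],
                      region_labels = w$region_labels[keep]),
                 class = "group_weight_matrix")
  fit <- fit_ammsb(g, stage_fit_config(config, seeds[1]))
  over <- binarize_assignment(fit)
  part <- kmeans_networks(w, K = config$n_networks, seed = seeds[2],
                          n_replicates = config$kmeans_replicates)
  nonover <- partition_to_topographies(part)
  cmp <- compare_to_reference(nonover, over, n_iter = config$n_permutations,
                              seed = seeds[3], alpha_fw = config$alpha_fw)
  # rows = overlapping networks for the report orientation
  sim_over <- structure(list(dice = t(cmp$similarity$dice),
                             p_values = t(cmp$similarity$p_values),
                             alpha_within = cmp$similarity$alpha_within,
                             significant = t(cmp$similarity$significant),
                             n_permutations = cmp$similarity$n_permutations),
                        class = "similarity_result")
  list(connectome = g, group_weights = w, assignment = fit,
       overlapping = over, partition = part, nonoverlapping = nonover,
       comparison = list(similarity = sim_over,
                         homologues = match_homologues(sim_over$dice)),
       excluded = c(px$excluded, dd$excluded),
       seeds = list(fit = seeds[1], kmeans = seeds[2], permutation = seeds[3]))
}

#' Membership-diversity report
#'
#' Computes the per-region diversity profile and, when a lookup table and
#' query coordinates are supplied, the named-region extraction report.
#'
#' @param assignment an [assignment_matrix()].
#' @param lookup optional [region_lookup()].
#' @param coordinates optional data.frame (name, x, y, z).
#' @param max_radius passed to [extract_named_regions()].
#' @return list: `profile` (a `diversity_profile`), `named_regions`
#'   (data.frame or `NULL`).
#' @export
run_diversity <- function(assignment, lookup = NULL, coordinates = NULL,
                          max_radius = Inf) {
  prof <- diversity_profile(assignment)
  named <- NULL
  if (!is.null(lookup) && !is.null(coordinates)) {
    named <- extract_named_regions(assignment, lookup, coordinates,
                                   max_radius = max_radius)
  }
  list(profile = prof, named_regions = named)
}
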