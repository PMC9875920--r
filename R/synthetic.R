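# Planted overlapping-network generator.
#
# A cohort of subjects is emulated from K latent network signals with mixed
# regional loadings: most regions belong to a single network, a controllable
# fraction load on 2-4 networks. The same membership matrix also drives a
# direct mixed-membership SBM graph sampler so the inference stage can be
# validated against planted truth without going through timeseries.

#' Construct a planted overlapping-network model
#'
#' @param membership region x K matrix; rows nonnegative, each summing to 1.
#' @param within_strength per-network within-community edge probability
#'   \eqn{\beta_k} in (0, 1]; recycled to length K.
#' @param background cross-community edge probability \eqn{\epsilon};
#'   must satisfy \eqn{\epsilon < \min_k \beta_k} (assortativity).
#' @param signal_sd standard deviation of each latent network signal.
#' @param noise_sd standard deviation of per-region observation noise.
#' @param frac_multi recorded fraction of rows intended to have 2+ memberships.
#' @param seed integer seed the model was generated from (bookkeeping).
#' @return object of class `planted_model`.
#' @export
planted_model <- function(membership, within_strength = 0.6, background = 0.01,
                          signal_sd = 1, noise_sd = 1, frac_multi = NA_real_,
                          seed = NA_integer_) {
  membership <- as.matrix(membership)
  if (any(membership < 0)) stop("membership entries must be nonnegative", call. = FALSE)
  rs <- rowSums(membership)
  if (any(abs(rs - 1) > 1e-9)) {
    stop("every membership row must sum to 1 (tolerance 1e-9)", call. = FALSE)
  }
  K <- ncol(membership)
  within_strength <- rep_len(within_strength, K)
  if (any(within_strength <= 0 | within_strength > 1)) {
    stop("within_strength must lie in (0, 1]", call. = FALSE)
  }
  if (background < 0 || background >= min(within_strength)) {
    stop("background must lie in [0, min(within_strength)) for assortativity",
         call. = FALSE)
  }
  if (is.null(rownames(membership))) {
    rownames(membership) <- default_region_labels(nrow(membership))
  }
  if (is.null(colnames(membership))) {
    colnames(membership) <- paste0("N", seq_len(K))
  }
  structure(
    list(membership = membership,
         n_regions = nrow(membership), n_networks = K,
         within_strength = within_strength, background = background,
         signal_sd = signal_sd, noise_sd = noise_sd,
         frac_multi = frac_multi, seed = seed),
    class = "planted_model")
}

#' @export
print.planted_model <- function(x, ...) {
  cat(sprintf("Planted overlapping-network model: %d regions, K = %d\n",
              x$n_regions, x$n_networks))
  cat(sprintf("  multi-membership rows: %d (%.0f%%); beta in [%.2f, %.2f], eps = %.3g\n",
              sum(rowSums(x$membership > 0) > 1),
              100 * mean(rowSums(x$membership > 0) > 1),
              min(x$within_strength), max(x$within_strength), x$background))
  invisible(x)
}

#' Sample a planted model with controlled multi-membership fraction
#'
#' `(1 - frac_multi)` of regions get a unit-basis membership row (one network);
#' the remainder load on 2-4 networks with weights from a sparse symmetric
#' Dirichlet restricted to the chosen support and renormalised. Base networks
#' are assigned in a balanced round-robin so no network is empty.
#'
#' @param n_regions number of regions (>= n_networks).
#' @param n_networks number of latent networks K (>= 2).
#' @param frac_multi fraction of regions with 2-4 memberships, in \[0, 1\].
#' @param seed integer seed; the draw is deterministic given the arguments.
#' @param dirichlet_alpha concentration of the within-support Dirichlet.
#' @param multi_support candidate numbers of networks for multi-membership
#'   rows; a subset of 2:4 (capped at K).
#' @inheritParams planted_model
#' @return a `planted_model`.
#' @export
sample_planted_model <- function(n_regions, n_networks, frac_multi = 0.3,
                                 seed = 1L, within_strength = 0.6,
                                 background = 0.01, signal_sd = 1,
                                 noise_sd = 1, dirichlet_alpha = 0.8,
                                 multi_support = 2:4) {
  stopif_not_count(n_regions, "n_regions", 2L)
  stopif_not_count(n_networks, "n_networks", 2L)
  if (n_regions < n_networks) stop("n_regions must be >= n_networks", call. = FALSE)
  if (!is.numeric(frac_multi) || frac_multi < 0 || frac_multi > 1) {
    stop("frac_multi must lie in [0, 1]", call. = FALSE)
  }
  K <- as.integer(n_networks)
  multi_support <- intersect(as.integer(multi_support), 2:min(4L, K))
  if (length(multi_support) == 0) {
    stop("multi_support must contain values in 2..min(4, K)", call. = FALSE)
  }
  theta <- with_seed(seed, {
    n_multi <- round(frac_multi * n_regions)
    # balanced base assignment, then random choice of which rows go multi
    base <- rep_len(seq_len(K), n_regions)[sample.int(n_regions)]
    multi_rows <- if (n_multi > 0) sample.int(n_regions, n_multi) else integer(0)
    th <- matrix(0, n_regions, K)
    th[cbind(seq_len(n_regions), base)] <- 1
    for (i in multi_rows) {
      s <- multi_support[sample.int(length(multi_support), 1L)]
      supp <- unique(c(base[i], sample.int(K, s)))[seq_len(s)]
      # sparse symmetric Dirichlet on the support via normalised gammas
      w <- rgamma(s, shape = dirichlet_alpha)
      while (any(w == 0) || sum(w) == 0) w <- rgamma(s, shape = dirichlet_alpha)
      th[i, ] <- 0
      th[i, supp] <- w / sum(w)
    }
    th
  })
  planted_model(theta, within_strength = within_strength,
                background = background, signal_sd = signal_sd,
                noise_sd = noise_sd, frac_multi = frac_multi,
                seed = as.integer(seed))
}

#' Sample a binary graph from the planted mixed-membership model
#'
#' Each unordered pair (i, j) receives an edge with probability
#' \deqn{\sum_k \theta_{ik}\theta_{jk}\beta_k +
#'       (1 - \sum_k \theta_{ik}\theta_{jk})\,\epsilon,}
#' the assortative mixed-membership SBM edge law.
#'
#' @param model a `planted_model`.
#' @param seed integer seed.
#' @return a [binary_connectome()].
#' @export
generate_graph <- function(model, seed = 1L) {
  stopifnot(inherits(model, "planted_model"))
  th <- model$membership
  n <- nrow(th)
  share <- tcrossprod(th)                      # sum_k theta_ik theta_jk
  p <- tcrossprod(th %*% diag(model$within_strength, ncol(th)), th) +
    (1 - share) * model$background
  adj <- matrix(0L, n, n, dimnames = list(rownames(th), rownames(th)))
  up <- upper.tri(p)
  adj[up] <- with_seed(seed, rbinom(sum(up), 1L, pmin(pmax(p[up], 0), 1)))
  adj[lower.tri(adj)] <- t(adj)[lower.tri(adj)]
  binary_connectome(adj, region_labels = rownames(th))
}

#' Simulate a cohort of subject timeseries from a planted model
#'
#' Each subject draws K independent Gaussian latent network signals; region
#' i's series is \eqn{\sum_k \theta_{ik}\,s_k(t)} plus Gaussian noise.
#' Optional AR(1) smoothing of the latent signals and per-subject-region
#' dropout (series zeroed, to exercise exclusion propagation) are available.
#'
#' @param model a `planted_model`.
#' @param n_subjects number of subjects (>= 2).
#' @param n_timepoints timepoints per subject (>= 50).
#' @param seed master seed; each subject uses a derived child seed.
#' @param dropout per subject x region probability of a missing (all-zero)
#'   series; default 0.
#' @param ar1 AR(1) coefficient applied to latent signals; 0 disables.
#' @return list of `subject_timeseries` objects.
#' @export
generate_cohort <- function(model, n_subjects, n_timepoints, seed = 1L,
                            dropout = 0, ar1 = 0) {
  stopifnot(inherits(model, "planted_model"))
  stopif_not_count(n_subjects, "n_subjects", 2L)
  stopif_not_count(n_timepoints, "n_timepoints", 50L)
  th <- model$membership
  K <- ncol(th)
  seeds <- split_seed(seed, n_subjects)
  lapply(seq_len(n_subjects), function(s) {
    x <- with_seed(seeds[s], {
      sig <- matrix(rnorm(K * n_timepoints, sd = model$signal_sd), K, n_timepoints)
      if (ar1 > 0) {
        for (t in 2:n_timepoints) sig[, t] <- ar1 * sig[, t - 1] + sig[, t]
      }
      dat <- th %*% sig +
        matrix(rnorm(nrow(th) * n_timepoints, sd = model$noise_sd),
               nrow(th), n_timepoints)
      if (dropout > 0) {
        drop <- runif(nrow(th)) < dropout
        dat[drop, ] <- 0
      }
      dat
    })
    subject_timeseries(sprintf("sub%03d", s), x, rownames(th))
  })
}

#' Ground-truth overlapping cover of a planted model
#'
#' Network k's region set is every region with a strictly positive membership
#' weight on k; the reference for all recovery tests.
#'
#' @param model a `planted_model`.
#' @return a [topography_set()].
#' @export
ground_truth_cover <- function(model) {
  stopifnot(inherits(model, "planted_model"))
  topography_set(model$membership > 0,
                 network_labels = colnames(model$membership),
                 region_labels = rownames(model$membership))
}

#' Construct a subject timeseries object
#'
#' @param subject_id subject identifier.
#' @param data region x time numeric matrix.
#' @param region_labels region names, one per row.
#' @return object of class `subject_timeseries`.
#' @export
subject_timeseries <- function(subject_id, data, region_labels = rownames(data)) {
  data <- as.matrix(data)
  if (is.null(region_labels)) region_labels <- default_region_labels(nrow(data))
  if (length(region_labels) != nrow(data)) {
    stop("region_labels must match the number of rows", call. = FALSE)
  }
  if (!all(is.finite(data))) stop("timeseries values must all be finite", call. = FALSE)
  rownames(data) <- region_labels
  structure(list(subject_id = as.character(subject_id), data = data,
                 region_labels = region_labels),
            class = "subject_timeseries")
}

#' @export
print.subject_timeseries <- function(x, ...) {
  cat(sprintf("Subject %s: %d regions x %d timepoints\n",
              x$subject_id, nrow(x$data), ncol(x$data)))
  invisible(x)
}

#' Write / read a cohort as per-subject TSV files
#'
#' One TSV per subject (label column + one column per timepoint) and a JSON
#' sidecar recording the planted model (membership, strengths, seed) when one
#' is supplied.
#'
#' @param cohort list of `subject_timeseries`.
#' @param dir output directory (created if needed).
#' @param model optional `planted_model` to record in `model.json`.
#' @return invisibly, the written file paths.
#' @export
write_cohort <- function(cohort, dir, model = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(cohort, function(ts) {
    p <- file.path(dir, paste0(ts$subject_id, ".tsv"))
    df <- data.frame(region = ts$region_labels, ts$data, check.names = FALSE)
    colnames(df) <- c("region", sprintf("t%04d", seq_len(ncol(ts$data))))
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }, character(1))
  if (!is.null(model)) {
    jsonlite::write_json(
      list(membership = model$membership,
           within_strength = model$within_strength,
           background = model$background, signal_sd = model$signal_sd,
           noise_sd = model$noise_sd, frac_multi = model$frac_multi,
           seed = model$seed,
           region_labels = rownames(model$membership),
           network_labels = colnames(model$membership)),
      file.path(dir, "model.json"), digits = NA)
    paths <- c(paths, file.path(dir, "model.json"))
  }
  invisible(paths)
}

#' @rdname write_cohort
#' @param files TSV paths, one per subject; subject id taken from file name.
#' @export
read_cohort <- function(files) {
  lapply(files, function(p) {
    df <- read.delim(p, check.names = FALSE)
    subject_timeseries(sub("\\.tsv$", "", basename(p)),
                       as.matrix(df[, -1, drop = FALSE]),
                       as.character(df[[1]]))
  })
}
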