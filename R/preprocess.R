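# Group-connectome construction: Fisher-z correlation, negative removal,
# proportional thresholding to a fixed graph density, subject averaging, and
# a final re-threshold of the group weight matrix.

#' Construct a binary connectome
#'
#' @param adjacency symmetric 0/1 matrix with zero diagonal.
#' @param region_labels region names.
#' @return object of class `binary_connectome`; `density` records the actual
#'   fraction of 1s among unordered off-diagonal pairs.
#' @export
binary_connectome <- function(adjacency, region_labels = rownames(adjacency)) {
  adjacency <- as.matrix(adjacency)
  n <- nrow(adjacency)
  if (is.null(region_labels)) region_labels <- default_region_labels(n)
  if (!check_symmetric(adjacency)) stop("adjacency must be symmetric", call. = FALSE)
  if (any(diag(adjacency) != 0)) stop("adjacency diagonal must be zero", call. = FALSE)
  if (!all(adjacency %in% c(0, 1))) stop("adjacency must be binary", call. = FALSE)
  storage.mode(adjacency) <- "integer"
  dimnames(adjacency) <- list(region_labels, region_labels)
  structure(list(adjacency = adjacency, region_labels = region_labels,
                 density = mean(adjacency[upper.tri(adjacency)])),
            class = "binary_connectome")
}

#' @export
print.binary_connectome <- function(x, ...) {
  cat(sprintf("Binary connectome: %d regions, density %.4f (%d edges)\n",
              length(x$region_labels), x$density,
              sum(x$adjacency[upper.tri(x$adjacency)])))
  invisible(x)
}

#' Fisher-z correlation matrix of one subject's timeseries
#'
#' Pearson correlations between region series, transformed by `atanh` with r
#' clipped to +/-(1 - 1e-7) so duplicate series stay finite; the diagonal is
#' set to zero. Constant series are an error — such regions are exclusions
#' and must be removed first (see [propagate_exclusions()]).
#'
#' @param ts a [subject_timeseries()].
#' @return region x region symmetric numeric matrix (Fisher-z units) with
#'   zero diagonal and region labels as dimnames.
#' @export
fisher_z_correlation <- function(ts) {
  stopifnot(inherits(ts, "subject_timeseries"))
  if (ncol(ts$data) < 3) stop("need at least 3 timepoints", call. = FALSE)
  sds <- apply(ts$data, 1, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("constant region series (exclusions) in subject %s: %s",
                 ts$subject_id,
                 paste(ts$region_labels[sds == 0], collapse = ", ")),
         call. = FALSE)
  }
  r <- cor(t(ts$data))
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  z <- atanh(r)
  diag(z) <- 0
  z <- (z + t(z)) / 2                      # enforce exact symmetry
  dimnames(z) <- list(ts$region_labels, ts$region_labels)
  z
}

#' Zero out negative correlations
#'
#' @param m symmetric numeric matrix.
#' @return `m` with every negative entry set to 0.
#' @export
remove_negatives <- function(m) {
  m[m < 0] <- 0
  m
}

#' Proportional threshold to a fixed graph density
#'
#' Retains the `ceiling(fraction * P)` largest strictly positive values over
#' the P unordered off-diagonal pairs as edges; everything else becomes 0.
#' Ties at the cut are broken deterministically by ascending (row, column)
#' index. If fewer positive values exist than the quota, all positives are
#' retained and a warning is raised.
#'
#' @param m symmetric numeric matrix (correlation or group-weight scale).
#' @param fraction target density in (0, 1).
#' @param region_labels optional labels (default: dimnames of `m`).
#' @return a [binary_connectome()].
#' @export
proportional_threshold <- function(m, fraction = 0.10,
                                   region_labels = rownames(m)) {
  if (inherits(m, "group_weight_matrix")) {
    region_labels <- m$region_labels
    m <- m$values
  }
  m <- as.matrix(m)
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction >= 1) {
    stop("fraction must lie in (0, 1)", call. = FALSE)
  }
  if (!check_symmetric(m, tol = 1e-9)) stop("matrix must be symmetric", call. = FALSE)
  n <- nrow(m)
  up <- which(upper.tri(m))
  P <- length(up)
  quota <- ceiling(fraction * P)
  v <- m[up]
  ij <- which(upper.tri(m), arr.ind = TRUE)
  pos <- which(v > 0)
  if (length(pos) < quota) {
    warning(sprintf("only %d positive pairs available for a quota of %d; retaining all",
                    length(pos), quota), call. = FALSE)
    keep <- pos
  } else {
    # descending value; ties broken by ascending (row, col) index
    ord <- pos[order(-v[pos], ij[pos, 1], ij[pos, 2])]
    keep <- ord[seq_len(quota)]
  }
  adj <- matrix(0L, n, n)
  adj[up[keep]] <- 1L
  adj[lower.tri(adj)] <- t(adj)[lower.tri(adj)]
  if (is.null(region_labels)) region_labels <- default_region_labels(n)
  binary_connectome(adj, region_labels)
}

#' Average binary connectomes across subjects
#'
#' Each pair's value is the fraction of subjects in which the edge survived
#' the subject-level threshold, weighting group-level connectivity by
#' cross-subject consistency.
#'
#' @param connectomes list of [binary_connectome()] with identical labels.
#' @return object of class `group_weight_matrix` with fields `values`
#'   (symmetric, zero diagonal, entries in \[0, 1\]) and `region_labels`.
#' @export
group_average <- function(connectomes) {
  if (length(connectomes) < 1) stop("need at least one connectome", call. = FALSE)
  labs <- connectomes[[1]]$region_labels
  for (i in seq_along(connectomes)) {
    match_labels(labs, connectomes[[i]]$region_labels,
                 sprintf("region labels (subject 1 vs %d)", i))
  }
  w <- Reduce(`+`, lapply(connectomes, function(x) x$adjacency)) /
    length(connectomes)
  structure(list(values = w, region_labels = labs),
            class = "group_weight_matrix")
}

#' @export
print.group_weight_matrix <- function(x, ...) {
  cat(sprintf("Group weight matrix: %d regions, mean weight %.4f\n",
              length(x$region_labels), mean(x$values[upper.tri(x$values)])))
  invisible(x)
}

#' Propagate region exclusions across a cohort
#'
#' A region whose series is constant (e.g. all-zero dropout) or non-finite in
#' ANY subject is removed from EVERY subject, so all subjects share a valid
#' region universe downstream.
#'
#' @param cohort list of [subject_timeseries()] over a shared label universe.
#' @return list with elements `cohort` (trimmed) and `excluded` (labels, in
#'   original order).
#' @export
propagate_exclusions <- function(cohort) {
  labs <- cohort[[1]]$region_labels
  for (i in seq_along(cohort)) {
    match_labels(labs, cohort[[i]]$region_labels,
                 sprintf("region labels (subject 1 vs %d)", i))
  }
  bad <- Reduce(`|`, lapply(cohort, function(ts) {
    apply(ts$data, 1, function(x) !all(is.finite(x)) || stats::sd(x) == 0)
  }))
  if (all(bad)) stop("all regions excluded; empty intersection", call. = FALSE)
  trimmed <- lapply(cohort, function(ts) {
    subject_timeseries(ts$subject_id, ts$data[!bad, , drop = FALSE],
                       labs[!bad])
  })
  list(cohort = trimmed, excluded = labs[bad])
}

#' Build the sparse binary group connectome for a cohort
#'
#' The full preprocessing chain: propagate exclusions, Fisher-z correlation
#' per subject, remove negatives, threshold each subject to the top
#' `fraction` of correlations, average the binary matrices across subjects,
#' and re-threshold the group weight matrix to the same density.
#'
#' @param cohort list of [subject_timeseries()].
#' @param fraction retained edge fraction at both thresholding stages
#'   (default 0.10).
#' @return a [binary_connectome()] with density
#'   `ceiling(fraction * P) / P` whenever enough positive weights exist.
#' @export
build_group_connectome <- function(cohort, fraction = 0.10) {
  px <- propagate_exclusions(cohort)
  per_subject <- lapply(px$cohort, function(ts) {
    proportional_threshold(remove_negatives(fisher_z_correlation(ts)), fraction)
  })
  w <- group_average(per_subject)
  proportional_threshold(w, fraction)
}

#' Restrict a binary connectome to a subset of regions
#'
#' Keeps the induced subgraph on `labels` (edge set unchanged otherwise);
#' used to propagate region exclusions into an already-thresholded graph.
#'
#' @param x a [binary_connectome()].
#' @param labels region labels to keep (order follows `x`).
#' @return a [binary_connectome()].
#' @export
connectome_subset <- function(x, labels) {
  stopifnot(inherits(x, "binary_connectome"))
  keep <- x$region_labels %in% labels
  if (!any(keep)) stop("no regions left after subsetting", call. = FALSE)
  binary_connectome(x$adjacency[keep, keep, drop = FALSE],
                    x$region_labels[keep])
}

#' Drop disconnected regions from one or more connectomes
#'
#' Regions with degree 0 in ANY of the supplied connectomes are removed from
#' ALL of them (exclusion propagation at the graph stage), iterating until
#' every remaining region has degree >= 1 everywhere.
#'
#' @param ... [binary_connectome()] objects over one region universe.
#' @return list with `connectomes` (same order) and `excluded` (labels).
#' @export
drop_disconnected <- function(...) {
  gs <- list(...)
  if (length(gs) == 1 && is.list(gs[[1]]) && !inherits(gs[[1]], "binary_connectome")) {
    gs <- gs[[1]]
  }
  labs <- gs[[1]]$region_labels
  for (g in gs) match_labels(labs, g$region_labels, "region labels")
  excluded <- character(0)
  repeat {
    bad <- Reduce(union, lapply(gs, function(g) {
      g$region_labels[rowSums(g$adjacency) == 0]
    }))
    if (length(bad) == 0) break
    excluded <- c(excluded, bad)
    keep <- setdiff(gs[[1]]$region_labels, bad)
    gs <- lapply(gs, connectome_subset, labels = keep)
  }
  list(connectomes = gs, excluded = excluded)
}

# ---- file formats -----------------------------------------------------------

#' Read / write square labelled TSV matrices
#'
#' Square matrices (correlation, group weight, adjacency) are stored as TSV
#' with a header row and a leading label column.
#'
#' @param m matrix with dimnames (or `group_weight_matrix`).
#' @param path file path.
#' @export
write_matrix_tsv <- function(m, path) {
  if (inherits(m, "group_weight_matrix")) m <- m$values
  if (inherits(m, "binary_connectome")) m <- m$adjacency
  df <- data.frame(region = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  m
}

#' Write / read an undirected edge list
#'
#' One `i<TAB>j` pair per line, 0-based integer node ids with i < j — the
#' format consumed by the mixed-membership fitting stage.
#'
#' @param x a [binary_connectome()].
#' @param path file path.
#' @export
write_edge_list <- function(x, path) {
  stopifnot(inherits(x, "binary_connectome"))
  idx <- which(upper.tri(x$adjacency) & x$adjacency == 1L, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  write.table(idx - 1L, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @param region_labels labels for nodes 0..n-1; n inferred from the maximum
#'   id when omitted.
#' @export
read_edge_list <- function(path, region_labels = NULL) {
  e <- as.matrix(read.delim(path, header = FALSE))
  n <- if (is.null(region_labels)) max(e) + 1L else length(region_labels)
  adj <- matrix(0L, n, n)
  adj[e + 1L] <- 1L
  adj[e[, c(2, 1), drop = FALSE] + 1L] <- 1L
  binary_connectome(adj, region_labels %||% default_region_labels(n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
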