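# Nonoverlapping comparison networks by k-means on the group-average
# correlation structure.

#' Partition object
#'
#' @param labels integer vector of per-region network indices in 1..K.
#' @param K number of networks.
#' @param region_labels region names.
#' @return object of class `network_partition`.
#' @export
network_partition <- function(labels, K, region_labels = names(labels)) {
  labels <- as.integer(labels)
  if (any(labels < 1 | labels > K)) stop("labels must lie in 1..K", call. = FALSE)
  if (length(unique(labels)) != K) {
    stop("every network 1..K must contain at least one region", call. = FALSE)
  }
  if (is.null(region_labels)) region_labels <- default_region_labels(length(labels))
  structure(list(labels = setNames(labels, region_labels), K = as.integer(K),
                 region_labels = region_labels),
            class = "network_partition")
}

#' @export
print.network_partition <- function(x, ...) {
  cat(sprintf("Nonoverlapping partition: %d regions into %d networks (sizes: %s)\n",
              length(x$labels), x$K, paste(tabulate(x$labels, x$K), collapse = ", ")))
  invisible(x)
}

#' K-means networks from a connectivity matrix
#'
#' Each region's feature vector is its row of the matrix; distances are
#' correlation distances (1 - Pearson r between rows), realised by running
#' `stats::kmeans` on row-standardised features, for which squared Euclidean
#' distance is proportional to correlation distance. The best of
#' `n_replicates` seeded restarts (lowest total within-cluster distance) is
#' returned; a replicate that degenerates to an empty cluster is re-seeded
#' and the event logged via `message()`.
#'
#' @param m a `group_weight_matrix`, or any square symmetric numeric matrix.
#' @param K number of networks.
#' @param seed integer seed; replicate sub-seeds derive from it.
#' @param n_replicates number of random restarts (default 100).
#' @return a [network_partition()].
#' @export
kmeans_networks <- function(m, K = 7L, seed = 1L, n_replicates = 100L) {
  if (inherits(m, "group_weight_matrix")) {
    labs <- m$region_labels
    m <- m$values
  } else {
    labs <- rownames(as.matrix(m))
    m <- as.matrix(m)
  }
  stopif_not_count(K, "K", 2L)
  stopif_not_count(n_replicates, "n_replicates", 1L)
  if (is.null(labs)) labs <- default_region_labels(nrow(m))
  if (K > nrow(m)) stop("K cannot exceed the number of regions", call. = FALSE)
  if (K == nrow(m)) {
    # degenerate partition: every region its own network
    return(network_partition(seq_len(K), K, labs))
  }
  # row-standardise: after centering and scaling, ||zi - zj||^2 = 2(p-1)(1 - r_ij)
  z <- t(scale(t(m)))
  if (any(!is.finite(z))) {
    stop("constant feature rows cannot be clustered under correlation distance",
         call. = FALSE)
  }
  seeds <- split_seed(seed, n_replicates)
  best <- NULL
  for (r in seq_len(n_replicates)) {
    s <- seeds[r]
    fit <- NULL
    tries <- 0L
    while (is.null(fit) && tries < 10L) {
      fit <- tryCatch(
        with_seed(s, kmeans(z, centers = K, iter.max = 100L, nstart = 1L)),
        error = function(e) NULL)
      if (is.null(fit) || any(fit$size == 0)) {
        message(sprintf("k-means replicate %d degenerated; re-seeding", r))
        s <- s + 1000003L
        tries <- tries + 1L
        if (!is.null(fit) && any(fit$size == 0)) fit <- NULL
      }
    }
    if (is.null(fit)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best)) stop("k-means failed in every replicate", call. = FALSE)
  network_partition(best$cluster, K, labs)
}

#' Convert a partition to (disjoint) network topographies
#'
#' @param p a [network_partition()].
#' @return a [topography_set()] with K pairwise-disjoint sets covering all
#'   regions; networks are named `KN1..KNK`.
#' @export
partition_to_topographies <- function(p) {
  stopifnot(inherits(p, "network_partition"))
  memb <- outer(p$labels, seq_len(p$K), `==`)
  topography_set(memb, network_labels = paste0("KN", seq_len(p$K)),
                 region_labels = p$region_labels)
}

#' Write a partition as a two-column TSV (region label, network index)
#'
#' @param p a [network_partition()].
#' @param path file path.
#' @export
write_partition_tsv <- function(p, path) {
  write.table(data.frame(region = p$region_labels, network = p$labels),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
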