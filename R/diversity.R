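# Membership diversity: how many networks each region belongs to, and how
# far its assignment vector lies from the uniform distribution over K
# networks (Kullback-Leibler divergence in nats, then min-max scaled so
# single-network regions sit at 1 and the most uniformly assigned region at
# 0).

#' Number of assigned networks in one assignment row
#'
#' @param row nonnegative weight vector.
#' @return count of strictly positive entries.
#' @export
count_networks <- function(row) {
  if (all(row == 0)) stop("all-zero assignment rows are invalid", call. = FALSE)
  sum(row > 0)
}

#' Kullback-Leibler divergence of an assignment row from uniform
#'
#' The row is renormalised to sum exactly 1, then
#' \eqn{D_{KL}(p \,\|\, u) = \sum_k p_k \log(p_k K)} in nats, with
#' \eqn{0 \log 0 = 0}. Ranges from 0 (uniform row) to \eqn{\log K}
#' (single-network row).
#'
#' @param row nonnegative weight vector of length K.
#' @param K number of networks (default `length(row)`).
#' @return divergence in nats.
#' @export
kl_to_uniform <- function(row, K = length(row)) {
  if (all(row == 0)) stop("all-zero assignment rows are invalid", call. = FALSE)
  p <- row / sum(row)
  pos <- p > 0
  sum(p[pos] * log(p[pos] * K))
}

#' Min-max scale divergence values to \[0, 1\]
#'
#' `(v - min) / (max - min)`. When at least one single-network region is
#' present the maximum equals `log(K)` and those regions scale to exactly 1;
#' if no value reaches `log(K)` the observed maximum is used and a warning
#' is raised. Constant input is an error.
#'
#' @param values vector of KL divergences (nats).
#' @param K number of networks; when supplied, checks the `log(K)` anchor.
#' @return scaled values in \[0, 1\].
#' @export
minmax_scale <- function(values, K = NULL) {
  if (length(values) < 2) stop("need at least two values to scale", call. = FALSE)
  lo <- min(values)
  hi <- max(values)
  if (hi - lo == 0) stop("constant input cannot be min-max scaled", call. = FALSE)
  if (!is.null(K) && abs(hi - log(K)) > 1e-9) {
    warning(sprintf("no single-network region present (max %.4f < log(K) = %.4f); scaling by the observed maximum",
                    hi, log(K)), call. = FALSE)
  }
  (values - lo) / (hi - lo)
}

#' Per-region membership-diversity profile
#'
#' For every region: the number of assigned networks, the KL divergence of
#' its assignment row from uniform (nats), and the min-max scaled divergence
#' (scaled jointly across all regions). Also attaches a 100-bin histogram of
#' the scaled values and the mean scaled divergence per assigned-network
#' count.
#'
#' @param a an [assignment_matrix()].
#' @param n_bins histogram bins over \[0, 1\] (default 100).
#' @return object of class `diversity_profile`: list with `table`
#'   (data.frame region, n_assigned, kl_nats, dkl_scaled), `histogram`
#'   (data.frame bin_lo, bin_hi, count) and `group_means` (data.frame
#'   n_assigned, mean_dkl, n_regions).
#' @export
diversity_profile <- function(a, n_bins = 100L) {
  stopifnot(inherits(a, "assignment_matrix"))
  K <- ncol(a$weights)
  n_assigned <- apply(a$weights, 1, count_networks)
  kl <- apply(a$weights, 1, kl_to_uniform, K = K)
  dkl <- minmax_scale(kl, K = K)
  tab <- data.frame(region = a$region_labels, n_assigned = n_assigned,
                    kl_nats = kl, dkl_scaled = dkl, row.names = NULL)
  edges <- seq(0, 1, length.out = n_bins + 1L)
  counts <- tabulate(pmin(findInterval(dkl, edges, rightmost.closed = TRUE),
                          n_bins), n_bins)
  hist <- data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                     count = counts)
  gm <- aggregate(dkl ~ n_assigned, data = data.frame(n_assigned, dkl), FUN = mean)
  group_means <- data.frame(n_assigned = gm$n_assigned, mean_dkl = gm$dkl,
                            n_regions = as.vector(table(n_assigned)[as.character(gm$n_assigned)]))
  structure(list(table = tab, histogram = hist, group_means = group_means),
            class = "diversity_profile")
}

#' @export
print.diversity_profile <- function(x, ...) {
  cat(sprintf("Membership diversity over %d regions:\n", nrow(x$table)))
  cat(sprintf("  regions at scaled DKL = 1 (single network): %d\n",
              sum(x$table$dkl_scaled == 1)))
  cat("  mean scaled DKL by number of assigned networks:\n")
  for (i in seq_len(nrow(x$group_means))) {
    cat(sprintf("    %d network(s): %.3f  (n = %d)\n",
                x$group_means$n_assigned[i], x$group_means$mean_dkl[i],
                x$group_means$n_regions[i]))
  }
  invisible(x)
}

#' Calibrate the min-max scaling minimum from reference rows
#'
#' When only a handful of assignment rows and their published scaled-DKL
#' values are available (rather than the full matrix), the scaling's lower
#' anchor (the dataset-minimum KL, in nats) can be recovered from rows with
#' known scaled values: each calibration row gives
#' `m = (kl - s * log(K)) / (1 - s)`; the mean across rows is returned.
#'
#' @param weights matrix (rows = calibration regions) of assignment weights.
#' @param scaled published scaled DKL value per calibration row.
#' @param K number of networks.
#' @return fitted minimum KL (nats).
#' @export
calibrate_scaling <- function(weights, scaled, K = ncol(weights)) {
  weights <- rbind(weights)
  if (nrow(weights) != length(scaled)) {
    stop("one scaled value per calibration row is required", call. = FALSE)
  }
  if (any(scaled >= 1)) {
    stop("calibration rows must have scaled DKL < 1 (multi-network rows)",
         call. = FALSE)
  }
  kl <- apply(weights, 1, kl_to_uniform, K = K)
  mean((kl - scaled * log(K)) / (1 - scaled))
}

#' Scale KL values with an explicit lower anchor
#'
#' `(kl - minimum) / (log(K) - minimum)` — the affine map whose upper anchor
#' is the single-network divergence `log(K)` and whose lower anchor is a
#' known or fitted dataset-minimum KL (see [calibrate_scaling()]).
#'
#' @param kl KL divergences in nats.
#' @param minimum lower anchor (nats).
#' @param K number of networks.
#' @return scaled values.
#' @export
scale_with_anchor <- function(kl, minimum, K) {
  (kl - minimum) / (log(K) - minimum)
}

#' Region lookup table
#'
#' Maps region labels to 3-D centroid coordinates so point coordinates from
#' the literature can be matched to regions of the parcellation in use.
#'
#' @param region labels (unique).
#' @param x,y,z centroid coordinates (mm).
#' @return data.frame of class `region_lookup`.
#' @export
region_lookup <- function(region, x, y, z) {
  if (anyDuplicated(region)) stop("lookup labels must be unique", call. = FALSE)
  structure(data.frame(region = as.character(region), x = x, y = y, z = z),
            class = c("region_lookup", "data.frame"))
}

#' Extract assignment vectors for named coordinates
#'
#' Matches each query coordinate to its nearest region centroid (Euclidean
#' distance; ties broken by label order) and reports that region's
#' assignment weights and scaled divergence — the per-region worked-example
#' report for seed coordinates of interest.
#'
#' @param a an [assignment_matrix()].
#' @param lookup a [region_lookup()] covering `a`'s regions.
#' @param coordinates data.frame with columns `name`, `x`, `y`, `z`.
#' @param max_radius coordinates farther than this from every centroid are an
#'   error (default `Inf`).
#' @param dkl_scaled optional precomputed scaled divergences named by region;
#'   defaults to the jointly scaled values from [diversity_profile()].
#' @return data.frame: name, region, distance, the K weights, dkl_scaled.
#' @export
extract_named_regions <- function(a, lookup, coordinates, max_radius = Inf,
                                  dkl_scaled = NULL) {
  stopifnot(inherits(a, "assignment_matrix"))
  missing_regions <- setdiff(lookup$region, a$region_labels)
  if (length(missing_regions) > 0) {
    stop(sprintf("lookup regions absent from the assignment: %s",
                 paste(missing_regions, collapse = ", ")), call. = FALSE)
  }
  if (is.null(dkl_scaled)) {
    prof <- diversity_profile(a)
    dkl_scaled <- setNames(prof$table$dkl_scaled, prof$table$region)
  }
  cent <- as.matrix(lookup[, c("x", "y", "z")])
  rows <- lapply(seq_len(nrow(coordinates)), function(i) {
    q <- as.numeric(coordinates[i, c("x", "y", "z")])
    d <- sqrt(colSums((t(cent) - q)^2))
    j <- order(d, lookup$region)[1]          # ties by label order
    if (d[j] > max_radius) {
      stop(sprintf("coordinate '%s' is %.1f mm from the nearest centroid (max_radius %.1f)",
                   coordinates$name[i], d[j], max_radius), call. = FALSE)
    }
    reg <- lookup$region[j]
    w <- a$weights[reg, , drop = FALSE]
    cbind(data.frame(name = coordinates$name[i], region = reg,
                     distance = d[j]),
          as.data.frame(w, row.names = NULL),
          data.frame(dkl_scaled = unname(dkl_scaled[reg])))
  })
  do.call(rbind, rows)
}

#' Render an assignment report with zero weights as dashes
#'
#' @param report data.frame from [extract_named_regions()] (or any frame
#'   with numeric weight columns).
#' @param weight_cols columns to render; default those named like networks.
#' @param digits decimals.
#' @return data.frame of characters with `"–"` in place of zeros.
#' @export
render_assignment_report <- function(report, weight_cols = NULL, digits = 3) {
  if (is.null(weight_cols)) {
    weight_cols <- grep("^(ON|N)[0-9]+$", names(report), value = TRUE)
  }
  out <- report
  for (cn in weight_cols) {
    v <- report[[cn]]
    out[[cn]] <- ifelse(v == 0, "–", formatC(v, digits = digits, format = "f"))
  }
  out
}

#' Published dual-networks seed-region assignment table
#'
#' The 16 frontoparietal (FP) and cingulo-opercular (CO) seed regions of the
#' dual-networks model of cognitive control, with their published MNI
#' coordinates, overlapping-network assignment weights over K = 7 networks,
#' and published scaled DKL values. Zero weights are stored as 0. Used as
#' the worked example for the membership-diversity statistics.
#'
#' @return data.frame: network (FP/CO), region, x, y, z, ON1..ON7,
#'   dkl_scaled_published.
#' @export
dual_networks_table <- function() {
  path <- system.file("extdata", "dualnet_regions.tsv", package = "overnet")
  df <- read.delim(path, check.names = FALSE)
  df
}
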