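# Assortative mixed-membership stochastic block model (a-MMSB), fitted by
# batch coordinate-ascent variational inference.
#
# Model: each region i holds a membership vector theta_i ~ Dirichlet(alpha)
# over K networks. For an unordered pair (i, j), each endpoint draws a
# network indicator from its membership; the edge appears with probability
# beta_k when both indicators agree on network k and epsilon otherwise, so
# the marginal edge probability is
#     sum_k theta_ik theta_jk beta_k + (1 - sum_k theta_ik theta_jk) epsilon
# with epsilon << beta_k (assortativity). Overlap arises wherever a region
# holds mass on several networks.
#
# Variational family: Dirichlet(gamma_i) per region, one joint categorical
# over the (z_{i->j}, z_{j->i}) indicator pair per unordered pair, and Beta
# posteriors for beta_k and epsilon. Because the indicator-pair distribution
# is the exact tilted conditional given the current Dirichlet and Beta
# expectations, its normaliser, marginals and agreement weights all have
# closed forms computed in O(K) per pair, and every sweep
# (pairs -> gamma -> beta, epsilon) is exact coordinate ascent, so the
# evidence lower bound (ELBO) is non-decreasing across sweeps.

#' Configuration for the mixed-membership fit
#'
#' @param n_networks number of networks K (default 7).
#' @param seed integer seed for the variational initialization.
#' @param max_iterations maximum coordinate-ascent sweeps.
#' @param elbo_tolerance relative ELBO change declaring convergence.
#' @param dirichlet_alpha membership prior concentration; the sparse default
#'   (0.01) favours membership rows supported by the graph and keeps the
#'   posterior residual mass on unsupported networks (about `alpha/(n-1)`)
#'   well below `zero_floor` at any fixture size.
#' @param strength_prior list with Beta prior shape pairs `beta` (within-
#'   network strength) and `epsilon` (background); the defaults encode weak
#'   assortativity.
#' @param zero_floor posterior-mean weight below which an entry is set to
#'   exact 0 before row renormalization, in \[0, 0.05\].
#' @param evidence_level significance level of the edge-support test used to
#'   sparsify membership rows: a claimed membership in network k is kept only
#'   if the node's edge count into k's core (weights >= 0.3) exceeds the
#'   `1 - evidence_level` binomial quantile expected from the fitted
#'   background rate alone. Guards against background edges masquerading as
#'   weak memberships, which the variational point estimate cannot tell
#'   apart. A row's dominant network is never pruned. Set to 0 to disable.
#' @param n_restarts independent seeded initializations; the fit with the
#'   best final ELBO is kept (default 1, a single round of assignment).
#' @param init_method `"spectral"` (default): k-means on the leading
#'   eigenvectors of the degree-regularised adjacency, softened towards
#'   uniform — batch coordinate ascent at K > 3 reliably freezes into poor
#'   local optima from flat random draws, and a spectral start lands in the
#'   high-ELBO basin; `"random"`: seeded symmetric Dirichlet rows.
#' @param init_weights optional n x K matrix of initial membership rows
#'   (overrides `init_method`; used e.g. for equivariance checks).
#' @param init_concentration symmetric Dirichlet concentration of the random
#'   initial membership rows (`init_method = "random"`).
#' @param init_scale equivalent sample size of the initialization: initial
#'   `gamma = alpha + init_scale * theta0`; default `n - 1` (one full data
#'   pass worth of confidence).
#' @return object of class `fit_config`.
#' @export
fit_config <- function(n_networks = 7L, seed = 1L, max_iterations = 1000L,
                       elbo_tolerance = 1e-7, dirichlet_alpha = 0.01,
                       strength_prior = list(beta = c(2, 1), epsilon = c(1, 10)),
                       zero_floor = 1e-3, evidence_level = 1e-3,
                       n_restarts = 1L,
                       init_method = c("spectral", "random"),
                       init_weights = NULL, init_concentration = 1,
                       init_scale = NULL) {
  init_method <- match.arg(init_method)
  stopif_not_count(n_networks, "n_networks", 2L)
  if (zero_floor < 0 || zero_floor > 0.05) {
    stop("zero_floor must lie in [0, 0.05]", call. = FALSE)
  }
  structure(list(n_networks = as.integer(n_networks), seed = as.integer(seed),
                 max_iterations = as.integer(max_iterations),
                 elbo_tolerance = elbo_tolerance,
                 dirichlet_alpha = dirichlet_alpha,
                 strength_prior = strength_prior, zero_floor = zero_floor,
                 evidence_level = evidence_level,
                 n_restarts = as.integer(n_restarts),
                 init_method = init_method,
                 init_weights = init_weights,
                 init_concentration = init_concentration,
                 init_scale = init_scale),
            class = "fit_config")
}

#' Construct an assignment matrix
#'
#' Region x K membership weights: each row is nonnegative and sums to 1.
#'
#' @param weights region x K numeric matrix.
#' @param network_labels names of the K networks (default `ON1..ONK`).
#' @param region_labels region names.
#' @return object of class `assignment_matrix`.
#' @export
assignment_matrix <- function(weights, network_labels = NULL,
                              region_labels = rownames(weights)) {
  weights <- as.matrix(weights)
  if (any(weights < 0)) stop("weights must be nonnegative", call. = FALSE)
  rs <- rowSums(weights)
  if (any(rs == 0)) stop("all-zero assignment rows are invalid", call. = FALSE)
  if (any(abs(rs - 1) > 1e-6)) {
    stop("assignment rows must sum to 1 (tolerance 1e-6)", call. = FALSE)
  }
  if (is.null(network_labels)) network_labels <- paste0("ON", seq_len(ncol(weights)))
  if (is.null(region_labels)) region_labels <- default_region_labels(nrow(weights))
  dimnames(weights) <- list(region_labels, network_labels)
  structure(list(weights = weights, network_labels = network_labels,
                 region_labels = region_labels),
            class = "assignment_matrix")
}

#' @export
print.assignment_matrix <- function(x, ...) {
  nn <- rowSums(x$weights > 0)
  cat(sprintf("Assignment matrix: %d regions x %d networks\n",
              nrow(x$weights), ncol(x$weights)))
  cat(sprintf("  multi-network regions: %d (%.0f%%); max networks per region: %d\n",
              sum(nn > 1), 100 * mean(nn > 1), max(nn)))
  if (!is.null(attr(x, "converged"))) {
    cat(sprintf("  fit: %s after %d iterations (ELBO %.2f)\n",
                if (attr(x, "converged")) "converged" else "NOT converged",
                attr(x, "n_iterations"), attr(x, "elbo")))
  }
  invisible(x)
}

#' Construct a set of K named binary network topographies
#'
#' @param membership logical (or 0/1) region x K matrix; `TRUE` marks the
#'   region as a member of the network. Sets may overlap.
#' @param network_labels names of the K networks.
#' @param region_labels region names.
#' @return object of class `topography_set`.
#' @export
topography_set <- function(membership, network_labels = colnames(membership),
                           region_labels = rownames(membership)) {
  membership <- as.matrix(membership)
  storage.mode(membership) <- "logical"
  if (is.null(network_labels)) network_labels <- paste0("ON", seq_len(ncol(membership)))
  if (is.null(region_labels)) region_labels <- default_region_labels(nrow(membership))
  dimnames(membership) <- list(region_labels, network_labels)
  structure(list(membership = membership, network_labels = network_labels,
                 region_labels = region_labels),
            class = "topography_set")
}

#' @export
print.topography_set <- function(x, ...) {
  cat(sprintf("Topography set: %d networks over %d regions (sizes: %s)\n",
              ncol(x$membership), nrow(x$membership),
              paste(colSums(x$membership), collapse = ", ")))
  invisible(x)
}

#' Fit the assortative mixed-membership SBM to a binary connectome
#'
#' Batch coordinate-ascent variational inference; returns the posterior-mean
#' membership rows, floored at `config$zero_floor` and renormalised.
#' Deterministic given `(graph, config)`.
#'
#' Attributes of the result: `converged`, `n_iterations`, `elbo` (final),
#' `elbo_trace` (per sweep, for the kept restart), `beta` and `epsilon`
#' (posterior-mean strengths), `elbo_delta` (last change).
#'
#' @param graph a [binary_connectome()]; every node must have degree >= 1
#'   (degree-0 nodes are exclusions the caller must handle; the error lists
#'   them).
#' @param config a [fit_config()].
#' @return an [assignment_matrix()] with fit diagnostics attached.
#' @export
fit_ammsb <- function(graph, config = fit_config()) {
  stopifnot(inherits(graph, "binary_connectome"), inherits(config, "fit_config"))
  Y <- graph$adjacency
  storage.mode(Y) <- "double"
  n <- nrow(Y)
  K <- config$n_networks
  if (n < K) stop("graph needs at least K nodes", call. = FALSE)
  deg <- rowSums(Y)
  if (any(deg == 0)) {
    stop(sprintf("degree-0 nodes must be excluded before fitting: %s",
                 paste(graph$region_labels[deg == 0], collapse = ", ")),
         call. = FALSE)
  }
  seeds <- split_seed(config$seed, config$n_restarts)
  best <- NULL
  for (r in seq_len(config$n_restarts)) {
    fit <- ammsb_cavi(Y, K, config, seeds[r])
    if (is.null(best) || fit$elbo > best$elbo) best <- fit
  }
  theta <- best$gamma / rowSums(best$gamma)
  theta[theta < config$zero_floor] <- 0
  if (config$evidence_level > 0) {
    # edge-support test: a membership claim must have more edges into the
    # network's core than the fitted background rate explains
    core <- theta >= 0.3
    support <- Y %*% core                      # n x K edge counts into cores
    thr <- vapply(colSums(core), function(sz) {
      max(stats::qbinom(1 - config$evidence_level, sz, best$epsilon) + 1L, 1L)
    }, numeric(1))
    dominant <- cbind(seq_len(n), max.col(theta, ties.method = "first"))
    keep_dom <- theta[dominant]
    theta[sweep(support, 2, thr, `<`)] <- 0
    theta[dominant] <- keep_dom                # the dominant network stays
  }
  theta <- theta / rowSums(theta)
  out <- assignment_matrix(theta, region_labels = graph$region_labels)
  attr(out, "converged") <- best$converged
  attr(out, "n_iterations") <- best$n_iterations
  attr(out, "elbo") <- best$elbo
  attr(out, "elbo_trace") <- best$elbo_trace
  attr(out, "elbo_delta") <- best$elbo_delta
  attr(out, "beta") <- best$beta
  attr(out, "epsilon") <- best$epsilon
  if (!best$converged) {
    warning(sprintf("a-MMSB fit did not converge in %d iterations (last relative ELBO change %.3g)",
                    config$max_iterations, best$elbo_delta), call. = FALSE)
  }
  out
}

# One CAVI run from one seeded initialization.
#' @noRd
ammsb_cavi <- function(Y, K, config, seed) {
  n <- nrow(Y)
  a <- config$dirichlet_alpha
  bp <- config$strength_prior$beta
  ep <- config$strength_prior$epsilon
  up <- upper.tri(Y)
  Yup <- Y[up]
  edge <- Y == 1
  diag(edge) <- FALSE

  theta0 <- config$init_weights
  if (is.null(theta0)) {
    theta0 <- switch(config$init_method,
      spectral = spectral_init(Y, K, seed),
      random = with_seed(seed, {
        g <- matrix(rgamma(n * K, shape = config$init_concentration), n, K)
        g / rowSums(g)
      }))
  } else {
    theta0 <- theta0 / rowSums(theta0)
  }
  init_scale <- config$init_scale
  if (is.null(init_scale)) init_scale <- n - 1
  gam <- a + init_scale * theta0
  ab <- cbind(rep(bp[1], K), rep(bp[2], K))   # q(beta_k) Beta shapes
  eab <- ep                                    # q(epsilon) Beta shapes

  elbo_trace <- numeric(0)
  elbo_prev <- -Inf
  converged <- FALSE
  delta <- NA_real_
  iter <- 0L

  for (iter in seq_len(config$max_iterations)) {
    Eltheta <- digamma(gam) - digamma(rowSums(gam))
    Elb <- digamma(ab[, 1]) - digamma(ab[, 1] + ab[, 2])
    El1b <- digamma(ab[, 2]) - digamma(ab[, 1] + ab[, 2])
    Ele <- digamma(eab[1]) - digamma(eab[1] + eab[2])
    El1e <- digamma(eab[2]) - digamma(eab[1] + eab[2])

    # exact indicator-pair update, in closed form:
    # q(z_i=k, z_j=l | pair ij) propto a_ik a_jl * C_kl(y), with
    # C_kk = exp(E log beta terms), C_{k!=l} = exp(E log eps terms)
    A <- exp(Eltheta)                 # n x K
    S <- rowSums(A)
    B1 <- exp(Elb); B0 <- exp(El1b)
    e1 <- exp(Ele); e0 <- exp(El1e)
    G <- tcrossprod(A)                             # sum_k a_ik a_jk
    H <- tcrossprod(A %*% diag(B0, K), A)          # non-edge agreement mass
    H[edge] <- tcrossprod(A %*% diag(B1, K), A)[edge]
    Ey <- matrix(e0, n, n); Ey[edge] <- e1
    Z <- Ey * (outer(S, S) - G) + H                # pair normalisers

    # ELBO at (q_z just updated; gamma/beta/epsilon it was computed from).
    # The pair term collapses to sum log Z because q_z is the exact tilt of
    # the pair factors under the current expectations.
    theta_term <- n * (lgamma(K * a) - K * lgamma(a)) +
      sum((a - gam) * Eltheta) -
      sum(lgamma(rowSums(gam))) + sum(lgamma(gam))
    beta_term <- sum(-lbeta(bp[1], bp[2]) + lbeta(ab[, 1], ab[, 2]) +
                       (bp[1] - ab[, 1]) * Elb + (bp[2] - ab[, 2]) * El1b)
    eps_term <- -lbeta(ep[1], ep[2]) + lbeta(eab[1], eab[2]) +
      (ep[1] - eab[1]) * Ele + (ep[2] - eab[2]) * El1e
    elbo <- sum(log(Z[up])) + theta_term + beta_term + eps_term
    elbo_trace <- c(elbo_trace, elbo)

    # gamma and strength updates from the pair marginals
    agree_up <- numeric(length(Yup))
    for (k in seq_len(K)) {
      Bky <- matrix(B0[k], n, n); Bky[edge] <- B1[k]
      ajk <- matrix(A[, k], n, n, byrow = TRUE)
      Mk <- matrix(A[, k], n, n) *
        (Ey * (matrix(S, n, n, byrow = TRUE) - ajk) + ajk * Bky) / Z
      diag(Mk) <- 0
      gam[, k] <- a + rowSums(Mk)
      Wk <- (tcrossprod(A[, k]) * Bky / Z)[up]
      ab[k, 1] <- bp[1] + sum(Wk * Yup)
      ab[k, 2] <- bp[2] + sum(Wk * (1 - Yup))
      agree_up <- agree_up + Wk
    }
    wo <- 1 - agree_up
    eab <- c(ep[1] + sum(wo * Yup), ep[2] + sum(wo * (1 - Yup)))
    delta <- (elbo - elbo_prev) / (abs(elbo) + 1e-12)
    if (iter > 1 && abs(delta) < config$elbo_tolerance) {
      converged <- TRUE
      break
    }
    elbo_prev <- elbo
  }

  list(gamma = gam,
       beta = ab[, 1] / rowSums(ab),
       epsilon = eab[1] / sum(eab),
       elbo = elbo_trace[length(elbo_trace)],
       elbo_trace = elbo_trace, elbo_delta = delta,
       converged = converged, n_iterations = iter)
}

# Spectral initialization: k-means on the row-normalised leading eigenvectors
# of the degree-regularised adjacency, softened towards uniform.
#' @noRd
spectral_init <- function(Y, K, seed, soft = 0.15) {
  n <- nrow(Y)
  d <- rowSums(Y)
  tau <- mean(d)
  L <- (Y + tau / n) / sqrt(outer(d + tau, d + tau))
  U <- eigen(L, symmetric = TRUE)$vectors[, seq_len(K), drop = FALSE]
  U <- U / pmax(sqrt(rowSums(U^2)), 1e-12)
  cl <- with_seed(seed, kmeans(U, K, nstart = 10, iter.max = 50)$cluster)
  cl <- match(cl, unique(cl))   # canonical labels: order of first occurrence
  (1 - soft) * outer(cl, seq_len(K), `==`) + soft / K
}

#' Binarize an assignment matrix into overlapping topographies
#'
#' Every strictly positive weight marks membership, with no further
#' thresholding, so overlap is preserved regardless of weight magnitude.
#'
#' @param a an [assignment_matrix()].
#' @return a [topography_set()].
#' @export
binarize_assignment <- function(a) {
  stopifnot(inherits(a, "assignment_matrix"))
  topography_set(a$weights > 0, network_labels = a$network_labels,
                 region_labels = a$region_labels)
}

#' Write / read an assignment matrix as TSV
#'
#' @param a an [assignment_matrix()].
#' @param path file path.
#' @export
write_assignment_tsv <- function(a, path) {
  df <- data.frame(region = a$region_labels, a$weights, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_assignment_tsv
#' @export
read_assignment_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  w <- as.matrix(df[, -1, drop = FALSE])
  assignment_matrix(w, network_labels = colnames(w),
                    region_labels = as.character(df[[1]]))
}

#' Write a topography set as a membership indicator table
#'
#' @param x a [topography_set()].
#' @param path file path.
#' @export
write_topographies_tsv <- function(x, path) {
  df <- data.frame(region = x$region_labels, x$membership + 0L,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
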