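# Independent oracles and tiny fixture builders shared across tests.

# all permutations of 1..n as a list, built by simple recursion —
# independent of the package's internal enumeration
perms_list <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in perms_list(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# brute-force optimal assignment: enumerate all K! pairings
brute_force_matching <- function(D) {
  K <- nrow(D)
  best <- -Inf
  best_p <- NULL
  for (p in perms_list(K)) {
    tot <- sum(D[cbind(seq_len(K), p)])
    if (tot > best + 1e-12) {
      best <- tot
      best_p <- p
    }
  }
  list(total = best, perm = best_p)
}

# direct Dice on label vectors
dice_oracle <- function(a, b) 2 * length(intersect(a, b)) / (length(a) + length(b))

# two disjoint cliques of size m each, as a binary_connectome
two_cliques <- function(m = 10L) {
  n <- 2L * m
  adj <- matrix(0L, n, n)
  adj[seq_len(m), seq_len(m)] <- 1L
  adj[(m + 1):n, (m + 1):n] <- 1L
  diag(adj) <- 0L
  binary_connectome(adj)
}

# a small deterministic timeseries subject: block-structured signals
block_subject <- function(id, n_per_block = 4L, n_time = 60L, noise = 0.1,
                          seed = 1L) {
  set.seed(seed)
  s1 <- rnorm(n_time)
  s2 <- rnorm(n_time)
  dat <- rbind(
    matrix(rep(s1, n_per_block), nrow = n_per_block, byrow = TRUE),
    matrix(rep(s2, n_per_block), nrow = n_per_block, byrow = TRUE)
  ) + matrix(rnorm(2 * n_per_block * n_time, sd = noise), 2 * n_per_block)
  subject_timeseries(id, dat)
}

# random overlapping cover: each region joins network k independently with
# probability p_k; per-network probabilities drawn from U(0.2, 0.7) unless
# fixed, so set sizes vary and the Dice null has a rich support
random_cover <- function(n, K, p = NULL, labels = sprintf("R%03d", seq_len(n))) {
  repeat {
    pk <- if (is.null(p)) runif(K, 0.2, 0.7) else rep_len(p, K)
    m <- sapply(pk, function(pp) runif(n) < pp)
    if (all(colSums(m) > 0)) break
  }
  topography_set(m, region_labels = labels)
}
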