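# Topographical similarity between two sets of K networks: Dice matrix,
# permutation-test significance with Bonferroni control, and optimal
# homologue pairing.

#' Dice coefficient between two region sets
#'
#' \eqn{2|a \cap b| / (|a| + |b|)} over a shared region universe.
#'
#' @param a,b logical membership vectors over the same regions, or character
#'   vectors of region labels.
#' @param universe region labels (required when `a`, `b` are label vectors).
#' @return similarity in \[0, 1\]. Two empty sets are an error.
#' @export
dice <- function(a, b, universe = NULL) {
  if (is.character(a) || is.character(b)) {
    if (is.null(universe)) stop("label-vector sets need a region universe", call. = FALSE)
    a <- universe %in% a
    b <- universe %in% b
  }
  if (length(a) != length(b)) stop("sets must share one region universe", call. = FALSE)
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) stop("Dice is undefined for two empty sets", call. = FALSE)
  2 * sum(a & b) / (sa + sb)
}

# K_A x K_B Dice matrix from two logical membership matrices.
#' @noRd
dice_matrix <- function(Ma, Mb) {
  inter <- crossprod(Ma, Mb)
  sizes <- outer(colSums(Ma), colSums(Mb), `+`)
  if (any(sizes == 0)) stop("Dice is undefined for two empty sets", call. = FALSE)
  2 * inter / sizes
}

#' Bonferroni-corrected per-comparison significance level
#'
#' @param alpha_fw family-wise error rate in (0, 1).
#' @param n_comparisons number of simultaneous comparisons.
#' @return `alpha_fw / n_comparisons`.
#' @export
bonferroni_alpha <- function(alpha_fw = 0.05, n_comparisons = 49L) {
  if (!is.numeric(alpha_fw) || alpha_fw <= 0 || alpha_fw >= 1) {
    stop("alpha_fw must lie in (0, 1)", call. = FALSE)
  }
  stopif_not_count(n_comparisons, "n_comparisons", 1L)
  alpha_fw / n_comparisons
}

#' Permutation test of Dice similarity between two topography sets
#'
#' The observed K_A x K_B Dice matrix is referred to a null built by
#' shuffling set B's region labels: each iteration applies one region
#' permutation simultaneously to all K of B's networks, preserving B's
#' overlap structure under the null. P-values use the plus-one correction
#' `p = (#{null >= observed} + 1) / (n_iter + 1)`.
#'
#' @param setA,setB [topography_set()]s over one region universe.
#' @param n_iter number of permutations (>= 100), or `"exhaustive"` to
#'   enumerate all `n!` region permutations (universes of <= 8 regions).
#' @param seed integer seed.
#' @param alpha_fw family-wise alpha; the per-cell level is
#'   `bonferroni_alpha(alpha_fw, K_A * K_B)`.
#' @param independent_shuffle shuffle each of B's networks with its own
#'   permutation instead of one shared permutation (sensitivity variant;
#'   default `FALSE`).
#' @return object of class `similarity_result` with fields `dice`,
#'   `p_values`, `alpha_within`, `significant`, `n_permutations`.
#' @export
permutation_test <- function(setA, setB, n_iter = 10000L, seed = 1L,
                             alpha_fw = 0.05, independent_shuffle = FALSE) {
  stopifnot(inherits(setA, "topography_set"), inherits(setB, "topography_set"))
  if (!identical(setA$region_labels, setB$region_labels)) {
    stop(sprintf("region universes differ; symmetric difference: %s",
                 paste(union(setdiff(setA$region_labels, setB$region_labels),
                             setdiff(setB$region_labels, setA$region_labels)),
                       collapse = ", ")), call. = FALSE)
  }
  Ma <- setA$membership * 1
  Mb <- setB$membership * 1
  n <- nrow(Ma)
  obs <- dice_matrix(Ma, Mb)
  exhaustive <- identical(n_iter, "exhaustive")
  if (!exhaustive) stopif_not_count(n_iter, "n_iter", 100L)

  if (exhaustive) {
    if (n > 8) stop("exhaustive enumeration supported for <= 8 regions", call. = FALSE)
    perms <- all_permutations(n)
    count <- matrix(0, ncol(Ma), ncol(Mb))
    for (i in seq_len(nrow(perms))) {
      count <- count + (dice_matrix(Ma, Mb[perms[i, ], , drop = FALSE]) >=
                          obs - 1e-12)
    }
    n_used <- nrow(perms)
  } else {
    n_used <- as.integer(n_iter)
    count <- with_seed(seed, {
      cnt <- matrix(0, ncol(Ma), ncol(Mb))
      for (i in seq_len(n_used)) {
        Mp <- if (independent_shuffle) {
          apply(Mb, 2, function(col) col[sample.int(n)])
        } else {
          Mb[sample.int(n), , drop = FALSE]
        }
        cnt <- cnt + (dice_matrix(Ma, Mp) >= obs - 1e-12)
      }
      cnt
    })
  }
  p <- (count + 1) / (n_used + 1)
  aw <- bonferroni_alpha(alpha_fw, ncol(Ma) * ncol(Mb))
  dimnames(obs) <- dimnames(p) <- list(setA$network_labels, setB$network_labels)
  structure(list(dice = obs, p_values = p, alpha_within = aw,
                 significant = p <= aw, n_permutations = n_used),
            class = "similarity_result")
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf("Dice similarity: %d x %d networks, %d permutations, alpha_within = %.4g\n",
              nrow(x$dice), ncol(x$dice), x$n_permutations, x$alpha_within))
  cat(sprintf("  significant cells: %d / %d\n", sum(x$significant),
              length(x$significant)))
  invisible(x)
}

# all n! permutations of 1..n (n <= 8), rows = permutations
#' @noRd
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (pos in seq_len(n)) {
    blk <- cbind(sub[, seq_len(pos - 1), drop = FALSE], n,
                 sub[, seq(pos, n - 1)[seq_len(n - pos)], drop = FALSE])
    out[r + seq_len(nrow(sub)), ] <- blk
    r <- r + nrow(sub)
  }
  out
}

#' Optimal one-to-one homologue pairing between two network sets
#'
#' Finds the pairing of set-A networks to set-B networks maximizing the
#' total Dice coefficient (optimal assignment via exact dynamic programming
#' over column subsets). Ties are broken by lexicographic pair order. Under
#' `constraint = "significant"`, nonsignificant cells are forbidden and an
#' infeasible pairing is an error naming the unmatched networks.
#'
#' @param dice K x K Dice matrix, or a `similarity_result`.
#' @param constraint `"all"` (default) or `"significant"`.
#' @param significant logical K x K mask; taken from the `similarity_result`
#'   when one is supplied.
#' @return object of class `homologue_map` with `pairs` (data.frame of
#'   a, b, dice) and `total_dice`.
#' @export
match_homologues <- function(dice, constraint = c("all", "significant"),
                             significant = NULL) {
  constraint <- match.arg(constraint)
  if (inherits(dice, "similarity_result")) {
    if (is.null(significant)) significant <- dice$significant
    dice <- dice$dice
  }
  dice <- as.matrix(dice)
  K <- nrow(dice)
  if (ncol(dice) != K) stop("dice matrix must be square", call. = FALSE)
  if (K > 10) stop("homologue matching supports K <= 10", call. = FALSE)
  score <- dice
  if (constraint == "significant") {
    if (is.null(significant)) stop("significance mask required", call. = FALSE)
    score[!significant] <- -Inf
  }
  # f[i, mask+1]: best total for rows i..K using exactly the columns in mask
  nmask <- bitwShiftL(1L, K)
  f <- matrix(-Inf, K + 1L, nmask)
  f[K + 1L, 1L] <- 0
  for (i in K:1) {
    for (mask in seq_len(nmask) - 1L) {
      if (sum(bitwAnd(mask, bitwShiftL(1L, 0:(K - 1))) > 0) != K - i + 1L) next
      best <- -Inf
      for (j in seq_len(K)) {
        bit <- bitwShiftL(1L, j - 1L)
        if (bitwAnd(mask, bit) == 0) next
        v <- score[i, j] + f[i + 1L, bitwXor(mask, bit) + 1L]
        if (v > best) best <- v
      }
      f[i, mask + 1L] <- best
    }
  }
  total <- f[1L, nmask]
  if (!is.finite(total)) {
    bad <- rownames(dice) %||% paste0("A", seq_len(K))
    stop(sprintf("no feasible pairing under the significant-only constraint (networks: %s)",
                 paste(bad[apply(score, 1, function(r) all(!is.finite(r)))],
                       collapse = ", ")), call. = FALSE)
  }
  # lexicographic reconstruction: for each row pick the smallest column on an
  # optimal completion
  mask <- nmask - 1L
  bcol <- integer(K)
  for (i in seq_len(K)) {
    for (j in seq_len(K)) {
      bit <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(mask, bit) == 0) next
      v <- score[i, j] + f[i + 1L, bitwXor(mask, bit) + 1L]
      if (is.finite(v) && abs(v - f[i, mask + 1L]) < 1e-12) {
        bcol[i] <- j
        mask <- bitwXor(mask, bit)
        break
      }
    }
  }
  an <- rownames(dice) %||% paste0("A", seq_len(K))
  bn <- colnames(dice) %||% paste0("B", seq_len(K))
  pairs <- data.frame(a = an, b = bn[bcol],
                      a_index = seq_len(K), b_index = bcol,
                      dice = dice[cbind(seq_len(K), bcol)])
  structure(list(pairs = pairs, total_dice = sum(pairs$dice)),
            class = "homologue_map")
}

#' @export
print.homologue_map <- function(x, ...) {
  cat(sprintf("Homologue pairing (total Dice %.3f):\n", x$total_dice))
  for (i in seq_len(nrow(x$pairs))) {
    cat(sprintf("  %s <-> %s  (%.3f)\n", x$pairs$a[i], x$pairs$b[i], x$pairs$dice[i]))
  }
  invisible(x)
}

#' Compare a topography set to a reference set
#'
#' Convenience composition: permutation test (shuffling `setA`, the
#' locally-derived set, when the reference is external) followed by
#' homologue matching.
#'
#' @param setA locally derived [topography_set()]; its labels are shuffled
#'   to build the null.
#' @param reference reference [topography_set()] over the same regions.
#' @inheritParams permutation_test
#' @param constraint passed to [match_homologues()].
#' @return list with `similarity` (a `similarity_result`, rows = `setA`
#'   networks) and `homologues` (a `homologue_map`).
#' @export
compare_to_reference <- function(setA, reference, n_iter = 10000L, seed = 1L,
                                 alpha_fw = 0.05, constraint = "all") {
  res <- permutation_test(reference, setA, n_iter = n_iter, seed = seed,
                          alpha_fw = alpha_fw)
  sim <- structure(list(dice = t(res$dice), p_values = t(res$p_values),
                        alpha_within = res$alpha_within,
                        significant = t(res$significant),
                        n_permutations = res$n_permutations),
                   class = "similarity_result")
  list(similarity = sim,
       homologues = match_homologues(sim$dice, constraint = constraint,
                                     significant = sim$significant))
}

#' Render a similarity result as a report table
#'
#' Dice coefficients for significant cells, `"–"` elsewhere, mirroring the
#' conventional rendering of network-similarity tables.
#'
#' @param x a `similarity_result`.
#' @param digits decimals for the Dice values.
#' @return character data.frame.
#' @export
similarity_report <- function(x, digits = 2) {
  stopifnot(inherits(x, "similarity_result"))
  out <- matrix("–", nrow(x$dice), ncol(x$dice),
                dimnames = dimnames(x$dice))
  out[x$significant] <- formatC(x$dice[x$significant], digits = digits,
                                format = "f")
  as.data.frame(out)
}

#' Write a similarity comparison as TSV + JSON
#'
#' TSV: the [similarity_report()] table. JSON: full Dice and p-value
#' matrices, the significance mask, homologue pairs, and run metadata.
#'
#' @param x a `similarity_result`.
#' @param homologues optional `homologue_map`.
#' @param path_tsv,path_json output paths (either may be `NULL`).
#' @param seed seed recorded in the JSON.
#' @export
write_similarity <- function(x, homologues = NULL, path_tsv = NULL,
                             path_json = NULL, seed = NA_integer_) {
  if (!is.null(path_tsv)) {
    rep <- similarity_report(x)
    write.table(cbind(network = rownames(rep), rep), path_tsv, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(path_json)) {
    jsonlite::write_json(
      list(dice = x$dice, p_values = x$p_values,
           alpha_within = x$alpha_within,
           significant = x$significant * 1L,
           n_permutations = x$n_permutations, seed = seed,
           homologues = if (!is.null(homologues)) homologues$pairs,
           total_dice = if (!is.null(homologues)) homologues$total_dice),
      path_json, digits = NA, auto_unbox = TRUE)
  }
  invisible(x)
}
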