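# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded generators do not disturb the
#' caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive child seeds from a master seed
#'
#' All randomness in the package flows from one integer seed through this
#' splitting scheme: child seed i is the i-th draw from `sample.int(2^31 - 2)`
#' under the master seed. Deterministic, collision-unlikely, and keeps every
#' derived seed a valid 32-bit integer.
#'
#' @param seed master integer seed.
#' @param n number of child seeds.
#' @return integer vector of length `n`.
#' @export
split_seed <- function(seed, n) {
  with_seed(seed, sample.int(2147483646L, n))
}

stopif_not_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) || x < min) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
}

check_symmetric <- function(m, tol = 1e-9) {
  isTRUE(all(abs(m - t(m)) <= tol))
}

default_region_labels <- function(n) sprintf("R%03d", seq_len(n))

#' @noRd
match_labels <- function(a, b, what = "region labels") {
  if (!identical(a, b)) {
    bad <- which(a != b)[1]
    if (is.na(bad) || length(a) != length(b)) {
      stop(sprintf("%s differ in length (%d vs %d)", what, length(a), length(b)),
           call. = FALSE)
    }
    stop(sprintf("%s mismatch at position %d: '%s' vs '%s'",
                 what, bad, a[bad], b[bad]), call. = FALSE)
  }
  invisible(TRUE)
}
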