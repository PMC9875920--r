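# Group-connectome preprocessing chain.

test_that("fisher z correlation matches the closed form and zeroes the diagonal", {
  set.seed(1)
  t1 <- rnorm(200)
  t2 <- 0.5 * t1 + sqrt(1 - 0.25) * rnorm(200)
  ts <- subject_timeseries("s1", rbind(t1, t2, rnorm(200)))
  z <- fisher_z_correlation(ts)
  r12 <- cor(t1, t2)
  expect_equal(z[1, 2], atanh(r12), tolerance = 1e-12)
  expect_true(all(diag(z) == 0))
  expect_equal(z, t(z))

  # identical series: r = 1 clipped, atanh stays finite
  ts2 <- subject_timeseries("s2", rbind(t1, t1, t2))
  z2 <- fisher_z_correlation(ts2)
  expect_true(is.finite(z2[1, 2]))
  expect_equal(z2[1, 2], atanh(1 - 1e-7))

  # constant region series are exclusions, not NaNs
  ts3 <- subject_timeseries("s3", rbind(t1, rep(0, 200)))
  expect_error(fisher_z_correlation(ts3), "constant region series")
})

test_that("remove_negatives zeroes exactly the negative entries", {
  m <- matrix(c(0, -0.2, 0.5, -0.2, 0, 0.1, 0.5, 0.1, 0), 3)
  out <- remove_negatives(m)
  expect_equal(sum(out == 0), sum(m < 0) + 3)   # negatives plus the diagonal
  expect_equal(out[1, 3], 0.5)
  expect_equal(remove_negatives(abs(m)), abs(m))
})

test_that("proportional threshold retains the exact quota with deterministic ties", {
  # 5 regions, 10 pairs, fraction 0.1 -> exactly the single largest pair
  set.seed(2)
  m <- matrix(0, 5, 5)
  m[upper.tri(m)] <- runif(10)
  m <- m + t(m)
  g <- proportional_threshold(m, 0.1)
  expect_equal(sum(g$adjacency) / 2, 1)
  ij <- which(m == max(m), arr.ind = TRUE)[1, ]
  expect_equal(g$adjacency[ij[1], ij[2]], 1L)

  # all-equal positives: tie-break keeps the first ceil(f * P) pairs in
  # ascending (row, col) order
  me <- matrix(1, 5, 5); diag(me) <- 0
  ge <- proportional_threshold(me, 0.5)
  expect_equal(sum(ge$adjacency) / 2, ceiling(0.5 * 10))
  picked <- which(upper.tri(me) & ge$adjacency == 1, arr.ind = TRUE)
  ord <- order(picked[, 1], picked[, 2])
  expect_equal(picked[ord, , drop = FALSE][1, ], c(row = 1, col = 2))

  # fewer positives than quota: all retained, with a warning
  ms <- matrix(0, 5, 5); ms[1, 2] <- ms[2, 1] <- 0.4; ms[3, 4] <- ms[4, 3] <- 0.2
  expect_warning(gs <- proportional_threshold(ms, 0.5), "positive pairs")
  expect_equal(sum(gs$adjacency) / 2, 2)

  expect_error(proportional_threshold(m, 1.5), "fraction")
})

test_that("thresholding is idempotent on its own output", {
  set.seed(3)
  m <- matrix(0, 12, 12)
  m[upper.tri(m)] <- runif(66)
  m <- m + t(m)
  g1 <- proportional_threshold(m, 0.25)
  g2 <- proportional_threshold(g1$adjacency, 0.25)
  expect_identical(g1$adjacency, g2$adjacency)
})

test_that("group averaging records subject consistency", {
  adj1 <- matrix(0L, 3, 3); adj1[1, 2] <- adj1[2, 1] <- 1L
  adj2 <- matrix(0L, 3, 3)
  w <- group_average(list(binary_connectome(adj1), binary_connectome(adj2)))
  expect_equal(w$values[1, 2], 0.5)
  w1 <- group_average(list(binary_connectome(adj1)))
  expect_equal(w1$values, adj1, ignore_attr = TRUE)

  bad <- binary_connectome(adj2, region_labels = c("x", "y", "z"))
  expect_error(group_average(list(binary_connectome(adj1), bad)), "mismatch")
})

test_that("exclusions propagate as the union across subjects", {
  set.seed(4)
  mk <- function(id, dead) {
    x <- matrix(rnorm(10 * 60), 10)
    x[dead, ] <- 0
    subject_timeseries(id, x, sprintf("R%02d", 1:10))
  }
  px <- propagate_exclusions(list(mk("a", c(1, 2)), mk("b", c(2, 3))))
  expect_equal(px$excluded, c("R01", "R02", "R03"))
  expect_true(all(vapply(px$cohort, function(ts) nrow(ts$data) == 7, logical(1))))

  ok <- list(mk("a", integer(0)), mk("b", integer(0)))
  px2 <- propagate_exclusions(ok)
  expect_length(px2$excluded, 0)
  expect_equal(px2$cohort[[1]]$data, ok[[1]]$data)
})

test_that("group connectome has the exact target density and block structure", {
  theta <- rbind(matrix(rep(c(1, 0), each = 6), 6),
                 matrix(rep(c(0, 1), each = 6), 6))
  model <- planted_model(theta, noise_sd = 0.05)
  cohort <- generate_cohort(model, 4, 120, seed = 1)
  g <- build_group_connectome(cohort, 0.10)
  P <- choose(12, 2)
  expect_equal(g$density, ceiling(0.10 * P) / P)
  # strongest correlations are within blocks
  blocks <- rep(1:2, each = 6)
  ij <- which(upper.tri(g$adjacency) & g$adjacency == 1, arr.ind = TRUE)
  expect_true(all(blocks[ij[, 1]] == blocks[ij[, 2]]))
})

test_that("group connectome is invariant to subject order", {
  model <- sample_planted_model(30, 3, frac_multi = 0.2, seed = 5)
  cohort <- generate_cohort(model, 5, 80, seed = 6)
  g1 <- build_group_connectome(cohort)
  g2 <- build_group_connectome(rev(cohort))
  expect_identical(g1$adjacency, g2$adjacency)
})

test_that("disconnected-region exclusion iterates to a clean universe", {
  adj <- matrix(0L, 5, 5)
  adj[1, 2] <- adj[2, 1] <- 1L
  adj[3, 4] <- adj[4, 3] <- 1L   # region 5 isolated
  g <- binary_connectome(adj)
  dd <- drop_disconnected(g)
  expect_equal(dd$excluded, "R005")
  expect_equal(length(dd$connectomes[[1]]$region_labels), 4)
  # pairwise propagation can cascade: graph 2 isolates region 4, removing
  # which strands region 3's only edge in graph 1, so region 3 goes too
  adj2 <- matrix(0L, 5, 5)
  adj2[1, 2] <- adj2[2, 1] <- 1L
  adj2[3, 5] <- adj2[5, 3] <- 1L  # region 4 isolated in graph 2
  dd2 <- drop_disconnected(g, binary_connectome(adj2))
  expect_setequal(dd2$excluded, c("R003", "R004", "R005"))
  expect_identical(dd2$connectomes[[1]]$region_labels,
                   dd2$connectomes[[2]]$region_labels)
  expect_identical(dd2$connectomes[[1]]$region_labels, c("R001", "R002"))
})

test_that("matrix and edge-list files round-trip", {
  dir <- withr::local_tempdir()
  set.seed(7)
  m <- matrix(0, 6, 6)
  m[upper.tri(m)] <- runif(15)
  m <- m + t(m)
  dimnames(m) <- list(sprintf("R%d", 1:6), sprintf("R%d", 1:6))
  p <- file.path(dir, "m.tsv")
  write_matrix_tsv(m, p)
  expect_equal(read_matrix_tsv(p), m, tolerance = 1e-12)

  g <- proportional_threshold(m, 0.3)
  pe <- file.path(dir, "g.edges")
  write_edge_list(g, pe)
  g2 <- read_edge_list(pe, region_labels = g$region_labels)
  expect_identical(g2$adjacency, g$adjacency)
})
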