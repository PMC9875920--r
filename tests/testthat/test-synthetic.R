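# Planted overlapping-network generator.

test_that("sample_planted_model controls the multi-membership fraction", {
  m0 <- sample_planted_model(40, 4, frac_multi = 0, seed = 1)
  expect_true(all(rowSums(m0$membership > 0) == 1))
  expect_true(all(m0$membership %in% c(0, 1)))

  m1 <- sample_planted_model(50, 7, frac_multi = 1, seed = 2)
  nn <- rowSums(m1$membership > 0)
  expect_true(all(nn >= 2 & nn <= 4))

  m4 <- sample_planted_model(60, 6, frac_multi = 0.5, seed = 3)
  expect_equal(sum(rowSums(m4$membership > 0) > 1), 30)
  expect_true(all(abs(rowSums(m4$membership) - 1) < 1e-9))
})

test_that("generators are deterministic given the seed", {
  a <- sample_planted_model(100, 7, frac_multi = 0.4, seed = 1)
  b <- sample_planted_model(100, 7, frac_multi = 0.4, seed = 1)
  expect_identical(a$membership, b$membership)

  expect_identical(generate_graph(a, seed = 5)$adjacency,
                   generate_graph(a, seed = 5)$adjacency)

  ca <- generate_cohort(a, 3, 60, seed = 9)
  cb <- generate_cohort(a, 3, 60, seed = 9)
  expect_identical(lapply(ca, `[[`, "data"), lapply(cb, `[[`, "data"))
  # different subjects differ
  expect_false(identical(ca[[1]]$data, ca[[2]]$data))
})

test_that("planted model validation rejects bad arguments", {
  expect_error(sample_planted_model(5, 7), "n_regions")
  expect_error(sample_planted_model(20, 3, frac_multi = 1.2), "frac_multi")
  expect_error(planted_model(matrix(c(0.5, 0.4, 0.3, 0.7), 2), background = 0.01),
               "sum to 1")
  expect_error(sample_planted_model(20, 3, within_strength = 0.3, background = 0.5),
               "assortativity")
})

test_that("graph sampler follows the mixed-membership edge law", {
  # beta = eps: every pair has edge probability eps regardless of membership
  m <- sample_planted_model(40, 4, frac_multi = 0.5, seed = 1,
                            within_strength = 0.2, background = 0.199999)
  m$background <- 0.2
  m$within_strength <- rep(0.2, 4)
  P <- choose(40, 2)
  dens <- vapply(1:12, function(s) generate_graph(m, seed = s)$density, numeric(1))
  se <- sqrt(0.2 * 0.8 / (P * 12))
  expect_lt(abs(mean(dens) - 0.2), 3 * se)

  # two disjoint blocks at beta = 1, eps = 0: two complete components
  m2 <- planted_model(rbind(matrix(rep(c(1, 0), each = 5), 5),
                            matrix(rep(c(0, 1), each = 5), 5)),
                      within_strength = 1, background = 0)
  g2 <- generate_graph(m2, seed = 1)
  expect_equal(g2$adjacency[1:5, 1:5] + diag(5), matrix(1, 5, 5),
               ignore_attr = TRUE)
  expect_true(all(g2$adjacency[1:5, 6:10] == 0))
})

test_that("half-half region has equal expected degree into both blocks", {
  theta <- rbind(matrix(rep(c(1, 0), each = 12), 12),
                 matrix(rep(c(0, 1), each = 12), 12),
                 c(0.5, 0.5))
  m <- planted_model(theta, within_strength = 0.8, background = 0)
  degs <- sapply(1:150, function(s) {
    adj <- generate_graph(m, seed = s)$adjacency
    c(sum(adj[25, 1:12]), sum(adj[25, 13:24]))
  })
  # expected degree to each block: 12 * (0.5 * 0.8) = 4.8
  se <- sqrt(12 * 0.4 * 0.6 / 150)
  expect_lt(abs(mean(degs[1, ]) - 4.8), 3 * se)
  expect_lt(abs(mean(degs[2, ]) - 4.8), 3 * se)
})

test_that("cohort timeseries reflect the mixing model", {
  theta <- rbind(matrix(rep(c(1, 0), each = 5), 5),
                 matrix(rep(c(0, 1), each = 5), 5),
                 c(0.5, 0.5))
  m <- planted_model(theta, noise_sd = 0, signal_sd = 1)
  co <- generate_cohort(m, 2, 400, seed = 1)
  x <- co[[1]]$data
  # noiseless single-membership pairs in one network correlate at exactly 1
  expect_equal(cor(x[1, ], x[2, ]), 1, tolerance = 1e-12)
  # disjoint networks: near-zero correlation
  expect_lt(abs(cor(x[1, ], x[6, ])), 3 / sqrt(400))
  # the mixed region correlates positively with pure members of both
  expect_gt(cor(x[11, ], x[1, ]), 0.5)
  expect_gt(cor(x[11, ], x[6, ]), 0.5)
})

test_that("ground-truth cover matches the membership support", {
  m <- sample_planted_model(30, 3, frac_multi = 0, seed = 4)
  cov0 <- ground_truth_cover(m)
  expect_equal(sum(cov0$membership), 30)          # partition when no overlap
  expect_true(all(rowSums(cov0$membership) == 1))

  theta <- rbind(diag(2), c(0.5, 0.5))
  m2 <- planted_model(theta, within_strength = 0.9, background = 0.05)
  cov2 <- ground_truth_cover(m2)
  expect_equal(rowSums(cov2$membership), c(1, 1, 2), ignore_attr = TRUE)
  expect_true(all(rowSums(cov2$membership) >= 1))  # union covers all regions
})

test_that("dropout produces constant series and cohort IO round-trips", {
  m <- sample_planted_model(20, 2, frac_multi = 0, seed = 1)
  co <- generate_cohort(m, 3, 60, seed = 2, dropout = 0.15)
  any_zero <- any(vapply(co, function(ts) any(apply(ts$data, 1, sd) == 0),
                         logical(1)))
  expect_true(any_zero)

  dir <- withr::local_tempdir()
  write_cohort(co, dir, model = m)
  files <- sort(list.files(dir, pattern = "^sub.*tsv$", full.names = TRUE))
  rt <- read_cohort(files)
  expect_equal(rt[[1]]$data, co[[1]]$data, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(rt[[2]]$region_labels, co[[2]]$region_labels)
  expect_true(file.exists(file.path(dir, "model.json")))
})
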