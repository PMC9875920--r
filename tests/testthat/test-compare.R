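# Dice similarity, permutation testing, Bonferroni, homologue matching.

test_that("dice matches direct set counts", {
  u <- sprintf("R%d", 1:6)
  expect_equal(dice(c("R1", "R2", "R3"), c("R2", "R3", "R4"), u), 2 / 3,
               tolerance = 1e-12)
  expect_equal(dice(c("R1"), c("R1"), u), 1)
  expect_equal(dice(c("R1", "R2"), c("R3", "R4"), u), 0)
  expect_error(dice(logical(6), logical(6)), "empty")
  # against the label-set oracle on random sets
  set.seed(1)
  for (i in 1:20) {
    a <- sample(u, sample(1:5, 1))
    b <- sample(u, sample(1:5, 1))
    expect_equal(dice(a, b, u), dice_oracle(a, b))
  }
})

test_that("bonferroni_alpha reproduces the family-wise arithmetic", {
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(bonferroni_alpha(0.05, 5), 0.01)
  expect_error(bonferroni_alpha(1.2, 5), "alpha_fw")
})

test_that("exhaustive permutation test matches the enumeration oracle", {
  labs <- sprintf("R%d", 1:8)
  memb <- matrix(FALSE, 8, 1, dimnames = list(labs, "N1"))
  memb[1:4, 1] <- TRUE
  A <- topography_set(memb)
  res <- permutation_test(A, A, n_iter = "exhaustive")
  # oracle: a permutation attains Dice 1 iff it maps the 4-set onto itself
  expect_equal(res$n_permutations, factorial(8))
  expect_equal(res$dice[1, 1], 1)
  expect_equal(res$p_values[1, 1],
               (factorial(4) * factorial(4) + 1) / (factorial(8) + 1),
               tolerance = 1e-12)

  # a network equal to the whole universe: null Dice constant, p = 1
  full <- topography_set(matrix(TRUE, 8, 1), region_labels = labs)
  res2 <- permutation_test(full, full, n_iter = "exhaustive")
  expect_equal(res2$p_values[1, 1], 1)
})

test_that("sampled permutation test is seeded and respects the universe", {
  set.seed(3)
  A <- random_cover(30, 3)
  B <- random_cover(30, 3)
  r1 <- permutation_test(A, B, n_iter = 300, seed = 5)
  r2 <- permutation_test(A, B, n_iter = 300, seed = 5)
  expect_identical(r1$p_values, r2$p_values)
  expect_true(all(r1$p_values >= 1 / 301))
  expect_equal(r1$alpha_within, 0.05 / 9)

  Bbad <- topography_set(B$membership, region_labels = sprintf("X%02d", 1:30))
  expect_error(permutation_test(A, Bbad), "universes differ")
})

test_that("p-values are invariant to consistent region relabeling (exhaustive)", {
  set.seed(4)
  A <- random_cover(7, 2, p = 0.4)
  B <- random_cover(7, 2, p = 0.4)
  r <- permutation_test(A, B, n_iter = "exhaustive")
  perm <- sample(7)
  Ap <- topography_set(A$membership[perm, ], region_labels = A$region_labels)
  Bp <- topography_set(B$membership[perm, ], region_labels = B$region_labels)
  rp <- permutation_test(Ap, Bp, n_iter = "exhaustive")
  expect_equal(r$p_values, rp$p_values, tolerance = 1e-12)
  expect_equal(r$dice, rp$dice, tolerance = 1e-12)
})

test_that("homologue matching equals brute-force enumeration", {
  D <- matrix(c(0.9, 0.3, 0.2, 0.8), 2)
  hm <- match_homologues(D)
  expect_equal(hm$pairs$b_index, c(1, 2))
  expect_equal(hm$total_dice, 1.7)

  ident <- diag(5)
  expect_equal(match_homologues(ident)$pairs$b_index, 1:5)
  expect_equal(match_homologues(ident)$total_dice, 5)

  set.seed(6)
  for (i in 1:40) {
    K <- sample(3:7, 1)
    D <- matrix(runif(K * K), K)
    hm <- match_homologues(D)
    bf <- brute_force_matching(D)
    expect_equal(hm$total_dice, bf$total, tolerance = 1e-12)
  }
})

test_that("significant-only matching forbids nonsignificant cells", {
  D <- matrix(c(0.9, 0.8, 0.85, 0.1), 2)
  sig <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2)
  hm <- match_homologues(D, constraint = "significant", significant = sig)
  # forced off the greedy diagonal: A1-B2 + A2-B1
  expect_equal(hm$pairs$b_index, c(2, 1))
  sig2 <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2)
  expect_error(match_homologues(D, constraint = "significant",
                                significant = sig2), "no feasible pairing")
})

test_that("compare_to_reference composes the test and the pairing", {
  set.seed(8)
  A <- random_cover(25, 4)
  out <- compare_to_reference(A, A, n_iter = 200, seed = 1)
  expect_equal(unname(diag(out$similarity$dice)), rep(1, 4))
  expect_equal(out$homologues$pairs$b_index, 1:4)
  expect_equal(out$homologues$total_dice, 4)
})

test_that("similarity reports render significant cells only and round-trip JSON", {
  dicem <- matrix(c(0.9, 0.1, 0.2, 0.85), 2,
                  dimnames = list(c("A1", "A2"), c("B1", "B2")))
  res <- structure(list(dice = dicem,
                        p_values = matrix(c(0.001, 0.8, 0.7, 0.002), 2),
                        alpha_within = 0.01,
                        significant = matrix(c(TRUE, FALSE, FALSE, TRUE), 2),
                        n_permutations = 1000L),
                   class = "similarity_result")
  rep <- similarity_report(res)
  expect_equal(rep["A1", "B1"], "0.90")
  expect_equal(rep["A1", "B2"], "–")

  dir <- withr::local_tempdir()
  write_similarity(res, match_homologues(res),
                   path_tsv = file.path(dir, "sim.tsv"),
                   path_json = file.path(dir, "sim.json"), seed = 3L)
  j <- jsonlite::read_json(file.path(dir, "sim.json"), simplifyVector = TRUE)
  expect_equal(j$n_permutations, 1000)
  expect_equal(j$total_dice, 1.75)
})
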