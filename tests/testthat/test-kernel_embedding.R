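test_that("default_gamma is 1/p", {
  expect_equal(default_gamma(5), 0.2)
  expect_equal(default_gamma(1), 1)
  expect_equal(default_gamma(876), 1 / 876)
  expect_error(default_gamma(0), "positive")
})

test_that("rbf_kernel_matrix matches closed forms and checks shapes", {
  x <- matrix(c(0), 1, 1); y <- matrix(c(1), 1, 1)
  expect_equal(rbf_kernel_matrix(x, x, 1)[1, 1], 1)
  expect_equal(rbf_kernel_matrix(x, y, 1)[1, 1], exp(-1))
  a <- matrix(c(1, 2), 1, 2); b <- matrix(c(3, 4), 1, 2)
  expect_equal(rbf_kernel_matrix(a, b, 0.5)[1, 1], exp(-4))
  expect_error(rbf_kernel_matrix(a, x, 1), "mismatch")
  expect_error(rbf_kernel_matrix(a, b, 0), "positive")
  # tiled result identical to one-block result
  set.seed(2)
  A <- matrix(rnorm(60), 20, 3); B <- matrix(rnorm(45), 15, 3)
  expect_equal(rbf_kernel_matrix(A, B, 0.4, block = 4L),
               rbf_kernel_matrix(A, B, 0.4))
})

test_that("subsample_cells is deterministic, without replacement", {
  dp <- donor_profile(matrix(seq_len(40), 20, 2), "d")
  s1 <- subsample_cells(dp, 10, seed = 7)
  s2 <- subsample_cells(dp, 10, seed = 7)
  expect_identical(s1$cells, s2$cells)
  expect_equal(anyDuplicated(s1$cells[, 1]), 0)
  # n == num_cells returns the full profile (possibly permuted)
  full <- subsample_cells(dp, 20, seed = 3)
  expect_setequal(full$cells[, 1], dp$expression[, 1])
  expect_error(subsample_cells(dp, 21, seed = 1), "21")
})

test_that("profile_inner_product equals the literal double loop", {
  set.seed(11)
  for (rep in 1:10) {
    p <- sample(1:4, 1)
    A <- matrix(rnorm(5 * p), 5, p); B <- matrix(rnorm(5 * p), 5, p)
    g <- runif(1, 0.1, 2)
    got <- profile_inner_product(make_sample(A), make_sample(B), g)
    expect_lt(abs(got - brute_inner_product(A, B, g)), 1e-12)
  }
  # n = 1 reduces to a single kernel value
  x <- matrix(c(0, 0), 1, 2); y <- matrix(c(1, 1), 1, 2)
  expect_equal(profile_inner_product(make_sample(x), make_sample(y), 1),
               exp(-2))
  # identical cells against itself -> 1
  same <- make_sample(matrix(1, 4, 2))
  expect_equal(profile_inner_product(same, same, 0.7), 1)
  expect_error(profile_inner_product(make_sample(x), same, 1), "common n")
})

test_that("profile_inner_product is exactly symmetric", {
  set.seed(5)
  si <- make_sample(matrix(rnorm(12), 4, 3))
  sj <- make_sample(matrix(rnorm(12), 4, 3))
  expect_identical(profile_inner_product(si, sj, 0.3),
                   profile_inner_product(sj, si, 0.3))
})

test_that("build_gram_matrix satisfies the Gram invariants", {
  samples <- random_cohort_samples(5, 8, 3, seed = 9)
  gm <- build_gram_matrix(samples, 1 / 3)
  G <- gm$values
  expect_identical(G, t(G))               # mirrored, not recomputed
  expect_true(all(G > 0 & G <= 1))
  for (i in 1:5) for (j in 1:5)
    expect_lte(G[i, j]^2, G[i, i] * G[j, j] * (1 + 1e-12))
  # constant matrix for identical samples
  same <- lapply(1:3, function(i) {
    s <- make_sample(samples[[1]]$cells, donor_id = paste0("x", i)); s })
  Gc <- build_gram_matrix(same, 0.5)$values
  expect_equal(max(Gc) - min(Gc), 0)
  # duplicate ids rejected
  dup <- samples; dup[[2]]$donor_id <- "d1"
  expect_error(build_gram_matrix(dup, 0.5), "duplicate")
  # N = 2 one-cell samples -> [[1, K],[K, 1]]
  g2 <- build_gram_matrix(list(make_sample(matrix(0, 1, 1), "a"),
                               make_sample(matrix(1, 1, 1), "b")), 1)$values
  expect_equal(unname(g2), matrix(c(1, exp(-1), exp(-1), 1), 2))
})

test_that("gamma limits behave as expected", {
  set.seed(21)
  s <- make_sample(matrix(rnorm(20), 10, 2))
  t <- make_sample(matrix(rnorm(20), 10, 2))
  expect_equal(profile_inner_product(s, t, 1e-12), 1, tolerance = 1e-6)
  # gamma -> Inf with distinct cells: self inner product -> 1/n
  expect_equal(profile_inner_product(s, s, 1e8), 1 / 10, tolerance = 1e-6)
})

test_that("inner product estimates converge with sample size", {
  # two fixed generating distributions; spread of the estimate shrinks with n
  est <- function(n, seed) {
    set.seed(seed)
    A <- matrix(rnorm(n * 2), n, 2)
    B <- matrix(rnorm(n * 2, mean = 1), n, 2)
    profile_inner_product(make_sample(A), make_sample(B), 0.5)
  }
  small <- vapply(1:8, function(s) est(50, s), 0)
  large <- vapply(1:8, function(s) est(200, s + 100), 0)
  expect_lt(sd(large), sd(small) + 0.01)
  expect_lt(abs(mean(large) - mean(small)), 0.05)
})

test_that("cohort subsampling is reproducible from one master seed", {
  dps <- lapply(1:3, function(i)
    donor_profile(matrix(rnorm(30, i), 10, 3), paste0("d", i)))
  a <- subsample_cohort(dps, 5, master_seed = 99)
  b <- subsample_cohort(dps, 5, master_seed = 99)
  expect_identical(lapply(a, `[[`, "cells"), lapply(b, `[[`, "cells"))
  c2 <- subsample_cohort(dps, 5, master_seed = 100)
  expect_false(identical(lapply(a, `[[`, "cells"),
                         lapply(c2, `[[`, "cells")))
})
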