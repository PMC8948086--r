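test_that("N=2 case matches the closed-form symmetric eigendecomposition", {
  # P = [[a, b], [b, a]] has eigenvalues a+b, a-b with eigenvectors
  # (1,1)/sqrt(2), (1,-1)/sqrt(2); G = exp(2P)
  a <- -0.1; b <- -0.35
  G <- exp(2 * matrix(c(a, b, b, a), 2))
  dec <- deef_decompose(G)
  pairs <- list(list(val = a + b, vec = c(1, 1) / sqrt(2)),
                list(val = a - b, vec = c(1, -1) / sqrt(2)))
  pairs <- pairs[order(vapply(pairs, `[[`, 0, "val"), decreasing = TRUE)]
  expect_equal(dec$eigenvalues, vapply(pairs, `[[`, 0, "val"),
               tolerance = 1e-12)
  expected_theta <- vapply(pairs, function(pp)
    sqrt(abs(pp$val)) * pp$vec, numeric(2))
  # both expected columns already have their largest-|entry| component
  # positive, matching the package sign convention
  expect_equal(unname(dec$theta), expected_theta, tolerance = 1e-12)
})

test_that("reconstruction and eigenvalue-sum invariants hold on random cohorts", {
  for (seed in 1:5) {
    samples <- random_cohort_samples(6, 10, 3, seed = seed)
    gm <- build_gram_matrix(samples, 1 / 3)
    dec <- deef_decompose(gm)
    P <- 0.5 * log(gm$values)
    S <- diag(sign(dec$eigenvalues), length(dec$eigenvalues))
    expect_lt(max(abs(dec$theta %*% S %*% t(dec$theta) - P)), 1e-8)
    expect_lt(abs(sum(dec$eigenvalues) - sum(diag(P))), 1e-8)
    # norm of each axis equals sqrt(|lambda|)
    expect_equal(colSums(dec$theta^2), abs(dec$eigenvalues),
                 tolerance = 1e-8, ignore_attr = TRUE)
    # ordering: signed descending
    expect_true(all(diff(dec$eigenvalues) <= 1e-12))
  }
})

test_that("identical donors receive identical coordinates", {
  s <- make_sample(matrix(rnorm(20), 10, 2))
  same <- lapply(1:4, function(i) { x <- s; x$donor_id <- paste0("d", i); x })
  dec <- deef_decompose(build_gram_matrix(same, 0.5))
  for (ax in 1:4)
    expect_lt(diff(range(dec$theta[, ax])), 1e-7)
})

test_that("degenerate and invalid inputs are rejected", {
  expect_error(deef_decompose(matrix(1, 1, 1)), "N >= 2")
  G <- matrix(c(1, 0, 0, 1), 2)
  expect_error(deef_decompose(G), "non-positive")
  asym <- matrix(c(1, 0.5, 0.4, 1), 2)
  expect_error(deef_decompose(asym), "symmetric")
})

test_that("positive_axes keeps strictly positive eigenvalues only", {
  samples <- random_cohort_samples(5, 8, 2, seed = 3)
  dec <- deef_decompose(build_gram_matrix(samples, 0.5))
  pos <- positive_axes(dec)
  expect_equal(ncol(pos), dec$n_positive)
  expect_true(all(dec$eigenvalues[seq_len(ncol(pos))] > 0))
  # constant matrix: the only nonzero eigenvalue is negative -> error
  Gneg <- matrix(0.5, 3, 3)
  expect_error(positive_axes(deef_decompose(Gneg)), "no positive")
})

test_that("top_theta slices the leading axes", {
  samples <- random_cohort_samples(4, 6, 2, seed = 8)
  dec <- deef_decompose(build_gram_matrix(samples, 0.5))
  expect_equal(top_theta(dec, 4), dec$theta)
  expect_equal(top_theta(dec, 1), dec$theta[, 1, drop = FALSE])
  expect_equal(colnames(top_theta(dec, 2)), c("theta1", "theta2"))
  expect_error(top_theta(dec, 0), "\\[1, 4\\]")
  expect_error(top_theta(dec, 5), "\\[1, 4\\]")
})

test_that("permuting donors permutes theta rows identically", {
  samples <- random_cohort_samples(6, 10, 3, seed = 13)
  dec <- deef_decompose(build_gram_matrix(samples, 1 / 3))
  perm <- c(3, 1, 6, 2, 5, 4)
  dec_p <- deef_decompose(build_gram_matrix(samples[perm], 1 / 3))
  # same axes up to the fixed sign convention; compare absolute values
  expect_equal(abs(unname(dec_p$theta)), abs(unname(dec$theta[perm, ])),
               tolerance = 1e-8)
})

test_that("resampling repetitions correlate on structured cohorts", {
  sim <- simulate_cytometry_cohort(default_cytometry_spec(
    n_donors_per_group = 6, n_cells_per_donor = 300, seed = 2))
  cfg <- kernel_config(n_cells = 200)
  st <- resampling_stability(sim$profiles, 200, cfg, n_reps = 3,
                             master_seed = 5)
  expect_equal(nrow(st$correlations), 2 * choose(3, 2))
  expect_gt(min(st$correlations$abs_pearson[st$correlations$axis == 1]),
            0.9)
  # coplot table: one row per donor per rep
  expect_equal(nrow(st$coplot), 3 * length(sim$profiles))
  # identical seeds give correlation exactly 1
  d1 <- embed_cohort(sim$profiles, cfg, 42)
  d2 <- embed_cohort(sim$profiles, cfg, 42)
  expect_equal(abs(cor(d1$theta[, 1], d2$theta[, 1])), 1)
})
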