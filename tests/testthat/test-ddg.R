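test_that("wilks_lambda matches the from-scratch SSCP oracle and MANOVA", {
  fx <- wilks_fixture()
  got <- wilks_lambda(fx$theta, fx$labels)
  expect_lt(abs(got - brute_wilks(fx$theta, fx$labels)), 1e-12)
  # independent implementation: stats::manova Wilks statistic
  fit <- stats::manova(fx$theta ~ fx$labels)
  ref <- summary(fit, test = "Wilks")$stats[1, "Wilks"]
  expect_lt(abs(got - ref), 1e-8)
  expect_gt(got, 0); expect_lte(got, 1)
})

test_that("wilks_lambda limiting cases", {
  # equal group means in-sample -> H = 0 -> lambda = 1
  x <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  x <- rbind(x, x)
  labels <- rep(c("a", "b"), each = 4)
  expect_equal(wilks_lambda(x, labels), 1)
  # zero within-group scatter, non-collinear group means (H nonsingular)
  # -> lambda = 0
  y <- rbind(matrix(rep(c(0, 0), 2), 2, byrow = TRUE),
             matrix(rep(c(1, 0), 2), 2, byrow = TRUE),
             matrix(rep(c(0, 1), 2), 2, byrow = TRUE))
  expect_equal(wilks_lambda(y, rep(c("a", "b", "c"), each = 2)), 0)
  # all points identical -> NA with warning
  z <- matrix(1, 6, 2)
  expect_warning(out <- wilks_lambda(z, rep(c("a", "b"), each = 3)),
                 "singular")
  expect_true(is.na(out))
  expect_error(wilks_lambda(x, rep("a", 8)), "2 groups")
  expect_error(wilks_lambda(x, c(rep("a", 7), "b")), "at least 2 donors")
})

test_that("wilks_lambda is invariant to relabeling, rigid motion, scaling", {
  fx <- wilks_fixture()
  base <- wilks_lambda(fx$theta, fx$labels)
  relab <- factor(ifelse(fx$labels == "ctrl", "g2", "g1"))
  expect_equal(wilks_lambda(fx$theta, relab), base, tolerance = 1e-12)
  ang <- 0.7
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
  moved <- sweep(fx$theta %*% R, 2, c(3, -1), "+")
  expect_equal(wilks_lambda(moved, fx$labels), base, tolerance = 1e-10)
  expect_equal(wilks_lambda(fx$theta * 7.3, fx$labels), base,
               tolerance = 1e-10)
})

test_that("permutation_null is a deterministic label permutation", {
  fx <- wilks_fixture()
  n1 <- permutation_null(fx$theta, fx$labels, seed = 5)
  n2 <- permutation_null(fx$theta, fx$labels, seed = 5)
  expect_identical(n1, n2)
  # equals wilks_lambda under the same derived permutation
  perm <- local({ set.seed(5); sample(length(fx$labels)) })
  expect_equal(n1, wilks_lambda(fx$theta, fx$labels[perm]))
  expect_error(permutation_null(fx$theta, rep("a", 8), 1), "2 groups")
})

test_that("per_gene_theta separates shifted expression distributions", {
  set.seed(31)
  mk <- function(id, mu) donor_profile(
    cbind(gene_a = rnorm(300, mu), gene_b = rnorm(300)), id)
  profiles <- c(lapply(1:4, function(i) mk(paste0("c", i), 0)),
                lapply(1:4, function(i) mk(paste0("u", i), 3)))
  th <- per_gene_theta(profiles, "gene_a", n = 250, seed = 3)
  expect_equal(dim(th), c(8L, 2L))
  grp <- rep(c(0, 1), each = 4)
  expect_gt(abs(cor(th[, 1], grp)), 0.8)
  # null gene: no group structure on theta1
  th_b <- per_gene_theta(profiles, "gene_b", n = 250, seed = 3)
  lam_a <- wilks_lambda(th, rep(c("c", "u"), each = 4))
  lam_b <- wilks_lambda(th_b, rep(c("c", "u"), each = 4))
  expect_lt(lam_a, lam_b)
  expect_error(per_gene_theta(profiles, "nope", 100, 1), "not present")
})

test_that("ddg_scan ranks, reports QQ data and is deterministic", {
  sim <- simulate_scrnaseq_cohort(n_donors_per_group = 4, n_cells = 200,
                                  n_genes = 40, n_signal_genes = 8,
                                  effect = "mean_shift", effect_size = 2,
                                  seed = 13)
  profs <- lapply(sim$profiles, log_normalize)
  res <- ddg_scan(profs, sim$labels, n = 150, master_seed = 6)
  expect_equal(nrow(res$table), 40)
  ranked <- res$table[!is.na(res$table$lambda), ]
  expect_true(all(diff(ranked$lambda) >= 0))       # ascending by lambda
  expect_equal(ranked$rank, seq_len(nrow(ranked)))
  expect_equal(names(res$theta_extreme),
               c(ranked$gene[1], ranked$gene[nrow(ranked)]))
  expect_equal(dim(res$theta_extreme[[1]]), c(8L, 2L))
  # signal genes concentrate at small lambda
  top <- merge(head(ranked, 10), sim$truth, by = "gene")
  expect_gt(sum(top$signal), 10 * 8 / 40)          # above base rate
  res2 <- ddg_scan(profs, sim$labels, n = 150, master_seed = 6)
  expect_identical(res$table, res2$table)
})

test_that("lambda is stable across cell resamplings on strong signal", {
  sim <- simulate_scrnaseq_cohort(n_donors_per_group = 5, n_cells = 300,
                                  n_genes = 60, n_signal_genes = 30,
                                  effect = "mean_shift", effect_size = 3,
                                  seed = 17)
  profs <- lapply(sim$profiles, log_normalize)
  st <- ddg_stability(profs, sim$labels, n = 250, master_seed = 9,
                      n_reps = 2)
  expect_gt(st$correlations$spearman[1], 0.8)
})
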