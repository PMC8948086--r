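quick_config <- function(n_cells = 100, ...) {
  classifier_config(n_estimators = 40, n_resamplings = 3, n_cells = n_cells,
                    ...)
}

test_that("select_and_fit finds a separating first axis with small k", {
  set.seed(5)
  theta <- cbind(c(rnorm(10, -4), rnorm(10, 4)), matrix(rnorm(60), 20, 3))
  labels <- rep(c("a", "b"), each = 10)
  fit <- select_and_fit(theta, labels, quick_config(), seed = 1)
  expect_equal(fit$cv_score, 1)
  expect_lte(fit$k_coords, 2)
  expect_equal(fit$max_depth, 2)    # tie rule: smallest depth at equal score
  expect_equal(mean(predict(fit$model,
                            theta[, seq_len(fit$k_coords), drop = FALSE])
                    == labels), 1)
})

test_that("patience = 0 stops at the first non-improving axis count", {
  set.seed(6)
  theta <- cbind(c(rnorm(8, -3), rnorm(8, 3)), matrix(rnorm(80), 16, 5))
  labels <- rep(c("a", "b"), each = 8)
  fit <- select_and_fit(theta, labels, quick_config(patience = 0), seed = 2)
  # k=1 scores 1.0; k=2 cannot improve; search must stop there
  expect_lte(max(fit$search$k), 2)
})

test_that("stratified folding is enforced", {
  theta <- matrix(rnorm(12), 6, 2)
  expect_error(select_and_fit(theta, c("a", rep("b", 5)), quick_config(),
                              seed = 1), "fewer than 2")
})

test_that("ensemble prediction vote equals the per-resampling mode", {
  sim <- simulate_cytometry_cohort(default_cytometry_spec(
    n_donors_per_group = 6, n_cells_per_donor = 150, seed = 7))
  donors <- names(sim$profiles)
  lab <- setNames(as.character(sim$labels), donors)
  sp <- train_test_split_donors(donors, sim$labels, 0.5, seed = 3)
  res <- ensemble_predict(sim$profiles[sp$train], lab[sp$train],
                          sim$profiles[sp$test], quick_config(),
                          master_seed = 8, test_labels = lab[sp$test])
  for (j in seq_along(res$ensemble)) {
    votes <- table(res$per_resampling[, j])
    expect_equal(as.character(res$ensemble[j]),
                 names(votes)[which.max(votes)])
  }
  expect_equal(dim(res$per_resampling), c(3L, length(sp$test)))
  expect_false(anyNA(res$hyperparams$k_coords))
  # determinism from the master seed
  res2 <- ensemble_predict(sim$profiles[sp$train], lab[sp$train],
                           sim$profiles[sp$test], quick_config(),
                           master_seed = 8, test_labels = lab[sp$test])
  expect_identical(res$per_resampling, res2$per_resampling)
})

test_that("n_resamplings must be odd", {
  expect_error(classifier_config(n_resamplings = 24), "odd")
})

test_that("concatenate_conditions stacks blocks in sorted condition order", {
  t1 <- matrix(1, 10, 3, dimnames = list(paste0("d", 1:10),
                                         paste0("theta", 1:3)))
  t2 <- matrix(2, 10, 3, dimnames = dimnames(t1))
  out <- concatenate_conditions(list(b = t2, a = t1))
  expect_equal(dim(out), c(10L, 6L))
  expect_equal(colnames(out)[1:3], paste0("a.theta", 1:3))
  expect_equal(unname(out[1, ]), c(1, 1, 1, 2, 2, 2))
  # single condition passes through (prefixed)
  one <- concatenate_conditions(list(only = t1))
  expect_equal(unname(one), unname(t1))
  # row-order mismatch names the first disagreeing donor
  t3 <- t2[c(2, 1, 3:10), ]
  expect_error(concatenate_conditions(list(a = t1, b = t3)), "d2")
  # seven conditions -> seven blocks
  seven <- setNames(rep(list(t1), 7), paste0("c", 1:7))
  expect_equal(ncol(concatenate_conditions(seven)), 21)
})

test_that("donor-level splits are stratified and deterministic", {
  donors <- paste0("d", 1:44)
  labels <- rep(c("case", "ctrl"), each = 22)
  sp <- train_test_split_donors(donors, labels, 0.5, seed = 4)
  expect_equal(length(sp$train), 22)
  expect_equal(length(sp$test), 22)
  expect_equal(sum(labels[match(sp$train, donors)] == "case"), 11)
  sp2 <- train_test_split_donors(donors, labels, 0.5, seed = 4)
  expect_identical(sp, sp2)
  expect_error(train_test_split_donors(donors, labels, 1.0), "\\(0, 1\\)")
  expect_error(train_test_split_donors(c("a", "b", "c"),
                                       c("x", "x", "y"), 0.5), "single donor")
})

test_that("multi-condition ensemble concatenates per-condition axes", {
  sim1 <- simulate_cytometry_cohort(default_cytometry_spec(
    n_donors_per_group = 8, n_cells_per_donor = 200, seed = 11))
  sim2 <- simulate_cytometry_cohort(default_cytometry_spec(
    n_donors_per_group = 8, n_cells_per_donor = 200, seed = 12))
  donors <- names(sim1$profiles)
  lab <- setNames(as.character(sim1$labels), donors)
  by_cond <- list(stim = setNames(sim1$profiles, donors),
                  unstim = setNames(sim2$profiles, donors))
  sp <- train_test_split_donors(donors, sim1$labels, 0.5, seed = 5)
  res <- ensemble_predict_conditions(by_cond, sp$train, sp$test, lab,
                                     quick_config(n_cells = 150),
                                     master_seed = 21,
                                     test_labels = lab[sp$test])
  expect_equal(ncol(res$per_resampling), length(sp$test))
  expect_true(all(res$hyperparams$k_coords >= 2))  # >= 1 axis per condition
  expect_gte(res$ensemble_accuracy, 0.7)
})
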