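# shared fixture builders; everything is generated in code

make_sample <- function(cells, donor_id = "d", seed = 1L) {
  structure(list(donor_id = donor_id, cells = as.matrix(cells),
                 n = nrow(cells), seed = as.integer(seed),
                 group_label = NULL, condition = NULL),
            class = "cell_sample")
}

random_cohort_samples <- function(N, n, p, seed) {
  set.seed(seed)
  lapply(seq_len(N), function(i)
    make_sample(matrix(rnorm(n * p, mean = rnorm(1)), n, p),
                donor_id = paste0("d", i)))
}

# literal double-loop version of the mean-embedding inner product
brute_inner_product <- function(A, B, gamma) {
  s <- 0
  for (k in seq_len(nrow(A))) for (l in seq_len(nrow(B)))
    s <- s + exp(-gamma * sum((A[k, ] - B[l, ])^2))
  s / (nrow(A) * nrow(B))
}

# fixed 8-donor, 2-group, 2-D fixture for the Wilks' lambda oracle
wilks_fixture <- function() {
  theta <- matrix(c(0.1, 0.4, -0.2, 0.3, 1.9, 2.2, 1.4, 2.6,
                    0.5, -0.1, 0.2, 0.8, -0.6, 0.1, -0.3, 0.4),
                  ncol = 2)
  labels <- factor(rep(c("ctrl", "case"), each = 4))
  list(theta = theta, labels = labels)
}

# independent from-scratch SSCP determinant-ratio computation
brute_wilks <- function(x, labels) {
  labels <- factor(labels)
  grand <- colMeans(x)
  E <- matrix(0, ncol(x), ncol(x)); H <- E
  for (lv in levels(labels)) {
    xi <- x[labels == lv, , drop = FALSE]
    m <- colMeans(xi)
    for (r in seq_len(nrow(xi)))
      E <- E + tcrossprod(xi[r, ] - m)
    H <- H + nrow(xi) * tcrossprod(m - grand)
  }
  det(E) / det(E + H)
}

tiny_counts_profile <- function(donor_id = "d1", seed = 1) {
  set.seed(seed)
  counts <- matrix(rpois(5 * 6, lambda = 3), 5, 6)
  donor_profile(counts, donor_id,
                feature_names = c("MT-CO1", paste0("g", 1:5)))
}
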