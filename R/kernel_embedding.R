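#' Default RBF bandwidth
#'
#' The package-wide automatic choice `gamma = 1/p`, where `p` is the number
#' of features entering the kernel: markers for cytometry, filtered genes
#' for a pooled scRNA-seq embedding, and 1 for a single-gene scan.
#'
#' @param p positive integer feature count.
#' @return `1/p`.
#' @examples
#' default_gamma(5)   # 0.2 for a five-marker panel
#' default_gamma(1)   # 1 for a per-gene scan
#' @export
default_gamma <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 1)
    stop("`p` must be a positive integer", call. = FALSE)
  1 / p
}

#' Subsample cells from a donor profile
#'
#' Draws `n` cells uniformly without replacement ("no duplication allowed"),
#' deterministically for a given seed.  A common `n` across donors -- the
#' cohort minimum in practice -- is required downstream.
#'
#' @param profile a [donor_profile].
#' @param n number of cells to draw, `1 <= n <= n_cells(profile)`.
#' @param seed integer seed for this draw.
#' @return a `cell_sample`: list with `donor_id`, `cells` (n x p matrix),
#'   `n`, `seed`, `group_label`, `condition`.
#' @export
subsample_cells <- function(profile, n, seed) {
  nc <- n_cells(profile)
  if (n < 1 || n > nc)
    stop("cannot pick n = ", n, " cells from donor '", profile$donor_id,
         "' with ", nc, " cells; choose n <= the cohort minimum",
         call. = FALSE)
  idx <- with_seed(seed, sample.int(nc, n, replace = FALSE))
  structure(list(donor_id = profile$donor_id,
                 cells = profile$expression[idx, , drop = FALSE],
                 n = as.integer(n), seed = as.integer(seed),
                 group_label = profile$group_label,
                 condition = profile$condition),
            class = "cell_sample")
}

#' RBF (Gaussian) kernel matrix between two cell sets
#'
#' Entry `(k, l)` is `exp(-gamma * ||A_k - B_l||^2)`.  Computed in blocks so
#' peak memory is bounded by `block^2` doubles even for large cell counts;
#' results are identical to the naive computation.
#'
#' @param A,B numeric matrices with the same number of columns.
#' @param gamma positive bandwidth.
#' @param block block edge length for tiling (default 2048).
#' @return `nrow(A)` x `nrow(B)` matrix with entries in `(0, 1]`.
#' @export
rbf_kernel_matrix <- function(A, B, gamma, block = 2048L) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (ncol(A) != ncol(B))
    stop("feature dimension mismatch: ", ncol(A), " vs ", ncol(B),
         call. = FALSE)
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0)
    stop("`gamma` must be a single positive number", call. = FALSE)
  out <- matrix(0, nrow(A), nrow(B))
  a2 <- rowSums(A^2)
  b2 <- rowSums(B^2)
  ai <- split(seq_len(nrow(A)), ceiling(seq_len(nrow(A)) / block))
  bi <- split(seq_len(nrow(B)), ceiling(seq_len(nrow(B)) / block))
  for (ia in ai) for (ib in bi) {
    d2 <- outer(a2[ia], b2[ib], "+") -
      2 * tcrossprod(A[ia, , drop = FALSE], B[ib, , drop = FALSE])
    d2[d2 < 0] <- 0  # clamp rounding noise
    out[ia, ib] <- exp(-gamma * d2)
  }
  out
}

#' Inner product of two cell-population distributions
#'
#' The kernel mean-embedding estimate of the inner product between the two
#' distributions the samples were drawn from: the mean of all `n^2` pairwise
#' RBF kernel values between the cells of the two samples.  Both samples
#' must hold the same number of cells.
#'
#' @param si,sj `cell_sample`s with equal `n` and feature dimension.
#' @param gamma positive RBF bandwidth.
#' @return a scalar in `(0, 1]`.
#' @export
profile_inner_product <- function(si, sj, gamma) {
  if (si$n != sj$n)
    stop("cell samples have different sizes (", si$n, " vs ", sj$n,
         "); a common n is required", call. = FALSE)
  mean(rbf_kernel_matrix(si$cells, sj$cells, gamma))
}

#' Donor-by-donor Gram matrix of distribution inner products
#'
#' Computes [profile_inner_product] for every unordered donor pair and
#' mirrors it, so the result is exactly symmetric.  Entries of an RBF Gram
#' matrix are strictly positive, at most 1, and satisfy Cauchy-Schwarz.
#'
#' @param samples list of `cell_sample`s with distinct donor ids, common `n`
#'   and feature dimension.
#' @param gamma positive RBF bandwidth.
#' @return a `gram_matrix`: list with `values` (N x N) and `donor_ids`.
#' @export
build_gram_matrix <- function(samples, gamma) {
  N <- length(samples)
  if (N < 2) stop("need at least 2 samples", call. = FALSE)
  ids <- vapply(samples, `[[`, "", "donor_id")
  if (anyDuplicated(ids))
    stop("duplicate donor ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  G <- matrix(0, N, N, dimnames = list(ids, ids))
  for (i in seq_len(N)) for (j in i:N) {
    v <- profile_inner_product(samples[[i]], samples[[j]], gamma)
    G[i, j] <- v
    G[j, i] <- v
  }
  structure(list(values = G, donor_ids = ids), class = "gram_matrix")
}

# internal: run code with a local RNG state seeded from `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# internal: expand one master seed into `k` reproducible sub-seeds.
# Documented rule: seed the generator with the master seed and draw k
# integers below 2^31; fully deterministic across platforms for a given R.
derive_seeds <- function(master_seed, k) {
  with_seed(master_seed, sample.int(.Machine$integer.max, k))
}

#' Subsample every donor of a cohort
#'
#' Expands one master seed into per-donor seeds by a fixed deterministic
#' rule and draws `n` cells from each profile, so a whole run is
#' reproducible from a single integer.
#'
#' @param profiles list of [donor_profile]s.
#' @param n cells per donor (must not exceed the smallest profile).
#' @param master_seed single integer.
#' @return list of `cell_sample`s in the input order.
#' @export
subsample_cohort <- function(profiles, n, master_seed) {
  seeds <- derive_seeds(master_seed, length(profiles))
  mapply(subsample_cells, profiles, seed = seeds,
         MoreArgs = list(n = n), SIMPLIFY = FALSE)
}
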