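#' Kernel configuration for an embedding run
#'
#' @param n_cells number of cells subsampled per donor.
#' @param gamma RBF bandwidth; `NULL` (default) means the automatic choice
#'   `1/p` resolved against the data at run time, see [default_gamma].
#' @return a `kernel_config` list.
#' @export
kernel_config <- function(n_cells, gamma = NULL) {
  if (!is.null(gamma) && (!is.numeric(gamma) || gamma <= 0))
    stop("`gamma` must be NULL or a positive number", call. = FALSE)
  stopifnot(is.numeric(n_cells), n_cells >= 1)
  structure(list(n_cells = as.integer(n_cells), gamma = gamma),
            class = "kernel_config")
}

#' DEEF decomposition of an inner-product matrix
#'
#' The coordinate-assignment step: form `P = 1/2 * log(G)` entrywise from
#' the donor-by-donor inner-product matrix `G`, take the symmetric
#' eigendecomposition `P = V diag(lambda) V'`, and define the i-th
#' coordinate axis as `theta_i = v_i * sqrt(|lambda_i|)`.  Axes are ordered
#' by signed eigenvalue, from the largest positive (`theta1`) to the largest
#' negative; eigenvalues may be negative because `P` need not be positive
#' semi-definite.  Then `sum_i sign(lambda_i) theta_i theta_i' = P`, so the
#' signed eigenvalues must accompany the coordinates.
#'
#' Eigenvector signs are underdetermined; each axis is flipped so that its
#' entry of largest absolute value is positive, making runs reproducible.
#' Eigenvalues within `zero_tol * max(|lambda|)` of zero are kept in the
#' decomposition but treated as zero by [positive_axes]; near-equal adjacent
#' eigenvalues are flagged in `tied_axes` since only their span is
#' identifiable.
#'
#' @param gram a `gram_matrix` from [build_gram_matrix], or a plain
#'   symmetric matrix of strictly positive inner products.
#' @param zero_tol relative tolerance below which an eigenvalue counts as
#'   zero (default `1e-10`).
#' @return a `theta_decomposition`: list with `theta` (N x N, column i is
#'   `theta_i`), `eigenvalues` (signed, descending), `donor_ids`,
#'   `n_positive`, `tied_axes`.
#' @export
deef_decompose <- function(gram, zero_tol = 1e-10) {
  if (inherits(gram, "gram_matrix")) {
    G <- gram$values; ids <- gram$donor_ids
  } else {
    G <- as.matrix(gram)
    ids <- rownames(G)
    if (is.null(ids)) ids <- paste0("donor", seq_len(nrow(G)))
  }
  N <- nrow(G)
  if (N < 2)
    stop("a one-donor decomposition is meaningless; need N >= 2",
         call. = FALSE)
  if (any(G <= 0)) {
    bad <- which(G <= 0, arr.ind = TRUE)[1, ]
    stop("inner-product matrix has a non-positive entry at (", bad[1], ",",
         bad[2], "); kernel mean-embedding inner products with an RBF ",
         "kernel are strictly positive", call. = FALSE)
  }
  if (max(abs(G - t(G))) > 1e-12 * max(abs(G)))
    stop("inner-product matrix is not symmetric", call. = FALSE)
  P <- 0.5 * log(G)
  eig <- eigen((P + t(P)) / 2, symmetric = TRUE)   # eigenvalues descending
  lambda <- eig$values
  V <- eig$vectors
  # sign convention: largest-|entry| component positive
  for (i in seq_len(N)) {
    piv <- which.max(abs(V[, i]))
    if (V[piv, i] < 0) V[, i] <- -V[, i]
  }
  theta <- V %*% diag(sqrt(abs(lambda)), N)
  dimnames(theta) <- list(ids, paste0("theta", seq_len(N)))
  tol <- zero_tol * max(abs(lambda), .Machine$double.eps)
  gaps <- abs(diff(lambda))
  tied <- which(gaps <= tol)
  tied_axes <- if (length(tied)) sort(unique(c(tied, tied + 1L)))
               else integer(0)
  structure(list(theta = theta,
                 eigenvalues = lambda,
                 donor_ids = ids,
                 n_positive = sum(lambda > tol),
                 zero_tol = tol,
                 tied_axes = tied_axes),
            class = "theta_decomposition")
}

#' @export
print.theta_decomposition <- function(x, ...) {
  cat("<theta_decomposition> ", length(x$donor_ids), " donors, ",
      x$n_positive, " positive axes; leading eigenvalues: ",
      paste(signif(utils::head(x$eigenvalues, 4), 3), collapse = ", "),
      " ...\n", sep = "")
  invisible(x)
}

#' Coordinate axes with positive eigenvalues
#'
#' Supervised workflows use only the axes whose eigenvalues are strictly
#' positive (above the decomposition's zero tolerance).
#'
#' @param dec a [deef_decompose] result.
#' @return N x n_positive matrix of theta columns, order preserved.
#' @export
positive_axes <- function(dec) {
  keep <- dec$eigenvalues > dec$zero_tol
  if (!any(keep))
    stop("no positive eigenvalues; inspect the Gram matrix (all donors ",
         "may be indistinguishable at this n and gamma)", call. = FALSE)
  dec$theta[, keep, drop = FALSE]
}

#' Leading theta coordinates
#'
#' The first `k` axes in signed-eigenvalue order -- the data-driven features
#' assigned to each donor.
#'
#' @param dec a [deef_decompose] result.
#' @param k number of leading axes, `1 <= k <= N`.
#' @return N x k matrix.
#' @export
top_theta <- function(dec, k) {
  N <- ncol(dec$theta)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > N)
    stop("`k` must be in [1, ", N, "]", call. = FALSE)
  dec$theta[, seq_len(k), drop = FALSE]
}

#' Embed a cohort: subsample, Gram, DEEF in one call
#'
#' @param profiles list of [donor_profile]s with common features.
#' @param config a [kernel_config].
#' @param master_seed integer controlling all subsampling.
#' @return a [deef_decompose] result with the resolved `gamma` and the Gram
#'   matrix attached as attributes.
#' @export
embed_cohort <- function(profiles, config, master_seed) {
  shared_features(profiles)
  p <- n_features(profiles[[1]])
  gamma <- if (is.null(config$gamma)) default_gamma(p) else config$gamma
  samples <- subsample_cohort(profiles, config$n_cells, master_seed)
  gram <- build_gram_matrix(samples, gamma)
  dec <- deef_decompose(gram)
  attr(dec, "gamma") <- gamma
  attr(dec, "gram") <- gram
  dec
}

#' Stability of theta coordinates under cell resampling
#'
#' Repeats the full subsample / Gram / DEEF pipeline with distinct seeds and
#' reports, per axis and per pair of repetitions, the absolute Pearson and
#' Spearman correlations of coordinate values across donors.  Correlations
#' are absolute because the eigenvector sign is arbitrary across runs.  High
#' correlations on the leading axes indicate the embedding is not driven by
#' sampling bias.
#'
#' @param profiles list of [donor_profile]s.
#' @param n cells per donor per repetition.
#' @param config a [kernel_config] (its `n_cells` is overridden by `n`).
#' @param n_reps number of repetitions, at least 2.
#' @param master_seed integer; repetition seeds are derived from it.
#' @param n_axes how many leading axes to correlate (default 2, the usual
#'   coplot axes).
#' @return list with `theta` (per-rep matrices), `correlations` (data frame:
#'   axis, rep_a, rep_b, abs_pearson, abs_spearman) and `coplot` (long-form
#'   donor x rep coordinate table).
#' @export
resampling_stability <- function(profiles, n, config, n_reps = 3,
                                 master_seed = 1, n_axes = 2) {
  if (n_reps < 2) stop("need n_reps >= 2", call. = FALSE)
  cfg <- kernel_config(n_cells = n, gamma = config$gamma)
  rep_seeds <- derive_seeds(master_seed, n_reps)
  decs <- lapply(rep_seeds, function(s) embed_cohort(profiles, cfg, s))
  n_axes <- min(n_axes, min(vapply(decs, function(d) ncol(d$theta), 0L)))
  thetas <- lapply(decs, function(d) top_theta(d, n_axes))
  pairs <- utils::combn(n_reps, 2)
  rows <- list()
  for (ax in seq_len(n_axes)) for (pi in seq_len(ncol(pairs))) {
    a <- pairs[1, pi]; b <- pairs[2, pi]
    xa <- thetas[[a]][, ax]; xb <- thetas[[b]][, ax]
    rows[[length(rows) + 1L]] <- data.frame(
      axis = ax, rep_a = a, rep_b = b,
      abs_pearson = abs(stats::cor(xa, xb)),
      abs_spearman = abs(stats::cor(xa, xb, method = "spearman")))
  }
  coplot <- do.call(rbind, lapply(seq_len(n_reps), function(r) {
    data.frame(donor_id = rownames(thetas[[r]]), rep = r,
               thetas[[r]], row.names = NULL, check.names = FALSE)
  }))
  list(theta = thetas, correlations = do.call(rbind, rows), coplot = coplot,
       eigenvalues = lapply(decs, `[[`, "eigenvalues"))
}
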