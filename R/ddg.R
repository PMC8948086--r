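#' Wilks' lambda for group separation on a coordinate plane
#'
#' The MANOVA statistic `Lambda = det(E) / det(E + H)`, where `E` is the
#' within-group sums-of-squares-and-cross-products matrix and `H` the
#' between-group SSCP (group-mean deviations from the grand mean weighted by
#' group size).  `Lambda` lies in `(0, 1]` for nondegenerate scatter; small
#' values mean strong label separation.  Degenerate input (singular total
#' scatter, e.g. all points identical) yields `NA` with a warning so callers
#' can exclude it from ranking.
#'
#' @param theta2 numeric matrix, donors in rows (any column count, usually
#'   the top two theta axes).
#' @param labels group labels, at least 2 donors per group.
#' @return scalar in `(0, 1]`, or `NA` for degenerate scatter.
#' @export
wilks_lambda <- function(theta2, labels) {
  x <- as.matrix(theta2)
  labels <- factor(labels)
  labels <- droplevels(labels)
  if (nlevels(labels) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(labels) < 2))
    stop("every group needs at least 2 donors", call. = FALSE)
  if (nrow(x) != length(labels)) stop("row/label length mismatch",
                                      call. = FALSE)
  grand <- colMeans(x)
  E <- matrix(0, ncol(x), ncol(x))
  H <- matrix(0, ncol(x), ncol(x))
  for (lv in levels(labels)) {
    xi <- x[labels == lv, , drop = FALSE]
    ci <- sweep(xi, 2, colMeans(xi))
    E <- E + crossprod(ci)
    d <- colMeans(xi) - grand
    H <- H + nrow(xi) * tcrossprod(d)
  }
  dT <- det(E + H)
  if (!is.finite(dT) || dT <= .Machine$double.eps * max(1, sum(diag(E + H)))^ncol(x)) {
    warning("singular total scatter; Wilks' lambda undefined")
    return(NA_real_)
  }
  max(det(E) / dT, 0)
}

#' Permutation-null Wilks' lambda
#'
#' Recomputes [wilks_lambda] after one uniformly random permutation of the
#' labels (deterministic given `seed`) -- the single-permutation null used
#' to build a pooled null distribution across genes.
#'
#' @inheritParams wilks_lambda
#' @param seed integer seed for the permutation.
#' @export
permutation_null <- function(theta2, labels, seed) {
  perm <- with_seed(seed, sample(length(labels)))
  wilks_lambda(theta2, labels[perm])
}

#' Top-two theta coordinates of one gene's expression distributions
#'
#' Runs the embedding on a single gene: subsample cells per donor, estimate
#' the donor-by-donor inner products of the 1-D expression distributions
#' (`gamma = 1` since `p = 1`), decompose, and return the two leading axes.
#'
#' @param profiles list of [donor_profile]s sharing feature names.
#' @param gene gene name present in all profiles.
#' @param n cells subsampled per donor.
#' @param seed integer master seed for the subsampling.
#' @param gamma RBF bandwidth (default `default_gamma(1)` = 1).
#' @param positive_only take the top axes among positive-eigenvalue axes
#'   only (default `FALSE`: the first two axes in signed order).
#' @return N x 2 matrix of donor coordinates.
#' @export
per_gene_theta <- function(profiles, gene, n, seed,
                           gamma = default_gamma(1), positive_only = FALSE) {
  feats <- shared_features(profiles)
  if (!gene %in% feats)
    stop("gene '", gene, "' not present in the profiles", call. = FALSE)
  samples <- subsample_cohort(profiles, n, seed)
  cols <- lapply(samples, function(s) s$cells[, gene])
  ids <- vapply(samples, `[[`, "", "donor_id")
  dec <- deef_decompose(gene_gram(cols, ids, gamma))
  theta_source(dec, gene, positive_only)
}

# internal: weighted 1-D gram from per-donor value vectors
gene_gram <- function(cols, ids, gamma) {
  comp <- lapply(cols, function(v) {
    tab <- table(v)
    list(values = as.numeric(names(tab)),
         weights = as.numeric(tab) / length(v))
  })
  G <- .gram1d_cpp(lapply(comp, `[[`, "values"),
                   lapply(comp, `[[`, "weights"), gamma)
  dimnames(G) <- list(ids, ids)
  structure(list(values = G, donor_ids = ids), class = "gram_matrix")
}

# internal: pick the two "top theta" columns per the configured convention
theta_source <- function(dec, gene, positive_only) {
  if (positive_only) {
    if (dec$n_positive < 2)
      stop("gene '", gene, "' yields fewer than 2 positive axes",
           call. = FALSE)
    positive_axes(dec)[, 1:2, drop = FALSE]
  } else {
    if (ncol(dec$theta) < 2)
      stop("gene '", gene, "' yields fewer than 2 axes", call. = FALSE)
    top_theta(dec, 2)
  }
}

#' Differential-distributed-gene scan
#'
#' For every gene: embed the donors by that gene's expression distribution
#' (1-D kernel mean embedding, DEEF, top two theta axes), compute the
#' observed Wilks' lambda for the group labels, and one label-permutation
#' null lambda.  Genes are ranked ascending by observed lambda -- the
#' smallest-lambda genes are the differentially distributed ones.  One
#' global cell subsample per donor is drawn for the whole run and the
#' per-gene distribution is that column slice; permutations are independent
#' per gene with derived seeds.  No multiple-testing correction is applied:
#' the scan exposes raw lambdas and the pooled permutation null, which the
#' QQ table compares.
#'
#' @param profiles list of [donor_profile]s sharing feature names.
#' @param labels group labels aligned with `profiles` (at least 2 donors
#'   per group).
#' @param genes genes to scan (default: all shared features).
#' @param n cells subsampled per donor.
#' @param master_seed integer; subsampling and per-gene permutation seeds
#'   derive from it.
#' @param gamma RBF bandwidth for the 1-D kernel (default 1).
#' @param positive_only restrict the top two axes to positive eigenvalues.
#' @param keep_theta how many extreme genes (from each end of the lambda
#'   ranking) retain their theta matrices for plotting (default 1).
#' @return a `ddg_result`: list with `table` (gene, lambda, null_lambda,
#'   rank -- `NA` lambdas are degenerate and excluded from ranking), `qq`
#'   (sorted observed vs sorted null), `theta_extreme` (named list of N x 2
#'   matrices), `degenerate` (character vector of flagged genes).
#' @export
ddg_scan <- function(profiles, labels, genes = NULL, n, master_seed,
                     gamma = default_gamma(1), positive_only = FALSE,
                     keep_theta = 1) {
  feats <- shared_features(profiles)
  if (is.null(genes)) genes <- feats
  if (!all(genes %in% feats))
    stop("unknown genes: ",
         paste(utils::head(setdiff(genes, feats), 5), collapse = ", "),
         call. = FALSE)
  labels <- factor(labels)
  seeds <- derive_seeds(master_seed, 1L + length(genes))
  samples <- subsample_cohort(profiles, n, seeds[1])
  ids <- vapply(samples, `[[`, "", "donor_id")
  obs <- null <- rep(NA_real_, length(genes))
  thetas <- vector("list", length(genes))
  degenerate <- character(0)
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    cols <- lapply(samples, function(s) s$cells[, g])
    th <- tryCatch({
      dec <- deef_decompose(gene_gram(cols, ids, gamma))
      theta_source(dec, g, positive_only)
    }, error = function(e) NULL)
    if (is.null(th)) { degenerate <- c(degenerate, g); next }
    thetas[[gi]] <- th
    obs[gi] <- suppressWarnings(wilks_lambda(th, labels))
    null[gi] <- suppressWarnings(permutation_null(th, labels,
                                                  seed = seeds[1L + gi]))
    if (is.na(obs[gi])) degenerate <- c(degenerate, g)
  }
  ok <- !is.na(obs)
  rank_vec <- rep(NA_integer_, length(genes))
  rank_vec[ok] <- rank(obs[ok], ties.method = "first")
  tab <- data.frame(gene = genes, lambda = obs, null_lambda = null,
                    rank = rank_vec)
  tab <- tab[order(is.na(tab$lambda), tab$rank), ]
  rownames(tab) <- NULL
  qq <- data.frame(null_quantile = sort(null[ok & !is.na(null)]),
                   observed_quantile = sort(obs[ok])[
                     seq_len(sum(ok & !is.na(null)))])
  extreme <- character(0)
  if (keep_theta > 0 && any(ok)) {
    ranked <- tab$gene[!is.na(tab$lambda)]
    extreme <- unique(c(utils::head(ranked, keep_theta),
                        utils::tail(ranked, keep_theta)))
  }
  theta_extreme <- stats::setNames(
    thetas[match(extreme, genes)], extreme)
  structure(list(table = tab, qq = qq, theta_extreme = theta_extreme,
                 degenerate = unique(degenerate),
                 donor_ids = ids, labels = labels),
            class = "ddg_result")
}

#' Stability of per-gene lambdas under cell resampling
#'
#' Runs [ddg_scan] several times with different subsampling seeds and
#' reports the pairwise Spearman correlation of per-gene observed lambdas
#' across repetitions.
#'
#' @inheritParams ddg_scan
#' @param n_reps number of repetitions (default 2).
#' @return list with `lambda` (genes x reps matrix) and `correlations`
#'   (data frame rep_a, rep_b, spearman).
#' @export
ddg_stability <- function(profiles, labels, genes = NULL, n, master_seed,
                          n_reps = 2, ...) {
  rep_seeds <- derive_seeds(master_seed, n_reps)
  scans <- lapply(rep_seeds, function(s)
    ddg_scan(profiles, labels, genes = genes, n = n, master_seed = s, ...))
  gene_names <- scans[[1]]$table$gene[order(scans[[1]]$table$gene)]
  lam <- vapply(scans, function(s)
    s$table$lambda[match(gene_names, s$table$gene)],
    numeric(length(gene_names)))
  rownames(lam) <- gene_names
  pairs <- utils::combn(n_reps, 2)
  cors <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(pi) {
    a <- pairs[1, pi]; b <- pairs[2, pi]
    data.frame(rep_a = a, rep_b = b,
               spearman = stats::cor(lam[, a], lam[, b],
                                     method = "spearman",
                                     use = "complete.obs"))
  }))
  list(lambda = lam, correlations = cors)
}
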