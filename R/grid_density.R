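#' Build an evaluation grid over the pooled marker ranges
#'
#' The grid-wise inner-product route evaluates each donor's density on a
#' common low-dimensional grid.  Per feature, the covered range is the
#' interval between the `alpha` and `1 - alpha` pooled percentiles (trimmed
#' so stray extreme events do not stretch the grid), divided into
#' equal-width bins whose centers are the grid coordinates.  The full grid
#' is the Cartesian product, `bins^p` points, which is why this estimator is
#' only for data with few markers.
#'
#' @param profiles list of [donor_profile]s with common features.
#' @param alpha percentile trim in `[0, 0.5)` (default 0.15).
#' @param bins bins per feature (default 10).
#' @param k neighbour count stored for later density estimation
#'   (default 100).
#' @param max_points guard on `bins^p` (default `1e7`).
#' @return a `grid_spec`: list with `centers` (per-feature bin centers),
#'   `grid_points` (`bins^p` x p matrix), `alpha`, `bins`, `k`, `range`.
#' @export
build_grid <- function(profiles, alpha = 0.15, bins = 10, k = 100,
                       max_points = 1e7) {
  if (alpha < 0 || alpha >= 0.5) stop("`alpha` must be in [0, 0.5)",
                                      call. = FALSE)
  if (bins < 2) stop("need at least 2 bins per feature", call. = FALSE)
  feats <- shared_features(profiles)
  p <- length(feats)
  if (bins^p > max_points)
    stop("grid would hold ", format(bins^p, scientific = TRUE), " points; ",
         "the grid-density route is designed for data with few markers ",
         "(use the kernel route for high-dimensional data)", call. = FALSE)
  pooled <- do.call(rbind, lapply(profiles, `[[`, "expression"))
  centers <- lapply(seq_len(p), function(j) {
    rng <- stats::quantile(pooled[, j], c(alpha, 1 - alpha), names = FALSE,
                           type = 7)
    if (diff(rng) <= 0)
      stop("degenerate pooled range for feature '", feats[j], "'",
           call. = FALSE)
    width <- diff(rng) / bins
    rng[1] + width * (seq_len(bins) - 0.5)
  })
  names(centers) <- feats
  grid_points <- as.matrix(expand.grid(centers, KEEP.OUT.ATTRS = FALSE))
  structure(list(centers = centers, grid_points = grid_points,
                 alpha = alpha, bins = as.integer(bins), k = as.integer(k),
                 range = lapply(seq_len(p), function(j)
                   stats::quantile(pooled[, j], c(alpha, 1 - alpha),
                                   names = FALSE))),
            class = "grid_spec")
}

#' k-nearest-neighbour density of a cell sample on a grid
#'
#' At each grid point `g` the raw kNN density estimate is proportional to
#' `k / (n * V(r_k(g)))`, with `r_k(g)` the Euclidean distance from `g` to
#' its k-th nearest cell and `V` the volume of the p-ball.  Because the
#' vector is normalized to sum to 1, all constants cancel and the
#' implementation uses `1 / r_k(g)^p`.  A grid point coinciding with at
#' least `k` cells (`r_k = 0`) is assigned the maximum finite density
#' before normalization.
#'
#' @param sample a `cell_sample` (or any n x p matrix via `cells`); requires
#'   `n >= grid$k`.
#' @param grid a [build_grid] result.
#' @return a `density_vector`: list with `donor_id` and `densities`
#'   (length `bins^p`, non-negative, summing to 1).
#' @export
knn_density <- function(sample, grid) {
  cells <- if (inherits(sample, "cell_sample")) sample$cells
           else as.matrix(sample)
  donor_id <- if (inherits(sample, "cell_sample")) sample$donor_id else NA
  n <- nrow(cells); p <- ncol(cells)
  k <- grid$k
  if (n < k)
    stop("sample has ", n, " cells but k = ", k,
         "; use a smaller k or a larger sample", call. = FALSE)
  if (p != ncol(grid$grid_points))
    stop("sample dimension ", p, " does not match grid dimension ",
         ncol(grid$grid_points), call. = FALSE)
  gp <- grid$grid_points
  c2 <- rowSums(cells^2)
  m <- nrow(gp)
  rk <- numeric(m)
  block <- max(1L, floor(2^22 / n))   # cap block x n distance matrix
  for (start in seq(1L, m, by = block)) {
    idx <- start:min(start + block - 1L, m)
    gsub <- gp[idx, , drop = FALSE]
    d2 <- outer(rowSums(gsub^2), c2, "+") - 2 * tcrossprod(gsub, cells)
    d2[d2 < 0] <- 0
    rk[idx] <- sqrt(apply(d2, 1L, function(row) sort(row, partial = k)[k]))
  }
  dens <- ifelse(rk > 0, 1 / rk^p, NA_real_)
  if (anyNA(dens)) {
    finite_max <- max(dens, na.rm = TRUE)
    message(sum(is.na(dens)), " grid point(s) coincide with >= k cells; ",
            "density set to the maximum finite value")
    dens[is.na(dens)] <- finite_max
  }
  dens <- dens / sum(dens)
  structure(list(donor_id = donor_id, densities = dens),
            class = "density_vector")
}

#' Inner product of two grid densities
#'
#' Plain dot product of two normalized density vectors on the same grid.
#'
#' @param di,dj `density_vector`s from [knn_density] on the same grid.
#' @return non-negative scalar.
#' @export
grid_inner_product <- function(di, dj) {
  a <- di$densities; b <- dj$densities
  if (length(a) != length(b))
    stop("density vectors have different lengths (", length(a), " vs ",
         length(b), "); were they built on the same grid?", call. = FALSE)
  sum(a * b)
}

#' Gram matrix from the grid-density route
#'
#' Builds the donor-by-donor inner-product matrix by grid-wise kNN density
#' estimation instead of kernel mean embedding.  Zero inner products
#' (disjoint supports) are floored at `1e-3` times the smallest positive
#' entry, with a warning, so the half-log DEEF step stays defined.
#'
#' @param samples list of `cell_sample`s.
#' @param grid a [build_grid] result.
#' @return a `gram_matrix` (same container as [build_gram_matrix]).
#' @export
build_grid_gram_matrix <- function(samples, grid) {
  ids <- vapply(samples, `[[`, "", "donor_id")
  if (anyDuplicated(ids)) stop("duplicate donor ids", call. = FALSE)
  dens <- lapply(samples, knn_density, grid = grid)
  N <- length(samples)
  G <- matrix(0, N, N, dimnames = list(ids, ids))
  for (i in seq_len(N)) for (j in i:N) {
    v <- grid_inner_product(dens[[i]], dens[[j]])
    G[i, j] <- v; G[j, i] <- v
  }
  if (any(G == 0)) {
    floor_val <- min(G[G > 0]) * 1e-3
    warning(sum(G == 0) / 2, " zero grid inner product(s) floored at ",
            signif(floor_val, 3), " before the log step")
    G[G == 0] <- floor_val
  }
  structure(list(values = G, donor_ids = ids), class = "gram_matrix")
}
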