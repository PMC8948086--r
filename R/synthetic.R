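#' Specification of a synthetic cytometry cohort
#'
#' Describes a cohort of donors per group, each donor a sample of cells
#' from a donor-specific Gaussian mixture: the components stand in for cell
#' subsets, group effects are encoded as differences between the per-group
#' mixtures, and donor-to-donor variation is a random shift of each
#' component mean.
#'
#' @param n_donors_per_group donors per group.
#' @param groups group labels.
#' @param n_cells_per_donor cells drawn per donor.
#' @param p number of markers.
#' @param mixture named list (one entry per group) of component lists, each
#'   component a list with `weight`, `mean` (length p), `cov` (p x p,
#'   symmetric positive definite).  Weights per group must sum to 1.
#' @param donor_effect_sd sd of the per-donor Normal shift applied to every
#'   component mean coordinate.
#' @param seed integer seed.
#' @return a `cohort_spec` list.
#' @seealso [default_cytometry_spec] for the reference three-subset cohort.
#' @export
cohort_spec <- function(n_donors_per_group, groups, n_cells_per_donor, p,
                        mixture, donor_effect_sd, seed) {
  stopifnot(identical(sort(names(mixture)), sort(as.character(groups))))
  for (g in names(mixture)) {
    w <- vapply(mixture[[g]], `[[`, 0, "weight")
    if (abs(sum(w) - 1) > 1e-8)
      stop("mixture weights for group '", g, "' sum to ", sum(w),
           ", not 1", call. = FALSE)
    for (comp in mixture[[g]]) {
      cov <- comp$cov
      if (!isSymmetric(unname(cov)) ||
          inherits(try(chol(cov), silent = TRUE), "try-error"))
        stop("a covariance for group '", g,
             "' is not symmetric positive definite", call. = FALSE)
      stopifnot(length(comp$mean) == p, nrow(cov) == p)
    }
  }
  structure(list(n_donors_per_group = as.integer(n_donors_per_group),
                 groups = as.character(groups),
                 n_cells_per_donor = as.integer(n_cells_per_donor),
                 p = as.integer(p), mixture = mixture,
                 donor_effect_sd = donor_effect_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Reference synthetic cytometry cohort: three subsets, one shifted
#'
#' Two groups, three mixture components per donor standing in for major
#' cell subsets (weights 0.5 / 0.3 / 0.2, unit covariance).  In group B the
#' second component's mean is shifted by `shift` standard deviations along
#' the first two markers -- a cohort where the groups differ in the location
#' of one cell subset, the situation a donor-level embedding must resolve.
#' Donor-to-donor variability perturbs every component mean with sd 0.2.
#'
#' @param n_donors_per_group donors per group (default 10).
#' @param n_cells_per_donor cells per donor (default 500).
#' @param p markers (default 5).
#' @param shift subset mean shift in group B, in within-subset sd units
#'   (default 3; 0 gives a null cohort).
#' @param donor_effect_sd per-donor mean jitter sd (default 0.2).
#' @param seed integer seed (default 1).
#' @return a `cohort_spec`.
#' @export
default_cytometry_spec <- function(n_donors_per_group = 10,
                                   n_cells_per_donor = 500, p = 5,
                                   shift = 3, donor_effect_sd = 0.2,
                                   seed = 1) {
  base_means <- list(rep(0, p),
                     c(3, rep(0, p - 1)),
                     c(0, 3, rep(0, p - 2))[seq_len(p)])
  comp <- function(w, m) list(weight = w, mean = m, cov = diag(p))
  mix_a <- list(comp(0.5, base_means[[1]]), comp(0.3, base_means[[2]]),
                comp(0.2, base_means[[3]]))
  shifted <- base_means[[2]] + c(shift, shift, rep(0, p - 2))[seq_len(p)]
  mix_b <- list(comp(0.5, base_means[[1]]), comp(0.3, shifted),
                comp(0.2, base_means[[3]]))
  cohort_spec(n_donors_per_group = n_donors_per_group,
              groups = c("A", "B"),
              n_cells_per_donor = n_cells_per_donor, p = p,
              mixture = list(A = mix_a, B = mix_b),
              donor_effect_sd = donor_effect_sd, seed = seed)
}

# internal: n draws from N(mean, cov) via Cholesky
rmvn <- function(n, mean, cov) {
  p <- length(mean)
  z <- matrix(stats::rnorm(n * p), n, p) %*% chol(cov)
  sweep(z, 2, mean, "+")
}

#' Simulate a cytometry cohort from a specification
#'
#' Per donor: draw a Normal(0, `donor_effect_sd`^2) perturbation of every
#' component mean coordinate, then `n_cells_per_donor` cells from the
#' resulting Gaussian mixture.  Deterministic given the spec's seed.
#'
#' @param spec a [cohort_spec].
#' @return list with `profiles` (list of [donor_profile]s) and `labels`
#'   (factor of group labels, one per donor).
#' @export
simulate_cytometry_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    profiles <- list(); labels <- character(0)
    markers <- paste0("marker", seq_len(spec$p))
    for (g in spec$groups) for (d in seq_len(spec$n_donors_per_group)) {
      comps <- spec$mixture[[g]]
      comps <- lapply(comps, function(cm) {
        cm$mean <- cm$mean + stats::rnorm(spec$p, 0, spec$donor_effect_sd)
        cm
      })
      w <- vapply(comps, `[[`, 0, "weight")
      assign_c <- sample.int(length(comps), spec$n_cells_per_donor,
                             replace = TRUE, prob = w)
      cells <- matrix(0, spec$n_cells_per_donor, spec$p)
      for (ci in seq_along(comps)) {
        rows <- which(assign_c == ci)
        if (length(rows))
          cells[rows, ] <- rmvn(length(rows), comps[[ci]]$mean,
                                comps[[ci]]$cov)
      }
      id <- paste0(g, d)
      profiles[[id]] <- donor_profile(cells, id, feature_names = markers,
                                      group_label = g)
      labels <- c(labels, g)
    }
    list(profiles = profiles, labels = factor(labels))
  })
}

#' Simulate a multi-donor scRNA-seq cohort with ground-truth signal genes
#'
#' Counts follow a per-gene negative-binomial model: base means are
#' log-normal (meanlog 0, sdlog 1), dispersions log-normal (size with
#' meanlog `log(2)`, sdlog 0.5), and each donor carries a small log-normal
#' random effect (sdlog 0.1) on every gene mean, so donors differ but only
#' signal genes differ *between groups*.  In the second group signal genes
#' are altered according to `effect`:
#' \describe{
#'   \item{`mean_shift`}{gene mean multiplied by `effect_size` (> 1).}
#'   \item{`variance_shift`}{dispersion inflated (size divided by
#'     `effect_size`) with the mean left untouched -- same average, wider
#'     distribution.}
#'   \item{`bimodality_shift`}{cells split evenly between a high mode at
#'     `mean * (1 + effect_size)` and a low mode at `mean * (1 -
#'     effect_size)` (`effect_size` in (0, 1)) -- same average, bimodal
#'     shape.}
#' }
#'
#' @param n_donors_per_group donors per group (default 6).
#' @param n_cells cells per donor (default 500).
#' @param n_genes total genes (default 500).
#' @param n_signal_genes genes carrying the group effect (default 50).
#' @param effect one of `"mean_shift"`, `"variance_shift"`,
#'   `"bimodality_shift"`.
#' @param effect_size effect magnitude (see above; 0 or 1 under
#'   `mean_shift` disables the signal).
#' @param seed integer seed.
#' @return list with `profiles` (raw-count [donor_profile]s), `labels`, and
#'   `truth` (data frame: gene, signal, effect); generator parameters are
#'   recorded in each profile's metadata.
#' @export
simulate_scrnaseq_cohort <- function(n_donors_per_group = 6, n_cells = 500,
                                     n_genes = 500, n_signal_genes = 50,
                                     effect = c("mean_shift",
                                                "variance_shift",
                                                "bimodality_shift"),
                                     effect_size = 1.5, seed = 1) {
  effect <- match.arg(effect)
  if (n_signal_genes > n_genes)
    stop("n_signal_genes exceeds n_genes", call. = FALSE)
  if (effect == "bimodality_shift" && (effect_size < 0 || effect_size >= 1))
    stop("bimodality_shift needs effect_size in [0, 1) or the low mode ",
         "mean turns negative", call. = FALSE)
  if (effect != "bimodality_shift" && effect_size < 0)
    stop("negative effect_size yields negative means", call. = FALSE)
  with_seed(seed, {
    genes <- sprintf("g%04d", seq_len(n_genes))
    base_mu <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 1)
    size <- stats::rlnorm(n_genes, meanlog = log(2), sdlog = 0.5)
    signal_idx <- sort(sample.int(n_genes, n_signal_genes))
    params <- list(base_mu_meanlog = 0, base_mu_sdlog = 1,
                   size_meanlog = log(2), size_sdlog = 0.5,
                   donor_effect_sdlog = 0.1,
                   effect = effect, effect_size = effect_size)
    profiles <- list(); labels <- character(0)
    groups <- c("ctrl", "case")
    for (g in groups) for (d in seq_len(n_donors_per_group)) {
      donor_mu <- base_mu * stats::rlnorm(n_genes, 0, 0.1)
      donor_size <- size
      counts <- matrix(0L, n_cells, n_genes)
      is_sig <- seq_len(n_genes) %in% signal_idx & g == "case"
      for (j in seq_len(n_genes)) {
        mu <- donor_mu[j]; sz <- donor_size[j]
        if (is_sig[j] && effect == "mean_shift") mu <- mu * effect_size
        if (is_sig[j] && effect == "variance_shift")
          sz <- sz / max(effect_size, 1e-8)
        if (is_sig[j] && effect == "bimodality_shift") {
          hi <- stats::rbinom(n_cells, 1, 0.5) == 1
          counts[, j] <- ifelse(hi,
            stats::rnbinom(n_cells, mu = mu * (1 + effect_size), size = sz),
            stats::rnbinom(n_cells, mu = mu * (1 - effect_size), size = sz))
        } else {
          counts[, j] <- stats::rnbinom(n_cells, mu = mu, size = sz)
        }
      }
      id <- paste0(g, d)
      profiles[[id]] <- donor_profile(counts, id, feature_names = genes,
                                      group_label = g,
                                      metadata = list(generator = params))
      labels <- c(labels, g)
    }
    truth <- data.frame(gene = genes,
                        signal = seq_len(n_genes) %in% signal_idx,
                        effect = ifelse(seq_len(n_genes) %in% signal_idx,
                                        effect, "none"))
    list(profiles = profiles, labels = factor(labels, levels = groups),
         truth = truth)
  })
}
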