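#' Configuration for the resampling-ensemble classifier
#'
#' Defaults are the reference supervised workflow: 5000 boosting rounds,
#' `max_depth` searched over {2, 3, 4, 5} by 5-fold cross-validation, the
#' number of leading theta axes searched incrementally with an
#' 11-non-improvement stop, 25 cell resamplings combined by majority vote,
#' and 1000 cells picked per donor.  Scale `n_estimators` and
#' `n_resamplings` down for quick runs; the defaults are tuned for accuracy,
#' not speed.
#'
#' @param n_estimators boosting rounds per fitted model.
#' @param max_depth_grid candidate tree depths.
#' @param cv_folds cross-validation folds.
#' @param patience consecutive non-improving axis counts tolerated before
#'   the incremental search stops.
#' @param n_resamplings number of cell resamplings in the ensemble; must be
#'   odd so a binary majority vote cannot tie.
#' @param n_cells cells subsampled per donor per resampling.
#' @param gamma RBF bandwidth; `NULL` = automatic `1/p`.
#' @param learner function `(x, y, max_depth, n_estimators)` returning an
#'   object whose `predict(object, newx)` yields labels; defaults to
#'   [gbt_fit].
#' @return a `classifier_config` list.
#' @export
classifier_config <- function(n_estimators = 5000,
                              max_depth_grid = c(2, 3, 4, 5),
                              cv_folds = 5, patience = 11,
                              n_resamplings = 25, n_cells = 1000,
                              gamma = NULL, learner = NULL) {
  if (n_resamplings %% 2 == 0)
    stop("`n_resamplings` must be odd so a binary majority vote cannot tie",
         call. = FALSE)
  if (is.null(learner))
    learner <- function(x, y, max_depth, n_estimators)
      gbt_fit(x, y, n_estimators = n_estimators, max_depth = max_depth)
  structure(list(n_estimators = as.integer(n_estimators),
                 max_depth_grid = as.integer(max_depth_grid),
                 cv_folds = as.integer(cv_folds),
                 patience = as.integer(patience),
                 n_resamplings = as.integer(n_resamplings),
                 n_cells = as.integer(n_cells),
                 gamma = gamma, learner = learner),
            class = "classifier_config")
}

# internal: stratified fold assignment; errors if a class cannot cover folds
stratified_folds <- function(labels, k, seed) {
  labels <- factor(labels)
  folds <- integer(length(labels))
  with_seed(seed, {
    for (lv in levels(labels)) {
      idx <- which(labels == lv)
      if (length(idx) < 2)
        stop("class '", lv, "' has fewer than 2 donors; stratified ",
             "cross-validation impossible", call. = FALSE)
      folds[sample(idx)] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Cross-validated selection of depth and axis count, then refit
#'
#' Grid-searches the tree depth and, incrementally, how many leading theta
#' axes to use.  For k = 1, 2, ... the first k columns are cross-validated
#' over the depth grid; the search stops once the best score ever seen has
#' not improved for more than `patience` consecutive k values (counter
#' resets on improvement), or k exhausts the columns.  Ties favour the
#' simpler model: the smaller depth, then the smaller k.  The model is
#' refitted on all training rows at the chosen setting.
#'
#' @param theta_train donors x axes matrix (positive-eigenvalue theta axes
#'   in contribution order).
#' @param labels_train class labels.
#' @param config a [classifier_config].
#' @param seed integer controlling fold assignment.
#' @return list with `model`, `k_coords`, `max_depth`, `cv_score`,
#'   `search` (per-(k, depth) CV accuracies).
#' @export
select_and_fit <- function(theta_train, labels_train, config, seed) {
  theta_train <- as.matrix(theta_train)
  labels_train <- factor(labels_train)
  folds <- stratified_folds(labels_train, config$cv_folds, seed)
  n_folds_eff <- length(unique(folds))
  best <- list(score = -Inf, k = NA_integer_, depth = NA_integer_)
  since_improve <- 0L
  search <- list()
  for (k in seq_len(ncol(theta_train))) {
    xk <- theta_train[, seq_len(k), drop = FALSE]
    improved <- FALSE
    for (depth in config$max_depth_grid) {
      acc <- vapply(seq_len(n_folds_eff), function(f) {
        tr <- folds != f
        if (nlevels(droplevels(labels_train[tr])) < 2) return(NA_real_)
        m <- config$learner(xk[tr, , drop = FALSE], labels_train[tr],
                            max_depth = depth,
                            n_estimators = config$n_estimators)
        mean(stats::predict(m, xk[!tr, , drop = FALSE]) ==
               labels_train[!tr])
      }, numeric(1))
      score <- mean(acc, na.rm = TRUE)
      search[[length(search) + 1L]] <-
        data.frame(k = k, max_depth = depth, cv_accuracy = score)
      if (score > best$score) {      # strict: ties keep smaller depth/k
        best <- list(score = score, k = k, depth = depth)
        improved <- TRUE
      }
    }
    since_improve <- if (improved) 0L else since_improve + 1L
    if (since_improve > config$patience) break
  }
  model <- config$learner(theta_train[, seq_len(best$k), drop = FALSE],
                          labels_train, max_depth = best$depth,
                          n_estimators = config$n_estimators)
  list(model = model, k_coords = best$k, max_depth = best$depth,
       cv_score = best$score, search = do.call(rbind, search))
}

#' Resampling-ensemble donor classification
#'
#' The full supervised workflow: for each of `n_resamplings` derived seeds,
#' subsample cells from *all* donors (training and test together -- the
#' embedding step is unsupervised, so no label information leaks), build one
#' joint Gram matrix, run the DEEF decomposition, keep the
#' positive-eigenvalue axes, tune and fit the learner on the training rows,
#' and predict the test rows.  The final label per test donor is the
#' majority vote over resamplings.  Multi-class vote ties are broken by the
#' highest mean predicted-class frequency, then lexicographically, and
#' flagged.
#'
#' @param train_profiles,test_profiles lists of [donor_profile]s.
#' @param train_labels labels aligned with `train_profiles`.
#' @param config a [classifier_config].
#' @param master_seed integer; every resampling seed derives from it.
#' @param test_labels optional true test labels; enables accuracy fields.
#' @return a `prediction_result`: list with `per_resampling` (labels,
#'   resamplings x test donors), `ensemble` (majority-vote labels),
#'   `per_resampling_accuracy`, `ensemble_accuracy` (NA without
#'   `test_labels`), `hyperparams` (per-resampling chosen depth and axis
#'   count), `tied_votes`.
#' @export
ensemble_predict <- function(train_profiles, train_labels, test_profiles,
                             config, master_seed, test_labels = NULL) {
  train_labels <- factor(train_labels)
  n_test <- length(test_profiles)
  all_profiles <- c(train_profiles, test_profiles)
  shared_features(all_profiles)
  p <- n_features(all_profiles[[1]])
  gamma <- if (is.null(config$gamma)) default_gamma(p) else config$gamma
  n_train <- length(train_profiles)
  seeds <- derive_seeds(master_seed, config$n_resamplings)
  preds <- matrix(NA_character_, config$n_resamplings, n_test)
  colnames(preds) <- vapply(test_profiles, `[[`, "", "donor_id")
  hyper <- data.frame(resampling = seq_len(config$n_resamplings),
                      k_coords = NA_integer_, max_depth = NA_integer_,
                      cv_score = NA_real_)
  for (r in seq_len(config$n_resamplings)) {
    samples <- subsample_cohort(all_profiles, config$n_cells, seeds[r])
    dec <- deef_decompose(build_gram_matrix(samples, gamma))
    pos <- positive_axes(dec)
    fit <- select_and_fit(pos[seq_len(n_train), , drop = FALSE],
                          train_labels, config, seed = seeds[r])
    preds[r, ] <- as.character(stats::predict(
      fit$model,
      pos[n_train + seq_len(n_test), seq_len(fit$k_coords), drop = FALSE]))
    hyper$k_coords[r] <- fit$k_coords
    hyper$max_depth[r] <- fit$max_depth
    hyper$cv_score[r] <- fit$cv_score
  }
  lev <- levels(train_labels)
  freq <- t(apply(preds, 2, function(v)
    tabulate(factor(v, levels = lev), nbins = length(lev))))
  top <- apply(freq, 1, max)
  tied <- rowSums(freq == top) > 1
  ensemble <- factor(lev[max.col(freq, ties.method = "first")], levels = lev)
  per_acc <- ens_acc <- NA_real_
  if (!is.null(test_labels)) {
    test_labels <- factor(test_labels, levels = lev)
    per_acc <- apply(preds, 1, function(v) mean(v == as.character(test_labels)))
    ens_acc <- mean(ensemble == test_labels)
  }
  structure(list(per_resampling = preds, ensemble = ensemble,
                 per_resampling_accuracy = per_acc,
                 ensemble_accuracy = ens_acc, hyperparams = hyper,
                 tied_votes = which(tied), levels = lev),
            class = "prediction_result")
}

# internal: depth-only CV grid search on a fixed feature matrix
cv_depth <- function(x, labels, config, seed) {
  folds <- stratified_folds(labels, config$cv_folds, seed)
  best <- list(score = -Inf, depth = config$max_depth_grid[1])
  for (depth in config$max_depth_grid) {
    acc <- vapply(unique(folds), function(f) {
      tr <- folds != f
      m <- config$learner(x[tr, , drop = FALSE], labels[tr],
                          max_depth = depth,
                          n_estimators = config$n_estimators)
      mean(stats::predict(m, x[!tr, , drop = FALSE]) == labels[!tr])
    }, numeric(1))
    score <- mean(acc, na.rm = TRUE)
    if (score > best$score) best <- list(score = score, depth = depth)
  }
  best
}

#' Resampling-ensemble classification across measurement conditions
#'
#' For cohorts where each donor is measured under several conditions
#' (stimulations, tubes): per resampling, each condition is embedded
#' jointly (train + test donors), the optimal axis count is determined per
#' condition on the training rows, the chosen leading axes of all
#' conditions are concatenated column-wise, and a single model (depth
#' selected by cross-validation on the concatenated matrix) predicts the
#' test donors.  Ensembling by majority vote as in [ensemble_predict].
#'
#' @param profiles_by_condition named list: condition -> named list of
#'   [donor_profile]s (names are donor ids; every condition must cover
#'   every donor).
#' @param train_ids,test_ids donor-id vectors.
#' @param labels named vector/factor of labels for all donors.
#' @param config a [classifier_config].
#' @param master_seed integer.
#' @param test_labels optional true test labels (in `test_ids` order).
#' @return a `prediction_result` (see [ensemble_predict]).
#' @export
ensemble_predict_conditions <- function(profiles_by_condition, train_ids,
                                        test_ids, labels, config,
                                        master_seed, test_labels = NULL) {
  conds <- sort(names(profiles_by_condition))
  donors <- c(train_ids, test_ids)
  train_labels <- factor(labels[train_ids])
  n_train <- length(train_ids)
  seeds <- derive_seeds(master_seed, config$n_resamplings)
  preds <- matrix(NA_character_, config$n_resamplings, length(test_ids))
  colnames(preds) <- test_ids
  hyper <- data.frame(resampling = seq_len(config$n_resamplings),
                      k_coords = NA_integer_, max_depth = NA_integer_,
                      cv_score = NA_real_)
  for (r in seq_len(config$n_resamplings)) {
    cond_seeds <- derive_seeds(seeds[r], length(conds))
    theta_tr <- list(); theta_te <- list()
    for (ci in seq_along(conds)) {
      profs <- profiles_by_condition[[conds[ci]]][donors]
      if (anyNA(names(profs)))
        stop("condition '", conds[ci], "' is missing donors", call. = FALSE)
      gamma <- if (is.null(config$gamma))
        default_gamma(n_features(profs[[1]])) else config$gamma
      samples <- subsample_cohort(profs, config$n_cells, cond_seeds[ci])
      pos <- positive_axes(deef_decompose(build_gram_matrix(samples, gamma)))
      fit <- select_and_fit(pos[seq_len(n_train), , drop = FALSE],
                            train_labels, config, seed = cond_seeds[ci])
      keep <- seq_len(fit$k_coords)
      theta_tr[[conds[ci]]] <- pos[seq_len(n_train), keep, drop = FALSE]
      theta_te[[conds[ci]]] <-
        pos[n_train + seq_along(test_ids), keep, drop = FALSE]
    }
    xtr <- concatenate_conditions(theta_tr)
    xte <- concatenate_conditions(theta_te)
    pick <- cv_depth(xtr, train_labels, config, seed = seeds[r])
    model <- config$learner(xtr, train_labels, max_depth = pick$depth,
                            n_estimators = config$n_estimators)
    preds[r, ] <- as.character(stats::predict(model, xte))
    hyper$k_coords[r] <- ncol(xtr)
    hyper$max_depth[r] <- pick$depth
    hyper$cv_score[r] <- pick$score
  }
  lev <- levels(train_labels)
  freq <- t(apply(preds, 2, function(v)
    tabulate(factor(v, levels = lev), nbins = length(lev))))
  tied <- rowSums(freq == apply(freq, 1, max)) > 1
  ensemble <- factor(lev[max.col(freq, ties.method = "first")], levels = lev)
  per_acc <- ens_acc <- NA_real_
  if (!is.null(test_labels)) {
    test_labels <- factor(test_labels, levels = lev)
    per_acc <- apply(preds, 1, function(v)
      mean(v == as.character(test_labels)))
    ens_acc <- mean(ensemble == test_labels)
  }
  structure(list(per_resampling = preds, ensemble = ensemble,
                 per_resampling_accuracy = per_acc,
                 ensemble_accuracy = ens_acc, hyperparams = hyper,
                 tied_votes = which(tied), levels = lev),
            class = "prediction_result")
}

#' Concatenate per-condition theta matrices column-wise
#'
#' For cohorts measured under several conditions the feature matrix is the
#' column-wise concatenation of each condition's theta matrix (with the
#' per-condition axis count fixed beforehand).  Conditions are stacked in
#' sorted name order; column names are prefixed by the condition.
#'
#' @param theta_by_condition named list of donors x axes matrices sharing an
#'   identical donor row order (row names required).
#' @return the combined matrix.
#' @export
concatenate_conditions <- function(theta_by_condition) {
  stopifnot(length(theta_by_condition) >= 1,
            !is.null(names(theta_by_condition)))
  ord <- order(names(theta_by_condition))
  theta_by_condition <- theta_by_condition[ord]
  ref <- rownames(theta_by_condition[[1]])
  if (is.null(ref)) stop("theta matrices need donor row names", call. = FALSE)
  for (nm in names(theta_by_condition)) {
    rn <- rownames(theta_by_condition[[nm]])
    if (!identical(rn, ref)) {
      bad <- which(rn != ref)[1]
      if (is.na(bad)) bad <- min(length(rn), length(ref)) + 1L
      stop("condition '", nm, "' disagrees on donor row order (first ",
           "mismatch: '", rn[min(bad, length(rn))], "')", call. = FALSE)
    }
  }
  blocks <- lapply(names(theta_by_condition), function(nm) {
    m <- theta_by_condition[[nm]]
    colnames(m) <- paste(nm, colnames(m), sep = ".")
    m
  })
  do.call(cbind, blocks)
}

#' Stratified donor-level train/test split
#'
#' Splits donors (never a single donor's conditions) into training and test
#' sets, stratified by label so both sides see every class.
#'
#' @param donors character vector of donor ids.
#' @param labels labels aligned with `donors`.
#' @param train_fraction fraction of each class assigned to training
#'   (default 0.5); the test side must be non-empty.
#' @param seed integer.
#' @return list with `train` and `test` donor-id vectors.
#' @export
train_test_split_donors <- function(donors, labels, train_fraction = 0.5,
                                    seed = 1) {
  labels <- factor(labels)
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("`train_fraction` must be in (0, 1)", call. = FALSE)
  train <- character(0)
  with_seed(seed, {
    for (lv in levels(labels)) {
      idx <- which(labels == lv)
      if (length(idx) < 2)
        stop("class '", lv, "' has a single donor; cannot split",
             call. = FALSE)
      n_tr <- max(1L, min(length(idx) - 1L,
                          round(length(idx) * train_fraction)))
      train <- c(train, donors[sample(idx, n_tr)])
    }
  })
  list(train = donors[donors %in% train],
       test = donors[!donors %in% train])
}
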