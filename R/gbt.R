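#' Gradient-boosted tree classifier
#'
#' The reference learner for the supervised workflow: second-order boosting
#' of depth-limited regression trees under binary logistic loss, with
#' shrinkage `eta` and L2 leaf regularization `lambda` (the standard
#' boosting-library defaults).  Multi-class labels are handled one-vs-rest.
#' The learner interface is deliberately small -- `fit(x, y)` returning an
#' object with a `predict` method producing labels -- so an alternative
#' implementation can be plugged into [ensemble_predict].
#'
#' @param x numeric feature matrix (donors in rows).
#' @param y factor (or coercible) of class labels, length `nrow(x)`.
#' @param n_estimators number of boosting rounds.
#' @param max_depth maximum tree depth.
#' @param eta learning rate (default 0.3).
#' @param lambda L2 regularization on leaf weights (default 1).
#' @param min_child_weight minimum hessian sum per leaf (default 1).
#' @return an object of class `gbt_model`.
#' @examples
#' x <- matrix(rnorm(60), 30, 2); y <- factor(x[, 1] > 0)
#' m <- gbt_fit(x, y, n_estimators = 30, max_depth = 2)
#' mean(predict(m, x) == y)
#' @export
gbt_fit <- function(x, y, n_estimators = 100, max_depth = 3, eta = 0.3,
                    lambda = 1, min_child_weight = 1) {
  x <- as.matrix(x); storage.mode(x) <- "double"
  y <- factor(y)
  if (nrow(x) != length(y)) stop("nrow(x) != length(y)", call. = FALSE)
  if (nlevels(y) < 2) stop("need at least 2 classes", call. = FALSE)
  fit1 <- function(y01) {
    pbar <- min(max(mean(y01), 1e-6), 1 - 1e-6)
    .gbt_fit_cpp(x, as.numeric(y01), as.integer(n_estimators),
                 as.integer(max_depth), eta, lambda, min_child_weight,
                 log(pbar / (1 - pbar)))
  }
  boosters <- if (nlevels(y) == 2L) list(fit1(as.integer(y) - 1L))
              else lapply(levels(y), function(lv) fit1(as.integer(y == lv)))
  structure(list(boosters = boosters, levels = levels(y),
                 n_estimators = n_estimators, max_depth = max_depth),
            class = "gbt_model")
}

#' @rdname gbt_fit
#' @param object a `gbt_model`.
#' @param newx feature matrix to predict.
#' @param type `"label"` (default) or `"prob"`.
#' @param ... unused.
#' @export
predict.gbt_model <- function(object, newx, type = c("label", "prob"), ...) {
  type <- match.arg(type)
  newx <- as.matrix(newx); storage.mode(newx) <- "double"
  margins <- vapply(object$boosters, function(b)
    .gbt_margin_cpp(b$trees, b$base_score, newx), numeric(nrow(newx)))
  margins <- matrix(margins, nrow = nrow(newx))
  prob <- 1 / (1 + exp(-margins))
  if (length(object$boosters) == 1L) {
    prob <- cbind(1 - prob[, 1], prob[, 1])
  } else {
    prob <- prob / rowSums(prob)
  }
  colnames(prob) <- object$levels
  if (type == "prob") return(prob)
  factor(object$levels[max.col(prob, ties.method = "first")],
         levels = object$levels)
}
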