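#' Spike-count features over the excitatory population
#'
#' The readout sees only how often each excitatory neuron fired during the
#' sample — a memoryless summary: permuting event times within a sample
#' leaves the features unchanged. Inhibitory events are ignored.
#'
#' @param raster A liquid [spike_raster()] from [simulate_liquid()].
#' @param excitatory_ids Integer ids of the excitatory neurons (e.g.
#'   `which(liquid$neurons$is_excitatory)`).
#' @return An integer count vector of length `length(excitatory_ids)`.
#' @export
extract_features <- function(raster, excitatory_ids) {
  counts <- tabulate(raster$source, nbins = n_sources(raster))
  counts[excitatory_ids]
}

# stratified fold assignment: each class is spread over the folds
stratified_folds <- function(labels, k, seed = 1L) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Fit the spike-count linear readout
#'
#' The only trained component: a multinomial logistic regression with an
#' L2 (ridge) penalty on raw integer spike counts, fitted with glmnet.
#' Only the regularization strength is tuned, by stratified K-fold
#' cross-validated accuracy over an inverse-strength grid `C` (the penalty
#' is `lambda = 1 / (C * n_samples)`); ties prefer the stronger penalty.
#'
#' @param features A samples x neurons numeric matrix (or list of count
#'   vectors).
#' @param labels Class labels (coerced to factor, >= 2 classes).
#' @param reg_grid Inverse-regularization grid (default
#'   `c(0.01, 0.1, 1, 10)`).
#' @param n_folds Cross-validation folds (default 5, capped at the
#'   smallest class size).
#' @param seed Seed for the fold assignment.
#' @return An `elsm_readout` object.
#' @examples
#' x <- rbind(matrix(rpois(60, 2), 10), matrix(rpois(60, 6), 10))
#' fit <- fit_readout(x, rep(c("a", "b"), each = 10), seed = 1)
#' glance(fit)
#' @export
fit_readout <- function(features, labels, reg_grid = c(0.01, 0.1, 1, 10),
                        n_folds = 5, seed = 1L) {
  x <- if (is.list(features)) do.call(rbind, features) else as.matrix(features)
  y <- factor(labels)
  if (nlevels(y) < 2) abort("At least two classes are required.")
  if (nrow(x) != length(y)) abort("`features` and `labels` length mismatch.")
  n <- nrow(x)
  lambdas <- sort(1 / (reg_grid * n), decreasing = TRUE)
  k <- max(2L, min(n_folds, min(table(y))))
  fold <- stratified_folds(y, k, seed)
  # CV folds are small by construction; glmnet's small-class warning is
  # expected there and muffled, all other warnings pass through.
  quiet_glmnet <- function(...) {
    withCallingHandlers(
      glmnet::glmnet(..., family = "multinomial", alpha = 0,
                     lambda = lambdas),
      warning = function(w) {
        if (grepl("fewer than 8", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
  }
  cv_acc <- matrix(NA_real_, k, length(lambdas))
  for (f in seq_len(k)) {
    tr <- fold != f
    fit <- quiet_glmnet(x[tr, , drop = FALSE], y[tr])
    pred <- predict(fit, x[!tr, , drop = FALSE], s = lambdas,
                    type = "class")
    cv_acc[f, ] <- colMeans(pred == as.character(y[!tr]))
  }
  mean_acc <- colMeans(cv_acc)
  # ties -> largest lambda (strongest penalty); lambdas are decreasing
  best <- which.max(mean_acc)
  model <- quiet_glmnet(x, y)
  structure(
    list(model = model, lambda = lambdas[best],
         C = 1 / (lambdas[best] * n), reg_grid = reg_grid,
         cv_accuracy = setNames(mean_acc, signif(lambdas, 4)),
         classes = levels(y), n_features = ncol(x), n_train = n,
         seed = as.integer(seed)),
    class = "elsm_readout"
  )
}

#' @export
print.elsm_readout <- function(x, ...) {
  cat(sprintf(
    "<elsm_readout> %d classes on %d spike-count features (n = %d)\n",
    length(x$classes), x$n_features, x$n_train
  ))
  cat(sprintf("  ridge lambda %.4g (C = %.3g), CV accuracy %.3f\n",
              x$lambda, x$C, max(x$cv_accuracy)))
  invisible(x)
}

#' Predict classes from spike-count features
#'
#' @param object An `elsm_readout`.
#' @param features Samples x neurons matrix (or list of count vectors).
#' @param ... Unused.
#' @return Factor of predicted classes.
#' @export
predict.elsm_readout <- function(object, features, ...) {
  x <- if (is.list(features)) do.call(rbind, features) else as.matrix(features)
  if (ncol(x) != object$n_features) {
    abort(sprintf("Expected %d features, got %d.",
                  object$n_features, ncol(x)))
  }
  pred <- predict(object$model, x, s = object$lambda, type = "class")
  factor(pred[, 1], levels = object$classes)
}

#' Classification accuracy of a fitted readout
#'
#' @param model An `elsm_readout`.
#' @param features,labels Evaluation data.
#' @return Fraction of correct argmax predictions.
#' @export
evaluate_readout <- function(model, features, labels) {
  y <- factor(labels, levels = model$classes)
  n <- if (is.list(features)) length(features) else nrow(as.matrix(features))
  if (n != length(y)) abort("`features` and `labels` length mismatch.")
  mean(predict(model, features) == y)
}

#' @rdname fit_readout
#' @param x An `elsm_readout`.
#' @param ... Unused.
#' @export
tidy.elsm_readout <- function(x, ...) {
  coefs <- glmnet::coef.glmnet(x$model, s = x$lambda)
  purrr::map_dfr(names(coefs), function(cl) {
    m <- as.matrix(coefs[[cl]])
    tibble(class = cl,
           term = rownames(m),
           estimate = m[, 1])
  })
}

#' @rdname fit_readout
#' @export
glance.elsm_readout <- function(x, ...) {
  tibble(
    n_classes = length(x$classes),
    n_features = x$n_features,
    n_train = x$n_train,
    lambda = x$lambda,
    C = x$C,
    cv_accuracy = max(x$cv_accuracy)
  )
}
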