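class_levels <- function(labels) {
  if (is.factor(labels)) levels(labels) else sort(unique(as.character(labels)))
}

#' Fit a Gaussian Naive Bayes classifier
#'
#' Per class and per feature, the maximum-likelihood mean and variance
#' (denominator n), with every variance floored at
#' `var_floor_frac x mean(all class variances)` so degenerate features never
#' divide by zero. Priors are the empirical class frequencies. The class order
#' is the factor level order (or sorted unique labels); ties in prediction
#' break toward the earlier class.
#'
#' @param x trials x features numeric matrix.
#' @param labels class label per trial (factor or character).
#' @param var_floor_frac variance floor as a fraction of the global mean
#'   feature variance.
#' @return a `gnb_model` with `classes`, `means`, `variances`, `log_priors`.
#' @export
gnb_fit <- function(x, labels, var_floor_frac = 1e-9) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels))
  cls <- class_levels(labels)
  if (length(cls) < 2) stop("need at least 2 classes", call. = FALSE)
  n_c <- table(factor(labels, levels = cls))
  if (any(n_c < 2)) {
    stop("insufficient data: class(es) with fewer than 2 trials: ",
         paste(cls[n_c < 2], collapse = ", "), call. = FALSE)
  }
  means <- do.call(rbind, lapply(cls, function(cl) {
    colMeans(x[labels == cl, , drop = FALSE])
  }))
  vars <- do.call(rbind, lapply(cls, function(cl) {
    xc <- x[labels == cl, , drop = FALSE]
    colMeans(xc^2) - colMeans(xc)^2
  }))
  rownames(means) <- rownames(vars) <- cls
  floor_val <- max(var_floor_frac * mean(vars), .Machine$double.xmin)
  vars <- pmax(vars, floor_val)
  structure(list(classes = cls, means = means, variances = vars,
                 log_priors = log(as.numeric(n_c) / sum(n_c)),
                 var_floor = floor_val),
            class = "gnb_model")
}

#' Predict with a Gaussian Naive Bayes model
#'
#' Argmax over classes of log prior + summed per-feature Gaussian log
#' densities; exact ties go to the earlier class in the model's class order.
#'
#' @param model a `gnb_model`.
#' @param x trials x features matrix with the training feature count.
#' @return list with `class` (predicted labels) and `log_posterior`
#'   (unnormalised trials x classes matrix).
#' @export
gnb_predict <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != ncol(model$means)) {
    stop("feature count does not match the fitted model", call. = FALSE)
  }
  lp <- vapply(seq_along(model$classes), function(ci) {
    mu <- model$means[ci, ]
    v <- model$variances[ci, ]
    dev <- sweep(x, 2, mu)
    -0.5 * sum(log(2 * pi * v)) -
      rowSums(sweep(dev^2, 2, 2 * v, "/")) + model$log_priors[ci]
  }, numeric(nrow(x)))
  lp <- matrix(lp, nrow = nrow(x), dimnames = list(NULL, model$classes))
  pred <- model$classes[max.col(lp, ties.method = "first")]
  list(class = pred, log_posterior = lp)
}

#' Pooled classification accuracy
#'
#' The ratio of correct predictions to total predictions regardless of class
#' (not class-balanced).
#'
#' @param predicted,actual equal-length label vectors.
#' @return proportion correct in \[0, 1\].
#' @export
accuracy <- function(predicted, actual) {
  if (length(predicted) == 0 || length(predicted) != length(actual)) {
    stop("predicted and actual must be equal-length and non-empty",
         call. = FALSE)
  }
  mean(as.character(predicted) == as.character(actual))
}

#' Leave-one-run-out cross-validation folds
#'
#' One fold per distinct run: that run's trials form the test set and all
#' other trials the training set, so every trial is tested exactly once. Fold
#' accuracies are averaged with equal weights (folds are equal-sized by
#' design).
#'
#' @param runs run identifier per trial.
#' @return list of folds, each `list(train =, test =)` of trial indices.
#' @export
leave_one_run_out_folds <- function(runs) {
  ids <- sort(unique(runs))
  if (length(ids) < 2) {
    stop("leave-one-run-out needs at least 2 runs; ",
         "use the single-split cross-modal path for one run", call. = FALSE)
  }
  lapply(ids, function(r) {
    list(train = which(runs != r), test = which(runs == r))
  })
}
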