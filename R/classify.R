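#' Labeled feature dataset
#'
#' @param x numeric feature matrix (rows = images).
#' @param labels factor or character vector with levels `cancerous` /
#'   `healthy` (the positive class is `cancerous`).
#' @return a `labeled_dataset` list.
#' @export
labeled_dataset <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels), all(labels %in% c("cancerous", "healthy")))
  if (any(!is.finite(x))) stop("missing or non-finite feature values")
  if (min(table(labels)) < 2) stop("need at least 2 samples per class")
  structure(list(x = x, labels = labels), class = "labeled_dataset")
}

rbf_kernel <- function(a, b, gamma) {
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, `+`) - 2 * a %*% t(b)
  exp(-gamma * pmax(d2, 0))
}

#' Train a C-SVC support vector machine
#'
#' Solves the usual dual with a compact SMO solver; the decision function
#' is `sign(sum_i y_i alpha_i K(x, x_i) + b)`. Features are z-scored with
#' statistics of the training set (stored in the model and re-applied at
#' prediction). Kernel: RBF with `gamma = 1/(d * var)` by default
#' (scikit-learn's "scale" heuristic), or linear.
#'
#' @param data a [labeled_dataset()] (`cancerous` maps to +1).
#' @param C box constraint (default 1).
#' @param gamma RBF width, `NULL` for the scale heuristic.
#' @param kernel `"rbf"` or `"linear"`.
#' @param tol,max_passes SMO stopping controls.
#' @param seed integer seed for the solver's internal index shuffling.
#' @return an `svm_model`.
#' @export
svm_train <- function(data, C = 1, gamma = NULL,
                      kernel = c("rbf", "linear"), tol = 1e-3,
                      max_passes = 5L, seed = 0L) {
  kernel <- match.arg(kernel)
  x <- data$x
  y <- ifelse(data$labels == "cancerous", 1, -1)
  if (length(unique(y)) < 2) stop("single-class data")
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  if (is.null(gamma)) {
    v <- mean(apply(xs, 2, stats::var))
    gamma <- if (v > 0) 1 / (ncol(xs) * v) else 1
  }
  K <- if (kernel == "rbf") rbf_kernel(xs, xs, gamma) else xs %*% t(xs)
  fit <- cpp_svm_smo(K, y, C, tol, as.integer(max_passes), as.integer(seed))
  structure(list(kernel = kernel, gamma = gamma, C = C, alpha = fit$alpha,
                 b = fit$b, sv = xs, y = y, center = ctr, scale = scl),
            class = "svm_model")
}

#' Decision values and class predictions
#'
#' @param model an `svm_model`.
#' @param x feature matrix with the training dimensionality.
#' @return `svm_decision`: raw decision values; `svm_predict`: labels
#'   (`cancerous` for decision >= 0 — ties break to the positive class).
#' @export
svm_decision <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != ncol(model$sv)) stop("feature dimension mismatch")
  xs <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  K <- if (model$kernel == "rbf") rbf_kernel(xs, model$sv, model$gamma)
       else xs %*% t(model$sv)
  as.vector(K %*% (model$alpha * model$y) + model$b)
}

#' @rdname svm_decision
#' @export
svm_predict <- function(model, x) {
  ifelse(svm_decision(model, x) >= 0, "cancerous", "healthy")
}

#' Confusion counts
#'
#' @param tp,fp,tn,fn nonnegative integer counts ("cancerous" is positive).
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn),
            class = "confusion_counts")
}

#' Count a prediction/truth confusion table
#' @param pred,truth label vectors in `{cancerous, healthy}`.
#' @export
count_confusion <- function(pred, truth) {
  stopifnot(length(pred) == length(truth), length(pred) > 0)
  confusion_counts(tp = sum(pred == "cancerous" & truth == "cancerous"),
                   fp = sum(pred == "cancerous" & truth == "healthy"),
                   tn = sum(pred == "healthy" & truth == "healthy"),
                   fn = sum(pred == "healthy" & truth == "cancerous"))
}

#' Five evaluation metrics from predictions
#'
#' PPV `= TP/(TP+FP)`, NPV `= TN/(TN+FN)`, specificity `= TN/(TN+FP)`,
#' accuracy `= (TP+TN)/total`, sensitivity `= TP/(TP+FN)`. A metric whose
#' denominator is zero is reported as 0 and listed in `undefined`.
#'
#' @param pred,truth label vectors in `{cancerous, healthy}`.
#' @return list with `confusion`, the five metrics, and `undefined`.
#' @export
evaluate_predictions <- function(pred, truth) {
  cc <- count_confusion(pred, truth)
  safe <- function(num, den) if (den == 0) 0 else num / den
  und <- character()
  if (cc$tp + cc$fp == 0) und <- c(und, "ppv")
  if (cc$tn + cc$fn == 0) und <- c(und, "npv")
  if (cc$tn + cc$fp == 0) und <- c(und, "specificity")
  if (cc$tp + cc$fn == 0) und <- c(und, "sensitivity")
  list(confusion = cc,
       ppv = safe(cc$tp, cc$tp + cc$fp),
       npv = safe(cc$tn, cc$tn + cc$fn),
       specificity = safe(cc$tn, cc$tn + cc$fp),
       accuracy = (cc$tp + cc$tn) / (cc$tp + cc$tn + cc$fp + cc$fn),
       sensitivity = safe(cc$tp, cc$tp + cc$fn),
       undefined = und)
}

stratified_split <- function(labels, train_frac) {
  idx_tr <- integer()
  for (cl in unique(labels)) {
    ix <- which(labels == cl)
    n_tr <- max(1L, round(train_frac * length(ix)))
    n_tr <- min(n_tr, length(ix) - 1L)
    idx_tr <- c(idx_tr, sample(ix, n_tr))
  }
  sort(idx_tr)
}

#' Repeated stratified 85/15 holdout evaluation
#'
#' For each seed: stratified 85/15 train/test split; wrapper feature
#' selection (MTEO + cost function) fit on the training split only; the
#' final SVM trained on the selected training features; the five metrics
#' computed on the held-out 15%. Returns per-seed rows plus a mean/sd
#' summary.
#'
#' @param data a [labeled_dataset()].
#' @param seeds integer vector, one holdout repetition per entry.
#' @param train_frac training fraction (default 0.85).
#' @param selection_cfg list of arguments passed to [select_features()]
#'   (e.g. `iters`, `restarts`, `pop_size`, `cv_folds`); `NULL` disables
#'   feature selection and uses all features.
#' @param C,gamma,kernel forwarded to [svm_train()].
#' @return list with `per_seed` (data.frame) and `summary` (mean and sd of
#'   each metric).
#' @export
holdout_protocol <- function(data, seeds = 1:10, train_frac = 0.85,
                             selection_cfg = list(), C = 1, gamma = NULL,
                             kernel = "rbf") {
  rows <- lapply(seeds, function(sd0) {
    set.seed(sd0)
    idx_tr <- stratified_split(data$labels, train_frac)
    tr <- labeled_dataset(data$x[idx_tr, , drop = FALSE],
                          data$labels[idx_tr])
    te_x <- data$x[-idx_tr, , drop = FALSE]
    te_y <- data$labels[-idx_tr]
    keep <- if (is.null(selection_cfg)) {
      rep(TRUE, ncol(data$x))
    } else {
      sel <- do.call(select_features,
                     c(list(data = tr, seed = sd0), selection_cfg))
      sel$bits == 1
    }
    tr_sel <- labeled_dataset(tr$x[, keep, drop = FALSE], tr$labels)
    model <- svm_train(tr_sel, C = C, gamma = gamma, kernel = kernel,
                       seed = sd0)
    pred <- svm_predict(model, te_x[, keep, drop = FALSE])
    ev <- evaluate_predictions(pred, te_y)
    data.frame(seed = sd0, n_test = length(te_y),
               n_selected = sum(keep), ppv = ev$ppv, npv = ev$npv,
               specificity = ev$specificity, accuracy = ev$accuracy,
               sensitivity = ev$sensitivity)
  })
  per_seed <- do.call(rbind, rows)
  metric_cols <- c("ppv", "npv", "specificity", "accuracy", "sensitivity")
  summary <- data.frame(metric = metric_cols,
                        mean = vapply(metric_cols,
                                      function(m) mean(per_seed[[m]]),
                                      numeric(1)),
                        sd = vapply(metric_cols,
                                    function(m) stats::sd(per_seed[[m]]),
                                    numeric(1)))
  list(per_seed = per_seed, summary = summary)
}
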