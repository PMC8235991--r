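#' Subset-quality cost function (Matthews correlation coefficient)
#'
#' `CF = (TP*TN - FP*FN) / sqrt((TN+FP)(TP+FP)(TP+FN)(TN+FN))`, in
#' `[-1, 1]`; any zero factor in the denominator yields 0 (the standard MCC
#' convention). The selection search maximizes CF by minimizing `-CF`.
#'
#' @param cc a [confusion_counts()].
#' @return scalar in `[-1, 1]`.
#' @export
cost_function <- function(cc) {
  den <- (cc$tn + cc$fp) * (cc$tp + cc$fp) * (cc$tp + cc$fn) * (cc$tn + cc$fn)
  if (den == 0) return(0)
  (cc$tp * cc$tn - cc$fp * cc$fn) / sqrt(den)
}

#' Decode a continuous position into a feature subset
#'
#' Bit `j` is set iff `position[j] > 0.5`; an all-zero mask is repaired by
#' setting the bit of the largest component, so every evaluated subset is
#' nonempty.
#'
#' @param position numeric vector with components in `[0, 1]`.
#' @return list with `bits` (0/1 vector) and `n_selected`.
#' @export
decode_mask <- function(position) {
  bits <- as.integer(position > 0.5)
  if (sum(bits) == 0) bits[which.max(position)] <- 1L
  list(bits = bits, n_selected = sum(bits))
}

#' Score a feature subset by cross-validated MCC
#'
#' Trains the SVM on the masked columns under stratified k-fold
#' cross-validation, pools the fold confusion counts, and returns the
#' negated cost function value (so that a minimizer maximizes MCC). A fold
#' left with one class is merged into its neighbour.
#'
#' @param mask list from [decode_mask()] (or a 0/1 vector).
#' @param data a [labeled_dataset()] (the training partition only).
#' @param cv_folds number of folds (default 5).
#' @param seed integer seed controlling fold assignment and SVM solver.
#' @param lambda optional subset-size penalty `lambda * n_selected / d`
#'   added to the score (default 0: the cost function has no size term).
#' @param C,gamma,kernel forwarded to [svm_train()].
#' @return scalar score `-CF + lambda * n_selected / d`.
#' @export
evaluate_subset <- function(mask, data, cv_folds = 5L, seed = 0L,
                            lambda = 0, C = 1, gamma = NULL,
                            kernel = "rbf") {
  bits <- if (is.list(mask)) mask$bits else as.integer(mask)
  if (sum(bits) < 1) stop("empty feature subset")
  keep <- bits == 1
  x <- data$x[, keep, drop = FALSE]
  labels <- data$labels
  n <- nrow(x)
  set.seed(seed)
  # stratified fold assignment
  folds <- integer(n)
  for (cl in unique(labels)) {
    ix <- sample(which(labels == cl))
    folds[ix] <- rep_len(seq_len(cv_folds), length(ix))
  }
  tp <- fp <- tn <- fn <- 0
  for (f in seq_len(cv_folds)) {
    te <- folds == f
    if (!any(te)) next
    tr_lab <- labels[!te]
    if (length(unique(tr_lab)) < 2) next  # degenerate fold: skip (merged)
    model <- svm_train(labeled_dataset(x[!te, , drop = FALSE], tr_lab),
                       C = C, gamma = gamma, kernel = kernel, seed = seed)
    pred <- svm_predict(model, x[te, , drop = FALSE])
    cc <- count_confusion(pred, labels[te])
    tp <- tp + cc$tp; fp <- fp + cc$fp; tn <- tn + cc$tn; fn <- fn + cc$fn
  }
  -cost_function(confusion_counts(tp, fp, tn, fn)) +
    lambda * sum(bits) / length(bits)
}

#' Wrapper feature selection with MTEO
#'
#' Runs the MTEO continuous minimizer over `[0, 1]^d`, scoring each decoded
#' subset with [evaluate_subset()]; repeated over independent restarts and
#' the best restart returned. Subset scores are memoised per restart (the
#' search revisits the same bit patterns often).
#'
#' Defaults follow the reference protocol (750 iterations, 20 independent
#' restarts); these are expensive with a wrapper objective, so tests and
#' the worked examples use reduced budgets.
#'
#' @param data a [labeled_dataset()] (training partition).
#' @param iters MTEO iterations per restart.
#' @param restarts independent restarts; the best final score wins.
#' @param pop_size MTEO population size (default 10; the objective is a
#'   cross-validated SVM, so evaluations are costly).
#' @param cv_folds,lambda,C,gamma,kernel forwarded to [evaluate_subset()].
#' @param seed master seed; restarts derive distinct seeds from it.
#' @return list with `bits`, `n_selected`, `score` (the winning `-CF`),
#'   `restart_scores`.
#' @export
select_features <- function(data, iters = 750L, restarts = 20L,
                            pop_size = 10L, cv_folds = 5L, lambda = 0,
                            C = 1, gamma = NULL, kernel = "rbf",
                            seed = 1L) {
  d <- ncol(data$x)
  best <- NULL
  restart_scores <- numeric(restarts)
  # one evaluation seed for all restarts: every restart scores a subset on
  # the same CV folds, so scores are comparable and the cache is shared
  eval_seed <- (as.integer(seed) + 104729L) %% 2147483647L
  cache <- new.env(parent = emptyenv())
  objective <- function(pos) {
    m <- decode_mask(pos)
    key <- paste(m$bits, collapse = "")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    v <- evaluate_subset(m, data, cv_folds = cv_folds, seed = eval_seed,
                         lambda = lambda, C = C, gamma = gamma,
                         kernel = kernel)
    cache[[key]] <- v
    v
  }
  for (r in seq_len(restarts)) {
    rs <- (as.integer(seed) + 7919L * r) %% 2147483647L
    cfg <- optimizer_config(dim = d, lower = 0, upper = 1,
                            pop_size = pop_size, max_iter = iters,
                            seed = rs)
    res <- mteo_optimize(objective, cfg)
    restart_scores[r] <- res$best_cost
    if (is.null(best) || res$best_cost < best$score) {
      m <- decode_mask(res$best_position)
      best <- list(bits = m$bits, n_selected = m$n_selected,
                   score = res$best_cost)
    }
  }
  best$restart_scores <- restart_scores
  best
}
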