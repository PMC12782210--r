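# One-vs-rest per-user classifiers: k-nearest neighbours, random forest and
# a feed-forward neural network, each tuned by exhaustive grid search with
# stratified threefold cross-validation on the training rows, selecting by
# F1 of the positive (target) class.

#' Hyperparameter grids for the classical models
#'
#' Defaults: `k` in \{5, 10, 100, 200\} for k-NN, maximum tree depth in
#' \{10, 50, 100\} for the random forest, and L2 strength alpha in
#' \{1e-1, ..., 1e-5\} for the neural network, searched with threefold
#' cross-validation.
#'
#' @param knn_k Integer set of neighbour counts.
#' @param rf_max_depth Integer set of maximum tree depths.
#' @param nn_l2_alpha Numeric set of L2 regularization strengths.
#' @param cv_folds Number of cross-validation folds (at least 2).
#' @return An object of class `hyperparameter_grid`.
#' @export
hyperparameter_grid <- function(knn_k = c(5L, 10L, 100L, 200L),
                                rf_max_depth = c(10L, 50L, 100L),
                                nn_l2_alpha = 10^-(1:5),
                                cv_folds = 3L) {
  if (length(knn_k) < 1L || length(rf_max_depth) < 1L || length(nn_l2_alpha) < 1L)
    stopf("hyperparameter sets must be non-empty")
  if (!is_count(cv_folds, min = 2L)) stopf("cv_folds must be an integer >= 2")
  structure(
    list(knn_k = as.integer(knn_k), rf_max_depth = as.integer(rf_max_depth),
         nn_l2_alpha = as.numeric(nn_l2_alpha), cv_folds = as.integer(cv_folds)),
    class = "hyperparameter_grid"
  )
}

# ---- internal fitters (one hyperparameter setting each) --------------------

# k-NN with class-probability scores: the score of a row is the fraction of
# its k nearest training rows (Euclidean distance, ties broken by training
# row order) that belong to the positive class.
.knn_fit <- function(X, y, k) {
  list(kind = "knn", X = X, y = y, k = as.integer(k))
}

# Indices of the k nearest training rows for every query row (Euclidean,
# ties broken by training-row order). Blockwise to bound memory. Ranking
# uses |b|^2 - 2ab, which orders identically to the full squared distance
# |a|^2 + |b|^2 - 2ab because |a|^2 is constant within a query row.
.knn_neighbors <- function(Xtr, Xte, k, block = 1024L) {
  sq <- rowSums(Xtr^2)
  n <- nrow(Xte)
  out <- matrix(0L, n, k)
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(start + block - 1L, n)
    M <- tcrossprod(Xte[rows, , drop = FALSE], Xtr)
    for (i in seq_along(rows)) {
      d <- sq - 2 * M[i, ]
      th <- sort.int(d, partial = k)[k]
      sel <- which(d <= th)
      if (length(sel) > k) sel <- sel[order(d[sel])[seq_len(k)]]  # stable ties
      out[rows[i], ] <- sel
    }
  }
  out
}

.knn_score <- function(fit, X) {
  nb <- .knn_neighbors(fit$X, as.matrix(X), fit$k)
  rowMeans(matrix(fit$y[nb], nrow(nb), ncol(nb)))
}

.rf_fit <- function(X, y, max_depth, seed, num_trees = 100L) {
  df <- as.data.frame(X)
  df$.y <- factor(y, levels = c(0, 1))
  fit <- ranger::ranger(
    dependent.variable.name = ".y", data = df,
    num.trees = num_trees, max.depth = max_depth,
    probability = TRUE, seed = seed, num.threads = 1L
  )
  list(kind = "rf", fit = fit, max_depth = max_depth)
}

.rf_score <- function(fit, X) {
  pr <- stats::predict(fit$fit, data = as.data.frame(X),
                       num.threads = 1L)$predictions
  as.numeric(pr[, "1"])
}

.nn_fit <- function(X, y, alpha, seed) {
  fit <- mlp_fit(X, y, hidden = 100L, alpha = alpha, epochs = 40L,
                 batch_size = 64L, lr = 1e-3, seed = seed)
  list(kind = "nn", fit = fit, alpha = alpha)
}

.nn_score <- function(fit, X) mlp_score(fit$fit, X)

.fit_one <- function(kind, X, y, setting, seed) {
  switch(kind,
         knn = .knn_fit(X, y, setting),
         rf = .rf_fit(X, y, setting, seed),
         nn = .nn_fit(X, y, setting, seed),
         stopf("unknown model kind '%s'", kind))
}

.score_one <- function(kind, fit, X) {
  switch(kind, knn = .knn_score(fit, X), rf = .rf_score(fit, X),
         nn = .nn_score(fit, X))
}

# Stratified fold assignment: both classes spread evenly over folds.
stratified_folds <- function(y, n_folds, seed) {
  with_seed(mix_seed(seed, 404L), {
    fold <- integer(length(y))
    for (cls in unique(y)) {
      rows <- which(y == cls)
      fold[rows] <- sample(rep_len(seq_len(n_folds), length(rows)))
    }
    fold
  })
}

#' Fit a per-user classical model with grid-search cross-validation
#'
#' Performs an exhaustive search over the model kind's hyperparameter set
#' using stratified threefold cross-validation on the training rows,
#' selects the setting with the highest mean F1 for the positive class
#' (ties broken by first-in-grid order), then refits on all training rows.
#' A grid with a single admissible setting is fit directly (no search). For
#' k-NN, settings with `k` not below the smallest fold training size are
#' skipped with a warning; it is an error if every setting is skipped.
#'
#' @param kind One of `"knn"`, `"rf"`, `"nn"`.
#' @param X Numeric matrix of normalized window features (rows = windows).
#' @param y Binary labels (1 = target user's windows); both classes must be
#'   present.
#' @param grid A [hyperparameter_grid()].
#' @param seed Integer seed controlling fold assignment and stochastic
#'   fitters.
#' @param target_user_id Optional identifier recorded on the model.
#' @return A `fitted_model` supporting [predict.fitted_model()]; carries the
#'   chosen setting, the per-setting CV table, and training provenance.
#' @export
fit_classical <- function(kind, X, y, grid = hyperparameter_grid(), seed = 1L,
                          target_user_id = NA_character_) {
  kind <- match.arg(kind, c("knn", "rf", "nn"))
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2L)
    stopf("training labels contain a single class; one-vs-rest fitting needs both")
  if (nrow(X) < grid$cv_folds)
    stopf("need at least %d training rows for %d-fold cross-validation",
          grid$cv_folds, grid$cv_folds)

  settings <- switch(kind, knn = grid$knn_k, rf = grid$rf_max_depth,
                     nn = grid$nn_l2_alpha)

  cv_table <- NULL
  if (kind == "knn") {
    fold <- stratified_folds(y, grid$cv_folds, seed)
    min_train <- min(vapply(seq_len(grid$cv_folds),
                            function(f) sum(fold != f), integer(1)))
    ok <- settings < min_train
    if (any(!ok))
      warning(sprintf("skipping k = {%s}: not below fold training size %d",
                      paste(settings[!ok], collapse = ", "), min_train),
              call. = FALSE)
    settings <- settings[ok]
    if (length(settings) == 0L)
      stopf("all k values were skipped (training set too small)")
  }

  if (length(settings) > 1L) {
    fold <- stratified_folds(y, grid$cv_folds, seed)
    cv_f1 <- vapply(settings, function(s) {
      f1s <- vapply(seq_len(grid$cv_folds), function(f) {
        tr <- fold != f
        fit <- .fit_one(kind, X[tr, , drop = FALSE], y[tr], s,
                        mix_seed(seed, 505L, f))
        sc <- .score_one(kind, fit, X[!tr, , drop = FALSE])
        compute_metrics(y[!tr], as.integer(sc >= 0.5))$f1
      }, numeric(1))
      mean(f1s)
    }, numeric(1))
    best <- settings[which.max(cv_f1)]  # which.max keeps first on ties
    cv_table <- data.frame(setting = settings, cv_f1 = cv_f1)
  } else {
    best <- settings[1L]
  }

  fit <- .fit_one(kind, X, y, best, mix_seed(seed, 606L))
  structure(
    list(model_kind = kind, target_user_id = target_user_id, fit = fit,
         hyperparameters = stats::setNames(list(best),
           switch(kind, knn = "k", rf = "max_depth", nn = "l2_alpha")),
         cv_table = cv_table, grid = grid, seed = seed,
         n_train = nrow(X), n_features = ncol(X),
         train_positive_rate = mean(y)),
    class = "fitted_model"
  )
}

#' Predict per-window scores and decisions
#'
#' Inputs must be shaped and normalized as at fit time (feature matrices
#' for classical models, raw window sequences for the transformer). Scores
#' lie in `[0, 1]`; the decision rule is `score >= 0.5`, so an exact 0.5
#' is a positive.
#'
#' @param object A `fitted_model`.
#' @param newdata Feature matrix (classical kinds) or list/array of raw
#'   window sequences (transformer).
#' @param ... Unused.
#' @return A data.frame with columns `score` and `decision` (0/1).
#' @export
predict.fitted_model <- function(object, newdata, ...) {
  score <- if (object$model_kind == "swipeformer") {
    .swipe_score(object$fit, newdata)
  } else {
    newdata <- as.matrix(newdata)
    if (ncol(newdata) != object$n_features)
      stopf("newdata has %d features but the model was fit on %d",
            ncol(newdata), object$n_features)
    .score_one(object$model_kind, object$fit, newdata)
  }
  data.frame(score = score, decision = as.integer(score >= 0.5))
}

#' @export
print.fitted_model <- function(x, ...) {
  hp <- paste(names(x$hyperparameters), unlist(x$hyperparameters),
              sep = " = ", collapse = ", ")
  cat(sprintf("<fitted_model> %s for target %s (%s); %d train windows\n",
              x$model_kind, x$target_user_id, hp, x$n_train))
  invisible(x)
}
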