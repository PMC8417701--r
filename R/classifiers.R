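#' Benchmarked classifier families
#'
#' The seven families entering the benchmark, identified by id: `KNN`
#' (k-nearest neighbors), `DT` (decision tree), `AB` (AdaBoost over
#' depth-1 stumps), `GNB` (Gaussian naive Bayes), `LDA` (linear
#' discriminant), `QDA` (shrinkage-regularized quadratic discriminant),
#' `SVM` (RBF support vector machine). Features are standardized on
#' training rows before fitting.
#'
#' @return Character vector of classifier ids.
#' @export
classifier_ids <- function() c("KNN", "DT", "AB", "GNB", "LDA", "QDA", "SVM")

#' Default hyperparameter grids
#'
#' Fixed, documented grids used by the 5-fold grid search; families with
#' no tunable parameter get a single empty configuration.
#'
#' @return Named list of data frames (one row per configuration).
#' @export
default_grids <- function() {
  list(
    KNN = data.frame(k = c(3, 5, 9)),
    DT = data.frame(maxdepth = c(2, 4, 8)),
    AB = data.frame(n_rounds = c(20, 50)),
    GNB = data.frame(dummy = 0),
    LDA = data.frame(dummy = 0),
    QDA = data.frame(lambda = c(0.2, 0.5)),
    SVM = data.frame(cost = c(0.1, 1, 10))
  )
}

# ---- AdaBoost.M1 over rpart stumps -------------------------------------

fit_adaboost <- function(x, y, n_rounds = 50, maxdepth = 1) {
  df <- data.frame(y = y, x, check.names = FALSE)
  n <- nrow(df)
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric()
  for (m in seq_len(n_rounds)) {
    fit <- rpart::rpart(y ~ ., data = df, weights = w, method = "class",
                        control = rpart::rpart.control(
                          maxdepth = maxdepth, cp = -1, minsplit = 2,
                          xval = 0, maxsurrogate = 0))
    pred <- predict(fit, df, type = "class")
    miss <- pred != y
    err <- sum(w[miss])
    if (err <= 1e-10) {
      stumps[[m]] <- fit; alphas[m] <- 10
      break
    }
    if (err >= 0.5) break
    alphas[m] <- 0.5 * log((1 - err) / err)
    stumps[[m]] <- fit
    w <- w * exp(ifelse(miss, alphas[m], -alphas[m]))
    w <- w / sum(w)
  }
  if (!length(stumps)) {
    # no weak learner beats chance: fall back to the majority class
    maj <- names(which.max(table(y)))
    return(structure(list(majority = maj, levels = levels(y)),
                     class = "mw_adaboost"))
  }
  structure(list(stumps = stumps, alphas = alphas, levels = levels(y)),
            class = "mw_adaboost")
}

predict_adaboost <- function(model, x) {
  lv <- model$levels
  if (!is.null(model$majority))
    return(factor(rep(model$majority, nrow(x)), levels = lv))
  df <- data.frame(x, check.names = FALSE)
  score <- rep(0, nrow(df))
  for (m in seq_along(model$stumps)) {
    pred <- predict(model$stumps[[m]], df, type = "class")
    score <- score + model$alphas[m] * ifelse(pred == lv[2], 1, -1)
  }
  factor(ifelse(score > 0, lv[2], lv[1]), levels = lv)
}

# ---- shrinkage-regularized quadratic discriminant ----------------------

fit_rqda <- function(x, y, lambda = 0.5) {
  lv <- levels(y)
  p <- ncol(x)
  cls <- lapply(lv, function(cl) {
    xi <- x[y == cl, , drop = FALSE]
    mu <- colMeans(xi)
    S <- if (nrow(xi) > 1) stats::cov(xi) else diag(p)
    S <- (1 - lambda) * S + lambda * mean(diag(S)) * diag(p)
    ch <- tryCatch(chol(S), error = function(e) chol(S + 1e-6 * diag(p)))
    list(mu = mu, chol = ch,
         logdet = 2 * sum(log(diag(ch))),
         logprior = log(nrow(xi) / nrow(x)))
  })
  names(cls) <- lv
  structure(list(classes = cls, levels = lv), class = "mw_rqda")
}

predict_rqda <- function(model, x) {
  x <- as.matrix(x)
  scores <- sapply(model$classes, function(cl) {
    z <- backsolve(cl$chol, t(sweep(x, 2, cl$mu)), transpose = TRUE)
    -0.5 * colSums(z^2) - 0.5 * cl$logdet + cl$logprior
  })
  factor(model$levels[max.col(scores, ties.method = "first")],
         levels = model$levels)
}

# ---- unified fit / predict ---------------------------------------------

#' Fit one classifier
#'
#' @param id classifier id (see [classifier_ids()]).
#' @param x numeric training matrix (already standardized).
#' @param y factor of class labels.
#' @param params one-row data frame of hyperparameters (a row of
#'   [default_grids()]).
#' @return Opaque model object for [predict_classifier()].
#' @export
fit_classifier <- function(id, x, y, params = NULL) {
  x <- as.matrix(x)
  y <- droplevels(factor(y))
  p <- as.list(params %||% default_grids()[[id]][1, , drop = FALSE])
  model <- switch(
    id,
    KNN = list(x = x, y = y, k = p$k %||% 5),
    DT = rpart::rpart(y ~ ., data = data.frame(y = y, x, check.names = FALSE),
                      method = "class",
                      control = rpart::rpart.control(
                        maxdepth = p$maxdepth %||% 8, xval = 0)),
    AB = fit_adaboost(x, y, n_rounds = p$n_rounds %||% 50),
    GNB = e1071::naiveBayes(x, y),
    LDA = suppressWarnings(MASS::lda(x, grouping = y, tol = 1e-10)),
    QDA = fit_rqda(x, y, lambda = p$lambda %||% 0.5),
    SVM = e1071::svm(x, y, kernel = "radial", cost = p$cost %||% 1,
                     scale = FALSE),
    stop("unknown classifier id: ", id))
  structure(list(id = id, model = model, levels = levels(y)),
            class = "mw_classifier")
}

#' Predict class labels
#'
#' @param fit object from [fit_classifier()].
#' @param x numeric matrix of test rows (standardized like the training
#'   rows).
#' @return Factor of predicted labels.
#' @export
predict_classifier <- function(fit, x) {
  x <- as.matrix(x)
  m <- fit$model
  switch(
    fit$id,
    KNN = class::knn(m$x, x, m$y, k = m$k),
    DT = predict(m, data.frame(x, check.names = FALSE), type = "class"),
    AB = predict_adaboost(m, x),
    GNB = predict(m, x),
    LDA = predict(m, x)$class,
    QDA = predict_rqda(m, x),
    SVM = predict(m, x))
}

#' Grid search with k-fold cross-validation
#'
#' Evaluates every row of the grid by stratified k-fold cross-validated
#' accuracy on `(x, y)` and returns the best configuration (first row on
#' ties, so the search is deterministic given the seed).
#'
#' @param id classifier id.
#' @param x,y training data.
#' @param grid data frame of configurations (default from
#'   [default_grids()]).
#' @param folds number of folds (default 5).
#' @param seed seed for the fold assignment.
#' @return Best one-row configuration with attribute `cv_accuracy`.
#' @export
grid_search_cv <- function(id, x, y, grid = default_grids()[[id]],
                           folds = 5, seed = 1L) {
  x <- as.matrix(x); y <- droplevels(factor(y))
  if (nrow(grid) == 1)
    return(structure(grid[1, , drop = FALSE], cv_accuracy = NA_real_))
  fold_id <- stratified_folds(y, folds, seed = seed)
  acc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    correct <- 0L
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      std <- standardizer_fit(x[tr, , drop = FALSE])
      fit <- fit_classifier(id, standardizer_apply(std, x[tr, , drop = FALSE]),
                            y[tr], grid[g, , drop = FALSE])
      pred <- predict_classifier(fit,
                                 standardizer_apply(std, x[!tr, , drop = FALSE]))
      correct <- correct + sum(pred == y[!tr])
    }
    acc[g] <- correct / length(y)
  }
  best <- which.max(acc)
  structure(grid[best, , drop = FALSE], cv_accuracy = acc[best])
}
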