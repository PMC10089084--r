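## Barcode reader: preprocessing, model zoo, cross-validated comparison,
## tuning, evaluation and prediction.

# deterministic per-stage seed derivation from one pipeline seed
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629)
}

#' Z-score standardizer
#'
#' Learns per-feature mean and standard deviation on training data; applying
#' it to its own training data yields mean 0 and sd 1 per feature. Constant
#' features (sd 0) map to 0.
#'
#' @param X Numeric matrix or data.frame of features.
#' @return Object of class `standardizer`.
#' @export
fit_standardizer <- function(X) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  sd <- apply(X, 2L, stats::sd)
  constant <- sd == 0 | !is.finite(sd)
  sd[constant] <- 1
  structure(list(mean = mu, sd = sd, constant = constant),
            class = "standardizer")
}

#' @rdname fit_standardizer
#' @param std A fitted `standardizer`.
#' @export
apply_standardizer <- function(std, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(std$mean)) stop("feature count mismatch")
  sweep(sweep(X, 2L, std$mean, `-`), 2L, std$sd, `/`)
}

#' Stratified train/test split
#'
#' Splits per class so both sides preserve the (possibly unbalanced) class
#' proportions: each class contributes `round(count * test_fraction)` test
#' records. Deterministic given the seed.
#'
#' @param table Fingerprint data.frame with a `label` column.
#' @param test_fraction Fraction held out, default 0.2.
#' @param seed Integer seed.
#' @return List with elements `train` and `test` (disjoint data.frames).
#' @export
stratified_split <- function(table, test_fraction = 0.2, seed = 1L) {
  if (!"label" %in% names(table)) stop("table must carry a label column")
  cnt <- table(table$label)
  if (any(cnt < 2L)) {
    stop(sprintf("class %s has fewer than 2 records",
                 names(cnt)[which(cnt < 2L)[1]]))
  }
  set.seed(seed)
  test_idx <- integer(0)
  for (cl in names(cnt)) {
    idx <- which(table$label == cl)
    n_test <- round(length(idx) * test_fraction)
    n_test <- min(max(n_test, 0L), length(idx) - 1L)
    if (n_test > 0L) test_idx <- c(test_idx, sample(idx, n_test))
  }
  list(train = table[-test_idx, , drop = FALSE],
       test = table[test_idx, , drop = FALSE])
}

# stratified fold assignment
stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' The classifier roster
#'
#' Fifteen model families: a multi-layer perceptron, two gradient-boosted
#' tree variants (a leaf-wise "lightgbm"-style booster and a depth-wise
#' booster), random forest, extremely randomized trees, radial and linear
#' SVM, multinomial logistic regression, k-nearest neighbours, a decision
#' tree, linear and quadratic discriminant analysis, a least-squares ridge
#' classifier, Gaussian naive Bayes and AdaBoost (SAMME over stumps).
#'
#' @return Character vector of family names.
#' @export
classifier_families <- function() {
  c("mlp", "lightgbm", "rf", "extra_trees", "svm_rbf", "svm_linear",
    "logreg", "knn", "dt", "lda", "ridge", "nb", "qda", "adaboost", "gbt")
}

# library-default hyperparameters per family
default_params <- function(family) {
  switch(family,
    mlp = list(size = 16, decay = 1e-4, maxit = 200),
    lightgbm = list(nrounds = 100, eta = 0.1, max_leaves = 31),
    gbt = list(nrounds = 100, eta = 0.1, max_depth = 3),
    rf = list(num.trees = 100, mtry = NULL),
    extra_trees = list(num.trees = 100, mtry = NULL),
    svm_rbf = list(cost = 1, gamma = NULL),
    svm_linear = list(cost = 1),
    logreg = list(maxit = 200, decay = 0),
    knn = list(k = 5),
    dt = list(cp = 0.01, maxdepth = 30),
    lda = list(),
    ridge = list(lambda = 1),
    nb = list(laplace = 0),
    qda = list(),
    adaboost = list(nrounds = 50),
    stop(sprintf("unknown model family '%s'", family))
  )
}

# tuning grids: small, documented, defaults always included as candidate 1
tuning_grid <- function(family) {
  switch(family,
    mlp = expand.grid(size = c(8, 16, 32), decay = c(0, 1e-4, 1e-2),
                      maxit = c(200, 400)),
    lightgbm = expand.grid(nrounds = c(50, 100, 200), eta = c(0.05, 0.1, 0.3),
                           max_leaves = c(15, 31, 63)),
    gbt = expand.grid(nrounds = c(50, 100, 200), eta = c(0.05, 0.1, 0.3),
                      max_depth = c(2, 3, 5)),
    rf = expand.grid(num.trees = c(100, 300), mtry = c(2, 4, 7)),
    extra_trees = expand.grid(num.trees = c(100, 300), mtry = c(2, 4, 7)),
    svm_rbf = expand.grid(cost = c(0.1, 1, 10), gamma = c(0.02, 0.0714, 0.2)),
    svm_linear = expand.grid(cost = c(0.1, 1, 10)),
    logreg = expand.grid(maxit = c(200, 400), decay = c(0, 1e-4, 1e-2)),
    knn = expand.grid(k = c(1, 3, 5, 9, 15)),
    dt = expand.grid(cp = c(0.001, 0.01, 0.05), maxdepth = c(10, 30)),
    ridge = expand.grid(lambda = c(0.1, 1, 10)),
    nb = expand.grid(laplace = c(0, 1)),
    adaboost = expand.grid(nrounds = c(25, 50, 100)),
    data.frame()                         # lda/qda: nothing to tune
  )
}

#' Fit one classifier family
#'
#' Low-level fit on an already-standardized feature matrix. Single-class
#' input yields a trivial constant predictor (used by backward elimination
#' at one remaining class).
#'
#' @param family One of [classifier_families()].
#' @param X Numeric feature matrix (standardized).
#' @param y Class labels (coerced to character).
#' @param params Hyperparameters; missing entries take family defaults.
#' @param seed Seed for stochastic learners.
#' @return Object of class `nb_classifier`.
#' @export
fit_classifier <- function(family, X, y, params = list(), seed = 1L) {
  X <- as.matrix(X)
  y <- as.character(y)
  classes <- sort(unique(y))
  p <- utils::modifyList(default_params(family), params)
  if (length(classes) == 1L) {
    return(structure(list(family = family, kind = "constant",
                          classes = classes, params = p),
                     class = "nb_classifier"))
  }
  if (!family %in% classifier_families()) stop(sprintf("unknown model family '%s'", family))
  set.seed(seed)
  yf <- factor(y, levels = classes)
  # zero-variance columns (e.g. all-sentinel channels for a class subset)
  # carry no information and break the discriminant families; drop them here
  # and at prediction time
  p_in <- ncol(X)
  keep <- which(apply(X, 2L, function(v) diff(range(v)) > 0))
  if (!length(keep)) keep <- 1L
  X <- X[, keep, drop = FALSE]
  fit <- suppressWarnings(switch(family,
    mlp = nnet::nnet(X, nnet::class.ind(yf), size = p$size, decay = p$decay,
                     maxit = p$maxit, softmax = TRUE, trace = FALSE,
                     MaxNWts = 100000),
    lightgbm = xgboost::xgb.train(
      params = list(objective = "multi:softprob", num_class = length(classes),
                    eta = p$eta, tree_method = "hist",
                    grow_policy = "lossguide", max_leaves = p$max_leaves,
                    max_depth = 0, nthread = 1, seed = seed),
      data = xgboost::xgb.DMatrix(X, label = as.integer(yf) - 1L, nthread = 1),
      nrounds = p$nrounds, verbose = 0),
    gbt = xgboost::xgb.train(
      params = list(objective = "multi:softprob", num_class = length(classes),
                    eta = p$eta, max_depth = p$max_depth,
                    tree_method = "exact", nthread = 1, seed = seed),
      data = xgboost::xgb.DMatrix(X, label = as.integer(yf) - 1L, nthread = 1),
      nrounds = p$nrounds, verbose = 0),
    rf = ranger::ranger(x = X, y = yf, num.trees = p$num.trees,
                        mtry = p$mtry, num.threads = 1, seed = seed),
    extra_trees = ranger::ranger(x = X, y = yf, num.trees = p$num.trees,
                                 mtry = p$mtry, splitrule = "extratrees",
                                 num.random.splits = 1, replace = FALSE,
                                 sample.fraction = 1, num.threads = 1,
                                 seed = seed),
    svm_rbf = e1071::svm(X, yf, kernel = "radial", cost = p$cost,
                         gamma = if (is.null(p$gamma)) 1 / ncol(X) else p$gamma,
                         scale = FALSE),
    svm_linear = e1071::svm(X, yf, kernel = "linear", cost = p$cost,
                            scale = FALSE),
    logreg = nnet::multinom(y ~ ., data = data.frame(X, y = yf),
                            maxit = p$maxit, decay = p$decay, trace = FALSE,
                            MaxNWts = 100000),
    knn = list(X = X, y = yf, k = p$k),
    dt = rpart::rpart(y ~ ., data = data.frame(X, y = yf), method = "class",
                      cp = p$cp, maxdepth = p$maxdepth),
    lda = MASS::lda(X, grouping = yf),
    ridge = fit_ridge_ls(X, yf, p$lambda),
    nb = e1071::naiveBayes(X, yf, laplace = p$laplace),
    qda = MASS::qda(X, grouping = yf),
    adaboost = fit_adaboost(X, yf, p$nrounds, seed)
  ))
  structure(list(family = family, kind = "fitted", fit = fit,
                 classes = classes, params = p, keep = keep,
                 n_features = p_in),
            class = "nb_classifier")
}

# least-squares ridge on the class indicator matrix (one-vs-all, argmax),
# intercept unpenalized
fit_ridge_ls <- function(X, yf, lambda) {
  Xi <- cbind(1, X)
  Yi <- nnet::class.ind(yf)
  pen <- diag(c(0, rep(lambda, ncol(X))))
  W <- solve(crossprod(Xi) + pen, crossprod(Xi, Yi))
  list(W = W, classes = levels(yf))
}

# AdaBoost SAMME over depth-1 rpart stumps
fit_adaboost <- function(X, yf, nrounds, seed) {
  n <- nrow(X); K <- nlevels(yf)
  w <- rep(1 / n, n)
  d <- data.frame(X, y = yf)
  stumps <- list(); alphas <- numeric(0)
  for (t in seq_len(nrounds)) {
    st <- rpart::rpart(y ~ ., data = d, weights = w, method = "class",
                       control = rpart::rpart.control(maxdepth = 1, cp = -1,
                                                      minsplit = 2, xval = 0))
    pr <- predict(st, d, type = "class")
    err <- sum(w * (pr != yf)) / sum(w)
    if (err >= 1 - 1 / K || err <= 0) {
      if (err <= 0) { stumps[[t]] <- st; alphas[t] <- 10 }
      break
    }
    a <- log((1 - err) / err) + log(K - 1)
    stumps[[t]] <- st; alphas[t] <- a
    w <- w * exp(a * (pr != yf))
    w <- w / sum(w)
  }
  list(stumps = stumps, alphas = alphas, classes = levels(yf))
}

#' Predict classes from a fitted classifier
#' @param object An `nb_classifier`.
#' @param X Standardized feature matrix.
#' @param ... Unused.
#' @return Character vector of predicted class labels.
#' @export
predict.nb_classifier <- function(object, X, ...) {
  X <- as.matrix(X)
  if (object$kind == "constant") return(rep(object$classes, nrow(X)))
  if (!is.null(object$n_features) && ncol(X) != object$n_features) {
    stop("feature count mismatch")
  }
  if (!is.null(object$keep)) X <- X[, object$keep, drop = FALSE]
  cls <- object$classes
  fit <- object$fit
  out <- switch(object$family,
    mlp = cls[max.col(predict(fit, X), ties.method = "first")],
    lightgbm = ,
    gbt = {
      pr <- predict(fit, xgboost::xgb.DMatrix(X, nthread = 1))
      if (is.null(dim(pr))) pr <- matrix(pr, ncol = length(cls), byrow = TRUE)
      cls[max.col(pr, ties.method = "first")]
    },
    rf = ,
    extra_trees = as.character(predict(fit, data = X,
                                       num.threads = 1)$predictions),
    svm_rbf = ,
    svm_linear = as.character(predict(fit, X)),
    logreg = as.character(predict(fit, data.frame(X))),
    knn = {
      # class::knn breaks distance ties at random; pin the stream locally
      # so predictions are reproducible
      if (exists(".Random.seed", envir = globalenv())) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
      }
      set.seed(0)
      as.character(class::knn(fit$X, X, fit$y, k = fit$k))
    },
    dt = as.character(predict(fit, data.frame(X), type = "class")),
    lda = ,
    qda = as.character(predict(fit, X)$class),
    ridge = {
      sc <- cbind(1, X) %*% fit$W
      fit$classes[max.col(sc, ties.method = "first")]
    },
    nb = as.character(predict(fit, X)),
    adaboost = {
      votes <- matrix(0, nrow(X), length(fit$classes))
      d <- data.frame(X)
      for (t in seq_along(fit$stumps)) {
        pr <- predict(fit$stumps[[t]], d, type = "class")
        votes[cbind(seq_len(nrow(X)), as.integer(pr))] <-
          votes[cbind(seq_len(nrow(X)), as.integer(pr))] + fit$alphas[t]
      }
      fit$classes[max.col(votes, ties.method = "first")]
    }
  )
  out
}

#' Confusion matrix with derived metrics
#'
#' @param true,pred Vectors of true and predicted class labels.
#' @param roster Class roster fixing row/column order; default the sorted
#'   union of observed labels.
#' @return Object of class `nb_confusion`: `counts` (true x predicted),
#'   `accuracy`, per-class `precision` (TP/(TP+FP), 0 when a class is never
#'   predicted) and `sensitivity` (TP/(TP+FN)), and their macro averages.
#' @export
confusion_matrix <- function(true, pred, roster = NULL) {
  true <- as.character(true); pred <- as.character(pred)
  if (is.null(roster)) roster <- sort(unique(c(true, pred)))
  roster <- as.character(roster)
  counts <- table(factor(true, levels = roster),
                  factor(pred, levels = roster))
  counts <- unclass(counts)
  names(dimnames(counts)) <- c("true", "predicted")
  tp <- diag(counts)
  col_tot <- colSums(counts)
  row_tot <- rowSums(counts)
  precision <- ifelse(col_tot > 0, tp / col_tot, 0)
  sensitivity <- ifelse(row_tot > 0, tp / row_tot, 0)
  structure(list(
    counts = counts,
    accuracy = sum(tp) / sum(counts),
    precision = precision,
    sensitivity = sensitivity,
    macro_precision = mean(precision[row_tot > 0]),
    macro_sensitivity = mean(sensitivity[row_tot > 0])
  ), class = "nb_confusion")
}

#' @export
print.nb_confusion <- function(x, ...) {
  cat(sprintf("Confusion matrix (%d classes, %d records)\n",
              nrow(x$counts), sum(x$counts)))
  cat(sprintf("accuracy %.4f  macro precision %.4f  macro sensitivity %.4f\n",
              x$accuracy, x$macro_precision, x$macro_sensitivity))
  invisible(x)
}

# one CV round for a family; returns per-fold accuracy/precision/sensitivity
cv_family <- function(family, X, y, folds, fold_id, params, seed) {
  acc <- prec <- sens <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    std <- fit_standardizer(X[tr, , drop = FALSE])
    clf <- fit_classifier(family, apply_standardizer(std, X[tr, , drop = FALSE]),
                          y[tr], params, derive_seed(seed, paste0(family, f)))
    pred <- predict(clf, apply_standardizer(std, X[!tr, , drop = FALSE]))
    cm <- confusion_matrix(y[!tr], pred, sort(unique(y)))
    acc[f] <- cm$accuracy; prec[f] <- cm$macro_precision
    sens[f] <- cm$macro_sensitivity
  }
  list(accuracy = acc, precision = prec, sensitivity = sens)
}

#' Compare classifier families under cross-validation
#'
#' Fits every family in the roster at its library defaults on standardized
#' training folds (standardization is learned inside each fold), scores with
#' stratified K-fold cross-validation and returns a leaderboard sorted on
#' mean CV accuracy. A family that fails to fit is recorded with score 0 and
#' a warning rather than aborting the comparison.
#'
#' @param train Fingerprint data.frame with `label`.
#' @param roster Families to compare, default all of
#'   [classifier_families()].
#' @param folds CV folds, default 10.
#' @param seed Integer seed.
#' @param features Feature column names, default [feature_columns()].
#' @return Data.frame of class `leaderboard`: `family`, `accuracy`,
#'   `precision`, `sensitivity` (CV means, sorted by accuracy descending),
#'   with per-fold scores in `attr(, "fold_scores")`.
#' @export
compare_models <- function(train, roster = classifier_families(), folds = 10L,
                           seed = 1L, features = feature_columns()) {
  if (!length(roster)) stop("roster must name at least one family")
  if (folds < 2L) stop("folds must be >= 2")
  X <- as.matrix(train[, features, drop = FALSE])
  y <- as.character(train$label)
  fold_id <- stratified_folds(y, folds, derive_seed(seed, "cvfolds"))
  rows <- vector("list", length(roster))
  fold_scores <- list()
  for (i in seq_along(roster)) {
    fam <- roster[i]
    res <- tryCatch(
      cv_family(fam, X, y, folds, fold_id, list(), seed),
      error = function(e) {
        warning(sprintf("family '%s' failed to fit: %s", fam,
                        conditionMessage(e)))
        list(accuracy = rep(0, folds), precision = rep(0, folds),
             sensitivity = rep(0, folds))
      })
    rows[[i]] <- data.frame(family = fam,
                            accuracy = mean(res$accuracy),
                            precision = mean(res$precision),
                            sensitivity = mean(res$sensitivity))
    fold_scores[[fam]] <- res$accuracy
  }
  lb <- do.call(rbind, rows)
  lb <- lb[order(-lb$accuracy), , drop = FALSE]
  rownames(lb) <- NULL
  attr(lb, "fold_scores") <- fold_scores
  attr(lb, "folds") <- folds
  class(lb) <- c("leaderboard", "data.frame")
  lb
}

#' Tune the top family and build the reader model
#'
#' Random search over a small per-family grid (the default configuration is
#' always candidate 1, so with budget 1 the defaults are returned and the
#' tuned CV accuracy can never fall below the untuned one). Each candidate
#' is scored by stratified K-fold CV accuracy; the best configuration is
#' refitted on the full training set together with its standardizer.
#'
#' @param train Fingerprint data.frame with `label`.
#' @param family Family to tune.
#' @param budget Number of candidate configurations, default 10.
#' @param folds CV folds, default 10.
#' @param seed Integer seed.
#' @param features Feature column names.
#' @return Object of class `reader_model`: standardizer, fitted classifier,
#'   hyperparameters, class roster, feature schema, seed and CV accuracy.
#' @export
tune_top <- function(train, family, budget = 10L, folds = 10L, seed = 1L,
                     features = feature_columns()) {
  if (!family %in% classifier_families()) {
    stop(sprintf("unknown model family '%s'", family))
  }
  X <- as.matrix(train[, features, drop = FALSE])
  y <- as.character(train$label)
  fold_id <- stratified_folds(y, folds, derive_seed(seed, "tunefolds"))
  grid <- tuning_grid(family)
  cands <- list(list())                         # candidate 1: defaults
  if (budget > 1L && nrow(grid) > 0L) {
    set.seed(derive_seed(seed, "tunegrid"))
    take <- sample(nrow(grid), min(budget - 1L, nrow(grid)))
    for (j in take) cands[[length(cands) + 1L]] <- as.list(grid[j, , drop = FALSE])
  }
  scores <- vapply(seq_along(cands), function(j) {
    mean(cv_family(family, X, y, folds, fold_id, cands[[j]],
                   derive_seed(seed, paste0("cand", j)))$accuracy)
  }, numeric(1))
  best <- which.max(scores)
  std <- fit_standardizer(X)
  clf <- fit_classifier(family, apply_standardizer(std, X), y,
                        cands[[best]], derive_seed(seed, "final"))
  structure(list(
    standardizer = std, family = family, params = clf$params,
    classifier = clf, roster = sort(unique(y)), features = features,
    seed = seed, folds = folds,
    cv_accuracy = scores[best], cv_accuracy_default = scores[1],
    candidate_scores = scores
  ), class = "reader_model")
}

#' Train a reader model without tuning
#'
#' Convenience wrapper: standardize, fit one family at given (or default)
#' hyperparameters.
#'
#' @inheritParams tune_top
#' @param params Hyperparameters (missing entries take defaults).
#' @return A `reader_model`.
#' @export
train_reader <- function(train, family, params = list(), seed = 1L,
                         features = feature_columns()) {
  X <- as.matrix(train[, features, drop = FALSE])
  y <- as.character(train$label)
  std <- fit_standardizer(X)
  clf <- fit_classifier(family, apply_standardizer(std, X), y, params,
                        derive_seed(seed, "fit"))
  structure(list(standardizer = std, family = family, params = clf$params,
                 classifier = clf, roster = sort(unique(y)),
                 features = features, seed = seed,
                 cv_accuracy = NA_real_),
            class = "reader_model")
}

#' @export
print.reader_model <- function(x, ...) {
  cat(sprintf("Reader model: %s, %d classes, %d features, CV accuracy %s\n",
              x$family, length(x$roster), length(x$features),
              ifelse(is.na(x$cv_accuracy), "untracked",
                     sprintf("%.4f", x$cv_accuracy))))
  invisible(x)
}

#' Evaluate a reader model on labeled data
#'
#' @param model A `reader_model`.
#' @param test Fingerprint data.frame with `label`; classes must be a subset
#'   of the model roster.
#' @return An `nb_confusion`.
#' @export
evaluate_reader <- function(model, test) {
  extra <- setdiff(unique(as.character(test$label)), model$roster)
  if (length(extra)) {
    stop(sprintf("test contains class(es) outside the model roster: %s",
                 paste(extra, collapse = ", ")))
  }
  pred <- predict(model, test)
  confusion_matrix(test$label, pred, model$roster)
}

#' Predict barcodes for (possibly unlabeled) fingerprints
#'
#' @param object A `reader_model`.
#' @param newdata Fingerprint data.frame carrying the model's feature
#'   columns.
#' @param ... Unused.
#' @return Character vector of predicted class labels.
#' @export
predict.reader_model <- function(object, newdata, ...) {
  miss <- setdiff(object$features, names(newdata))
  if (length(miss)) {
    stop(sprintf("missing feature column(s): %s", paste(miss, collapse = ", ")))
  }
  X <- apply_standardizer(object$standardizer,
                          newdata[, object$features, drop = FALSE])
  if (nrow(X) == 0L) return(character(0))
  predict(object$classifier, X)
}

#' @rdname predict.reader_model
#' @param model A `reader_model`.
#' @param table Fingerprint data.frame.
#' @return `predict_reader`: list with `class` (per-record predictions) and
#'   `histogram` (named count of predictions per roster class).
#' @export
predict_reader <- function(model, table) {
  pred <- predict(model, table)
  hist <- table(factor(pred, levels = model$roster))
  list(class = pred, histogram = unclass(hist))
}

#' Persist / restore a reader model
#'
#' The bundle directory holds the standardizer, hyperparameters, roster and
#' feature schema in a YAML manifest plus the fitted classifier serialized
#' with R's native serialization.
#'
#' @param model A `reader_model`.
#' @param dir Bundle directory (created if needed).
#' @return `dir` (save) / the model (load).
#' @export
save_reader <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(list(
    family = model$family,
    params = model$params,
    roster = as.list(model$roster),
    features = as.list(model$features),
    seed = model$seed,
    cv_accuracy = model$cv_accuracy,
    standardizer = list(mean = as.list(model$standardizer$mean),
                        sd = as.list(model$standardizer$sd))
  ), file.path(dir, "manifest.yaml"))
  saveRDS(model, file.path(dir, "model.rds"))
  invisible(dir)
}

#' @rdname save_reader
#' @export
load_reader <- function(dir) {
  readRDS(file.path(dir, "model.rds"))
}
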