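## Experiments around the barcode reader: backward class elimination,
## Y-scrambling, feature importance/ablation, learning curve, PCA and
## virtual mixtures.

#' Backward class elimination
#'
#' Starting from all classes, repeatedly: split stratified, compare the
#' model roster under CV, tune the top family, evaluate on the held-out
#' test set, then drop the class with the worst test precision (ties broken
#' by lowest class id) and repeat until one class remains. Every iteration
#' re-splits, re-compares and re-tunes, so the top family may change along
#' the trace. Deterministic given `seed`.
#'
#' @param table Fingerprint data.frame with `label`.
#' @param roster Families compared at each iteration.
#' @param folds,budget CV folds and tuning budget per iteration.
#' @param test_fraction Held-out fraction per iteration.
#' @param seed Integer seed.
#' @param features Feature columns.
#' @return Object of class `elimination_trace`: a data.frame with one row
#'   per iteration (`iteration`, `n_classes`, `top_family`, `accuracy`,
#'   `macro_precision`, `macro_sensitivity`, `dropped`) plus attributes
#'   `remaining` (list of class-id vectors) and `class_precision` (list of
#'   named per-class precision vectors).
#' @export
backward_eliminate <- function(table, roster = classifier_families(),
                               folds = 10L, budget = 10L,
                               test_fraction = 0.2, seed = 1L,
                               features = feature_columns()) {
  classes <- sort(unique(as.character(table$label)))
  if (length(classes) < 2L) stop("need at least 2 classes to eliminate")
  remaining <- classes
  rows <- list(); rem_list <- list(); prec_list <- list()
  it <- 0L
  while (length(remaining) >= 1L) {
    it <- it + 1L
    sub <- table[table$label %in% remaining, , drop = FALSE]
    it_seed <- derive_seed(seed, paste0("elim", it))
    if (length(remaining) > 1L) {
      sp <- stratified_split(sub, test_fraction, it_seed)
      lb <- compare_models(sp$train, roster, folds, it_seed, features)
      model <- tune_top(sp$train, lb$family[1], budget, folds, it_seed,
                        features)
      cm <- evaluate_reader(model, sp$test)
      prec <- cm$precision
      acc <- cm$accuracy; mp <- cm$macro_precision; ms <- cm$macro_sensitivity
      fam <- lb$family[1]
    } else {
      # single class: the reader is trivially perfect
      prec <- stats::setNames(1, remaining)
      acc <- 1; mp <- 1; ms <- 1; fam <- "constant"
    }
    # argmin precision, ties -> lowest numeric id (or first name)
    ord <- order(prec, as.numeric(names(prec)))
    dropped <- names(prec)[ord[1]]
    rows[[it]] <- data.frame(iteration = it, n_classes = length(remaining),
                             top_family = fam, accuracy = acc,
                             macro_precision = mp, macro_sensitivity = ms,
                             dropped = dropped, stringsAsFactors = FALSE)
    rem_list[[it]] <- remaining
    prec_list[[it]] <- prec
    if (length(remaining) == 1L) break
    remaining <- setdiff(remaining, dropped)
  }
  trace <- do.call(rbind, rows)
  attr(trace, "remaining") <- rem_list
  attr(trace, "class_precision") <- prec_list
  class(trace) <- c("elimination_trace", "data.frame")
  trace
}

#' Y-scrambling (label permutation) control
#'
#' Refits the (untuned) family on training sets whose labels were randomly
#' permuted, scoring each on the untouched test set. A real signal shows as
#' the unscrambled accuracy sitting far above the scrambled distribution,
#' which itself concentrates near chance (1/K for balanced classes).
#'
#' @param train,test Fingerprint data.frames with `label`.
#' @param family Model family.
#' @param repeats Number of permutations, default 100.
#' @param seed Integer seed.
#' @param features Feature columns.
#' @return List: `scrambled` (accuracy per repeat), `reference` (unscrambled
#'   accuracy), `n_classes`.
#' @export
y_scramble <- function(train, test, family, repeats = 100L, seed = 1L,
                       features = feature_columns()) {
  if (repeats < 1L) stop("repeats must be >= 1")
  ref_model <- train_reader(train, family, seed = derive_seed(seed, "ref"),
                            features = features)
  reference <- evaluate_reader(ref_model, test)$accuracy
  scrambled <- numeric(repeats)
  for (r in seq_len(repeats)) {
    set.seed(derive_seed(seed, paste0("scramble", r)))
    perm <- train
    perm$label <- sample(perm$label)
    m <- train_reader(perm, family, seed = derive_seed(seed, paste0("fit", r)),
                      features = features)
    pred <- predict(m, test)
    scrambled[r] <- mean(pred == as.character(test$label))
  }
  list(scrambled = scrambled, reference = reference,
       n_classes = length(unique(train$label)))
}

#' Gain-based feature importance from a tree ensemble
#'
#' Fits a gradient-boosted-trees (or other tree-ensemble) family and
#' extracts split importance: the total improvement of the objective
#' contributed by splits on each feature, weighted by the observations each
#' node is responsible for.
#'
#' @param train Fingerprint data.frame with `label`.
#' @param family One of `lightgbm`, `gbt`, `rf`, `extra_trees`.
#' @param seed Integer seed.
#' @param features Feature columns.
#' @return Data.frame `feature`, `gain` (normalized to sum 1), sorted
#'   descending; unused features appear with gain 0.
#' @export
feature_importance <- function(train, family = "lightgbm", seed = 1L,
                               features = feature_columns()) {
  if (!family %in% c("lightgbm", "gbt", "rf", "extra_trees")) {
    stop("feature importance requires a tree-ensemble family")
  }
  model <- train_reader(train, family, seed = seed, features = features)
  fit <- model$classifier$fit
  if (family %in% c("lightgbm", "gbt")) {
    imp <- xgboost::xgb.importance(model = fit)
    gain <- stats::setNames(rep(0, length(features)), features)
    gain[imp$Feature] <- imp$Gain
  } else {
    # refit with impurity importance recorded
    X <- apply_standardizer(model$standardizer,
                            train[, features, drop = FALSE])
    rf <- ranger::ranger(x = X, y = factor(train$label),
                         num.trees = default_params(family)$num.trees,
                         splitrule = if (family == "extra_trees") "extratrees" else "gini",
                         importance = "impurity", num.threads = 1,
                         seed = seed)
    gain <- rf$variable.importance
    gain <- gain / sum(gain)
    gain <- gain[features]
  }
  out <- data.frame(feature = names(gain), gain = as.numeric(gain))
  out <- out[order(-out$gain), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Accuracy vs number of retained features
#'
#' Retrains the untuned family with the top-j features of an importance
#' ranking, for j from all features down to 1, and records test accuracy.
#'
#' @param train,test Fingerprint data.frames with `label`.
#' @param ranking Character vector of features, most important first
#'   (e.g. `feature_importance(...)$feature`).
#' @param family Model family to retrain, default `lightgbm`.
#' @param seed Integer seed.
#' @return Data.frame `n_features`, `accuracy`, `dropped` (feature removed
#'   relative to the previous row), from all features down to 1.
#' @export
feature_ablation_curve <- function(train, test, ranking, family = "lightgbm",
                                   seed = 1L) {
  if (!all(ranking %in% names(train))) stop("ranking names unknown features")
  rows <- list()
  for (j in rev(seq_along(ranking))) {
    feats <- ranking[seq_len(j)]
    m <- train_reader(train, family, seed = derive_seed(seed, paste0("abl", j)),
                      features = feats)
    acc <- evaluate_reader(m, test)$accuracy
    rows[[length(rows) + 1L]] <- data.frame(
      n_features = j, accuracy = acc,
      dropped = if (j == length(ranking)) NA_character_ else ranking[j + 1L])
  }
  do.call(rbind, rows)
}

#' Learning curve over observations per class
#'
#' For each requested size, subsamples that many records per class without
#' replacement, makes a fresh stratified split, trains the (untuned) family
#' and records test accuracy.
#'
#' @param table Fingerprint data.frame with `label`.
#' @param sizes Observations per class to evaluate.
#' @param family Model family.
#' @param test_fraction Held-out fraction.
#' @param seed Integer seed.
#' @param features Feature columns.
#' @return Data.frame `size`, `accuracy`.
#' @export
learning_curve <- function(table, sizes, family = "mlp", test_fraction = 0.2,
                           seed = 1L, features = feature_columns()) {
  cnt <- table(as.character(table$label))
  for (n in sizes) {
    short <- names(cnt)[cnt < n]
    if (length(short)) {
      stop(sprintf("class %s has fewer than %d records", short[1], n))
    }
  }
  rows <- list()
  for (n in sizes) {
    set.seed(derive_seed(seed, paste0("lcsub", n)))
    idx <- unlist(lapply(split(seq_len(nrow(table)), table$label),
                         function(i) sample(i, n)), use.names = FALSE)
    sub <- table[idx, , drop = FALSE]
    sp <- stratified_split(sub, test_fraction, derive_seed(seed, paste0("lcsp", n)))
    m <- train_reader(sp$train, family, seed = derive_seed(seed, paste0("lcfit", n)),
                      features = features)
    rows[[length(rows) + 1L]] <- data.frame(
      size = n, accuracy = evaluate_reader(m, sp$test)$accuracy)
  }
  do.call(rbind, rows)
}

#' PCA of the optical fingerprints
#'
#' Mean-centers the 14 features (no variance scaling by default, matching
#' the centering-only convention of MATLAB's `pca`; set `scale = TRUE` for
#' the Z-scored variant) and decomposes by SVD.
#'
#' @param table Fingerprint data.frame.
#' @param components Number of score components to return, default 3.
#' @param scale Scale features to unit variance before the SVD?
#' @param features Feature columns.
#' @return Object of class `pca_fingerprint`: `coefficients` (features x
#'   components), `scores` (records x `components`), `explained_variance`
#'   (percent per component, all components), `center`, `label` (carried
#'   through when present).
#' @export
pca_fingerprint <- function(table, components = 3L, scale = FALSE,
                            features = feature_columns()) {
  X <- as.matrix(table[, features, drop = FALSE])
  if (components > ncol(X)) stop("components exceeds the feature count")
  pc <- stats::prcomp(X, center = TRUE, scale. = scale)
  ev <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  structure(list(
    coefficients = pc$rotation,
    scores = pc$x[, seq_len(components), drop = FALSE],
    explained_variance = ev,
    center = pc$center,
    label = if ("label" %in% names(table)) table$label else NULL
  ), class = "pca_fingerprint")
}

#' @export
print.pca_fingerprint <- function(x, ...) {
  cat(sprintf("PCA fingerprint: %d records; explained variance %s%%\n",
              nrow(x$scores),
              paste(sprintf("%.1f", x$explained_variance[seq_len(
                min(3, length(x$explained_variance)))]), collapse = " / ")))
  invisible(x)
}

#' Build a virtual mixture from a held-out pool
#'
#' Samples an equal number of records per requested class from an unseen
#' pool (without replacement), strips the labels and seals them in a key for
#' later scoring — mimicking reading an unknown equal-ratio mixture.
#'
#' @param pool Fingerprint data.frame with `label`, disjoint from training.
#' @param class_ids Classes to mix.
#' @param n_per_class Records per class.
#' @param seed Integer seed.
#' @return Object of class `virtual_mixture`: `table` (unlabeled, shuffled)
#'   and `key` (true labels aligned to `table` rows).
#' @export
make_mixture <- function(pool, class_ids, n_per_class, seed = 1L) {
  class_ids <- as.character(class_ids)
  set.seed(seed)
  idx <- integer(0)
  for (cl in class_ids) {
    avail <- which(as.character(pool$label) == cl)
    if (length(avail) < n_per_class) {
      stop(sprintf("pool has only %d record(s) of class %s, need %d",
                   length(avail), cl, n_per_class))
    }
    idx <- c(idx, sample(avail, n_per_class))
  }
  idx <- sample(idx)
  key <- as.character(pool$label[idx])
  tab <- pool[idx, , drop = FALSE]
  tab$label <- NULL
  rownames(tab) <- NULL
  structure(list(table = tab, key = key, classes = class_ids),
            class = "virtual_mixture")
}

#' Score a reader model on a virtual mixture
#'
#' @param model A `reader_model`.
#' @param mixture A `virtual_mixture`.
#' @return List: `confusion` (an `nb_confusion` over the model roster) and
#'   `histogram` (prediction counts per roster class).
#' @export
evaluate_mixture <- function(model, mixture) {
  pred <- predict(model, mixture$table)
  list(confusion = confusion_matrix(mixture$key, pred, model$roster),
       histogram = unclass(table(factor(pred, levels = model$roster))))
}
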