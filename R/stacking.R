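#' Binarize labels against one positive class
#'
#' Recodes a label vector to 1 for the positive class and 0 otherwise, the
#' convention used by the one-vs-rest meta-models (e.g. 1 = normal,
#' 0 = tumor for two-class expression data).
#'
#' @param y label vector or factor.
#' @param positive_class the label mapped to 1; must occur in the class set.
#' @return integer vector of 0/1.
#' @export
binarize_labels <- function(y, positive_class) {
  y <- as.character(y)
  if (!positive_class %in% y) {
    abort("positive_class '", positive_class, "' not among the labels",
          class = "moostack_validation_error")
  }
  as.integer(y == positive_class)
}

# integer class codes (0-based, sorted class-name order)
class_codes <- function(labels, class_names) {
  match(as.character(labels), class_names) - 1L
}

#' Append base-model predictions as features
#'
#' Implements the stacking augmentation: each of the N base solutions
#' predicts a class label for every sample, and the integer class codes are
#' appended as N new numeric columns `P_1..P_N`; original columns are left
#' unchanged.  The same procedure is applied to the training and the test
#' split (with models fit on the training split only).
#'
#' @param data an [expr_dataset()].
#' @param trained_bases list of fitted base models as produced by
#'   [fit_stack()]: each element has `model` (a `base_model`) and `mask`.
#' @return an `expr_dataset` with `n_features + N` columns.
#' @export
augment <- function(data, trained_bases) {
  stopifnot(length(trained_bases) >= 1)
  preds <- vapply(seq_along(trained_bases), function(j) {
    b <- trained_bases[[j]]
    if (length(b$mask) != n_features(data)) {
      abort("base ", j, " mask width (", length(b$mask),
            ") does not match the dataset (", n_features(data), ")",
            class = "moostack_validation_error")
    }
    p <- predict(b$model, data$X[, b$mask, drop = FALSE])
    as.numeric(class_codes(p, data$class_names))
  }, numeric(n_samples(data)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1)
  colnames(preds) <- paste0("P_", seq_along(trained_bases))
  out <- expr_dataset(cbind(data$X, preds), as.character(data$y),
                      c(data$feature_names, colnames(preds)))
  rownames(out$X) <- rownames(data$X)
  out
}

#' Stage 2: stacked ensemble of the unique rank-1 solutions
#'
#' Retrieves the unique rank-1 solutions of the stage-1 front, fits each on
#' the training split restricted to its own feature mask, augments train and
#' test matrices with the N prediction columns, and refits the solution with
#' the highest stage-1 F-measure as meta-learner on the augmented training
#' set.  Binary problems use a single meta-model; k-class problems train one
#' meta-model per class on 1-vs-rest labels and predict the class whose
#' model yields the highest positive score (ties to the lowest class code).
#' The returned accuracy is that of the meta predictions on the augmented
#' test set.
#'
#' @param front a `pareto_front` from [run_nsga2()] (rank-1 non-empty).
#' @param split a `split_dataset` (the same feature space the front was
#'   searched on).
#' @param seed integer seed.
#' @param meta_features which columns the meta-learner sees: `"all"`
#'   (default; original features plus the N prediction columns),
#'   `"mask+preds"` (the meta solution's own mask plus predictions) or
#'   `"preds_only"`.
#' @param train_augmentation how the *training* prediction columns are
#'   obtained: `"loocv"` (default) uses each base's leave-one-out
#'   cross-validated predictions, so a memorizing base cannot hand the
#'   meta-learner a column that merely copies the training labels;
#'   `"insample"` uses the fitted bases' own training-set predictions.
#'   Test-set columns always come from bases fit on the full training split.
#' @param force_ovr fit one-vs-rest meta-models even for 2 classes
#'   (consistency checks; the decision rule is unchanged).
#' @return list with `model` (a `stacked_model`), `test_accuracy`,
#'   `base_test_accuracies`, `predictions` (factor over the test split) and
#'   `bases` (the unique rank-1 members used).
#' @export
fit_stack <- function(front, split, seed = 1,
                      meta_features = c("all", "mask+preds", "preds_only"),
                      train_augmentation = c("loocv", "insample"),
                      force_ovr = FALSE) {
  meta_features <- match.arg(meta_features)
  train_augmentation <- match.arg(train_augmentation)
  bases <- unique_rank1(front)
  train <- split$train
  test <- split$test
  classes <- train$class_names
  if (!identical(classes, test$class_names)) {
    abort("train and test class sets differ")
  }

  trained <- lapply(seq_along(bases), function(j) {
    b <- bases[[j]]
    mask <- b$chromosome$mask
    model <- fit_classifier(b$chromosome$spec,
                            train$X[, mask, drop = FALSE], train$y,
                            seed = derive_seed(seed, 100 + j))
    list(model = model, mask = mask, spec = b$chromosome$spec,
         f_measure = b$objectives$f_measure)
  })
  base_acc <- vapply(trained, function(b) {
    mean(predict(b$model, test$X[, b$mask, drop = FALSE]) == test$y)
  }, numeric(1))

  aug_train <- if (train_augmentation == "insample") {
    augment(train, trained)
  } else {
    # out-of-fold augmentation: column j holds base j's LOOCV predictions
    preds <- vapply(seq_along(trained), function(j) {
      ev <- loocv_evaluate(trained[[j]]$spec, train, trained[[j]]$mask,
                           seed = derive_seed(seed, 300 + j))
      as.numeric(class_codes(ev$predictions, classes))
    }, numeric(n_samples(train)))
    if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1)
    colnames(preds) <- paste0("P_", seq_along(trained))
    expr_dataset(cbind(train$X, preds), as.character(train$y),
                 c(train$feature_names, colnames(preds)))
  }
  aug_test <- augment(test, trained)
  meta <- trained[[1]]  # highest stage-1 F-measure (unique_rank1 order)
  meta_cols <- switch(meta_features,
    all = rep(TRUE, n_features(aug_train)),
    `mask+preds` = c(meta$mask, rep(TRUE, length(trained))),
    preds_only = c(rep(FALSE, n_features(train)), rep(TRUE, length(trained))))
  Xtr <- aug_train$X[, meta_cols, drop = FALSE]
  Xte <- aug_test$X[, meta_cols, drop = FALSE]

  if (length(classes) == 2 && !force_ovr) {
    meta_model <- fit_classifier(meta$spec, Xtr, aug_train$y,
                                 seed = derive_seed(seed, 200))
    pred <- predict(meta_model, Xte)
    meta_models <- list(meta_model)
  } else {
    scores <- matrix(NA_real_, nrow(Xte), length(classes),
                     dimnames = list(NULL, classes))
    meta_models <- vector("list", length(classes))
    for (ci in seq_along(classes)) {
      ybin <- factor(binarize_labels(aug_train$y, classes[ci]),
                     levels = c(0, 1))
      meta_models[[ci]] <- fit_classifier(meta$spec, Xtr, ybin,
                                          seed = derive_seed(seed, 200 + ci))
      scores[, ci] <- predict_score(meta_models[[ci]], Xte, positive = "1")
    }
    # highest positive score wins; ties to the lowest class code
    pred <- factor(classes[apply(scores, 1, which.max)], levels = classes)
  }
  model <- structure(
    list(base_solutions = lapply(trained, function(b)
           list(spec = b$spec, mask = b$mask)),
         trained_bases = trained,
         meta_spec = meta$spec,
         meta_models = meta_models,
         meta_features = meta_features,
         classes = classes,
         augmented_feature_names = aug_train$feature_names),
    class = "stacked_model")
  list(model = model,
       test_accuracy = mean(pred == test$y),
       base_test_accuracies = base_acc,
       predictions = pred,
       bases = bases)
}

#' @export
print.stacked_model <- function(x, ...) {
  cat("<stacked_model> ", length(x$base_solutions), " base solution(s), meta = ",
      format(x$meta_spec), ", ", length(x$meta_models), " meta model(s)\n",
      sep = "")
  invisible(x)
}

#' Predict with a fitted stacked model
#' @param object a `stacked_model`.
#' @param data an [expr_dataset()] on the original feature space.
#' @param ... unused.
#' @return factor of predicted class labels.
#' @export
predict.stacked_model <- function(object, data, ...) {
  aug <- augment(data, object$trained_bases)
  meta_cols <- switch(object$meta_features,
    all = rep(TRUE, n_features(aug)),
    `mask+preds` = c(object$trained_bases[[1]]$mask,
                     rep(TRUE, length(object$trained_bases))),
    preds_only = c(rep(FALSE, n_features(data)),
                   rep(TRUE, length(object$trained_bases))))
  X <- aug$X[, meta_cols, drop = FALSE]
  classes <- object$classes
  if (length(object$meta_models) == 1) {
    predict(object$meta_models[[1]], X)
  } else {
    scores <- vapply(seq_along(classes), function(ci) {
      predict_score(object$meta_models[[ci]], X, positive = "1")
    }, numeric(nrow(X)))
    if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
    factor(classes[apply(scores, 1, which.max)], levels = classes)
  }
}
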