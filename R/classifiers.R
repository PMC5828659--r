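
# Hyperparameter grids of the four base learners.  Codes: 1=RF, 2=RT,
# 3=SMO (linear-kernel SVM, "complexity" = box constraint C), 4=LR.
# A randomly-chosen-features value of 0 means "use the learner's default
# heuristic count".
classifier_grids <- list(
  `1` = list(name = "RF",
             slots = list(n_trees = c(10, 20, 30),
                          n_rand_features = c(0, 5, 6))),
  `2` = list(name = "RT",
             slots = list(min_leaf_weight = c(1.0, 1.05, 1.25),
                          n_rand_features = c(0, 3, 7))),
  `3` = list(name = "SMO",
             slots = list(complexity = c(1, 3, 8))),
  `4` = list(name = "LR", slots = list())
)

#' Classifier specification
#'
#' A candidate base learner: integer code (1 = random forest, 2 = random
#' tree, 3 = SMO / linear SVM, 4 = logistic regression) plus ordered
#' hyperparameter slot values drawn from that learner's grid:
#' * RF: number of trees in \{10, 20, 30\}; candidate features per split in
#'   \{0, 5, 6\} (0 = default heuristic, `floor(sqrt(p))`).
#' * RT: minimum total leaf weight in \{1.0, 1.05, 1.25\} (fractional weights
#'   rounded up to a minimum node size); candidate features per split in
#'   \{0, 3, 7\}.
#' * SMO: box constraint C in \{1, 3, 8\}, linear kernel.
#' * LR: no tuned parameters.
#'
#' @param code integer in 1..4.
#' @param params numeric vector of slot values, one per slot of `code`'s grid.
#' @return a `classifier_spec`.
#' @export
classifier_spec <- function(code, params = numeric(0)) {
  code <- as.integer(code)
  if (!code %in% 1:4) {
    abort("classifier code must be in 1..4, got ", code,
          class = "moostack_validation_error")
  }
  grid <- classifier_grids[[as.character(code)]]
  params <- as.numeric(params)
  if (length(params) != length(grid$slots)) {
    abort(grid$name, " takes ", length(grid$slots), " parameter(s), got ",
          length(params), class = "moostack_validation_error")
  }
  for (i in seq_along(grid$slots)) {
    if (!params[i] %in% grid$slots[[i]]) {
      abort(grid$name, " parameter '", names(grid$slots)[i], "' = ", params[i],
            " not in grid {", paste(grid$slots[[i]], collapse = ", "), "}",
            class = "moostack_validation_error")
    }
  }
  structure(list(code = code, params = params, name = grid$name),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  cat("<classifier_spec> ", x$name,
      if (length(x$params)) paste0("(", paste(x$params, collapse = ", "), ")")
      else "(defaults)", "\n", sep = "")
  invisible(x)
}

#' @export
format.classifier_spec <- function(x, ...) {
  paste0(x$name, "[", paste(x$params, collapse = ","), "]")
}

# uniformly sample a spec from the grids (uses the current RNG stream)
random_classifier_spec <- function(code = sample(1:4, 1)) {
  grid <- classifier_grids[[as.character(code)]]
  params <- vapply(grid$slots, function(v) v[sample.int(length(v), 1)],
                   numeric(1))
  classifier_spec(code, unname(params))
}

default_mtry <- function(requested, p) {
  if (requested == 0) max(1L, floor(sqrt(p))) else min(as.integer(requested), p)
}

#' Train a base classifier
#'
#' Fits the learner described by `spec` on a feature matrix.  All learners
#' are made deterministic given `seed` (the RF/RT bootstrap and split
#' sampling, and the LR weight initialization, are seeded; the global RNG
#' stream is left untouched).  A degenerate single-class training set yields
#' a constant predictor of that class, so leave-one-out folds that lose a
#' class never fail.
#'
#' @param spec a [classifier_spec()].
#' @param X numeric training matrix (samples x features).
#' @param y factor of training labels.
#' @param seed integer seed.
#' @return a `base_model` with `predict` and score support.
#' @export
fit_classifier <- function(spec, X, y, seed = 1) {
  stopifnot(inherits(spec, "classifier_spec"))
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  levels_all <- levels(y)
  model <- NULL
  kind <- spec$name
  if (nlevels(y) < 2) {
    kind <- "constant"
    model <- levels(y)[1]
  } else {
    preserve_rng({
      set.seed(seed)
      model <- switch(
        spec$name,
        RF = randomForest::randomForest(
          x = X, y = y, ntree = spec$params[1],
          mtry = default_mtry(spec$params[2], ncol(X))),
        RT = randomForest::randomForest(
          x = X, y = y, ntree = 1, replace = FALSE, sampsize = nrow(X),
          mtry = default_mtry(spec$params[2], ncol(X)),
          nodesize = ceiling(spec$params[1])),
        SMO = e1071::svm(x = X, y = y, kernel = "linear",
                         cost = spec$params[1], scale = FALSE,
                         probability = FALSE),
        # tiny ridge keeps the fit well-posed when classes are separable
        # (unpenalized ML diverges and its direction is arbitrary)
        LR = nnet::multinom(y ~ ., data = data.frame(y = y, X,
                                                     check.names = FALSE),
                            trace = FALSE, maxit = 500, MaxNWts = 20000,
                            decay = 1e-4)
      )
    })
  }
  structure(list(model = model, kind = kind, spec = spec, classes = levels_all,
                 feature_names = colnames(X)),
            class = "base_model")
}

#' Predict class labels from a fitted base model
#' @param object a `base_model`.
#' @param newdata numeric matrix with the training columns.
#' @param ... unused.
#' @return factor of predicted labels with the training class levels.
#' @export
predict.base_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  colnames(newdata) <- object$feature_names
  p <- switch(
    object$kind,
    constant = rep(object$model, nrow(newdata)),
    RF = ,
    RT = as.character(predict(object$model, newdata)),
    SMO = as.character(predict(object$model, newdata)),
    LR = as.character(predict(object$model,
                              newdata = data.frame(newdata, check.names = FALSE),
                              type = "class"))
  )
  factor(p, levels = object$classes)
}

# Numeric score for one designated positive class (used by the one-vs-rest
# meta-models, which always train on binary 0/1 labels).  Higher = more
# confident the sample is positive.
predict_score <- function(object, newdata, positive) {
  stopifnot(inherits(object, "base_model"))
  newdata <- as.matrix(newdata)
  colnames(newdata) <- object$feature_names
  if (object$kind == "constant") {
    return(rep(if (object$model == positive) 1 else 0, nrow(newdata)))
  }
  switch(
    object$kind,
    RF = ,
    RT = {
      pr <- predict(object$model, newdata, type = "prob")
      as.numeric(pr[, positive])
    },
    SMO = {
      pv <- predict(object$model, newdata, decision.values = TRUE)
      dv <- attr(pv, "decision.values")
      lab <- colnames(dv)[1]  # "A/B": decision value positive favors A
      parts <- strsplit(lab, "/", fixed = TRUE)[[1]]
      if (parts[1] == positive) as.numeric(dv[, 1]) else -as.numeric(dv[, 1])
    },
    LR = {
      pr <- predict(object$model,
                    newdata = data.frame(newdata, check.names = FALSE),
                    type = "probs")
      if (is.matrix(pr)) as.numeric(pr[, positive])
      else if (object$classes[2] == positive) as.numeric(pr)
      else 1 - as.numeric(pr)
    }
  )
}

#' Macro-averaged precision, recall and F-measure
#'
#' Pools a truth/prediction pair into a confusion matrix over `classes` and
#' macro-averages per-class precision (`TP / predicted`) and recall
#' (`TP / actual`) with equal class weights.  A class with zero predicted
#' instances contributes precision 0; F is the harmonic mean, 0 when both
#' components are 0.
#'
#' @param truth,pred factors or label vectors of equal length.
#' @param classes class name vector; defaults to the union of levels.
#' @return list with `precision`, `recall`, `f_measure`, `accuracy`.
#' @export
macro_metrics <- function(truth, pred, classes = NULL) {
  if (is.null(classes)) classes <- sort(unique(c(as.character(truth),
                                                 as.character(pred))))
  truth <- factor(as.character(truth), levels = classes)
  pred <- factor(as.character(pred), levels = classes)
  cm <- table(truth, pred)
  tp <- diag(cm)
  prec_c <- ifelse(colSums(cm) == 0, 0, tp / colSums(cm))
  rec_c <- ifelse(rowSums(cm) == 0, 0, tp / rowSums(cm))
  precision <- mean(prec_c)
  recall <- mean(rec_c)
  f <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f_measure = f,
       accuracy = sum(tp) / sum(cm))
}

#' Leave-one-out cross-validated objective values
#'
#' For every sample i the learner is trained on all other samples restricted
#' to the masked features and predicts sample i; the pooled predictions give
#' macro precision and recall, and the feature count is the popcount of the
#' mask.  Each fold's model fit uses a seed derived from `(seed, i)` so runs
#' are reproducible without identically seeding every fold.
#'
#' @param spec a [classifier_spec()].
#' @param data an [expr_dataset()] with >= 3 samples.
#' @param feature_mask logical vector over features with >= 1 bit set.
#' @param seed integer seed.
#' @return an `eval_result`: list with `precision`, `recall`, `n_features`,
#'   `f_measure` (and the pooled `predictions`).
#' @export
loocv_evaluate <- function(spec, data, feature_mask, seed = 1) {
  if (length(feature_mask) != n_features(data)) {
    abort("feature_mask length (", length(feature_mask),
          ") != number of features (", n_features(data), ")")
  }
  if (!any(feature_mask)) {
    abort("feature mask is empty; at least one feature is required",
          class = "moostack_validation_error")
  }
  n <- n_samples(data)
  if (n < 3) abort("LOOCV needs >= 3 samples")
  Xm <- data$X[, feature_mask, drop = FALSE]
  pred <- character(n)
  for (i in seq_len(n)) {
    fit <- fit_classifier(spec, Xm[-i, , drop = FALSE], data$y[-i],
                          seed = derive_seed(seed, i))
    pred[i] <- as.character(predict(fit, Xm[i, , drop = FALSE]))
  }
  m <- macro_metrics(data$y, pred, data$class_names)
  structure(list(precision = m$precision, recall = m$recall,
                 n_features = sum(feature_mask), f_measure = m$f_measure,
                 predictions = factor(pred, levels = data$class_names)),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> precision %.4f  recall %.4f  F %.4f  |S| = %d\n",
              x$precision, x$recall, x$f_measure, x$n_features))
  invisible(x)
}
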