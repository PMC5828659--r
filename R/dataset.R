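#' Labeled expression dataset
#'
#' The central container: a numeric samples-by-features matrix `X` (expression
#' values or binary clinical features), a label factor `y`, and the feature /
#' class name vectors.  Class names are the sorted distinct labels, so the
#' integer coding of classes is reproducible regardless of file row order.
#'
#' @param X numeric matrix, samples in rows, features in columns.
#' @param y vector of class labels, one per row of `X`; coerced to character.
#' @param feature_names character vector naming the columns of `X`; defaults
#'   to existing column names.
#' @return an object of class `expr_dataset` with fields `X`, `y`
#'   (factor with levels = `class_names`), `feature_names`, `class_names`.
#' @export
expr_dataset <- function(X, y, feature_names = colnames(X)) {
  X <- as.matrix(X)
  if (!is.numeric(X)) abort("X must be a numeric matrix")
  y <- as.character(y)
  if (nrow(X) != length(y)) {
    abort("row count of X (", nrow(X), ") != length of y (", length(y), ")")
  }
  if (is.null(feature_names)) feature_names <- paste0("f", seq_len(ncol(X)))
  feature_names <- as.character(feature_names)
  if (length(feature_names) != ncol(X)) {
    abort("feature_names length != number of columns of X")
  }
  if (anyDuplicated(feature_names)) {
    abort("duplicate feature names: ",
          paste(unique(feature_names[duplicated(feature_names)]), collapse = ", "))
  }
  class_names <- sort(unique(y))
  if (length(class_names) < 2) {
    abort("dataset must contain at least 2 classes, found ",
          length(class_names), class = "moostack_validation_error")
  }
  colnames(X) <- feature_names
  if (is.null(rownames(X))) rownames(X) <- paste0("s", seq_len(nrow(X)))
  structure(
    list(
      X = X,
      y = factor(y, levels = class_names),
      feature_names = feature_names,
      class_names = class_names
    ),
    class = "expr_dataset"
  )
}

#' @export
print.expr_dataset <- function(x, ...) {
  cat("<expr_dataset> ", nrow(x$X), " samples x ", ncol(x$X), " features\n",
      sep = "")
  tab <- table(x$y)
  cat("classes:", paste0(names(tab), " (", as.integer(tab), ")", collapse = ", "),
      "\n")
  invisible(x)
}

#' Number of samples / features
#' @param data an `expr_dataset`.
#' @export
n_samples <- function(data) nrow(data$X)

#' @rdname n_samples
#' @export
n_features <- function(data) ncol(data$X)

#' Restrict a dataset to a subset of features
#'
#' @param data an `expr_dataset`.
#' @param features logical mask over columns, or a character vector of
#'   feature names (order of `features` is honored for names).
#' @return an `expr_dataset` with the selected columns.
#' @export
subset_features <- function(data, features) {
  if (is.logical(features)) {
    if (length(features) != n_features(data)) {
      abort("feature mask length != number of features")
    }
    idx <- which(features)
  } else {
    idx <- match(features, data$feature_names)
    if (anyNA(idx)) abort("unknown feature(s): ",
                          paste(features[is.na(idx)], collapse = ", "))
  }
  if (length(idx) == 0) abort("feature selection is empty")
  expr_dataset(data$X[, idx, drop = FALSE], as.character(data$y),
               data$feature_names[idx])
}

#' Read a delimited samples-by-features table
#'
#' Expects a header row; every column except the label column must be numeric.
#' Column order of `X` preserves file order minus the label column.  Labels
#' are read as strings; class codes follow sorted label order.
#'
#' @param path file path.
#' @param label_column name of the label column, or its 1-based column index.
#' @param delimiter field separator (default ",").
#' @return an [expr_dataset()].
#' @export
read_dataset <- function(path, label_column = "label", delimiter = ",") {
  if (!file.exists(path)) abort("file not found: ", path, class = "moostack_io_error")
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", comment.char = "")
  if (is.numeric(label_column)) {
    if (label_column < 1 || label_column > ncol(df)) {
      abort("label column index ", label_column, " out of range")
    }
    lab_idx <- as.integer(label_column)
  } else {
    lab_idx <- match(label_column, colnames(df))
    if (is.na(lab_idx)) {
      abort("label column '", label_column, "' not found; columns: ",
            paste(utils::head(colnames(df), 10), collapse = ", "))
    }
  }
  y <- df[[lab_idx]]
  feat <- df[, -lab_idx, drop = FALSE]
  X <- matrix(NA_real_, nrow(feat), ncol(feat),
              dimnames = list(NULL, colnames(feat)))
  for (j in seq_len(ncol(feat))) {
    v <- suppressWarnings(as.numeric(feat[[j]]))
    bad <- which(is.na(v) & !is.na(feat[[j]]))
    if (length(bad) > 0) {
      abort("non-numeric value '", feat[[j]][bad[1]], "' at row ", bad[1],
            ", column '", colnames(feat)[j], "'",
            class = "moostack_parse_error")
    }
    X[, j] <- v
  }
  expr_dataset(X, y)
}

#' Write a dataset as a delimited table
#'
#' Numeric cells are written with 17 significant digits so that
#' `read_dataset(write_dataset(d))` reproduces `X` bit-exactly.
#'
#' @param data an `expr_dataset`.
#' @param path output file path.
#' @param label_column name to give the label column.
#' @param delimiter field separator (default ",").
#' @export
write_dataset <- function(data, path, label_column = "label", delimiter = ",") {
  if (label_column %in% data$feature_names) {
    abort("label column name '", label_column, "' collides with a feature name")
  }
  chr <- matrix(sprintf("%.17g", data$X), nrow(data$X), ncol(data$X))
  out <- cbind(chr, as.character(data$y))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(data$feature_names, label_column), collapse = delimiter),
             con)
  writeLines(apply(out, 1, paste, collapse = delimiter), con)
  invisible(path)
}

#' Stratified train/test split
#'
#' Per class `c`, the training set receives `round(train_fraction * count(c))`
#' samples (round-half-up), the remainder go to the test set, so class
#' proportions stay as uniform as the arithmetic allows in both sets.
#'
#' @param data an `expr_dataset`; every class needs at least 2 samples.
#' @param train_fraction proportion in (0, 1) of each class assigned to the
#'   training set (default 0.6).
#' @param seed integer seed controlling which samples land in which set.
#' @return a `split_dataset`: list with `train` and `test` `expr_dataset`s
#'   sharing `feature_names` and `class_names`.
#' @export
stratified_split <- function(data, train_fraction = 0.6, seed = 1) {
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
    abort("train_fraction must lie in (0, 1)")
  }
  counts <- table(data$y)
  if (any(counts < 2)) {
    abort("every class needs >= 2 samples; offending class(es): ",
          paste(names(counts)[counts < 2], collapse = ", "),
          class = "moostack_validation_error")
  }
  train_idx <- integer(0)
  preserve_rng({
    set.seed(derive_seed(seed, 17))
    for (cl in data$class_names) {
      idx <- which(data$y == cl)
      n_tr <- round_half_up(train_fraction * length(idx))
      n_tr <- max(1L, min(length(idx) - 1L, n_tr))  # both sets keep the class
      train_idx <- c(train_idx, sample(idx, n_tr))
    }
  })
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(n_samples(data)), train_idx)
  mk <- function(idx) {
    expr_dataset(data$X[idx, , drop = FALSE], as.character(data$y[idx]),
                 data$feature_names)
  }
  structure(list(train = mk(train_idx), test = mk(test_idx)),
            class = "split_dataset")
}

#' @export
print.split_dataset <- function(x, ...) {
  cat("<split_dataset>\n  train: ", nrow(x$train$X), " samples\n  test:  ",
      nrow(x$test$X), " samples\n", sep = "")
  invisible(x)
}
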