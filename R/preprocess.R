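#' Feature score table
#'
#' Result of a filter-style feature ranking: one score per feature plus the
#' boolean selection mask implied by the producing rule.
#'
#' @param feature_names character vector.
#' @param scores numeric vector, same length.
#' @param selected logical vector, same length.
#' @param method short string identifying the producing filter.
#' @return a `feature_scores` data.frame with columns `feature`, `score`,
#'   `selected`, ordered as in the input dataset.
#' @export
feature_scores <- function(feature_names, scores, selected, method = "") {
  stopifnot(length(scores) == length(feature_names),
            length(selected) == length(feature_names))
  structure(
    data.frame(feature = feature_names, score = scores, selected = selected,
               stringsAsFactors = FALSE),
    method = method,
    class = c("feature_scores", "data.frame")
  )
}

#' Names of the selected features, ranked by decreasing score
#' @param tab a `feature_scores` table.
#' @export
selected_features <- function(tab) {
  sel <- tab[tab$selected, , drop = FALSE]
  sel$feature[order(-sel$score, match(sel$feature, tab$feature))]
}

#' Write a feature score table as TSV
#' @param tab a `feature_scores` table.
#' @param path output path.
#' @export
write_feature_scores <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# chi-squared statistic of independence, no continuity correction;
# cells with expected count 0 contribute 0
chi2_stat <- function(tab) {
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  ok <- expected > 0
  sum((tab[ok] - expected[ok])^2 / expected[ok])
}

# Discretize a feature for the chi-squared test: features with at most
# n_bins distinct values are treated as categorical as-is; continuous
# features get equal-frequency bins from quantile breaks.
discretize_feature <- function(x, n_bins) {
  ux <- unique(x)
  if (length(ux) <= n_bins) return(factor(x, levels = sort(ux)))
  breaks <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                                   names = FALSE, type = 7))
  if (length(breaks) < 2) return(factor(rep("bin1", length(x))))
  cut(x, breaks = breaks, include.lowest = TRUE)
}

#' Chi-squared attribute ranking (top-k)
#'
#' Scores every feature by the chi-squared statistic of independence between
#' the (discretized) feature and the class label, then selects the `k`
#' largest (ties broken by ascending feature index).  Continuous features are
#' discretized into `n_bins` equal-frequency bins first; a constant feature
#' scores 0.  No continuity correction is applied.
#'
#' @param data an [expr_dataset()].
#' @param k number of features to retain; must not exceed `n_features(data)`.
#' @param n_bins number of equal-frequency bins for continuous features.
#' @return a [feature_scores()] table with exactly `k` selected features.
#' @export
chi2_top_k <- function(data, k, n_bins = 10) {
  if (k < 1 || k > n_features(data)) {
    abort("k must lie in [1, ", n_features(data), "], got ", k,
          class = "moostack_validation_error")
  }
  scores <- vapply(seq_len(n_features(data)), function(j) {
    b <- discretize_feature(data$X[, j], n_bins)
    if (nlevels(b) < 2) return(0)
    chi2_stat(table(b, data$y))
  }, numeric(1))
  sel_idx <- order(-scores, seq_along(scores))[seq_len(k)]
  selected <- seq_along(scores) %in% sel_idx
  feature_scores(data$feature_names, scores, selected, method = "chi2")
}

#' Per-sample normalization to mean 0, variance 1
#'
#' Centers and scales every sample (row) of the expression matrix so its
#' values have mean 0 and unit sample variance, the usual per-array
#' standardization before signal-to-noise filtering.
#'
#' @param data an [expr_dataset()]; every row needs >= 2 distinct values.
#' @return an `expr_dataset` with normalized `X`.
#' @export
normalize_samples <- function(data) {
  sds <- apply(data$X, 1, stats::sd)
  if (any(sds == 0)) {
    abort("constant sample(s) cannot be normalized: ",
          paste(rownames(data$X)[sds == 0], collapse = ", "),
          class = "moostack_validation_error")
  }
  Xn <- (data$X - rowMeans(data$X)) / sds
  out <- expr_dataset(Xn, as.character(data$y), data$feature_names)
  rownames(out$X) <- rownames(data$X)
  out
}

#' Signal-to-noise-ratio feature filter (two-class)
#'
#' Computes the Golub signal-to-noise statistic per feature,
#' `SNR = (mu1 - mu2) / (sd1 + sd2)`, where `mu`/`sd` are the per-class mean
#' and sample standard deviation and class 1/2 follow sorted class-name
#' order.  Features with `|SNR|` at or above the mean of all `|SNR|` values
#' are selected.  A feature with `sd1 + sd2 = 0` gets SNR 0 with a warning.
#'
#' @param data an [expr_dataset()] with exactly 2 classes, each holding
#'   >= 2 samples.
#' @return a [feature_scores()] table; `score` holds the signed SNR.
#' @export
snr_filter <- function(data) {
  if (length(data$class_names) != 2) {
    abort("SNR filter requires exactly 2 classes, found ",
          length(data$class_names), class = "moostack_validation_error")
  }
  if (any(table(data$y) < 2)) {
    abort("each class needs >= 2 samples for per-class standard deviations",
          class = "moostack_validation_error")
  }
  i1 <- data$y == data$class_names[1]
  X1 <- data$X[i1, , drop = FALSE]
  X2 <- data$X[!i1, , drop = FALSE]
  mu1 <- colMeans(X1); mu2 <- colMeans(X2)
  sd1 <- apply(X1, 2, stats::sd); sd2 <- apply(X2, 2, stats::sd)
  denom <- sd1 + sd2
  snr <- ifelse(denom == 0, 0, (mu1 - mu2) / denom)
  if (any(denom == 0)) {
    warning("feature(s) with zero within-class spread get SNR 0: ",
            paste(data$feature_names[denom == 0], collapse = ", "))
  }
  selected <- abs(snr) >= mean(abs(snr))
  feature_scores(data$feature_names, unname(snr), unname(selected),
                 method = "snr")
}

#' Fit a feature filter on one dataset and apply it to others
#'
#' Convenience wrapper implementing the leak-free default: the filter is fit
#' on the training split only and the resulting feature subset is applied to
#' both splits.
#'
#' @param split a `split_dataset`.
#' @param method one of "chi2", "snr", "none".
#' @param top_k retained feature count for the chi2 method.
#' @param n_bins discretization bins for the chi2 method.
#' @param fit_on "train" (default, leak-free) or "all" (fit the filter on the
#'   union of both splits before subsetting).
#' @return list with the filtered `split` and the `scores` table (`NULL` for
#'   method "none").
#' @export
apply_filter <- function(split, method = c("none", "chi2", "snr"),
                         top_k = 100, n_bins = 10,
                         fit_on = c("train", "all")) {
  method <- match.arg(method)
  fit_on <- match.arg(fit_on)
  if (method == "none") return(list(split = split, scores = NULL))
  fit_data <- if (fit_on == "train") split$train else
    expr_dataset(rbind(split$train$X, split$test$X),
                 c(as.character(split$train$y), as.character(split$test$y)),
                 split$train$feature_names)
  if (method == "snr") {
    fit_data <- normalize_samples(fit_data)
    split <- structure(list(train = normalize_samples(split$train),
                            test = normalize_samples(split$test)),
                       class = "split_dataset")
  }
  tab <- switch(method,
                chi2 = chi2_top_k(fit_data, k = min(top_k, n_features(fit_data)),
                                  n_bins = n_bins),
                snr = snr_filter(fit_data))
  keep <- tab$selected
  out <- structure(list(train = subset_features(split$train, keep),
                        test = subset_features(split$test, keep)),
                   class = "split_dataset")
  list(split = out, scores = tab)
}
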