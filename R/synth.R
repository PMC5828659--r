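#' Synthetic expression dataset with planted informative features
#'
#' Gaussian class-conditional generator emulating the structure the search
#' assumes: a small set of informative features whose class means are
#' shifted, buried among pure-noise features.  Informative feature values in
#' class `c` (1-based, sorted label order) are drawn from
#' `N((c - 1) * effect_size, noise_sd^2)`; noise features are
#' `N(0, noise_sd^2)` in every class.  Feature names mark the planted
#' features (`inf_1..`, `noise_1..`); class labels are `class01..classK`.
#'
#' @param n_per_class samples per class (default 25).
#' @param n_features total feature count (default 100).
#' @param n_informative number of planted features, `<= n_features`
#'   (default 5).
#' @param effect_size mean shift between consecutive classes in units of
#'   `noise_sd` (default 3).
#' @param n_classes number of classes, >= 2 (default 2).
#' @param noise_sd within-class standard deviation (default 1).
#' @param seed integer seed; the same seed reproduces the matrix exactly.
#' @return an [expr_dataset()].
#' @export
synth_dataset <- function(n_per_class = 25, n_features = 100,
                          n_informative = 5, effect_size = 3,
                          n_classes = 2, noise_sd = 1, seed = 1) {
  if (n_informative > n_features) {
    abort("n_informative (", n_informative, ") > n_features (", n_features, ")",
          class = "moostack_validation_error")
  }
  if (n_classes < 2) abort("n_classes must be >= 2",
                           class = "moostack_validation_error")
  if (noise_sd <= 0) abort("noise_sd must be positive",
                           class = "moostack_validation_error")
  if (n_per_class < 1) abort("n_per_class must be >= 1",
                             class = "moostack_validation_error")
  n <- n_per_class * n_classes
  y <- rep(sprintf("class%02d", seq_len(n_classes)), each = n_per_class)
  X <- preserve_rng({
    set.seed(derive_seed(seed, 31))
    M <- matrix(stats::rnorm(n * n_features, sd = noise_sd), n, n_features)
    if (n_informative > 0) {
      shift <- (rep(seq_len(n_classes), each = n_per_class) - 1) * effect_size
      M[, seq_len(n_informative)] <- M[, seq_len(n_informative)] + shift
    }
    M
  })
  names_inf <- if (n_informative > 0) paste0("inf_", seq_len(n_informative))
               else character(0)
  names_noise <- if (n_features > n_informative)
    paste0("noise_", seq_len(n_features - n_informative)) else character(0)
  expr_dataset(X, y, c(names_inf, names_noise))
}

#' Synthetic dataset with one perfectly informative feature
#'
#' A harder-edged fixture: feature `inf_1` equals the 0-based class code
#' exactly (zero noise), all remaining features are pure `N(0, 1)` noise.
#' Any consistent learner reaches perfect LOOCV precision and recall using
#' that single feature, so the search optimum is known to be
#' `(1, 1, 1)`.
#'
#' @param n_per_class samples per class.
#' @param n_features total feature count.
#' @param n_classes number of classes.
#' @param seed integer seed.
#' @return an [expr_dataset()].
#' @export
synth_perfect_feature <- function(n_per_class = 25, n_features = 20,
                                  n_classes = 2, seed = 1) {
  data <- synth_dataset(n_per_class = n_per_class, n_features = n_features,
                        n_informative = 1, effect_size = 0,
                        n_classes = n_classes, seed = seed)
  data$X[, 1] <- as.numeric(data$y) - 1
  data
}
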