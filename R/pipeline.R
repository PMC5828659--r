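#' End-to-end pipeline: split, filter, search, stack, report
#'
#' Orchestrates the full two-stage analysis on one labeled dataset:
#' stratified train/test split (unless a pre-split test set is supplied),
#' optional filter-based dimensionality reduction fit on the training split,
#' the stage-1 NSGA-II search on the training split, and the stage-2 stacked
#' ensemble scored on the test split.  Writes `front.json`, `report.json`
#' and `run.log` into `out_dir`.  One global seed fans out to per-stage
#' child seeds, so reruns with the same inputs and seed are byte-identical
#' in both JSON files.
#'
#' @param data an [expr_dataset()], or a file path readable by
#'   [read_dataset()].
#' @param test_data optional pre-split test set (same type as `data`); when
#'   given, `data` is used as the training set verbatim.
#' @param label_column,delimiter passed to [read_dataset()] for file input.
#' @param train_fraction stratified split fraction (default 0.6).
#' @param filter_method "none", "chi2" or "snr" (see [apply_filter()]).
#' @param top_k,n_bins,fit_on filter options (see [apply_filter()]).
#' @param pop_size,n_generations,p_cross,p_mut stage-1 settings; defaults
#'   52 / 50 / 0.9 / 0.1.
#' @param meta_features meta-learner column set (see [fit_stack()]).
#' @param seed global integer seed.
#' @param out_dir output directory (created if missing); `NULL` skips file
#'   output.
#' @param verbose print per-generation progress.
#' @return (invisibly) list with `split`, `front`, `stack`, `report`.
#' @export
run_pipeline <- function(data, test_data = NULL,
                         label_column = "label", delimiter = ",",
                         train_fraction = 0.6,
                         filter_method = c("none", "chi2", "snr"),
                         top_k = 100, n_bins = 10, fit_on = "train",
                         pop_size = 52, n_generations = 50,
                         p_cross = 0.9, p_mut = 0.1,
                         meta_features = "all",
                         seed = 1, out_dir = NULL, verbose = FALSE) {
  filter_method <- match.arg(filter_method)
  logf <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    logf <- file.path(out_dir, "run.log")
    cat("", file = logf)
  }
  say <- function(...) {
    msg <- paste0(...)
    if (verbose) message(msg)
    if (!is.null(logf)) cat(msg, "\n", file = logf, append = TRUE, sep = "")
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort("stage '", name, "' failed: ", conditionMessage(e))
    })
  }

  if (is.character(data)) {
    data <- stage("read", read_dataset(data, label_column, delimiter))
  }
  if (is.character(test_data)) {
    test_data <- stage("read", read_dataset(test_data, label_column, delimiter))
  }
  split <- stage("split", {
    if (is.null(test_data)) {
      stratified_split(data, train_fraction, seed = derive_seed(seed, 101))
    } else {
      if (!identical(data$feature_names, test_data$feature_names)) {
        abort("train and test feature names differ")
      }
      structure(list(train = data, test = test_data),
                class = "split_dataset")
    }
  })
  say("split: ", n_samples(split$train), " train / ", n_samples(split$test),
      " test samples, ", n_features(split$train), " features")

  filt <- stage("preprocess",
                apply_filter(split, filter_method, top_k = top_k,
                             n_bins = n_bins, fit_on = fit_on))
  split <- filt$split
  say("preprocess (", filter_method, "): ", n_features(split$train),
      " features retained")

  front <- stage("stage1",
                 run_nsga2(split$train, pop_size = pop_size,
                           n_generations = n_generations,
                           p_cross = p_cross, p_mut = p_mut,
                           seed = derive_seed(seed, 102), verbose = verbose))
  for (g in seq_len(nrow(front$history))) {
    h <- front$history[g, ]
    say(sprintf(
      "stage1 gen %3d | best P %.4f R %.4f | min |S| %d | HV %.4f | evals %d",
      h$generation, h$best_precision, h$best_recall, h$min_features,
      h$hv_rank1, h$n_evals))
  }

  stack <- stage("stage2",
                 fit_stack(front, split, seed = derive_seed(seed, 103),
                           meta_features = meta_features))
  bases <- stack$bases
  say("stage2: ", length(bases), " unique rank-1 solution(s), meta = ",
      format(stack$model$meta_spec),
      sprintf(", stacked test accuracy %.4f", stack$test_accuracy))

  report <- list(
    n_train = n_samples(split$train),
    n_test = n_samples(split$test),
    n_features = n_features(split$train),
    class_names = split$train$class_names,
    filter_method = filter_method,
    n_unique_solutions = length(bases),
    bases = lapply(seq_along(bases), function(j) {
      b <- bases[[j]]
      list(code = b$chromosome$spec$code,
           classifier = b$chromosome$spec$name,
           params = b$chromosome$spec$params,
           n_features = b$objectives$n_features,
           loocv_precision = b$objectives$precision,
           loocv_recall = b$objectives$recall,
           loocv_f_measure = b$objectives$f_measure,
           test_accuracy = stack$base_test_accuracies[j],
           features = split$train$feature_names[b$chromosome$mask])
    }),
    meta = list(code = stack$model$meta_spec$code,
                classifier = stack$model$meta_spec$name,
                params = stack$model$meta_spec$params,
                meta_features = meta_features),
    selected_features =
      split$train$feature_names[bases[[1]]$chromosome$mask],
    stacked_test_accuracy = stack$test_accuracy,
    seed = seed)

  if (!is.null(out_dir)) {
    write_front_json(front, file.path(out_dir, "front.json"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    say("wrote front.json, report.json")
  }
  invisible(list(split = split, front = front, stack = stack,
                 report = report))
}

#' Run the pipeline from a YAML or JSON config file
#'
#' Reads a flat config mapping whose keys are the arguments of
#' [run_pipeline()] (e.g. `data`, `train_fraction`, `pop_size`, `seed`,
#' `out_dir`); entries in `overrides` take precedence over the file.
#'
#' @param config_path path to a YAML (.yml/.yaml, needs the `yaml` package)
#'   or JSON config file.
#' @param ... overrides for individual config entries.
#' @return see [run_pipeline()].
#' @export
run_pipeline_config <- function(config_path, ...) {
  cfg <- if (grepl("\\.ya?ml$", config_path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("reading YAML configs requires the 'yaml' package")
    }
    yaml::read_yaml(config_path)
  } else {
    jsonlite::read_json(config_path, simplifyVector = TRUE)
  }
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  do.call(run_pipeline, cfg)
}
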