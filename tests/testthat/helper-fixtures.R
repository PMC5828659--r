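# Small in-code fixtures and independent oracles shared across test files.

# tiny labeled dataset with explicit values
toy_dataset <- function() {
  X <- matrix(c(1, 2, 3,
                2, 3, 4,
                10, 11, 12,
                11, 12, 13), nrow = 4, byrow = TRUE)
  expr_dataset(X, c("A", "A", "B", "B"), c("f1", "f2", "f3"))
}

# binary dataset whose first feature equals the 0/1 class code exactly
perfect_feature_dataset <- function(n_per_class = 5, n_noise = 3, seed = 7) {
  set.seed(seed)
  n <- 2 * n_per_class
  X <- cbind(rep(c(0, 1), each = n_per_class),
             matrix(rnorm(n * n_noise), n, n_noise))
  expr_dataset(X, rep(c("neg", "pos"), each = n_per_class),
               c("sig", paste0("ns", seq_len(n_noise))))
}

# brute-force non-dominated ranking: repeatedly peel the set of solutions
# not dominated by any remaining solution (O(n^2 * m) dominance counting)
oracle_ranks <- function(O) {
  dom <- function(a, b) {
    all(c(a[1] >= b[1], a[2] >= b[2], a[3] <= b[3])) &&
      (a[1] > b[1] || a[2] > b[2] || a[3] < b[3])
  }
  n <- nrow(O)
  rank <- rep(NA_integer_, n)
  r <- 1L
  while (anyNA(rank)) {
    remaining <- which(is.na(rank))
    front <- remaining[vapply(remaining, function(i) {
      !any(vapply(remaining, function(j) j != i && dom(O[j, ], O[i, ]),
                  logical(1)))
    }, logical(1))]
    rank[front] <- r
    r <- r + 1L
  }
  rank
}

# random objective matrix (precision, recall in [0,1]; n_features integer)
random_objectives <- function(n, max_features = 10) {
  cbind(round(runif(n), 2), round(runif(n), 2),
        sample.int(max_features, n, replace = TRUE))
}

# hand-built pareto_front wrapper for stacking tests
make_front <- function(members, n_feat, feature_names, class_names) {
  structure(list(members = members, history = NULL, n_features = n_feat,
                 feature_names = feature_names, class_names = class_names,
                 params = list()),
            class = "pareto_front")
}

front_member <- function(spec, mask, precision, recall, f = NULL, rank = 1L) {
  if (is.null(f)) {
    f <- if (precision + recall == 0) 0 else
      2 * precision * recall / (precision + recall)
  }
  list(chromosome = chromosome(spec, mask),
       objectives = structure(list(precision = precision, recall = recall,
                                   n_features = sum(mask), f_measure = f),
                              class = "eval_result"),
       rank = rank, crowding = Inf)
}

# surrogate objective for fast GA-mechanics tests: rewards mask overlap with
# the first `n_inf` features, no model fitting involved
surrogate_evaluate <- function(n_inf) {
  function(ch) {
    hits <- sum(ch$mask[seq_len(n_inf)])
    p <- hits / n_inf
    structure(list(precision = p, recall = p,
                   n_features = sum(ch$mask),
                   f_measure = p),
              class = "eval_result")
  }
}
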