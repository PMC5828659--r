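#' Chromosome: classifier spec plus binary feature mask
#'
#' One candidate solution of the stage-1 search, mirroring the three-part
#' string encoding: classifier type, its hyperparameter slots, and a binary
#' feature-inclusion mask.  An all-zero mask is repaired at creation by
#' setting one uniformly chosen bit (the wrapper objectives need at least
#' one feature).
#'
#' @param spec a [classifier_spec()].
#' @param mask logical vector over the dataset's features.
#' @return a `chromosome`.
#' @export
chromosome <- function(spec, mask) {
  stopifnot(inherits(spec, "classifier_spec"), is.logical(mask),
            length(mask) >= 1)
  if (!any(mask)) mask[sample.int(length(mask), 1)] <- TRUE
  structure(list(spec = spec, mask = mask), class = "chromosome")
}

#' @export
print.chromosome <- function(x, ...) {
  cat("<chromosome> ", format(x$spec), " |S| = ", sum(x$mask), "/",
      length(x$mask), "\n", sep = "")
  invisible(x)
}

chromosome_key <- function(c) {
  paste(c$spec$code, paste(c$spec$params, collapse = ","),
        paste(as.integer(c$mask), collapse = ""), sep = "|")
}

#' Random initial population
#'
#' Each chromosome draws its classifier code uniformly from 1..4, each
#' hyperparameter slot uniformly from the code's grid, and each mask bit
#' uniformly from \{0, 1\}; empty masks are repaired.  Consumes the current
#' RNG stream (seed with `set.seed` for reproducibility).
#'
#' @param pop_size number of chromosomes (>= 2).
#' @param n_features mask length.
#' @return list of [chromosome()]s.
#' @export
init_population <- function(pop_size, n_features) {
  if (pop_size < 2) abort("pop_size must be >= 2")
  lapply(seq_len(pop_size), function(i) {
    chromosome(random_classifier_spec(),
               stats::runif(n_features) < 0.5)
  })
}

# a dominates b: >= on precision & recall, <= on n_features, strict somewhere.
# obj rows are c(precision, recall, n_features).
dominates <- function(a, b) {
  ge <- a[1] >= b[1] && a[2] >= b[2] && a[3] <= b[3]
  ge && (a[1] > b[1] || a[2] > b[2] || a[3] < b[3])
}

#' Fast non-dominated sorting
#'
#' Deb's fast non-dominated sort over objective vectors
#' (precision max, recall max, feature count min).  Identical vectors are
#' mutually non-dominating and share a rank.
#'
#' @param objs numeric matrix with columns precision, recall, n_features
#'   (one row per solution), or a list of such length-3 vectors.
#' @return integer vector of ranks (1 = non-dominated).
#' @export
non_dominated_sort <- function(objs) {
  O <- objectives_matrix(objs)
  n <- nrow(O)
  if (n == 0) abort("empty objective list")
  dominated_by <- vector("list", n)  # who i dominates
  n_dom <- integer(n)                # how many dominate i
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (dominates(O[i, ], O[j, ])) {
        dominated_by[[i]] <- c(dominated_by[[i]], j)
      } else if (dominates(O[j, ], O[i, ])) {
        n_dom[i] <- n_dom[i] + 1L
      }
    }
  }
  rank <- integer(n)
  current <- which(n_dom == 0)
  r <- 1L
  while (length(current) > 0) {
    rank[current] <- r
    nxt <- integer(0)
    for (i in current) {
      for (j in dominated_by[[i]]) {
        n_dom[j] <- n_dom[j] - 1L
        if (n_dom[j] == 0L) nxt <- c(nxt, j)
      }
    }
    current <- nxt
    r <- r + 1L
  }
  rank
}

objectives_matrix <- function(objs) {
  if (is.matrix(objs)) return(objs)
  if (inherits(objs, "eval_result")) objs <- list(objs)
  do.call(rbind, lapply(objs, function(o) {
    if (inherits(o, "eval_result")) c(o$precision, o$recall, o$n_features)
    else as.numeric(o[1:3])
  }))
}

#' Crowding distance within one front
#'
#' Per objective, solutions are sorted and each interior solution accrues
#' the gap between its neighbors normalized by the objective's range over
#' the front; boundary solutions get `Inf`; an objective with zero range
#' contributes 0.
#'
#' @param objs objective matrix or list for the members of a single front.
#' @return numeric vector of crowding distances.
#' @export
crowding_distance <- function(objs) {
  O <- objectives_matrix(objs)
  n <- nrow(O)
  if (n <= 2) return(rep(Inf, n))
  d <- numeric(n)
  for (m in seq_len(ncol(O))) {
    ord <- order(O[, m])
    d[ord[1]] <- Inf
    d[ord[n]] <- Inf
    rng <- O[ord[n], m] - O[ord[1], m]
    if (rng > 0) {
      for (i in 2:(n - 1)) {
        d[ord[i]] <- d[ord[i]] + (O[ord[i + 1], m] - O[ord[i - 1], m]) / rng
      }
    }
  }
  d
}

#' Single-point crossover on the feature part
#'
#' With probability `p_cross` the two masks exchange tails after a uniformly
#' chosen cut point in `[1, n_features - 1]`; classifier type and parameters
#' are copied from the respective parent unchanged.  Children with empty
#' masks are repaired.  Consumes the current RNG stream.
#'
#' @param a,b parent [chromosome()]s with equal mask lengths.
#' @param p_cross crossover probability.
#' @return list of two child chromosomes.
#' @export
crossover <- function(a, b, p_cross = 0.9) {
  if (length(a$mask) != length(b$mask)) abort("mask lengths differ")
  n <- length(a$mask)
  m1 <- a$mask; m2 <- b$mask
  if (n >= 2 && stats::runif(1) < p_cross) {
    cut <- sample.int(n - 1, 1)
    tail_idx <- (cut + 1):n
    tmp <- m1[tail_idx]
    m1[tail_idx] <- m2[tail_idx]
    m2[tail_idx] <- tmp
  }
  list(chromosome(a$spec, m1), chromosome(b$spec, m2))
}

#' Mutation with three scopes
#'
#' Every call applies one mutation operator whose type is drawn uniformly
#' from \{1, 2, 3\}; `p_mut` is the per-position change probability inside
#' the operator, so `p_mut = 0` is the identity:
#' * type 1 — whole string: with probability `p_mut` the classifier code is
#'   resampled uniformly (all parameter slots are then redrawn from the new
#'   code's grid); otherwise each parameter slot is independently resampled
#'   with probability `p_mut`; each mask bit flips with probability `p_mut`;
#' * type 2 — parameters + features: each parameter slot is resampled with
#'   probability `p_mut`; mask bits flip at the same rate;
#' * type 3 — features only: mask bits flip with probability `p_mut`.
#'
#' Empty masks are repaired.  Consumes the current RNG stream.
#'
#' @param c a [chromosome()].
#' @param p_mut per-position mutation probability.
#' @return a (possibly unchanged) chromosome.
#' @export
mutate <- function(c, p_mut = 0.1) {
  if (p_mut <= 0) return(c)
  type <- sample.int(3, 1)
  spec <- c$spec
  if (type == 1 && stats::runif(1) < p_mut) {
    spec <- random_classifier_spec(sample(1:4, 1))
  } else if (type <= 2 && length(spec$params) > 0) {
    grid <- classifier_grids[[as.character(spec$code)]]
    params <- spec$params
    for (i in seq_along(params)) {
      if (stats::runif(1) < p_mut) {
        v <- grid$slots[[i]]
        params[i] <- v[sample.int(length(v), 1)]
      }
    }
    spec <- classifier_spec(spec$code, params)
  }
  mask <- c$mask
  if (type <= 3) {
    flip <- stats::runif(length(mask)) < p_mut
    mask <- xor(mask, flip)
  }
  chromosome(spec, mask)
}

# binary tournament on (rank asc, crowding desc); ties broken uniformly
tournament_pick <- function(rank, crowd) {
  cand <- sample.int(length(rank), 2, replace = TRUE)
  i <- cand[1]; j <- cand[2]
  if (rank[i] < rank[j]) return(i)
  if (rank[j] < rank[i]) return(j)
  if (crowd[i] > crowd[j]) return(i)
  if (crowd[j] > crowd[i]) return(j)
  cand[sample.int(2, 1)]
}

#' Hypervolume of a front
#'
#' Volume dominated by the given objective vectors with respect to a
#' reference point `(precision, recall, n_features) = ref` (precision and
#' recall maximized, feature count minimized).  Computed exactly by slicing
#' the feature-count axis and accumulating 2-D staircase areas.
#'
#' @param objs objective matrix or list.
#' @param ref reference point, default `c(0, 0, max n_features + 1)`.
#' @return non-negative scalar.
#' @export
hypervolume <- function(objs, ref = NULL) {
  O <- objectives_matrix(objs)
  if (is.null(ref)) ref <- c(0, 0, max(O[, 3]) + 1)
  # transform to maximization with the reference at the origin
  P <- cbind(O[, 1] - ref[1], O[, 2] - ref[2], ref[3] - O[, 3])
  P <- P[P[, 1] > 0 & P[, 2] > 0 & P[, 3] > 0, , drop = FALSE]
  if (nrow(P) == 0) return(0)
  area2d <- function(pts) {
    ord <- order(-pts[, 1], -pts[, 2])
    pts <- pts[ord, , drop = FALSE]
    maxr <- 0
    a <- 0
    for (i in seq_len(nrow(pts))) {
      if (pts[i, 2] > maxr) {
        a <- a + pts[i, 1] * (pts[i, 2] - maxr)
        maxr <- pts[i, 2]
      }
    }
    a
  }
  levels <- sort(unique(P[, 3]), decreasing = TRUE)
  hv <- 0
  lower <- c(levels[-1], 0)
  for (k in seq_along(levels)) {
    active <- P[P[, 3] >= levels[k], 1:2, drop = FALSE]
    hv <- hv + (levels[k] - lower[k]) * area2d(active)
  }
  hv
}

#' Stage 1: elitist NSGA-II over classifier, parameters and features
#'
#' Runs the generational loop: evaluate (LOOCV macro precision / recall /
#' feature count, cached per unique chromosome), binary tournament on
#' (rank, crowding), feature-part crossover, three-scope mutation, then
#' elitist truncation of the merged parent+offspring population by
#' (rank, crowding).  Deterministic given `seed`.
#'
#' @param data an [expr_dataset()] (typically the training split).
#' @param pop_size even population size (default 52).
#' @param n_generations number of generations (default 50).
#' @param p_cross feature-part crossover probability (default 0.9).
#' @param p_mut per-chromosome mutation probability (default 0.1).
#' @param seed integer seed.
#' @param evaluate optional replacement objective function
#'   `function(chromosome) -> eval_result`; default is
#'   [loocv_evaluate()] on `data`.  Intended for surrogate objectives in
#'   experiments.
#' @param initial_population optional warm-start list of `pop_size`
#'   [chromosome()]s replacing the random initialization.
#' @param verbose print a per-generation progress line.
#' @return a `pareto_front`: list with `members` (each holding `chromosome`,
#'   `objectives`, `rank`, `crowding`), a per-generation `history`
#'   data.frame (best objectives, rank-1 hypervolume, evaluation count),
#'   `n_features`, `feature_names` and the run parameters.
#' @export
run_nsga2 <- function(data, pop_size = 52, n_generations = 50,
                      p_cross = 0.9, p_mut = 0.1, seed = 1,
                      evaluate = NULL, initial_population = NULL,
                      verbose = FALSE) {
  if (pop_size %% 2 != 0) abort("pop_size must be even")
  nf <- n_features(data)
  eval_seed <- derive_seed(seed, 2)
  cache <- new.env(parent = emptyenv())
  n_evals <- 0L
  if (is.null(evaluate)) {
    evaluate <- function(ch) loocv_evaluate(ch$spec, data, ch$mask,
                                            seed = eval_seed)
  }
  eval_cached <- function(ch) {
    key <- chromosome_key(ch)
    if (!is.null(cache[[key]])) return(cache[[key]])
    res <- preserve_rng(evaluate(ch))
    n_evals <<- n_evals + 1L
    cache[[key]] <- res
    res
  }
  set.seed(derive_seed(seed, 1))
  pop <- if (is.null(initial_population)) {
    init_population(pop_size, nf)
  } else {
    if (length(initial_population) != pop_size) {
      abort("initial_population must hold pop_size chromosomes")
    }
    initial_population
  }
  objs <- lapply(pop, eval_cached)
  rank <- non_dominated_sort(objs)
  crowd <- crowding_by_front(objs, rank)
  history <- list()
  log_gen <- function(gen) {
    O <- objectives_matrix(objs)
    r1 <- which(rank == 1)
    history[[length(history) + 1]] <<- data.frame(
      generation = gen,
      best_precision = max(O[, 1]),
      best_recall = max(O[, 2]),
      min_features = min(O[r1, 3]),
      hv_rank1 = hypervolume(O[r1, , drop = FALSE], ref = c(0, 0, nf + 1)),
      n_rank1 = length(r1),
      n_evals = n_evals)
    if (verbose) {
      h <- history[[length(history)]]
      message(sprintf(
        "gen %3d | best P %.3f R %.3f | min |S| %d | HV %.3f | evals %d",
        h$generation, h$best_precision, h$best_recall, h$min_features,
        h$hv_rank1, h$n_evals))
    }
  }
  log_gen(0L)
  for (gen in seq_len(n_generations)) {
    offspring <- vector("list", pop_size)
    for (k in seq_len(pop_size / 2)) {
      pa <- pop[[tournament_pick(rank, crowd)]]
      pb <- pop[[tournament_pick(rank, crowd)]]
      kids <- crossover(pa, pb, p_cross)
      offspring[[2 * k - 1]] <- mutate(kids[[1]], p_mut)
      offspring[[2 * k]] <- mutate(kids[[2]], p_mut)
    }
    merged <- c(pop, offspring)
    merged_objs <- lapply(merged, eval_cached)
    m_rank <- non_dominated_sort(merged_objs)
    m_crowd <- crowding_by_front(merged_objs, m_rank)
    keep <- truncate_by_rank_crowding(m_rank, m_crowd, pop_size)
    pop <- merged[keep]
    objs <- merged_objs[keep]
    rank <- non_dominated_sort(objs)
    crowd <- crowding_by_front(objs, rank)
    log_gen(gen)
  }
  members <- lapply(seq_along(pop), function(i) {
    list(chromosome = pop[[i]], objectives = objs[[i]], rank = rank[i],
         crowding = crowd[i])
  })
  structure(
    list(members = members, history = do.call(rbind, history),
         n_features = nf, feature_names = data$feature_names,
         class_names = data$class_names,
         params = list(pop_size = pop_size, n_generations = n_generations,
                       p_cross = p_cross, p_mut = p_mut, seed = seed)),
    class = "pareto_front")
}

# crowding computed within each front of the whole population
crowding_by_front <- function(objs, rank) {
  O <- objectives_matrix(objs)
  crowd <- numeric(nrow(O))
  for (r in unique(rank)) {
    idx <- which(rank == r)
    crowd[idx] <- crowding_distance(O[idx, , drop = FALSE])
  }
  crowd
}

# elitist environmental selection: whole fronts in rank order, the
# overflowing front by descending crowding (ties by original index)
truncate_by_rank_crowding <- function(rank, crowd, pop_size) {
  keep <- integer(0)
  for (r in sort(unique(rank))) {
    idx <- which(rank == r)
    if (length(keep) + length(idx) <= pop_size) {
      keep <- c(keep, idx)
    } else {
      room <- pop_size - length(keep)
      if (room > 0) keep <- c(keep, idx[order(-crowd[idx], idx)][seq_len(room)])
      break
    }
  }
  sort(keep)
}

#' @export
print.pareto_front <- function(x, ...) {
  r1 <- sum(vapply(x$members, function(m) m$rank == 1L, logical(1)))
  cat("<pareto_front> ", length(x$members), " members, ", r1,
      " in rank 1; ", x$params$n_generations, " generations\n", sep = "")
  invisible(x)
}

#' Unique rank-1 solutions, best first
#'
#' Deduplicates the rank-1 members of a front on the triple (classifier
#' code, parameters, mask) and orders them by descending LOOCV F-measure,
#' then by fewer features, then by first occurrence.  These are the base
#' solutions fed to the stage-2 stacked ensemble.
#'
#' @param front a `pareto_front` from [run_nsga2()].
#' @return list of members (`chromosome`, `objectives`).
#' @export
unique_rank1 <- function(front) {
  stopifnot(inherits(front, "pareto_front"))
  r1 <- Filter(function(m) m$rank == 1L, front$members)
  if (length(r1) == 0) abort("front has no rank-1 members")
  keys <- vapply(r1, function(m) chromosome_key(m$chromosome), character(1))
  r1 <- r1[!duplicated(keys)]
  f <- vapply(r1, function(m) m$objectives$f_measure, numeric(1))
  s <- vapply(r1, function(m) m$objectives$n_features, numeric(1))
  r1[order(-f, s, seq_along(r1))]
}

#' Export a Pareto front as JSON
#'
#' Serializes chromosomes (code, parameter values, 0/1 mask), objective
#' values, ranks and crowding distances plus the per-generation history.
#' Infinite crowding distances appear as the JSON string `"Inf"`.
#'
#' @param front a `pareto_front`.
#' @param path output path.
#' @export
write_front_json <- function(front, path) {
  members <- lapply(front$members, function(m) {
    list(code = m$chromosome$spec$code,
         classifier = m$chromosome$spec$name,
         params = m$chromosome$spec$params,
         mask = as.integer(m$chromosome$mask),
         precision = m$objectives$precision,
         recall = m$objectives$recall,
         n_features = m$objectives$n_features,
         f_measure = m$objectives$f_measure,
         rank = m$rank,
         crowding = m$crowding)
  })
  out <- list(params = front$params, n_features = front$n_features,
              feature_names = front$feature_names,
              class_names = front$class_names,
              members = members,
              history = front$history)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a Pareto front written by [write_front_json()]
#' @param path JSON path.
#' @return a `pareto_front`.
#' @export
read_front_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  members <- lapply(raw$members, function(m) {
    list(chromosome = chromosome(classifier_spec(m$code, unlist(m$params)),
                                 as.logical(unlist(m$mask))),
         objectives = structure(list(precision = m$precision,
                                     recall = m$recall,
                                     n_features = m$n_features,
                                     f_measure = m$f_measure),
                                class = "eval_result"),
         rank = as.integer(m$rank),
         crowding = if (identical(m$crowding, "Inf")) Inf
                    else as.numeric(m$crowding))
  })
  structure(
    list(members = members, history = raw$history,
         n_features = raw$n_features, feature_names = raw$feature_names,
         class_names = raw$class_names, params = raw$params),
    class = "pareto_front")
}
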