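test_that("chromosomes repair empty masks and validate their spec", {
  set.seed(1)
  ch <- chromosome(classifier_spec(3, 1), rep(FALSE, 10))
  expect_equal(sum(ch$mask), 1)
  expect_error(chromosome("not a spec", rep(TRUE, 3)))
})

test_that("population initialization is seeded, valid and near-uniform", {
  set.seed(7)
  pop <- init_population(52, 15)
  expect_length(pop, 52)
  expect_true(all(vapply(pop, function(c) any(c$mask), logical(1))))

  set.seed(7)
  pop2 <- init_population(52, 15)
  expect_identical(pop, pop2)

  # classifier code frequencies within 4 sd of n/4 over 10,000 draws
  set.seed(123)
  big <- init_population(10000, 5)
  codes <- vapply(big, function(c) c$spec$code, integer(1))
  sd4 <- 4 * sqrt(10000 * 0.25 * 0.75)
  expect_true(all(abs(table(factor(codes, levels = 1:4)) - 2500) < sd4))
})

test_that("non-dominated sorting handles the forced small cases", {
  expect_equal(non_dominated_sort(matrix(c(0.5, 0.5, 3), 1)), 1L)
  # strict domination in every coordinate
  expect_equal(non_dominated_sort(rbind(c(1, 1, 1), c(0.5, 0.5, 5))),
               c(1L, 2L))
  # identical vectors are mutually non-dominating and share a rank
  expect_equal(non_dominated_sort(rbind(c(0.7, 0.7, 2), c(0.7, 0.7, 2))),
               c(1L, 1L))
  # trade-off chain: nobody dominates anybody
  expect_equal(non_dominated_sort(rbind(c(0.9, 0.2, 1), c(0.2, 0.9, 1),
                                        c(0.5, 0.5, 1))), rep(1L, 3))
})

test_that("non-dominated sorting matches the brute-force oracle", {
  set.seed(31)
  for (trial in 1:60) {
    O <- random_objectives(sample(2:25, 1))
    expect_identical(non_dominated_sort(O), oracle_ranks(O))
  }
})

test_that("crowding distance follows the normalized-gap definition", {
  # fronts of size <= 2 are all boundary
  expect_equal(crowding_distance(rbind(c(1, 1, 1))), Inf)
  expect_equal(crowding_distance(rbind(c(1, 0, 1), c(0, 1, 2))), c(Inf, Inf))

  # 3 equally spaced points varying on one objective: middle contribution 1.0
  O <- rbind(c(0.2, 0.5, 4), c(0.4, 0.5, 4), c(0.6, 0.5, 4))
  d <- crowding_distance(O)
  expect_equal(d, c(Inf, 1.0, Inf))

  # two varying objectives, equal spacing: middle point accrues 1 + 1
  O2 <- rbind(c(0.2, 0.1, 4), c(0.4, 0.3, 4), c(0.6, 0.5, 4))
  expect_equal(crowding_distance(O2)[2], 2.0)

  # identical vectors: finite members get 0
  O3 <- rbind(c(0.5, 0.5, 2), c(0.5, 0.5, 2), c(0.5, 0.5, 2), c(0.5, 0.5, 2))
  d3 <- crowding_distance(O3)
  expect_true(all(d3[is.finite(d3)] == 0))
})

test_that("crossover exchanges mask tails and conserves set bits", {
  spec_a <- classifier_spec(1, c(10, 5))
  spec_b <- classifier_spec(3, 8)
  a <- chromosome(spec_a, c(TRUE, TRUE, TRUE, TRUE))
  b <- chromosome(spec_b, c(TRUE, FALSE, FALSE, FALSE))

  # p_cross = 0: children equal parents
  kids0 <- crossover(a, b, p_cross = 0)
  expect_identical(kids0[[1]], a)
  expect_identical(kids0[[2]], b)

  # forced crossover: spec parts copied unchanged, masks recombined
  set.seed(2)
  kids <- crossover(a, b, p_cross = 1)
  expect_identical(kids[[1]]$spec, spec_a)
  expect_identical(kids[[2]]$spec, spec_b)

  # conservation of total set bits over children; parent a carries both
  # boundary bits so each child inherits at least one and repair never fires
  set.seed(14)
  conserved <- TRUE
  for (i in 1:200) {
    n <- sample(4:20, 1)
    ma <- runif(n) < 0.5; ma[c(1, n)] <- TRUE
    mb <- runif(n) < 0.5
    ka <- chromosome(spec_a, ma); kb <- chromosome(spec_b, mb)
    kk <- crossover(ka, kb, p_cross = 1)
    conserved <- conserved &&
      sum(kk[[1]]$mask) + sum(kk[[2]]$mask) == sum(ka$mask) + sum(kb$mask)
  }
  expect_true(conserved)

  expect_error(crossover(a, chromosome(spec_b, rep(TRUE, 3)), 1), "lengths")
})

test_that("mutation respects operator scopes and p_mut = 0 is the identity", {
  set.seed(3)
  ch <- chromosome(classifier_spec(1, c(20, 6)), c(TRUE, FALSE, TRUE, FALSE))
  expect_identical(mutate(ch, p_mut = 0), ch)

  # operators never produce an out-of-grid spec or an empty mask, and after a
  # code change the params always satisfy the NEW code's grid (validated
  # inside classifier_spec); audit over many applications
  set.seed(77)
  ok <- TRUE
  for (i in 1:2000) {
    m <- mutate(ch, p_mut = 0.5)
    ok <- ok && any(m$mask) &&
      inherits(classifier_spec(m$spec$code, m$spec$params), "classifier_spec")
  }
  expect_true(ok)
})

test_that("hypervolume matches closed-form values", {
  # single point (1,1,1) against ref (0,0,21): 1 * 1 * 20
  expect_equal(hypervolume(rbind(c(1, 1, 1)), ref = c(0, 0, 21)), 20)
  # dominated point adds nothing
  expect_equal(hypervolume(rbind(c(1, 1, 1), c(0.5, 0.5, 3)),
                           ref = c(0, 0, 21)), 20)
  # hand-computed union of two boxes: points (1,1,2) and (0.5,0.5,1),
  # ref (0,0,4) -> slices (3->2): 0.25, (2->0): 2 * 1 -> total 2.25
  expect_equal(hypervolume(rbind(c(1, 1, 2), c(0.5, 0.5, 1)),
                           ref = c(0, 0, 4)), 2.25)
  # point at or beyond the reference contributes nothing
  expect_equal(hypervolume(rbind(c(0, 0, 5)), ref = c(0, 0, 4)), 0)
})

test_that("the generational loop is elitist, valid and deterministic", {
  # fast surrogate objective (mask overlap), no model fitting
  d <- synth_dataset(n_per_class = 5, n_features = 12, n_informative = 3,
                     seed = 5)
  fr1 <- run_nsga2(d, pop_size = 12, n_generations = 8, seed = 11,
                   evaluate = surrogate_evaluate(3))
  fr2 <- run_nsga2(d, pop_size = 12, n_generations = 8, seed = 11,
                   evaluate = surrogate_evaluate(3))
  expect_identical(fr1$members, fr2$members)
  expect_identical(fr1$history, fr2$history)

  # all chromosomes satisfy grid and non-empty-mask invariants
  for (m in fr1$members) {
    expect_true(any(m$chromosome$mask))
    expect_s3_class(classifier_spec(m$chromosome$spec$code,
                                    m$chromosome$spec$params),
                    "classifier_spec")
  }
  # elitist pressure: rank-1 hypervolume never decreases
  expect_true(all(diff(fr1$history$hv_rank1) >= -1e-12))
  # surrogate optimum (1, 1, |S|=3) should be reached on this easy landscape
  hit <- any(vapply(fr1$members, function(m) {
    m$objectives$precision == 1 && m$objectives$n_features == 3
  }, logical(1)))
  expect_true(hit)

  expect_error(run_nsga2(d, pop_size = 7, n_generations = 1, seed = 1,
                         evaluate = surrogate_evaluate(3)), "even")
})

test_that("survivor truncation keeps every rank-1 solution when it fits", {
  set.seed(8)
  for (trial in 1:30) {
    O <- random_objectives(20)
    rank <- non_dominated_sort(O)
    crowd <- moostack:::crowding_by_front(lapply(seq_len(nrow(O)),
                                                 function(i) O[i, ]), rank)
    keep <- moostack:::truncate_by_rank_crowding(rank, crowd, 10)
    expect_length(keep, 10)
    r1 <- which(rank == 1)
    if (length(r1) <= 10) expect_true(all(r1 %in% keep))
  }
})

test_that("a homogeneous population without mutation is a fixed point", {
  d <- synth_dataset(n_per_class = 4, n_features = 6, n_informative = 2,
                     seed = 9)
  ch <- chromosome(classifier_spec(3, 3),
                   c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE))
  fr <- run_nsga2(d, pop_size = 8, n_generations = 4, seed = 13,
                  p_cross = 0.9, p_mut = 0,
                  evaluate = surrogate_evaluate(2),
                  initial_population = rep(list(ch), 8))
  for (m in fr$members) {
    expect_identical(m$chromosome$mask,
                     c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE))
    expect_equal(m$chromosome$spec$code, 3)
  }
})

test_that("unique_rank1 deduplicates and orders by F, size, occurrence", {
  sp1 <- classifier_spec(3, 1)
  sp2 <- classifier_spec(4)
  m1 <- front_member(sp1, c(TRUE, FALSE, TRUE), 0.9, 0.9)
  m1_dup <- front_member(sp1, c(TRUE, FALSE, TRUE), 0.9, 0.9)
  m2 <- front_member(sp2, c(TRUE, TRUE, TRUE), 0.95, 0.95)
  m3 <- front_member(sp2, c(TRUE, FALSE, FALSE), 0.9, 0.9)
  m4 <- front_member(sp1, c(FALSE, TRUE, FALSE), 0.5, 0.5, rank = 2L)
  front <- make_front(list(m1, m1_dup, m2, m3, m4), 3,
                      c("a", "b", "c"), c("x", "y"))
  u <- unique_rank1(front)
  expect_length(u, 3)  # duplicate collapsed, rank-2 excluded
  # ordered by descending F, then fewer features (m3 before m1), then order
  expect_identical(u[[1]]$chromosome$spec$code, sp2$code)
  expect_equal(u[[1]]$objectives$n_features, 3)
  expect_equal(u[[2]]$objectives$n_features, 1)
  expect_equal(u[[3]]$objectives$n_features, 2)
})

test_that("front JSON round-trips through write/read", {
  d <- synth_dataset(n_per_class = 5, n_features = 10, n_informative = 2,
                     seed = 3)
  fr <- run_nsga2(d, pop_size = 8, n_generations = 3, seed = 21,
                  evaluate = surrogate_evaluate(2))
  path <- withr::local_tempfile(fileext = ".json")
  write_front_json(fr, path)
  fr2 <- read_front_json(path)
  expect_equal(length(fr2$members), length(fr$members))
  u1 <- unique_rank1(fr)
  u2 <- unique_rank1(fr2)
  expect_equal(length(u1), length(u2))
  for (i in seq_along(u1)) {
    expect_identical(u2[[i]]$chromosome$mask, u1[[i]]$chromosome$mask)
    expect_equal(u2[[i]]$objectives$f_measure, u1[[i]]$objectives$f_measure)
  }
})
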