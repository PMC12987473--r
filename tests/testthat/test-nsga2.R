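test_that("Pareto dominance is the strict componentwise relation", {
  expect_true(dominates(c(1, 2, 3), c(2, 3, 4)))
  expect_false(dominates(c(1, 2), c(2, 1)))
  expect_false(dominates(c(2, 1), c(1, 2)))
  expect_false(dominates(c(1, 2), c(1, 2)))
  expect_true(dominates(c(1, 2), c(1, 3)))
  expect_error(dominates(c(1, 2), c(1, 2, 3)), "shape")
})

test_that("fast non-dominated sort reproduces the brute-force fronts", {
  one <- fast_nondominated_sort(matrix(c(1, 2, 3), 1))
  expect_identical(one$fronts, list(1L))
  chain <- fast_nondominated_sort(rbind(c(3, 3), c(1, 1), c(2, 2)))
  expect_identical(chain$fronts, list(2L, 3L, 1L))
  expect_identical(chain$rank, c(3L, 1L, 2L))

  set.seed(19)
  for (rep in 1:30) {
    n <- sample(5:30, 1)
    obj <- matrix(sample(1:8, n * 3, replace = TRUE), n, 3)
    got <- fast_nondominated_sort(obj)
    ora <- naive_fronts(obj)
    expect_identical(lapply(got$fronts, sort), lapply(ora, sort))
    expect_identical(sort(unlist(got$fronts)), 1:n)  # partition
  }
})

test_that("crowding distance matches its definition", {
  expect_identical(crowding_distance(matrix(1:4, 2)), c(Inf, Inf))
  expect_identical(crowding_distance(matrix(1, 1, 3)), Inf)
  d3 <- crowding_distance(cbind(c(0, 5, 10)))
  expect_identical(is.infinite(d3), c(TRUE, FALSE, TRUE))
  expect_equal(d3[2], 1)
  set.seed(23)
  for (rep in 1:20) {
    obj <- matrix(runif(15), 5, 3)
    expect_equal(crowding_distance(obj), naive_crowding(obj))
  }
  # a zero-range objective contributes nothing
  obj <- cbind(c(1, 2, 3, 4), rep(7, 4))
  expect_equal(crowding_distance(obj), naive_crowding(obj))
})

test_that("offspring generation honors its probability switches", {
  pop <- melonopt:::with_seed(1, melonopt:::random_genomes(20))
  rank <- rep(1L, 20)
  crowd <- rep(Inf, 20)
  p0 <- ga_params(population_size = 50, crossover_prob = 0,
                  mutation_prob = 0, seed = 1)
  off <- melonopt:::with_seed(2, make_offspring(pop, rank, crowd, p0))
  key <- function(g) paste(g[, 1], g[, 2])
  expect_true(all(key(off) %in% key(pop)))  # pure copies of parents

  p1 <- ga_params(population_size = 500, mutation_prob = 1, seed = 1)
  off1 <- melonopt:::with_seed(3, make_offspring(pop, rank, crowd, p1))
  expect_true(all(off1[, 1] %in% 0:10) && all(off1[, 2] %in% 1:4))
  # every gene resampled uniformly: all feasible values appear
  expect_setequal(unique(off1[, 1]), 0:10)
  expect_setequal(unique(off1[, 2]), 1:4)

  offa <- melonopt:::with_seed(4, make_offspring(pop, rank, crowd,
                                                 ga_params(seed = 9)))
  offb <- melonopt:::with_seed(4, make_offspring(pop, rank, crowd,
                                                 ga_params(seed = 9)))
  expect_identical(offa, offb)
})

test_that("evolution recovers the exhaustive Pareto set on trained and
           arbitrary surrogates", {
  ds <- generate_trial(trial_scenario(spacings = seq(30, 80, 5),
                                      design = "factorial",
                                      noise_frac = 0.03), seed = 2)
  fit <- train_surrogate(ds, surrogate_config(restarts = 1,
                                              split_mode = "none",
                                              max_epochs = 80, seed = 3))
  fr <- evolve(fit$model, ga_params(seed = 4))
  bf <- brute_force_pareto(fit$model)
  expect_identical(fr$solutions, bf$solutions)

  for (s in c(31, 57, 91)) {
    m <- random_weight_surrogate(s)
    expect_identical(evolve(m, ga_params(seed = s + 1))$solutions,
                     brute_force_pareto(m)$solutions)
  }
})

test_that("a constant surrogate leaves all 44 designs mutually
           non-dominated", {
  ds <- generate_trial(trial_scenario(spacings = seq(30, 80, 5),
                                      design = "factorial", noise_frac = 0),
                       seed = 1)
  ds$responses$duration <- 100
  ds$responses$yield <- 40
  ds$responses$ci <- 0.5
  fit <- train_surrogate(ds, surrogate_config(restarts = 1,
                                              split_mode = "none",
                                              max_epochs = 3, seed = 1))
  bf <- brute_force_pareto(fit$model)
  expect_identical(nrow(bf$solutions), 44L)
  fr <- evolve(fit$model, ga_params(generations = 20, seed = 2))
  expect_identical(nrow(fr$solutions), 44L)
})

test_that("evolution is deterministic under a fixed seed", {
  m <- random_weight_surrogate(77)
  f1 <- evolve(m, ga_params(seed = 123))
  f2 <- evolve(m, ga_params(seed = 123))
  expect_identical(f1, f2)
})

test_that("front solutions are pairwise non-dominated and deduplicated", {
  m <- random_weight_surrogate(5)
  fr <- evolve(m, ga_params(seed = 6))
  sol <- fr$solutions
  key <- paste(sol$spacing, sol$pruning_code)
  expect_identical(anyDuplicated(key), 0L)
  obj <- cbind(sol$duration, -sol$yield, -sol$ci)
  for (i in seq_len(nrow(obj))) {
    for (j in seq_len(nrow(obj))) {
      if (i != j) expect_false(dominates(obj[i, ], obj[j, ]))
    }
  }
})
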