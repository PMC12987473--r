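#' NSGA-II parameters
#'
#' Defaults follow the optimizer contract: population 100, 100
#' generations, crossover probability 0.8, mutation probability 0.1.
#'
#' @param population_size population size (mu; offspring count lambda = mu).
#' @param generations number of generations.
#' @param crossover_prob per-pair uniform crossover probability.
#' @param mutation_prob per-gene random-reset mutation probability.
#' @param seed integer seed; the whole run is deterministic given it.
#' @return list of class `ga_params`.
#' @export
ga_params <- function(population_size = 100, generations = 100,
                      crossover_prob = 0.8, mutation_prob = 0.1, seed = 1L) {
  stopifnot(population_size >= 2, generations >= 1,
            crossover_prob >= 0, crossover_prob <= 1,
            mutation_prob >= 0, mutation_prob <= 1)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob, seed = as.integer(seed)),
            class = "ga_params")
}

#' Pareto dominance (minimization sense)
#'
#' `a` dominates `b` iff `a <= b` in every objective and `a < b` in at
#' least one.
#'
#' @param a,b numeric objective vectors of equal length.
#' @return logical scalar.
#' @export
dominates <- function(a, b) {
  if (length(a) != length(b)) {
    stop("shape error: objective vectors of length ", length(a), " vs ",
         length(b))
  }
  all(a <= b) && any(a < b)
}

# n x n logical matrix D[i, j] = TRUE iff row i dominates row j, vectorized
# over the population.
domination_matrix <- function(obj) {
  n <- nrow(obj)
  le <- matrix(TRUE, n, n)
  lt <- matrix(FALSE, n, n)
  for (k in seq_len(ncol(obj))) {
    ok <- outer(obj[, k], obj[, k], "<=")
    le <- le & ok
    lt <- lt | outer(obj[, k], obj[, k], "<")
  }
  le & lt
}

#' Fast non-dominated sorting
#'
#' Deb's fast non-dominated sort: front 1 is the non-dominated set; each
#' subsequent front is non-dominated once earlier fronts are removed.
#'
#' @param obj numeric matrix, one row of (minimized) objectives per
#'   individual.
#' @return list with `fronts` (list of index vectors, best first) and
#'   `rank` (integer vector; 1 = first front).
#' @export
fast_nondominated_sort <- function(obj) {
  obj <- as.matrix(obj)
  n <- nrow(obj)
  D <- domination_matrix(obj)
  n_dominators <- colSums(D)       # how many individuals dominate j
  rank <- integer(n)
  fronts <- list()
  current <- which(n_dominators == 0)
  f <- 0L
  remaining <- n
  while (length(current)) {
    f <- f + 1L
    rank[current] <- f
    fronts[[f]] <- current
    remaining <- remaining - length(current)
    if (!remaining) break
    # remove this front's domination counts
    drop <- if (length(current) == 1) D[current, ] else colSums(D[current, , drop = FALSE])
    n_dominators <- n_dominators - drop
    n_dominators[current] <- NA
    current <- which(!is.na(n_dominators) & n_dominators == 0)
  }
  list(fronts = fronts, rank = rank)
}

#' Crowding distance within a front
#'
#' Standard crowding-distance assignment: for each objective, the extreme
#' solutions get infinite distance and interior solutions accumulate the
#' normalized gap between their neighbours; an objective with zero range
#' contributes nothing.
#'
#' @param obj numeric matrix of the front's objective rows.
#' @return numeric vector of crowding distances (may be `Inf`).
#' @export
crowding_distance <- function(obj) {
  obj <- as.matrix(obj)
  n <- nrow(obj)
  if (n == 0) stop("empty front")
  if (n <= 2) return(rep(Inf, n))
  d <- numeric(n)
  for (k in seq_len(ncol(obj))) {
    o <- order(obj[, k])
    rng <- obj[o[n], k] - obj[o[1], k]
    d[o[c(1, n)]] <- Inf
    if (rng > 0) {
      mid <- o[2:(n - 1)]
      d[mid] <- d[mid] + (obj[o[3:n], k] - obj[o[1:(n - 2)], k]) / rng
    }
  }
  d
}

# Crowded-comparison key: lower rank wins; within rank, larger crowding.
crowded_lt <- function(rank_a, crowd_a, rank_b, crowd_b) {
  rank_a < rank_b | (rank_a == rank_b & crowd_a > crowd_b)
}

# Random feasible genomes (spacing index 0..10, pruning code 1..4).
random_genomes <- function(n) {
  cbind(spacing_index = sample.int(11, n, replace = TRUE) - 1L,
        pruning_code = sample.int(4, n, replace = TRUE))
}

# Initial population: with only 44 feasible genomes, a population of >= 44
# is seeded with one copy of every feasible design (elitism then guarantees
# no non-dominated design is ever lost) and topped up at random; smaller
# populations are fully random.
init_genomes <- function(n) {
  full <- as.matrix(expand.grid(spacing_index = 0:10, pruning_code = 1:4,
                                KEEP.OUT.ATTRS = FALSE))
  storage.mode(full) <- "integer"
  if (n >= nrow(full)) {
    extra <- n - nrow(full)
    if (extra > 0) full <- rbind(full, random_genomes(extra))
    full
  } else {
    random_genomes(n)
  }
}

decode_genomes <- function(g) {
  data.frame(spacing = SPACING_MIN + SPACING_STEP * g[, 1],
             pruning_code = as.integer(g[, 2]))
}

#' Offspring generation: tournament selection, uniform crossover,
#' random-reset mutation
#'
#' Binary tournament on (rank ascending, crowding descending); uniform
#' per-gene crossover applied to each selected pair with probability
#' `crossover_prob`; per-gene uniform random-reset mutation with
#' probability `mutation_prob`. Offspring are feasible by construction.
#'
#' @param pop integer genome matrix (rows = individuals).
#' @param rank,crowd rank and crowding vectors for `pop`.
#' @param params a [ga_params()].
#' @return genome matrix of `params$population_size` offspring. Uses the
#'   current RNG stream; seed management belongs to the caller.
#' @export
make_offspring <- function(pop, rank, crowd, params) {
  n <- nrow(pop)
  n_off <- params$population_size
  pick <- function(k) {
    i <- sample.int(n, k, replace = TRUE)
    j <- sample.int(n, k, replace = TRUE)
    ifelse(crowded_lt(rank[i], crowd[i], rank[j], crowd[j]), i, j)
  }
  p1 <- pop[pick(n_off), , drop = FALSE]
  p2 <- pop[pick(n_off), , drop = FALSE]
  cross_pair <- stats::runif(n_off) < params$crossover_prob
  swap <- matrix(stats::runif(n_off * 2) < 0.5, n_off, 2) & cross_pair
  child <- p1
  child[swap] <- p2[swap]
  mut <- matrix(stats::runif(n_off * 2) < params$mutation_prob, n_off, 2)
  if (any(mut[, 1])) {
    child[mut[, 1], 1] <- sample.int(11, sum(mut[, 1]), replace = TRUE) - 1L
  }
  if (any(mut[, 2])) {
    child[mut[, 2], 2] <- sample.int(4, sum(mut[, 2]), replace = TRUE)
  }
  child
}

# Evaluate genomes through a surrogate in minimization sense:
# (duration, -yield, -ci). With only 44 feasible genomes, predictions are
# looked up from a precomputed grid table.
grid_objectives <- function(surrogate) {
  grid <- design_grid()
  pred <- stats::predict(surrogate, grid)
  list(
    grid = grid,
    physical = pred,
    # lookup[spacing_index + 1, code] -> row in grid
    index = matrix(seq_len(nrow(grid)), nrow = 11, ncol = 4),
    minimized = cbind(duration = pred$duration, neg_yield = -pred$yield,
                      neg_ci = -pred$ci)
  )
}

genome_rows <- function(g, gtab) {
  gtab$index[cbind(g[, 1] + 1L, g[, 2])]
}

front_from_rows <- function(rows, gtab, provenance) {
  rows <- sort(unique(rows))
  obj <- gtab$minimized[rows, , drop = FALSE]
  keep <- !vapply(seq_along(rows), function(i) {
    any(vapply(seq_along(rows), function(j) {
      j != i && dominates(obj[j, ], obj[i, ])
    }, logical(1)))
  }, logical(1))
  rows <- rows[keep]
  sol <- gtab$physical[rows, , drop = FALSE]
  sol$pruning <- pruning_label(sol$pruning_code)
  sol <- sol[order(sol$duration, -sol$yield, -sol$ci), ]
  rownames(sol) <- NULL
  structure(list(solutions = sol, provenance = provenance),
            class = "pareto_front")
}

#' @export
print.pareto_front <- function(x, digits = 3, ...) {
  cat("Pareto front:", nrow(x$solutions), "non-dominated design(s)\n")
  print(x$solutions[, c("spacing", "pruning", "duration", "yield", "ci")],
        row.names = FALSE, digits = digits)
  invisible(x)
}

#' Evolve the design population with elitist NSGA-II
#'
#' Minimizes (growth duration, -yield, -Ci) predicted by the surrogate
#' over the 44-point feasible grid. Each generation forms a mu+lambda pool
#' of parents and offspring and truncates it by (front rank, crowding
#' distance). Returns the deduplicated first front in physical units.
#'
#' With the default population of 100 the initial population is seeded
#' with one copy of each of the 44 feasible designs (plus random fill);
#' since elitist truncation never discards a first-front member when the
#' front fits in the population, the returned front then provably equals
#' the exhaustive non-dominated set. Populations smaller than the grid
#' start fully random and rely on the genetic search.
#'
#' @param surrogate a trained `melon_surrogate`.
#' @param params a [ga_params()].
#' @return a `pareto_front`: `solutions` data.frame (spacing, pruning,
#'   duration, yield, ci; pairwise non-dominated, genotypically
#'   deduplicated) plus provenance (params and seed).
#' @export
evolve <- function(surrogate, params = ga_params()) {
  stopifnot(inherits(surrogate, "melon_surrogate"),
            inherits(params, "ga_params"))
  gtab <- grid_objectives(surrogate)
  with_seed(params$seed, {
    pop <- init_genomes(params$population_size)
    obj <- gtab$minimized[genome_rows(pop, gtab), , drop = FALSE]
    fs <- fast_nondominated_sort(obj)
    crowd <- numeric(nrow(pop))
    for (f in fs$fronts) crowd[f] <- crowding_distance(obj[f, , drop = FALSE])
    for (gen in seq_len(params$generations)) {
      off <- make_offspring(pop, fs$rank, crowd, params)
      pool <- rbind(pop, off)
      pobj <- gtab$minimized[genome_rows(pool, gtab), , drop = FALSE]
      pfs <- fast_nondominated_sort(pobj)
      pcrowd <- numeric(nrow(pool))
      keep <- integer(0)
      for (f in pfs$fronts) {
        pcrowd[f] <- crowding_distance(pobj[f, , drop = FALSE])
        if (length(keep) + length(f) <= params$population_size) {
          keep <- c(keep, f)
        } else {
          room <- params$population_size - length(keep)
          if (room > 0) {
            keep <- c(keep, f[order(pcrowd[f], decreasing = TRUE)[seq_len(room)]])
          }
          break
        }
      }
      pop <- pool[keep, , drop = FALSE]
      obj <- pobj[keep, , drop = FALSE]
      fs <- fast_nondominated_sort(obj)
      crowd <- pcrowd[keep]
    }
    front_from_rows(genome_rows(pop[fs$fronts[[1]], , drop = FALSE], gtab),
                    gtab,
                    provenance = list(method = "nsga2", params = params,
                                      seed = params$seed))
  })
}

#' Exhaustive Pareto front over the feasible grid
#'
#' Evaluates the surrogate on every feasible design (11 spacings x 4
#' pruning codes = 44) and returns the exact non-dominated set by pairwise
#' comparison — the oracle against which [evolve()] is checked.
#'
#' @param surrogate a trained `melon_surrogate`.
#' @return a `pareto_front`.
#' @export
brute_force_pareto <- function(surrogate) {
  gtab <- grid_objectives(surrogate)
  front_from_rows(seq_len(nrow(gtab$grid)), gtab,
                  provenance = list(method = "exhaustive"))
}
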