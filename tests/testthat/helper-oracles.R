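# Independent straight-from-formula oracles, written as naive loops with no
# shared code with the package internals.

# Entropy-weight TOPSIS: plain double loops over the printed formulas.
naive_topsis <- function(X, separation_scale = c("rms", "unit")) {
  separation_scale <- match.arg(separation_scale)
  a <- nrow(X); b <- ncol(X)
  Y <- matrix(0, a, b)
  for (j in 1:b) {
    ss <- 0
    for (i in 1:a) ss <- ss + X[i, j]^2
    for (i in 1:a) Y[i, j] <- X[i, j] / sqrt(ss)
  }
  P <- matrix(0, a, b)
  for (j in 1:b) {
    cs <- 0
    for (i in 1:a) cs <- cs + Y[i, j]
    for (i in 1:a) P[i, j] <- Y[i, j] / cs
  }
  H <- numeric(b)
  for (j in 1:b) {
    s <- 0
    for (i in 1:a) if (P[i, j] > 0) s <- s + P[i, j] * log(P[i, j])
    H[j] <- -s / log(a)
  }
  w <- numeric(b)
  denom <- b - sum(H)
  for (j in 1:b) w[j] <- (1 - H[j]) / denom
  Z <- matrix(0, a, b)
  for (j in 1:b) for (i in 1:a) Z[i, j] <- w[j] * Y[i, j]
  zp <- apply(Z, 2, max); zm <- apply(Z, 2, min)
  dp <- dm <- numeric(a)
  for (i in 1:a) {
    sp <- sm <- 0
    for (j in 1:b) {
      sp <- sp + (zp[j] - Z[i, j])^2
      sm <- sm + (zm[j] - Z[i, j])^2
    }
    dp[i] <- sqrt(sp); dm[i] <- sqrt(sm)
  }
  if (separation_scale == "rms") {
    dp <- dp * sqrt(a); dm <- dm * sqrt(a)
  }
  ci <- dm / (dp + dm)
  list(weights = w, entropies = H, d_plus = dp, d_minus = dm, ci = ci)
}

# Non-dominated sorting by repeated O(n^2 m) scans.
naive_fronts <- function(obj) {
  n <- nrow(obj)
  dominated_by <- function(i, alive) {
    for (j in alive) {
      if (j != i && all(obj[j, ] <= obj[i, ]) && any(obj[j, ] < obj[i, ])) {
        return(TRUE)
      }
    }
    FALSE
  }
  alive <- seq_len(n)
  fronts <- list()
  while (length(alive)) {
    fr <- alive[!vapply(alive, dominated_by, logical(1), alive = alive)]
    fronts[[length(fronts) + 1]] <- fr
    alive <- setdiff(alive, fr)
  }
  fronts
}

# Crowding distance straight from its definition.
naive_crowding <- function(obj) {
  n <- nrow(obj)
  if (n <= 2) return(rep(Inf, n))
  d <- numeric(n)
  for (k in seq_len(ncol(obj))) {
    o <- order(obj[, k])
    d[o[1]] <- Inf
    d[o[n]] <- Inf
    rng <- obj[o[n], k] - obj[o[1], k]
    if (rng > 0) {
      for (p in 2:(n - 1)) {
        d[o[p]] <- d[o[p]] + (obj[o[p + 1], k] - obj[o[p - 1], k]) / rng
      }
    }
  }
  d
}

# Exhaustive weighted-sum scoring of a front data.frame.
naive_select <- function(sol, weights = c(1, 1, 1)) {
  nrm <- function(v, hb) {
    r <- max(v) - min(v)
    if (r == 0) return(rep(1, length(v)))
    if (hb) (v - min(v)) / r else (max(v) - v) / r
  }
  sc <- weights[1] * nrm(sol$duration, FALSE) +
    weights[2] * nrm(sol$yield, TRUE) + weights[3] * nrm(sol$ci, TRUE)
  best <- which(abs(sc - max(sc)) < 1e-12)
  if (length(best) > 1) {
    best <- best[order(sol$duration[best], -sol$yield[best], -sol$ci[best])]
  }
  sol[best[1], ]
}

# A valid surrogate object with arbitrary weights, for optimizer tests that
# need "some trained model" without the training cost.
random_weight_surrogate <- function(seed, yscale_rng = c(25, 40, 0.9)) {
  layout <- melonopt:::mlp_layout(c(2, 12, 8, 3))
  theta <- melonopt:::with_seed(seed, stats::runif(layout$count, -1, 1))
  structure(list(
    theta = theta, layout = layout, encoding = "ordinal",
    yscale = list(lo = c(95, 20, 0.05), hi = c(95, 20, 0.05) + yscale_rng,
                  rng = yscale_rng),
    outputs = c("duration", "yield", "ci"), config = NULL,
    meta = list(seed = seed, restart = 1, epochs = 0, train_mse = NA,
                val_mse = NA, stop_reason = "none")
  ), class = "melon_surrogate")
}
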